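#' Minimal DICOM CT series I/O
#'
#' Reads and writes axial CT slice files in Explicit VR Little Endian with
#' only the tags needed for geometry and HU rescaling (image position and
#' orientation, pixel spacing, rows/columns, rescale slope/intercept, series
#' identity, and kVp/exposure as informational pass-through).  This is not a
#' conformant DICOM implementation: compressed transfer syntaxes, sequences
#' with undefined length, and non-axial orientations are rejected.
#'
#' Stored pixel values are 16-bit unsigned; HU = slope * stored + intercept
#' is always applied on read, so analysis code never sees stored values.
#'
#' @name series_io
NULL

.uid_root <- "1.2.826.0.1.3680043.10.1437"
.ts_explicit_le <- "1.2.840.10008.1.2.1"
.sop_ct <- "1.2.840.10008.5.1.4.1.1.2"

.new_uid <- function(suffix) paste0(.uid_root, ".", suffix)

# ---- writer -----------------------------------------------------------------

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# one explicit-VR data element as a raw vector
.dcm_element <- function(group, elem, vr, payload) {
  if (is.character(payload)) {
    payload <- charToRaw(payload)
    if (length(payload) %% 2 == 1)
      payload <- c(payload, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  head <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0, 0)), .u32(length(payload)), payload)
  else
    c(head, .u16(length(payload)), payload)
}

.ds <- function(x) paste(format(x, trim = TRUE, digits = 10), collapse = "\\")

#' Write a volume as a DICOM CT series
#'
#' One file per axial slice (\code{slice_###.dcm}), Explicit VR Little
#' Endian, rescale slope 1 and intercept -1024.
#'
#' @param vol a \code{volume_grid}.
#' @param dir output directory (created if missing).
#' @param kvp,exposure_mas optional acquisition annotations written to the
#'   corresponding tags.
#' @return The directory, invisibly.
#' @export
write_ct_series <- function(vol, dir, kvp = NULL, exposure_mas = NULL) {
  stopifnot(inherits(vol, "volume_grid"))
  if (length(vol$data) == 0) stop("empty volume")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$data)
  series_uid <- .new_uid(paste0("2.", format(round(stats::runif(1) * 1e8))))
  study_uid <- .new_uid("1.1")
  zs <- vol_axes(vol)$z
  intercept <- -1024; slope <- 1
  for (k in seq_len(d[3])) {
    sop_uid <- .new_uid(paste0("3.", k))
    stored <- round((as.vector(vol$data[, , k]) - intercept) / slope)
    stored <- pmin(pmax(stored, 0), 65535)
    meta_el <- c(
      .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm_element(0x0002, 0x0002, "UI", .sop_ct),
      .dcm_element(0x0002, 0x0003, "UI", sop_uid),
      .dcm_element(0x0002, 0x0010, "UI", .ts_explicit_le),
      .dcm_element(0x0002, 0x0012, "UI", .uid_root)
    )
    body <- c(
      .dcm_element(0x0008, 0x0016, "UI", .sop_ct),
      .dcm_element(0x0008, 0x0018, "UI", sop_uid),
      .dcm_element(0x0008, 0x0060, "CS", "CT"),
      .dcm_element(0x0018, 0x0050, "DS", .ds(vol$spacing[3])),
      if (!is.null(kvp)) .dcm_element(0x0018, 0x0060, "DS", .ds(kvp)),
      if (!is.null(exposure_mas))
        .dcm_element(0x0018, 0x1152, "IS", format(round(exposure_mas))),
      .dcm_element(0x0020, 0x000D, "UI", study_uid),
      .dcm_element(0x0020, 0x000E, "UI", series_uid),
      .dcm_element(0x0020, 0x0013, "IS", format(k)),
      .dcm_element(0x0020, 0x0032, "DS",
                   .ds(c(vol$origin[1], vol$origin[2], zs[k]))),
      .dcm_element(0x0020, 0x0037, "DS", .ds(c(1, 0, 0, 0, 1, 0))),
      .dcm_element(0x0028, 0x0002, "US", .u16(1)),
      .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_element(0x0028, 0x0010, "US", .u16(d[2])),   # rows    = y
      .dcm_element(0x0028, 0x0011, "US", .u16(d[1])),   # columns = x
      .dcm_element(0x0028, 0x0030, "DS",
                   .ds(c(vol$spacing[2], vol$spacing[1]))),
      .dcm_element(0x0028, 0x0100, "US", .u16(16)),
      .dcm_element(0x0028, 0x0101, "US", .u16(16)),
      .dcm_element(0x0028, 0x0102, "US", .u16(15)),
      .dcm_element(0x0028, 0x0103, "US", .u16(0)),
      .dcm_element(0x0028, 0x1052, "DS", .ds(intercept)),
      .dcm_element(0x0028, 0x1053, "DS", .ds(slope)),
      .dcm_element(0x7FE0, 0x0010, "OW",
                   writeBin(as.integer(stored), raw(), size = 2,
                            endian = "little"))
    )
    meta_len <- .dcm_element(0x0002, 0x0000, "UL", .u32(length(meta_el)))
    con <- file(file.path(dir, sprintf("slice_%03d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta_len, meta_el, body), con)
    close(con)
  }
  invisible(dir)
}

# ---- reader -----------------------------------------------------------------

.rd_u16 <- function(r, at) sum(as.integer(r[at + 0:1]) * c(1, 256))
.rd_u32 <- function(r, at) sum(as.integer(r[at + 0:3]) * 256^(0:3))

# parse one explicit-VR-LE DICOM file, returning the tags we care about
.parse_dicom <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  pos <- 133
  ts <- NULL
  while (pos + 7 <= length(r)) {
    grp <- .rd_u16(r, pos); el <- .rd_u16(r, pos + 2)
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- .rd_u32(r, pos + 8); hdr <- 12
    } else {
      len <- .rd_u16(r, pos + 6); hdr <- 8
    }
    if (len == 0xFFFFFFFF) stop("undefined-length element not supported")
    val_at <- pos + hdr
    key <- sprintf("%04X,%04X", grp, el)
    want <- c("0002,0010", "0008,0018", "0020,000D", "0020,000E",
              "0020,0013", "0020,0032", "0020,0037", "0028,0010",
              "0028,0011", "0028,0030", "0028,1052", "0028,1053",
              "0018,0050", "0018,0060", "0018,1152", "7FE0,0010")
    binary_keys <- c("7FE0,0010", "0028,0010", "0028,0011")
    if (key %in% want) {
      payload <- if (len > 0) r[val_at:(val_at + len - 1)] else raw(0)
      tags[[key]] <- if (key %in% binary_keys) payload
                     else trimws(rawToChar(payload[payload != as.raw(0)]))
    }
    if (key == "0002,0010") ts <- tags[[key]]
    pos <- val_at + len
  }
  if (is.null(ts) || ts != .ts_explicit_le)
    stop("unsupported transfer syntax (only Explicit VR Little Endian): ",
         path)
  tags
}

.ds_num <- function(s) as.numeric(strsplit(s, "\\\\")[[1]])

#' Read a DICOM CT series as a volume
#'
#' Reads all \code{.dcm} files in a directory, checks they form one series
#' with uniform slice spacing, sorts slices by position, and maps stored
#' values to HU via \code{slope * v + intercept}.
#'
#' @param path directory holding the slice files of exactly one series.
#' @param spacing_tol relative tolerance on slice-spacing uniformity.
#' @return A list with elements \code{volume} (a \code{volume_grid}) and
#'   \code{meta} (spacing, slice positions, rescale, kVp/exposure if present,
#'   source path).
#' @export
read_ct_series <- function(path, spacing_tol = 1e-3) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no DICOM files found in ", path)
  parsed <- lapply(files, .parse_dicom)
  series <- vapply(parsed, function(t) t[["0020,000E"]] %||% "", "")
  if (length(unique(series)) != 1)
    stop("mixed series identifiers: ", paste(unique(series), collapse = ", "))
  for (t in parsed)
    if (is.null(t[["0028,1052"]]) || is.null(t[["0028,1053"]]))
      stop("missing rescale slope/intercept tags")
  ipp <- t(vapply(parsed, function(t) .ds_num(t[["0020,0032"]]), numeric(3)))
  o <- order(ipp[, 3])
  parsed <- parsed[o]; ipp <- ipp[o, , drop = FALSE]
  nz <- length(parsed)
  if (nz > 1) {
    dz <- diff(ipp[, 3])
    if (any(dz <= 0)) stop("duplicate slice positions")
    if ((max(dz) - min(dz)) > spacing_tol * mean(dz))
      stop("non-uniform slice spacing beyond tolerance")
    dzm <- mean(dz)
  } else dzm <- as.numeric(parsed[[1]][["0018,0050"]] %||% "1")
  t1 <- parsed[[1]]
  rows <- .rd_u16(t1[["0028,0010"]], 1)
  cols <- .rd_u16(t1[["0028,0011"]], 1)
  ps <- .ds_num(t1[["0028,0030"]])           # (row spacing = dy, col = dx)
  arr <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    tk <- parsed[[k]]
    slope <- as.numeric(tk[["0028,1053"]])
    intercept <- as.numeric(tk[["0028,1052"]])
    px <- tk[["7FE0,0010"]]
    stored <- readBin(px, "integer", n = rows * cols, size = 2,
                      signed = FALSE, endian = "little")
    arr[, , k] <- slope * stored + intercept
  }
  meta <- list(
    spacing = c(ps[2], ps[1], dzm),
    slice_positions = ipp[, 3],
    rescale = c(slope = as.numeric(t1[["0028,1053"]]),
                intercept = as.numeric(t1[["0028,1052"]])),
    kvp = if (!is.null(t1[["0018,0060"]])) as.numeric(t1[["0018,0060"]]),
    exposure_mas = if (!is.null(t1[["0018,1152"]]))
      as.numeric(t1[["0018,1152"]]),
    source = path
  )
  vol <- volume_grid(arr, meta$spacing,
                     c(ipp[1, 1], ipp[1, 2], ipp[1, 3]), meta = meta)
  list(volume = vol, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
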