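#' CT volume container
#'
#' A \code{volume_grid} holds a 3D array of Hounsfield units plus the physical
#' geometry needed to interpret it: voxel spacing (mm per axis) and the
#' physical position of the first voxel centre.  Axial slices are stacked
#' along the third axis.  Conventions, used everywhere in the package:
#' voxel indexing is 1-based in R but coordinates are voxel-centre based, so
#' the centre of voxel \code{(i, j, k)} is
#' \code{origin + (c(i, j, k) - 1) * spacing} mm.  HU values are clipped to
#' the representable CT range [-1024, 3071] on construction.
#'
#' @param data 3D numeric array of HU, dimensions (x, y, z).
#' @param spacing length-3 positive numeric, mm per voxel along (x, y, z).
#' @param origin length-3 numeric, mm position of the centre of voxel (1,1,1).
#' @param meta optional named list of annotations (kVp, exposure, warnings...).
#' @return An object of class \code{volume_grid}.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0), meta = list()) {
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (length(spacing) != 3 || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (length(origin) != 3) stop("origin must have length 3")
  data[data < -1024] <- -1024
  data[data > 3071] <- 3071
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), meta = meta),
            class = "volume_grid")
}

#' Physical axis coordinates of a volume
#'
#' @param vol a \code{volume_grid}.
#' @return List of numeric vectors \code{x}, \code{y}, \code{z}: the physical
#'   voxel-centre coordinate along each axis.
#' @export
vol_axes <- function(vol) {
  d <- dim(vol$data)
  list(
    x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
    y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
    z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "volume_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm, HU range [%g, %g]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$data), max(x$data)))
  invisible(x)
}

#' Bilinear in-plane sampling of one axial slice
#'
#' Samples HU at arbitrary in-plane physical points on slice \code{k} by
#' bilinear interpolation; points outside the slice return \code{fill}.
#' Shared by the geometric resampler in \code{\link{degrade}} and the
#' bar-pattern modulation measurement.
#'
#' @param vol a \code{volume_grid}.
#' @param k slice index.
#' @param px,py physical x/y coordinates (mm) of the sample points.
#' @param fill value for out-of-bounds points (default -1024, air).
#' @return Numeric vector of interpolated HU.
#' @export
sample_slice <- function(vol, k, px, py, fill = -1024) {
  d <- dim(vol$data)
  fx <- (px - vol$origin[1]) / vol$spacing[1] + 1
  fy <- (py - vol$origin[2]) / vol$spacing[2] + 1
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  ok <- i0 >= 1 & i0 <= d[1] - 1 & j0 >= 1 & j0 <= d[2] - 1
  out <- rep(fill, length(px))
  if (!any(ok)) return(out)
  sl <- vol$data[, , k]
  i0 <- i0[ok]; j0 <- j0[ok]; wxo <- wx[ok]; wyo <- wy[ok]
  v00 <- sl[cbind(i0, j0)];     v10 <- sl[cbind(i0 + 1, j0)]
  v01 <- sl[cbind(i0, j0 + 1)]; v11 <- sl[cbind(i0 + 1, j0 + 1)]
  out[ok] <- v00 * (1 - wxo) * (1 - wyo) + v10 * wxo * (1 - wyo) +
             v01 * (1 - wxo) * wyo       + v11 * wxo * wyo
  out
}

#' Write / read a volume in the internal on-disk format
#'
#' Array-on-disk with a JSON sidecar: \code{<path>} holds the voxel data as
#' little-endian float64 in column-major order and \code{<path>.json} holds
#' dimensions, spacing, origin and metadata.  The round trip is lossless.
#'
#' @param vol a \code{volume_grid}.
#' @param path file path for the binary array (sidecar gets ".json" appended).
#' @return \code{write_volume}: the path, invisibly. \code{read_volume}: the
#'   \code{volume_grid}.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  if (length(vol$data) == 0) stop("empty volume")
  hdr <- list(format = "acrct-volume", version = 1L, dim = dim(vol$data),
              spacing = vol$spacing, origin = vol$origin, meta = vol$meta)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side) || !file.exists(path))
    stop("volume files not found at ", path)
  hdr <- tryCatch(jsonlite::read_json(side, simplifyVector = TRUE),
                  error = function(e) stop("corrupt volume header: ",
                                           conditionMessage(e)))
  if (is.null(hdr$format) || hdr$format != "acrct-volume")
    stop("corrupt volume header: not an acrct volume")
  n <- prod(hdr$dim)
  if (n == 0) stop("empty volume")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(v) != n) stop("corrupt volume data: expected ", n, " voxels")
  meta <- hdr$meta
  if (length(meta) == 0) meta <- list()
  volume_grid(array(v, dim = hdr$dim), hdr$spacing, hdr$origin,
              meta = as.list(meta))
}
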