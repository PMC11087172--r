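#' ACR criteria configuration
#'
#' The classification bands used to grade the nine per-protocol criteria.
#' Defaults follow the ACR CT accreditation program:
#' \itemize{
#'   \item HU passing ranges (inclusive): water -7..7, acrylic 110..135,
#'     bone 850..970, air -1005..-970, polyethylene -107..-84 HU.  No minor
#'     band is configured by default, so any value outside the passing range
#'     is a major deviation ("failing"); per-material minor bands can be
#'     supplied via \code{hu_minor}.
#'   \item uniformity: pass strictly below 5 HU maximum peripheral-to-centre
#'     difference, minor deviation in [5, 7], major above 7.
#'   \item CNR minima per protocol class: 1.0 for adult head, adult body and
#'     pediatric head; 0.4 for pediatric body.
#'   \item spatial resolution minima: 6 lp/cm for head-type, 5 lp/cm for
#'     body-type protocols.
#'   \item image scaling: pass when the percent error is at most 1.0.
#' }
#' The protocol-class map assigns each named imaging protocol to one of
#' adult_head / adult_body / pediatric_head / pediatric_body; criteria are
#' selected by protocol class regardless of which phantom was scanned.
#'
#' @param hu_ranges named list of length-2 inclusive passing ranges.
#' @param hu_minor named list of length-2 minor-deviation ranges (outer
#'   bands); empty by default.
#' @param uniformity_pass_below,uniformity_minor_max uniformity band edges.
#' @param cnr_min named numeric, minimum CNR per protocol class.
#' @param resolution_min named numeric, minimum lp/cm for head/body types.
#' @param scaling_tol_pct maximum passing scaling error, percent.
#' @param protocol_classes named character, protocol name -> class.
#' @param baseline_tol_hu clinical baseline tolerance (default 50 HU).
#' @return An object of class \code{criteria_config}.
#' @export
acr_criteria <- function(
    hu_ranges = list(acrylic = c(110, 135), air = c(-1005, -970),
                     bone = c(850, 970), polyethylene = c(-107, -84),
                     water = c(-7, 7)),
    hu_minor = list(),
    uniformity_pass_below = 5, uniformity_minor_max = 7,
    cnr_min = c(adult_head = 1.0, adult_body = 1.0,
                pediatric_head = 1.0, pediatric_body = 0.4),
    resolution_min = c(head = 6, body = 5),
    scaling_tol_pct = 1.0,
    protocol_classes = c(
      "Head" = "adult_head", "H&N" = "adult_head",
      "Thorax" = "adult_body", "Thorax slow" = "adult_body",
      "Breast" = "adult_body", "Abdomen" = "adult_body",
      "Abdomen large" = "adult_body", "Pelvis" = "adult_body",
      "Pelvis large" = "adult_body",
      "Pediatric head" = "pediatric_head",
      "Pediatric abdomen" = "pediatric_body"),
    baseline_tol_hu = 50) {
  for (r in c(hu_ranges, hu_minor))
    if (length(r) != 2 || r[1] >= r[2]) stop("each range must satisfy lo < hi")
  for (m in names(hu_minor)) {
    if (!m %in% names(hu_ranges)) stop("minor band for unknown material ", m)
    if (hu_minor[[m]][1] > hu_ranges[[m]][1] ||
        hu_minor[[m]][2] < hu_ranges[[m]][2])
      stop("minor band must nest outside the passing band for ", m)
  }
  stopifnot(uniformity_pass_below <= uniformity_minor_max,
            scaling_tol_pct > 0, baseline_tol_hu > 0)
  structure(list(
    hu_ranges = hu_ranges, hu_minor = hu_minor,
    uniformity_pass_below = uniformity_pass_below,
    uniformity_minor_max = uniformity_minor_max,
    cnr_min = cnr_min, resolution_min = resolution_min,
    scaling_tol_pct = scaling_tol_pct,
    protocol_classes = protocol_classes,
    baseline_tol_hu = baseline_tol_hu
  ), class = "criteria_config")
}

#' Write / read a criteria configuration as YAML
#' @param config a \code{criteria_config}.
#' @param path file path.
#' @return \code{write_criteria}: the path, invisibly; \code{read_criteria}:
#'   the \code{criteria_config}.
#' @export
write_criteria <- function(config, path) {
  x <- unclass(config)
  for (f in c("cnr_min", "resolution_min", "protocol_classes"))
    x[[f]] <- as.list(x[[f]])           # yaml drops names of atomic vectors
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(acr_criteria, list(
    hu_ranges = lapply(x$hu_ranges, as.numeric),
    hu_minor = lapply(x$hu_minor, as.numeric),
    uniformity_pass_below = x$uniformity_pass_below,
    uniformity_minor_max = x$uniformity_minor_max,
    cnr_min = unlist(x$cnr_min), resolution_min = unlist(x$resolution_min),
    scaling_tol_pct = x$scaling_tol_pct,
    protocol_classes = unlist(x$protocol_classes),
    baseline_tol_hu = x$baseline_tol_hu))
}

.verdict <- function(level, value, criterion)
  structure(list(level = level, value = value, criterion = criterion),
            class = "acr_verdict")

#' Classify a uniformity measurement
#'
#' Pass below 5 HU, minor deviation in [5, 7] (inclusive at both edges, the
#' convention consistent with 4.98 passing and 5.10 being minor), major
#' above 7.
#'
#' @param max_abs_diff maximum absolute peripheral-to-centre difference, HU.
#' @param config a \code{criteria_config}.
#' @return An \code{acr_verdict}.
#' @export
classify_uniformity <- function(max_abs_diff, config = acr_criteria()) {
  if (!is.finite(max_abs_diff) || max_abs_diff < 0)
    stop("uniformity value must be a nonnegative number")
  level <- if (max_abs_diff < config$uniformity_pass_below) "pass"
           else if (max_abs_diff <= config$uniformity_minor_max) "minor"
           else "major"
  .verdict(level, max_abs_diff, "uniformity")
}

#' Classify a mean HU against a material's passing range
#'
#' Passing range bounds are inclusive.  With no minor band configured for
#' the material, any value outside the passing range is a major deviation.
#'
#' @param material material name (must exist in the config).
#' @param mean_hu measured mean HU.
#' @param config a \code{criteria_config}.
#' @return An \code{acr_verdict}.
#' @export
classify_hu <- function(material, mean_hu, config = acr_criteria()) {
  rng <- config$hu_ranges[[material]]
  if (is.null(rng)) stop("unknown material: ", material)
  level <- if (mean_hu >= rng[1] && mean_hu <= rng[2]) "pass"
  else {
    mb <- config$hu_minor[[material]]
    if (!is.null(mb) && mean_hu >= mb[1] && mean_hu <= mb[2]) "minor"
    else "major"
  }
  .verdict(level, mean_hu, paste0("hu_", material))
}

#' @rdname classify_hu
#' @param cnr measured contrast-to-noise ratio.
#' @param protocol_class one of the classes in \code{config$cnr_min}.
#' @export
classify_cnr <- function(cnr, protocol_class, config = acr_criteria()) {
  m <- unname(config$cnr_min[protocol_class])
  if (length(m) != 1 || is.na(m))
    stop("unknown protocol class: ", protocol_class)
  .verdict(if (cnr >= m) "pass" else "major", cnr, "contrast_resolution")
}

#' @rdname classify_hu
#' @param lp resolved spatial frequency, lp/cm.
#' @export
classify_resolution <- function(lp, protocol_class, config = acr_criteria()) {
  type <- if (grepl("head", protocol_class)) "head" else "body"
  m <- config$resolution_min[[type]]
  .verdict(if (lp >= m) "pass" else "major", lp, "spatial_resolution")
}

#' @rdname classify_hu
#' @param pct scaling percent error.
#' @export
classify_scaling <- function(pct, config = acr_criteria()) {
  if (!is.finite(pct) || pct < 0) stop("scaling error must be nonnegative")
  .verdict(if (pct <= config$scaling_tol_pct) "pass" else "major", pct,
           "image_scaling")
}

#' Distance beyond a passing range
#'
#' 0 for values inside the (inclusive) range, otherwise the distance to the
#' nearest violated bound.  Continuous and 1-Lipschitz in the value.
#'
#' @param value measured value.
#' @param range length-2 numeric, lo < hi.
#' @return Nonnegative distance, same units as the value.
#' @export
deviation_beyond_range <- function(value, range) {
  stopifnot(length(range) == 2, range[1] < range[2])
  ifelse(value < range[1], range[1] - value,
         ifelse(value > range[2], value - range[2], 0))
}

#' Summarize failures of one criterion across protocols
#'
#' Over the values falling outside the passing range only: the count, the
#' mean distance beyond the nearest violated bound, and its sample standard
#' deviation (NA when fewer than two values fail).
#'
#' @param values numeric vector of measured values (one per protocol).
#' @param range length-2 passing range.
#' @return A list with \code{n_failing}, \code{mean_deviation},
#'   \code{sd_deviation}.
#' @export
summarize_failures <- function(values, range) {
  d <- deviation_beyond_range(values, range)
  d <- d[d > 0]
  list(n_failing = length(d),
       mean_deviation = if (length(d)) mean(d) else NA_real_,
       sd_deviation = if (length(d) >= 2) stats::sd(d) else NA_real_)
}

.metric_cols <- c("contrast_resolution", "spatial_resolution", "acrylic",
                  "air", "bone", "polyethylene", "water", "scaling_pct",
                  "uniformity_hu")

#' Evaluate the nine ACR criteria for one protocol
#'
#' @param metrics named list / one-row data frame holding the nine measured
#'   values: \code{contrast_resolution}, \code{spatial_resolution},
#'   \code{acrylic}, \code{air}, \code{bone}, \code{polyethylene},
#'   \code{water}, \code{scaling_pct}, \code{uniformity_hu}.
#' @param protocol_class protocol class selecting the CNR and resolution
#'   minima (independent of which phantom was scanned).
#' @param config a \code{criteria_config}.
#' @return A \code{protocol_verdict}: the nine \code{acr_verdict}s plus
#'   \code{n_pass} (criteria met with no deviation) and \code{overall}
#'   (\code{"pass"} iff all nine pass).
#' @export
evaluate_protocol <- function(metrics, protocol_class,
                              config = acr_criteria()) {
  miss <- setdiff(.metric_cols, names(metrics))
  if (length(miss))
    stop("missing metric(s): ", paste(miss, collapse = ", "))
  v <- list(
    contrast_resolution = classify_cnr(metrics[["contrast_resolution"]],
                                       protocol_class, config),
    spatial_resolution = classify_resolution(
      metrics[["spatial_resolution"]], protocol_class, config),
    acrylic = classify_hu("acrylic", metrics[["acrylic"]], config),
    air = classify_hu("air", metrics[["air"]], config),
    bone = classify_hu("bone", metrics[["bone"]], config),
    polyethylene = classify_hu("polyethylene", metrics[["polyethylene"]],
                               config),
    water = classify_hu("water", metrics[["water"]], config),
    image_scaling = classify_scaling(metrics[["scaling_pct"]], config),
    uniformity = classify_uniformity(metrics[["uniformity_hu"]], config)
  )
  levels <- vapply(v, `[[`, "", "level")
  structure(list(verdicts = v, levels = levels,
                 n_pass = sum(levels == "pass"),
                 overall = if (all(levels == "pass")) "pass" else "fail",
                 protocol_class = protocol_class),
            class = "protocol_verdict")
}

#' Tally verdict levels for one criterion across protocols
#'
#' @param verdicts list of \code{protocol_verdict}s.
#' @param criterion criterion name (one of the nine).
#' @return Named integer vector \code{c(pass, minor, major)}.
#' @export
tally_verdicts <- function(verdicts, criterion) {
  lv <- vapply(verdicts, function(pv) pv$levels[[criterion]], "")
  c(pass = sum(lv == "pass"), minor = sum(lv == "minor"),
    major = sum(lv == "major"))
}

#' Build per-material HU baselines
#'
#' Clinical QA practice tracks CBCT HU against a per-material baseline with
#' a +/- 50 HU tolerance rather than fixed accreditation ranges.  The
#' baseline is the arithmetic mean of the supplied per-protocol values.
#'
#' @param hu_table data frame with one column per material (any subset of
#'   acrylic, air, bone, polyethylene, water), one row per protocol/scan.
#' @param tolerance_hu tolerance (default 50 HU).
#' @return A list of class \code{baseline_set} with \code{baseline} (named
#'   means) and \code{tolerance_hu}.
#' @export
build_baseline <- function(hu_table, tolerance_hu = 50) {
  stopifnot(nrow(hu_table) >= 1, tolerance_hu > 0)
  mats <- intersect(c("acrylic", "air", "bone", "polyethylene", "water"),
                    names(hu_table))
  if (!length(mats)) stop("no material columns found")
  structure(list(baseline = vapply(hu_table[mats], mean, numeric(1)),
                 tolerance_hu = tolerance_hu),
            class = "baseline_set")
}

#' @rdname build_baseline
#' @param value measured HU.
#' @param material material name present in the baseline.
#' @param baseline a \code{baseline_set}.
#' @return \code{check_against_baseline}: logical, TRUE iff
#'   |value - baseline| <= tolerance.
#' @export
check_against_baseline <- function(value, material, baseline) {
  b <- unname(baseline$baseline[material])
  if (length(b) != 1 || is.na(b)) stop("no baseline for material ", material)
  abs(value - b) <= baseline$tolerance_hu
}

#' CT-number stability across exposure settings
#'
#' For each (protocol, material) the range (max - min) of the mean HU across
#' exposure settings; returns the maximum range and where it occurs, plus
#' the full per-cell table.
#'
#' @param exposure_table data frame with columns \code{protocol} and the five
#'   material columns, one row per exposure setting.
#' @return A list with \code{max_range_hu}, \code{at} (protocol, material)
#'   and \code{ranges} (long data frame).
#' @export
exposure_stability <- function(exposure_table) {
  mats <- intersect(c("acrylic", "air", "bone", "polyethylene", "water"),
                    names(exposure_table))
  if (!length(mats)) stop("no material columns found")
  out <- do.call(rbind, lapply(split(exposure_table, exposure_table$protocol),
    function(g) {
      if (nrow(g) < 2)
        stop("protocol ", g$protocol[1], " has fewer than 2 exposures")
      data.frame(protocol = g$protocol[1], material = mats,
                 range_hu = vapply(mats, function(m) diff(range(g[[m]])),
                                   numeric(1)),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  i <- which.max(out$range_hu)
  list(max_range_hu = out$range_hu[i],
       at = c(protocol = out$protocol[i], material = out$material[i]),
       ranges = out)
}
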