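#' Analyze a scanned volume end to end
#'
#' The full measurement pipeline on one volume: estimate the phantom pose,
#' map the nominal ROI layouts of all four modules into image coordinates,
#' and compute the nine scorecard metrics (CNR, resolvable lp/cm, five
#' material mean HU, scaling percent error, uniformity max difference).
#'
#' @param vol a \code{volume_grid}.
#' @param spec the \code{phantom_spec} scanned.
#' @param resolution_threshold modulation threshold for the resolvable
#'   frequency (default 0.25).
#' @param nslices slices pooled per ROI (default 3).
#' @return A list with \code{metrics} (one-row data frame in scorecard column
#'   order), \code{transform} (the estimated pose), and \code{details}
#'   (per-metric intermediate results and mapped ROIs).
#' @export
analyze_scan <- function(vol, spec = default_head_phantom(),
                         resolution_threshold = 0.25, nslices = 3) {
  tf <- estimate_phantom_transform(vol, spec)
  centred <- function(layout) { layout$z <- layout$z - spec$length / 2; layout }
  lay <- lapply(1:4, function(i)
    map_rois(centred(nominal_roi_layout(spec, i)), tf, vol))

  hu <- measure_hu_accuracy(vol, lay[[1]], nslices)
  cnr <- compute_cnr(roi_stats(vol, lay[[2]][lay[[2]]$name == "A", ], nslices),
                     roi_stats(vol, lay[[2]][lay[[2]]$name == "B", ], nslices))
  unif <- measure_uniformity(vol, lay[[3]], nslices)
  scal <- measure_scaling(vol)
  contrast <- spec$materials[[spec$modules[[4]]$patterns$bar_material[1]]] -
              spec$materials[[spec$body_material]]
  res <- measure_resolution(vol, lay[[4]], resolution_threshold,
                            nominal_contrast = contrast, nslices = nslices)

  metrics <- data.frame(
    contrast_resolution = cnr$cnr,
    spatial_resolution = res$resolvable_lp,
    acrylic = hu[["acrylic"]], air = hu[["air"]], bone = hu[["bone"]],
    polyethylene = hu[["polyethylene"]], water = hu[["water"]],
    scaling_pct = scal$percent_error,
    uniformity_hu = unif$max_abs_diff
  )
  list(metrics = metrics, transform = tf,
       details = list(hu = hu, cnr = cnr, uniformity = unif,
                      scaling = scal, resolution = res, rois = lay))
}

#' Score a metric table against the ACR criteria
#'
#' Applies \code{\link{evaluate_protocol}} to every row of a measured-metric
#' table (the scorecard layout: protocol plus the nine metric columns) and
#' appends the per-criterion verdict levels, the no-deviation count and the
#' overall outcome.
#'
#' @param tab data frame with a \code{protocol} column and the nine metric
#'   columns; extra columns (machine, phantom, dose) are carried through.
#' @param config a \code{criteria_config}; protocols are classed via its
#'   protocol-class map.
#' @return \code{tab} with columns \code{v_<criterion>} (levels),
#'   \code{n_pass} and \code{overall} appended, plus the list of
#'   \code{protocol_verdict}s as attribute \code{"verdicts"}.
#' @export
score_metric_table <- function(tab, config = acr_criteria()) {
  cls <- config$protocol_classes[tab$protocol]
  if (any(is.na(cls)))
    stop("protocol(s) not in the protocol-class map: ",
         paste(unique(tab$protocol[is.na(cls)]), collapse = ", "))
  pvs <- lapply(seq_len(nrow(tab)), function(i)
    evaluate_protocol(tab[i, ], cls[[i]], config))
  lv <- t(vapply(pvs, `[[`, character(9), "levels"))
  colnames(lv) <- paste0("v_", colnames(lv))
  out <- cbind(tab, as.data.frame(lv, stringsAsFactors = FALSE),
               n_pass = vapply(pvs, `[[`, integer(1), "n_pass"),
               overall = vapply(pvs, `[[`, character(1), "overall"))
  attr(out, "verdicts") <- pvs
  out
}

#' Compare scorecards across machines or sessions
#'
#' Given two or more scored metric tables covering the same protocols (e.g.
#' one per machine, or an original and a repeat session), reports the
#' per-protocol no-deviation counts side by side, the per-material HU
#' differences of every input against the first (the reference), and
#' baseline checks of each input's HU values against baselines built from
#' the reference.
#'
#' @param scorecards named list of scored tables from
#'   \code{\link{score_metric_table}}; names identify the machines/sessions.
#' @param config a \code{criteria_config} (for the baseline tolerance).
#' @return A list with \code{counts} (protocol x machine no-deviation
#'   counts), \code{hu_differences} (long data frame of absolute differences
#'   vs the reference) and \code{baseline_ok} (logical flags).
#' @export
compare_scorecards <- function(scorecards, config = acr_criteria()) {
  stopifnot(length(scorecards) >= 2, !is.null(names(scorecards)))
  protos <- lapply(scorecards, function(s) sort(s$protocol))
  for (i in 2:length(protos))
    if (!identical(protos[[1]], protos[[i]]))
      stop("mismatched protocol sets between scorecards")
  ref <- scorecards[[1]]
  mats <- c("acrylic", "air", "bone", "polyethylene", "water")
  counts <- data.frame(protocol = ref$protocol, stringsAsFactors = FALSE)
  for (nm in names(scorecards)) {
    s <- scorecards[[nm]]
    counts[[nm]] <- s$n_pass[match(counts$protocol, s$protocol)]
  }
  base <- build_baseline(ref[mats], config$baseline_tol_hu)
  diffs <- list(); flags <- list()
  for (nm in names(scorecards)[-1]) {
    s <- scorecards[[nm]]
    s <- s[match(ref$protocol, s$protocol), ]
    for (m in mats) {
      diffs[[length(diffs) + 1]] <- data.frame(
        machine = nm, protocol = ref$protocol, material = m,
        abs_difference_hu = abs(s[[m]] - ref[[m]]),
        stringsAsFactors = FALSE)
    }
  }
  for (nm in names(scorecards)) {
    s <- scorecards[[nm]]
    for (m in mats) {
      flags[[length(flags) + 1]] <- data.frame(
        machine = nm, protocol = s$protocol, material = m,
        within_baseline = vapply(s[[m]], check_against_baseline,
                                 logical(1), material = m, baseline = base),
        stringsAsFactors = FALSE)
    }
  }
  list(counts = counts,
       hu_differences = do.call(rbind, diffs),
       baseline = base,
       baseline_ok = do.call(rbind, flags))
}

#' Bundled measured-metric tables
#'
#' The published scorecard tables shipped with the package as plain CSV:
#' \code{"table2_head"} and \code{"table2_body"} (all 11 vendor protocols on
#' the head and body phantoms), \code{"table3_exposure"} (pediatric
#' protocols at four exposure settings) and \code{"table4_machines"} (the
#' four-machine comparison; rows the source did not measure are absent).
#'
#' @param name table name.
#' @return A data frame.
#' @export
acr_table <- function(name = c("table2_head", "table2_body",
                               "table3_exposure", "table4_machines")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "acrct")
  if (path == "") stop("bundled table not found: ", name)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Round a scorecard for display
#'
#' HU, lp/cm and percent values to one decimal, matching the published table
#' layout; machine-readable outputs keep full precision.
#'
#' @param tab a (scored) metric table.
#' @return The table with numeric metric columns rounded.
#' @export
format_scorecard <- function(tab) {
  for (cc in intersect(.metric_cols, names(tab)))
    tab[[cc]] <- round(tab[[cc]], 1)
  tab
}
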