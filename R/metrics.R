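#' ROI statistics
#'
#' Mean, sample standard deviation and voxel count over all voxels whose
#' centres fall inside a circular ROI, averaged over \code{nslices} slices
#' centred on the ROI's z position (single representative slices are noisy;
#' the default of 3 is the package's documented convention).
#'
#' @param vol a \code{volume_grid}.
#' @param roi one-row data frame or list with \code{x, y, z} (mm, physical)
#'   and \code{diameter} (mm).
#' @param nslices odd number of slices to pool (default 3, truncated at the
#'   volume edges).
#' @return A list with \code{mean}, \code{sd} (sample, \code{NA} for a single
#'   voxel), \code{n}.
#' @export
roi_stats <- function(vol, roi, nslices = 3) {
  ax <- vol_axes(vol)
  k0 <- which.min(abs(ax$z - roi$z))
  hw <- (nslices - 1) %/% 2
  ks <- max(1, k0 - hw):min(dim(vol$data)[3], k0 + hw)
  r <- roi$diameter / 2
  ii <- which(abs(ax$x - roi$x) <= r)
  jj <- which(abs(ax$y - roi$y) <= r)
  if (!length(ii) || !length(jj)) stop("no voxels inside ROI ", roi$name %||% "")
  inside <- outer(ax$x[ii] - roi$x, ax$y[jj] - roi$y,
                  function(a, b) a^2 + b^2) <= r^2
  if (!any(inside)) stop("no voxels inside ROI ", roi$name %||% "")
  v <- as.numeric(apply(vol$data[ii, jj, ks, drop = FALSE], 3,
                        function(sl) sl[inside]))
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Contrast-to-noise ratio
#'
#' CNR = (mean A - mean B) / SD of B, the ACR low-contrast figure of merit.
#' The sign of (A - B) is preserved.
#'
#' @param stats_a,stats_b ROI statistics as returned by \code{\link{roi_stats}}
#'   for the contrast ROI (A) and the background ROI (B).
#' @return A list with \code{stats_a}, \code{stats_b} and \code{cnr}.
#' @export
compute_cnr <- function(stats_a, stats_b) {
  if (!is.finite(stats_b$sd) || stats_b$sd <= 0)
    stop("CNR undefined: background ROI standard deviation is zero")
  list(stats_a = stats_a, stats_b = stats_b,
       cnr = (stats_a$mean - stats_b$mean) / stats_b$sd)
}

#' HU uniformity
#'
#' Signed differences between each of the four peripheral ROI means and the
#' central ROI mean on the uniform slab, and their maximum absolute value
#' (the ACR uniformity statistic).
#'
#' @param vol a \code{volume_grid}.
#' @param rois five equal-area ROIs; the one named \code{"center"} (or the
#'   first row) is the central ROI.
#' @param nslices slices to pool per ROI.
#' @return A list with \code{center_mean}, \code{peripheral_means},
#'   \code{diffs} (signed, peripheral - center) and \code{max_abs_diff}.
#' @export
measure_uniformity <- function(vol, rois, nslices = 3) {
  if (nrow(rois) != 5) stop("uniformity needs exactly 5 ROIs, got ", nrow(rois))
  if (length(unique(round(rois$diameter, 6))) != 1)
    stop("uniformity ROIs must have equal areas")
  ic <- if ("center" %in% rois$name) which(rois$name == "center") else 1L
  st <- lapply(seq_len(5), function(i) roi_stats(vol, rois[i, ], nslices))
  cm <- st[[ic]]$mean
  pm <- vapply(st[-ic], `[[`, numeric(1), "mean")
  names(pm) <- rois$name[-ic]
  diffs <- pm - cm
  list(center_mean = cm, peripheral_means = pm, diffs = diffs,
       max_abs_diff = max(abs(diffs)))
}

#' Image scaling from the ball-bearing pair
#'
#' Measures the sub-voxel centroid separation of the two metal markers and
#' reports the percent error against the nominal 100 mm spacing.
#'
#' @param vol a \code{volume_grid}.
#' @param nominal_mm nominal separation (default 100).
#' @param threshold metal detection threshold, HU.
#' @return A list with \code{measured_mm}, \code{nominal_mm},
#'   \code{percent_error}.
#' @export
measure_scaling <- function(vol, nominal_mm = 100, threshold = 1500) {
  bb <- find_ball_bearings(vol, threshold)
  measured <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  list(measured_mm = measured, nominal_mm = nominal_mm,
       percent_error = 100 * abs(measured - nominal_mm) / nominal_mm)
}

#' Bar-pattern spatial resolution
#'
#' For each bar pattern the modulation is (mean HU over strips at the bar
#' centres - mean over strips at the gap centres) / nominal bar-gap
#' contrast, clipped to [0, 1]; strips are sampled by bilinear interpolation
#' in the pattern's own (possibly rotated) frame.  The resolvable frequency
#' is the highest one whose modulation reaches \code{threshold} with every
#' lower frequency also reaching it, mirroring how a human reader scores the
#' "last fully visible" pattern; 0 when even the coarsest pattern fails.
#'
#' @param vol a \code{volume_grid}.
#' @param patterns mapped resolution-module layout (columns \code{x, y, z,
#'   frequency, width, height, orientation}).
#' @param threshold modulation threshold (default 0.25; the automated stand-in
#'   for by-eye visibility scoring).
#' @param nominal_contrast bar-gap HU contrast of the rendered patterns.
#' @param nslices slices to pool.
#' @return A list with \code{modulation} (named per frequency) and
#'   \code{resolvable_lp}.
#' @export
measure_resolution <- function(vol, patterns, threshold = 0.25,
                               nominal_contrast = 955, nslices = 3) {
  ax <- vol_axes(vol)
  if (any(patterns$x < min(ax$x) | patterns$x > max(ax$x) |
          patterns$y < min(ax$y) | patterns$y > max(ax$y)))
    stop("bar pattern outside volume")
  o <- order(patterns$frequency)
  patterns <- patterns[o, , drop = FALSE]
  mods <- numeric(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    period <- 10 / p$frequency
    m <- floor(p$width / period)
    u0 <- -p$width / 2
    ub <- u0 + (seq_len(m) - 1) * period + period / 4
    ug <- ub + period / 2
    du <- seq(-period / 12, period / 12, length.out = 3)
    vv <- seq(-0.35 * p$height, 0.35 * p$height, length.out = 15)
    th <- p$orientation * pi / 180
    k0 <- which.min(abs(ax$z - p$z))
    hw <- (nslices - 1) %/% 2
    ks <- max(1, k0 - hw):min(dim(vol$data)[3], k0 + hw)
    strip_mean <- function(uc) {
      uu <- rep(outer(uc, du, `+`), times = length(vv))
      vvv <- rep(vv, each = length(uc) * length(du))
      px <- p$x + cos(th) * uu - sin(th) * vvv
      py <- p$y + sin(th) * uu + cos(th) * vvv
      mean(vapply(ks, function(k) mean(sample_slice(vol, k, px, py)),
                  numeric(1)))
    }
    mods[i] <- min(1, max(0, (strip_mean(ub) - strip_mean(ug)) /
                               nominal_contrast))
  }
  names(mods) <- sprintf("%g", patterns$frequency)
  ok <- mods >= threshold
  resolvable <- if (!ok[1]) 0 else patterns$frequency[max(which(cumall(ok)))]
  list(modulation = mods, resolvable_lp = resolvable)
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

#' HU accuracy over the material inserts
#'
#' Mean HU in an ROI centred on each of the five accuracy inserts.
#'
#' @param vol a \code{volume_grid}.
#' @param rois mapped HU-module layout: one ROI per material, named by it.
#' @param nslices slices to pool.
#' @return Named numeric vector of per-material mean HU (acrylic, air, bone,
#'   polyethylene, water).
#' @export
measure_hu_accuracy <- function(vol, rois, nslices = 3) {
  need <- c("acrylic", "air", "bone", "polyethylene", "water")
  missing <- setdiff(need, rois$name)
  if (length(missing))
    stop("missing material ROI(s): ", paste(missing, collapse = ", "))
  out <- vapply(need, function(m) {
    roi_stats(vol, rois[rois$name == m, ][1, ], nslices)$mean
  }, numeric(1))
  out
}
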