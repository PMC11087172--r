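# Shared fixtures: small simulated volumes, built once per test run.
.fixtures <- new.env()

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# nominal ROI layout with z in centred physical coordinates
centred_layout <- function(spec, module_index, ...) {
  l <- nominal_roi_layout(spec, module_index, ...)
  l$z <- l$z - spec$length / 2
  l
}

# single-module volumes at modest resolution; z ranges are the centred
# physical extents of modules 1 (HU inserts) and 3 (uniformity slab)
hu_module_volume <- function(spacing = 2, noise_sd = 0, seed = 1, ...) {
  spec <- default_head_phantom()
  p <- simulation_params(in_plane_spacing = spacing, slice_thickness = 4,
                         noise_sd = noise_sd, z_range = c(-80, -40),
                         seed = seed, ...)
  simulate_scan(spec, p)
}

unif_module_volume <- function(spacing = 2, noise_sd = 0, seed = 1, ...) {
  spec <- default_head_phantom()
  p <- simulation_params(in_plane_spacing = spacing, slice_thickness = 4,
                         noise_sd = noise_sd, z_range = c(0, 40),
                         seed = seed, ...)
  simulate_scan(spec, p)
}

# fine-grid bar-pattern volume restricted to the resolution module
resolution_volume <- function(blur_fwhm = 0, spacing = 0.25, fov = 160,
                              seed = 1, ...) {
  spec <- default_head_phantom()
  p <- simulation_params(in_plane_spacing = spacing, slice_thickness = 4,
                         blur_fwhm = blur_fwhm, z_range = c(54, 66),
                         fov_mm = fov, supersample = 2, seed = seed, ...)
  simulate_scan(spec, p)
}

# independent 1D oracle for bar-pattern modulation: a square wave of unit
# contrast convolved with a Gaussian of the stated FWHM, averaged over the
# same strip offsets the measurement uses
oracle_modulation <- function(frequency, blur_fwhm, width = 12) {
  period <- 10 / frequency
  nbar <- floor(width / period)
  starts <- -width / 2 + (seq_len(nbar) - 1) * period
  profile <- function(u) {
    if (blur_fwhm == 0) {
      val <- rowSums(outer(u, starts, function(uu, s)
        as.numeric(uu >= s & uu < s + period / 2)))
    } else {
      sigma <- blur_fwhm / 2.3548
      val <- rowSums(outer(u, starts, function(uu, s)
        stats::pnorm((uu - s) / sigma) -
        stats::pnorm((uu - s - period / 2) / sigma)))
    }
    val
  }
  du <- seq(-period / 12, period / 12, length.out = 3)
  ub <- starts + period / 4
  ug <- ub + period / 2
  mean(profile(as.numeric(outer(ub, du, `+`)))) -
    mean(profile(as.numeric(outer(ug, du, `+`))))
}

# brute-force ROI statistics: per-voxel loop, no vectorized machinery shared
# with roi_stats
brute_roi_stats <- function(vol, roi, nslices = 3) {
  ax <- vol_axes(vol)
  k0 <- which.min(abs(ax$z - roi$z))
  hw <- (nslices - 1) %/% 2
  ks <- max(1, k0 - hw):min(dim(vol$data)[3], k0 + hw)
  vals <- c()
  for (k in ks)
    for (i in seq_along(ax$x))
      for (j in seq_along(ax$y))
        if ((ax$x[i] - roi$x)^2 + (ax$y[j] - roi$y)^2 <= (roi$diameter / 2)^2)
          vals <- c(vals, vol$data[i, j, k])
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}
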