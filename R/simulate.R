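#' Simulation parameters for a synthetic phantom scan
#'
#' Collects the acquisition geometry and the controllable degradations that
#' the simulator applies.  Degradations are applied by \code{\link{degrade}}
#' in a fixed, documented order: geometric scale/shift/rotation resampling,
#' in-plane Gaussian blur, radial cupping, per-material HU bias, then i.i.d.
#' Gaussian noise.
#'
#' @param in_plane_spacing mm per voxel in-plane (default 1).
#' @param slice_thickness mm per slice (default 3, the scanner default the
#'   scorecards use).
#' @param noise_sd HU standard deviation of white Gaussian noise (default 0).
#' @param blur_fwhm in-plane Gaussian blur full-width-half-maximum, mm.
#' @param cupping_amplitude HU centre-to-edge offset of the radial cupping
#'   field; the field is 0 at the phantom centre and reaches
#'   \code{-cupping_amplitude} at the peripheral-uniformity ROI ring radius
#'   (flat beyond it), so the uniformity metric reads the amplitude directly.
#' @param material_bias named numeric vector of HU offsets applied inside the
#'   insert discs of the named materials; the pseudo-material \code{"body"}
#'   offsets the entire phantom support.
#' @param scale_factor unitless geometric magnification (default 1).
#' @param shift length-2 in-plane offset, mm.
#' @param rotation in-plane rotation, degrees counter-clockwise.
#' @param seed integer RNG seed for the noise field.
#' @param fov_mm in-plane field of view (default: phantom/ring diameter + 20).
#' @param z_range length-2 range of slice centres in centred phantom
#'   coordinates (default: the full phantom length).
#' @param supersample integer in-plane anti-aliasing factor for rendering.
#' @return A list of class \code{simulation_params}.
#' @export
simulation_params <- function(in_plane_spacing = 1, slice_thickness = 3,
                              noise_sd = 0, blur_fwhm = 0,
                              cupping_amplitude = 0,
                              material_bias = numeric(0),
                              scale_factor = 1, shift = c(0, 0),
                              rotation = 0, seed = 1L,
                              fov_mm = NULL, z_range = NULL,
                              supersample = 4) {
  stopifnot(in_plane_spacing > 0, slice_thickness > 0, noise_sd >= 0,
            blur_fwhm >= 0, scale_factor > 0, length(shift) == 2,
            supersample >= 1)
  structure(list(
    in_plane_spacing = in_plane_spacing, slice_thickness = slice_thickness,
    noise_sd = noise_sd, blur_fwhm = blur_fwhm,
    cupping_amplitude = cupping_amplitude, material_bias = material_bias,
    scale_factor = scale_factor, shift = as.numeric(shift),
    rotation = rotation, seed = as.integer(seed), fov_mm = fov_mm,
    z_range = z_range, supersample = as.integer(supersample)
  ), class = "simulation_params")
}

# average an (s*nx) x (s*ny) supersampled matrix into nx x ny voxel blocks
.block_mean <- function(M, s) {
  if (s == 1) return(M)
  nx <- nrow(M) / s; ny <- ncol(M) / s
  A <- array(M, c(s, nx, s, ny))
  B <- colSums(A) / s                      # (nx, s, ny)
  colSums(aperm(B, c(2, 1, 3))) / s        # (nx, ny)
}

# render one module's in-plane HU template on the supersampled grid
.render_template <- function(spec, module, xs, ys) {
  n <- length(xs); m <- length(ys)
  X <- matrix(xs, n, m)
  Y <- matrix(ys, n, m, byrow = TRUE)
  R2 <- X^2 + Y^2
  mats <- spec$materials
  hu <- matrix(mats[["air"]], n, m)
  if (!is.null(spec$body_ring)) {
    rr <- spec$body_ring$outer_diameter / 2
    hu[R2 <= rr^2] <- mats[[spec$body_ring$material]]
  }
  hu[R2 <= (spec$head_diameter / 2)^2] <- mats[[spec$body_material]]
  if (!is.null(module$inserts)) {
    for (i in seq_len(nrow(module$inserts))) {
      ins <- module$inserts[i, ]
      d2 <- (X - ins$x)^2 + (Y - ins$y)^2
      hu[d2 <= (ins$diameter / 2)^2] <- mats[[ins$material]]
    }
  }
  if (!is.null(module$patterns)) {
    for (i in seq_len(nrow(module$patterns))) {
      p <- module$patterns[i, ]
      th <- p$orientation * pi / 180
      u <- cos(th) * (X - p$x) + sin(th) * (Y - p$y)
      v <- -sin(th) * (X - p$x) + cos(th) * (Y - p$y)
      inside <- abs(u) <= p$width / 2 & abs(v) <= p$height / 2
      period <- 10 / p$frequency            # lp/cm -> mm period
      bar <- inside & ((u + p$width / 2) %% period) < period / 2
      hu[bar] <- mats[[p$bar_material]]
    }
  }
  hu
}

#' Render a noiseless phantom volume
#'
#' Voxelizes a \code{\link{default_head_phantom}}-style spec: each voxel's HU
#' is the in-plane area-weighted average of the nominal material HU it covers
#' (computed on a \code{supersample}-times finer grid), background outside
#' the phantom is air.  Ball bearings are rendered as spheres with per-voxel
#' partial-volume weighting.  If the in-plane spacing is too coarse to
#' represent the finest bar pattern (Nyquist: > 1/(2 x 12 lp/cm) = 0.417 mm)
#' a warning string is recorded in the volume metadata; rendering itself
#' always happens on the finer supersampled grid.
#'
#' @param spec a \code{phantom_spec}.
#' @param params a \code{simulation_params}.
#' @return A \code{volume_grid} of nominal HU.
#' @export
render_volume <- function(spec, params) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(params, "simulation_params"))
  sp <- params$in_plane_spacing
  s <- params$supersample
  fov <- params$fov_mm
  if (is.null(fov)) {
    outer_d <- if (is.null(spec$body_ring)) spec$head_diameter
               else spec$body_ring$outer_diameter
    fov <- outer_d + 20
  }
  nx <- as.integer(ceiling(fov / sp))
  xs <- (seq_len(nx) - (nx + 1) / 2) * sp
  # supersampled sub-centres of every voxel
  xss <- rep(xs, each = s) + ((seq_len(s) - 0.5) / s - 0.5) * sp
  zr <- params$z_range
  if (is.null(zr)) zr <- c(-spec$length / 2, spec$length / 2)
  dt <- params$slice_thickness
  nz <- max(1L, as.integer(round((zr[2] - zr[1]) / dt)))
  zs <- zr[1] + (seq_len(nz) - 0.5) * dt

  meta <- list(params = unclass(params))
  if (sp > 10 / (2 * 12))
    meta$warnings <- c(meta$warnings, sprintf(
      "in-plane spacing %.3g mm exceeds the Nyquist limit (0.417 mm) for the 12 lp/cm pattern; stored voxels cannot fully represent it", sp))

  zext <- t(vapply(spec$modules, function(m) m$z, numeric(2)))
  arr <- array(spec$materials[["air"]], dim = c(nx, nx, nz))
  tmpl_cache <- vector("list", length(spec$modules))
  for (k in seq_len(nz)) {
    zf <- zs[k] + spec$length / 2          # face-referenced z
    mi <- which(zf >= zext[, 1] & zf < zext[, 2])
    if (length(mi) == 0 && abs(zf - spec$length) < 1e-9)
      mi <- nrow(zext)                     # top face belongs to last module
    if (length(mi) == 0) next              # outside phantom: air
    mi <- mi[1]
    if (is.null(tmpl_cache[[mi]]))
      tmpl_cache[[mi]] <- .block_mean(
        .render_template(spec, spec$modules[[mi]], xss, xss), s)
    sl <- tmpl_cache[[mi]]
    mk <- spec$modules[[mi]]$markers
    if (!is.null(mk)) {
      r_bb <- mk$diameter / 2
      dz <- zs[k] - (mk$z - spec$length / 2)
      if (abs(dz) < r_bb) {
        rr <- sqrt(r_bb^2 - dz^2)          # in-plane radius of sphere section
        sl <- .paint_disc(sl, xs, xs, rbind(mk$a, mk$b), rr,
                          spec$materials[["metal"]], s)
      }
    }
    arr[, , k] <- sl
  }
  volume_grid(arr, c(sp, sp, dt), c(xs[1], xs[1], zs[1]), meta = meta)
}

# blend metal discs into a slice with supersampled partial-volume coverage
.paint_disc <- function(sl, xs, ys, centers, radius, hu, s) {
  sp <- xs[2] - xs[1]
  off <- ((seq_len(s) - 0.5) / s - 0.5) * sp
  for (b in seq_len(nrow(centers))) {
    cx <- centers[b, 1]; cy <- centers[b, 2]
    ii <- which(abs(xs - cx) <= radius + sp)
    jj <- which(abs(ys - cy) <= radius + sp)
    if (!length(ii) || !length(jj)) next
    for (i in ii) for (j in jj) {
      sx <- xs[i] + off; sy <- ys[j] + off
      cover <- mean(outer(sx - cx, sy - cy,
                          function(a, b) a^2 + b^2) <= radius^2)
      if (cover > 0) sl[i, j] <- (1 - cover) * sl[i, j] + cover * hu
    }
  }
  sl
}

#' Apply degradations to a rendered volume
#'
#' Applies, in order: in-plane geometric transform (magnification
#' \code{scale_factor}, rotation, shift; bilinear resampling), Gaussian blur
#' of the stated FWHM, the radial cupping field, per-material HU bias inside
#' the (transformed) material regions, and finally white Gaussian noise drawn
#' with \code{params$seed}.  Deterministic given (volume, params).  With
#' all-zero degradation parameters the volume is returned unchanged.
#'
#' @param vol a \code{volume_grid} as produced by \code{\link{render_volume}}.
#' @param params a \code{simulation_params}.
#' @param spec the \code{phantom_spec} the volume renders (needed for the
#'   cupping reference radius and the material-bias masks).
#' @return The degraded \code{volume_grid}.
#' @export
degrade <- function(vol, params, spec = default_head_phantom()) {
  stopifnot(inherits(vol, "volume_grid"),
            inherits(params, "simulation_params"))
  arr <- vol$data
  d <- dim(arr)
  ax <- vol_axes(vol)

  # 1. geometry: output voxel at p samples the input at R^-1 (p - shift)/scale
  if (params$scale_factor != 1 || any(params$shift != 0) ||
      params$rotation != 0) {
    th <- params$rotation * pi / 180
    X <- matrix(ax$x, d[1], d[2]); Y <- matrix(ax$y, d[1], d[2], byrow = TRUE)
    Xs <- (X - params$shift[1]); Ys <- (Y - params$shift[2])
    sx <- (cos(th) * Xs + sin(th) * Ys) / params$scale_factor
    sy <- (-sin(th) * Xs + cos(th) * Ys) / params$scale_factor
    src <- vol
    for (k in seq_len(d[3]))
      arr[, , k] <- sample_slice(src, k, as.numeric(sx), as.numeric(sy))
  }

  # 2. in-plane Gaussian blur
  if (params$blur_fwhm > 0) {
    sigma_vox <- params$blur_fwhm / 2.3548 / vol$spacing[1]
    for (k in seq_len(d[3]))
      arr[, , k] <- EBImage::gblur(arr[, , k], sigma = sigma_vox)
  }

  # geometry of the (transformed) phantom for cupping + bias masks
  sc <- params$scale_factor
  ctr <- params$shift
  outer_r <- sc * (if (is.null(spec$body_ring)) spec$head_diameter
                   else spec$body_ring$outer_diameter) / 2

  # 3. radial cupping: 0 at centre, -A at the uniformity ROI ring, flat beyond
  if (params$cupping_amplitude != 0) {
    r_ref <- sc * uniformity_ring_radius(spec)
    X <- matrix(ax$x, d[1], d[2]); Y <- matrix(ax$y, d[1], d[2], byrow = TRUE)
    r2 <- (X - ctr[1])^2 + (Y - ctr[2])^2
    field <- -params$cupping_amplitude * pmin(r2 / r_ref^2, 1)
    field[r2 > outer_r^2] <- 0
    for (k in seq_len(d[3])) arr[, , k] <- arr[, , k] + field
  }

  # 4. per-material bias inside transformed insert discs ("body" = support)
  if (length(params$material_bias) > 0) {
    th <- params$rotation * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    X <- matrix(ax$x, d[1], d[2]); Y <- matrix(ax$y, d[1], d[2], byrow = TRUE)
    for (nm in names(params$material_bias)) {
      b <- params$material_bias[[nm]]
      if (nm == "body") {
        mask2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= outer_r^2
        for (k in seq_len(d[3]))
          arr[, , k][mask2] <- arr[, , k][mask2] + b
        next
      }
      for (mi in seq_along(spec$modules)) {
        m <- spec$modules[[mi]]
        if (is.null(m$inserts)) next
        sel <- which(m$inserts$material == nm)
        for (i in sel) {
          cen <- sc * as.numeric(R %*% c(m$inserts$x[i], m$inserts$y[i])) + ctr
          rad <- sc * m$inserts$diameter[i] / 2
          mask2 <- (X - cen[1])^2 + (Y - cen[2])^2 <= rad^2
          zf <- ax$z + spec$length / 2
          for (k in which(zf >= m$z[1] & zf < m$z[2]))
            arr[, , k][mask2] <- arr[, , k][mask2] + b
        }
      }
    }
  }

  # 5. white Gaussian noise, seeded; RNG state restored afterwards
  if (params$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(params$seed)
    arr <- arr + stats::rnorm(length(arr), 0, params$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  volume_grid(arr, vol$spacing, vol$origin, meta = vol$meta)
}

#' Simulate a complete phantom scan
#'
#' \code{\link{render_volume}} followed by \code{\link{degrade}}.  The same
#' spec, params and seed always produce a bit-identical volume.
#'
#' @inheritParams degrade
#' @inheritParams render_volume
#' @return A \code{volume_grid}.
#' @export
simulate_scan <- function(spec, params) {
  degrade(render_volume(spec, params), params, spec)
}

#' Named simulation presets
#'
#' \code{"clean_diagnostic"} emulates a sharp, low-noise fan-beam CT
#' acquisition whose ground truth sits comfortably inside every ACR passing
#' range; \code{"cbct_degraded"} emulates a noisy cone-beam acquisition with
#' strong cupping, built to fail the CNR and uniformity criteria.
#'
#' @param name preset name.
#' @param seed RNG seed forwarded to the parameters.
#' @return A \code{simulation_params}.
#' @export
preset_params <- function(name = c("clean_diagnostic", "cbct_degraded"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    clean_diagnostic = simulation_params(
      in_plane_spacing = 0.5, slice_thickness = 3,
      noise_sd = 3, blur_fwhm = 0.6, cupping_amplitude = 1, seed = seed),
    cbct_degraded = simulation_params(
      in_plane_spacing = 0.5, slice_thickness = 3,
      noise_sd = 9, blur_fwhm = 1.2, cupping_amplitude = 8, seed = seed)
  )
}
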