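spec <- default_head_phantom()

test_that("ROI statistics match a brute-force per-voxel oracle", {
  vol <- fixture("unif_noisy4", function()
    unif_module_volume(spacing = 4, noise_sd = 8, seed = 13))
  rois <- list(
    list(name = "ctr", x = 0, y = 0, z = 20, diameter = 24),
    list(name = "off", x = 31, y = -17, z = 20, diameter = 17),
    list(name = "tiny", x = -40, y = 22, z = 12, diameter = 9)
  )
  for (roi in rois) {
    fast <- roi_stats(vol, roi)
    slow <- brute_roi_stats(vol, roi)
    expect_equal(fast$mean, slow$mean)
    expect_equal(fast$sd, slow$sd)
    expect_equal(fast$n, slow$n)
  }
})

test_that("ROI statistics handle constant and degenerate regions", {
  v <- volume_grid(array(100, c(30, 30, 3)), c(2, 2, 4))
  st <- roi_stats(v, list(name = "c", x = 30, y = 30, z = 4, diameter = 20))
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
  expect_error(
    roi_stats(v, list(name = "out", x = 300, y = 0, z = 4, diameter = 5)),
    "no voxels")
})

test_that("sample sd of a pure-noise ROI is chi-square consistent", {
  set.seed(77)
  v <- volume_grid(array(stats::rnorm(120 * 120 * 3, 0, 10), c(120, 120, 3)),
                   c(1, 1, 4))
  st <- roi_stats(v, list(name = "big", x = 60, y = 60, z = 4, diameter = 70))
  expect_gt(st$n, 1e4)
  expect_lt(abs(st$sd - 10), 0.5)
})

test_that("CNR follows its defining ratio and invariances", {
  a <- list(mean = 120, sd = 4, n = 100)
  b <- list(mean = 100, sd = 10, n = 100)
  expect_equal(compute_cnr(a, b)$cnr, 2)
  expect_equal(compute_cnr(b, b)$cnr, 0)
  expect_error(compute_cnr(a, list(mean = 0, sd = 0, n = 5)), "undefined")

  # additive offsets cancel; contrast scales linearly at fixed noise
  set.seed(3)
  for (i in 1:20) {
    mb <- runif(1, -50, 50); sdb <- runif(1, 1, 20)
    contrast <- runif(1, -30, 30); c0 <- runif(1, -500, 500)
    k <- runif(1, 0.5, 3)
    base <- compute_cnr(list(mean = mb + contrast, sd = 5, n = 10),
                        list(mean = mb, sd = sdb, n = 10))$cnr
    shifted <- compute_cnr(list(mean = mb + contrast + c0, sd = 5, n = 10),
                           list(mean = mb + c0, sd = sdb, n = 10))$cnr
    scaled <- compute_cnr(list(mean = mb + k * contrast, sd = 5, n = 10),
                          list(mean = mb, sd = sdb, n = 10))$cnr
    expect_equal(shifted, base)
    expect_equal(scaled, k * base)
  }
})

test_that("CNR on volumes is invariant to adding a constant", {
  vol <- fixture("cnr_noisy", function() {
    p <- simulation_params(in_plane_spacing = 2, slice_thickness = 4,
                           noise_sd = 3, z_range = c(-40, 0), seed = 17)
    simulate_scan(spec, p)
  })
  lay <- centred_layout(spec, 2)
  cnr1 <- compute_cnr(roi_stats(vol, lay[lay$name == "A", ]),
                      roi_stats(vol, lay[lay$name == "B", ]))$cnr
  shifted <- volume_grid(vol$data + 40, vol$spacing, vol$origin)
  cnr2 <- compute_cnr(roi_stats(shifted, lay[lay$name == "A", ]),
                      roi_stats(shifted, lay[lay$name == "B", ]))$cnr
  expect_equal(cnr2, cnr1, tolerance = 1e-10)
})

test_that("simulated low-contrast rod yields CNR = contrast/noise", {
  # rod is +6 HU over water; noise sd 3 (unblurred) -> CNR about 2
  cnrs <- vapply(1:12, function(s) {
    p <- simulation_params(in_plane_spacing = 2, slice_thickness = 4,
                           noise_sd = 3, z_range = c(-40, 0), seed = 100 + s)
    vol <- simulate_scan(spec, p)
    lay <- centred_layout(spec, 2)
    compute_cnr(roi_stats(vol, lay[lay$name == "A", ]),
                roi_stats(vol, lay[lay$name == "B", ]))$cnr
  }, numeric(1))
  expect_lt(abs(mean(cnrs) - 2), 0.3)
})

test_that("uniformity statistics follow their definition", {
  vol <- fixture("unif0", function() unif_module_volume())
  lay <- centred_layout(spec, 3)
  u0 <- measure_uniformity(vol, lay)
  expect_equal(u0$max_abs_diff, 0)            # noiseless uniform slab

  # paint known offsets into the peripheral ROI discs
  v <- vol
  ax <- vol_axes(v)
  offs <- c(p12 = 1, p3 = 2, p6 = -3, p9 = 4)
  for (nm in names(offs)) {
    roi <- lay[lay$name == nm, ]
    ii <- abs(ax$x - roi$x) <= roi$diameter / 2
    jj <- abs(ax$y - roi$y) <= roi$diameter / 2
    v$data[ii, jj, ] <- v$data[ii, jj, ] + offs[[nm]]
  }
  u <- measure_uniformity(v, lay)
  expect_equal(u$max_abs_diff, 4)
  expect_equal(sort(unname(u$diffs)), c(-3, 1, 2, 4))
  expect_error(measure_uniformity(vol, lay[1:4, ]), "exactly 5")
})

test_that("uniformity noise floor scales like sd/sqrt(n)", {
  lay <- centred_layout(spec, 3)
  sigma <- 8
  vals <- vapply(1:10, function(s)
    measure_uniformity(unif_module_volume(noise_sd = sigma, seed = 200 + s),
                       lay)$max_abs_diff, numeric(1))
  n_roi <- roi_stats(fixture("unif0", function() unif_module_volume()),
                     lay[1, ])$n
  unit <- sigma * sqrt(2 / n_roi)             # sd of one peripheral-centre diff
  expect_gt(mean(vals), 0.5 * unit)
  expect_lt(mean(vals), 3 * unit)
})

test_that("cupping produces the configured uniformity deviation", {
  lay <- centred_layout(spec, 3)
  u <- measure_uniformity(unif_module_volume(cupping_amplitude = 6), lay)
  expect_lt(abs(u$max_abs_diff - 6), 1)
  expect_equal(classify_uniformity(u$max_abs_diff)$level, "minor")
})

test_that("scaling percent error tracks the simulated magnification", {
  s <- measure_scaling(fixture("unif0", function() unif_module_volume()))
  expect_lt(s$percent_error, 0.5)             # half a 2 mm voxel over 100 mm
  sm <- measure_scaling(unif_module_volume(scale_factor = 1.005))
  expect_lt(abs(sm$measured_mm - 100.5), 1)
  expect_equal(sm$percent_error,
               100 * abs(sm$measured_mm - 100) / 100)
})

test_that("bar-pattern modulation matches the 1D convolution oracle", {
  lay <- centred_layout(spec, 4)
  for (fw in c(0.8, 1.2)) {
    vol <- fixture(paste0("res", fw), function() resolution_volume(fw))
    got <- measure_resolution(vol, lay, nominal_contrast = 955)$modulation
    want <- vapply(c(4, 5, 6, 7, 8, 9, 10, 12), oracle_modulation,
                   numeric(1), blur_fwhm = fw)
    want <- pmin(1, pmax(0, want))
    expect_lt(max(abs(got - want)), 0.08)
  }
})

test_that("an unblurred fine scan resolves all eight patterns", {
  vol <- fixture("res0", function() resolution_volume(0))
  r <- measure_resolution(vol, centred_layout(spec, 4),
                          nominal_contrast = 955)
  expect_equal(r$resolvable_lp, 12)
  expect_true(all(r$modulation >= 0 & r$modulation <= 1))
})

test_that("heavy blur drops the resolvable frequency to 5 lp/cm or below", {
  vol <- fixture("res2", function() resolution_volume(2))
  r <- measure_resolution(vol, centred_layout(spec, 4),
                          nominal_contrast = 955)
  expect_lte(r$resolvable_lp, 5)
})

test_that("HU accuracy requires all five materials", {
  vol <- fixture("hu0", function() hu_module_volume())
  lay <- centred_layout(spec, 1)
  hu <- measure_hu_accuracy(vol, lay)
  expect_named(hu, c("acrylic", "air", "bone", "polyethylene", "water"))
  expect_error(measure_hu_accuracy(vol, lay[lay$name != "bone", ]),
               "missing material")
})
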