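cfg <- acr_criteria()

test_that("uniformity bands partition the line with the documented edges", {
  expect_equal(classify_uniformity(4.05)$level, "pass")
  expect_equal(classify_uniformity(4.98)$level, "pass")
  expect_equal(classify_uniformity(5.10)$level, "minor")
  expect_equal(classify_uniformity(5.00)$level, "minor")   # inclusive at 5
  expect_equal(classify_uniformity(7.00)$level, "minor")   # inclusive at 7
  expect_equal(classify_uniformity(8.17)$level, "major")
  expect_error(classify_uniformity(-1), "nonnegative")
  # totality: every finite value maps to exactly one level
  for (v in seq(0, 12, by = 0.25))
    expect_true(classify_uniformity(v)$level %in% c("pass", "minor", "major"))
})

test_that("HU classification uses inclusive passing ranges", {
  expect_equal(classify_hu("water", -3.1)$level, "pass")
  expect_equal(classify_hu("water", -11.6)$level, "major")
  expect_equal(classify_hu("water", 7)$level, "pass")      # boundary passes
  expect_equal(classify_hu("water", -7)$level, "pass")
  expect_equal(classify_hu("bone", 849.9)$level, "major")
  expect_error(classify_hu("titanium", 0), "unknown material")
  # an optional minor band sits between pass and major
  cfg2 <- acr_criteria(hu_minor = list(water = c(-12, 12)))
  expect_equal(classify_hu("water", -10, cfg2)$level, "minor")
  expect_equal(classify_hu("water", -15, cfg2)$level, "major")
  expect_error(acr_criteria(hu_minor = list(water = c(-3, 3))), "nest")
})

test_that("CNR, resolution and scaling criteria depend on protocol class", {
  expect_equal(classify_cnr(0.7, "pediatric_body")$level, "pass")
  expect_equal(classify_cnr(0.7, "adult_head")$level, "major")
  expect_error(classify_cnr(1, "canine_head"), "unknown protocol class")
  expect_equal(classify_resolution(5, "adult_body")$level, "pass")
  expect_equal(classify_resolution(5, "adult_head")$level, "major")
  expect_equal(classify_resolution(6, "pediatric_head")$level, "pass")
  expect_equal(classify_scaling(0.9)$level, "pass")
  expect_equal(classify_scaling(1.2)$level, "major")
  expect_error(classify_scaling(-0.1), "nonnegative")
})

test_that("deviation beyond a range is 0 inside and 1-Lipschitz outside", {
  rng <- c(-7, 7)
  expect_equal(deviation_beyond_range(0, rng), 0)
  expect_equal(deviation_beyond_range(-11.6, rng), 4.6)
  expect_equal(deviation_beyond_range(831.0, c(850, 970)), 19.0)
  vs <- seq(-30, 30, by = 0.5)
  d <- deviation_beyond_range(vs, rng)
  expect_true(all(d >= 0))
  expect_true(all(d[vs >= -7 & vs <= 7] == 0))
  expect_true(all(abs(diff(d)) <= 0.5 + 1e-12))            # Lipschitz
})

test_that("failure summaries cover only out-of-range values", {
  s <- summarize_failures(c(0, 1, -2), c(-7, 7))
  expect_equal(s$n_failing, 0)
  expect_true(is.na(s$mean_deviation))
  s2 <- summarize_failures(c(-10, 10, 0), c(-7, 7))
  expect_equal(s2$n_failing, 2)
  expect_equal(s2$mean_deviation, 3)
  expect_equal(s2$sd_deviation, 0)
})

test_that("protocol evaluation needs all nine metrics", {
  row <- list(contrast_resolution = 2, spatial_resolution = 6, acrylic = 120,
              air = -990, bone = 900, polyethylene = -95, water = 0,
              scaling_pct = 0.5, uniformity_hu = 3)
  pv <- evaluate_protocol(row, "adult_head")
  expect_equal(pv$overall, "pass")
  expect_equal(pv$n_pass, 9)
  row$uniformity_hu <- 6
  pv2 <- evaluate_protocol(row, "adult_head")
  expect_equal(pv2$overall, "fail")
  expect_equal(pv2$n_pass, 8)
  expect_equal(pv2$levels[["uniformity"]], "minor")
  expect_error(evaluate_protocol(row[-3], "adult_head"), "missing metric")
})

test_that("verdict tallies count every protocol exactly once", {
  rows <- lapply(c(3, 5.5, 9, 4), function(u)
    evaluate_protocol(list(contrast_resolution = 2, spatial_resolution = 6,
                           acrylic = 120, air = -990, bone = 900,
                           polyethylene = -95, water = 0, scaling_pct = 0.5,
                           uniformity_hu = u), "adult_head"))
  t <- tally_verdicts(rows, "uniformity")
  expect_equal(unname(t), c(2, 1, 1))
  expect_equal(sum(t), 4)
  expect_equal(unname(tally_verdicts(list(), "uniformity")), c(0, 0, 0))
})

test_that("baselines are per-material means with a 50 HU tolerance", {
  b <- build_baseline(data.frame(water = c(-1, 1, 3), bone = c(900, 910, 920)))
  expect_equal(unname(b$baseline["water"]), 1)
  expect_true(check_against_baseline(51, "water", b))
  expect_false(check_against_baseline(51.1, "water", b))
  b1 <- build_baseline(data.frame(acrylic = 117))
  expect_equal(unname(b1$baseline["acrylic"]), 117)
  expect_error(check_against_baseline(0, "bone", b1), "no baseline")
})

test_that("exposure stability needs repeated exposures", {
  tab <- data.frame(protocol = c("A", "A", "B", "B"),
                    water = c(0, 1.2, -1, 0.5), air = c(-999, -999, -998, -998))
  es <- exposure_stability(tab)
  expect_equal(es$max_range_hu, 1.5)
  expect_equal(unname(es$at["protocol"]), "B")
  expect_error(exposure_stability(data.frame(protocol = "A", water = 0)),
               "fewer than 2 exposures")
})

test_that("criteria configuration survives a YAML round trip", {
  cfg2 <- acr_criteria(hu_minor = list(water = c(-12, 12)),
                       scaling_tol_pct = 0.8)
  f <- tempfile(fileext = ".yaml")
  write_criteria(cfg2, f)
  back <- read_criteria(f)
  expect_equal(back, cfg2)
})
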