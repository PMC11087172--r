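spec <- default_head_phantom()

test_that("internal volume format round-trips bit-identically", {
  vol <- fixture("unif_noisy", function()
    unif_module_volume(spacing = 2, noise_sd = 5, seed = 3))
  f <- tempfile()
  write_volume(vol, f)
  back <- read_volume(f)
  expect_identical(back$data, vol$data)
  expect_identical(back$spacing, vol$spacing)
  expect_identical(back$origin, vol$origin)
})

test_that("round trip preserves downstream metrics exactly", {
  vol <- fixture("unif_noisy", function()
    unif_module_volume(spacing = 2, noise_sd = 5, seed = 3))
  f <- tempfile()
  write_volume(vol, f)
  back <- read_volume(f)
  lay <- centred_layout(spec, 3)
  expect_identical(measure_uniformity(back, lay),
                   measure_uniformity(vol, lay))
  expect_identical(measure_scaling(back), measure_scaling(vol))
})

test_that("corrupt or empty inputs are rejected", {
  v0 <- volume_grid(array(0, c(2, 2, 1)), c(1, 1, 1))
  v0$data <- v0$data[, , 0, drop = FALSE]
  expect_error(write_volume(v0, tempfile()), "empty")
  f <- tempfile()
  writeLines("not json", paste0(f, ".json")); file.create(f)
  expect_error(read_volume(f), "corrupt")
  expect_error(read_volume(tempfile()), "not found")
})

test_that("DICOM series round-trips HU, geometry and annotations", {
  vol <- fixture("unif_noisy", function()
    unif_module_volume(spacing = 2, noise_sd = 5, seed = 3))
  d <- file.path(tempdir(), "dcm_rt")
  write_ct_series(vol, d, kvp = 125, exposure_mas = 806)
  rt <- read_ct_series(d)
  # 16-bit storage quantizes to whole HU; geometry must be exact
  expect_equal(rt$volume$data, round(vol$data))
  expect_equal(rt$volume$spacing, vol$spacing)
  expect_equal(rt$volume$origin, vol$origin)
  expect_equal(rt$meta$kvp, 125)
  expect_equal(rt$meta$exposure_mas, 806)
  expect_equal(unname(rt$meta$rescale), c(1, -1024))
  unlink(d, recursive = TRUE)
})

test_that("stored value 0 with slope 1, intercept -1024 reads as -1024 HU", {
  v <- volume_grid(array(-1024, c(3, 3, 2)), c(1, 1, 1))
  d <- file.path(tempdir(), "dcm_air")
  write_ct_series(v, d)
  rt <- read_ct_series(d)
  expect_true(all(rt$volume$data == -1024))
  unlink(d, recursive = TRUE)
})

test_that("mixed series and non-uniform slice spacing are rejected", {
  v <- volume_grid(array(0, c(3, 3, 4)), c(1, 1, 2))
  d <- file.path(tempdir(), "dcm_bad")
  unlink(d, recursive = TRUE)
  write_ct_series(v, d)
  # removing an interior slice breaks spacing uniformity
  file.remove(file.path(d, "slice_002.dcm"))
  expect_error(read_ct_series(d), "non-uniform slice spacing")
  # a slice from a different series (fresh series UID) in the same directory
  v2 <- volume_grid(array(0, c(3, 3, 1)), c(1, 1, 2), origin = c(0, 0, 9))
  d2 <- file.path(tempdir(), "dcm_other")
  write_ct_series(v2, d2)
  file.copy(file.path(d2, "slice_001.dcm"), file.path(d, "slice_009.dcm"))
  expect_error(read_ct_series(d), "mixed series")
  unlink(c(d, d2), recursive = TRUE)
})

test_that("missing rescale tags are rejected", {
  v <- volume_grid(array(0, c(3, 3, 1)), c(1, 1, 2))
  d <- file.path(tempdir(), "dcm_norescale")
  unlink(d, recursive = TRUE)
  write_ct_series(v, d)
  f <- file.path(d, "slice_001.dcm")
  r <- readBin(f, "raw", file.info(f)$size)
  # excise the RescaleIntercept element (0028,1052), VR DS, 8-byte header
  tag <- as.raw(c(0x28, 0x00, 0x52, 0x10))
  hit <- which(vapply(seq_len(length(r) - 3), function(i)
    all(r[i + 0:3] == tag), logical(1)))[1]
  len <- as.integer(r[hit + 6]) + 256L * as.integer(r[hit + 7])
  r <- r[-(hit:(hit + 7 + len))]
  writeBin(r, f)
  expect_error(read_ct_series(d), "missing rescale")
  unlink(d, recursive = TRUE)
})

test_that("an independent DICOM reader agrees with ours", {
  py <- Sys.which("python")
  expect_true(nzchar(py))                     # pre-installed interpreter
  vol <- volume_grid(array(round(stats::rnorm(5 * 4 * 2, 0, 200)),
                           c(5, 4, 2)), c(1.5, 2, 3), c(-3, -3, 0))
  d <- file.path(tempdir(), "dcm_py")
  unlink(d, recursive = TRUE)
  write_ct_series(vol, d)
  out <- tempfile(fileext = ".txt")
  script <- sprintf(
    "import pydicom, glob\nvals = []\nfor f in sorted(glob.glob('%s/*.dcm')):\n    ds = pydicom.dcmread(f)\n    hu = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)\n    vals.extend(hu.flatten().tolist())\nopen('%s', 'w').write('\\n'.join(str(v) for v in vals) + '\\n')\n",
    d, out)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  expect_equal(system2(py, sf), 0)
  got <- as.numeric(readLines(out))
  # pydicom flattens row-major per slice: rows (y) outer, columns (x) inner
  want <- as.numeric(do.call(c, lapply(1:2, function(k)
    as.vector(vol$data[, , k]))))
  expect_equal(got, want)
  unlink(d, recursive = TRUE)
})
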