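test_that("intensity windowing maps the window linearly onto [0, 255] with saturation", {
  w <- window_spec(center = 100, width = 200)
  expect_equal(window_to_unit_range(matrix(100), w), matrix(127.5))
  expect_equal(window_to_unit_range(matrix(0), w), matrix(0))
  expect_equal(window_to_unit_range(matrix(200), w), matrix(255))
  ## saturation below/above the window
  expect_equal(window_to_unit_range(matrix(-50), w), matrix(0))
  expect_equal(window_to_unit_range(matrix(10 * 1000), w), matrix(255))
  expect_error(window_spec(0, 0), "width")
})

test_that("windowing is monotone non-decreasing in the raw intensity", {
  w <- window_spec(center = 40, width = 73)
  x <- sort(runif(500, -100, 200))
  y <- window_to_unit_range(matrix(x, 1), w)
  expect_true(all(diff(as.vector(y)) >= 0))
})

test_that("full-range fallback spans the observed intensities", {
  set.seed(51)
  raw <- matrix(runif(100, -40, 900), 10)
  y <- window_to_unit_range(raw, window_full_range(raw))
  expect_equal(min(y), 0)
  expect_equal(max(y), 255)
})

test_that("geometry standardization always yields the model-size square", {
  set.seed(52)
  for (dims in list(c(64, 64), c(128, 96), c(96, 128), c(200, 37),
                    c(17, 300))) {
    img <- matrix(runif(prod(dims), 0, 255), dims[1], dims[2])
    out <- standardize_geometry(img, target_canvas = 64L, model_size = 32L)
    expect_equal(dim(out), c(32L, 32L))
    expect_true(all(is.finite(out)))
  }
  expect_error(standardize_geometry(matrix(numeric(0), 0, 0)), "degenerate")
})

test_that("a canvas-square input only gets the final down-sample", {
  ## constant image: any sequence of averaging steps preserves the value
  img <- matrix(7, 64, 64)
  out <- standardize_geometry(img, 64L, 32L)
  expect_equal(out, matrix(7, 32, 32))
  ## 2048x1536 wide-format: width scaled to the canvas, height padded
  img2 <- matrix(100, 1536, 2048)
  out2 <- standardize_geometry(img2, 128L, 32L)
  expect_equal(dim(out2), c(32L, 32L))
  ## padded rows are zero, interior preserved
  expect_equal(out2[16, 16], 100, tolerance = 1e-9)
  expect_equal(out2[1, 1], 0)
})

test_that("taller-than-canvas images are symmetrically truncated", {
  img <- matrix(rep(seq_len(200), 100), 200, 100)   # vertical ramp
  out <- standardize_geometry(img, 100L, 100L)
  ## center rows survive: mean close to the ramp's center value
  expect_equal(mean(out), 100.5, tolerance = 1)
})

test_that("bicubic up-sampling is exact on flats and near-exact on ramps", {
  flat <- matrix(42, 16, 16)
  expect_equal(upsample_output(flat, 32), matrix(42, 32, 32))
  expect_equal(upsample_output(flat, 16), flat)
  ramp <- matrix(rep(seq(0, 255, length.out = 64), 64), 64, 64)
  up <- upsample_output(ramp, 128)
  want <- matrix(rep(seq(0, 255, length.out = 64), each = 2), 128, 128)
  ## interior agrees with the linear ramp to < 0.5 intensity units
  interior <- 5:124
  ideal <- (row(up) - 0.5) / 2 + 0.5     # source-position ramp value
  ideal <- (ideal - 1) * 255 / 63
  expect_lt(max(abs(up[interior, interior] - ideal[interior, interior])),
            0.5)
  expect_error(upsample_output(matrix(0, 2, 3), 4), "square")
})

test_that("preprocessing is deterministic", {
  set.seed(53)
  img <- matrix(runif(120 * 90, 0, 4000), 120, 90)
  w <- window_spec(2000, 3500)
  a <- standardize_geometry(window_to_unit_range(img, w), 64L, 32L)
  b <- standardize_geometry(window_to_unit_range(img, w), 64L, 32L)
  expect_identical(a, b)
})

test_that("images survive a PNG write/read round trip at 8-bit precision", {
  set.seed(54)
  img <- matrix(round(runif(64, 0, 255)), 8, 8)
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(back, img, tolerance = 0.51, ignore_attr = TRUE)
})
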