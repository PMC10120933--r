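test_that("Gaussian blur preserves constants, mass and the input range", {
  const <- raster_image(matrix(77, 21, 21), 1)
  expect_equal(gaussian_blur(const, 1)$pixels, const$pixels)

  # unit impulse: centre response equals the normalized kernel at the origin
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  out <- gaussian_blur(raster_image(imp, 1), 1, quantize = FALSE)
  expect_equal(out$pixels[21, 21], 1 / (2 * pi), tolerance = 1e-4)

  # total intensity preserved when the support stays away from the borders
  set.seed(11)
  for (k in 1:5) {
    px <- matrix(0, 40, 40)
    px[13:28, 13:28] <- sample(0:255, 16 * 16, replace = TRUE)
    raw <- gaussian_blur(raster_image(px, 1), 1.5, quantize = FALSE)$pixels
    expect_equal(sum(raw), sum(px), tolerance = 1e-8)
    # and quantized output never over/undershoots the input range
    q <- gaussian_blur(raster_image(px, 1), 1.5)$pixels
    expect_true(all(q >= min(px) & q <= max(px)))
  }
  expect_error(gaussian_blur(const, 0), "positive")
})

test_that("Frangi vesselness highlights bright ridges and nothing else", {
  expect_equal(frangi_vesselness(raster_image(matrix(50, 32, 32), 1))$pixels,
               matrix(0, 32, 32))

  # bright horizontal ridge: Gaussian profile across rows
  prof <- exp(-((1:64) - 32)^2 / (2 * 2^2))
  ridge <- round(200 * matrix(prof, 64, 64))
  v <- frangi_vesselness(raster_image(ridge, 1))$pixels
  crest <- v[32, 10:54]
  bg <- v[c(1:16, 48:64), 10:54]  # >= 3 sigma plus scale support away
  expect_true(min(crest) > max(bg))

  # dark ridge on bright background: zero response on the crest
  vd <- frangi_vesselness(raster_image(200 - ridge, 1))$pixels
  expect_true(all(vd[32, 5:60] == 0))

  # invariance under addition of a constant (the Hessian is unchanged; the
  # 8-bit rescale may flip individual pixels by one quantization level)
  set.seed(3)
  px <- matrix(sample(0:200, 48 * 48, replace = TRUE), 48, 48)
  d <- frangi_vesselness(raster_image(px, 1))$pixels -
    frangi_vesselness(raster_image(px + 30, 1))$pixels
  expect_lte(max(abs(d)), 1)
  expect_error(frangi_vesselness(raster_image(px, 1), scales = numeric()),
               "non-empty")
})

test_that("local median threshold matches its definition on hand cases", {
  # single bright pixel: only it exceeds its window median
  px <- matrix(0, 32, 32); px[16, 16] <- 255
  bw <- local_median_threshold(raster_image(px, 1), radius = 8)$mask
  expect_equal(which(bw), which(px == 255))

  # checkerboard at radius 1: interior windows hold five of the centre's own
  # colour, so the strict > rule classifies every interior pixel background
  # (the lower median of a 255-pixel's window is 255 itself) — pinned by the
  # brute-force oracle
  cb <- 255 * outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  bwc <- local_median_threshold(raster_image(cb, 1), radius = 1)$mask
  expect_identical(bwc, oracle_median_mask(cb, 1))
  expect_false(any(bwc[2:15, 2:15]))
  expect_false(any(bwc[cb == 0]))

  # constant image: strict comparison leaves everything background
  expect_false(any(local_median_threshold(raster_image(matrix(9, 20, 20), 1),
                                          radius = 3)$mask))

  # ROI restriction
  roi <- roi_mask(matrix(rep(c(TRUE, FALSE), each = 16 * 32), 32, 32))
  bwr <- local_median_threshold(raster_image(px, 1), 8, 0, roi)$mask
  expect_true(all(!bwr[!roi$mask]))
})

test_that("local median threshold agrees with the brute-force oracle", {
  set.seed(42)
  for (k in 1:20) {
    px <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
    radius <- sample(c(1, 2, 5, 8), 1)
    offset <- sample(c(-5, 0, 3), 1)
    got <- local_median_threshold(raster_image(px, 1), radius, offset)$mask
    expect_identical(got, oracle_median_mask(px, radius, offset))
  }
})

test_that("Mexican-hat filter is zero-mean, blob-selective and symmetric", {
  const <- raster_image(matrix(123, 30, 30), 1)
  expect_equal(mexican_hat(const, 13)$pixels, matrix(0, 30, 30))

  # bright disc of radius ~ sigma: response peaks at the disc centre
  rr <- matrix(1:64, 64, 64); cc <- t(rr)
  disc <- 20 + 180 * ((rr - 32)^2 + (cc - 32)^2 <= 4^2)
  out <- mexican_hat(raster_image(disc, 1), 13, quantize = FALSE)$pixels
  expect_true(out[32, 32] > max(out[(rr - 32)^2 + (cc - 32)^2 >= 20^2]))

  # radially symmetric kernel: response commutes with 90-degree rotation
  set.seed(5)
  px <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  rot90 <- function(m) t(m)[, nrow(m):1]
  a <- mexican_hat(raster_image(rot90(px), 1), 9)$pixels
  b <- rot90(mexican_hat(raster_image(px, 1), 9)$pixels)
  expect_equal(a, b)
})
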