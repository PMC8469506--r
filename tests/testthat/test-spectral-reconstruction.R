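# RGB -> 401-band spectral reconstruction: transfer curves, feature
# expansion, the conversion fit and its per-pixel application.

test_that("transfer linearization matches the standard piecewise curve", {
  expect_equal(linearize_rgb(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(linearize_rgb(c(1, 1, 1)), c(1, 1, 1))
  # mid-gray through the standard curve: ((0.5 + 0.055) / 1.055)^2.4
  expect_equal(linearize_rgb(c(0.5, 0.5, 0.5)),
               rep(((0.5 + 0.055) / 1.055)^2.4, 3), tolerance = 1e-12)
  expect_equal(linearize_rgb(c(0.3, 0.7, 0.2), "identity"), c(0.3, 0.7, 0.2))
  # monotone channel-wise, and encode inverts
  v <- seq(0, 1, length.out = 50)
  for (tr in c("srgb", "gamma", "identity")) {
    lin <- linearize_rgb(v, tr)
    expect_true(all(diff(lin) > 0))
    expect_equal(encode_rgb(lin, tr), v, tolerance = 1e-12)
  }
  expect_error(linearize_rgb(c(0.2, 1.4, 0.1)), "out of \\[0,1\\].*g")
  expect_error(linearize_rgb(c(-0.1, 0.4, 0.1)), "out of \\[0,1\\].*r")
})

test_that("feature expansion enumerates all monomials up to the degree", {
  f1 <- expand_features(c(0.2, 0.4, 0.6), degree = 1)
  expect_equal(as.numeric(f1), c(1, 0.2, 0.4, 0.6))
  expect_equal(colnames(f1), c("1", "r", "g", "b"))
  # monomial counts choose(degree + 3, 3)
  expect_equal(ncol(expand_features(c(0.1, 0.2, 0.3), degree = 2)), 10)
  f3 <- expand_features(c(0, 0, 0), degree = 3)
  expect_equal(ncol(f3), 20)
  expect_equal(as.numeric(f3), c(1, rep(0, 19)))
  expect_equal(feature_count(2), 10)
  expect_equal(feature_count(3), 20)
  # documented degree-2 ordering
  f2 <- expand_features(c(2, 3, 5), degree = 2)
  expect_equal(as.numeric(f2), c(1, 2, 3, 5, 4, 6, 10, 9, 15, 25))
  expect_error(expand_features(c(0.1, 0.2, 0.3), degree = 0), "degree")
})

test_that("least squares recovers an exactly linear spectral model", {
  fx <- make_exact_linear_fixture(degree = 2)
  cal <- spectral_calibration(fx$rgb, fx$reference, degree = 2, ridge = 0,
                              linearized = TRUE)
  expect_false(cal$rank_deficient)
  expect_true(all(cal$rmse_per_patch <= 1e-9))
  expect_equal(cal$coefficients, fx$m_true, tolerance = 1e-6,
               ignore_attr = TRUE)
  # consistency: a 1x1 image equal to a training patch reproduces its
  # reference spectrum
  sp <- predict(cal, fx$rgb[7, ])
  expect_lt(spectrum_rmse(as.numeric(sp), fx$reference[7, ]), 1e-9)
  expect_equal(dim(coef(cal)), c(10, 401))
})

test_that("degree-3 fit has a 20 x 401 conversion matrix", {
  target <- make_color_target(seed = 1)
  cam <- camera_model("wli")
  cal <- spectral_calibration(capture_color_target(target, cam), target,
                              degree = 3, ridge = 1e-6)
  expect_equal(dim(cal$coefficients), c(20, 401))
  # synthetic-target regression fixture: mean training RMSE well under
  # 0.02 reflectance
  expect_lt(mean(cal$rmse_per_patch), 0.02)
  expect_true(all(cal$rmse_per_patch >= 0))
})

test_that("fitted coefficients are a least-squares optimum (lambda = 0)", {
  fx <- make_exact_linear_fixture(degree = 2, seed = 7)
  # make the problem non-exact so the optimum is interior
  set.seed(8)
  ref <- pmin(pmax(fx$reference + matrix(rnorm(24 * 401, sd = 0.01), 24), 0), 1.5)
  cal <- spectral_calibration(fx$rgb, ref, degree = 2, ridge = 0,
                              linearized = TRUE)
  x <- expand_features(fx$rgb, 2)
  sse <- function(b) sum((x %*% b - ref)^2)
  base <- sse(cal$coefficients)
  set.seed(9)
  for (i in 1:25) {
    b2 <- cal$coefficients
    b2[sample(10, 1), sample(401, 1)] <- b2[sample(10, 1), sample(401, 1)] +
      sample(c(-1e-3, 1e-3), 1)
    expect_gte(sse(b2), base)
  }
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  fx <- make_exact_linear_fixture(degree = 1, seed = 11)
  rgb <- fx$rgb
  rgb[, 3] <- rgb[, 1]           # collinear channels: rank-deficient design
  x <- expand_features(rgb, 1)
  ref <- x %*% fx$m_true[1:4, ]
  cal <- spectral_calibration(rgb, ref, degree = 1, ridge = 0,
                              linearized = TRUE)
  expect_true(cal$rank_deficient)
  expect_true(all(cal$rmse_per_patch <= 1e-9))  # still fits the data
})

test_that("per-pixel application preserves geometry and clips negatives", {
  fx <- make_exact_linear_fixture(degree = 2, zero_constant = TRUE)
  cal <- spectral_calibration(fx$rgb, fx$reference, degree = 2, ridge = 0,
                              linearized = TRUE)
  img <- array(0, dim = c(5, 4, 3))
  cube <- predict(cal, img)
  expect_s3_class(cube, "spectral_cube")
  expect_equal(dim(cube), c(5, 4, 401))
  # all-black image with (numerically) zero constant row -> zero spectra
  expect_lt(max(abs(cube$values)), 1e-8)
  # negative clipping
  m <- matrix(c(1, rep(0, 9)), 1) # constant-only design row
  cal_neg <- cal
  cal_neg$coefficients[1, ] <- -0.1
  sp <- predict(cal_neg, c(0, 0, 0))
  expect_true(all(sp >= 0))
  expect_gt(attr(sp, "clip_rate"), 0)
})

test_that("degree-1 reconstruction is homogeneous in exposure", {
  # scaling all linear patch RGBs and the test pixel by the same factor
  # scales the non-constant part of the reconstruction identically
  fx <- make_exact_linear_fixture(degree = 1, seed = 21, zero_constant = TRUE)
  cal <- spectral_calibration(fx$rgb, fx$reference, degree = 1, ridge = 0,
                              linearized = TRUE)
  px <- c(0.4, 0.3, 0.6)
  for (s in c(0.25, 0.5)) {
    cal_s <- spectral_calibration(fx$rgb * s, fx$reference, degree = 1,
                                  ridge = 0, linearized = TRUE)
    expect_equal(as.numeric(predict(cal_s, px * s)),
                 as.numeric(predict(cal, px)), tolerance = 1e-8)
  }
})

test_that("spectrum_rmse has its closed forms and rejects grid mismatch", {
  a <- rep(0.2, 401)
  expect_equal(spectrum_rmse(a, a), 0)
  expect_equal(spectrum_rmse(a, a + 0.1), 0.1)
  expect_equal(spectrum_rmse(rep(0.2, 401), rep(0.5, 401)), 0.3)
  expect_error(spectrum_rmse(a, rep(0.2, 400)), "grid mismatch")
})
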