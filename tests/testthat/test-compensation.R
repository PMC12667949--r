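test_that("middle-bout selection returns exactly k - 2 bouts per epoch", {
  for (k in c(2, 3, 7)) {
    rec <- generate_recording(swimmer_params(duration_h = 0.5, seed = 40 + k,
                                             max_bouts = k))
    seg <- seg_of(rec)
    mid <- select_middle_bouts(seg)
    expect_equal(nrow(mid), max(0, nrow(seg$bouts) - 2))
    if (nrow(mid) > 0) {
      expect_true(all(is.finite(mid$prev_drift)))
      expect_true(all(is.finite(mid$next_drift)))
    }
  }
})

test_that("long/short IBI classification uses a strict median threshold", {
  cls <- classify_ibi(1:5, reference = 1:5)
  expect_equal(attr(cls, "threshold"), 3)
  expect_equal(unname(cls == "long"), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # ties at the threshold are short
  expect_true(all(classify_ibi(rep(3, 10), reference = 1:5) == "short"))
  expect_error(classify_ibi(1:3, numeric(0)), "empty reference")

  # well-separated bimodal mixture: the reference is a 50/50 mix, so its
  # median falls between the modes and the long fraction of a 70/30 test
  # sample equals the long-mode weight
  set.seed(77)
  short_mode <- function(n) rgamma(n, shape = 16, scale = 0.05)  # ~0.8 s
  long_mode <- function(n) rgamma(n, shape = 16, scale = 0.30)   # ~4.8 s
  ref <- c(short_mode(2500), long_mode(2500))
  mix <- c(short_mode(3500), long_mode(1500))
  got <- classify_ibi(mix, ref)
  expect_lt(abs(mean(got == "long") - 0.3), 0.02)
})

test_that("bisquare regression recovers an exact line and resists gross outliers", {
  set.seed(55)
  x <- rnorm(400, -8, 4)
  y <- -0.8 * x
  f <- fit_compensation(x, y)
  expect_equal(f$slope, -0.8, tolerance = 1e-9)
  expect_equal(f$gain, 0.8, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_true(f$converged)

  # 5% gross outliers at +40 deg on the largest drifts: ordinary least
  # squares (independent oracle) is pulled, the bisquare fit is not
  y2 <- y + rnorm(400, 0, 0.5)
  out_idx <- order(x)[1:20]
  y2[out_idx] <- 40
  fb <- fit_compensation(x, y2)
  ols <- stats::lm(y2 ~ x)
  expect_lt(abs(fb$slope - (-0.8)), 0.02)
  expect_gt(abs(coef(ols)[2] - (-0.8)), 0.1)

  expect_error(fit_compensation(rep(1, 20), rnorm(20)), "zero variance")
  expect_error(fit_compensation(1:5, 1:5), "at least 10")
})

test_that("bisquare agrees with least squares on clean Gaussian data and with MASS::rlm", {
  set.seed(56)
  n <- 1e4
  x <- rnorm(n, 0, 5)
  y <- 1.5 - 0.6 * x + rnorm(n, 0, 0.1)
  f <- fit_compensation(x, y)
  ols <- stats::lm(y ~ x)
  expect_lt(abs(f$slope - unname(coef(ols)[2])), 1e-3)
  expect_lt(abs(f$intercept - unname(coef(ols)[1])), 1e-3)
  skip_if_not_installed("MASS")
  set.seed(57)
  xo <- rnorm(500, -5, 3)
  yo <- -0.9 * xo + rnorm(500, 0, 1)
  yo[1:25] <- yo[1:25] + 30
  f2 <- fit_compensation(xo, yo)
  rlm_fit <- MASS::rlm(yo ~ xo, psi = MASS::psi.bisquare, maxit = 100)
  expect_lt(abs(f2$slope - unname(coef(rlm_fit)[2])), 0.02)
})

test_that("null data yields a near-zero slope and a non-significant bootstrap p", {
  set.seed(58)
  x <- rnorm(2000, -8, 3)
  y <- rnorm(2000, 0, 2)
  f <- fit_compensation(x, y)
  expect_lt(abs(f$slope), 0.05)
  p <- bootstrap_slope_p(x, y, B = 400, seed = 3)
  expect_gt(as.numeric(p), 0.05)
})

test_that("bootstrap p is deterministic, bounded and detects strong relations", {
  set.seed(59)
  x <- rnorm(500, -8, 4)
  y <- -0.8 * x + rnorm(500, 0, 2.6)   # R^2 around 0.6
  p1 <- bootstrap_slope_p(x, y, B = 2999, seed = 11)
  p2 <- bootstrap_slope_p(x, y, B = 2999, seed = 11)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_lt(as.numeric(p1), 0.001)
  expect_gte(as.numeric(p1), 2 / 3000)  # add-one correction floor
  expect_error(bootstrap_slope_p(x, y, B = 0), "positive")
})

test_that("compensation residuals and MAD variability behave as defined", {
  expect_equal(compensation_residuals(-5, 5)$residuals, 0)
  expect_equal(compensation_residuals(rep(-3, 20), rep(5, 20))$variability, 0)

  # oracle: MAD of simulated residuals equals direct computation
  set.seed(60)
  drift <- rnorm(3000, -6, 3)
  rot <- -1.0 * drift + rnorm(3000, 0, 2)
  rs <- compensation_residuals(drift, rot)
  r <- drift + rot
  expect_equal(rs$variability, median(abs(r - median(r))))
  # with gain 1 the residual is pure noise: MAD ~ 0.6745 * sigma
  expect_lt(abs(rs$variability - 0.6745 * 2), 0.15)

  # translation invariance and linear scaling
  rs2 <- compensation_residuals(drift + 10, rot)
  expect_equal(rs2$variability, rs$variability)
  rs3 <- compensation_residuals(3 * drift, 3 * rot)
  expect_equal(rs3$variability, 3 * rs$variability, tolerance = 1e-12)
})

test_that("gain is recovered from simulated drift/rotation pairs across g", {
  set.seed(61)
  for (g in c(0.5, 0.86, 1.0)) {
    drift <- -3 * (0.3 + rexp(3000, 1 / 2.3))
    rot <- -g * drift + rnorm(3000, 0, 2)
    f <- fit_compensation(drift, rot)
    expect_lt(abs(f$gain - g), 0.05)
  }
})

test_that("the four-way compensation report has the expected layout", {
  rec <- generate_recording(swimmer_params(
    duration_h = 1, seed = 62,
    dark = strategy_params(rotation_noise = 2, drift_rate = 3)))
  seg <- seg_of(rec)
  rep <- compensation_report(seg, bootstrap_B = 50, seed = 1)
  expect_equal(nrow(rep), 4)
  expect_setequal(rep$ibi_class, c("long", "short"))
  expect_setequal(rep$ibi_side, c("previous", "next"))
  expect_true(all(rep$gain >= 0, na.rm = TRUE))
  expect_true(all(rep$bootstrap_p >= 0 & rep$bootstrap_p <= 1, na.rm = TRUE))
  # with a strong programmed gain, the long-previous cell is significant
  lp <- rep[rep$ibi_class == "long" & rep$ibi_side == "previous", ]
  expect_lt(abs(lp$gain - 0.86), 0.1)
})
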