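test_that("welch_psd concentrates a 10 Hz tone in the alpha band", {
  fs <- 1000
  x <- tone_matrix(10, fs, 8, n_regions = 1)
  sp <- welch_psd(x, fs = fs, window_s = 4)
  sel <- sp$freqs >= 8 & sp$freqs <= 13
  expect_gt(sum(sp$psd[sel, 1]) / sum(sp$psd[, 1]), 0.95)
  expect_true(all(sp$psd >= 0))
  expect_true(all(diff(sp$freqs) > 0))
})

test_that("welch_psd satisfies Parseval consistency for stationary noise", {
  set.seed(1)
  fs <- 250
  x <- matrix(rnorm(20 * fs), ncol = 1)
  sp <- welch_psd(x, fs = fs, window_s = 4)
  f <- sp$freqs
  p <- sp$psd[, 1]
  integral <- sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
  expect_lt(abs(integral - var(x[, 1])) / var(x[, 1]), 0.05)
})

test_that("welch_psd of a constant signal has zero power at nonzero frequencies", {
  fs <- 250
  x <- matrix(7.3, nrow = 4 * fs, ncol = 1)
  sp <- welch_psd(x, fs = fs, window_s = 2)
  expect_equal(max(sp$psd[sp$freqs > 0, 1]), 0)
})

test_that("white-noise alpha share matches the flat-spectrum proportion", {
  fs <- 250
  shares <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(30 * fs), ncol = 1)
    sp <- welch_psd(x, fs = fs, window_s = 4)
    f <- sp$freqs
    p <- sp$psd[, 1]
    band_int <- function(sel) sum(diff(f[sel]) *
                                    (head(p[sel], -1) + tail(p[sel], -1)) / 2)
    band_int(f >= 8 & f <= 13) / band_int(f >= 0)
  }, numeric(1))
  expect_lt(abs(mean(shares) - 5 / (fs / 2)), 0.15 * 5 / (fs / 2))
})

test_that("welch_psd rejects series shorter than one window", {
  expect_error(welch_psd(matrix(rnorm(100), ncol = 1), fs = 250, window_s = 4),
               "shorter than one window")
})

test_that("alpha_power is linear, averages regions, and ignores out-of-band tones", {
  fs <- 250
  x <- tone_matrix(10, fs, 12, n_regions = 1)
  sp <- welch_psd(x, fs = fs)
  a1 <- alpha_power(sp)
  sp2 <- sp
  sp2$psd <- 2 * sp$psd
  expect_equal(alpha_power(sp2), 2 * a1)

  # two regions with band powers p and 3p average to 2p
  sp3 <- sp
  sp3$psd <- cbind(sp$psd[, 1], 3 * sp$psd[, 1])
  expect_equal(alpha_power(sp3), 2 * a1)

  # 20 Hz tone: residual leakage well below 1% of the in-band tone power
  y <- tone_matrix(20, fs, 12, n_regions = 1)
  spy <- welch_psd(y, fs = fs)
  expect_lt(alpha_power(spy), 0.01 * a1)
})

test_that("alpha_power rejects a band outside the grid", {
  sp <- welch_psd(tone_matrix(10, 250, 8), fs = 250)
  expect_error(alpha_power(sp, band = c(8, 1000)), "outside")
})

test_that("PLV is 1 for identical and constant-lag signals", {
  fs <- 250
  x <- tone_matrix(10, fs, 20, n_regions = 1)
  lagged <- tone_matrix(10, fs, 20, n_regions = 1, phase = 0)  # base
  xy <- cbind(x, x)
  p1 <- plv_matrix(xy, fs = fs)
  expect_equal(p1$plv[1, 2], 1, tolerance = 1e-6)

  # quarter-cycle lag within the band keeps the phase difference constant
  xl <- cbind(tone_matrix(10, fs, 20), tone_matrix(10, fs, 20, phase = pi / 2))[, c(1, 4)]
  p2 <- plv_matrix(xl, fs = fs)
  expect_equal(p2$plv[1, 2], 1, tolerance = 1e-3)
})

test_that("independent-noise PLV matches the Rayleigh Monte-Carlo oracle", {
  fs <- 250
  n_s <- 12
  # oracle: 1000-replicate Monte-Carlo of |mean(unit phasors)| for
  # independent uniform phase-difference increments with the same effective
  # number of independent phase samples as the band-filtered series.
  # The alpha band (8-13 Hz) of white noise has about bw independent
  # phase samples per second.
  plvs <- vapply(1:24, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(2 * n_s * fs), ncol = 2)
    plv_matrix(x, fs = fs)$plv[1, 2]
  }, numeric(1))
  set.seed(4242)
  n_eff <- 5 * (n_s - 2)   # bandwidth x trimmed duration
  oracle <- vapply(1:1000, function(i)
    Mod(mean(exp(1i * runif(n_eff, 0, 2 * pi)))), numeric(1))
  expect_lt(abs(mean(plvs) - mean(oracle)) / mean(oracle), 0.15)
})

test_that("PLV is invariant to per-region amplitude rescaling", {
  set.seed(3)
  fs <- 250
  x <- matrix(rnorm(10 * fs * 2), ncol = 2)
  p1 <- plv_matrix(x, fs = fs)
  p2 <- plv_matrix(x %*% diag(c(7, 0.01)), fs = fs)
  expect_equal(p1$plv, p2$plv, tolerance = 1e-6)
})

test_that("plv_matrix enforces its preconditions", {
  fs <- 250
  expect_error(plv_matrix(matrix(rnorm(fs * 10), ncol = 1), fs = fs), "2 regions")
  const <- cbind(rep(1, 10 * fs), rnorm(10 * fs))
  expect_error(plv_matrix(const, fs = fs), "constant")
  short <- matrix(rnorm(2 * fs * 2), ncol = 2)
  expect_error(plv_matrix(short, fs = fs), "5 cycles")
})

test_that("plv matrix invariants hold on simulated-like input", {
  set.seed(9)
  fs <- 250
  x <- matrix(rnorm(8 * fs * 4), ncol = 4)
  p <- plv_matrix(x, fs = fs)
  expect_equal(p$plv, t(p$plv))
  expect_equal(diag(p$plv), rep(1, 4))
  expect_true(all(p$plv >= 0 & p$plv <= 1))
})

test_that("mean_plv averages the strict upper triangle", {
  m <- diag(3)
  m[upper.tri(m)] <- c(0.2, 0.4, 0.6)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  expect_equal(mean_plv(m), 0.4)
  expect_equal(mean_plv(diag(2)), 0)
  all_half <- matrix(0.5, 4, 4); diag(all_half) <- 1
  expect_equal(mean_plv(all_half), 0.5)
  expect_error(mean_plv(matrix(1, 1, 1)), "2 regions")
})

test_that("percent_change reproduces ratio arithmetic exactly", {
  b <- 3.7
  expect_equal(percent_change(2.566 * b, b), 156.6)
  expect_equal(percent_change(b, b), 0)
  expect_equal(percent_change(0.41 * b, b), -59)
  expect_error(percent_change(1, 0), "zero baseline")
})
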