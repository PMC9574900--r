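test_that("firing_rate is the saturating logistic with the exact closed form", {
  p <- ct_params()
  expect_equal(firing_rate(p$theta, p), p$Q_max / 2)
  expect_equal(firing_rate(-10, p), 0, tolerance = 1e-12)
  expect_equal(firing_rate(10, p), p$Q_max)
  expect_equal(firing_rate(p$theta + p$sigma_prime * log(3), p),
               0.75 * p$Q_max)
  v <- seq(-0.05, 0.05, length.out = 201)
  q <- firing_rate(v, p)
  expect_true(all(diff(q) > 0))
  expect_true(all(q > 0 & q < p$Q_max))
  expect_error(firing_rate(NaN, p), "finite")
})

test_that("parameter validation enforces the stated invariants", {
  expect_error(ct_params(Q_max = -1), "Q_max")
  expect_error(ct_params(alpha_d = 200, beta_d = 50), "beta_d > alpha_d")
  expect_error(ct_params(duration = 1, transient = 2), "duration")
  expect_error(ct_params(dt = 0), "dt")
  expect_error(coupling_set(nu_ei = 1e-3), "inhibitory-source")
  expect_error(coupling_set(nu_ee = -1e-3, random_connectivity = FALSE),
               "excitatory-source")
})

test_that("random intracortical connectivity ties the inhibitory afferents", {
  cs <- coupling_set()
  expect_equal(cs$nu_ie, cs$nu_ee)
  expect_equal(cs$nu_ii, cs$nu_ei)
  expect_equal(cs$nu_is, cs$nu_es)
})

test_that("steady state with zero couplings and zero drive is the origin", {
  cs <- coupling_set(nu_ee = 0, nu_ei = 0, nu_es = 0, nu_re = 0, nu_rs = 0,
                     nu_se = 0, nu_sr = 0, nu_sn = 0)
  p <- ct_params(couplings = cs, noise_mean = 0)
  ss <- steady_state(p)
  expect_equal(unname(ss$V), rep(0, 4), tolerance = 1e-9)
  expect_lt(ss$residual, 1e-9)
})

test_that("relay fixed point responds monotonically to excitatory drive", {
  p <- ct_params()
  drives <- c(0.5, 1, 2, 4)
  vs <- vapply(drives, function(d) steady_state(p, external_drive = d)$V[["s"]],
               numeric(1))
  expect_true(all(diff(vs) >= 0))
})

test_that("steady state satisfies the time-independent equations to tolerance", {
  p <- ct_params()
  ss <- steady_state(p)
  expect_lt(ss$residual, 1e-9)
  cs <- p$couplings
  Q <- ss$Q
  expect_equal(ss$V[["e"]],
               cs$nu_ee * Q[["e"]] + cs$nu_ei * Q[["i"]] + cs$nu_es * Q[["s"]],
               tolerance = 1e-8)
  expect_equal(ss$V[["s"]],
               cs$nu_se * Q[["e"]] + cs$nu_sr * Q[["r"]] +
                 cs$nu_sn * p$noise_mean, tolerance = 1e-8)
})

test_that("dendritic filter has unit DC gain and the closed-form impulse peak", {
  p <- ct_params()
  dt <- 1e-5
  # step response converges to the drive level (DC gain 1)
  n <- round(0.5 / dt)
  step <- .ct_dendritic_filter(rep(2.5, n), p$alpha_d, p$beta_d, dt)
  expect_equal(step[n], 2.5, tolerance = 1e-6)
  # impulse response peak at ln(beta/alpha)/(beta - alpha)
  imp <- numeric(n)
  imp[1] <- 1 / dt
  h <- .ct_dendritic_filter(imp, p$alpha_d, p$beta_d, dt)
  t_peak <- (which.max(h) - 1) * dt
  t_star <- log(p$beta_d / p$alpha_d) / (p$beta_d - p$alpha_d)
  expect_lt(abs(t_peak - t_star), 2 * dt)
})

test_that("connectome validation catches each invariant violation", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(connectome(W), "connectome")
  expect_error(connectome(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(connectome(matrix(c(1, 1, 1, 0), 2, 2)), "diagonal")
  expect_error(connectome(-W), ">= 0")
  W4 <- diag(4) * 0
  W4[1, 2] <- W4[2, 1] <- 1
  W4[3, 4] <- W4[4, 3] <- 1
  expect_error(connectome(W4), "connected")
  expect_error(connectome(W, global_coupling = -1), "global_coupling")
})
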