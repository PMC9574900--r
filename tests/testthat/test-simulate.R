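test_that("identical seed and configuration give bit-identical output", {
  p <- quick_params()
  cn <- small_connectome(n = 6, seed = 1)
  a <- simulate_network(p, cn, seed = 77)
  b <- simulate_network(p, cn, seed = 77)
  expect_identical(a$series, b$series)
  expect_identical(a$params_hash, b$params_hash)
  c2 <- simulate_network(p, cn, seed = 78)
  expect_false(identical(a$series, c2$series))
})

test_that("simulation output has the declared shape and finite values", {
  p <- quick_params()
  sim <- simulate_network(p, small_connectome(n = 5, seed = 2), seed = 1)
  expect_equal(nrow(sim$series),
               round((p$duration - p$transient) * sim$fs))
  expect_equal(ncol(sim$series), 5)
  expect_true(all(is.finite(sim$series)))
  expect_equal(sim$fs, 250)
})

test_that("zero global coupling reduces regions to independent units", {
  p <- quick_params(duration = 6, transient = 1)
  cn <- small_connectome(n = 4, seed = 3, gc = 0)
  sim <- simulate_network(p, cn, seed = 5)
  unit <- simulate_network(p, NULL, seed = 5)
  # marginal spectra of each region match the single-unit spectrum within
  # estimation error (same model, independent noise streams)
  spn <- welch_psd(sim, window_s = 2)
  spu <- welch_psd(unit, window_s = 2)
  sel <- spn$freqs >= 2 & spn$freqs <= 30
  ref <- spu$psd[sel, 1]
  for (j in 1:4) {
    rel <- sum(abs(spn$psd[sel, j] - ref)) / sum(ref)
    expect_lt(rel, 0.8)  # broad band-shape agreement at short duration
  }
})

test_that("noise-free simulation started at the fixed point stays there", {
  p <- quick_params(noise_std = 0, duration = 2, transient = 0)
  ss <- steady_state(p)
  sim <- simulate_network(p, NULL, seed = 1)
  expect_lt(max(abs(sim$series - ss$phi_e)), 1e-6 * max(1, abs(ss$phi_e)))
})

test_that("coupling scale preconditions and dt resolution are enforced", {
  p <- quick_params()
  cn <- small_connectome(n = 3, seed = 4)
  expect_error(simulate_network(p, cn, coupling_scales = c(0, 1)), "scales")
  expect_error(simulate_network(p, cn, coupling_scales = c(1, 1.2)), "scales")
  p2 <- quick_params(dt = 0.02)   # t0/dt = 4 < 10
  expect_error(simulate_network(p2, cn), "resolve t0")
  expect_error(simulate_network(p, cn, fs_out = 333), "divide")
})

test_that("divergent dynamics raise an instability signal naming the region", {
  # runaway positive feedback: strong excitatory self-coupling, no inhibition
  cs <- coupling_set(nu_ee = 80e-3, nu_ei = 0, nu_es = 1e-3,
                     nu_re = 0.1e-3, nu_rs = 0.1e-3, nu_se = 1e-3,
                     nu_sr = 0, nu_sn = 1e-3)
  p <- quick_params(couplings = cs, noise_mean = 30, noise_std = 0)
  init <- matrix(c(0.05, 0.05, 0, 0, 200), 1, 5)
  err <- tryCatch(simulate_network(p, NULL, seed = 1, init = init),
                  corthal_instability = function(e) e)
  expect_s3_class(err, "corthal_instability")
  expect_match(conditionMessage(err), "region")
  expect_match(conditionMessage(err), "step")
})

test_that("simulation export writes a table plus JSON sidecar", {
  p <- quick_params(duration = 1.5, transient = 0.5)
  sim <- simulate_network(p, small_connectome(n = 3, seed = 6), seed = 2)
  path <- tempfile(fileext = ".tsv")
  export_simulation(sim, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(sim$series))
  expect_equal(ncol(tab), 4)  # time + 3 regions
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$seed, 2)
  expect_equal(meta$fs, 250)
})

test_that("per-iteration seed derivation is deterministic and in integer range", {
  s1 <- vapply(0:50, function(i) corthal:::derive_seed(123, i), numeric(1))
  s2 <- vapply(0:50, function(i) corthal:::derive_seed(123, i), numeric(1))
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_equal(length(unique(s1)), 51)
})
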