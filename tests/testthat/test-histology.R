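make_records <- function() generate_histology(histology_sim_config(seed = 11))

test_that("aggregate_rois averages same-type ROIs and keeps tissue types separate", {
  rec <- data.frame(
    subject_id = "S1", group = "NAGM", marker = "exc_synapse", layer = "VI",
    roi_id = c("r1", "r2"), density = c(100, 140),
    age = 60, sex = "F", pmd = 300)
  agg <- aggregate_rois(rec)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$density, 120)

  # one NAGM and one DEMYEL ROI stay separate
  rec2 <- rec
  rec2$group <- c("NAGM", "DEMYEL")
  agg2 <- aggregate_rois(rec2)
  expect_equal(nrow(agg2), 2)
  expect_setequal(as.character(agg2$group), c("NAGM", "DEMYEL"))

  # single ROI unchanged, and aggregation is idempotent
  one <- rec[1, ]
  expect_equal(aggregate_rois(one)$density, 100)
  big <- make_records()
  once <- aggregate_rois(big)
  twice <- aggregate_rois(once)
  expect_equal(twice$density, once$density)
  expect_equal(nrow(twice), nrow(once))
})

test_that("validation rejects conflicting covariates and malformed records", {
  rec <- data.frame(
    subject_id = "S1", group = "NAGM", marker = "exc_synapse", layer = "VI",
    roi_id = c("r1", "r2"), density = c(100, 140),
    age = c(60, 61), sex = "F", pmd = 300)
  expect_error(aggregate_rois(rec), "conflicting covariates")
  rec$age <- 60
  rec$density[1] <- -5
  expect_error(aggregate_rois(rec), "density")
  rec$density[1] <- 100
  rec$layer <- NA
  expect_error(validate_density_records(rec), "layer")
})

test_that("percent_difference reproduces the printed contrasts exactly", {
  expect_equal(percent_difference(851, 1000), -14.9)
  expect_equal(percent_difference(707, 1000), -29.3)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "reference")
})

test_that("mixed-model stage recovers the injected layer-VI percent losses", {
  rec <- aggregate_rois(make_records())
  fit <- fit_density_model(rec, marker_class = "synapse")
  expect_s3_class(fit, "density_fit")
  expect_true(all(c("exc_synapse", "inh_synapse") %in% fit$interaction$marker))
  ctr <- fit$contrasts
  vi_inh <- ctr[ctr$marker == "inh_synapse" & ctr$layer == "VI" &
                  ctr$comparison == "NAGM vs NC", ]
  expect_equal(nrow(vi_inh), 1)
  expect_true(vi_inh$ci_low <= vi_inh$estimate &
                vi_inh$estimate <= vi_inh$ci_high)

  # small-ensemble recovery of the injected contrasts (tight 200-replicate
  # calibration is covered in the acceptance suite)
  pct <- t(vapply(1:6, function(s) {
    r <- aggregate_rois(generate_histology(histology_sim_config(seed = 50 + s)))
    d <- fit_density_model(r, marker_class = "synapse",
                           follow_up = "always")$contrasts
    c(nagm = d$pct_diff[d$marker == "inh_synapse" & d$layer == "VI" &
                          d$comparison == "NAGM vs NC"],
      dem = d$pct_diff[d$marker == "inh_synapse" & d$layer == "VI" &
                         d$comparison == "DEMYEL vs NC"])
  }, numeric(2)))
  expect_lt(abs(mean(pct[, "nagm"]) - (-14.9)), 5)
  expect_lt(abs(mean(pct[, "dem"]) - (-29.3)), 5)
})

test_that("percent differences are invariant to density unit rescaling", {
  rec <- aggregate_rois(make_records())
  fit1 <- fit_density_model(rec, marker_class = "synapse",
                            follow_up = "always")
  rec2 <- rec
  rec2$density <- rec2$density * 1000
  fit2 <- fit_density_model(rec2, marker_class = "synapse",
                            follow_up = "always")
  expect_equal(fit1$contrasts$pct_diff, fit2$contrasts$pct_diff,
               tolerance = 1e-6)
  expect_equal(fit1$contrasts$estimate * 1000, fit2$contrasts$estimate,
               tolerance = 1e-6)
})

test_that("neuron markers are fitted without a layer term", {
  rec <- aggregate_rois(make_records())
  fit <- fit_density_model(rec, marker_class = "neuron")
  expect_null(fit$interaction)
  expect_true(all(is.na(fit$contrasts$layer)))
  expect_setequal(unique(fit$contrasts$marker), c("NeuN", "PV", "CR"))
})

test_that("degenerate constant input yields a diagnostic, not a crash", {
  cfg <- histology_sim_config(between_subject_sd = 0, within_subject_sd = 0,
                              effect_multiplier = data.frame(
                                group = character(), marker = character(),
                                layer = character(), multiplier = numeric()),
                              seed = 2)
  rec <- aggregate_rois(generate_histology(cfg))
  fit <- fit_density_model(rec, marker_class = "synapse",
                           follow_up = "always")
  expect_s3_class(fit, "density_fit")
  expect_true(length(fit$meta$diagnostics) > 0)
  if (nrow(fit$contrasts))
    expect_true(all(abs(fit$contrasts$estimate) < 1e-6, na.rm = TRUE))
})

test_that("zero-variance subject effect makes mixed and fixed models agree", {
  cfg <- histology_sim_config(between_subject_sd = 0, seed = 8)
  rec <- aggregate_rois(generate_histology(cfg))
  d <- droplevels(rec[rec$marker == "inh_synapse" & rec$layer == "VI", ])
  fit <- suppressMessages(lmerTest::lmer(
    density ~ group + age + sex + pmd + (1 | subject_id), data = d,
    control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4))))
  ols <- lm(density ~ group + age + sex + pmd, data = d)
  expect_equal(lme4::fixef(fit)[["groupNAGM"]], coef(ols)[["groupNAGM"]],
               tolerance = 0.02)
})
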