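#' Default effect-multiplier presets for the histology generator
#'
#' One row per group x marker x layer cell whose density deviates from
#' baseline.  The default presets inject the measured layer-VI percent
#' losses: NAGM -12.5% excitatory / -14.9% inhibitory; demyelinated cortex
#' -18.5% / -29.3%.  The transient layer-I excitatory increase is available
#' as an optional preset (off by default, since it did not survive
#' NeuN-covariate correction).
#'
#' @param layer_I_excitatory include a +8% layer-I excitatory NAGM effect?
#' @return data.frame with columns `group`, `marker`, `layer`,
#'   `multiplier`.
#' @export
default_effect_multipliers <- function(layer_I_excitatory = FALSE) {
  eff <- data.frame(
    group = c("NAGM", "NAGM", "DEMYEL", "DEMYEL"),
    marker = c("exc_synapse", "inh_synapse", "exc_synapse", "inh_synapse"),
    layer = c("VI", "VI", "VI", "VI"),
    multiplier = c(0.875, 0.851, 0.815, 0.707))
  if (layer_I_excitatory)
    eff <- rbind(eff, data.frame(group = "NAGM", marker = "exc_synapse",
                                 layer = "I", multiplier = 1.08))
  eff
}

#' Configuration for the synthetic histology generator
#'
#' Emulates the nested post-mortem design: `n_nc` control subjects with two
#' normal-cortex ROIs each; `n_ms` MS subjects of whom `n_ms_with_demyel`
#' carry demyelinated cortex -- `n_ms_demyel_only` of those contribute two
#' demyelinated ROIs and the rest one NAGM plus one demyelinated ROI; the
#' remaining MS subjects contribute two NAGM ROIs.  The defaults aggregate
#' to 9 NC, 29 NAGM and 13 demyelinated measurement units.  Densities are
#' log-normal around `baseline * multiplier` with a subject-level random
#' effect and ROI-level noise (both on the log scale); covariates are
#' sampled per group, with post-mortem delay markedly shorter in MS.
#'
#' @param n_nc,n_ms,n_ms_with_demyel,n_ms_demyel_only group structure (see
#'   above); requires `n_ms >= n_ms_with_demyel >= n_ms_demyel_only`.
#' @param rois_per_subject ROIs sampled per subject (default 2).
#' @param baseline_synapse named per-layer baseline synapse density
#'   (counts/mm^2), shared by both synapse markers.
#' @param baseline_neuron named per-marker baseline neuron density.
#' @param effect_multiplier data.frame of group x marker x layer
#'   multipliers; see [default_effect_multipliers()].
#' @param between_subject_sd,within_subject_sd log-scale standard
#'   deviations of the subject effect and ROI noise.
#' @param seed integer seed.
#' @return Object of class `histology_sim_config`.
#' @export
histology_sim_config <- function(n_nc = 9, n_ms = 33, n_ms_with_demyel = 13,
                                 n_ms_demyel_only = 4, rois_per_subject = 2,
                                 baseline_synapse = c(I = 1200, II = 1400,
                                                      III = 1300, VI = 1000),
                                 baseline_neuron = c(NeuN = 100, PV = 12, CR = 15),
                                 effect_multiplier = default_effect_multipliers(),
                                 between_subject_sd = 0.10,
                                 within_subject_sd = 0.08,
                                 seed = 1L) {
  if (n_ms_with_demyel > n_ms || n_ms_demyel_only > n_ms_with_demyel)
    stop("histology_sim_config: need n_ms >= n_ms_with_demyel >= n_ms_demyel_only",
         call. = FALSE)
  stopifnot(n_nc >= 1, n_ms >= 1, rois_per_subject >= 1,
            between_subject_sd >= 0, within_subject_sd >= 0,
            all(baseline_synapse > 0), all(baseline_neuron > 0),
            all(effect_multiplier$multiplier > 0))
  structure(list(n_nc = n_nc, n_ms = n_ms,
                 n_ms_with_demyel = n_ms_with_demyel,
                 n_ms_demyel_only = n_ms_demyel_only,
                 rois_per_subject = rois_per_subject,
                 baseline_synapse = baseline_synapse,
                 baseline_neuron = baseline_neuron,
                 effect_multiplier = effect_multiplier,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 seed = as.integer(seed)),
            class = "histology_sim_config")
}

# multiplier lookup with default 1
lookup_multiplier <- function(eff, group, marker, layer) {
  hit <- eff$group == group & eff$marker == marker &
    (is.na(layer) | eff$layer %in% layer)
  if (any(hit)) eff$multiplier[hit][1] else 1
}

#' Generate a synthetic nested histology density table
#'
#' Draws ROI-level densities for all synapse markers (four cortical layers)
#' and neuron markers (whole cortex) under the nested design described in
#' [histology_sim_config()]:
#' `log(density) = log(baseline * multiplier) + b_subject + e_roi` with
#' `b_subject ~ N(0, between_subject_sd^2)` per subject x marker and
#' `e_roi ~ N(0, within_subject_sd^2)` per record.  Deterministic under the
#' config seed.
#'
#' @param cfg a [histology_sim_config()].
#' @return data.frame of ROI-level density records (see
#'   [validate_density_records()]).
#' @export
generate_histology <- function(cfg = histology_sim_config()) {
  stopifnot(inherits(cfg, "histology_sim_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(cfg$seed)

  n_mixed <- cfg$n_ms_with_demyel - cfg$n_ms_demyel_only
  subjects <- data.frame(
    subject_id = c(sprintf("NC%02d", seq_len(cfg$n_nc)),
                   sprintf("MS%02d", seq_len(cfg$n_ms))),
    cohort = c(rep("NC", cfg$n_nc), rep("MS", cfg$n_ms)))
  # ROI tissue types per subject
  roi_types <- function(k) {
    if (subjects$cohort[k] == "NC") return(rep("NC", cfg$rois_per_subject))
    idx <- k - cfg$n_nc
    if (idx <= cfg$n_ms_demyel_only) rep("DEMYEL", cfg$rois_per_subject)
    else if (idx <= cfg$n_ms_demyel_only + n_mixed)
      c("NAGM", "DEMYEL", rep("NAGM", max(0, cfg$rois_per_subject - 2)))
    else rep("NAGM", cfg$rois_per_subject)
  }

  # covariates: age and sex comparable across cohorts, pmd shorter in MS
  ns <- nrow(subjects)
  is_ms <- subjects$cohort == "MS"
  subjects$age <- round(ifelse(is_ms, rnorm(ns, 62, 10), rnorm(ns, 71, 6)))
  subjects$age <- pmin(pmax(subjects$age, 35), 95)
  subjects$sex <- ifelse(runif(ns) < ifelse(is_ms, 0.64, 0.56), "F", "M")
  subjects$pmd <- round(pmax(ifelse(is_ms, rnorm(ns, 330, 70),
                                    rnorm(ns, 570, 140)), 90))

  markers <- c(SYNAPSE_MARKERS, NEURON_MARKERS)

  # ROI table: one row per subject x ROI with its tissue type
  rois <- do.call(rbind, lapply(seq_len(ns), function(k) {
    types <- roi_types(k)
    data.frame(subj_idx = k, subject_id = subjects$subject_id[k],
               group = types,
               roi_id = sprintf("%s_roi%d", subjects$subject_id[k],
                                seq_along(types)))
  }))

  # subject-level random effect, one per subject x marker (log scale)
  b_subj <- matrix(rnorm(ns * length(markers), 0, cfg$between_subject_sd),
                   ns, length(markers), dimnames = list(NULL, markers))

  layers <- names(cfg$baseline_synapse)
  syn <- expand.grid(row = seq_len(nrow(rois)), marker = SYNAPSE_MARKERS,
                     layer = layers, stringsAsFactors = FALSE)
  neu <- expand.grid(row = seq_len(nrow(rois)), marker = NEURON_MARKERS,
                     stringsAsFactors = FALSE)
  neu$layer <- NA_character_
  recs <- rbind(syn, neu)

  base <- ifelse(is.na(recs$layer),
                 cfg$baseline_neuron[recs$marker],
                 cfg$baseline_synapse[recs$layer])
  mult <- rep(1, nrow(recs))
  eff <- cfg$effect_multiplier
  for (e in seq_len(nrow(eff))) {
    hit <- rois$group[recs$row] == eff$group[e] & recs$marker == eff$marker[e] &
      (!is.na(recs$layer) & recs$layer == eff$layer[e])
    if (eff$marker[e] %in% NEURON_MARKERS)
      hit <- rois$group[recs$row] == eff$group[e] & recs$marker == eff$marker[e]
    mult[hit] <- eff$multiplier[e]
  }
  bs <- b_subj[cbind(rois$subj_idx[recs$row], match(recs$marker, markers))]
  dens <- exp(log(base * mult) + bs + rnorm(nrow(recs), 0, cfg$within_subject_sd))

  out <- data.frame(subject_id = rois$subject_id[recs$row],
                    group = rois$group[recs$row],
                    marker = recs$marker, layer = recs$layer,
                    roi_id = rois$roi_id[recs$row], density = dens,
                    age = subjects$age[rois$subj_idx[recs$row]],
                    sex = subjects$sex[rois$subj_idx[recs$row]],
                    pmd = subjects$pmd[rois$subj_idx[recs$row]])
  rownames(out) <- NULL
  validate_density_records(out)
}
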