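DENSITY_COLS <- c("subject_id", "group", "marker", "layer", "roi_id",
                  "density", "age", "sex", "pmd")
SYNAPSE_MARKERS <- c("exc_synapse", "inh_synapse")
NEURON_MARKERS <- c("NeuN", "PV", "CR")
GROUPS <- c("NC", "NAGM", "DEMYEL")
LAYERS <- c("I", "II", "III", "VI")

#' Validate a long-format density table
#'
#' One row per ROI-level density measurement: subject, tissue type (`NC`,
#' `NAGM`, `DEMYEL`), marker (`exc_synapse`/`inh_synapse` with a cortical
#' layer, or `NeuN`/`PV`/`CR` whole-cortex with layer `NA`), ROI id,
#' density in counts/mm^2 (> 0), and the subject-level covariates age
#' (years), sex, and post-mortem delay `pmd` (minutes), which must be
#' constant within a subject.
#'
#' @param records data.frame of ROI-level records.
#' @return The validated data.frame (invisibly usable), with `group`,
#'   `marker`, `layer`, `sex` as factors.
#' @export
validate_density_records <- function(records) {
  missing_cols <- setdiff(DENSITY_COLS, names(records))
  if (length(missing_cols))
    stop("density records: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records$group <- factor(as.character(records$group), levels = GROUPS)
  records$marker <- factor(as.character(records$marker),
                           levels = c(SYNAPSE_MARKERS, NEURON_MARKERS))
  records$layer <- factor(as.character(records$layer), levels = LAYERS)
  records$sex <- factor(records$sex)
  if (any(is.na(records$group))) stop("density records: unknown group", call. = FALSE)
  if (any(is.na(records$marker))) stop("density records: unknown marker", call. = FALSE)
  if (any(!is.finite(records$density) | records$density <= 0))
    stop("density records: density must be > 0", call. = FALSE)
  syn <- records$marker %in% SYNAPSE_MARKERS
  if (any(is.na(records$layer[syn])))
    stop("density records: synapse records must carry a layer", call. = FALSE)
  if (any(!is.na(records$layer[!syn])))
    stop("density records: neuron records must not carry a layer", call. = FALSE)
  cov_chk <- tapply(seq_len(nrow(records)), records$subject_id, function(idx) {
    length(unique(records$age[idx])) == 1 &&
      length(unique(as.character(records$sex[idx]))) == 1 &&
      length(unique(records$pmd[idx])) == 1
  })
  if (any(!cov_chk))
    stop("density records: conflicting covariates within subject(s): ",
         paste(names(cov_chk)[!cov_chk], collapse = ", "), call. = FALSE)
  records
}

#' Average same-type ROIs within subject
#'
#' Within each subject, ROI measurements of the same tissue type, marker
#' and layer are replaced by their arithmetic mean; differing tissue types
#' are kept separate, so a subject can contribute both a NAGM and a
#' demyelinated measurement.  Idempotent.
#'
#' @param records ROI-level density records (see
#'   [validate_density_records()]).
#' @return Aggregated records, one row per subject x group x marker x
#'   layer, with `roi_id` set to `"pooled"`.
#' @export
aggregate_rois <- function(records) {
  records <- validate_density_records(records)
  key <- interaction(records$subject_id, records$group, records$marker,
                     addNA(records$layer), drop = TRUE)
  agg <- lapply(split(records, key), function(d) {
    out <- d[1, , drop = FALSE]
    out$density <- mean(d$density)
    out$roi_id <- "pooled"
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$marker, out$layer, out$group, out$subject_id), ]
}

#' Percent difference between adjusted group means
#'
#' `100 * (a - ref) / ref`; the convention for all covariate-adjusted
#' tissue-type contrasts (e.g. NAGM vs NC).
#'
#' @param adjusted_mean_a,adjusted_mean_ref adjusted means (counts/mm^2);
#'   the reference must be positive.
#' @return Percent difference.
#' @export
percent_difference <- function(adjusted_mean_a, adjusted_mean_ref) {
  if (any(adjusted_mean_ref <= 0))
    stop("percent_difference: reference mean must be > 0", call. = FALSE)
  100 * (adjusted_mean_a - adjusted_mean_ref) / adjusted_mean_ref
}

#' Nested mixed-effects density contrasts
#'
#' Fits the density analysis for one marker class with linear mixed-effects
#' models (REML, Satterthwaite degrees of freedom, random intercept per
#' subject) to account for the nested design (multiple tissue types and,
#' for synapses, multiple cortical layers per subject).
#'
#' For synapse markers the full model is
#' `density ~ group * layer + age + sex + pmd + (1 | subject_id)`; the
#' tissue-type x layer interaction is tested first and, when its p-value is
#' below `alpha` (or `follow_up = "always"`), per-layer models
#' `density ~ group + age + sex + pmd + (1 | subject_id)` provide pairwise
#' tissue-type contrasts.  Neuron markers get the per-layer model directly
#' (no layer term).  Percent differences come from covariate-adjusted
#' marginal means at covariate averages ([emmeans::emmeans()]).
#'
#' @param records aggregated density records (see [aggregate_rois()]).
#' @param marker_class `"synapse"` or `"neuron"`.
#' @param extra_covariate optional extra covariate column name (e.g. a
#'   NeuN-density column merged into `records`) added to all fixed-effect
#'   formulas.
#' @param alpha interaction-test threshold gating per-layer follow-ups.
#' @param follow_up `"if_significant"` (default) or `"always"`.
#' @return Object of class `density_fit`: list with `contrasts` (one row
#'   per marker x layer x comparison: estimate, pct_diff, ci_low, ci_high,
#'   p_value), `interaction` (marker-level F tests; synapses only),
#'   `meta` (model descriptions and any singular-fit diagnostics).
#' @export
fit_density_model <- function(records, marker_class = c("synapse", "neuron"),
                              extra_covariate = NULL, alpha = 0.05,
                              follow_up = c("if_significant", "always")) {
  marker_class <- match.arg(marker_class)
  follow_up <- match.arg(follow_up)
  records <- validate_density_records(records)
  markers <- if (marker_class == "synapse") SYNAPSE_MARKERS else NEURON_MARKERS
  covs <- c("age", "sex", "pmd", extra_covariate)
  cov_str <- paste(covs, collapse = " + ")

  interaction_rows <- list()
  contrast_rows <- list()
  diagnostics <- character(0)

  for (mk in markers) {
    d <- droplevels(records[records$marker == mk, , drop = FALSE])
    if (nrow(d) == 0) next
    if (nlevels(d$group) < 2) {
      diagnostics <- c(diagnostics, sprintf("%s: fewer than 2 groups", mk))
      next
    }

    if (marker_class == "synapse") {
      if (nlevels(d$layer) < 2)
        stop("fit_density_model: synapse analysis needs >= 2 layers", call. = FALSE)
      form <- as.formula(paste("density ~ group * layer +", cov_str,
                               "+ (1 | subject_id)"))
      full <- fit_lmm(form, d, mk, diagnostics)
      diagnostics <- full$diagnostics
      if (is.null(full$model)) next
      an <- tryCatch(stats::anova(full$model, type = 3),
                     error = function(e) NULL)
      ia <- if (!is.null(an) && "group:layer" %in% rownames(an))
        an["group:layer", , drop = FALSE] else NULL
      ia_p <- if (!is.null(ia)) ia[["Pr(>F)"]] else NA_real_
      interaction_rows[[mk]] <- data.frame(
        marker = mk,
        F_value = if (!is.null(ia)) ia[["F value"]] else NA_real_,
        df1 = if (!is.null(ia)) ia[["NumDF"]] else NA_real_,
        df2 = if (!is.null(ia)) ia[["DenDF"]] else NA_real_,
        p_value = ia_p)
      do_layers <- follow_up == "always" || (is.finite(ia_p) && ia_p < alpha)
      if (do_layers) {
        for (ly in levels(d$layer)) {
          dl <- droplevels(d[d$layer == ly, , drop = FALSE])
          if (nlevels(dl$group) < 2) next
          res <- group_contrasts(dl, cov_str, mk, ly, diagnostics)
          diagnostics <- res$diagnostics
          contrast_rows <- c(contrast_rows, res$rows)
        }
      }
    } else {
      res <- group_contrasts(d, cov_str, mk, NA_character_, diagnostics)
      diagnostics <- res$diagnostics
      contrast_rows <- c(contrast_rows, res$rows)
    }
  }

  contrasts <- if (length(contrast_rows)) do.call(rbind, contrast_rows) else
    data.frame(marker = character(), layer = character(),
               comparison = character(), estimate = numeric(),
               pct_diff = numeric(), ci_low = numeric(), ci_high = numeric(),
               p_value = numeric())
  rownames(contrasts) <- NULL
  interaction <- if (length(interaction_rows)) do.call(rbind, interaction_rows)
    else NULL
  if (!is.null(interaction)) rownames(interaction) <- NULL
  structure(list(contrasts = contrasts, interaction = interaction,
                 meta = list(marker_class = marker_class,
                             fixed = paste("group [* layer] +", cov_str),
                             random = "(1 | subject_id)",
                             method = "REML, Satterthwaite df, treatment coding (NC reference)",
                             alpha = alpha,
                             diagnostics = diagnostics)),
            class = "density_fit")
}

# fit one lmer model, recording singularity / convergence diagnostics
fit_lmm <- function(form, data, mk, diagnostics) {
  model <- tryCatch(
    withCallingHandlers(
      suppressMessages(lmerTest::lmer(form, data = data, REML = TRUE,
                                      control = lme4::lmerControl(
                                        check.conv.singular = lme4::.makeCC(
                                          action = "ignore", tol = 1e-4)))),
      warning = function(w) {
        diagnostics <<- c(diagnostics,
                          sprintf("%s: %s", mk, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
    error = function(e) {
      diagnostics <<- c(diagnostics,
                        sprintf("%s: model failure (%s)", mk, conditionMessage(e)))
      NULL
    })
  if (!is.null(model) && lme4::isSingular(model, tol = 1e-4))
    diagnostics <- c(diagnostics, sprintf(
      "%s: singular fit (subject random-intercept variance near zero)", mk))
  list(model = model, diagnostics = diagnostics)
}

# per-layer (or neuron) model: adjusted means + pairwise tissue contrasts
group_contrasts <- function(d, cov_str, mk, ly, diagnostics) {
  form <- as.formula(paste("density ~ group +", cov_str, "+ (1 | subject_id)"))
  fit <- fit_lmm(form, d, paste0(mk, if (!is.na(ly)) paste0(" layer ", ly)),
                 diagnostics)
  if (is.null(fit$model)) return(list(rows = list(), diagnostics = fit$diagnostics))
  emm <- tryCatch(
    emmeans::emmeans(fit$model, ~group, lmer.df = "satterthwaite"),
    error = function(e) NULL)
  if (is.null(emm)) {
    return(list(rows = list(),
                diagnostics = c(fit$diagnostics,
                                sprintf("%s: adjusted means unavailable", mk))))
  }
  es <- as.data.frame(emm)
  adj <- setNames(es$emmean, as.character(es$group))
  ctr <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  ci <- as.data.frame(stats::confint(emmeans::contrast(emm, method = "revpairwise")))
  rows <- lapply(seq_len(nrow(ctr)), function(r) {
    cmp <- as.character(ctr$contrast[r])     # e.g. "NAGM - NC"
    parts <- strsplit(cmp, " - ", fixed = TRUE)[[1]]
    ref <- adj[parts[2]]
    data.frame(marker = mk, layer = ly,
               comparison = sprintf("%s vs %s", parts[1], parts[2]),
               estimate = ctr$estimate[r],
               pct_diff = if (ref > 0) percent_difference(adj[parts[1]], ref)
                          else NA_real_,
               ci_low = ci$lower.CL[r], ci_high = ci$upper.CL[r],
               p_value = ctr$p.value[r], row.names = NULL)
  })
  list(rows = rows, diagnostics = fit$diagnostics)
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf("<density_fit> %s markers; %s\n", x$meta$marker_class, x$meta$method))
  if (!is.null(x$interaction)) {
    cat("tissue-type x layer interaction:\n")
    print(x$interaction, row.names = FALSE, digits = 4)
  }
  if (nrow(x$contrasts)) {
    cat("adjusted tissue-type contrasts:\n")
    print(x$contrasts, row.names = FALSE, digits = 4)
  } else cat("no follow-up contrasts (interaction not significant)\n")
  if (length(x$meta$diagnostics))
    cat("diagnostics:\n ", paste(x$meta$diagnostics, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
summary.density_fit <- function(object, ...) print(object, ...)

#' Write a density_fit to CSV plus JSON metadata sidecar
#'
#' @param x a `density_fit`.
#' @param path output CSV path for the contrasts table; metadata goes to
#'   `paste0(path, ".json")`.
#' @export
write_density_fit <- function(x, path) {
  stopifnot(inherits(x, "density_fit"))
  write.table(x$contrasts, path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- x$meta
  if (!is.null(x$interaction)) meta$interaction <- x$interaction
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
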