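# deterministic per-iteration seed derived from the master seed; kept
# below 2^31 - 1 so it round-trips through R integers
derive_seed <- function(master, i) {
  m <- as.numeric(master) %% 2147483647
  ((m * 1009 + (i + 1) * 97561) %% 2147483647) + 1
}

#' Run the synaptic-reduction iteration experiment
#'
#' For each retained iteration of the schedule, scales the cortical
#' couplings per [scale_at()], simulates the full network, and computes the
#' two outcome measures: mean alpha-band power ([alpha_power()]) and mean
#' phase-locking value ([mean_plv()]), plus their percent changes relative
#' to iteration 0.  Per-iteration noise realizations are fresh by default
#' (seeds derived deterministically from the master seed and the iteration
#' index); `frozen_noise = TRUE` reuses the iteration-0 realization to
#' isolate coupling effects.
#'
#' If the integration destabilizes at some iteration the experiment aborts
#' there: the partial outcome table is returned with attribute
#' `failed_at` set to the offending iteration.
#'
#' @param params a [ct_params()] object.
#' @param connectome a [connectome()].
#' @param schedule a [reduction_schedule()].
#' @param metrics_cfg list with `band` (Hz), `window_s` (s, default 2),
#'   `edge_trim` (s).
#' @param seed integer master seed.
#' @param iterations iteration indices to simulate; must include 0;
#'   defaults to `0:n_iterations`.
#' @param policy reduction policy, see [apply_reduction()].
#' @param frozen_noise reuse the same noise realization at every iteration?
#' @return Object of class `ct_experiment`: a data.frame with columns
#'   `iteration`, `alpha_power`, `mean_plv`, `pct_power`, `pct_plv`, with
#'   the configuration in attributes.
#' @export
run_experiment <- function(params, connectome, schedule,
                           metrics_cfg = list(band = c(8, 13), window_s = 2,
                                              overlap = 0.5, edge_trim = 1),
                           seed = 1L, iterations = NULL,
                           policy = c("intracortical_longrange", "intracortical"),
                           frozen_noise = FALSE) {
  policy <- match.arg(policy)
  stopifnot(inherits(schedule, "reduction_schedule"))
  validate_connectome(connectome)
  mc <- modifyList(list(band = c(8, 13), window_s = 2, overlap = 0.5,
                        edge_trim = 1), metrics_cfg)
  if (is.null(iterations)) iterations <- 0:schedule$n_iterations
  iterations <- sort(unique(as.integer(iterations)))
  if (iterations[1] != 0)
    stop("run_experiment: iterations must include the baseline iteration 0",
         call. = FALSE)

  rows <- vector("list", length(iterations))
  failed_at <- NA_integer_
  for (k in seq_along(iterations)) {
    i <- iterations[k]
    sc <- scale_at(schedule, i)
    seed_i <- if (frozen_noise) derive_seed(seed, 0) else derive_seed(seed, i)
    sim <- tryCatch(
      simulate_network(params, connectome,
                       coupling_scales = list(s_E = sc$s_E, s_I = sc$s_I),
                       seed = seed_i, policy = policy),
      corthal_instability = function(e) e)
    if (inherits(sim, "corthal_instability")) { failed_at <- i; break }
    spec <- welch_psd(sim, window_s = mc$window_s, overlap = mc$overlap)
    ap <- alpha_power(spec, band = mc$band)
    mp <- mean_plv(plv_matrix(sim, band = mc$band, edge_trim = mc$edge_trim))
    rows[[k]] <- data.frame(iteration = i, alpha_power = ap, mean_plv = mp)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("run_experiment: baseline iteration failed (instability at iteration 0)",
         call. = FALSE)
  out$pct_power <- percent_change(out$alpha_power, out$alpha_power[1])
  out$pct_plv <- percent_change(out$mean_plv, out$mean_plv[1])
  attr(out, "schedule") <- schedule
  attr(out, "seed") <- seed
  attr(out, "policy") <- policy
  attr(out, "metrics_cfg") <- mc
  attr(out, "failed_at") <- failed_at
  class(out) <- c("ct_experiment", "data.frame")
  out
}

#' @export
print.ct_experiment <- function(x, ...) {
  sch <- attr(x, "schedule")
  cat(sprintf("<ct_experiment> condition %s, %d iterations retained (seed %s)%s\n",
              sch$condition, nrow(x), format(attr(x, "seed")),
              if (!is.na(attr(x, "failed_at")))
                sprintf(" [ABORTED at iteration %d]", attr(x, "failed_at")) else ""))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.ct_experiment <- function(object, ...) {
  fin <- object[nrow(object), ]
  sch <- attr(object, "schedule")
  cat(sprintf("condition %-10s  final iteration %d:  alpha power %+0.1f%%,  mean PLV %+0.1f%%\n",
              sch$condition, fin$iteration, fin$pct_power, fin$pct_plv))
  invisible(fin)
}

#' @export
plot.ct_experiment <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$iteration, x$pct_power, type = "b", pch = 16,
       xlab = "iteration", ylab = "alpha power change (%)", ...)
  abline(h = 0, lty = 3)
  plot(x$iteration, x$pct_plv, type = "b", pch = 16,
       xlab = "iteration", ylab = "mean PLV change (%)", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Export experiment outcome curves to delimited text
#'
#' Writes the per-iteration outcome table (`iteration`, `alpha_power`,
#' `mean_plv`, `pct_power`, `pct_plv`) for one condition.
#'
#' @param x a `ct_experiment` (or a list of them, combined with a
#'   `condition` column).
#' @param path output path.
#' @param sep delimiter.
#' @export
write_outcomes <- function(x, path, sep = "\t") {
  if (inherits(x, "ct_experiment")) {
    df <- as.data.frame(x)
    df <- cbind(condition = attr(x, "schedule")$condition, df)
  } else {
    df <- do.call(rbind, lapply(x, function(e)
      cbind(condition = attr(e, "schedule")$condition, as.data.frame(e))))
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
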