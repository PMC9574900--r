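#' Fixed point of one corticothalamic unit
#'
#' Solves the time-independent model equations for the potentials of the
#' four populations of an isolated unit (optionally including a constant
#' long-range excitatory gain, for the spatially uniform network mode).
#' Because both dendritic and axonal transfer operators have unit DC gain,
#' the fixed point satisfies `V_a = sum_b nu_ab Q_b(V_b)` with
#' `phi_e = Q_e(V_e)` and `phi_n` replaced by its mean.  The low-firing
#' branch is targeted by starting the damped Newton iteration at V = 0.
#'
#' @param params a [ct_params()] object.
#' @param external_drive constant drive level replacing the mean of
#'   \eqn{\phi_n} (s^-1); defaults to `params$noise_mean`.
#' @param extra_ee additional excitatory-excitatory DC gain (V s), e.g. the
#'   effective long-range gain `global_coupling` of a row-normalized
#'   connectome in the uniform network state.
#' @param tol residual tolerance (V).
#' @param branch `"low"` (default) returns the lowest-firing fixed point;
#'   `"all"` returns every root of the scalar reduced equation found on the
#'   search grid (as a list).
#' @return A list of class `ct_steady_state` with elements `V` (named
#'   potentials, V), `Q` (firing rates, s^-1), `phi_e`, `residual` and
#'   `converged`.  Failure to bracket a root raises an error of class
#'   `corthal_no_convergence`.
#' @export
steady_state <- function(params, external_drive = params$noise_mean,
                         extra_ee = 0, tol = 1e-12, branch = c("low", "all")) {
  branch <- match.arg(branch)
  validate_ct_params(params)
  cs <- params$couplings
  S <- function(V) firing_rate(V, params)
  Sinv <- function(q) params$theta -
    params$sigma_prime * log(params$Q_max / q - 1)

  # The fixed-point system is solved by nested monotone 1D reductions in
  # the excitatory field x = phi_e = Q_e:
  #   V_s: V_s = nu_se x + nu_sr S(V_r(V_s)) + nu_sn drive, with
  #        V_r = nu_re x + nu_rs S(V_s); the map is decreasing in V_s
  #        (nu_sr <= 0), so the root is unique.
  #   V_i: V_i = nu_ie x + nu_ii S(V_i) + nu_is S(V_s); decreasing in V_i.
  #   x:   g(x) = S^-1(x) - [ (nu_ee + extra_ee) x + nu_ei S(V_i)
  #        + nu_es S(V_s) ] spans -Inf..+Inf over x in (0, Q_max).
  vs_of <- function(x) {
    h <- function(Vs) cs$nu_se * x +
      cs$nu_sr * S(cs$nu_re * x + cs$nu_rs * S(Vs)) +
      cs$nu_sn * external_drive - Vs
    stats::uniroot(h, c(-1, 1), tol = tol / 10)$root
  }
  vi_of <- function(x, qs) {
    k <- function(Vi) cs$nu_ie * x + cs$nu_ii * S(Vi) + cs$nu_is * qs - Vi
    stats::uniroot(k, c(-1, 1), tol = tol / 10)$root
  }
  g <- function(x) {
    vs <- vs_of(x)
    vi <- vi_of(x, S(vs))
    Sinv(x) - ((cs$nu_ee + extra_ee) * x + cs$nu_ei * S(vi) + cs$nu_es * S(vs))
  }

  # scan for sign changes of g on a log-spaced firing-rate grid
  xs <- params$Q_max / (1 + exp(-seq(-14, 14, length.out = 120)))
  gv <- vapply(xs, function(x) tryCatch(g(x), error = function(e) NA_real_),
               numeric(1))
  ok <- which(!is.na(gv))
  sgn <- which(diff(sign(gv[ok])) != 0)
  if (!length(sgn)) {
    cond <- structure(class = c("corthal_no_convergence", "error", "condition"),
                      list(message = "steady_state: no root bracketed on (0, Q_max)",
                           call = sys.call(-1)))
    stop(cond)
  }
  solve_at <- function(k) {
    r <- stats::uniroot(g, c(xs[ok[k]], xs[ok[k + 1]]), tol = 1e-14)
    x <- r$root
    vs <- vs_of(x)
    vi <- vi_of(x, S(vs))
    vr <- cs$nu_re * x + cs$nu_rs * S(vs)
    c(Sinv(x), vi, vr, vs)
  }
  if (branch == "all") {
    return(lapply(sgn, function(k) {
      V <- solve_at(k)
      finish_steady_state(V, params, cs, extra_ee, external_drive)
    }))
  }
  V <- solve_at(sgn[1])
  finish_steady_state(V, params, cs, extra_ee, external_drive)
}

finish_steady_state <- function(V, params, cs, extra_ee, external_drive) {
  Q <- firing_rate(V, params)
  rhs <- c((cs$nu_ee + extra_ee) * Q[1] + cs$nu_ei * Q[2] + cs$nu_es * Q[4],
           cs$nu_ie * Q[1] + cs$nu_ii * Q[2] + cs$nu_is * Q[4],
           cs$nu_re * Q[1] + cs$nu_rs * Q[4],
           cs$nu_se * Q[1] + cs$nu_sr * Q[3] + cs$nu_sn * external_drive)
  f <- V - rhs
  structure(list(V = setNames(V, c("e", "i", "r", "s")),
                 Q = setNames(Q, c("e", "i", "r", "s")),
                 phi_e = Q[[1]], residual = max(abs(f)),
                 converged = TRUE),
            class = "ct_steady_state")
}

#' @export
print.ct_steady_state <- function(x, ...) {
  cat("<ct_steady_state>  residual", format(x$residual, digits = 3), "V\n")
  cat("  V (mV):", paste(sprintf("%s=%.4f", names(x$V), 1e3 * x$V), collapse = "  "), "\n")
  cat("  Q (s^-1):", paste(sprintf("%s=%.4f", names(x$Q), x$Q), collapse = "  "), "\n")
  invisible(x)
}
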