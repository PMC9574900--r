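#' Corticothalamic model parameters
#'
#' Collects the physiological constants of one corticothalamic unit: sigmoid
#' firing-rate parameters, dendritic and axonal rate constants, the
#' corticothalamic loop delay, the external noise drive to the thalamic
#' relay population, and the integration grid.  Defaults place the model in
#' a stable, noise-driven alpha regime (dominant spectral peak inside
#' 8-13 Hz) and follow the value ranges conventional for this model family.
#'
#' @param Q_max maximum population firing rate (s^-1).
#' @param theta mean firing threshold (V).
#' @param sigma_prime sigmoid slope parameter (V).
#' @param alpha_d dendritic decay rate (s^-1).
#' @param beta_d dendritic rise rate (s^-1); must exceed `alpha_d`.
#' @param gamma_e cortical axonal damping rate (s^-1).
#' @param t0 full corticothalamic loop delay (s); each leg contributes
#'   `t0/2`.
#' @param couplings a [coupling_set()].
#' @param noise_mean mean external drive \eqn{\phi_n} to the relay
#'   population (s^-1).
#' @param noise_std white-noise amplitude of the drive (s^-1 per sqrt(Hz);
#'   the integrator adds `noise_std * N(0,1) / sqrt(dt)` to \eqn{\phi_n}).
#' @param dt integration step (s).
#' @param duration simulated time per run (s).
#' @param transient initial span discarded before analysis (s).
#' @return An object of class `ct_params`.
#' @export
ct_params <- function(Q_max = 340, theta = 12.924e-3, sigma_prime = 3.929e-3,
                      alpha_d = 83, beta_d = 769, gamma_e = 116,
                      t0 = 85e-3, couplings = coupling_set(),
                      noise_mean = 5.0264, noise_std = 0.8,
                      dt = 1e-4, duration = 12, transient = 2) {
  p <- list(Q_max = Q_max, theta = theta, sigma_prime = sigma_prime,
            alpha_d = alpha_d, beta_d = beta_d, gamma_e = gamma_e,
            t0 = t0, couplings = couplings,
            noise_mean = noise_mean, noise_std = noise_std,
            dt = dt, duration = duration, transient = transient)
  class(p) <- "ct_params"
  validate_ct_params(p)
  p
}

validate_ct_params <- function(p) {
  stopifnot(inherits(p, "ct_params"))
  num <- p[setdiff(names(p), "couplings")]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("ct_params: all fields must be finite scalars", call. = FALSE)
  if (p$Q_max <= 0) stop("ct_params: Q_max must be > 0", call. = FALSE)
  if (p$sigma_prime <= 0) stop("ct_params: sigma_prime must be > 0", call. = FALSE)
  if (!(p$beta_d > p$alpha_d && p$alpha_d > 0))
    stop("ct_params: need beta_d > alpha_d > 0", call. = FALSE)
  if (p$gamma_e <= 0) stop("ct_params: gamma_e must be > 0", call. = FALSE)
  if (p$t0 < 0) stop("ct_params: t0 must be >= 0", call. = FALSE)
  if (p$dt <= 0) stop("ct_params: dt must be > 0", call. = FALSE)
  if (p$noise_std < 0) stop("ct_params: noise_std must be >= 0", call. = FALSE)
  if (!(p$duration > p$transient && p$transient >= 0))
    stop("ct_params: need duration > transient >= 0", call. = FALSE)
  validate_coupling_set(p$couplings)
  invisible(p)
}

#' @export
print.ct_params <- function(x, ...) {
  cat("<ct_params>\n")
  cat(sprintf("  sigmoid: Q_max %g s^-1, theta %g mV, sigma' %g mV\n",
              x$Q_max, 1e3 * x$theta, 1e3 * x$sigma_prime))
  cat(sprintf("  rates:   alpha %g, beta %g, gamma_e %g s^-1; loop delay t0 %g ms\n",
              x$alpha_d, x$beta_d, x$gamma_e, 1e3 * x$t0))
  cat(sprintf("  drive:   phi_n %g s^-1 (noise sd %g); dt %g s, duration %g s (transient %g s)\n",
              x$noise_mean, x$noise_std, x$dt, x$duration, x$transient))
  print(x$couplings)
  invisible(x)
}

#' Population firing-rate function
#'
#' The saturating sigmoid converting mean membrane potential to population
#' firing rate, `Q(V) = Q_max / (1 + exp(-(V - theta)/sigma_prime))`.
#' Strictly increasing in `V` with values in (0, Q_max).
#'
#' @param V membrane potential (V); vectorized.
#' @param params a [ct_params()] object.
#' @return Firing rate(s) in s^-1.
#' @export
firing_rate <- function(V, params) {
  validate_ct_params(params)
  if (any(!is.finite(V))) stop("firing_rate: V must be finite", call. = FALSE)
  params$Q_max / (1 + exp(-(V - params$theta) / params$sigma_prime))
}

# derivative dQ/dV, used by the linearization
firing_rate_slope <- function(V, params) {
  q <- firing_rate(V, params)
  q * (1 - q / params$Q_max) / params$sigma_prime
}

# short stable identifier of a configuration (FNV-1a over the deparsed
# numeric content); used to tag SimulationResult provenance
params_hash <- function(...) {
  txt <- paste(vapply(list(...), function(x)
    paste(deparse(unclass(x)), collapse = " "), character(1)), collapse = "|")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
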