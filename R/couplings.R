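#' Synaptic coupling strengths of one corticothalamic unit
#'
#' A coupling set holds the eleven synaptic strengths \eqn{\nu_{ab}} (in
#' V s), indexed target <- source over the populations e (cortical
#' excitatory), i (cortical inhibitory), r (thalamic reticular), s (thalamic
#' relay) and n (external noise drive).  Couplings whose source population is
#' inhibitory (`nu_ei`, `nu_ii`, `nu_sr`) must be <= 0; all others >= 0.
#'
#' With `random_connectivity = TRUE` (the default) intracortical connectivity
#' is assumed random, which ties `nu_ie = nu_ee`, `nu_ii = nu_ei` and
#' `nu_is = nu_es`, so both cortical populations receive identical afferents.
#'
#' @param nu_ee,nu_es,nu_re,nu_rs,nu_se,nu_sn excitatory-source couplings
#'   (V s, >= 0).
#' @param nu_ei,nu_sr inhibitory-source couplings (V s, <= 0).
#' @param nu_ie,nu_ii,nu_is cortical couplings onto the inhibitory
#'   population; defaults mirror the excitatory population under the
#'   random-connectivity assumption.
#' @param random_connectivity logical; enforce the intracortical symmetry.
#' @return An object of class `coupling_set` (a named list).
#' @export
coupling_set <- function(nu_ee = 1.52224e-3, nu_ei = -4.87117e-3,
                         nu_es = 5.51884e-4,
                         nu_ie = nu_ee, nu_ii = nu_ei, nu_is = nu_es,
                         nu_re = 5.35850e-4, nu_rs = 2.02739e-5,
                         nu_se = 3.36020e-3, nu_sr = -7.50779e-4,
                         nu_sn = 1.0e-3,
                         random_connectivity = TRUE) {
  cs <- list(nu_ee = nu_ee, nu_ei = nu_ei, nu_es = nu_es,
             nu_ie = nu_ie, nu_ii = nu_ii, nu_is = nu_is,
             nu_re = nu_re, nu_rs = nu_rs,
             nu_se = nu_se, nu_sr = nu_sr, nu_sn = nu_sn)
  if (isTRUE(random_connectivity)) {
    cs$nu_ie <- cs$nu_ee; cs$nu_ii <- cs$nu_ei; cs$nu_is <- cs$nu_es
  }
  class(cs) <- "coupling_set"
  validate_coupling_set(cs)
  cs
}

validate_coupling_set <- function(cs) {
  stopifnot(inherits(cs, "coupling_set"))
  vals <- unlist(cs)
  if (any(!is.finite(vals)))
    stop("coupling_set: all couplings must be finite", call. = FALSE)
  neg <- c("nu_ei", "nu_ii", "nu_sr")
  pos <- setdiff(names(cs), neg)
  if (any(vals[neg] > 0))
    stop("coupling_set: inhibitory-source couplings (nu_ei, nu_ii, nu_sr) must be <= 0",
         call. = FALSE)
  if (any(vals[pos] < 0))
    stop("coupling_set: excitatory-source couplings must be >= 0", call. = FALSE)
  invisible(cs)
}

#' @export
print.coupling_set <- function(x, ...) {
  cat("<coupling_set> (V s)\n")
  v <- unlist(x)
  print(signif(v, 4))
  invisible(x)
}

#' Scale cortical couplings by excitatory / inhibitory reduction factors
#'
#' Applies multiplicative reduction factors to the synaptic couplings of one
#' unit.  Both policies multiply the cortical excitatory couplings
#' (`nu_ee`, `nu_ie`) by `s_E` and the cortical inhibitory couplings
#' (`nu_ei`, `nu_ii`) by `s_I`; thalamic and noise couplings are untouched.
#' Under the default `"intracortical_longrange"` policy long-range
#' cortico-cortical synapses count as excitatory cortical synapses too:
#' the returned object carries an attribute `gc_scale = s_E` that
#' [simulate_network()] applies to the connectome gain.  `"intracortical"`
#' leaves long-range input unscaled (`gc_scale = 1`).
#'
#' @param couplings a [coupling_set()].
#' @param s_E,s_I scalar factors in (0, 1].
#' @param policy `"intracortical_longrange"` (default) or `"intracortical"`.
#' @return A new `coupling_set`; the input is not modified.
#' @export
apply_reduction <- function(couplings, s_E = 1, s_I = 1,
                            policy = c("intracortical_longrange", "intracortical")) {
  policy <- match.arg(policy)
  validate_coupling_set(couplings)
  stopifnot(length(s_E) == 1, length(s_I) == 1,
            s_E > 0, s_E <= 1, s_I > 0, s_I <= 1)
  out <- couplings
  out$nu_ee <- couplings$nu_ee * s_E
  out$nu_ie <- couplings$nu_ie * s_E
  out$nu_ei <- couplings$nu_ei * s_I
  out$nu_ii <- couplings$nu_ii * s_I
  attr(out, "gc_scale") <- if (policy == "intracortical_longrange") s_E else 1
  validate_coupling_set(out)
  out
}
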