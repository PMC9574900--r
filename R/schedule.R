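#' Synaptic reduction schedule
#'
#' Defines one experimental condition: which synaptic type(s) are reduced,
#' over how many iterations, and to which end-point fractions.  The default
#' end-points are the empirically measured layer-VI losses in
#' normal-appearing MS gray matter: -12.5% excitatory and -14.9%
#' inhibitory.  A `demyelinated` preset (`preset = "demyelinated"`) swaps in
#' the demyelinated-cortex end-points (-18.5% / -29.3%).
#'
#' In `"graded"` spatial mode a per-region weight profile in \[0, 1\] (with
#' maximum exactly 1) scales the reduction regionally, so the most affected
#' region reaches exactly the end-point at the final iteration.
#'
#' @param condition `"excitatory"`, `"inhibitory"` or `"combined"`.
#' @param n_iterations number of reduction steps (default 50).
#' @param endpoint_E,endpoint_I maximal reduction fractions in \[0, 1).
#' @param spatial_mode `"uniform"` (default) or `"graded"`.
#' @param region_weights per-region profile, graded mode only.
#' @param preset optional `"nagm"` (default end-points) or
#'   `"demyelinated"`.
#' @return Object of class `reduction_schedule`.
#' @export
reduction_schedule <- function(condition = c("excitatory", "inhibitory", "combined"),
                               n_iterations = 50,
                               endpoint_E = 0.125, endpoint_I = 0.149,
                               spatial_mode = c("uniform", "graded"),
                               region_weights = NULL,
                               preset = NULL) {
  condition <- match.arg(condition)
  spatial_mode <- match.arg(spatial_mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("nagm", "demyelinated"))
    if (preset == "demyelinated") { endpoint_E <- 0.185; endpoint_I <- 0.293 }
  }
  stopifnot(n_iterations >= 1,
            endpoint_E >= 0, endpoint_E < 1, endpoint_I >= 0, endpoint_I < 1)
  if (spatial_mode == "graded") {
    if (is.null(region_weights))
      stop("reduction_schedule: graded mode needs region_weights", call. = FALSE)
    if (any(region_weights < 0 | region_weights > 1) ||
        abs(max(region_weights) - 1) > 1e-12)
      stop("reduction_schedule: region_weights must lie in [0, 1] with max exactly 1",
           call. = FALSE)
  }
  structure(list(condition = condition, n_iterations = as.integer(n_iterations),
                 endpoint_E = endpoint_E, endpoint_I = endpoint_I,
                 spatial_mode = spatial_mode, region_weights = region_weights),
            class = "reduction_schedule")
}

#' @export
print.reduction_schedule <- function(x, ...) {
  cat(sprintf("<reduction_schedule> %s, %d iterations, end-points E -%.1f%% / I -%.1f%% (%s)\n",
              x$condition, x$n_iterations, 100 * x$endpoint_E,
              100 * x$endpoint_I, x$spatial_mode))
  invisible(x)
}

#' Coupling scales at one iteration of a schedule
#'
#' Linear interpolation from baseline to the end-point:
#' `s_X(i) = 1 - endpoint_X * i / n_iterations` for each reduced type, 1
#' for the untouched type.  In graded mode each region's reduction is
#' multiplied by its profile weight and per-region vectors are returned.
#'
#' @param schedule a [reduction_schedule()].
#' @param i iteration index in `0:n_iterations`.
#' @return List with elements `s_E` and `s_I` (scalars, or vectors in
#'   graded mode).
#' @export
scale_at <- function(schedule, i) {
  stopifnot(inherits(schedule, "reduction_schedule"))
  if (length(i) != 1 || i < 0 || i > schedule$n_iterations)
    stop("scale_at: iteration index out of range", call. = FALSE)
  frac <- i / schedule$n_iterations
  w <- if (schedule$spatial_mode == "graded") schedule$region_weights else 1
  redE <- if (schedule$condition %in% c("excitatory", "combined"))
    schedule$endpoint_E * frac * w else 0 * w
  redI <- if (schedule$condition %in% c("inhibitory", "combined"))
    schedule$endpoint_I * frac * w else 0 * w
  list(s_E = 1 - redE, s_I = 1 - redI)
}
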