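#' Read model parameters from a YAML or JSON configuration file
#'
#' The file maps [ct_params()] fields at the top level and [coupling_set()]
#' fields under a `couplings` key; [connectome()] gains may be given under
#' a `connectome` key (`global_coupling`, `inter_delay`).  Unknown keys are
#' an error, so typos cannot silently fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with elements `params` (a `ct_params`) and `connectome_opts`
#'   (list of gains, possibly empty).
#' @export
read_params_config <- function(path) {
  cfg <- read_config_file(path)
  known_par <- setdiff(names(formals(ct_params)), "couplings")
  known_cs <- setdiff(names(formals(coupling_set)), "random_connectivity")
  conn_keys <- c("global_coupling", "inter_delay")
  unknown <- setdiff(names(cfg), c(known_par, "couplings", "connectome"))
  if (length(unknown))
    stop("read_params_config: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cs_args <- cfg$couplings
  if (!is.null(cs_args)) {
    bad <- setdiff(names(cs_args), c(known_cs, "random_connectivity"))
    if (length(bad))
      stop("read_params_config: unknown coupling keys: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  conn <- cfg$connectome
  if (!is.null(conn)) {
    bad <- setdiff(names(conn), conn_keys)
    if (length(bad))
      stop("read_params_config: unknown connectome keys: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  par_args <- cfg[intersect(names(cfg), known_par)]
  if (!is.null(cs_args)) par_args$couplings <- do.call(coupling_set, cs_args)
  list(params = do.call(ct_params, par_args),
       connectome_opts = if (is.null(conn)) list() else conn)
}

#' Read an experiment configuration file
#'
#' Keys: `condition`, `n_iterations`, `endpoint_E`, `endpoint_I`,
#' `spatial_mode`, `region_weights`, `preset`, `policy`, `seed`,
#' `iterations`, `frozen_noise`, and a `metrics` block (`band`,
#' `window_s`, `overlap`, `edge_trim`).  Unknown keys are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with `schedule` (a [reduction_schedule()]), `policy`,
#'   `seed`, `iterations`, `frozen_noise`, `metrics_cfg`.
#' @export
read_experiment_config <- function(path) {
  cfg <- read_config_file(path)
  sched_keys <- names(formals(reduction_schedule))
  other <- c("policy", "seed", "iterations", "frozen_noise", "metrics")
  unknown <- setdiff(names(cfg), c(sched_keys, other))
  if (length(unknown))
    stop("read_experiment_config: unknown keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$metrics)) {
    bad <- setdiff(names(cfg$metrics), c("band", "window_s", "overlap", "edge_trim"))
    if (length(bad))
      stop("read_experiment_config: unknown metrics keys: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  sched <- do.call(reduction_schedule, cfg[intersect(names(cfg), sched_keys)])
  list(schedule = sched,
       policy = if (is.null(cfg$policy)) "intracortical_longrange" else cfg$policy,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       iterations = cfg$iterations,
       frozen_noise = isTRUE(cfg$frozen_noise),
       metrics_cfg = if (is.null(cfg$metrics)) list() else cfg$metrics)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
}
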