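#' Configuration for the synthetic connectome generator
#'
#' The generator emulates the statistical regularities of empirical
#' tractography matrices: nonnegative symmetric weights, zero diagonal,
#' moderate edge density, heavy-tailed (log-normal) weights attenuated by
#' an exponential distance rule over random 3D region positions, and a
#' connected graph.
#'
#' @param n_regions number of cortical regions (default 78).
#' @param edge_density fraction of nonzero off-diagonal pairs, in (0, 1].
#' @param weight_meanlog,weight_sdlog log-normal weight law parameters.
#' @param distance_lambda exponential distance-rule length scale (in units
#'   of the unit cube holding the random region positions).
#' @param seed integer seed.
#' @return Object of class `connectome_sim_config`.
#' @export
connectome_sim_config <- function(n_regions = 78, edge_density = 0.3,
                                  weight_meanlog = 0, weight_sdlog = 0.9,
                                  distance_lambda = 0.35, seed = 1L) {
  stopifnot(n_regions >= 2, edge_density > 0, edge_density <= 1,
            weight_sdlog >= 0, distance_lambda > 0)
  structure(list(n_regions = as.integer(n_regions),
                 edge_density = edge_density,
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 distance_lambda = distance_lambda,
                 seed = as.integer(seed)),
            class = "connectome_sim_config")
}

#' Generate a synthetic structural connectome
#'
#' Samples random 3D region positions in the unit cube, retains the
#' `edge_density` fraction of pairs with the highest exponential-distance
#' scores `exp(-d/lambda)`, assigns log-normal weights modulated by the
#' same distance factor, deterministically bridges any disconnected
#' components (closest inter-component pair, at the median positive
#' weight), and normalizes to maximum weight 1.  Deterministic under the
#' config seed.
#'
#' @param cfg a [connectome_sim_config()].
#' @param global_coupling,inter_delay passed to [connectome()].
#' @return A [connectome()] object.
#' @export
generate_connectome <- function(cfg = connectome_sim_config(),
                                global_coupling = 1e-4, inter_delay = 0) {
  stopifnot(inherits(cfg, "connectome_sim_config"))
  n <- cfg$n_regions
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(cfg$seed)

  pos <- matrix(runif(3 * n), n, 3)
  D <- as.matrix(dist(pos))
  score <- exp(-D / cfg$distance_lambda)
  ut <- which(upper.tri(D))
  m <- max(1L, round(cfg$edge_density * length(ut)))
  keep <- ut[order(score[ut], decreasing = TRUE)[seq_len(m)]]

  W <- matrix(0, n, n)
  wts <- rlnorm(m, cfg$weight_meanlog, cfg$weight_sdlog) * score[keep]
  W[keep] <- wts
  W <- W + t(W)

  # deterministic bridging of disconnected components
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  budget <- n  # at most n-1 bridges ever needed
  while (comp$no > 1 && budget > 0) {
    in1 <- which(comp$membership == 1)
    out1 <- which(comp$membership != 1)
    sub <- D[in1, out1, drop = FALSE]
    idx <- arrayInd(which.min(sub), dim(sub))
    a <- in1[idx[1]]; b <- out1[idx[2]]
    W[a, b] <- W[b, a] <- median(W[W > 0])
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)
    budget <- budget - 1
  }
  if (comp$no > 1)
    stop("generate_connectome: could not connect the graph within the bridging budget",
         call. = FALSE)
  W <- W / max(W)
  diag(W) <- 0
  connectome(W, global_coupling = global_coupling, inter_delay = inter_delay)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
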