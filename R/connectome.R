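#' Structural connectome container
#'
#' A weighted, symmetric, nonnegative region-by-region matrix with zero
#' diagonal routing long-range excitatory input between corticothalamic
#' units, plus a global coupling gain.  The graph of nonzero weights must be
#' connected.  Before simulation the rows are normalized to unit row-sum, so
#' `global_coupling` (V s) is the total long-range synaptic strength each
#' region receives.
#'
#' @param weights square numeric matrix (nonnegative, symmetric, zero
#'   diagonal, connected).
#' @param labels optional region names; defaults to `region_001`, ...
#' @param global_coupling scalar gain (V s, >= 0) on inter-regional
#'   excitatory input.
#' @param inter_delay inter-regional conduction delay (s, default 0).
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, labels = NULL, global_coupling = 1e-4,
                       inter_delay = 0) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(labels)) labels <- sprintf("region_%03d", seq_len(n))
  obj <- structure(list(n_regions = n, weights = unname(weights),
                        labels = labels, global_coupling = global_coupling,
                        inter_delay = inter_delay),
                   class = "connectome")
  validate_connectome(obj)
  obj
}

validate_connectome <- function(x) {
  stopifnot(inherits(x, "connectome"))
  W <- x$weights
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("connectome: weights must be a square matrix", call. = FALSE)
  if (any(!is.finite(W)) || any(W < 0))
    stop("connectome: weights must be finite and >= 0", call. = FALSE)
  if (any(abs(W - t(W)) > 1e-12 * max(abs(W), 1)))
    stop("connectome: weights must be symmetric", call. = FALSE)
  if (any(diag(W) != 0))
    stop("connectome: diagonal must be zero", call. = FALSE)
  if (length(x$labels) != nrow(W))
    stop("connectome: labels length must match matrix", call. = FALSE)
  if (!is.numeric(x$global_coupling) || x$global_coupling < 0)
    stop("connectome: global_coupling must be >= 0", call. = FALSE)
  if (x$inter_delay < 0)
    stop("connectome: inter_delay must be >= 0", call. = FALSE)
  if (nrow(W) > 1) {
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                             diag = FALSE)
    if (igraph::components(g)$no != 1)
      stop("connectome: graph of nonzero weights must be connected", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  W <- x$weights
  dens <- if (x$n_regions > 1)
    mean(W[upper.tri(W)] > 0) else NA_real_
  cat(sprintf("<connectome> %d regions, edge density %.3f, global_coupling %g V s, inter_delay %g s\n",
              x$n_regions, dens, x$global_coupling, x$inter_delay))
  invisible(x)
}

# rows scaled to unit sum; used by the integrator
row_normalize <- function(W) {
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W / rs
}

#' Read a connectome matrix from a delimited text file
#'
#' Accepts a plain-text square matrix, tab- or comma-delimited, with an
#' optional header row of region labels.  Near-symmetric input (relative
#' asymmetry within `tol`) is symmetrized by averaging; larger asymmetry is
#' an error.
#'
#' @param path file path.
#' @param global_coupling,inter_delay passed to [connectome()].
#' @param tol relative symmetry tolerance.
#' @return A [connectome()] object.
#' @export
read_connectome <- function(path, global_coupling = 1e-4, inter_delay = 0,
                            tol = 1e-8) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(fields))))
  df <- read.table(path, sep = sep, header = header, check.names = FALSE)
  M <- as.matrix(df)
  labels <- if (header) colnames(df) else NULL
  mode(M) <- "numeric"
  if (any(!is.finite(M))) stop("read_connectome: non-numeric entries", call. = FALSE)
  asym <- max(abs(M - t(M))) / max(abs(M), .Machine$double.eps)
  if (asym > tol)
    stop(sprintf("read_connectome: relative asymmetry %.3g exceeds tolerance %g",
                 asym, tol), call. = FALSE)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  connectome(M, labels = labels, global_coupling = global_coupling,
             inter_delay = inter_delay)
}

#' Write a connectome matrix to a delimited text file
#'
#' @param x a [connectome()].
#' @param path output path.
#' @param sep field delimiter (`"\t"` or `","`).
#' @param labels write the region labels as a header row?
#' @export
write_connectome <- function(x, path, sep = "\t", labels = TRUE) {
  validate_connectome(x)
  W <- x$weights
  colnames(W) <- x$labels
  write.table(W, path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = labels)
  invisible(path)
}
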