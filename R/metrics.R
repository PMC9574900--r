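#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with Hann windows: each segment is
#' demeaned, windowed, and its one-sided periodogram accumulated with
#' density scaling `2 / (fs * sum(w^2))` (DC and Nyquist bins unscaled by
#' the factor 2), so that the trapezoidal integral of the PSD over frequency
#' recovers the signal variance for stationary input.
#'
#' @param x a `ct_sim` object, or a numeric matrix (time x region) /
#'   vector.
#' @param fs sampling rate (Hz); taken from the `ct_sim` if omitted.
#' @param window_s window length (s); the 2 s default gives about 9
#'   averaged segments on the default 10 s records.
#' @param overlap fractional overlap between successive windows.
#' @return Object of class `spectrum_estimate`: list with `freqs` (Hz),
#'   `psd` (frequency x region matrix, units^2/Hz), `window_s`, `overlap`,
#'   `n_segments`.
#' @export
welch_psd <- function(x, fs = NULL, window_s = 2, overlap = 0.5) {
  if (inherits(x, "ct_sim")) { fs <- x$fs; x <- x$series }
  if (is.null(fs)) stop("welch_psd: fs required for matrix input", call. = FALSE)
  x <- as.matrix(x)
  nwin <- round(window_s * fs)
  nt <- nrow(x)
  if (nt < nwin)
    stop("welch_psd: series shorter than one window", call. = FALSE)
  step <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, nt - nwin + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / nwin)  # periodic Hann
  U <- sum(w^2)
  nfreq <- nwin %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * fs / nwin
  psd <- matrix(0, nfreq, ncol(x))
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    X <- mvfft(seg * w)
    P <- Mod(X[seq_len(nfreq), , drop = FALSE])^2 / (fs * U)
    scale2 <- rep(2, nfreq); scale2[1] <- 1
    if (nwin %% 2 == 0) scale2[nfreq] <- 1
    psd <- psd + P * scale2
  }
  psd <- psd / length(starts)
  structure(list(freqs = freqs, psd = psd, window_s = window_s,
                 overlap = overlap, n_segments = length(starts)),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d freqs (0-%.1f Hz), %d region(s), %d segments of %g s\n",
              length(x$freqs), max(x$freqs), ncol(x$psd), x$n_segments, x$window_s))
  invisible(x)
}

#' Mean alpha-band power
#'
#' Band-integrated power spectral density (trapezoidal rule over grid points
#' inside the band, inclusive), averaged over regions.  This is the
#' "mean activity" outcome of the simulation experiment.
#'
#' @param spec a [welch_psd()] result.
#' @param band numeric pair (Hz), default the alpha band `c(8, 13)`.
#' @return Scalar band power (units^2).
#' @export
alpha_power <- function(spec, band = c(8, 13)) {
  stopifnot(inherits(spec, "spectrum_estimate"), length(band) == 2)
  if (band[1] < min(spec$freqs) || band[2] > max(spec$freqs))
    stop("alpha_power: band outside the frequency grid", call. = FALSE)
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (sum(sel) < 2)
    stop("alpha_power: band contains fewer than two grid points", call. = FALSE)
  f <- spec$freqs[sel]
  bp <- apply(spec$psd[sel, , drop = FALSE], 2,
              function(p) sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2))
  mean(bp)
}

# zero-phase alpha band-pass: 4th-order Butterworth, forward-backward
band_filter <- function(x, fs, band = c(8, 13), order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  apply(as.matrix(x), 2, function(col) signal::filtfilt(bf, col))
}

# analytic signal per column via the frequency-domain construction
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(x) * h
  mvfft(X, inverse = TRUE) / n
}

#' Phase-locking-value connectivity matrix
#'
#' Pairwise phase locking of the alpha-band-filtered signals:
#' `PLV(x, y) = |mean(exp(i (phi_x - phi_y)))|` with phases from the
#' analytic signal of the zero-phase band-passed series.  One second is
#' trimmed from each edge before averaging to suppress filter transients.
#'
#' @param x a `ct_sim` object or numeric matrix (time x region).
#' @param fs sampling rate (Hz); from the `ct_sim` if omitted.
#' @param band analysis band (Hz).
#' @param edge_trim span discarded at each edge (s).
#' @return Object of class `connectivity_matrix`: list with `plv` (n x n,
#'   symmetric, unit diagonal), `band`.
#' @export
plv_matrix <- function(x, fs = NULL, band = c(8, 13), edge_trim = 1) {
  if (inherits(x, "ct_sim")) { fs <- x$fs; x <- x$series }
  if (is.null(fs)) stop("plv_matrix: fs required for matrix input", call. = FALSE)
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2) stop("plv_matrix: need at least 2 regions", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds < .Machine$double.eps * 1e3))
    stop("plv_matrix: constant region series, phase undefined", call. = FALSE)
  trim <- round(edge_trim * fs)
  keep <- nrow(x) - 2 * trim
  if (keep < 5 * fs / band[1])
    stop("plv_matrix: series too short for >= 5 cycles at the band low edge",
         call. = FALSE)
  xb <- band_filter(x, fs, band)
  za <- analytic_signal(xb)
  za <- za[(trim + 1):(nrow(x) - trim), , drop = FALSE]
  z <- za / Mod(za)
  C <- Mod(t(Conj(z)) %*% z) / nrow(z)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1
  structure(list(plv = C, band = band), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x$plv)
  cat(sprintf("<connectivity_matrix> %d x %d, band %g-%g Hz, mean PLV %.3f\n",
              n, n, x$band[1], x$band[2], mean_plv(x)))
  invisible(x)
}

#' Mean phase-locking value
#'
#' Mean of the strictly off-diagonal upper-triangle entries of a PLV
#' matrix; the diagonal self-locking values are excluded.
#'
#' @param mat a [plv_matrix()] result or a square numeric matrix.
#' @return Scalar in \[0, 1\].
#' @export
mean_plv <- function(mat) {
  M <- if (inherits(mat, "connectivity_matrix")) mat$plv else as.matrix(mat)
  if (nrow(M) < 2) stop("mean_plv: need at least 2 regions", call. = FALSE)
  if (any(M < 0 | M > 1)) stop("mean_plv: entries must lie in [0, 1]", call. = FALSE)
  mean(M[upper.tri(M)])
}

#' Percent change relative to a baseline
#'
#' `100 * (value - baseline) / baseline`, the convention used for all
#' "relative to initial conditions" outcome curves.
#'
#' @param value,baseline numeric; `baseline` must be nonzero.
#' @return Percent change (vectorized over `value`).
#' @export
percent_change <- function(value, baseline) {
  if (any(baseline == 0))
    stop("percent_change: zero baseline", call. = FALSE)
  100 * (value - baseline) / baseline
}

#' Export a PLV matrix or spectra to delimited text
#'
#' @param x a `connectivity_matrix` or `spectrum_estimate`.
#' @param path output path.
#' @param sep delimiter.
#' @export
export_metric <- function(x, path, sep = "\t") {
  if (inherits(x, "connectivity_matrix")) {
    write.table(x$plv, path, sep = sep, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else if (inherits(x, "spectrum_estimate")) {
    reg <- colnames(x$psd)
    if (is.null(reg)) reg <- sprintf("region_%03d", seq_len(ncol(x$psd)))
    long <- data.frame(region = rep(reg, each = length(x$freqs)),
                       freq = rep(x$freqs, ncol(x$psd)),
                       psd = as.vector(x$psd))
    write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else stop("export_metric: unsupported object", call. = FALSE)
  invisible(path)
}
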