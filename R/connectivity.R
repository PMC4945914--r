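#' Connectivity matrix container
#'
#' @param weights symmetric N x N numeric matrix with zero diagonal.
#' @param estimator one of `"correlation"`, `"coherence"`, `"phase_order"`,
#'   `"sync_likelihood"`.
#' @param subject_id subject identifier.
#' @param n_epochs_used number of artifact-free epochs that entered the
#'   estimate.
#' @param channel_labels optional channel labels.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, estimator, subject_id = "s01",
                                n_epochs_used = NA_integer_,
                                channel_labels = NULL) {
  estimator <- match.arg(estimator, estimator_names())
  if (!isSymmetric(unname(weights), tol = 1e-8)) stop_fc("`weights` must be symmetric")
  diag(weights) <- 0
  if (!is.null(channel_labels)) dimnames(weights) <- list(channel_labels, channel_labels)
  structure(
    list(weights = weights, estimator = estimator, subject_id = subject_id,
         n_epochs_used = as.integer(n_epochs_used)),
    class = "connectivity_matrix"
  )
}

estimator_names <- function() c("correlation", "coherence", "phase_order", "sync_likelihood")

#' @export
print.connectivity_matrix <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf(
    "<connectivity_matrix> %s, subject=%s: %d nodes, weights in [%.3f, %.3f], %d epochs used\n",
    x$estimator, x$subject_id, nrow(x$weights), min(w), max(w), x$n_epochs_used))
  invisible(x)
}

#' Absolute Pearson correlation matrix of one epoch
#'
#' Entry (i, j) is `|cov(i, j) / sqrt(var(i) var(j))|`. The absolute value
#' makes the weights non-negative so that threshold/density/MST/MCC
#' binarization is meaningful; `mode = "positive"` instead clips negative
#' correlations to zero.
#'
#' @param epoch channels x samples numeric matrix.
#' @param mode `"abs"` (default) or `"positive"`.
#' @return Symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
pearson_matrix <- function(epoch, mode = c("abs", "positive")) {
  mode <- match.arg(mode)
  v <- apply(epoch, 1, var)
  if (any(v == 0)) {
    stop_fc("zero-variance channel(s): %s — correlation undefined",
            paste(which(v == 0), collapse = ", "))
  }
  r <- cor(t(epoch))
  r <- if (mode == "abs") abs(r) else pmax(r, 0)
  diag(r) <- 0
  r
}

#' Per-bin magnitude-squared coherence spectrum
#'
#' Epoch-pooled cross-spectral estimate: rectangular-windowed periodograms
#' of every artifact-free epoch are accumulated, and coherence
#' `|G_ij(f)|^2 / (G_ii(f) G_jj(f))` is formed at every requested frequency
#' bin. Values lie in `[0, 1]` per bin.
#'
#' @param es an epoch set with >= 2 clean epochs.
#' @param bins integer FFT bin indices (1 = DC); defaults to all positive
#'   frequencies up to Nyquist.
#' @return A list with `coherence` (bins x N x N array), `freq_hz`.
#' @export
coherence_spectrum <- function(es, bins = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  eps <- clean_epochs(es)
  K <- dim(eps)[1]
  if (K < 2) stop_fc("coherence requires multiple epochs (%d clean epoch available)", K)
  C <- dim(eps)[2]; Tn <- dim(eps)[3]
  freqs <- (0:(Tn - 1)) * es$fs_hz / Tn
  if (is.null(bins)) bins <- which(freqs > 0 & freqs <= es$fs_hz / 2)
  G <- array(0i, dim = c(length(bins), C, C))
  for (k in seq_len(K)) {
    Fm <- mvfft(t(matrix(eps[k, , ], nrow = C)))  # samples x channels
    for (b in seq_along(bins)) {
      v <- Fm[bins[b], ]
      G[b, , ] <- G[b, , ] + outer(v, Conj(v))
    }
  }
  coh <- array(0, dim = dim(G))
  for (b in seq_along(bins)) {
    Gb <- G[b, , ]
    auto <- Re(diag(Gb))
    cb <- Mod(Gb)^2 / outer(auto, auto)
    diag(cb) <- 0
    coh[b, , ] <- (cb + t(cb)) / 2
  }
  list(coherence = coh, freq_hz = freqs[bins])
}

#' Band-averaged magnitude-squared coherence
#'
#' Auto- and cross-power spectra are estimated from rectangular-windowed
#' periodograms of each artifact-free epoch and pooled across epochs
#' (epochs act as the realizations of a Welch estimate); coherence
#' `|G_ij(f)|^2 / (G_ii(f) G_jj(f))` is then formed per frequency bin and
#' averaged over every bin whose center lies inside `band_hz` (inclusive).
#' Single-segment coherence is identically 1, hence the two-epoch minimum.
#'
#' @param es an epoch set with at least 2 clean epochs.
#' @param band_hz length-2 band in Hz; defaults to the epoch set's filter
#'   band, or 7-13 Hz if none is recorded.
#' @return Symmetric matrix, entries in `[0, 1]`, zero diagonal.
#' @export
coherence_matrix <- function(es, band_hz = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  band_hz <- band_hz %||% es$band_hz %||% c(7, 13)
  Tn <- dim(es$epochs)[3]
  freqs <- (0:(Tn - 1)) * es$fs_hz / Tn
  bins <- which(freqs >= band_hz[1] & freqs <= band_hz[2] & freqs <= es$fs_hz / 2)
  if (length(bins) == 0) stop_fc("band [%g, %g] Hz contains no frequency bin", band_hz[1], band_hz[2])
  spec <- coherence_spectrum(es, bins)
  apply(spec$coherence, c(2, 3), mean)
}

# Analytic signal via the FFT half-spectrum method: doubles positive
# frequencies, zeroes negative ones, keeps DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous Hilbert phase of a band-limited series
#'
#' Phase of the analytic signal, in `(-pi, pi]`. The first and last 10% of
#' samples are flagged edge-unreliable (Hilbert edge effects) via the
#' `"edge"` attribute, a logical vector that is `TRUE` on trustworthy
#' samples.
#'
#' @param series numeric sample vector (band-pass it first).
#' @param edge_frac fraction of samples flagged at each end (default 0.1).
#' @return Phase vector with attribute `keep` (logical, `FALSE` at edges).
#' @export
hilbert_phase <- function(series, edge_frac = 0.1) {
  if (length(series) < 4) stop_fc("series too short for a phase estimate")
  if (max(series) - min(series) == 0) stop_fc("constant series: phase undefined")
  phi <- Arg(analytic_signal(series))
  n <- length(phi)
  k <- floor(edge_frac * n)
  keep <- rep(TRUE, n)
  if (k > 0) keep[c(seq_len(k), (n - k + 1):n)] <- FALSE
  attr(phi, "keep") <- keep
  phi
}

#' Phase order parameter of two phase series
#'
#' Modulus of the time-averaged complex exponential of the phase difference,
#' `|mean(exp(1i * (phi_u - phi_v)))|`: 1 for perfect phase locking (at any
#' constant lag), about `sqrt(pi) / (2 sqrt(T))` on average for T independent
#' uniform phases.
#'
#' @param phi_u,phi_v phase vectors in radians, equal length.
#' @param keep optional logical vector selecting the samples to average
#'   (e.g. the non-edge samples flagged by [hilbert_phase()]).
#' @return Scalar in `[0, 1]`.
#' @export
phase_order_index <- function(phi_u, phi_v, keep = NULL) {
  if (length(phi_u) != length(phi_v)) stop_fc("phase vectors must have equal length")
  d <- phi_u - phi_v
  if (!is.null(keep)) d <- d[keep]
  Mod(mean(exp(1i * d)))
}

#' Phase order parameter matrix
#'
#' For each channel pair (u, v) and each artifact-free epoch, the phase
#' order parameter is `|mean(exp(1i * (phi_u - phi_v)))|` over the
#' non-edge samples of the epoch; the per-epoch values are averaged over
#' epochs. The index lies in `[0, 1]`: ~0 for independent phases, 1 for
#' perfect phase locking (including locking at a constant nonzero lag).
#'
#' @param es an epoch set (band-pass filtered).
#' @param edge_frac edge fraction excluded from the phase averages.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
phase_order_matrix <- function(es, edge_frac = 0.1) {
  stopifnot(inherits(es, "epoch_set"))
  eps <- clean_epochs(es)
  K <- dim(eps)[1]; C <- dim(eps)[2]
  if (K < 1) stop_fc("no clean epochs")
  acc <- matrix(0, C, C)
  for (k in seq_len(K)) {
    x <- matrix(eps[k, , ], nrow = C)
    Z <- matrix(0i, nrow = ncol(x), ncol = C)
    keep <- NULL
    for (ch in seq_len(C)) {
      phi <- hilbert_phase(x[ch, ], edge_frac)
      keep <- attr(phi, "keep")
      Z[, ch] <- exp(1i * phi)
    }
    Zk <- Z[keep, , drop = FALSE]
    P <- Mod(crossprod(Conj(Zk), Zk)) / nrow(Zk)
    acc <- acc + P
  }
  P <- acc / K
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P
}

#' Per-subject connectivity matrix
#'
#' Runs one dependency estimator on every artifact-free epoch and averages
#' the per-epoch matrices elementwise (coherence instead pools spectra
#' across epochs, the only reading under which 1-s epochs give informative
#' coherence).
#'
#' @param es an epoch set.
#' @param estimator `"correlation"`, `"coherence"`, `"phase_order"` or
#'   `"sync_likelihood"`.
#' @param sl an [sl_params()] list for synchronization likelihood.
#' @param band_hz coherence band override.
#' @param cor_mode forwarded to [pearson_matrix()].
#' @return A [connectivity_matrix()].
#' @export
subject_connectivity <- function(es, estimator = "correlation",
                                 sl = sl_params(), band_hz = NULL,
                                 cor_mode = "abs") {
  stopifnot(inherits(es, "epoch_set"))
  if (!estimator %in% estimator_names()) {
    stop_fc("unknown estimator \"%s\"; valid estimators: %s",
            estimator, paste(estimator_names(), collapse = ", "))
  }
  K <- n_clean_epochs(es)
  if (K < 1) stop_fc("no clean epochs")
  w <- switch(estimator,
    correlation = {
      eps <- clean_epochs(es)
      acc <- 0
      for (k in seq_len(K)) {
        acc <- acc + pearson_matrix(matrix(eps[k, , ], nrow = dim(eps)[2]), mode = cor_mode)
      }
      acc / K
    },
    coherence = coherence_matrix(es, band_hz),
    phase_order = phase_order_matrix(es),
    sync_likelihood = sync_likelihood_matrix(es, sl)
  )
  connectivity_matrix(w, estimator, subject_id = es$subject_id,
                      n_epochs_used = K, channel_labels = es$channel_labels)
}
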