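#' Synchronization likelihood parameters
#'
#' Defaults follow the standard choices for alpha-band EEG at 500 Hz:
#' reference probability `p_ref = 0.01`, embedding lag `L = 10` samples,
#' embedding dimension `e = 10`, Theiler correction `w = 0.1` (interpreted
#' as a fraction of the number of embedded vectors; set
#' `theiler_samples = TRUE` to read it literally as a sample count).
#'
#' @param p_ref reference probability in (0, 1).
#' @param lag_L embedding lag in samples (>= 1).
#' @param embed_e embedding dimension (>= 2; 1 gives the raw scalar series).
#' @param theiler_w Theiler correction, in `[0, 1)` when a fraction.
#' @param theiler_samples logical; interpret `theiler_w` as an absolute
#'   sample separation instead of a fraction.
#' @return A list of class `sl_params`.
#' @export
sl_params <- function(p_ref = 0.01, lag_L = 10, embed_e = 10,
                      theiler_w = 0.1, theiler_samples = FALSE) {
  if (!(p_ref > 0 && p_ref < 1)) stop_fc("`p_ref` must be in (0, 1)")
  if (lag_L < 1) stop_fc("`lag_L` must be >= 1")
  if (embed_e < 1) stop_fc("`embed_e` must be >= 1")
  if (!theiler_samples && !(theiler_w >= 0 && theiler_w < 1)) {
    stop_fc("fractional `theiler_w` must be in [0, 1)")
  }
  structure(list(p_ref = p_ref, lag_L = as.integer(lag_L),
                 embed_e = as.integer(embed_e), theiler_w = theiler_w,
                 theiler_samples = theiler_samples),
            class = "sl_params")
}

#' Time-delay embedding of a scalar series
#'
#' Reconstructs state-space vectors `(y(t), y(t+L), ..., y(t+(e-1)L))`.
#'
#' @param series numeric sample vector of length `T > (e-1) * L`.
#' @param embed_e embedding dimension.
#' @param lag_L lag in samples.
#' @return An `N x e` matrix of `N = T - (e-1) * L` state vectors.
#' @export
embed_delay <- function(series, embed_e = 10, lag_L = 10) {
  Tn <- length(series)
  span <- (embed_e - 1) * lag_L
  if (Tn <= span) {
    stop_fc("series of length %d too short: need T > (e-1)*L = %d", Tn, span)
  }
  N <- Tn - span
  vapply(seq_len(embed_e), function(k) series[(seq_len(N)) + (k - 1) * lag_L],
         numeric(N))
}

theiler_window <- function(N, params) {
  if (params$theiler_samples) as.integer(params$theiler_w)
  else as.integer(ceiling(params$theiler_w * N))
}

# Time separations |t - s| for the elements of dist(x) in their native
# ordering (pairs (s, t), t > s, grouped by s).
dist_separations <- function(N) {
  unlist(lapply(seq_len(N - 1), function(s) seq_len(N - s)))
}

# Euclidean pair distances restricted to Theiler-admissible pairs |t-s| > W.
admissible_distances <- function(vectors, W) {
  N <- nrow(vectors)
  d <- as.vector(dist(vectors))
  d[dist_separations(N) > W]
}

#' Correlation integral of an embedded trajectory
#'
#' The fraction of Theiler-admissible vector pairs (|t - s| greater than the
#' Theiler window) whose Euclidean distance is strictly below `r`.
#'
#' @param vectors `N x e` matrix of state vectors (see [embed_delay()]).
#' @param r radius.
#' @param theiler_w Theiler correction (fraction of `N` by default).
#' @param theiler_samples interpret `theiler_w` as a sample count.
#' @return A probability in `[0, 1]`, non-decreasing in `r`.
#' @export
correlation_integral <- function(vectors, r, theiler_w = 0.1,
                                 theiler_samples = FALSE) {
  p <- sl_params(theiler_w = if (theiler_samples) 0 else theiler_w,
                 theiler_samples = theiler_samples)
  if (theiler_samples) p$theiler_w <- theiler_w
  W <- theiler_window(nrow(vectors), p)
  d <- admissible_distances(vectors, W)
  if (length(d) < 1) stop_fc("no admissible vector pairs after Theiler exclusion")
  mean(d < r)
}

# Radius whose correlation integral is as close as achievable to p_ref,
# given the sorted admissible distances.
radius_at_quantile <- function(d_adm, p_ref) {
  np <- length(d_adm)
  d <- sort(d_adm)
  k <- round(p_ref * np)
  if (k < 1) {
    warning(sprintf("p_ref = %g below resolution 1/%d; using smallest nonzero distance", p_ref, np))
    pos <- d[d > 0]
    if (length(pos) == 0) stop_fc("all admissible distances are zero")
    return(pos[1])
  }
  if (k >= np) return(d[np] * (1 + 1e-9) + 1e-300)
  (d[k] + d[k + 1]) / 2
}

#' Critical radius for a target correlation integral
#'
#' Finds `r` with `CI(r)` as close as achievable to `p_ref` by sorting the
#' admissible pair distances and taking the `p_ref` quantile; the round trip
#' `CI(critical_radius(...))` lands within `1/n_pairs` of `p_ref`.
#'
#' @inheritParams correlation_integral
#' @param p_ref target probability.
#' @return A radius.
#' @export
critical_radius <- function(vectors, p_ref = 0.01, theiler_w = 0.1,
                            theiler_samples = FALSE) {
  p <- sl_params(p_ref = p_ref,
                 theiler_w = if (theiler_samples) 0 else theiler_w,
                 theiler_samples = theiler_samples)
  if (theiler_samples) p$theiler_w <- theiler_w
  W <- theiler_window(nrow(vectors), p)
  d <- admissible_distances(vectors, W)
  if (length(d) < 1) stop_fc("no admissible vector pairs after Theiler exclusion")
  radius_at_quantile(d, p_ref)
}

# Symmetrized synchronization likelihood from two channels' admissible
# distance vectors (same pair ordering).
sl_from_distances <- function(di, dj, p_ref) {
  ri <- radius_at_quantile(di, p_ref)
  rj <- radius_at_quantile(dj, p_ref)
  bi <- di < ri
  bj <- dj < rj
  ni <- sum(bi); nj <- sum(bj)
  if (ni == 0 || nj == 0) {
    stop_fc("empty conditioning set: no admissible pair within the critical radius")
  }
  both <- sum(bi & bj)
  (both / nj + both / ni) / 2
}

#' Synchronization likelihood of one channel pair in one epoch
#'
#' Both series are delay-embedded; per-channel critical radii are calibrated
#' so that the correlation integral equals `p_ref`; the synchronization
#' likelihood in direction i|j is the fraction of j-recurrent admissible
#' pairs that are also i-recurrent, and the reported value is the arithmetic
#' mean of the two directions. It ranges from about `p_ref` (independent
#' series) to 1 (identical recurrence structure).
#'
#' @param xi,xj numeric sample vectors of equal length.
#' @param params an [sl_params()].
#' @return Scalar synchronization likelihood.
#' @export
sl_pair <- function(xi, xj, params = sl_params()) {
  if (length(xi) != length(xj)) stop_fc("series must have equal length")
  Ei <- embed_delay(xi, params$embed_e, params$lag_L)
  Ej <- embed_delay(xj, params$embed_e, params$lag_L)
  W <- theiler_window(nrow(Ei), params)
  di <- admissible_distances(Ei, W)
  dj <- admissible_distances(Ej, W)
  if (length(di) < 2) stop_fc("no admissible vector pairs after Theiler exclusion")
  sl_from_distances(di, dj, params$p_ref)
}

#' Synchronization likelihood matrix
#'
#' [sl_pair()] applied to every channel pair of every artifact-free epoch,
#' averaged over epochs.
#'
#' @param es an epoch set.
#' @param params an [sl_params()].
#' @return Symmetric matrix with entries in `[0, 1]` and zero diagonal.
#' @export
sync_likelihood_matrix <- function(es, params = sl_params()) {
  stopifnot(inherits(es, "epoch_set"))
  eps <- clean_epochs(es)
  K <- dim(eps)[1]; C <- dim(eps)[2]; Tn <- dim(eps)[3]
  if (K < 1) stop_fc("no clean epochs")
  acc <- matrix(0, C, C)
  for (k in seq_len(K)) {
    x <- matrix(eps[k, , ], nrow = C)
    # embed + calibrate every channel once per epoch
    emb <- lapply(seq_len(C), function(ch) embed_delay(x[ch, ], params$embed_e, params$lag_L))
    W <- theiler_window(nrow(emb[[1]]), params)
    dists <- lapply(emb, admissible_distances, W = W)
    radii <- vapply(dists, radius_at_quantile, numeric(1), p_ref = params$p_ref)
    hits <- lapply(seq_len(C), function(ch) which(dists[[ch]] < radii[ch]))
    counts <- lengths(hits)
    if (any(counts == 0)) stop_fc("empty conditioning set for channel(s) %s",
                                  paste(which(counts == 0), collapse = ", "))
    S <- matrix(0, C, C)
    for (i in seq_len(C - 1)) {
      for (j in (i + 1):C) {
        both <- length(intersect(hits[[i]], hits[[j]]))
        S[i, j] <- S[j, i] <- (both / counts[[j]] + both / counts[[i]]) / 2
      }
    }
    acc <- acc + S
  }
  acc / K
}
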