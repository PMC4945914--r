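# Brute-force oracles used across the test files. These deliberately use
# naive enumeration (Floyd-Warshall, explicit path counting, exhaustive
# partition / spanning-tree enumeration) so they share no code path with the
# package implementations they check.

random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- as.integer(runif(length(ut)) < p)
  a + t(a)
}

random_weights <- function(n) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  w[ut] <- runif(length(ut))
  w + t(w)
}

# Floyd-Warshall all-pairs shortest paths
oracle_dist <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_dist(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Shortest-path counts sigma[s, t] by dynamic programming on distance layers
oracle_sigma <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || is.infinite(D[s, t])) next
      preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_node_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_dist(A)
  sigma <- oracle_sigma(A, D)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(D[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc
}

oracle_edge_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_dist(A)
  sigma <- oracle_sigma(A, D)
  eb <- matrix(0, n, n)
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(ut))) {
    u <- ut[k, 1]; v <- ut[k, 2]
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (is.infinite(D[s, t])) next
        cnt <- 0
        if (D[s, u] + 1 + D[v, t] == D[s, t]) cnt <- cnt + sigma[s, u] * sigma[v, t]
        if (D[s, v] + 1 + D[u, t] == D[s, t]) cnt <- cnt + sigma[s, v] * sigma[u, t]
        eb[u, v] <- eb[u, v] + cnt / sigma[s, t]
      }
    }
    eb[ut[k, 2], ut[k, 1]] <- eb[u, v]
  }
  eb
}

# All set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0)
  out
}

oracle_modularity_q <- function(A, memb) {
  m2 <- sum(A)
  q <- 0
  for (l in unique(memb)) {
    idx <- memb == l
    q <- q + sum(A[idx, idx]) / m2 - (sum(A[idx, ]) / m2)^2
  }
  q
}

oracle_best_partition_q <- function(A) {
  max(vapply(all_partitions(nrow(A)), function(m) oracle_modularity_q(A, m),
             numeric(1)))
}

is_connected_acyclic_tree <- function(n, edges) {
  if (nrow(edges) != n - 1) return(FALSE)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
    if (ri == rj) return(FALSE)
    parent[ri] <- rj
  }
  TRUE
}

# Minimum total-distance spanning tree by exhaustive edge-subset enumeration
oracle_min_spanning_distance <- function(dmat) {
  n <- nrow(dmat)
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  best <- Inf
  for (sel in combn(nrow(ut), n - 1, simplify = FALSE)) {
    e <- ut[sel, , drop = FALSE]
    if (is_connected_acyclic_tree(n, e)) {
      best <- min(best, sum(dmat[e]))
    }
  }
  best
}

is_connected_adj <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# Independent synchronization-likelihood oracle: explicit double loops over
# embedded vectors, mirroring the package's conventions (strict inequalities,
# Theiler fraction, quantile radius, symmetrized directions).
oracle_sl_pair <- function(xi, xj, p_ref = 0.05, lag = 1, dim = 2,
                           theiler_w = 0.1) {
  embed_loops <- function(x) {
    N <- length(x) - (dim - 1) * lag
    E <- matrix(0, N, dim)
    for (t in seq_len(N)) for (k in seq_len(dim)) E[t, k] <- x[t + (k - 1) * lag]
    E
  }
  Ei <- embed_loops(xi); Ej <- embed_loops(xj)
  N <- nrow(Ei)
  W <- ceiling(theiler_w * N)
  di <- c(); dj <- c()
  for (t in seq_len(N - 1)) {
    for (s in (t + 1):N) {
      if (s - t > W) {
        di <- c(di, sqrt(sum((Ei[t, ] - Ei[s, ])^2)))
        dj <- c(dj, sqrt(sum((Ej[t, ] - Ej[s, ])^2)))
      }
    }
  }
  radius <- function(d) {
    np <- length(d)
    ds <- sort(d)
    k <- round(p_ref * np)
    if (k < 1) return(min(ds[ds > 0]))
    if (k >= np) return(ds[np] * (1 + 1e-9) + 1e-300)
    (ds[k] + ds[k + 1]) / 2
  }
  ri <- radius(di); rj <- radius(dj)
  both <- sum(di < ri & dj < rj)
  (both / sum(dj < rj) + both / sum(di < ri)) / 2
}

# small convenience: quick band-limited test epoch
test_epoch_sinusoid <- function(freq = 10, fs = 500, n = 500, phase = 0) {
  sin(2 * pi * freq * seq_len(n) / fs + phase)
}
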