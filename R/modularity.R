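#' Newman-Girvan modularity of a given partition
#'
#' `Q = sum_m (e_mm - a_m^2)` where `e_mm` is the fraction of edges inside
#' module m and `a_m` the fraction of edge ends attached to module m. The
#' single-module partition always scores 0.
#'
#' @param G a [binary_network()] or 0/1 adjacency matrix.
#' @param membership integer module label per node.
#' @return Scalar Q.
#' @export
modularity_q <- function(G, membership) {
  A <- adjacency_of(G)
  m2 <- sum(A)                     # twice the edge count
  if (m2 == 0) stop_fc("modularity undefined for an empty graph")
  if (length(membership) != nrow(A)) stop_fc("`membership` must label every node")
  labs <- unique(membership)
  q <- 0
  for (l in labs) {
    idx <- membership == l
    e_mm <- sum(A[idx, idx]) / m2
    a_m <- sum(A[idx, ]) / m2
    q <- q + e_mm - a_m^2
  }
  q
}

# One optimization run: alternate greedy community merges (best delta-Q
# pair) and Kernighan-Lin style single-node moves until neither phase
# improves Q. Scan order is randomized per restart for tie diversity.
modularity_one_run <- function(A, greedy = TRUE) {
  n <- nrow(A)
  m2 <- sum(A)
  memb <- sample.int(n)            # random distinct labels = singleton start
  q <- modularity_q(A, memb)

  # Agglomeration: `greedy` takes the best delta-Q merge each step; the
  # randomized variant picks any positive-gain merge, which spreads the
  # restarts over different basins of attraction.
  merge_phase <- function(memb, q) {
    repeat {
      labs <- unique(memb)
      pairs <- list()
      gains <- numeric(0)
      for (a_i in seq_along(labs)) {
        for (b_i in seq_len(a_i - 1L)) {
          la <- labs[a_i]; lb <- labs[b_i]
          ia <- memb == la; ib <- memb == lb
          e_ab <- sum(A[ia, ib]) / m2
          gain <- 2 * (e_ab - (sum(A[ia, ]) / m2) * (sum(A[ib, ]) / m2))
          if (gain > 1e-12) {
            pairs[[length(pairs) + 1]] <- c(la, lb)
            gains <- c(gains, gain)
          }
        }
      }
      if (length(pairs) == 0) break
      pick <- if (greedy) which.max(gains) else sample.int(length(pairs), 1)
      memb[memb == pairs[[pick]][1]] <- pairs[[pick]][2]
      q <- q + gains[pick]
    }
    list(memb = memb, q = modularity_q(A, memb))
  }

  # Kernighan-Lin pass: tentatively move every node exactly once, always
  # taking the best available move even when it lowers Q, then keep the best
  # intermediate partition seen. Escapes local optima that pure greedy
  # moves cannot leave.
  kl_pass <- function(memb, q) {
    best_memb <- memb; best_q <- q
    unlocked <- rep(TRUE, n)
    cur <- memb; cur_q <- q
    while (any(unlocked)) {
      step_q <- -Inf; step_v <- NA; step_c <- NA
      for (v in which(unlocked)) {
        fresh <- setdiff(seq_len(n), cur)[1]
        cands <- unique(c(cur[A[v, ] > 0], fresh))
        cands <- setdiff(cands[!is.na(cands)], cur[v])
        for (cand in cands) {
          old <- cur[v]
          cur[v] <- cand
          qn <- modularity_q(A, cur)
          cur[v] <- old
          if (qn > step_q) { step_q <- qn; step_v <- v; step_c <- cand }
        }
      }
      if (is.na(step_v)) break
      cur[step_v] <- step_c
      cur_q <- step_q
      unlocked[step_v] <- FALSE
      if (cur_q > best_q + 1e-12) { best_q <- cur_q; best_memb <- cur }
    }
    list(memb = best_memb, q = best_q)
  }

  repeat {
    st <- merge_phase(memb, q)
    st <- kl_pass(st$memb, st$q)
    if (st$q <= q + 1e-12) { memb <- st$memb; q <- st$q; break }
    memb <- st$memb; q <- st$q
  }
  list(Q = q, membership = match(memb, unique(memb)))
}

#' Optimized modularity index
#'
#' Maximizes the Newman-Girvan Q over partitions with a deterministic
#' seeded greedy agglomerative optimizer plus single-node move refinement,
#' taking the best of `restarts` randomized runs.
#'
#' @param G a [binary_network()] or adjacency matrix with at least one edge.
#' @param restarts number of randomized restarts (default 10).
#' @param seed integer seed making the optimization deterministic.
#' @return List with `Q` and the optimal `membership`.
#' @export
modularity_optimal <- function(G, restarts = 10, seed = 42L) {
  A <- adjacency_of(G)
  if (sum(A) == 0) stop_fc("modularity undefined for an empty graph")
  with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      run <- modularity_one_run(A, greedy = (r == 1))
      if (is.null(best) || run$Q > best$Q) best <- run
    }
    best
  })
}
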