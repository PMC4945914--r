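adjacency_of <- function(G) {
  if (inherits(G, "binary_network")) G$adjacency else (unname(as.matrix(G)) != 0) * 1L
}

# BFS shortest-path lengths from one source on a 0/1 adjacency matrix.
# Unreached nodes get Inf.
bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- which(
      (if (length(frontier) == 1) A[frontier, ] else colSums(A[frontier, , drop = FALSE])) > 0 &
        is.infinite(d))
    if (!length(nxt)) break
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

all_pairs_dist <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(s) bfs_dist(A, s), numeric(n))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs,
#' `1/(N(N-1)) * sum_{i != j} 1 / l_ij`, with `1/l = 0` for disconnected
#' pairs. 1 for a complete graph, 0 for an empty one.
#'
#' @param G a [binary_network()] or 0/1 adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(G) {
  A <- adjacency_of(G)
  n <- nrow(A)
  if (n < 2) return(0)
  D <- all_pairs_dist(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Brandes accumulation over all sources; returns node and edge betweenness
# for unordered pairs (ordered-pair sums halved). Endpoint pairs count for
# edges, not for nodes.
brandes <- function(A) {
  n <- nrow(A)
  nbc <- numeric(n)
  ebc <- matrix(0, n, n)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    d <- rep(-1L, n); d[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (u in nbrs[[v]]) {
        if (d[u] < 0) { d[u] <- d[v] + 1L; queue <- c(queue, u) }
        if (d[u] == d[v] + 1L) {
          sigma[u] <- sigma[u] + sigma[v]
          preds[[u]] <- c(preds[[u]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        c_vw <- sigma[v] / sigma[w] * (1 + delta[w])
        ebc[v, w] <- ebc[v, w] + c_vw
        delta[v] <- delta[v] + c_vw
      }
      if (w != s) nbc[w] <- nbc[w] + delta[w]
    }
  }
  list(node = nbc / 2, edge = (ebc + t(ebc)) / 2)
}

#' Node betweenness centrality
#'
#' For each node, the sum over unordered node pairs (excluding pairs that
#' include the node) of the fraction of shortest paths passing through it,
#' by Brandes accumulation. Unnormalized.
#'
#' @param G a [binary_network()] or adjacency matrix.
#' @return List with `values` (per node) and `mean`.
#' @export
node_betweenness <- function(G) {
  A <- adjacency_of(G)
  if (nrow(A) < 3) stop_fc("node betweenness needs at least 3 nodes")
  b <- brandes(A)$node
  list(values = b, mean = mean(b))
}

#' Edge betweenness centrality
#'
#' For each edge, the sum over unordered node pairs (endpoint pairs
#' included) of the fraction of shortest paths using the edge. Unnormalized.
#'
#' @param G a [binary_network()] or adjacency matrix.
#' @return List with `values` (data.frame i, j, ebc) and `mean`.
#' @export
edge_betweenness <- function(G) {
  A <- adjacency_of(G)
  if (sum(A) == 0) stop_fc("edge betweenness needs at least one edge")
  eb <- brandes(A)$edge
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  vals <- data.frame(i = ut[, 1], j = ut[, 2], ebc = eb[ut])
  list(values = vals, mean = mean(vals$ebc))
}

#' Local efficiency
#'
#' Per node: the [global_efficiency()] of the subgraph induced by the
#' node's neighbors (excluding the node itself); 0 when the degree is
#' below 2. The network value is the mean over all nodes. Every tree —
#' including any MST-binarized network — has local efficiency exactly 0.
#'
#' @param G a [binary_network()] or adjacency matrix.
#' @return List with `values` (per node) and `mean`.
#' @export
local_efficiency <- function(G) {
  A <- adjacency_of(G)
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  list(values = vals, mean = mean(vals))
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two endpoints of each edge
#' (each edge contributes both orientations). Positive values mean hubs
#' attach to hubs. Undefined (NA, with a `reason` attribute) for
#' degree-regular graphs, where the endpoint degrees have zero variance.
#'
#' @param G a [binary_network()] or adjacency matrix.
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
assortativity_degree <- function(G) {
  A <- adjacency_of(G)
  if (sum(A) < 4) stop_fc("assortativity needs at least 2 edges")
  deg <- rowSums(A)
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  x <- c(deg[ut[, 1]], deg[ut[, 2]])
  y <- c(deg[ut[, 2]], deg[ut[, 1]])
  if (var(x) == 0 || var(y) == 0) {
    r <- NA_real_
    attr(r, "reason") <- "degree-regular graph: endpoint degree variance is zero"
    return(r)
  }
  cor(x, y)
}

#' Compute a named graph metric
#'
#' Scalar (network-level) value of one of the six supported metrics:
#' `global_efficiency`, `node_betweenness` (mean over nodes),
#' `edge_betweenness` (mean over edges), `local_efficiency` (mean over
#' nodes), `modularity` (optimized Newman Q), `assortativity`.
#'
#' @param G a [binary_network()] or adjacency matrix.
#' @param metric metric name.
#' @param ... forwarded to the metric function (e.g. modularity optimizer
#'   settings).
#' @return Scalar value (`NA` with a reason attribute when undefined).
#' @export
graph_metric <- function(G, metric, ...) {
  metric <- match.arg(metric, metric_names())
  switch(metric,
    global_efficiency = global_efficiency(G),
    node_betweenness = node_betweenness(G)$mean,
    edge_betweenness = edge_betweenness(G)$mean,
    local_efficiency = local_efficiency(G)$mean,
    modularity = modularity_optimal(G, ...)$Q,
    assortativity = assortativity_degree(G)
  )
}

metric_names <- function() {
  c("global_efficiency", "node_betweenness", "edge_betweenness",
    "local_efficiency", "modularity", "assortativity")
}
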