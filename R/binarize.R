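#' Binary network container
#'
#' @param adjacency 0/1 symmetric matrix with zero diagonal.
#' @param method one of `"threshold"`, `"density"`, `"mst"`, `"mcc"`.
#' @param parameter threshold value or density, `NA` for mst/mcc.
#' @return An object of class `binary_network`.
#' @export
binary_network <- function(adjacency, method, parameter = NA_real_) {
  method <- match.arg(method, binarizer_names())
  adjacency <- (unname(adjacency) != 0) * 1L
  if (!isSymmetric(adjacency)) stop_fc("`adjacency` must be symmetric")
  diag(adjacency) <- 0L
  structure(
    list(adjacency = adjacency, method = method, parameter = parameter,
         n_edges = sum(adjacency) / 2L),
    class = "binary_network"
  )
}

binarizer_names <- function() c("threshold", "density", "mst", "mcc")

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %s%s: %d nodes, %d edges\n",
              x$method,
              if (is.na(x$parameter)) "" else sprintf("(%g)", x$parameter),
              nrow(x$adjacency), x$n_edges))
  invisible(x)
}

weights_of <- function(W) {
  if (inherits(W, "connectivity_matrix")) W$weights else unname(as.matrix(W))
}

# Upper-triangle edges of a weight matrix ordered by descending weight,
# ties broken lexicographically by (i, j). Deterministic.
ordered_edges <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[ut], ut[, 1], ut[, 2])
  data.frame(i = ut[ord, 1], j = ut[ord, 2], w = w[ut][ord])
}

#' Uniform-threshold binarization
#'
#' Keeps edge (i, j) iff its weight is strictly greater than `th`. The
#' result may be disconnected or empty; downstream metrics treat
#' disconnected pairs as infinitely distant.
#'
#' @param W a [connectivity_matrix()] or plain symmetric weight matrix.
#' @param th threshold, `>= 0`.
#' @return A [binary_network()].
#' @export
threshold_binarize <- function(W, th) {
  if (th < 0) stop_fc("`th` must be >= 0")
  w <- weights_of(W)
  binary_network((w > th) * 1L, "threshold", th)
}

#' Fixed-density binarization
#'
#' Retains the `round(kappa * N * (N - 1) / 2)` strongest edges, so that
#' every subject's network has the same edge count regardless of its weight
#' scale. Ties at the cut are broken by descending weight then lexicographic
#' (i, j) order.
#'
#' @param W weight matrix or [connectivity_matrix()].
#' @param kappa target density in `(0, 1]`.
#' @return A [binary_network()].
#' @export
density_binarize <- function(W, kappa) {
  if (!(kappa > 0 && kappa <= 1)) stop_fc("`kappa` must be in (0, 1]")
  w <- weights_of(W)
  n <- nrow(w)
  m <- round(kappa * n * (n - 1) / 2)
  if (m < 1) stop_fc("kappa = %g yields zero edges on %d nodes", kappa, n)
  ed <- head(ordered_edges(w), m)
  a <- matrix(0L, n, n)
  a[cbind(ed$i, ed$j)] <- 1L
  a <- a + t(a)
  binary_network(a, "density", kappa)
}

check_weighted_connected <- function(w, method) {
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected", diag = FALSE)
  if (igraph::components(g)$no > 1) {
    stop_fc("%s requires a connected weighted graph (nonzero weights leave it disconnected)", method)
  }
}

#' Minimum spanning tree binarization
#'
#' Weights are converted to distances (`d = 1 - w` by default, so the
#' strongest dependencies become the shortest distances) and the minimum
#' spanning tree of the distance graph is kept: exactly `N - 1` edges,
#' connected, acyclic. Any strictly decreasing transform gives the same
#' tree when weights are distinct; `transform = "inverse"` uses `d = 1/w`.
#'
#' @param W weight matrix or [connectivity_matrix()]; must be connected on
#'   its nonzero entries.
#' @param transform `"one_minus"` (default) or `"inverse"`.
#' @return A [binary_network()] with `N - 1` edges.
#' @export
mst_binarize <- function(W, transform = c("one_minus", "inverse")) {
  transform <- match.arg(transform)
  w <- weights_of(W)
  check_weighted_connected(w, "mst")
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  dist_w <- switch(transform, one_minus = 1 - w[ut], inverse = 1 / w[ut])
  g <- igraph::graph_from_edgelist(ut, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = dist_w)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  tree <- igraph::mst(g, algorithm = "prim")
  a <- matrix(0L, n, n)
  el <- igraph::as_edgelist(tree)
  a[el] <- 1L
  a <- (a + t(a) > 0) * 1L
  binary_network(a, "mst")
}

#' Minimum connected component binarization
#'
#' Starting from N isolated nodes, edges are added in strictly descending
#' weight order — including edges internal to an already-formed component —
#' until the graph is connected. Equal weights at the connecting step are
#' added as a whole tie group. The result is connected with at least
#' `N - 1` edges and always contains the strongest-spanning-tree (MST on
#' `d = 1 - w`) edge set.
#'
#' @param W weight matrix or [connectivity_matrix()]; must be connected on
#'   its nonzero entries.
#' @return A [binary_network()].
#' @export
mcc_binarize <- function(W) {
  w <- weights_of(W)
  check_weighted_connected(w, "mcc")
  n <- nrow(w)
  ed <- ordered_edges(w)
  ed <- ed[ed$w > 0, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  a <- matrix(0L, n, n)
  n_comp <- n
  k <- 1
  while (k <= nrow(ed) && n_comp > 1) {
    # take the whole tie group at this weight
    wk <- ed$w[k]
    grp <- k
    while (grp < nrow(ed) && ed$w[grp + 1] == wk) grp <- grp + 1
    for (t in k:grp) {
      i <- ed$i[t]; j <- ed$j[t]
      a[i, j] <- a[j, i] <- 1L
      ri <- find(i); rj <- find(j)
      if (ri != rj) { parent[ri] <- rj; n_comp <- n_comp - 1 }
    }
    k <- grp + 1
  }
  if (n_comp > 1) stop_fc("mcc: graph never became connected")
  binary_network(a, "mcc")
}

#' Dispatch a binarizer by name
#'
#' @param W weight matrix or [connectivity_matrix()].
#' @param method `"threshold"`, `"density"`, `"mst"` or `"mcc"`.
#' @param parameter threshold value or density; ignored for mst/mcc.
#' @return A [binary_network()].
#' @export
binarize <- function(W, method, parameter = NA_real_) {
  method <- match.arg(method, binarizer_names())
  switch(method,
    threshold = threshold_binarize(W, parameter),
    density = density_binarize(W, parameter),
    mst = mst_binarize(W),
    mcc = mcc_binarize(W)
  )
}
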