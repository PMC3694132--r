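#' Pearson correlation matrix of node time series
#'
#' @param ts a [timeseries_matrix()].
#' @return Symmetric correlation matrix with unit diagonal, node labels as
#'   dimnames.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  v <- apply(ts$values, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance time series for node(s): ",
         paste(ts$node_ids[v == 0], collapse = ", "))
  r <- stats::cor(t(ts$values))
  dimnames(r) <- list(ts$node_ids, ts$node_ids)
  r
}

#' Convert a correlation matrix to a rectified Fisher-z weight matrix
#'
#' Off-diagonal weights are `|atanh(r)|` (Fisher r-to-z transform followed
#' by rectification to absolute value); the diagonal is set to zero.
#'
#' @param corr symmetric correlation matrix (unit diagonal).
#' @return Symmetric nonnegative weight matrix with zero diagonal.
#' @export
to_weight_matrix <- function(corr) {
  corr <- as.matrix(corr)
  off <- corr
  diag(off) <- 0
  if (any(abs(off) >= 1))
    stop("off-diagonal |r| >= 1 gives an infinite Fisher-z weight")
  w <- abs(atanh(off))
  diag(w) <- 0
  w
}

#' Number of edges retained at a given network cost
#'
#' Cost (sparsity) is the fraction of all `n(n-1)/2` node pairs kept as
#' edges. The edge count is `cost * n(n-1)/2` rounded half up. The cost
#' must leave room for the spanning backbone (`n - 1` edges).
#'
#' @param n_nodes number of nodes (>= 2).
#' @param cost cost in (0, 1].
#' @return Integer edge count.
#' @examples
#' edges_for_cost(116, 0.03)  # 200
#' @export
edges_for_cost <- function(n_nodes, cost) {
  if (n_nodes < 2L) stop("need at least 2 nodes")
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  if (cost <= 0 || cost > 1) stop("cost must be in (0, 1]")
  m <- round_half_up(cost * n_pairs)
  if (m < n_nodes - 1L)
    stop(sprintf(
      "cost %.4g keeps %d edges but the spanning backbone needs %d; minimum feasible cost is %.4g",
      cost, m, n_nodes - 1L, (n_nodes - 1 - 0.5) / n_pairs))
  as.integer(m)
}

# Deterministic ranking of all node pairs: descending weight, ties broken
# lexicographically on (smaller index, larger index). Returns the pair
# list and, within it, which pairs form the maximum-weight spanning tree
# (Kruskal with union-find) and the growth order of the remaining pairs.
rank_edges <- function(weights) {
  n <- nrow(weights)
  pr <- pair_indices(n)
  wv <- weights[cbind(pr$i, pr$j)]
  ord <- order(-wv, pr$i, pr$j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(length(ord))
  n_tree <- 0L
  for (k in seq_along(ord)) {
    e <- ord[k]
    ri <- find(pr$i[e])
    rj <- find(pr$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      in_tree[k] <- TRUE
      n_tree <- n_tree + 1L
      if (n_tree == n - 1L) break
    }
  }
  # retained order: backbone edges first (in rank order), then the rest
  list(i = pr$i, j = pr$j, w = wv,
       retained_order = c(ord[in_tree], ord[!in_tree]))
}

make_thresholded <- function(weights, cost, mode, ranked, node_ids) {
  n <- nrow(weights)
  m <- edges_for_cost(n, cost)
  keep <- ranked$retained_order[seq_len(m)]
  ei <- ranked$i[keep]
  ej <- ranked$j[keep]
  A <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  val <- if (mode == "binary") rep(1, m) else ranked$w[keep]
  A[cbind(ei, ej)] <- val
  A[cbind(ej, ei)] <- val
  structure(list(adjacency = A,
                 edges = cbind(i = ei, j = ej),
                 cost = cost, mode = mode, n_edges = m,
                 node_ids = node_ids),
            class = "thresholded_graph")
}

#' Threshold a weight matrix into a connected graph at a fixed cost
#'
#' Implements spanning-backbone thresholding: first a maximum-weight
#' spanning tree is kept (every node reaches every other, no isolated
#' "islands"), then the remaining node pairs are added in strictly
#' descending weight order until the edge count for the requested cost is
#' reached. The output is therefore connected at every feasible cost. In
#' binary mode retained edges are set to one; in weighted mode they keep
#' their weight. Equal weights are broken deterministically by node index.
#'
#' @param weights symmetric nonnegative weight matrix
#'   (see [to_weight_matrix()]).
#' @param cost cost in (0, 1]; see [edges_for_cost()].
#' @param mode `"binary"` or `"weighted"`.
#' @return A `thresholded_graph`: `adjacency` (dense symmetric matrix),
#'   `edges` (2-column index matrix in retention order), `cost`, `mode`,
#'   `n_edges`, `node_ids`.
#' @export
mst_threshold <- function(weights, cost, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  weights <- as.matrix(weights)
  if (any(weights < 0) || any(diag(weights) != 0) ||
      !isTRUE(all.equal(weights, t(weights))))
    stop("weights must be symmetric and nonnegative with zero diagonal")
  node_ids <- rownames(weights)
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(nrow(weights)))
  ranked <- rank_edges(weights)
  make_thresholded(weights, cost, mode, ranked, node_ids)
}

#' Threshold at a sweep of costs
#'
#' Produces one graph per cost. The edge ranking (backbone first, then
#' descending weight) is computed once, so edge sets are nested across the
#' sweep: the graph at a lower cost is a subgraph of the graph at any
#' higher cost.
#'
#' @param weights symmetric nonnegative weight matrix.
#' @param costs ascending vector of costs; default the conventional sweep
#'   0.03 to 0.40 in steps of 0.01 ([default_cost_grid()]).
#' @param mode `"binary"` or `"weighted"`.
#' @return Named list of `thresholded_graph`s, one per cost.
#' @export
cost_sweep <- function(weights, costs = default_cost_grid(),
                       mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  if (is.unsorted(costs, strictly = TRUE))
    stop("costs must be strictly ascending")
  weights <- as.matrix(weights)
  node_ids <- rownames(weights)
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(nrow(weights)))
  ranked <- rank_edges(weights)
  out <- lapply(costs, function(co)
    make_thresholded(weights, co, mode, ranked, node_ids))
  names(out) <- sprintf("%.2f", costs)
  out
}

#' Default cost grid: 0.03 to 0.40 in 0.01 steps (38 costs)
#' @return Numeric vector of costs.
#' @export
default_cost_grid <- function() round(seq(0.03, 0.40, by = 0.01), 2)

#' Convert a thresholded graph to an igraph object
#'
#' @param g a `thresholded_graph`.
#' @return An undirected `igraph` graph; in weighted mode the edge weights
#'   are carried in the `weight` edge attribute.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  ig <- igraph::graph_from_adjacency_matrix(
    g$adjacency, mode = "undirected",
    weighted = if (g$mode == "weighted") TRUE else NULL)
  ig
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d edges (cost %.2f, %s)\n",
              length(x$node_ids), x$n_edges, x$cost, x$mode))
  invisible(x)
}
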