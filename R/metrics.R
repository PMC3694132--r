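# binarised topology of the input, as an igraph object
as_binary_igraph <- function(g) {
  if (inherits(g, "thresholded_graph")) {
    A <- (g$adjacency != 0) * 1
    igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  } else if (igraph::is_igraph(g)) {
    if ("weight" %in% igraph::edge_attr_names(g))
      g <- igraph::delete_edge_attr(g, "weight")
    g
  } else {
    stop("expected a thresholded_graph or igraph object")
  }
}

#' Watts-Strogatz small-world metrics: clustering and path length
#'
#' `Cp` is the mean over nodes of the local clustering coefficient
#' (fraction of a node's neighbour pairs that are themselves connected;
#' zero for nodes of degree below two). `Lp` is the characteristic path
#' length: the mean shortest-path length over all unordered node pairs.
#' Both are defined on the binarised topology; `Lp` requires a connected
#' graph (guaranteed for graphs from [mst_threshold()]).
#'
#' @param g a `thresholded_graph` (or undirected igraph).
#' @return List with elements `Cp` and `Lp`.
#' @export
smallworld_metrics <- function(g) {
  ig <- as_binary_igraph(g)
  if (!igraph::is_connected(ig))
    stop("characteristic path length requires a connected graph")
  Cp <- mean(igraph::transitivity(ig, type = "localundirected",
                                  isolates = "zero"))
  Lp <- igraph::mean_distance(ig, directed = FALSE)
  list(Cp = Cp, Lp = Lp)
}

#' Latora-Marchiori network efficiency
#'
#' `Eglobal` is the mean over unordered node pairs of the inverse shortest
#' path length (`1/Inf = 0` for disconnected pairs). `Elocal` is the mean
#' over nodes of the global efficiency of the subgraph induced by the
#' node's neighbours (zero for nodes with fewer than two neighbours).
#'
#' @param g a `thresholded_graph` (or undirected igraph); need not be
#'   connected.
#' @return List with elements `Eglobal` and `Elocal`.
#' @export
efficiency <- function(g) {
  ig <- as_binary_igraph(g)
  n <- igraph::vcount(ig)
  eglob <- function(h) {
    nv <- igraph::vcount(h)
    if (nv < 2L) return(0)
    d <- igraph::distances(h)
    inv <- 1 / d[upper.tri(d)]
    mean(ifelse(is.finite(inv), inv, 0))
  }
  Eglobal <- eglob(ig)
  Elocal <- mean(vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(ig, v))
    if (length(nb) < 2L) return(0)
    eglob(igraph::induced_subgraph(ig, nb))
  }, numeric(1)))
  list(Eglobal = Eglobal, Elocal = Elocal)
}

#' All four topological metrics of a graph
#'
#' @param g a connected `thresholded_graph`.
#' @return List with `Cp`, `Lp`, `Eglobal`, `Elocal`.
#' @export
metric_set <- function(g) {
  c(smallworld_metrics(g), efficiency(g))
}

# is the adjacency matrix connected? (BFS)
adj_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  count <- 1L
  while (length(frontier)) {
    nb <- which((rowSums(A[, frontier, drop = FALSE]) > 0) & !seen)
    seen[nb] <- TRUE
    count <- count + length(nb)
    frontier <- nb
  }
  count == n
}

# connectedness-preserving degree-sequence-preserving double edge swaps
rewire_connected <- function(A, n_attempts) {
  n <- nrow(A)
  el <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  m <- nrow(el)
  for (k in seq_len(n_attempts)) {
    e <- sample.int(m, 2L)
    a <- el[e[1L], 1L]; b <- el[e[1L], 2L]
    c_ <- el[e[2L], 1L]; d <- el[e[2L], 2L]
    if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    # propose (a,b),(c,d) -> (a,d),(c,b)
    if (length(unique(c(a, b, c_, d))) < 4L) next
    if (A[a, d] != 0 || A[c_, b] != 0) next
    A[a, b] <- A[b, a] <- 0
    A[c_, d] <- A[d, c_] <- 0
    A[a, d] <- A[d, a] <- 1
    A[c_, b] <- A[b, c_] <- 1
    if (adj_connected(A)) {
      el[e[1L], ] <- sort(c(a, d))
      el[e[2L], ] <- sort(c(c_, b))
    } else {  # revert
      A[a, d] <- A[d, a] <- 0
      A[c_, b] <- A[b, c_] <- 0
      A[a, b] <- A[b, a] <- 1
      A[c_, d] <- A[d, c_] <- 1
    }
  }
  A
}

#' Ring-lattice regular graph with a given node and edge count
#'
#' Edges are laid on a circle by increasing circular distance: complete
#' rings at distance 1, 2, ... as long as whole rings fit, then the
#' remaining edges at the next distance, assigned to the lowest-indexed
#' nodes. Matches the edge count of the observed graph so lattice metrics
#' are comparable.
#'
#' @param n number of nodes.
#' @param m number of edges (at most `n(n-1)/2`).
#' @return Adjacency matrix of the lattice.
#' @export
ring_lattice <- function(n, m) {
  stopifnot(m <= n * (n - 1) / 2)
  A <- matrix(0, n, n)
  left <- m
  d <- 1L
  while (left > 0L) {
    ring_size <- if (2L * d == n) n %/% 2L else n
    take <- min(left, ring_size)
    for (i in seq_len(take)) {
      j <- ((i + d - 1L) %% n) + 1L
      A[i, j] <- A[j, i] <- 1
    }
    left <- left - take
    d <- d + 1L
    if (d > n %/% 2L && left > 0L)
      stop("cannot place all edges on a ring lattice")
  }
  A
}

#' Reference (null) networks for small-world normalisation
#'
#' Random references are degree-preserving double-edge-swap rewirings of
#' the observed graph (10 x |E| swap attempts each, every accepted swap
#' keeps the graph connected), as is standard for small-world
#' normalisation. The regular reference is a ring lattice with the same
#' node and edge count.
#'
#' @param g a connected binary `thresholded_graph`.
#' @param n_random number of random rewired references (default 20).
#' @param seed integer RNG seed.
#' @return List with `random` (list of adjacency matrices) and `lattice`
#'   (one adjacency matrix).
#' @export
reference_networks <- function(g, n_random = 20, seed) {
  stopifnot(inherits(g, "thresholded_graph"))
  if (n_random < 1L) stop("n_random must be at least 1")
  A <- (g$adjacency != 0) * 1
  dimnames(A) <- NULL
  m <- g$n_edges
  set.seed(as.integer(seed))
  random <- lapply(seq_len(n_random), function(k)
    rewire_connected(A, 10L * m))
  list(random = random, lattice = ring_lattice(nrow(A), m))
}

metrics_of_adjacency <- function(A) {
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  list(Cp = mean(igraph::transitivity(ig, type = "localundirected",
                                      isolates = "zero")),
       Lp = igraph::mean_distance(ig, directed = FALSE))
}

#' Humphries-Gurney small-worldness
#'
#' `sigma = (Cp / <Cp_random>) / (Lp / <Lp_random>)`: the clustering of the
#' observed graph relative to degree-matched random references, divided by
#' its relative path length. Values clearly above 1 indicate a small-world
#' regime (lattice-like clustering with random-like path lengths).
#'
#' @param g a connected binary `thresholded_graph`.
#' @param refs a [reference_networks()] result for `g`.
#' @return sigma (single number).
#' @export
small_worldness <- function(g, refs) {
  stopifnot(length(refs$random) >= 1L)
  obs <- smallworld_metrics(g)
  rnd <- lapply(refs$random, metrics_of_adjacency)
  mCp <- mean(vapply(rnd, `[[`, numeric(1), "Cp"))
  mLp <- mean(vapply(rnd, `[[`, numeric(1), "Lp"))
  if (mCp == 0) stop("mean random clustering is zero; sigma undefined")
  (obs$Cp / mCp) / (obs$Lp / mLp)
}

#' Per-subject metric curves over a cost sweep
#'
#' @param cohort_graphs nested list: group -> subject -> cost ->
#'   `thresholded_graph` (as produced by sweeping each subject of a
#'   cohort with [cost_sweep()]).
#' @return A long data.frame with columns `group`, `subject`, `cost`,
#'   `Cp`, `Lp`, `Eglobal`, `Elocal`.
#' @export
metric_curves <- function(cohort_graphs) {
  rows <- list()
  for (g in names(cohort_graphs)) {
    for (si in seq_along(cohort_graphs[[g]])) {
      sweep_ <- cohort_graphs[[g]][[si]]
      for (cn in names(sweep_)) {
        ms <- metric_set(sweep_[[cn]])
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, subject = si, cost = sweep_[[cn]]$cost,
          Cp = ms$Cp, Lp = ms$Lp, Eglobal = ms$Eglobal,
          Elocal = ms$Elocal, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Group mean and standard error of metric curves
#'
#' @param curves a [metric_curves()] data.frame.
#' @return Long data.frame with columns `group`, `cost`, `metric`, `mean`,
#'   `sem`, `n`.
#' @export
summarize_metric_curves <- function(curves) {
  metrics <- c("Cp", "Lp", "Eglobal", "Elocal")
  out <- list()
  for (met in metrics) {
    agg <- stats::aggregate(curves[[met]],
                            by = list(group = curves$group,
                                      cost = curves$cost),
                            FUN = function(x)
                              c(mean = mean(x),
                                sem = stats::sd(x) / sqrt(length(x)),
                                n = length(x)))
    out[[met]] <- data.frame(group = agg$group, cost = agg$cost,
                             metric = met,
                             mean = agg$x[, "mean"], sem = agg$x[, "sem"],
                             n = agg$x[, "n"], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
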