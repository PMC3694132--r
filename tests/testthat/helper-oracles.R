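# Brute-force oracles, independent of the package implementation paths.

# all-pairs shortest path lengths by Floyd-Warshall on a binary adjacency
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1)))
}

oracle_path_length <- function(A) {
  D <- oracle_floyd_warshall(A)
  mean(D[upper.tri(D)])
}

oracle_eglobal <- function(A) {
  if (nrow(A) < 2) return(0)
  D <- oracle_floyd_warshall(A)
  inv <- 1 / D[upper.tri(D)]
  mean(ifelse(is.finite(inv), inv, 0))
}

oracle_elocal <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_eglobal(A[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# random connected Erdos-Renyi adjacency (resampled until connected)
random_connected_adjacency <- function(n, p) {
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- as.numeric(stats::runif(sum(up)) < p)
    A <- A + t(A)
    D <- oracle_floyd_warshall(A)
    if (all(is.finite(D))) return(A)
  }
}

# wrap an adjacency matrix as a thresholded_graph for metric/partition calls
graph_from_adjacency_fixture <- function(A, mode = "binary") {
  n <- nrow(A)
  ids <- sprintf("n%03d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  structure(list(adjacency = A,
                 edges = cbind(i = idx[, 1], j = idx[, 2]),
                 cost = sum(A != 0) / (n * (n - 1)),
                 mode = mode, n_edges = nrow(idx), node_ids = ids),
            class = "thresholded_graph")
}

# exhaustive assignment oracle: maximise total overlap over permutations
oracle_best_assignment_value <- function(M) {
  k <- max(nrow(M), ncol(M))
  P <- matrix(0, k, k)
  P[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- -Inf
  for (pp in perms(seq_len(k)))
    best <- max(best, sum(P[cbind(seq_len(k), pp)]))
  best
}

# all set partitions of 1..n (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_id) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (id in seq_len(next_id))
      grow(c(labels, id), max(next_id, id + 1))
  }
  grow(integer(0), 1)
  out
}

# random weight matrix fixture (symmetric, nonnegative, zero diagonal)
random_weight_matrix <- function(n) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  W[up] <- abs(stats::rnorm(sum(up)))
  W + t(W)
}

# sample correlation mean within / between planted modules
mean_block_correlations <- function(ts, partition) {
  r <- correlation_matrix(ts)
  same <- outer(partition, partition, "==")
  up <- upper.tri(r)
  list(within = mean(r[same & up]), between = mean(r[!same & up]))
}
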