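#' Detect a modular partition by seeded Louvain modularity maximisation
#'
#' Runs Louvain community detection `n_restarts` times, each on a random
#' permutation of the vertex order (the only source of variability in the
#' greedy optimiser), and keeps the partition with the highest Newman
#' modularity Q. In weighted mode both the optimisation and Q use the edge
#' weights.
#'
#' @param g a connected `thresholded_graph` (binary or weighted).
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @param n_restarts number of restarts (default 20).
#' @return A `partition` object: `labels` (named integer vector,
#'   contiguous ids in first-appearance order), `Q` (modularity on the
#'   input graph), `cost`, `mode`.
#' @export
detect_partition <- function(g, seed, n_restarts = 20) {
  stopifnot(inherits(g, "thresholded_graph"))
  ig <- as_igraph(g)
  w <- if (g$mode == "weighted") igraph::E(ig)$weight else NULL
  n <- length(g$node_ids)
  set.seed(as.integer(seed))
  best <- NULL
  bestQ <- -Inf
  for (r in seq_len(n_restarts)) {
    perm <- sample.int(n)
    igp <- igraph::permute(ig, perm)
    cl <- igraph::cluster_louvain(igp, weights = if (g$mode == "weighted")
      igraph::E(igp)$weight else NULL)
    memb <- igraph::membership(cl)[perm]
    Q <- igraph::modularity(ig, memb, weights = w)
    if (Q > bestQ) {
      bestQ <- Q
      best <- memb
    }
  }
  labels <- as.integer(factor(best, levels = unique(best)))
  names(labels) <- g$node_ids
  structure(list(labels = labels, Q = bestQ, cost = g$cost, mode = g$mode),
            class = "partition")
}

#' Wrap an explicit labeling as a partition object
#'
#' @param labels vector of module labels, one per node (names = node ids).
#' @param Q optional modularity value to attach.
#' @return A `partition`.
#' @export
as_partition <- function(labels, Q = NA_real_) {
  # numeric labels are kept as-is (ids may be meaningful, e.g. after
  # match_labels); non-numeric labels are coded in first-appearance order
  lv <- if (is.numeric(labels)) as.integer(labels)
        else as.integer(factor(labels, levels = unique(labels)))
  names(lv) <- names(labels)
  structure(list(labels = lv, Q = Q, cost = NA_real_, mode = NA_character_),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes, %d modules, Q = %.4f\n",
              length(x$labels), length(unique(x$labels)), x$Q))
  invisible(x)
}

partition_labels <- function(p) {
  if (inherits(p, "partition")) p$labels else p
}

#' Count major modules (at least `min_size` nodes)
#'
#' @param p a `partition` (or plain label vector).
#' @param min_size minimum module size to count as major (default 6).
#' @return Integer count of major modules.
#' @export
count_major_modules <- function(p, min_size = 6) {
  sum(table(partition_labels(p)) >= min_size)
}

# fast cross-tabulation of two small integer label vectors
crosstab <- function(a, b) {
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  ka <- max(a)
  kb <- max(b)
  matrix(tabulate((b - 1L) * ka + a, nbins = ka * kb), ka, kb)
}

#' Normalized mutual information between two partitions
#'
#' `NMI = 2 I(A;B) / (H(A) + H(B))` with natural logarithms
#' (arithmetic-mean normalisation). Equals 1 when the partitions are
#' identical up to relabeling and 0 when they are independent. Degenerate
#' zero-entropy cases: two single-module partitions are defined as
#' identical (NMI 1); a single-module partition against a structured one
#' gives 0.
#'
#' @param pa,pb `partition` objects (or label vectors) over the same node
#'   set.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(pa, pb) {
  a <- partition_labels(pa)
  b <- partition_labels(pb)
  if (length(a) != length(b))
    stop("partitions are over different node sets")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b)))
    stop("partitions are over different node sets")
  ct <- crosstab(a, b)
  n <- sum(ct)
  pi_ <- rowSums(ct) / n
  pj <- colSums(ct) / n
  Ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  Hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  pij <- ct / n
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  max(0, min(1, 2 * I / (Ha + Hb)))
}

# S x S pairwise NMI matrix of a list of partitions
pairwise_nmi <- function(partitions) {
  S <- length(partitions)
  M <- diag(1, S)
  for (i in seq_len(S - 1L))
    for (j in (i + 1L):S)
      M[i, j] <- M[j, i] <- nmi(partitions[[i]], partitions[[j]])
  M
}

#' Group-membership permutation test of partition similarity
#'
#' Tests whether subjects' modular architectures are more similar within
#' groups than between groups. The observed statistic is the mean pairwise
#' similarity (NMI) over all within-group subject pairs (both groups
#' pooled) minus the mean over between-group pairs. The null distribution
#' is built by shuffling the pooled group membership (group sizes
#' preserved); the one-sided p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)` and therefore
#' can never be exactly zero.
#'
#' @param partitions_a,partitions_b lists of `partition`s, one per subject
#'   of each group (at least 2 subjects per group).
#' @param n_permutations number of label shuffles (default 10000).
#' @param seed integer RNG seed.
#' @return A `similarity_test` object: `observed`, `null_values`, `p`,
#'   `n_permutations`, plus descriptive `within_a`, `within_b`, `between`
#'   mean similarities.
#' @export
similarity_permutation_test <- function(partitions_a, partitions_b,
                                        n_permutations = 10000, seed) {
  if (length(partitions_a) < 2L || length(partitions_b) < 2L)
    stop("each group needs at least 2 subjects")
  parts <- c(partitions_a, partitions_b)
  group <- rep(c("a", "b"), c(length(partitions_a), length(partitions_b)))
  M <- pairwise_nmi(parts)
  pr <- pair_indices(length(parts))
  sim <- matrix(M[cbind(pr$i, pr$j)], ncol = 1L)
  res <- comembership_perm_test(sim, group, n_permutations, seed)
  wa <- group[pr$i] == "a" & group[pr$j] == "a"
  wb <- group[pr$i] == "b" & group[pr$j] == "b"
  structure(list(observed = res$observed[1L],
                 null_values = res$null[, 1L],
                 p = res$p[1L],
                 n_permutations = n_permutations,
                 within_a = mean(sim[wa, 1L]),
                 within_b = mean(sim[wb, 1L]),
                 between = mean(sim[!(wa | wb), 1L])),
            class = "similarity_test")
}

#' @export
print.similarity_test <- function(x, ...) {
  cat(sprintf(
    "<similarity_test> observed (within - between) = %.4f, p = %.4g (%d permutations)\n",
    x$observed, x$p, x$n_permutations))
  invisible(x)
}

#' Pick the representative subject of a group
#'
#' The representative is the subject whose partition has the highest mean
#' NMI to all other subjects' partitions; ties go to the lowest index.
#'
#' @param partitions list of `partition`s (length >= 1).
#' @return 1-based index of the representative subject.
#' @export
select_representative <- function(partitions) {
  if (length(partitions) < 1L) stop("need at least one partition")
  if (length(partitions) == 1L) return(1L)
  M <- pairwise_nmi(partitions)
  diag(M) <- NA
  which.max(rowMeans(M, na.rm = TRUE))
}

#' Relabel a partition to best match a reference partition
#'
#' Solves the optimal assignment on the module contingency table
#' (Hungarian algorithm) so that renamed module ids maximise the total
#' node overlap with the reference. Modules left without a reference
#' counterpart (when the partition has more modules than the reference, or
#' a module is assigned to an empty slot) receive fresh ids above the
#' reference's maximum. Only ids change: the partition structure, and
#' hence its NMI to the reference, is untouched.
#'
#' @param p `partition` to relabel.
#' @param reference `partition` over the same node set.
#' @return A `partition` with relabelled module ids.
#' @export
match_labels <- function(p, reference) {
  lp <- partition_labels(p)
  lr <- partition_labels(reference)
  if (length(lp) != length(lr))
    stop("partitions are over different node sets")
  fp <- as.integer(factor(lp))
  ref_ids <- sort(unique(lr))
  fr <- match(lr, ref_ids)
  ct <- crosstab(fp, fr)           # kp x kr overlap counts
  kp <- nrow(ct)
  kr <- ncol(ct)
  k <- max(kp, kr)
  padded <- matrix(0, k, k)
  padded[seq_len(kp), seq_len(kr)] <- ct
  assign <- solve_assignment(max(padded) - padded)
  new_ids <- integer(kp)
  fresh <- if (length(ref_ids)) max(ref_ids) else 0L
  for (i in seq_len(kp)) {
    j <- assign[i]
    if (j <= kr) {
      new_ids[i] <- ref_ids[j]
    } else {
      fresh <- fresh + 1L
      new_ids[i] <- fresh
    }
  }
  labels <- new_ids[fp]
  names(labels) <- names(lp)
  structure(list(labels = labels, Q = if (inherits(p, "partition")) p$Q
                 else NA_real_,
                 cost = if (inherits(p, "partition")) p$cost else NA_real_,
                 mode = if (inherits(p, "partition")) p$mode
                 else NA_character_),
            class = "partition")
}

#' Consensus modular map of a group
#'
#' Given subjects' partitions already matched to a common reference (see
#' [select_representative()] and [match_labels()]), assigns each node its
#' most frequent module label across subjects; the frequency of that label
#' quantifies the confidence of the assignment. Ties go to the smaller
#' label id.
#'
#' @param matched list of matched `partition`s.
#' @return A `consensus_partition`: data.frame with columns `node`,
#'   `label`, `frequency`.
#' @export
consensus_partition <- function(matched) {
  stopifnot(length(matched) >= 1L)
  L <- do.call(cbind, lapply(matched, partition_labels))
  S <- ncol(L)
  modal <- apply(L, 1L, function(x) {
    tb <- table(x)
    ids <- as.integer(names(tb))
    best <- which(tb == max(tb))
    id <- min(ids[best])
    c(id, tb[[as.character(id)]])
  })
  node <- rownames(L)
  if (is.null(node)) node <- sprintf("n%03d", seq_len(nrow(L)))
  structure(data.frame(node = node,
                       label = as.integer(modal[1L, ]),
                       frequency = modal[2L, ] / S,
                       stringsAsFactors = FALSE),
            class = c("consensus_partition", "data.frame"))
}

#' Per-subject partitions of a cohort at one cost
#'
#' Convenience wrapper running the full per-subject chain (correlation,
#' Fisher-z weights, spanning-backbone thresholding, Louvain detection)
#' for every subject of every group at a single cost.
#'
#' @param cohort a [generate_cohort()] result (or any object with a
#'   `subjects` list of `timeseries_matrix` per group).
#' @param cost network cost (default 0.03, the group-level analysis cost).
#' @param mode `"binary"` or `"weighted"`.
#' @param seed integer seed; per-subject detection seeds are fanned out
#'   deterministically.
#' @param n_restarts Louvain restarts per subject (default 20).
#' @return Named list (per group) of lists of `partition`s.
#' @export
cohort_partitions <- function(cohort, cost = 0.03,
                              mode = c("binary", "weighted"),
                              seed, n_restarts = 20) {
  mode <- match.arg(mode)
  out <- list()
  for (gi in seq_along(cohort$subjects)) {
    gname <- names(cohort$subjects)[gi]
    out[[gname]] <- lapply(seq_along(cohort$subjects[[gi]]), function(si) {
      ts <- cohort$subjects[[gi]][[si]]
      w <- to_weight_matrix(correlation_matrix(ts))
      g <- mst_threshold(w, cost, mode)
      detect_partition(g, seed = subject_seed(seed, gi, si),
                       n_restarts = n_restarts)
    })
  }
  out
}
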