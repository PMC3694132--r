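two_cliques_graph <- function() {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1
  A[6:10, 6:10] <- 1
  diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 1
  graph_from_adjacency_fixture(A)
}

test_that("Louvain recovers planted cliques with the closed-form modularity", {
  g <- two_cliques_graph()
  p <- detect_partition(g, seed = 1, n_restarts = 10)
  expect_identical(length(unique(p$labels)), 2L)
  expect_identical(unname(p$labels[1:5]), rep(p$labels[[1]], 5))
  expect_identical(unname(p$labels[6:10]), rep(p$labels[[6]], 5))
  # Q for the clique split of the 21-edge graph: 20/21 - 1/2
  expect_equal(p$Q, 20 / 21 - 0.5, tolerance = 1e-9)

  # complete graph collapses to one module with non-positive Q
  K <- matrix(1, 8, 8) - diag(8)
  pk <- detect_partition(graph_from_adjacency_fixture(K), seed = 2,
                         n_restarts = 5)
  expect_identical(length(unique(pk$labels)), 1L)
  expect_lte(pk$Q, 0)
})

test_that("planted four-module graphs are recovered with high NMI", {
  set.seed(77)
  planted <- rep(1:4, each = 15)
  nmis <- Qgap <- numeric(10)
  for (k in 1:10) {
    A <- matrix(0, 60, 60)
    up <- upper.tri(A)
    same <- outer(planted, planted, "==")
    pr <- ifelse(same, 0.8, 0.05)
    A[up] <- as.numeric(stats::runif(sum(up)) < pr[up])
    A <- A + t(A)
    g <- graph_from_adjacency_fixture(A)
    p <- detect_partition(g, seed = 100 + k, n_restarts = 20)
    nmis[k] <- nmi(p, as_partition(planted))
    # maximiser property: detected Q at least the planted partition's Q
    ig <- as_igraph(g)
    Qgap[k] <- p$Q - igraph::modularity(ig, planted)
  }
  expect_gte(mean(nmis), 0.9)
  expect_true(all(Qgap >= -1e-9))
})

test_that("NMI worked examples, range, symmetry and relabeling invariance", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1)   # both single-module
  expect_equal(nmi(c(1, 1, 1, 1), c(1, 1, 2, 2)), 0)  # one uninformative
  set.seed(42)
  for (k in 1:20) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    v <- nmi(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, nmi(b, a))
    # invariant under relabeling of module ids
    expect_equal(v, nmi(7 - a, b))
    # agrees with the independent igraph implementation
    expect_equal(v, igraph::compare(a, b, method = "nmi"),
                 tolerance = 1e-12)
  }
  expect_error(nmi(c(1, 2), c(1, 2, 3)), "node set")
})

test_that("NMI is 1 exactly for relabelings: brute force over partitions of 5", {
  parts <- all_set_partitions(5)
  for (i in seq_along(parts)) {
    for (j in seq_along(parts)) {
      same_struct <- identical(
        outer(parts[[i]], parts[[i]], "=="),
        outer(parts[[j]], parts[[j]], "=="))
      v <- nmi(parts[[i]], parts[[j]])
      if (same_struct) expect_equal(v, 1) else expect_lt(v, 1)
    }
  }
})

test_that("similarity permutation test: degenerate and hand-checked cases", {
  base <- as_partition(rep(1:3, each = 4))
  identicals <- replicate(4, base, simplify = FALSE)
  st <- similarity_permutation_test(identicals, identicals,
                                    n_permutations = 200, seed = 1)
  expect_equal(st$observed, 0)
  expect_equal(st$p, 1)
  expect_gt(min(st$p, na.rm = TRUE), 0)  # add-one rule: p never 0

  # hand-checked observed statistic on a 2+2 design
  pa <- list(as_partition(c(1, 1, 2, 2)), as_partition(c(1, 1, 2, 2)))
  pb <- list(as_partition(c(1, 2, 1, 2)), as_partition(c(1, 2, 1, 2)))
  st2 <- similarity_permutation_test(pa, pb, n_permutations = 100, seed = 2)
  # within pairs: nmi = 1 (twice); between pairs: nmi = 0 (four times)
  expect_equal(st2$observed, 1)
  expect_equal(st2$within_a, 1)
  expect_equal(st2$within_b, 1)
  expect_equal(st2$between, 0)
  expect_identical(length(st2$null_values), 100L)

  expect_error(similarity_permutation_test(pa[1], pb, 10, seed = 1),
               "at least 2")
})

test_that("permutation engine is calibrated under exchangeable nulls", {
  set.seed(11)
  ps <- numeric(200)
  group <- rep(c("a", "b"), each = 8)
  npair <- choose(16, 2)
  for (k in 1:200) {
    sim <- matrix(stats::rnorm(npair), ncol = 1)  # exchangeable similarities
    ps[k] <- modnet:::comembership_perm_test(sim, group, 199,
                                             seed = 1000 + k)$p
  }
  # p-values are discrete at 199 permutations; KS ties warning is expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("representative selection maximises mean similarity to the others", {
  base <- as_partition(rep(1:2, each = 5))
  other <- as_partition(c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2))
  parts <- c(replicate(9, base, simplify = FALSE), list(other))
  expect_identical(select_representative(parts), 1L)
  expect_identical(select_representative(list(other)), 1L)

  # middle partition is closest to both extremes by construction
  p1 <- as_partition(c(1, 1, 1, 1, 2, 2, 2, 2))
  p2 <- as_partition(c(1, 1, 1, 2, 2, 2, 2, 2))
  p3 <- as_partition(c(1, 1, 2, 2, 2, 2, 2, 2))
  trio <- list(p1, p2, p3)
  mean_to_others <- vapply(1:3, function(i)
    mean(vapply(setdiff(1:3, i), function(j) nmi(trio[[i]], trio[[j]]),
                numeric(1))), numeric(1))
  expect_identical(which.max(mean_to_others), 2L)
  expect_identical(select_representative(trio), 2L)
})

test_that("label matching maximises overlap and preserves structure", {
  ref <- as_partition(c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  # same structure, permuted ids -> identical labels after matching
  p <- as_partition(c(3, 3, 3, 1, 1, 1, 2, 2, 2))
  m <- match_labels(p, ref)
  expect_identical(unname(m$labels), unname(ref$labels))
  expect_equal(nmi(m, ref), nmi(p, ref))

  # co-membership structure untouched by renaming
  set.seed(9)
  q <- as_partition(sample(1:3, 9, replace = TRUE))
  mq <- match_labels(q, ref)
  expect_identical(outer(mq$labels, mq$labels, "=="),
                   outer(q$labels, q$labels, "=="))

  # 3 modules matched to a 2-module reference: exactly one fresh id
  ref2 <- as_partition(c(1, 1, 1, 1, 2, 2, 2, 2, 2))
  p3m <- as_partition(c(1, 1, 1, 1, 2, 2, 2, 3, 3))
  m3 <- match_labels(p3m, ref2)
  fresh <- setdiff(unique(m3$labels), unique(ref2$labels))
  expect_identical(length(fresh), 1L)
  expect_true(all(fresh > max(ref2$labels)))

  # optimal assignment: total overlap equals the brute-force optimum
  for (k in 1:10) {
    a <- sample(1:3, 10, replace = TRUE)
    b <- sample(1:4, 10, replace = TRUE)
    mm <- match_labels(as_partition(a), as_partition(b))
    got <- sum(mm$labels == as_partition(b)$labels)
    expect_equal(got, oracle_best_assignment_value(table(a, b)))
  }
})

test_that("Hungarian solver agrees with exhaustive search", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(2:5, 1)
    m <- sample(n:6, 1)
    C <- matrix(stats::runif(n * m), n, m)
    assign <- modnet:::solve_assignment(C)
    expect_identical(length(unique(assign)), n)
    got <- sum(C[cbind(seq_len(n), assign)])
    best <- -oracle_best_assignment_value(-C)
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("consensus maps report modal labels and frequencies", {
  base <- as_partition(c(1, 1, 2, 2))
  cp <- consensus_partition(replicate(5, base, simplify = FALSE))
  expect_true(all(cp$frequency == 1))
  expect_identical(cp$label, c(1L, 1L, 2L, 2L))

  # node 1 labelled 1 by 7/10 subjects
  parts <- c(replicate(7, as_partition(c(1, 1, 2, 2)), simplify = FALSE),
             replicate(3, as_partition(c(2, 1, 2, 2)), simplify = FALSE))
  cp2 <- consensus_partition(parts)
  expect_identical(cp2$label[1], 1L)
  expect_equal(cp2$frequency[1], 0.7)

  # ties go to the smaller label id
  tie <- c(replicate(2, as_partition(c(1, 1, 2, 2)), simplify = FALSE),
           replicate(2, as_partition(c(2, 1, 2, 2)), simplify = FALSE))
  expect_identical(consensus_partition(tie)$label[1], 1L)
})

test_that("major-module counting", {
  expect_identical(count_major_modules(rep(1:3, c(10, 7, 3))), 2L)
  expect_identical(count_major_modules(1:8), 0L)
  expect_identical(count_major_modules(rep(1, 6)), 1L)
  expect_identical(count_major_modules(rep(1:2, c(5, 4)), min_size = 4), 2L)
})
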