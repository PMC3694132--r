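# Internal helpers shared across modules.

# round() in R rounds half to even; edge counts use round-half-up.
round_half_up <- function(x) floor(x + 0.5)

#' Derive a per-subject random seed from a master seed
#'
#' Deterministic fan-out so that adding a group or subject to a design never
#' changes the seeds (and hence the data) of existing subjects. The value is
#' kept below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param master_seed integer master seed of the cohort design.
#' @param group_index 1-based index of the group within the design.
#' @param subject_index 1-based index of the subject within the group.
#' @return A single integer seed.
#' @export
subject_seed <- function(master_seed, group_index, subject_index) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master_seed) %% m
  h <- (h * 48271) %% m
  h <- (h + as.numeric(group_index) * 69621) %% m
  h <- (h * 48271) %% m
  h <- (h + as.numeric(subject_index)) %% m
  as.integer((h * 48271) %% m)
}

# Hungarian algorithm (shortest augmenting path formulation) for the
# rectangular assignment problem: rows n <= cols m, minimise total cost.
# Returns an integer vector: column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)   # row potentials, index i+1 (u[1] = dummy row 0)
  v <- numeric(m + 1L)   # column potentials, index j+1 (v[1] = dummy col 0)
  p <- integer(m + 1L)   # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

# Indices (i < j) of all unordered subject pairs.
pair_indices <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

# Core permutation engine shared by the NMI group test and the NOI scan.
#
# sim:   P x K matrix of pairwise similarities; column k is one statistic
#        (one node of interest, or a single column for the NMI test), rows
#        follow pair_indices(S) order. NA entries mark undefined pairs
#        (excluded from within/between means).
# group: length-S vector of group labels (two groups).
# Returns observed statistic per column, a B x K null matrix, and the
# one-sided add-one p-value per column.
comembership_perm_test <- function(sim, group, n_permutations, seed,
                                   chunk_size = 2000L) {
  sim <- as.matrix(sim)
  S <- length(group)
  pr <- pair_indices(S)
  P <- length(pr$i)
  stopifnot(nrow(sim) == P)
  K <- ncol(sim)
  valid <- !is.na(sim)
  sim0 <- sim
  sim0[!valid] <- 0
  tot_s <- colSums(sim0)
  tot_n <- colSums(valid)

  stat_for <- function(lab) {
    w <- lab[pr$i] == lab[pr$j]
    ws <- colSums(sim0[w, , drop = FALSE])
    wn <- colSums(valid[w, , drop = FALSE])
    bs <- tot_s - ws
    bn <- tot_n - wn
    ifelse(wn > 0 & bn > 0, ws / wn - bs / bn, NA_real_)
  }

  observed <- stat_for(group)

  set.seed(seed)
  null <- matrix(NA_real_, nrow = n_permutations, ncol = K)
  done <- 0L
  while (done < n_permutations) {
    nb <- min(chunk_size, n_permutations - done)
    W <- matrix(0, nrow = nb, ncol = P)
    for (b in seq_len(nb)) {
      lab <- group[sample.int(S)]
      W[b, ] <- as.numeric(lab[pr$i] == lab[pr$j])
    }
    ws <- W %*% sim0
    wn <- W %*% valid
    bs <- sweep(-ws, 2L, tot_s, "+")
    bn <- sweep(-wn, 2L, tot_n, "+")
    res <- ws / wn - bs / bn
    res[!(wn > 0 & bn > 0)] <- NA_real_
    null[done + seq_len(nb), ] <- res
    done <- done + nb
  }

  p <- vapply(seq_len(K), function(k) {
    (1 + sum(null[, k] >= observed[k], na.rm = TRUE)) / (1 + n_permutations)
  }, numeric(1))

  list(observed = observed, null = null, p = p,
       n_permutations = n_permutations)
}

# FNV-1a 32-bit hash of a character string; used to stamp pipeline outputs
# with the configuration that produced them.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches the low byte only
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split to stay inside the 2^53 exact-double range
    h <- (h * 403 + (h %% 256) * 16777216) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
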