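test_that("factor model hits the planted correlation targets", {
  part <- rep(1:2, each = 10)
  ts <- generate_subject_timeseries(part, n_volumes = 5000,
                                    within_r = 0.6, between_r = 0.1,
                                    seed = 11)
  bc <- mean_block_correlations(ts, part)
  expect_gte(bc$within, 0.57)
  expect_lte(bc$within, 0.63)
  expect_gte(bc$between, 0.07)
  expect_lte(bc$between, 0.13)

  # no structure requested: off-diagonal correlations average to zero
  ts0 <- generate_subject_timeseries(part, n_volumes = 5000,
                                     within_r = 0, between_r = 0, seed = 12)
  r0 <- correlation_matrix(ts0)
  expect_lt(abs(mean(r0[upper.tri(r0)])), 0.02)

  # convergence at large n_volumes, tolerance 0.03 on both targets
  expect_lt(abs(bc$within - 0.6), 0.03)
  expect_lt(abs(bc$between - 0.1), 0.03)
})

test_that("subject generator defaults, determinism and parameter checks", {
  part <- rep(1:4, each = 5)
  ts <- generate_subject_timeseries(part, within_r = 0.5, between_r = 0.1,
                                    seed = 3)
  expect_equal(ncol(ts$values), 200)  # 204-volume run minus 4 discarded
  expect_equal(ts$tr_seconds, 2.5)

  ts2 <- generate_subject_timeseries(part, within_r = 0.5, between_r = 0.1,
                                     seed = 3)
  expect_identical(ts$values, ts2$values)

  expect_error(generate_subject_timeseries(part, within_r = 0.2,
                                           between_r = 0.5, seed = 1),
               "positive definite")
  expect_error(generate_subject_timeseries(part, within_r = 1,
                                           between_r = 0.1, seed = 1),
               "positive definite")
  expect_error(generate_subject_timeseries(part, n_volumes = 1,
                                           within_r = 0.5, between_r = 0.1,
                                           seed = 1))
  # degenerate equal targets are allowed (null world)
  expect_silent(generate_subject_timeseries(part, within_r = 0.3,
                                            between_r = 0.3, seed = 1))
})

test_that("cohort generation is deterministic with stable seed fan-out", {
  part <- rep(1:3, each = 8)
  gA <- cohort_group("a", 3, part, 0.6, 0.1)
  gB <- cohort_group("b", 3, part, 0.6, 0.1,
                     noi_reassignments = c("3" = 2))
  d1 <- cohort_design(list(gA, gB), n_volumes = 50, master_seed = 77)
  c1 <- generate_cohort(d1)
  c2 <- generate_cohort(d1)
  expect_identical(c1$subjects, c2$subjects)

  # adding a group never changes existing subjects
  gC <- cohort_group("c", 2, part, 0.6, 0.1)
  d3 <- cohort_design(list(gA, gB, gC), n_volumes = 50, master_seed = 77)
  c3 <- generate_cohort(d3)
  expect_identical(c1$subjects$a, c3$subjects$a)
  expect_identical(c1$subjects$b, c3$subjects$b)

  expect_error(cohort_design(list(gA, gA), n_volumes = 50, master_seed = 1),
               "duplicate group names")
  expect_error(cohort_group("x", 3, part, 0.6, 0.1,
                            noi_reassignments = c("3" = 9)),
               "unknown modules")
})

test_that("group reassignments move the planted community of named nodes", {
  part <- stats::setNames(rep(1:2, each = 6), sprintf("r%02d", 1:12))
  grp <- cohort_group("b", 2, part, 0.7, 0.0,
                      noi_reassignments = c(r01 = 2))
  des <- cohort_design(list(cohort_group("a", 2, part, 0.7, 0.0), grp),
                       n_volumes = 4000, master_seed = 5)
  coh <- generate_cohort(des)
  r <- correlation_matrix(coh$subjects$b[[1]])
  # r01 now rides module 2's factor: high correlation with module-2 nodes
  expect_gt(mean(r["r01", 8:12]), 0.5)
  expect_lt(mean(r["r01", 2:6]), 0.2)
})

test_that("study design uses the four post-exclusion group sizes", {
  demo <- study_demographics()
  expect_identical(unname(colSums(demo$gender)), c(27, 28, 30, 29))
})

test_that("nuisance regression projects out covariates", {
  set.seed(42)
  nvol <- 2000
  cov1 <- stats::rnorm(nvol)
  tpts <- seq_len(nvol)
  sinu <- sin(2 * pi * tpts / 50)
  sinu <- stats::lm.fit(cbind(1, cov1), sinu)$residuals  # orthogonalise
  vals <- rbind(cov1,                       # exactly the covariate
                cov1 + sinu,                # covariate + orthogonal signal
                stats::rnorm(nvol))
  ts <- timeseries_matrix(vals, node_ids = c("a", "b", "c"))
  out <- regress_nuisance(ts, cbind(x = cov1))
  expect_lt(max(abs(out$values["a", ])), 1e-10)
  expect_gt(stats::cor(out$values["b", ], sinu), 0.999)
  # residuals orthogonal to the covariate
  expect_lt(abs(stats::cor(out$values["c", ], cov1)), 1e-10)

  # intercept-only: mean-centering
  out0 <- regress_nuisance(ts)
  expect_equal(out0$values, ts$values - rowMeans(ts$values),
               tolerance = 1e-12)

  # two series sharing only the removed covariate decorrelate
  y1 <- 0.9 * cov1 + stats::rnorm(nvol, sd = 0.5)
  y2 <- 0.9 * cov1 + stats::rnorm(nvol, sd = 0.5)
  tsy <- timeseries_matrix(rbind(y1, y2), node_ids = c("y1", "y2"))
  ry <- correlation_matrix(regress_nuisance(tsy, cbind(cov1)))
  expect_lt(abs(ry["y1", "y2"]), 0.05)

  expect_error(regress_nuisance(ts, cbind(a = cov1, b = 2 * cov1)),
               "collinear")
  expect_error(regress_nuisance(ts, matrix(1, 10, 1)), "volumes")
})

test_that("band-pass keeps the low-frequency band and is zero-phase", {
  tr <- 2.5
  nvol <- 2000
  tpts <- (seq_len(nvol) - 1) * tr
  amp_of <- function(y, f) {
    X <- cbind(sin(2 * pi * f * tpts), cos(2 * pi * f * tpts))
    sqrt(sum(stats::lm.fit(X, y)$coefficients^2))
  }
  pass <- sin(2 * pi * 0.05 * tpts)
  stopb <- sin(2 * pi * 0.18 * tpts)
  ts <- timeseries_matrix(rbind(const = rep(3, nvol), pass = pass,
                                stop = stopb), tr_seconds = tr)
  out <- bandpass(ts)
  expect_lt(max(abs(out$values["const", ])), 1e-8)
  expect_gte(amp_of(out$values["pass", ], 0.05), 0.9)
  expect_lte(amp_of(out$values["stop", ], 0.18), 0.1)

  # zero phase: a pure sine stays a pure sine (no cosine component leaks in)
  X <- cbind(s = sin(2 * pi * 0.05 * tpts), c = cos(2 * pi * 0.05 * tpts))
  cf <- stats::lm.fit(X, out$values["pass", ])$coefficients
  expect_lt(abs(cf[["c"]]) / abs(cf[["s"]]), 0.02)

  expect_error(bandpass(ts, high_hz = 0.25), "Nyquist")
  expect_error(bandpass(ts, low_hz = 0.2, high_hz = 0.1))
})

test_that("time-series TSV round trip preserves data and metadata", {
  part <- rep(1:2, each = 4)
  ts <- generate_subject_timeseries(part, n_volumes = 20, within_r = 0.4,
                                    between_r = 0.1, seed = 9,
                                    tr_seconds = 2.0)
  path <- tempfile(fileext = ".tsv")
  write_timeseries_tsv(ts, path)
  back <- read_timeseries_tsv(path)
  expect_equal(back$values, ts$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$node_ids, ts$node_ids)
  expect_equal(back$tr_seconds, 2.0)
})
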