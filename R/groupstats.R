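#' Summary statistics of one group
#'
#' @param mean group mean.
#' @param sd group standard deviation (positive).
#' @param n group size (>= 2).
#' @param name optional group name.
#' @return A `summary_stat` list.
#' @export
summary_stat <- function(mean, sd, n, name = NULL) {
  if (n < 2L) stop("n must be at least 2")
  if (sd <= 0) stop("sd must be positive")
  structure(list(mean = mean, sd = sd, n = as.integer(n), name = name),
            class = "summary_stat")
}

#' Two-tailed pooled-variance two-sample t test from summary statistics
#'
#' \deqn{t = (\bar x_a - \bar x_b) / \sqrt{s_p^2 (1/n_a + 1/n_b)}, \quad
#'       s_p^2 = \frac{(n_a-1) s_a^2 + (n_b-1) s_b^2}{n_a + n_b - 2}}
#' with `df = n_a + n_b - 2` (pooled, not Welch, matching conventional
#' demographic-table reporting).
#'
#' @param a,b [summary_stat()] objects.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @examples
#' pooled_t_from_summary(summary_stat(24.5, 3.1, 27),
#'                       summary_stat(21.8, 2.1, 29))
#' @export
pooled_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from summary statistics
#'
#' Reconstructs the between- and within-group sums of squares from group
#' means, standard deviations and sizes.
#'
#' @param groups list of [summary_stat()] objects (>= 2 groups).
#' @return List with `F`, `df_between` (= k - 1), `df_within` (= N - k),
#'   `p`, and `ms_within` (reused by the Tukey test).
#' @export
oneway_anova_from_summary <- function(groups) {
  stopifnot(length(groups) >= 2L)
  stopifnot(all(vapply(groups, inherits, logical(1), "summary_stat")))
  ns <- vapply(groups, `[[`, integer(1), "n")
  means <- vapply(groups, `[[`, numeric(1), "mean")
  sds <- vapply(groups, `[[`, numeric(1), "sd")
  k <- length(groups)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df_b <- k - 1L
  df_w <- N - k
  Fval <- (ssb / df_b) / (ssw / df_w)
  list(F = Fval, df_between = df_b, df_within = df_w,
       p = stats::pf(Fval, df_b, df_w, lower.tail = FALSE),
       ms_within = ssw / df_w)
}

#' Tukey HSD pairwise comparisons from summary statistics
#'
#' Tukey-Kramer form: for each pair the standard error uses the ANOVA
#' `MS_within` and the harmonic mean of the two group sizes; p-values come
#' from the studentized range distribution with `k` means and the ANOVA
#' within-group degrees of freedom.
#'
#' @param groups list of [summary_stat()] objects (>= 3 groups; names
#'   taken from the `name` field or `names(groups)`).
#' @return data.frame with columns `group1`, `group2`, `diff`, `q`, `p`.
#' @export
tukey_hsd_from_summary <- function(groups) {
  stopifnot(length(groups) >= 3L)
  an <- oneway_anova_from_summary(groups)
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms))
    nms <- vapply(seq_along(groups), function(i) {
      nm <- groups[[i]]$name
      if (is.null(nm)) sprintf("group%d", i) else nm
    }, character(1))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      gi <- groups[[i]]
      gj <- groups[[j]]
      nh <- 2 / (1 / gi$n + 1 / gj$n)
      se <- sqrt(an$ms_within / nh)
      q <- abs(gi$mean - gj$mean) / se
      p <- stats::ptukey(q, nmeans = k, df = an$df_within,
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = nms[i], group2 = nms[j],
        diff = gi$mean - gj$mean, q = q, p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Chi-square test of count homogeneity (e.g. gender by group)
#'
#' Standard Pearson chi-square on a 2 x k contingency table, without
#' continuity correction.
#'
#' @param counts 2 x k matrix of counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_counts <- function(counts) {
  counts <- as.matrix(counts)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Per-cost two-sample comparison of metric curves
#'
#' Pooled two-tailed t tests of each metric at each cost between two
#' groups of subjects; p-values are uncorrected across costs.
#'
#' @param curves a [metric_curves()] data.frame.
#' @param group_a,group_b names of the two groups to compare.
#' @return Long data.frame with columns `cost`, `metric`, `t`, `df`, `p`.
#' @export
compare_metric_curves <- function(curves, group_a, group_b) {
  metrics <- intersect(c("Cp", "Lp", "Eglobal", "Elocal", "sigma"),
                       names(curves))
  rows <- list()
  for (co in sort(unique(curves$cost))) {
    for (met in metrics) {
      xa <- curves[curves$group == group_a & curves$cost == co, met]
      xb <- curves[curves$group == group_b & curves$cost == co, met]
      tt <- pooled_t_from_summary(
        summary_stat(mean(xa), stats::sd(xa), length(xa)),
        summary_stat(mean(xb), stats::sd(xb), length(xb)))
      rows[[length(rows) + 1L]] <- data.frame(
        cost = co, metric = met, t = tt$t, df = tt$df, p = tt$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Demographic summary table of the emulated study
#'
#' The four study groups with gender counts and the printed age and
#' training-duration summaries; group sizes are the post-exclusion sizes
#' implied by the gender counts (27, 28, 30, 29).
#'
#' @return List with components `gender` (2 x 4 count matrix), `age` and
#'   `duration` (named lists of [summary_stat()]).
#' @export
study_demographics <- function() {
  gender <- matrix(c(12, 15, 12, 16, 13, 17, 12, 17), nrow = 2,
                   dimnames = list(c("M", "F"),
                                   c("control", "painter", "dancer",
                                     "pianist")))
  ns <- colSums(gender)
  age <- list(
    control = summary_stat(24.5, 3.1, ns[["control"]], "control"),
    painter = summary_stat(23.0, 2.5, ns[["painter"]], "painter"),
    dancer = summary_stat(19.7, 2.1, ns[["dancer"]], "dancer"),
    pianist = summary_stat(21.8, 2.1, ns[["pianist"]], "pianist"))
  duration <- list(
    painter = summary_stat(11.3, 4.1, ns[["painter"]], "painter"),
    dancer = summary_stat(11.2, 3.8, ns[["dancer"]], "dancer"),
    pianist = summary_stat(15.9, 2.4, ns[["pianist"]], "pianist"))
  list(gender = gender, age = age, duration = duration)
}
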