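#' Generate one subject's node time series with planted modular correlation
#'
#' Draws a node-by-volume Gaussian time-series matrix whose population
#' correlation structure follows a planted module partition: two nodes in
#' the same module correlate at `within_r`, two nodes in different modules
#' at `between_r`. The generative model is a factor model with one shared
#' global factor, one latent factor per module, and independent node noise,
#'
#' \deqn{x_i(t) = a\,g(t) + c\,f_{m(i)}(t) + \epsilon_i(t),}
#'
#' with mixing weights solved analytically so the targets hold exactly in
#' expectation: with total per-node variance \eqn{V = \sigma^2/(1 - r_w)},
#' \eqn{a = \sqrt{r_b V}} and \eqn{c = \sqrt{(r_w - r_b) V}}, where
#' \eqn{\sigma} is the idiosyncratic noise s.d.
#'
#' @param partition vector of module labels, one per node; names (if any)
#'   become the node ids.
#' @param n_volumes number of time points; default 200 (a 204-volume
#'   acquisition at TR 2.5 s with the first four volumes discarded).
#' @param within_r target correlation for same-module node pairs, in `[0, 1)`.
#' @param between_r target correlation for different-module pairs, in
#'   `[0, within_r]`.
#' @param noise_sd standard deviation of the idiosyncratic node noise.
#' @param seed integer RNG seed; output is bit-identical for a fixed seed.
#' @param tr_seconds sampling interval in seconds (default 2.5).
#' @return A [timeseries_matrix()].
#' @examples
#' part <- rep(1:2, each = 10)
#' ts <- generate_subject_timeseries(part, n_volumes = 200,
#'                                   within_r = 0.6, between_r = 0.1,
#'                                   seed = 1)
#' @export
generate_subject_timeseries <- function(partition, n_volumes = 200,
                                        within_r, between_r,
                                        noise_sd = 1, seed,
                                        tr_seconds = 2.5) {
  if (n_volumes < 2L) stop("n_volumes must be at least 2")
  if (between_r < 0 || within_r < between_r || within_r >= 1)
    stop("implied covariance is not positive definite: require ",
         "0 <= between_r <= within_r < 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n_nodes <- length(partition)
  node_ids <- names(partition)
  mod <- as.integer(factor(partition))
  n_mod <- max(mod)

  V <- noise_sd^2 / (1 - within_r)        # total per-node variance
  a <- sqrt(between_r * V)                # global-factor loading
  cc <- sqrt((within_r - between_r) * V)  # module-factor loading

  set.seed(as.integer(seed))
  g <- stats::rnorm(n_volumes)
  f <- matrix(stats::rnorm(n_mod * n_volumes), n_mod, n_volumes)
  eps <- matrix(stats::rnorm(n_nodes * n_volumes, sd = noise_sd),
                n_nodes, n_volumes)
  vals <- eps + cc * f[mod, , drop = FALSE]
  vals <- vals + rep(a * g, each = n_nodes)
  timeseries_matrix(vals, tr_seconds = tr_seconds, node_ids = node_ids)
}

#' Describe one group of a synthetic cohort
#'
#' @param name group name (must be unique within a design).
#' @param n_subjects number of subjects.
#' @param partition generative module partition (vector of labels, one per
#'   node); shared dimensions are validated by [cohort_design()].
#' @param within_r,between_r target same-module / cross-module correlations.
#' @param noi_reassignments named vector mapping node index (or node id,
#'   when the partition is named) to the module label it is moved to in
#'   this group, or `NULL` for none.
#' @param noise_sd idiosyncratic noise s.d. (default 1).
#' @return A `cohort_group` specification list.
#' @export
cohort_group <- function(name, n_subjects, partition,
                         within_r, between_r,
                         noi_reassignments = NULL, noise_sd = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (n_subjects < 1L) stop("n_subjects must be at least 1")
  if (!is.null(noi_reassignments)) {
    keys <- names(noi_reassignments)
    if (is.null(keys)) stop("noi_reassignments must be a named vector")
    known <- unique(as.character(partition))
    bad <- setdiff(as.character(noi_reassignments), known)
    if (length(bad))
      stop("reassignment targets name unknown modules: ",
           paste(bad, collapse = ", "))
  }
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 partition = partition, within_r = within_r,
                 between_r = between_r,
                 noi_reassignments = noi_reassignments,
                 noise_sd = noise_sd),
            class = "cohort_group")
}

#' Specify a full synthetic cohort design
#'
#' @param groups list of [cohort_group()] specifications.
#' @param n_volumes volumes per subject (default 200).
#' @param master_seed integer master seed; per-subject seeds are fanned out
#'   deterministically with [subject_seed()], so adding a group never
#'   changes existing subjects.
#' @param tr_seconds sampling interval (default 2.5 s).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(groups, n_volumes = 200, master_seed,
                          tr_seconds = 2.5) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (!all(vapply(groups, inherits, logical(1), "cohort_group")))
    stop("groups must be a list of cohort_group() specifications")
  nms <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate group names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sizes <- vapply(groups, function(g) length(g$partition), integer(1))
  if (length(unique(sizes)) != 1L)
    stop("all groups must share the same number of nodes")
  names(groups) <- nms
  structure(list(groups = groups, n_nodes = sizes[[1L]],
                 n_volumes = as.integer(n_volumes),
                 master_seed = as.integer(master_seed),
                 tr_seconds = tr_seconds),
            class = "cohort_design")
}

apply_reassignments <- function(partition, reassignments) {
  if (is.null(reassignments)) return(partition)
  keys <- names(reassignments)
  if (!is.null(names(partition)) && all(keys %in% names(partition))) {
    idx <- match(keys, names(partition))
  } else {
    idx <- suppressWarnings(as.integer(keys))
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(partition)))
      stop("reassignment keys must be node ids or 1-based node indices")
  }
  partition[idx] <- reassignments
  partition
}

#' Generate a full synthetic cohort from a design
#'
#' Draws every subject of every group with
#' [generate_subject_timeseries()], applying the group's node
#' reassignments to its generative partition first. Per-subject seeds are
#' derived deterministically from the design's master seed, so the whole
#' cohort is reproducible bit for bit.
#'
#' @param design a [cohort_design()].
#' @return A `cohort` object: `subjects` is a named list (one entry per
#'   group) of lists of `timeseries_matrix`; `seeds` records the seed used
#'   for each subject; `design` is attached as provenance.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  subjects <- list()
  seeds <- list()
  for (gi in seq_along(design$groups)) {
    grp <- design$groups[[gi]]
    part <- apply_reassignments(grp$partition, grp$noi_reassignments)
    subs <- vector("list", grp$n_subjects)
    sds <- integer(grp$n_subjects)
    for (si in seq_len(grp$n_subjects)) {
      sds[si] <- subject_seed(design$master_seed, gi, si)
      subs[[si]] <- generate_subject_timeseries(
        part, n_volumes = design$n_volumes,
        within_r = grp$within_r, between_r = grp$between_r,
        noise_sd = grp$noise_sd, seed = sds[si],
        tr_seconds = design$tr_seconds)
    }
    subjects[[grp$name]] <- subs
    seeds[[grp$name]] <- sds
  }
  structure(list(subjects = subjects, seeds = seeds, design = design),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  sizes <- vapply(x$subjects, length, integer(1))
  cat(sprintf("<cohort> %d nodes, %d volumes; groups: %s\n",
              x$design$n_nodes, x$design$n_volumes,
              paste(sprintf("%s (n=%d)", names(sizes), sizes),
                    collapse = ", ")))
  invisible(x)
}

#' A five-module whole-brain demonstration design
#'
#' Convenience constructor for the default synthetic world used in tests
#' and examples: 116 nodes partitioned into five planted modules (sizes 24,
#' 23, 23, 23, 23 -- echoing the five major modules typically recovered in
#' control resting-state networks), `within_r = 0.6`, `between_r = 0.1`,
#' unit noise, 200 volumes. Group "b" optionally moves `n_reassigned`
#' nodes (the first nodes of module 1) into module 2, the planted effect
#' every downstream permutation test is asked to recover.
#'
#' @param n_subjects subjects per group (default 20).
#' @param n_reassigned number of nodes moved in group "b" (default 0: a
#'   null cohort with identical generative structure in both groups).
#' @param master_seed integer master seed.
#' @param within_r,between_r correlation targets (defaults 0.6 / 0.1).
#' @param n_volumes volumes per subject (default 200).
#' @return A [cohort_design()] with groups `"a"` and `"b"`.
#' @export
demo_design <- function(n_subjects = 20, n_reassigned = 0, master_seed,
                        within_r = 0.6, between_r = 0.1, n_volumes = 200) {
  labels <- aal_labels()
  part <- rep(1:5, times = c(24, 23, 23, 23, 23))
  names(part) <- labels
  reass <- NULL
  if (n_reassigned > 0) {
    stopifnot(n_reassigned <= 24)
    reass <- stats::setNames(rep(2L, n_reassigned),
                             labels[seq_len(n_reassigned)])
  }
  cohort_design(
    groups = list(
      cohort_group("a", n_subjects, part, within_r, between_r),
      cohort_group("b", n_subjects, part, within_r, between_r,
                   noi_reassignments = reass)),
    n_volumes = n_volumes, master_seed = master_seed)
}

#' Write a cohort to disk as TSV files plus a JSON manifest
#'
#' Each subject's series goes to `<dir>/<group>_s<k>.tsv` (see
#' [write_timeseries_tsv()]); `manifest.json` records group, subject id,
#' file and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (g in names(cohort$subjects)) {
    for (si in seq_along(cohort$subjects[[g]])) {
      fn <- sprintf("%s_s%02d.tsv", g, si)
      write_timeseries_tsv(cohort$subjects[[g]][[si]], file.path(dir, fn))
      manifest[[length(manifest) + 1L]] <-
        list(group = g, subject = si, file = fn,
             seed = cohort$seeds[[g]][si])
    }
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

#' @rdname write_cohort
#' @param dir directory containing `manifest.json` and the subject files.
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(mp, simplifyVector = FALSE)
  subjects <- list()
  seeds <- list()
  for (entry in manifest) {
    ts <- read_timeseries_tsv(file.path(dir, entry$file))
    subjects[[entry$group]] <- c(subjects[[entry$group]], list(ts))
    seeds[[entry$group]] <- c(seeds[[entry$group]], entry$seed)
  }
  structure(list(subjects = subjects, seeds = seeds, design = NULL),
            class = "cohort")
}
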