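#' Assemble a pipeline configuration
#'
#' Defaults follow the conventional analysis settings: binarised networks
#' over costs 0.03-0.40 (step 0.01) for metric curves, group-level modular
#' analyses at cost 0.03 (the sparsity preserving the strongest
#' connections), 10000 permutations, alpha 0.05.
#'
#' @param design a [cohort_design()] for simulate mode, or `NULL` when
#'   `input_dir` points at a cohort written by [write_cohort()].
#' @param input_dir directory with a cohort manifest (ignored when
#'   `design` is given).
#' @param cost_grid ascending costs for metric curves.
#' @param group_cost single cost for modular analyses (default 0.03).
#' @param mode `"binary"`, `"weighted"` or `"both"` (modular analyses are
#'   re-run in weighted mode as a robustness check).
#' @param n_permutations permutations for the NMI test and NOI scan.
#' @param n_random_refs random references per graph for small-worldness.
#' @param alpha significance level.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory.
#' @param metric_curves compute per-cost metric curves (slowest stage;
#'   set `FALSE` to skip).
#' @param n_restarts Louvain restarts per subject.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL, input_dir = NULL,
                            cost_grid = default_cost_grid(),
                            group_cost = 0.03,
                            mode = c("binary", "weighted", "both"),
                            n_permutations = 10000,
                            n_random_refs = 20,
                            alpha = 0.05, seed, out_dir,
                            metric_curves = TRUE,
                            n_restarts = 20) {
  mode <- match.arg(mode)
  if (is.null(design) && is.null(input_dir))
    stop("either a design (simulate mode) or an input_dir is required")
  structure(list(design = design, input_dir = input_dir,
                 cost_grid = cost_grid, group_cost = group_cost,
                 mode = mode, n_permutations = as.integer(n_permutations),
                 n_random_refs = as.integer(n_random_refs),
                 alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir, metric_curves = metric_curves,
                 n_restarts = as.integer(n_restarts)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  fnv1a32(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA,
                           force = TRUE))
}

#' Write a labelled numeric matrix as TSV
#'
#' Header row and first column carry the node labels.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

write_partition_tsv <- function(p, path) {
  utils::write.table(
    data.frame(node = names(p$labels), module = unname(p$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

similarity_test_summary <- function(st) {
  list(observed = st$observed, p = st$p,
       n_permutations = st$n_permutations,
       within_a = st$within_a, within_b = st$within_b,
       between = st$between)
}

modular_stage <- function(cohort, config, mode, out_dir, tag) {
  parts <- cohort_partitions(cohort, cost = config$group_cost, mode = mode,
                             seed = subject_seed(config$seed,
                                                 1e6L, match(tag, c("binary",
                                                                    "weighted"))),
                             n_restarts = config$n_restarts)
  gnames <- names(parts)
  for (g in gnames) {
    for (si in seq_along(parts[[g]]))
      write_partition_tsv(parts[[g]][[si]],
                          file.path(out_dir,
                                    sprintf("partition_%s_%s_s%02d.tsv",
                                            tag, g, si)))
  }
  # consensus map per group
  consensus <- list()
  for (g in gnames) {
    rep_idx <- select_representative(parts[[g]])
    matched <- lapply(parts[[g]], match_labels,
                      reference = parts[[g]][[rep_idx]])
    cp <- consensus_partition(matched)
    utils::write.table(cp, file.path(out_dir,
                                     sprintf("consensus_%s_%s.tsv", tag, g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    consensus[[g]] <- list(representative = rep_idx,
                           n_major_modules = count_major_modules(
                             stats::setNames(cp$label, cp$node)))
  }
  # pairwise group tests
  nmi_tests <- list()
  noi_tests <- list()
  if (length(gnames) >= 2L) {
    combs <- utils::combn(gnames, 2L, simplify = FALSE)
    for (pair in combs) {
      key <- paste(pair, collapse = "_vs_")
      st <- similarity_permutation_test(
        parts[[pair[1L]]], parts[[pair[2L]]],
        n_permutations = config$n_permutations,
        seed = subject_seed(config$seed, 2e6L, length(nmi_tests) + 1L))
      nmi_tests[[key]] <- similarity_test_summary(st)
      ns <- noi_scan(parts[[pair[1L]]], parts[[pair[2L]]],
                     n_permutations = config$n_permutations,
                     alpha = config$alpha,
                     seed = subject_seed(config$seed, 3e6L,
                                         length(noi_tests) + 1L))
      utils::write.table(ns$results,
                         file.path(out_dir,
                                   sprintf("noi_scan_%s_%s.tsv", tag, key)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      noi_tests[[key]] <- list(
        n_nodes_tested = ns$n_nodes_tested,
        alpha_corrected = ns$alpha_corrected,
        significant_corrected = ns$results$node[ns$results$sig_corrected],
        significant_uncorrected = ns$results$node[ns$results$sig_uncorrected])
    }
  }
  modularity_by_group <- lapply(parts, function(pp)
    vapply(pp, `[[`, numeric(1), "Q"))
  n_modules_by_group <- lapply(parts, function(pp)
    vapply(pp, function(p) length(unique(p$labels)), numeric(1)))
  list(partitions = parts,
       summary = list(modularity = modularity_by_group,
                      n_modules = n_modules_by_group,
                      consensus = consensus,
                      nmi_tests = nmi_tests, noi_tests = noi_tests))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, writes per-subject weight matrices and
#' thresholded edge lists, computes metric curves over the cost grid,
#' performs modular analyses at the group-level cost (partitions, NMI
#' permutation tests between every pair of groups, NOI scans, consensus
#' maps) in binary and/or weighted mode, and writes a JSON summary
#' stamped with a hash of the configuration. Deterministic for a fixed
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return The summary list, invisibly; `summary.json` and all stage
#'   outputs are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stage_times <- list()

  cohort <- if (!is.null(config$design)) generate_cohort(config$design)
            else read_cohort(config$input_dir)
  stage_times$cohort <- proc.time()[["elapsed"]] - t0

  # per-subject weight matrices and thresholded edge lists
  t1 <- proc.time()[["elapsed"]]
  gnames <- names(cohort$subjects)
  sweeps <- list()
  for (gi in seq_along(gnames)) {
    g <- gnames[gi]
    sweeps[[g]] <- lapply(seq_along(cohort$subjects[[g]]), function(si) {
      ts <- cohort$subjects[[g]][[si]]
      w <- to_weight_matrix(correlation_matrix(ts))
      write_matrix_tsv(round(w, 6),
                       file.path(out_dir,
                                 sprintf("weights_%s_s%02d.tsv", g, si)))
      sw <- cost_sweep(w, config$cost_grid, mode = "binary")
      gl <- sw[[sprintf("%.2f", config$group_cost)]]
      if (!is.null(gl)) {
        el <- data.frame(from = gl$node_ids[gl$edges[, 1L]],
                         to = gl$node_ids[gl$edges[, 2L]])
        utils::write.table(el,
                           file.path(out_dir,
                                     sprintf("edges_%s_s%02d_cost%.2f.tsv",
                                             g, si, config$group_cost)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        igraph::write_graph(as_igraph(gl),
                            file.path(out_dir,
                                      sprintf("graph_%s_s%02d_cost%.2f.graphml",
                                              g, si, config$group_cost)),
                            format = "graphml")
      }
      sw
    })
  }
  stage_times$networks <- proc.time()[["elapsed"]] - t1

  # metric curves
  curves_summary <- NULL
  metric_tests <- NULL
  if (isTRUE(config$metric_curves)) {
    t2 <- proc.time()[["elapsed"]]
    curves <- metric_curves(sweeps)
    utils::write.table(curves, file.path(out_dir, "metric_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    curves_summary <- summarize_metric_curves(curves)
    if (length(gnames) >= 2L) {
      combs <- utils::combn(gnames, 2L, simplify = FALSE)
      metric_tests <- lapply(combs, function(pair) {
        ct <- compare_metric_curves(curves, pair[1L], pair[2L])
        list(pair = paste(pair, collapse = "_vs_"),
             n_significant_uncorrected = sum(ct$p < config$alpha),
             n_cells = nrow(ct),
             note = "p-values uncorrected across costs")
      })
    }
    stage_times$metrics <- proc.time()[["elapsed"]] - t2
  }

  # modular analyses
  t3 <- proc.time()[["elapsed"]]
  modes <- switch(config$mode,
                  binary = "binary", weighted = "weighted",
                  both = c("binary", "weighted"))
  modular <- list()
  for (md in modes)
    modular[[md]] <- modular_stage(cohort, config, md, out_dir, md)$summary
  stage_times$modules <- proc.time()[["elapsed"]] - t3

  summary <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    groups = as.list(stats::setNames(
      vapply(cohort$subjects, length, integer(1)), gnames)),
    n_costs = length(config$cost_grid),
    group_cost = config$group_cost,
    seeds = cohort$seeds,
    modular = modular,
    metric_tests = metric_tests)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # wall times go to a separate log so summary.json is rerun-identical
  jsonlite::write_json(lapply(stage_times, function(x) round(x, 3)),
                       file.path(out_dir, "log.json"), auto_unbox = TRUE)
  invisible(summary)
}
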