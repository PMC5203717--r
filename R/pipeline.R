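#' Configuration for the end-to-end pneumotype pipeline
#'
#' @param counts_path,taxonomy_path,tree_path,metadata_path Input files
#'   (TSV / newick); ignored when `simulate = TRUE`.
#' @param simulate Generate a synthetic cohort instead of reading files.
#' @param sim_config `sim_config` used when `simulate = TRUE` (default
#'   [default_config()] at `seed`).
#' @param depth Rarefaction depth and minimum-depth cut (default 2000).
#' @param sdi_z Diversity-outlier cut in standard deviations (default 5).
#' @param metric Beta-diversity metric, `"wunifrac"` or `"jsd"`.
#' @param k `"auto"` (silhouette selection) or an integer.
#' @param k_range Candidate k values for selection.
#' @param n_perm_optimality,n_perm_indicators,n_perm_ratio Permutation counts.
#' @param seed Master seed; stage seeds are derived from it.
#' @param outdir Optional output directory for the report bundle.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, taxonomy_path = NULL,
                            tree_path = NULL, metadata_path = NULL,
                            simulate = is.null(counts_path),
                            sim_config = NULL,
                            depth = 2000, sdi_z = 5,
                            metric = c("wunifrac", "jsd"),
                            k = "auto", k_range = 2:10,
                            n_perm_optimality = 10000,
                            n_perm_indicators = 999,
                            n_perm_ratio = 10000,
                            seed = 1, outdir = NULL) {
  structure(list(counts_path = counts_path, taxonomy_path = taxonomy_path,
                 tree_path = tree_path, metadata_path = metadata_path,
                 simulate = simulate, sim_config = sim_config,
                 depth = depth, sdi_z = sdi_z, metric = match.arg(metric),
                 k = k, k_range = k_range,
                 n_perm_optimality = n_perm_optimality,
                 n_perm_indicators = n_perm_indicators,
                 n_perm_ratio = n_perm_ratio,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full pneumotype analysis pipeline
#'
#' Executes depth filtering, diversity-outlier exclusion, rarefaction, alpha
#' diversity, beta-diversity distances, PAM pneumotype clustering with
#' silhouette k-selection and permutation validation, indicator-OTU
#' analysis, per-subject core-microbiota statistics, pneumotype transition /
#' stability tests and the within- versus between-subject distance-ratio
#' permutation tests. Every stochastic stage uses a seed derived from
#' `config$seed`, and the report records them, so identical seeds give
#' byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return The report (a nested list, JSON-serialisable); when
#'   `config$outdir` is set the report and tidy TSVs are also written there.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(rarefy = config$seed + 101L, optimality = config$seed + 202L,
                indicators = config$seed + 303L, ratio1 = config$seed + 404L,
                ratio2 = config$seed + 505L)

  if (config$simulate) {
    cohort <- with_stage("simulate", {
      sc <- if (is.null(config$sim_config)) default_config(seed = config$seed)
            else config$sim_config
      generate_cohort(sc)
    })
    table <- cohort$table
    tree <- cohort$tree
    metadata <- cohort$metadata
  } else {
    table <- with_stage("read", read_otu_table(config$counts_path, config$taxonomy_path))
    metadata <- with_stage("read", read_sample_metadata(config$metadata_path))
    tree <- NULL
    if (!is.null(config$tree_path))
      tree <- with_stage("read", ape::read.tree(config$tree_path))
    cohort <- NULL
  }
  if (config$metric == "wunifrac" && is.null(tree))
    stop("[read] metric 'wunifrac' requires a phylogenetic tree", call. = FALSE)

  dep <- with_stage("filter_depth", filter_min_depth(table, config$depth))
  outl <- with_stage("filter_outliers",
                     exclude_diversity_outliers(dep$table, config$sdi_z))
  rare <- with_stage("rarefy",
                     rarefy_table(outl$table, config$depth, seed = seeds$rarefy))
  metadata <- metadata[metadata$sample_id %in% sample_ids(rare), , drop = FALSE]

  alpha <- with_stage("alpha", alpha_diversity(rare))
  alpha$timepoint <- metadata$timepoint[match(alpha$sample_id, metadata$sample_id)]

  d <- with_stage("distance", distance_matrix(rare, tree, metric = config$metric))
  fit <- with_stage("cluster",
                    pneumotype(d, k = config$k, k_range = config$k_range,
                               metric = config$metric))
  opt <- with_stage("optimality",
                    cluster_optimality_test(d, fit$labels,
                                            n_perm = config$n_perm_optimality,
                                            seed = seeds$optimality))
  ind <- with_stage("indicators",
                    indicator_analysis(rare, fit$labels,
                                       n_perm = config$n_perm_indicators,
                                       seed = seeds$indicators))
  ind$genus <- otu_rank(rare, "genus")[ind$otu_id]

  assignments <- data.frame(
    subject_id = metadata$subject_id[match(names(fit$labels), metadata$sample_id)],
    timepoint = metadata$timepoint[match(names(fit$labels), metadata$sample_id)],
    label = as.integer(fit$labels), stringsAsFactors = FALSE)

  core <- with_stage("core", core_profiles(rare, metadata))
  core_trend <- with_stage("core", core_trend_test(core$profiles))
  stable <- subject_stability(assignments)
  core_stab <- with_stage("core", tryCatch(
    core_by_stability(core$profiles, stable),
    error = function(e) list(error = conditionMessage(e))))

  trans12 <- transition_counts(assignments, "W1", "M1")
  trans23 <- transition_counts(assignments, "M1", "M3")
  dep12 <- with_stage("trajectory", dependence_test(trans12))
  dep23 <- with_stage("trajectory", dependence_test(trans23))
  agree <- with_stage("trajectory", agreement_comparison(assignments))
  stab <- with_stage("trajectory", stability_test(assignments))

  ratio12 <- with_stage("ratio",
    ratio_permutation_test(d, metadata, "W1", "M1",
                           n_perm = config$n_perm_ratio, seed = seeds$ratio1))
  ratio23 <- with_stage("ratio",
    ratio_permutation_test(d, metadata, "M1", "M3",
                           n_perm = config$n_perm_ratio, seed = seeds$ratio2))

  top_ind <- do.call(rbind, lapply(split(ind, ind$cluster), function(x)
    x[which.max(x$indval), c("cluster", "otu_id", "genus", "indval", "p_value")]))

  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    stage_seeds = seeds,
    params = list(depth = config$depth, sdi_z = config$sdi_z,
                  metric = config$metric, k = config$k,
                  k_range = config$k_range,
                  n_perm = list(optimality = config$n_perm_optimality,
                                indicators = config$n_perm_indicators,
                                ratio = config$n_perm_ratio)),
    qc = list(n_input = n_samples(table),
              excluded_low_depth = dep$excluded,
              excluded_outliers = outl$excluded,
              n_analysed = n_samples(rare)),
    alpha = list(mean_shannon = tapply(alpha$shannon, alpha$timepoint, mean),
                 mean_richness = tapply(alpha$richness, alpha$timepoint, mean)),
    cluster = list(k = fit$k, asw = fit$asw, asw_by_k = fit$asw_by_k,
                   medoids = fit$medoids,
                   sizes = as.list(table(fit$labels)),
                   optimality = opt[c("statistic", "p_value", "n_perm", "scheme")]),
    indicators = list(top_per_cluster = top_ind,
                      n_significant = sum(ind$sig)),
    core = list(median_abundance = list(W1 = stats::median(core$profiles$W1),
                                        M1 = stats::median(core$profiles$M1),
                                        M3 = stats::median(core$profiles$M3)),
                n_subjects = nrow(core$profiles),
                trend = core_trend,
                by_stability = core_stab[setdiff(names(core_stab), "per_timepoint")],
                by_stability_timepoint = core_stab$per_timepoint),
    trajectory = list(transitions_w1_m1 = as.data.frame.matrix(trans12),
                      transitions_m1_m3 = as.data.frame.matrix(trans23),
                      dependence_p = c(W1_M1 = dep12$p_value, M1_M3 = dep23$p_value),
                      agreement = agree[c("agreement", "n", "p_value")],
                      stability = stab),
    ratio = list(W1_M1 = ratio12[c("median_ratio", "n", "p_value", "n_perm",
                                   "denominator", "scheme")],
                 M1_M3 = ratio23[c("median_ratio", "n", "p_value", "n_perm",
                                   "denominator", "scheme")]))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(data.frame(sample_id = names(fit$labels),
                                  pneumotype = as.integer(fit$labels)),
                       file.path(config$outdir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fit$asw_by_k, file.path(config$outdir, "asw_by_k.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ind, file.path(config$outdir, "indicators.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(core$profiles, file.path(config$outdir, "core_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(alpha, file.path(config$outdir, "alpha.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
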