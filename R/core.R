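#' Per-subject core OTUs
#'
#' A subject's core microbiota is the set of OTUs detected (count >= 1) in
#' all three of its longitudinal samples. Compute on the even-depth
#' (rarefied) table so presence is comparable across samples.
#'
#' @param subject_counts 3-row count matrix (rows = W1, M1, M3 samples of one
#'   subject; columns = OTUs).
#' @return Character vector of core OTU ids.
#' @export
core_otus <- function(subject_counts) {
  if (!is.matrix(subject_counts) || nrow(subject_counts) != 3L)
    stop("need exactly one sample per time-point (3 rows)", call. = FALSE)
  colnames(subject_counts)[colSums(subject_counts > 0) == 3L]
}

#' Fraction of reads from the core microbiota, per time-point
#'
#' @param subject_counts 3-row count matrix as in [core_otus()].
#' @param core Character vector of core OTU ids.
#' @return Numeric vector in `[0, 1]`, one entry per row.
#' @export
core_abundance <- function(subject_counts, core) {
  tot <- rowSums(subject_counts)
  num <- rowSums(subject_counts[, colnames(subject_counts) %in% core, drop = FALSE])
  num / ifelse(tot > 0, tot, 1)
}

#' Core-microbiota profiles for a cohort
#'
#' Computes each subject's core OTU set and core relative abundance per
#' time-point. Subjects lacking a sample at any of the three time-points are
#' excluded.
#'
#' @param table A rarefied [otu_table()].
#' @param metadata Metadata data.frame covering the table's samples.
#' @return List with `profiles` (data.frame `subject_id`, `n_core`, `W1`,
#'   `M1`, `M3`) and `core_sets` (named list of OTU id vectors).
#' @export
core_profiles <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  md <- metadata[metadata$sample_id %in% sample_ids(table), , drop = FALSE]
  tp <- timepoint_levels()
  keep <- names(which(table(md$subject_id) == 3L))
  rows <- list()
  sets <- list()
  for (s in keep) {
    sm <- md[md$subject_id == s, , drop = FALSE]
    sm <- sm[match(tp, as.character(sm$timepoint)), , drop = FALSE]
    counts <- table$counts[sm$sample_id, , drop = FALSE]
    core <- core_otus(counts)
    ab <- core_abundance(counts, core)
    sets[[s]] <- core
    rows[[s]] <- data.frame(subject_id = s, n_core = length(core),
                            W1 = ab[1L], M1 = ab[2L], M3 = ab[3L],
                            stringsAsFactors = FALSE)
  }
  profiles <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
              else data.frame(subject_id = character(), n_core = integer(),
                              W1 = numeric(), M1 = numeric(), M3 = numeric())
  list(profiles = profiles, core_sets = sets)
}

#' Paired test of core-abundance change between consecutive time-points
#'
#' Two-sided paired Wilcoxon signed-rank tests of core relative abundance,
#' 1 week vs 1 month and 1 month vs 3 months. When every within-subject
#' difference is zero there is no evidence of change and p = 1.
#'
#' @param profiles The `profiles` data.frame from [core_profiles()]
#'   (>= 10 subjects).
#' @return data.frame with `pair`, `median_from`, `median_to`, `p_value`.
#' @export
core_trend_test <- function(profiles) {
  if (nrow(profiles) < 10L) stop("need at least 10 core profiles", call. = FALSE)
  pair_test <- function(x, y) {
    if (all(x == y)) return(1)
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))$p.value
  }
  data.frame(pair = c("W1_M1", "M1_M3"),
             median_from = c(stats::median(profiles$W1), stats::median(profiles$M1)),
             median_to = c(stats::median(profiles$M1), stats::median(profiles$M3)),
             p_value = c(pair_test(profiles$W1, profiles$M1),
                         pair_test(profiles$M1, profiles$M3)),
             stringsAsFactors = FALSE)
}

#' Which subjects keep the same pneumotype at all three time-points
#'
#' @param assignments data.frame with `subject_id`, `timepoint`, `label`.
#' @return Named logical vector over subjects with all three time-points.
#' @export
subject_stability <- function(assignments) {
  wide <- assignment_wide(assignments)
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  stats::setNames(wide[, 1L] == wide[, 2L] & wide[, 2L] == wide[, 3L],
                  rownames(wide))
}

#' Core abundance of stable versus changing subjects
#'
#' Compares core relative abundance between subjects that keep one pneumotype
#' at all three time-points and subjects that change, with a two-sample
#' Wilcoxon rank-sum test at each time-point and a one-way ANOVA of core
#' abundance on stability overall.
#'
#' @param profiles The `profiles` data.frame from [core_profiles()].
#' @param stable Named logical vector (as from [subject_stability()]).
#' @return List with `per_timepoint` (data.frame of group medians and
#'   Wilcoxon p per time-point), `anova_p` and the group sizes `n`.
#' @export
core_by_stability <- function(profiles, stable) {
  profiles <- profiles[profiles$subject_id %in% names(stable), , drop = FALSE]
  grp <- stable[profiles$subject_id]
  if (sum(grp) < 2L || sum(!grp) < 2L)
    stop("each stability group needs at least 2 subjects", call. = FALSE)
  tp <- timepoint_levels()
  per <- do.call(rbind, lapply(tp, function(t) {
    x <- profiles[[t]][grp]
    y <- profiles[[t]][!grp]
    data.frame(timepoint = t,
               median_stable = stats::median(x),
               median_changing = stats::median(y),
               p_value = suppressWarnings(stats::wilcox.test(x, y))$p.value,
               stringsAsFactors = FALSE)
  }))
  long <- data.frame(abundance = c(profiles$W1, profiles$M1, profiles$M3),
                     stable = rep(grp, 3L))
  fit <- stats::aov(abundance ~ stable, data = long)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  list(per_timepoint = per, anova_p = anova_p,
       n = c(stable = sum(grp), changing = sum(!grp)))
}
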