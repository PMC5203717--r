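#' Reshape long pneumotype assignments to a subjects-by-timepoint matrix
#'
#' @param assignments data.frame with `subject_id`, `timepoint` (W1/M1/M3)
#'   and `label`.
#' @return Character matrix, rows = subjects, columns = W1, M1, M3 (NA where
#'   a time-point is missing).
#' @export
assignment_wide <- function(assignments) {
  stopifnot(all(c("subject_id", "timepoint", "label") %in% names(assignments)))
  tp <- timepoint_levels()
  subj <- unique(as.character(assignments$subject_id))
  wide <- matrix(NA_character_, length(subj), length(tp),
                 dimnames = list(subj, tp))
  wide[cbind(match(as.character(assignments$subject_id), subj),
             match(as.character(assignments$timepoint), tp))] <-
    as.character(assignments$label)
  wide
}

#' Pneumotype transition counts between two time-points
#'
#' @param assignments Long assignment data.frame (see [assignment_wide()]).
#' @param t_from,t_to Time-points of the transition.
#' @param levels Optional fixed set of pneumotype labels for the matrix
#'   dimensions (default: all labels seen).
#' @return k x k integer matrix; cell (i, j) counts subjects moving from
#'   label i at `t_from` to label j at `t_to`.
#' @export
transition_counts <- function(assignments, t_from = "W1", t_to = "M1",
                              levels = NULL) {
  wide <- assignment_wide(assignments)
  from <- wide[, t_from]
  to <- wide[, t_to]
  ok <- !is.na(from) & !is.na(to)
  if (is.null(levels)) levels <- sort(unique(c(from[ok], to[ok])))
  as.matrix(table(factor(from[ok], levels), factor(to[ok], levels)))
}

#' Chi-squared test of dependence on a transition table
#'
#' Pearson's chi-squared test of independence between the row and column
#' labels, with expected counts from the margins. Zero-margin rows/columns
#' are dropped with a warning; Yates continuity correction is applied to
#' 2 x 2 tables only (toggleable).
#'
#' @param mat k x k contingency matrix (total >= 20).
#' @param correct Continuity correction; default: 2 x 2 tables only.
#' @return List with `statistic`, `df`, `p_value`, `expected` and
#'   `small_expected` (TRUE when any expected count < 5).
#' @export
dependence_test <- function(mat, correct = NULL) {
  mat <- as.matrix(mat)
  keep_r <- rowSums(mat) > 0
  keep_c <- colSums(mat) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns")
    mat <- mat[keep_r, keep_c, drop = FALSE]
  }
  if (sum(mat) < 20) warning("table total below 20; chi-squared approximation is poor")
  if (is.null(correct)) correct <- all(dim(mat) == 2L)
  ht <- suppressWarnings(stats::chisq.test(mat, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected,
       small_expected = any(ht$expected < 5))
}

#' Compare pneumotype agreement across the two consecutive time spans
#'
#' The proportion of subjects with the same pneumotype at 1 month and
#' 3 months versus at 1 week and 1 month, with a chi-squared test on the
#' 2 x 2 (same/different x time-span) table.
#'
#' @param assignments Long assignment data.frame.
#' @return List with `agreement` (named proportions), `n` (subjects per
#'   span), `table` and `p_value`.
#' @export
agreement_comparison <- function(assignments) {
  wide <- assignment_wide(assignments)
  same <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    c(same = sum(a[ok] == b[ok]), n = sum(ok))
  }
  s1 <- same(wide[, "W1"], wide[, "M1"])
  s2 <- same(wide[, "M1"], wide[, "M3"])
  tab <- rbind(W1_M1 = c(s1["same"], s1["n"] - s1["same"]),
               M1_M3 = c(s2["same"], s2["n"] - s2["same"]))
  colnames(tab) <- c("same", "different")
  p <- if (identical(tab[1, ], tab[2, ])) 1
       else suppressWarnings(stats::chisq.test(tab))$p.value
  list(agreement = c(W1_M1 = unname(s1["same"] / s1["n"]),
                     M1_M3 = unname(s2["same"] / s2["n"])),
       n = c(W1_M1 = unname(s1["n"]), M1_M3 = unname(s2["n"])),
       table = tab, p_value = p)
}

#' Test pneumotype stability against an independence null
#'
#' Observed proportion of subjects keeping one pneumotype at all three
#' time-points, against the proportion expected were the three assignments
#' independent draws from their empirical marginals
#' (`sum_k p_k(W1) p_k(M1) p_k(M3)`), with a 1-df chi-squared goodness-of-fit
#' test on (stable, not stable). Also reported per pneumotype.
#'
#' @param assignments Long assignment data.frame; only subjects with all
#'   three time-points enter.
#' @return List with `n`, `observed`, `expected` (proportions), `p_value`
#'   and `per_pneumotype` (data.frame with the same test restricted to each
#'   label).
#' @export
stability_test <- function(assignments) {
  wide <- assignment_wide(assignments)
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  n <- nrow(wide)
  if (n < 20) warning("fewer than 20 complete subjects")
  lev <- sort(unique(as.vector(wide)))
  marg <- sapply(timepoint_levels(), function(t)
    as.numeric(prop.table(table(factor(wide[, t], lev)))))
  rownames(marg) <- lev
  exp_k <- apply(marg, 1L, prod)
  stable_lab <- ifelse(wide[, 1L] == wide[, 2L] & wide[, 2L] == wide[, 3L],
                       wide[, 1L], NA)
  gof <- function(obs_n, exp_p) {
    if (exp_p <= 0 || exp_p >= 1) return(NA_real_)
    suppressWarnings(stats::chisq.test(c(obs_n, n - obs_n),
                                       p = c(exp_p, 1 - exp_p)))$p.value
  }
  obs <- sum(!is.na(stable_lab))
  per <- do.call(rbind, lapply(lev, function(k) {
    ok <- sum(stable_lab == k, na.rm = TRUE)
    data.frame(pneumotype = k, observed = ok / n, expected = exp_k[[k]],
               p_value = gof(ok, exp_k[[k]]), stringsAsFactors = FALSE)
  }))
  list(n = n, observed = obs / n, expected = sum(exp_k),
       p_value = gof(obs, sum(exp_k)), per_pneumotype = per)
}

# Distance sub-matrix between each subject's t_from sample (rows) and every
# subject's t_to sample (columns); rows/cols indexed by subject.
subject_cross_distances <- function(d, metadata, t_from, t_to) {
  metadata <- validate_metadata(metadata)
  dm <- as.matrix(d)
  md <- metadata[metadata$sample_id %in% rownames(dm), , drop = FALSE]
  from <- md[md$timepoint == t_from, , drop = FALSE]
  to <- md[md$timepoint == t_to, , drop = FALSE]
  subj <- intersect(from$subject_id, to$subject_id)
  if (length(subj) < 10) stop("need >= 10 subjects with both time-points", call. = FALSE)
  Dft <- dm[from$sample_id[match(subj, from$subject_id)],
            to$sample_id[match(subj, to$subject_id)], drop = FALSE]
  dimnames(Dft) <- list(subj, subj)
  Dft
}

# Median of each row after deleting one column, for every (row, deleted
# column) pair, from a single sort per row.
row_loo_medians <- function(X) {
  n <- ncol(X)
  out <- matrix(NA_real_, nrow(X), n, dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    s <- sort(X[i, ])
    r <- rank(X[i, ], ties.method = "first")
    if ((n - 1) %% 2L == 1L) {            # n even
      h <- n %/% 2L
      out[i, ] <- ifelse(r <= h, s[h + 1L], s[h])
    } else {                              # n odd
      h <- (n - 1L) %/% 2L
      out[i, ] <- ifelse(r <= h, (s[h + 1L] + s[h + 2L]) / 2,
                  ifelse(r >= h + 2L, (s[h] + s[h + 1L]) / 2,
                         (s[h] + s[h + 2L]) / 2))
    }
  }
  out
}

#' Within- versus between-subject distance ratio
#'
#' For each subject, the distance from its `t_from` sample to its own `t_to`
#' sample divided by the median (or mean) distance from its `t_from` sample
#' to the other subjects' `t_to` samples. A cohort-median ratio below 1 means
#' subjects stay closer to themselves than to others over that time span.
#'
#' @param d Beta-diversity `dist` over samples.
#' @param metadata Metadata data.frame (links samples to subjects and
#'   time-points); >= 10 subjects must have both samples.
#' @param t_from,t_to The time span, e.g. `"W1"` to `"M1"`.
#' @param denominator `"median"` (robust, default) or `"mean"` of the
#'   cross-subject distances.
#' @return List with `ratios` (named per subject), `median_ratio`, `n`,
#'   `t_from`, `t_to`, `denominator`. Subjects with a zero denominator are
#'   dropped with a warning.
#' @export
distance_ratio <- function(d, metadata, t_from = "W1", t_to = "M1",
                           denominator = c("median", "mean")) {
  denominator <- match.arg(denominator)
  Dft <- subject_cross_distances(d, metadata, t_from, t_to)
  n <- nrow(Dft)
  own <- diag(Dft)
  cross <- vapply(seq_len(n), function(i)
    if (denominator == "median") stats::median(Dft[i, -i]) else mean(Dft[i, -i]),
    numeric(1))
  if (any(cross == 0)) {
    warning("dropping subject(s) with zero cross-subject distance: ",
            paste(rownames(Dft)[cross == 0], collapse = ", "))
    own <- own[cross > 0]
    names(own) <- rownames(Dft)[cross > 0]
    cross <- cross[cross > 0]
  } else names(own) <- rownames(Dft)
  ratios <- own / cross
  list(ratios = ratios, median_ratio = stats::median(ratios),
       n = length(ratios), t_from = t_from, t_to = t_to,
       denominator = denominator)
}

#' Permutation test of the within/between distance ratio
#'
#' Under the null that a subject's own `t_to` sample is no closer than anyone
#' else's, each subject's "own" column is reassigned to a uniformly random
#' `t_to` sample (its true column included, independently across subjects)
#' and the cohort-median ratio recomputed. One-sided
#' `p = (1 + #{median_perm <= median_obs}) / (1 + n_perm)`; the two-sided p
#' doubles the smaller tail.
#'
#' @inheritParams distance_ratio
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param tail `"one"` (ratio < 1) or `"two"`.
#' @return The [distance_ratio()] list plus `p_value`, `n_perm`, `tail` and
#'   `scheme`.
#' @export
ratio_permutation_test <- function(d, metadata, t_from = "W1", t_to = "M1",
                                   n_perm = 10000, seed = 1,
                                   denominator = c("median", "mean"),
                                   tail = c("one", "two")) {
  denominator <- match.arg(denominator)
  tail <- match.arg(tail)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- distance_ratio(d, metadata, t_from, t_to, denominator)
  Dft <- subject_cross_distances(d, metadata, t_from, t_to)
  Dft <- Dft[names(obs$ratios), names(obs$ratios), drop = FALSE]
  n <- nrow(Dft)
  L <- if (denominator == "median") row_loo_medians(Dft)
       else (rowSums(Dft) - Dft) / (n - 1)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(p) {
    j <- sample.int(n, n, replace = TRUE)
    stats::median(Dft[cbind(seq_len(n), j)] / L[cbind(seq_len(n), j)])
  }, numeric(1))
  p_low <- (1 + sum(null <= obs$median_ratio)) / (1 + n_perm)
  p_high <- (1 + sum(null >= obs$median_ratio)) / (1 + n_perm)
  obs$p_value <- if (tail == "one") p_low else min(1, 2 * min(p_low, p_high))
  obs$n_perm <- n_perm
  obs$tail <- tail
  obs$scheme <- "own t_to column reassigned uniformly at random per subject (true column included), add-one p"
  obs
}
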