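# Group-equalised indicator value (IndVal.g) analysis.
# A (specificity) uses group MEAN relative abundances so unequal cluster
# sizes do not bias the numerator; B (fidelity) is within-group prevalence.

indval_components <- function(R, labels) {
  labels <- as.integer(factor(labels))
  ng <- tabulate(labels)
  gmean <- rowsum(R, labels) / ng                 # k x otus group means
  tot <- colSums(gmean)
  A <- sweep(gmean, 2L, ifelse(tot > 0, tot, 1), `/`)
  A[, tot == 0] <- 0
  B <- rowsum((R > 0) + 0, labels) / ng
  list(A = A, B = B, indval = sqrt(A * B))
}

#' Indicator value of one OTU for one cluster (IndVal.g)
#'
#' `A` is the cluster's mean relative abundance of the OTU divided by the sum
#' of all clusters' means (the group-size-equalising "g" correction); `B` is
#' the fraction of the cluster's samples where the OTU is present;
#' `indval = sqrt(A * B)`.
#'
#' @param table An [otu_table()] (raw or rarefied; proportions are used, so
#'   the result is invariant to per-sample depth).
#' @param labels Cluster labels, one per sample.
#' @param otu OTU id.
#' @param cluster Cluster (value of `labels`).
#' @return List with `A`, `B`, `indval` and `present` (FALSE when the OTU has
#'   no reads anywhere, in which case indval is 0).
#' @export
indval_g <- function(table, labels, otu, cluster) {
  R <- rel_abund(table)
  stopifnot(length(labels) == nrow(R))
  if (!otu %in% colnames(R)) stop("unknown OTU: ", otu, call. = FALSE)
  g <- match(as.character(cluster), levels(factor(labels)))
  if (is.na(g)) stop("unknown cluster: ", cluster, call. = FALSE)
  cmp <- indval_components(R, labels)
  present <- sum(R[, otu]) > 0
  list(A = unname(cmp$A[g, otu]), B = unname(cmp$B[g, otu]),
       indval = unname(cmp$indval[g, otu]), present = present)
}

#' Indicator-OTU analysis with permutation p-values
#'
#' For every OTU, finds the single cluster it marks most strongly (largest
#' IndVal.g) and attaches a permutation p-value: labels are shuffled
#' `n_perm` times and `p = (1 + #{max-indval_perm >= observed}) / (1 +
#' n_perm)`. Combinations of clusters are not considered.
#'
#' @param table An [otu_table()].
#' @param labels Cluster labels, one per sample.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed.
#' @param alpha Significance level recorded in the result's `sig` column.
#' @return data.frame with one row per OTU (`otu_id`, `cluster`, `A`, `B`,
#'   `indval`, `p_value`, `sig`, `present`), sorted by cluster then
#'   decreasing indval.
#' @export
indicator_analysis <- function(table, labels, n_perm = 999, seed = 1,
                               alpha = 0.05) {
  R <- rel_abund(table)
  stopifnot(length(labels) == nrow(R))
  lab_f <- factor(labels)
  cmp <- indval_components(R, labels)
  best <- apply(cmp$indval, 2L, which.max)        # ties -> lowest cluster
  obs <- cmp$indval[cbind(best, seq_along(best))]
  set.seed(seed)
  n <- nrow(R)
  exceed <- integer(length(best))
  for (p in seq_len(n_perm)) {
    perm <- indval_components(R, lab_f[sample.int(n)])
    pmax_stat <- apply(perm$indval, 2L, max)
    exceed <- exceed + (pmax_stat >= obs)
  }
  pval <- (1 + exceed) / (1 + n_perm)
  present <- colSums(R) > 0
  out <- data.frame(otu_id = colnames(R),
                    cluster = levels(lab_f)[best],
                    A = cmp$A[cbind(best, seq_along(best))],
                    B = cmp$B[cbind(best, seq_along(best))],
                    indval = obs,
                    p_value = pval,
                    sig = pval <= alpha,
                    present = present,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$indval[!present] <- 0
  out[order(out$cluster, -out$indval), , drop = FALSE]
}
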