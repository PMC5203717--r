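#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over the positive relative abundances of the
#' sample. Counts are renormalised internally, so rarefied and raw vectors
#' give the same value.
#'
#' @param counts Non-negative numeric vector with at least one positive entry.
#' @return Diversity in nats.
#' @export
shannon <- function(counts) {
  if (all(counts == 0)) stop("all-zero count vector", call. = FALSE)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Observed richness
#'
#' @param counts Non-negative numeric vector.
#' @return Number of strictly positive entries.
#' @export
observed_richness <- function(counts) {
  sum(counts > 0)
}

#' Per-sample alpha diversity of an OTU table
#'
#' @param table An [otu_table()].
#' @return data.frame with `sample_id`, `shannon` (nats), `richness`.
#' @export
alpha_diversity <- function(table) {
  data.frame(sample_id = sample_ids(table),
             shannon = apply(table$counts, 1L, shannon),
             richness = apply(table$counts, 1L, observed_richness),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefaction curve for one sample
#'
#' Mean observed richness and Shannon diversity over `replicates` seeded
#' without-replacement subsamples at each depth.
#'
#' @param counts Non-negative integer vector (one sample).
#' @param depths Increasing integer depths, none above the total count.
#' @param replicates Subsamples per depth.
#' @param seed Integer seed.
#' @return data.frame with `depth`, `mean_richness`, `mean_shannon`.
#' @export
rarefaction_curve <- function(counts, depths, replicates = 10, seed = 1) {
  total <- sum(counts)
  if (any(depths > total))
    stop("depth exceeds the sample's total count (", total, ")", call. = FALSE)
  set.seed(seed)
  res <- vapply(depths, function(d) {
    sub <- suppressWarnings(
      vegan::rrarefy(matrix(rep(counts, replicates), nrow = replicates,
                            byrow = TRUE), d))
    c(mean(apply(sub, 1L, observed_richness)),
      mean(apply(sub, 1L, shannon)))
  }, numeric(2))
  data.frame(depth = depths, mean_richness = res[1L, ], mean_shannon = res[2L, ])
}
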