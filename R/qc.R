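#' Exclude samples below a minimum sequencing depth
#'
#' Samples with fewer total reads than `min_depth` are removed; a sample at
#' exactly the threshold is kept.
#'
#' @param table An [otu_table()].
#' @param min_depth Minimum read count per sample (default 2000).
#' @return List with `table` (retained samples) and `excluded`
#'   (data.frame of `sample_id`, `depth` for the removed samples).
#' @export
filter_min_depth <- function(table, min_depth = 2000) {
  stopifnot(min_depth >= 1)
  depth <- rowSums(table$counts)
  drop <- depth < min_depth
  excluded <- data.frame(sample_id = sample_ids(table)[drop],
                         depth = unname(depth[drop]),
                         stringsAsFactors = FALSE)
  table$counts <- table$counts[!drop, , drop = FALSE]
  list(table = table, excluded = excluded)
}

#' Exclude unusually diverse samples
#'
#' Removes samples whose Shannon diversity exceeds `mean + z * sd`, with mean
#' and standard deviation taken once over all samples (a single pass, not
#' iterated). Only the high tail is excluded.
#'
#' @param table An [otu_table()]; every sample must have at least one read.
#' @param z Number of standard deviations above the mean (default 5).
#' @return List with `table`, `excluded` (data.frame `sample_id`, `shannon`)
#'   and the `threshold` used.
#' @export
exclude_diversity_outliers <- function(table, z = 5) {
  if (n_samples(table) < 2L) stop("need at least 2 samples", call. = FALSE)
  sdi <- apply(table$counts, 1L, shannon)
  thr <- mean(sdi) + z * stats::sd(sdi)
  drop <- is.finite(thr) & sdi > thr
  excluded <- data.frame(sample_id = sample_ids(table)[drop],
                         shannon = unname(sdi[drop]),
                         stringsAsFactors = FALSE)
  table$counts <- table$counts[!drop, , drop = FALSE]
  list(table = table, excluded = excluded, threshold = thr)
}

#' Rarefy every sample to an even depth
#'
#' Each sample's reads are subsampled uniformly at random without replacement
#' (multivariate hypergeometric) to exactly `depth` reads, in a single seeded
#' draw per sample. Samples shallower than `depth` are an error; run
#' [filter_min_depth()] first.
#'
#' @param table An [otu_table()].
#' @param depth Target depth (default 2000).
#' @param seed Integer seed; the same seed gives a bit-identical result.
#' @return The rarefied [otu_table()].
#' @export
rarefy_table <- function(table, depth = 2000, seed = 1) {
  tot <- rowSums(table$counts)
  shallow <- tot < depth
  if (any(shallow))
    stop("sample(s) shallower than rarefaction depth: ",
         paste(sample_ids(table)[shallow], collapse = ", "), call. = FALSE)
  set.seed(seed)
  rar <- suppressWarnings(vegan::rrarefy(table$counts, depth))
  storage.mode(rar) <- "integer"
  table$counts <- rar
  table
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Counts are summed over OTUs sharing the taxon name at `rank`; OTUs with an
#' unknown name at that rank are pooled into `"unclassified"`. Per-sample
#' totals are conserved.
#'
#' @param table An [otu_table()] with taxonomy.
#' @param rank One of `phylum, class, order, family, genus`.
#' @return An `otu_table` whose columns are taxa at `rank` (no taxonomy).
#' @export
aggregate_rank <- function(table, rank = "genus") {
  rank <- match.arg(rank, setdiff(tax_ranks(), "domain"))
  taxon <- otu_rank(table, rank)
  taxon[is.na(taxon) | taxon == ""] <- "unclassified"
  agg <- t(rowsum(t(table$counts), group = taxon))
  otu_table(agg)
}

#' Bin extracted-DNA concentrations
#'
#' Bins follow the fixed cut-points 0.1, 0.33, 0.8, 1.79 and 4.58 ng/ul; each
#' bin is closed below and open above, the last closed below at 4.58.
#'
#' @param conc Numeric vector of DNA concentrations (ng/ul), all >= 0.
#' @return Factor with levels `extremely_low < very_low < low < medium <
#'   high < very_high`.
#' @export
categorize_dna_concentration <- function(conc) {
  if (any(is.na(conc)) || any(conc < 0)) stop("negative DNA concentration", call. = FALSE)
  lv <- c("extremely_low", "very_low", "low", "medium", "high", "very_high")
  cut(conc, breaks = c(-Inf, 0.1, 0.33, 0.8, 1.79, 4.58, Inf),
      labels = lv, right = FALSE, ordered_result = TRUE)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed cohort tables use the common
#' half-up convention (51.5 -> 52).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count with its percentage, table style
#'
#' @param count Numerator count.
#' @param denom Denominator.
#' @param digits Decimal places for the percentage: 0 for subject-level
#'   (Table-1 style), 1 for per-pneumotype (Table-2 style) output.
#' @return Character vector like `"356 (51%)"` / `"126 (76.4%)"`.
#' @export
percent_label <- function(count, denom, digits = 0) {
  pct <- ifelse(denom > 0, 100 * count / denom, 0)
  sprintf(paste0("%d (%.", digits, "f%%)"), count, round_half_up(pct, digits))
}

#' Cohort characteristics summary
#'
#' Counts and percentages for the boolean covariates of a cohort metadata
#' sheet. Subject-level fields (sex, siblings, caesarean section, maternal
#' asthma) are summarised once per subject; visit-level fields (antibiotics,
#' exclusive breastfeeding) per time-point. An explicit per-field denominator
#' override supports covariates with missing values.
#'
#' @param metadata Metadata data.frame (see [read_sample_metadata()]).
#' @param by Optional grouping column (e.g. a pneumotype label column) for a
#'   per-group, per-time-point breakdown.
#' @param digits Decimal places for percentages (0 or 1).
#' @param denominators Optional named numeric vector overriding the
#'   denominator for specific fields.
#' @return data.frame with `field`, `group`, `timepoint`, `n`, `denom`,
#'   `percent` and the formatted `label`.
#' @export
cohort_summary <- function(metadata, by = NULL, digits = 0, denominators = NULL) {
  metadata <- validate_metadata(metadata)
  subject_fields <- intersect(c("sex", "siblings", "csection", "mother_asthma"),
                              names(metadata))
  visit_fields <- intersect(c("antibiotics", "exclusively_breastfed"),
                            names(metadata))
  one_row <- function(field, group, timepoint, x, denom) {
    if (!is.null(denominators) && field %in% names(denominators))
      denom <- unname(denominators[[field]])
    n <- sum(x, na.rm = TRUE)
    data.frame(field = field, group = group, timepoint = timepoint,
               n = n, denom = denom,
               percent = round_half_up(ifelse(denom > 0, 100 * n / denom, 0), digits),
               label = percent_label(n, denom, digits),
               stringsAsFactors = FALSE)
  }
  split_by <- if (is.null(by)) list(all = metadata) else split(metadata, metadata[[by]])
  out <- list()
  for (g in names(split_by)) {
    md <- split_by[[g]]
    subj <- md[!duplicated(md$subject_id), , drop = FALSE]
    for (f in subject_fields) {
      x <- subj[[f]]
      if (f == "sex") x <- x %in% c("male", "M", TRUE)
      out[[length(out) + 1L]] <-
        one_row(f, g, "subject", as.logical(x), sum(!is.na(x)))
    }
    for (f in visit_fields) {
      for (tp in levels(md$timepoint)) {
        x <- md[[f]][md$timepoint == tp]
        out[[length(out) + 1L]] <-
          one_row(f, g, tp, as.logical(x), sum(!is.na(x)))
      }
    }
  }
  do.call(rbind, out)
}
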