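#' OTU count table with taxonomy
#'
#' An `otu_table` couples a samples-by-OTUs matrix of non-negative integer
#' read counts with an optional per-OTU taxonomic lineage. It is the common
#' currency of the pipeline: QC filters, rarefaction, diversity kernels,
#' clustering and the core-microbiota statistics all consume and return it.
#'
#' @param counts Numeric matrix of non-negative integers; rows are samples,
#'   columns are OTUs. Row and column names are required and must be unique.
#' @param taxonomy Optional data.frame of per-OTU lineages with row names
#'   matching OTU ids and (a subset of) the columns
#'   `domain, phylum, class, order, family, genus`. Unknown ranks are `""`.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (data.frame or `NULL`).
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 7L, 1L, 1L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("OTU1", "OTU2")))
#' tab <- otu_table(m)
#' n_samples(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no samples", call. = FALSE)
  if (ncol(counts) == 0L) stop("no OTUs", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("count for sample '%s', OTU '%s' is not a non-negative integer",
                 rownames(counts)[i[1L]], colnames(counts)[i[2L]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    miss <- setdiff(colnames(counts), rownames(taxonomy))
    if (length(miss)) {  # pad unknown OTUs with empty lineages
      pad <- taxonomy[rep(NA_integer_, length(miss)), , drop = FALSE]
      pad[is.na(pad)] <- ""
      rownames(pad) <- miss
      taxonomy <- rbind(taxonomy, pad)
    }
    taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total reads: %.0f (per-sample depth %d-%d)\n",
              sum(as.numeric(x$counts)),
              min(rowSums(x$counts)), max(rowSums(x$counts))))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy: %s\n", paste(names(x$taxonomy), collapse = ", ")))
  invisible(x)
}

#' @rdname otu_table
#' @param x,table An `otu_table`.
#' @export
n_samples <- function(table) nrow(table$counts)

#' @rdname otu_table
#' @export
n_otus <- function(table) ncol(table$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(table) colnames(table$counts)

#' Subset an OTU table by sample and/or OTU
#'
#' @param x An `otu_table`.
#' @param i Sample index, names or logical vector.
#' @param j OTU index, names or logical vector.
#' @param ... Ignored.
#' @export
`[.otu_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[colnames(counts), , drop = FALSE]
  structure(list(counts = counts, taxonomy = tax), class = "otu_table")
}

#' Relative-abundance view of an OTU table
#'
#' @param table An `otu_table`.
#' @return Matrix of per-sample proportions; rows with zero total stay zero.
#' @export
rel_abund <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- rowSums(counts)
  out <- counts / ifelse(tot > 0, tot, 1)
  out
}

#' Genus (or other rank) of each OTU
#'
#' @param table An `otu_table` with taxonomy.
#' @param rank One of `domain, phylum, class, order, family, genus`.
#' @return Named character vector, `""` where the rank is unknown.
#' @export
otu_rank <- function(table, rank = "genus") {
  rank <- match.arg(rank, tax_ranks())
  if (is.null(table$taxonomy) || !rank %in% names(table$taxonomy))
    return(stats::setNames(rep("", n_otus(table)), otu_ids(table)))
  stats::setNames(as.character(table$taxonomy[[rank]]), otu_ids(table))
}

tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")

#' Read an OTU table (and taxonomy) from TSV
#'
#' The counts file is rectangular: a header row of OTU ids and a first column
#' of sample ids. The taxonomy file maps `otu_id` to a semicolon-separated
#' lineage (`domain;phylum;class;order;family;genus`, possibly truncated).
#'
#' @param counts_path Path to the counts TSV.
#' @param taxonomy_path Optional path to the taxonomy TSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(counts_path, taxonomy_path = NULL) {
  if (length(readLines(counts_path, warn = FALSE)) == 0L)
    stop("no samples", call. = FALSE)
  raw <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no samples", call. = FALSE)
  counts <- as.matrix(raw)
  tax <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  otu_table(counts, taxonomy = tax)
}

#' Read a two-column OTU taxonomy TSV (otu_id, semicolon lineage)
#'
#' @param path Path to the taxonomy TSV (no header).
#' @return data.frame of ranks, row names = OTU ids.
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("otu_id", "lineage"))
  parse_lineage(stats::setNames(raw$lineage, raw$otu_id))
}

#' Split semicolon lineages into a rank table
#'
#' @param lineage Named character vector of `;`-separated lineages.
#' @return data.frame with columns `domain..genus`; missing ranks are `""`.
#' @export
parse_lineage <- function(lineage) {
  ranks <- tax_ranks()
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    c(p, rep("", length(ranks)))[seq_along(ranks)]
  }, character(length(ranks))))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- ranks
  rownames(out) <- names(lineage)
  out
}

#' Read a sample metadata sheet
#'
#' Expected columns: `sample_id`, `subject_id`, `timepoint` (W1/M1/M3) and any
#' of `age_days`, `sex`, `siblings`, `csection`, `antibiotics`,
#' `exclusively_breastfed`, `mother_asthma`, `birth_month`, `dna_conc`.
#' At most one sample per (subject, timepoint) is allowed.
#'
#' @param path Path to a TSV with a header row.
#' @return data.frame with `timepoint` as a factor with levels W1, M1, M3.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' Validate a sample metadata data.frame
#'
#' @param md data.frame with at least `sample_id`, `subject_id`, `timepoint`.
#' @return The validated data.frame (timepoint coerced to the W1/M1/M3 factor).
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "timepoint")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata", call. = FALSE)
  bad <- setdiff(unique(as.character(md$timepoint)), timepoint_levels())
  if (length(bad)) stop("unknown timepoint(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  md$timepoint <- factor(as.character(md$timepoint), levels = timepoint_levels())
  if (anyDuplicated(md[, c("subject_id", "timepoint")]))
    stop("more than one sample for some (subject, timepoint)", call. = FALSE)
  md
}

#' @rdname validate_metadata
#' @export
timepoint_levels <- function() c("W1", "M1", "M3")

#' Write / read a square labelled distance matrix as TSV
#'
#' @param d A `dist` object or square matrix.
#' @param path Output path.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @param path Path to a TSV written by [write_distance_tsv()].
#' @export
read_distance_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  stats::as.dist(m)
}

#' Write an OTU table's counts as TSV
#'
#' @param table An `otu_table`.
#' @param path Output path.
#' @export
write_counts_tsv <- function(table, path) {
  utils::write.table(data.frame(sample_id = sample_ids(table), table$counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
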