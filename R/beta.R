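#' @keywords internal
#' Tip-by-edge incidence of a rooted tree: entry (t, e) is TRUE when tip t
#' descends from edge e's child node. Built in one post-order pass.
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  M <- matrix(FALSE, nt, nrow(tree$edge),
              dimnames = list(tree$tip.label, NULL))
  node_sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) node_sets[[i]] <- i
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    s <- node_sets[[child]]
    M[s, e] <- TRUE
    node_sets[[parent]] <- c(node_sets[[parent]], s)
  }
  M
}

check_tree <- function(tree, otus) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  miss <- setdiff(otus, tree$tip.label)
  if (length(miss))
    stop("OTU(s) missing from tree: ", paste(miss, collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' Weighted UniFrac distance between two samples
#'
#' The raw statistic is `sum_e l_e * |A_e - B_e|` over all branches `e`, where
#' `A_e` and `B_e` are the fractions of each sample's reads descending from
#' the branch. The normalised variant divides by
#' `sum_j d_j * (p_aj + p_bj)` with `d_j` the root-to-tip path length of tip
#' `j`, bounding the distance to `[0, 1]`.
#'
#' @param a,b Named non-negative count (or proportion) vectors; names must be
#'   tips of `tree`. Renormalised internally.
#' @param tree Rooted `phylo` tree with branch lengths covering all OTUs.
#' @param normalized Divide by the maximal attainable value (default TRUE).
#' @return A single non-negative distance.
#' @export
weighted_unifrac <- function(a, b, tree, normalized = TRUE) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("count vectors must be named by OTU id", call. = FALSE)
  if (sum(a) <= 0 || sum(b) <= 0) stop("zero-total sample", call. = FALSE)
  otus <- union(names(a), names(b))
  check_tree(tree, otus)
  p <- q <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  p[names(a)] <- a / sum(a)
  q[names(b)] <- b / sum(b)
  M <- edge_tip_incidence(tree)
  A <- as.numeric(crossprod(M, p))
  B <- as.numeric(crossprod(M, q))
  W <- sum(tree$edge.length * abs(A - B))
  if (!normalized) return(W)
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  D <- sum(d * (p + q))
  if (D == 0) 0 else W / D
}

#' Jensen-Shannon divergence between two compositions
#'
#' `JSD = KL(p||m)/2 + KL(q||m)/2` with `m = (p + q)/2`, natural log, and the
#' convention `0 * log 0 = 0`. Bounded by `log(2)`; `sqrt(JSD)` is a metric.
#'
#' @param p,q Non-negative vectors of equal length; renormalised internally.
#' @return Divergence in nats.
#' @export
jensen_shannon <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(x) {
    i <- x > 0
    sum(x[i] * log(x[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

#' All pairwise beta-diversity distances of an OTU table
#'
#' Weighted UniFrac is computed from a single tip-by-edge incidence pass:
#' per-sample branch fractions reduce the raw statistic to a weighted L1
#' distance between rows, and the normalisation denominator to the sum of two
#' per-sample constants, so the full matrix costs one matrix product.
#'
#' @param table An [otu_table()] with at least one sample.
#' @param tree Rooted `phylo` tree (required for `metric = "wunifrac"`).
#' @param metric `"wunifrac"` or `"jsd"`.
#' @param normalized Normalise UniFrac to `[0, 1]` (default TRUE).
#' @param sqrt_jsd Return `sqrt(JSD)` (a metric) instead of the divergence.
#' @return A `dist` object labelled by sample id.
#' @export
distance_matrix <- function(table, tree = NULL,
                            metric = c("wunifrac", "jsd"),
                            normalized = TRUE, sqrt_jsd = FALSE) {
  metric <- match.arg(metric)
  if (n_samples(table) == 0L) stop("empty table", call. = FALSE)
  P <- rel_abund(table)
  if (any(rowSums(table$counts) == 0))
    stop("zero-total sample: ",
         paste(sample_ids(table)[rowSums(table$counts) == 0], collapse = ", "),
         call. = FALSE)
  if (metric == "wunifrac") {
    if (is.null(tree)) stop("metric 'wunifrac' requires a tree", call. = FALSE)
    check_tree(tree, otu_ids(table))
    Pt <- matrix(0, nrow(P), length(tree$tip.label),
                 dimnames = list(rownames(P), tree$tip.label))
    Pt[, colnames(P)] <- P
    M <- edge_tip_incidence(tree)
    A <- Pt %*% M                               # samples x edges branch fractions
    W <- stats::dist(sweep(A, 2L, tree$edge.length, `*`), method = "manhattan")
    if (!normalized) return(W)
    d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    u <- as.numeric(Pt %*% d)                   # per-sample mean root-to-tip depth
    D <- stats::as.dist(outer(u, u, `+`))
    out <- W
    out[] <- ifelse(as.numeric(D) == 0, 0, as.numeric(W) / as.numeric(D))
    return(out)
  }
  # JSD via the entropy identity H(m) - (H(p) + H(q))/2, one row at a time
  n <- nrow(P)
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  }
  H <- apply(P, 1L, ent)
  out <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n)) {
    Mi <- sweep(P, 2L, P[i, ], `+`) / 2
    L <- Mi * log(Mi)
    L[Mi == 0] <- 0
    Hm <- -rowSums(L)
    out[i, ] <- Hm - (H + H[i]) / 2
  }
  out <- stats::as.dist((out + t(out)) / 2)
  out[out < 0] <- 0                             # clip numerical negatives
  if (sqrt_jsd) sqrt(out) else out
}
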