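# Shared fixtures and independent oracles, all built in code.

toy_counts <- function() {
  matrix(c(5L, 0L, 0L, 7L, 1L, 1L), nrow = 3, byrow = TRUE,
         dimnames = list(c("S1", "S2", "S3"), c("OTU1", "OTU2")))
}

write_counts_file <- function(counts) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent weighted-UniFrac oracle: per tip, walk its root path and add
# its mass to every edge on the path (no post-order pass, no incidence
# matrix), then sum branch-by-branch.
unifrac_oracle <- function(a, b, tree, normalized = TRUE) {
  p <- q <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  p[names(a)] <- a / sum(a)
  q[names(b)] <- b / sum(b)
  nt <- length(tree$tip.label)
  parent <- edge_of <- integer(nt + tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    parent[tree$edge[r, 2]] <- tree$edge[r, 1]
    edge_of[tree$edge[r, 2]] <- r
  }
  root <- nt + 1L
  A <- B <- numeric(nrow(tree$edge))
  depth <- numeric(nt)
  for (j in seq_len(nt)) {
    node <- j
    while (node != root) {
      e <- edge_of[node]
      A[e] <- A[e] + p[j]
      B[e] <- B[e] + q[j]
      depth[j] <- depth[j] + tree$edge.length[e]
      node <- parent[node]
    }
  }
  W <- sum(tree$edge.length * abs(A - B))
  if (!normalized) return(W)
  W / sum(depth * (p + q))
}

# Exhaustive k-medoids optimum by enumeration of every medoid subset.
exhaustive_pam_cost <- function(dm, k) {
  n <- nrow(dm)
  best <- Inf
  for (m in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(dm[, m, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

random_tip_tree <- function(n_tips) {
  tree <- ape::rtree(n_tips, tip.label = paste0("OTU", seq_len(n_tips)))
  tree$edge.length <- tree$edge.length + 0.05   # keep branches positive
  tree
}

random_composition <- function(n, sparse = FALSE) {
  x <- stats::rgamma(n, if (sparse) 0.5 else 1.5)
  x / sum(x)
}

make_assignments <- function(w1, m1, m3, subjects = NULL) {
  if (is.null(subjects)) subjects <- paste0("S", seq_along(w1))
  data.frame(subject_id = rep(subjects, 3),
             timepoint = rep(c("W1", "M1", "M3"), each = length(subjects)),
             label = c(w1, m1, m3), stringsAsFactors = FALSE)
}

# small synthetic cohort for module tests (quick to generate)
small_cohort <- function(n_subjects = 60, seed = 1, ...) {
  cfg <- default_config(n_subjects = n_subjects, seed = seed)
  extra <- list(...)
  cfg[names(extra)] <- extra
  generate_cohort(cfg)
}

rarefied_cohort <- function(cohort, depth = 2000, seed = 1) {
  dep <- filter_min_depth(cohort$table, depth)
  out <- exclude_diversity_outliers(dep$table)
  rarefy_table(out$table, depth, seed = seed)
}
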