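#' k-medoids (PAM) on a distance matrix
#'
#' Finds `k` medoid samples minimising the total distance of every sample to
#' its nearest medoid. Small instances (`choose(n, k) <= exact_limit`) are
#' solved exactly by enumerating all medoid subsets in lexicographic order
#' (ties therefore resolve to the lowest sample indices); larger instances
#' use the deterministic BUILD + SWAP heuristic of [cluster::pam()].
#'
#' @param d A `dist` object (or square matrix) with sample labels.
#' @param k Number of clusters, `2 <= k < n`.
#' @param exact_limit Maximum number of medoid subsets to enumerate exactly.
#' @return List with `medoids` (sample ids, ascending index order), `labels`
#'   (named integer vector, cluster of each sample), `cost` (total distance
#'   to assigned medoids) and `method` (`"exact"` or `"build_swap"`).
#' @export
pam_medoids <- function(d, k, exact_limit = 5000) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- as.character(seq_len(n))
  if (k < 2 || k >= n) stop("need 2 <= k < n samples", call. = FALSE)
  if (choose(n, k) <= exact_limit) {
    best <- Inf
    best_med <- NULL
    sets <- utils::combn(n, k)
    for (j in seq_len(ncol(sets))) {
      m <- sets[, j]
      cost <- sum(do.call(pmin, lapply(m, function(i) dm[, i])))
      if (cost < best - 1e-12) {
        best <- cost
        best_med <- m
      }
    }
    med_idx <- best_med
    method <- "exact"
  } else {
    fit <- cluster::pam(stats::as.dist(dm), k, diss = TRUE)
    med_idx <- sort(match(fit$medoids, rownames(dm)))
    method <- "build_swap"
  }
  med_idx <- sort(med_idx)
  assign <- apply(dm[, med_idx, drop = FALSE], 1L, which.min)  # ties -> lowest medoid
  labels <- stats::setNames(as.integer(assign), rownames(dm))
  cost <- sum(dm[cbind(seq_len(n), med_idx[assign])])
  list(medoids = rownames(dm)[med_idx], labels = labels, cost = cost,
       method = method)
}

#' Per-sample silhouette widths and their average
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance to
#' the sample's own cluster (excluding itself) and `b(i)` the smallest mean
#' distance to another cluster. Samples in singleton clusters, and the
#' degenerate all-distances-zero case, get `s(i) = 0`.
#'
#' @param d A `dist` object or square matrix.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return List with `widths` (named numeric) and `asw` (their mean).
#' @export
silhouette_widths <- function(d, labels) {
  d <- stats::as.dist(as.matrix(d))
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least 2 clusters", call. = FALSE)
  sil <- cluster::silhouette(labels, dist = d)
  w <- sil[, "sil_width"]
  w[!is.finite(w)] <- 0
  names(w) <- attr(d, "Labels")
  list(widths = w, asw = mean(w))
}

#' Fit a pneumotype (community state type) model
#'
#' Clusters samples of a beta-diversity distance matrix with PAM and, when
#' `k = "auto"`, chooses the number of clusters maximising the average
#' silhouette width over `k_range` (ties to the smallest k). This is the
#' distance-based community-typing procedure used for gut enterotypes,
#' applied to airway samples.
#'
#' @param d A `dist` object of pairwise sample distances (weighted UniFrac or
#'   Jensen-Shannon divergence; see [distance_matrix()]).
#' @param k `"auto"` or a fixed integer number of clusters.
#' @param k_range Candidate cluster numbers scanned when `k = "auto"`.
#' @param metric Optional label recording which distance was used.
#' @return An object of class `pneumotype`: list with `k`, `medoids`,
#'   `labels` (named integer vector), `silhouette` (per-sample widths),
#'   `asw`, `asw_by_k` (data.frame `k`, `asw`), `cost`, `metric`, `call`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
#' fit <- pneumotype(dist(x), k_range = 2:4)
#' fit$k
#' @export
pneumotype <- function(d, k = "auto", k_range = 2:10, metric = NULL) {
  n <- attr(stats::as.dist(as.matrix(d)), "Size")
  fit_one <- function(kk) {
    p <- pam_medoids(d, kk)
    s <- silhouette_widths(d, p$labels)
    list(pam = p, sil = s)
  }
  if (identical(k, "auto")) {
    k_range <- k_range[k_range < n]
    fits <- lapply(k_range, fit_one)
    asw_by_k <- data.frame(k = k_range,
                           asw = vapply(fits, function(f) f$sil$asw, numeric(1)))
    pick <- which.max(asw_by_k$asw)   # first maximum -> smallest k on ties
    chosen <- fits[[pick]]
    k_star <- k_range[pick]
  } else {
    chosen <- fit_one(as.integer(k))
    k_star <- as.integer(k)
    asw_by_k <- data.frame(k = k_star, asw = chosen$sil$asw)
  }
  structure(list(k = k_star,
                 medoids = chosen$pam$medoids,
                 labels = chosen$pam$labels,
                 silhouette = chosen$sil$widths,
                 asw = chosen$sil$asw,
                 asw_by_k = asw_by_k,
                 cost = chosen$pam$cost,
                 metric = metric,
                 call = match.call()),
            class = "pneumotype")
}

#' @export
print.pneumotype <- function(x, ...) {
  cat(sprintf("Pneumotype model: %d clusters over %d samples%s\n",
              x$k, length(x$labels),
              if (is.null(x$metric)) "" else sprintf(" (%s)", x$metric)))
  cat(sprintf("  average silhouette width: %.3f\n", x$asw))
  sizes <- table(x$labels)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pneumotype <- function(object, ...) {
  per_cluster <- data.frame(
    cluster = sort(unique(object$labels)),
    n = as.integer(table(object$labels)),
    medoid = object$medoids,
    mean_silhouette = as.numeric(tapply(object$silhouette, object$labels, mean)))
  out <- list(k = object$k, asw = object$asw, per_cluster = per_cluster,
              asw_by_k = object$asw_by_k)
  class(out) <- "summary.pneumotype"
  out
}

#' @export
print.summary.pneumotype <- function(x, ...) {
  cat(sprintf("Pneumotype model, k = %d (ASW %.3f)\n", x$k, x$asw))
  print(x$per_cluster, row.names = FALSE)
  if (nrow(x$asw_by_k) > 1L) {
    cat("ASW by k:\n")
    print(x$asw_by_k, row.names = FALSE)
  }
  invisible(x)
}

#' @export
labels.pneumotype <- function(object, ...) object$labels

#' @export
fitted.pneumotype <- function(object, ...) object$labels

#' Silhouette diagnostics plot for a pneumotype model
#'
#' Left panel: average silhouette width against the number of clusters (the
#' model-selection curve). Right panel: sorted per-sample silhouette widths
#' by cluster.
#'
#' @param x A `pneumotype` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pneumotype <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$asw_by_k$k, x$asw_by_k$asw, type = "b", xlab = "k",
       ylab = "average silhouette width", ...)
  graphics::abline(v = x$k, lty = 2)
  ord <- order(x$labels, -x$silhouette)
  graphics::barplot(x$silhouette[ord], col = x$labels[ord], border = NA,
                    names.arg = rep("", length(ord)),
                    ylab = "silhouette width", xlab = "samples by cluster")
  invisible(x)
}

#' Permutation test of cluster optimality
#'
#' Tests whether the observed clustering has smaller size-normalised
#' within-cluster distances than random groupings of the same sizes. The
#' statistic is `T = sum_c W_c / n_c`, with `W_c` the sum of within-cluster
#' pairwise distances; the null distribution is `T` under random label
#' permutations, and `p = (1 + #{T_perm <= T_obs}) / (1 + n_perm)`.
#'
#' @param d A `dist` object or square matrix.
#' @param labels Cluster labels.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `statistic`, `p_value`, `n_perm`, `null_mean`,
#'   `null_sd` and a `scheme` string describing the test.
#' @export
cluster_optimality_test <- function(d, labels, n_perm = 10000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  stat <- function(lab) {
    idx <- split(seq_len(n), lab)
    sum(vapply(idx, function(i) sum(dm[i, i]) / (2 * length(i)), numeric(1)))
  }
  obs <- stat(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat(labels[sample.int(n)]),
                 numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(null <= obs)) / (1 + n_perm),
       n_perm = n_perm,
       null_mean = mean(null),
       null_sd = stats::sd(null),
       scheme = "size-normalised within-cluster distance sums vs size-preserving label permutations, lower tail, add-one p")
}
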