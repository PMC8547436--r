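#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `d = sum(|x - y|) / sum(x + y)`, bounded in `[0, 1]`: 0 for identical
#' profiles, 1 for disjoint supports.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length", "bad-argument")
  if (any(x < 0) || any(y < 0)) abort("abundances must be nonnegative", "bad-argument")
  denom <- sum(x) + sum(y)
  if (denom == 0) abort("both vectors are all-zero", "undefined-distance")
  sum(abs(x - y)) / denom
}

#' Bray-Curtis distance matrix over samples
#'
#' Computes all pairwise Bray-Curtis dissimilarities between the columns of
#' an abundance matrix (isolates in columns, e.g. the TIC-normalized,
#' replicate-merged table).
#'
#' @param x numeric matrix (features x isolates) or a [feature_table()].
#' @return a `dist` object with `method` attribute `"bray-curtis"`.
#' @export
bray_curtis_dist <- function(x) {
  if (inherits(x, "feature_table")) x <- x$abundance
  tot <- colSums(x)
  if (any(tot == 0)) abort("all-zero sample column", "undefined-distance")
  man <- stats::dist(t(x), method = "manhattan")
  n <- ncol(x)
  pair_tot <- utils::combn(n, 2, function(ij) tot[ij[1]] + tot[ij[2]])
  d <- man / pair_tot
  attr(d, "method") <- "bray-curtis"
  d
}

#' Principal-coordinate analysis (classical MDS)
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Axes with eigenvalues at or below `tol` are dropped;
#' negative eigenvalues (non-Euclidean distances such as Bray-Curtis) are
#' dropped without correction and flagged.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param tol eigenvalues <= `tol` are discarded.
#' @return list of class `pcoa_result`: `coordinates` (n x n_axes),
#'   `eigenvalues` (descending, all of them), `proportion_explained`
#'   (over positive eigenvalues), `negative_eigenvalues` flag.
#' @export
pcoa <- function(d, tol = sqrt(.Machine$double.eps)) {
  m <- as.matrix(d)
  if (nrow(m) < 2) abort("need at least two samples", "bad-argument")
  if (!isSymmetric(unname(m), tol = 1e-8)) abort("distance matrix must be symmetric",
                                                 "invalid-distance")
  n <- nrow(m)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- which(eig > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = eig[pos] / sum(eig[pos]),
    negative_eigenvalues = any(eig < -tol)
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes%s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              if (x$negative_eigenvalues) " (negative eigenvalues dropped)" else ""))
  cat("  proportion explained:",
      paste0(round(100 * x$proportion_explained[seq_len(min(3, ncol(x$coordinates)))], 1),
             "%", collapse = ", "), "...\n")
  invisible(x)
}

#' Hierarchical clustering of isolates with silhouette-selected k
#'
#' Builds an average-linkage (UPGMA) tree on the distance matrix, cuts it at
#' every candidate number of clusters, scores each cut by its mean
#' silhouette width `s(i) = (b_i - a_i) / max(a_i, b_i)` computed from the
#' same distances, and returns the labeling that maximizes the mean
#' silhouette (ties broken toward smaller k, i.e. parsimony).
#'
#' @param d a `dist` object or symmetric distance matrix over isolates.
#' @param k_range candidate cluster counts, a subset of `2:(n-1)`.
#' @param linkage linkage method passed to [stats::hclust()] ("average").
#' @return list of class `cluster_assignment`: `labels` (integer vector,
#'   1..k per isolate), `k`, `silhouette` (named mean silhouette per
#'   candidate k), `tree` (the hclust object).
#' @export
cluster_isolates <- function(d, k_range = 2:10, linkage = "average") {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3) abort("need at least three samples to cluster", "too-few-samples")
  if (all(m[upper.tri(m)] == 0))
    abort("all distances are zero; silhouette undefined", "degenerate-distances")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    abort("k_range must lie within [2, n-1]", "bad-argument")
  tree <- stats::hclust(stats::as.dist(m), method = linkage)
  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(cl, dmatrix = m)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  best <- k_range[which.max(sil)]   # first max -> smallest k on ties
  labels <- stats::cutree(tree, k = best)
  structure(list(labels = labels, k = best, silhouette = sil, tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d (mean silhouette %.3f)\n",
              x$k, x$silhouette[as.character(x$k)]))
  print(table(x$labels))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix. With `N` samples in `k` groups:
#' `SS_total = sum_{i<j} d_ij^2 / N`; `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`; `pseudo-F = (SS_between/(k-1)) / (SS_within/(N-k))`. The
#' p-value permutes group labels and uses the add-one convention
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so the observed statistic
#' is always a member of its own reference set and p is never zero.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups, each non-empty, no
#'   group equal to the whole sample).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed for the permutations; the caller's RNG
#'   state is left untouched.
#' @return list of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_perm`, `df` (between, within), `ss` (between, within, total).
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  d2 <- as.matrix(d)^2
  N <- nrow(d2)
  labels <- as.character(labels)
  if (length(labels) != N) abort("one label per sample required", "bad-argument")
  k <- length(unique(labels))
  if (k < 2) abort("need at least two groups", "degenerate-design")
  if (max(table(labels)) == N) abort("a group equals the whole sample", "degenerate-design")
  if (n_perm < 1) abort("n_perm must be >= 1", "bad-argument")

  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_w <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1) s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_w(lab)
    ((ss_total - ssw) / (k - 1)) / (ssw / (N - k))
  }
  f_obs <- f_stat(labels)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  f_perm <- vapply(seq_len(n_perm), function(i) f_stat(sample(labels)), numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  ssw_obs <- ss_w(labels)
  structure(list(pseudo_F = f_obs, p_value = p, n_perm = n_perm,
                 df = c(between = k - 1, within = N - k),
                 ss = c(between = ss_total - ssw_obs, within = ssw_obs,
                        total = ss_total)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_perm))
  invisible(x)
}
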