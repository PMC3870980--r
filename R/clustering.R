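#' Cluster genes by expression with a permutation-derived correlation cutoff
#'
#' Hierarchical clustering with centered-Pearson distance (1 - r) and complete
#' linkage. The tree is cut at height 1 - \code{threshold_r} so that every
#' reported cluster satisfies the all-pairwise rule (all within-cluster
#' correlations > \code{threshold_r}). The cutoff itself is chosen by a
#' permutation null: each gene's values are permuted independently across
#' samples \code{n_permutations} times, and the smallest r on
#' \code{threshold_grid} is kept for which the mean number of chance clusters
#' of size >= 2 falls below \code{max_chance_clusters}.
#'
#' @param x Expression matrix (genes x samples) or \code{expression_matrix};
#'   >= 10 genes, >= 4 samples.
#' @param n_permutations Number of permutation rounds for the null.
#' @param threshold_grid Candidate correlation cutoffs (increasing).
#' @param max_chance_clusters Expected chance clusters tolerated (this design
#'   allowed "fewer than three").
#' @param seed Integer seed for the permutations.
#' @return List of class \code{cluster_set}: \code{clusters} (list of gene id
#'   vectors, size >= 2), \code{threshold_r}, \code{n_permutations}.
#' @export
cluster_genes <- function(x, n_permutations = 10,
                          threshold_grid = seq(0.50, 0.99, by = 0.01),
                          max_chance_clusters = 3, seed = 1L) {
  v <- expr_values(x)
  if (nrow(v) < 10) stop("need at least 10 genes")
  if (ncol(v) < 4) stop("need at least 4 samples")
  genes <- if (is.null(rownames(v))) as.character(seq_len(nrow(v))) else rownames(v)

  clusters_at <- function(mat, r) {
    hc <- stats::hclust(stats::as.dist(1 - stats::cor(t(mat))), method = "complete")
    grp <- stats::cutree(hc, h = 1 - r)
    sizes <- table(grp)
    as.integer(names(sizes)[sizes >= 2])
  }
  count_at_all <- function(mat) {
    cm <- stats::cor(t(mat))
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "complete")
    vapply(threshold_grid, function(r) {
      sizes <- table(stats::cutree(hc, h = 1 - r))
      sum(sizes >= 2)
    }, numeric(1))
  }

  set.seed(seed)
  null_counts <- matrix(0, nrow = n_permutations, ncol = length(threshold_grid))
  for (b in seq_len(n_permutations)) {
    perm <- t(apply(v, 1, sample))
    null_counts[b, ] <- count_at_all(perm)
  }
  mean_null <- colMeans(null_counts)
  ok <- which(mean_null < max_chance_clusters)
  if (length(ok) == 0) {
    threshold_r <- max(threshold_grid)
    warning("no cutoff on the grid controls the chance-cluster count; using the maximum")
  } else threshold_r <- threshold_grid[ok[1]]

  cm <- stats::cor(t(v))
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "complete")
  grp <- stats::cutree(hc, h = 1 - threshold_r)
  out <- list()
  for (g in unique(grp)) {
    members <- genes[grp == g]
    if (length(members) < 2) next
    sub <- cm[grp == g, grp == g]
    if (min(sub[upper.tri(sub)]) > threshold_r)  # enforce the strict all-pairwise rule
      out[[length(out) + 1L]] <- members
  }
  structure(list(clusters = out, threshold_r = threshold_r,
                 n_permutations = n_permutations),
            class = "cluster_set")
}
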