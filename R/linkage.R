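#' Conditional genotype probabilities on a pseudo-marker grid
#'
#' Builds a scan grid per chromosome (all marker positions plus pseudo-markers
#' every \code{step_cM}) and computes, per segregant and grid locus, the
#' probability of carrying the P1 allele conditional on the nearest
#' non-missing flanking markers under the Haldane model. At a genotyped,
#' non-missing marker the probability is exactly 0 or 1 (for
#' \code{error_rate = 0}).
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param step_cM Pseudo-marker spacing in centimorgans (2.5 cM = 7.5 kbp).
#' @param error_rate Assumed genotyping error rate; typed markers are treated
#'   as correct with probability \code{1 - error_rate}.
#' @return List of class \code{genotype_probabilities}: \code{grid}
#'   (data.frame \code{chromosome}, \code{pos_kbp}, \code{pos_cM},
#'   \code{is_marker}, \code{marker_id}) and \code{probs} (matrix grid loci x
#'   segregants of P(P1)).
#' @export
genotype_probabilities <- function(genotypes, step_cM = 2.5, error_rate = 0) {
  stopifnot(step_cM > 0, error_rate >= 0, error_rate < 0.5)
  map <- genotypes$map
  validate_marker_map(map)
  x <- genotype_numeric(genotypes)
  n_seg <- ncol(x)

  grids <- lapply(sort(unique(map$chromosome)), function(ch) {
    i <- which(map$chromosome == ch)
    mcm <- map$pos_cM[i]
    pseudo <- setdiff(seq(min(mcm), max(mcm), by = step_cM), mcm)
    cm <- sort(c(mcm, pseudo))
    is_m <- cm %in% mcm
    data.frame(chromosome = ch, pos_kbp = ifelse(is_m,
                 map$pos_kbp[i][match(cm, mcm)], cm * KBP_PER_CM),
               pos_cM = cm, is_marker = is_m,
               marker_id = ifelse(is_m, map$marker_id[i][match(cm, mcm)], NA),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grids)
  probs <- matrix(NA_real_, nrow = nrow(grid), ncol = n_seg,
                  dimnames = list(NULL, colnames(x)))

  for (ch in unique(grid$chromosome)) {
    gi <- which(grid$chromosome == ch)
    mi <- which(map$chromosome == ch)
    loc_cm <- grid$pos_cM[gi]
    for (s in seq_len(n_seg)) {
      obs <- which(!is.na(x[mi, s]))
      if (length(obs) == 0) {
        warning(sprintf("segregant %s has no informative marker on chromosome %s",
                        colnames(x)[s], ch))
        probs[gi, s] <- 0.5
        next
      }
      ocm <- map$pos_cM[mi][obs]
      og <- x[mi, s][obs]
      if (error_rate > 0) og <- og * (1 - 2 * error_rate) + error_rate
      left <- findInterval(loc_cm, ocm)           # index of flank at <= locus
      right <- length(ocm) - findInterval(-loc_cm, rev(-ocm)) + 1L
      p <- numeric(length(loc_cm))
      for (k in seq_along(loc_cm)) {
        L <- left[k]; R <- right[k]
        if (L >= 1 && R <= length(ocm) && L == R) {       # at a typed marker
          p[k] <- og[L]
        } else if (L >= 1 && R <= length(ocm)) {          # interior interval
          rl <- haldane_r(loc_cm[k] - ocm[L])
          rr <- haldane_r(ocm[R] - loc_cm[k])
          rt <- rl + rr - 2 * rl * rr
          gl <- og[L]; gr <- og[R]
          # P(locus = P1 | flanks), averaging over flank uncertainty
          num <- gl * gr * (1 - rl) * (1 - rr) +
                 gl * (1 - gr) * (1 - rl) * rr +
                 (1 - gl) * gr * rl * (1 - rr) +
                 (1 - gl) * (1 - gr) * rl * rr
          den <- gl * gr * (1 - rt) + gl * (1 - gr) * rt +
                 (1 - gl) * gr * rt + (1 - gl) * (1 - gr) * (1 - rt)
          p[k] <- num / den
        } else if (L >= 1) {                              # right of last marker
          rl <- haldane_r(loc_cm[k] - ocm[L])
          p[k] <- og[L] * (1 - rl) + (1 - og[L]) * rl
        } else {                                          # left of first marker
          rr <- haldane_r(ocm[R] - loc_cm[k])
          p[k] <- og[R] * (1 - rr) + (1 - og[R]) * rr
        }
      }
      probs[gi, s] <- p
    }
  }
  structure(list(grid = grid, probs = probs), class = "genotype_probabilities")
}

#' Haley-Knott single-QTL genome scan for one trait
#'
#' At each grid locus the trait is regressed on P(P1);
#' LOD = (n/2) log10(RSS0 / RSS1) against the mean-only null model. A
#' zero-variance trait yields an all-zero profile with a warning; perfect
#' fits are capped via RSS1 >= 1e-12 RSS0.
#'
#' @param probs A \code{genotype_probabilities}.
#' @param trait Numeric vector, one value per segregant; missing values are
#'   dropped (>= 8 non-missing required).
#' @return data.frame of class \code{lod_profile}: the grid columns plus
#'   \code{lod}.
#' @export
hk_scan <- function(probs, trait) {
  X <- probs$probs
  if (length(trait) != ncol(X)) stop("trait length must equal segregant count")
  keep <- !is.na(trait)
  if (sum(keep) < 8) stop("need >= 8 non-missing trait values")
  lod <- drop(hk_scan_matrix(probs, matrix(trait[keep], nrow = 1),
                             sample_subset = which(keep)))
  out <- probs$grid
  out$lod <- lod
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Haley-Knott scan of many traits/transcripts at once
#'
#' Vectorized version of \code{\link{hk_scan}} for complete-data matrices
#' (no missing values), used for transcriptome scans and permutations.
#'
#' @param probs A \code{genotype_probabilities}.
#' @param Y Numeric matrix traits x segregants.
#' @param sample_subset Optional integer index of segregant columns to use.
#' @return Matrix grid loci x traits of LOD scores.
#' @export
hk_scan_matrix <- function(probs, Y, sample_subset = NULL) {
  X <- probs$probs
  if (!is.null(sample_subset)) X <- X[, sample_subset, drop = FALSE]
  if (ncol(Y) != ncol(X)) stop("Y must have one column per segregant")
  if (anyNA(Y)) stop("hk_scan_matrix requires complete data; use hk_scan per trait")
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  rss0 <- rowSums(Yc^2)
  zero_var <- rss0 == 0
  if (any(zero_var)) warning("zero-variance trait(s): all-zero LOD profile returned")
  sxx <- rowSums(Xc^2)
  S <- Xc %*% t(Yc)                       # loci x traits
  expl <- S^2 / ifelse(sxx > 0, sxx, Inf)
  rss1 <- pmax(rep(rss0, each = nrow(X)) - expl,
               1e-12 * rep(rss0, each = nrow(X)))
  dim(rss1) <- dim(expl)
  lod <- (n / 2) * log10(rep(rss0, each = nrow(X)) / rss1)
  dim(lod) <- dim(expl)
  lod[, zero_var] <- 0
  lod[!is.finite(lod)] <- 0
  colnames(lod) <- rownames(Y)
  lod
}

#' Genome-wide LOD threshold for one trait by permutation
#'
#' Permutes the trait across segregants (genotypes fixed), records the
#' genome-wide maximum LOD of each permutation, and returns the
#' \code{1 - fdr} quantile of the null maxima.
#'
#' @param probs A \code{genotype_probabilities}.
#' @param trait Numeric trait vector (complete cases used).
#' @param n_perm Number of permutations (>= 100).
#' @param fdr Genome-wide error rate (default 0.05).
#' @param seed Integer seed.
#' @return LOD threshold (with the null maxima in \code{attr(, "null_max")}).
#' @export
permutation_threshold_trait <- function(probs, trait, n_perm = 1000,
                                        fdr = 0.05, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  keep <- which(!is.na(trait))
  y <- trait[keep]
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(b) sample(y), numeric(length(y)))
  lod <- hk_scan_matrix(probs, t(perms), sample_subset = keep)
  null_max <- apply(lod, 2, max)
  th <- unname(stats::quantile(null_max, 1 - fdr))
  attr(th, "null_max") <- null_max
  th
}

#' Transcriptome-wide FDR table by whole-matrix permutation
#'
#' Each permutation applies one shared shuffle of segregant labels to the
#' whole expression matrix (preserving transcript-transcript correlation),
#' rescans all transcripts, and counts transcripts whose genome-wide maximum
#' LOD reaches each grid threshold. FDR(t) = mean null count / observed
#' count, clipped to [0, 1]; thresholds with zero observed count get
#' \code{NA}.
#'
#' @param probs A \code{genotype_probabilities}.
#' @param x Expression matrix (genes x samples) or \code{expression_matrix}.
#' @param n_perm Number of permutation rounds (default 20).
#' @param lod_grid Thresholds at which counts are tabulated.
#' @param seed Integer seed.
#' @return data.frame of class \code{fdr_table}: \code{lod},
#'   \code{observed}, \code{null_mean}, \code{fdr}.
#' @export
permutation_fdr_transcriptome <- function(probs, x, n_perm = 20,
                                          lod_grid = seq(2, 8, by = 0.1),
                                          seed = 1L) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  Y <- expr_values(x)
  obs_max <- apply(hk_scan_matrix(probs, Y), 2, max)
  observed <- vapply(lod_grid, function(t) sum(obs_max >= t), numeric(1))
  set.seed(seed)
  null_counts <- matrix(0, nrow = n_perm, ncol = length(lod_grid))
  n <- ncol(Y)
  for (b in seq_len(n_perm)) {
    idx <- sample(n)
    null_max <- apply(hk_scan_matrix(probs, Y[, idx, drop = FALSE]), 2, max)
    null_counts[b, ] <- vapply(lod_grid, function(t) sum(null_max >= t), numeric(1))
  }
  null_mean <- colMeans(null_counts)
  fdr <- ifelse(observed > 0, pmin(null_mean / observed, 1), NA_real_)
  structure(data.frame(lod = lod_grid, observed = observed,
                       null_mean = null_mean, fdr = fdr),
            class = c("fdr_table", "data.frame"))
}

#' Smallest LOD threshold attaining a target transcriptome FDR
#'
#' @param fdr_table Output of \code{\link{permutation_fdr_transcriptome}}.
#' @param target Target FDR.
#' @return The smallest grid LOD with estimated FDR <= target; if none, the
#'   smallest grid LOD at which no transcript passes (vacuous control); if
#'   none of either, \code{Inf} with a warning.
#' @export
fdr_lod_threshold <- function(fdr_table, target = 0.05) {
  ok <- which(!is.na(fdr_table$fdr) & fdr_table$fdr <= target)
  if (length(ok) > 0) return(fdr_table$lod[ok[1]])
  empty <- which(fdr_table$observed == 0)
  if (length(empty) > 0) return(fdr_table$lod[empty[1]])
  warning("no grid threshold attains the target FDR")
  Inf
}

#' Call linkages from a LOD profile
#'
#' Per chromosome: if the maximum LOD reaches \code{threshold}, one record is
#' emitted at the peak locus (leftmost maximum on ties) with the 1-LOD
#' support interval, the contiguous region around the peak where
#' LOD >= peak - \code{drop}.
#'
#' @param profile A \code{lod_profile} (grid + \code{lod}).
#' @param threshold LOD threshold (> 0).
#' @param drop Support-interval LOD drop (default 1.0).
#' @return data.frame \code{peak_chrom}, \code{peak_kbp}, \code{lod},
#'   \code{ci_lo_kbp}, \code{ci_hi_kbp} (zero rows when nothing passes).
#' @export
call_linkages <- function(profile, threshold, drop = 1.0) {
  stopifnot(threshold > 0)
  recs <- list()
  for (ch in unique(profile$chromosome)) {
    i <- which(profile$chromosome == ch)
    lod <- profile$lod[i]
    m <- max(lod)
    if (m < threshold) next
    pk <- which.max(lod)                       # leftmost maximum
    inside <- lod >= m - drop
    lo <- pk; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
    hi <- pk; while (hi < length(i) && inside[hi + 1]) hi <- hi + 1
    recs[[length(recs) + 1L]] <- data.frame(
      peak_chrom = ch, peak_kbp = profile$pos_kbp[i][pk], lod = m,
      ci_lo_kbp = profile$pos_kbp[i][lo], ci_hi_kbp = profile$pos_kbp[i][hi])
  }
  if (length(recs) == 0)
    return(data.frame(peak_chrom = integer(0), peak_kbp = numeric(0),
                      lod = numeric(0), ci_lo_kbp = numeric(0),
                      ci_hi_kbp = numeric(0)))
  do.call(rbind, recs)
}
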