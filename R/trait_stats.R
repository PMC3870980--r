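expr_values <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: each
#' rank is replaced by the mean of the per-rank values across samples, with
#' within-sample ranks preserved. Backed by \code{limma::normalizeQuantiles}.
#'
#' @param x Numeric matrix genes x samples, or an \code{expression_matrix}.
#' @return Same shape as the input (an \code{expression_matrix} is returned
#'   with its \code{values} replaced).
#' @export
quantile_normalize <- function(x) {
  v <- expr_values(x)
  if (ncol(v) < 2) stop("need at least two samples")
  if (anyNA(v)) stop("missing values present; impute before normalizing")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  if (inherits(x, "expression_matrix")) { x$values <- out; x } else out
}

#' Two-group differential expression on log2 values
#'
#' Per-gene two-sample t statistics with Benjamini-Hochberg adjustment across
#' all genes, and the design's joint filter: adjusted p below \code{alpha} and
#' absolute log2 fold-change above \code{fc_threshold}. The default test is
#' Welch's t; \code{method = "moderated"} uses limma's empirical-Bayes
#' variance shrinkage instead.
#'
#' @param x Expression matrix (genes x samples) or \code{expression_matrix}.
#' @param groupA,groupB Disjoint sample id (or column index) vectors, each of
#'   size >= 2.
#' @param alpha Adjusted-p cutoff.
#' @param fc_threshold Absolute log2 fold-change cutoff.
#' @param method \code{"welch"} (default) or \code{"moderated"}.
#' @return data.frame \code{gene}, \code{logFC} (mean A - mean B), \code{p},
#'   \code{adjPv}, \code{passes_filter}.
#' @export
differential_expression <- function(x, groupA, groupB, alpha = 0.01,
                                    fc_threshold = 0.7,
                                    method = c("welch", "moderated")) {
  method <- match.arg(method)
  v <- expr_values(x)
  if (length(intersect(groupA, groupB)) > 0) stop("groups must be disjoint")
  if (length(groupA) < 2 || length(groupB) < 2) stop("each group needs >= 2 samples")
  a <- v[, groupA, drop = FALSE]
  b <- v[, groupB, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)
  logFC <- mA - mB
  if (method == "welch") {
    vA <- rowSums((a - mA)^2) / (nA - 1)
    vB <- rowSums((b - mB)^2) / (nB - 1)
    se2 <- vA / nA + vB / nB
    tt <- logFC / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    p[se2 == 0] <- ifelse(logFC[se2 == 0] == 0, 1, 0)
  } else {
    design <- cbind(Intercept = 1,
                    A = c(rep(1, nA), rep(0, nB)))
    fit <- limma::lmFit(cbind(a, b), design)
    fit <- limma::eBayes(fit)
    p <- fit$p.value[, "A"]
  }
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = if (is.null(rownames(v))) seq_len(nrow(v)) else rownames(v),
             logFC = logFC, p = p, adjPv = adj,
             passes_filter = adj < alpha & abs(logFC) > fc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Broad-sense heritability of a trait
#'
#' H2 = 100 (Var_seg - Var_env) / Var_seg, where Var_seg is the sample
#' variance across segregant values and Var_env the pooled variance of the
#' parental replicate measurements. Negative estimates are returned as-is
#' with a warning (attribute \code{negative}).
#'
#' @param trait A list with \code{values} (segregant measurements, >= 2),
#'   \code{parent1} and \code{parent2} (replicate measurements, >= 2 each).
#' @return Heritability in percent.
#' @export
heritability <- function(trait) {
  v <- trait$values
  if (length(v) < 2) stop("need at least 2 segregant values")
  p1 <- trait$parent1; p2 <- trait$parent2
  if (length(p1) < 2 || length(p2) < 2) stop("need >= 2 replicates per parent")
  var_seg <- stats::var(v)
  if (var_seg == 0) stop("zero segregant variance: heritability undefined")
  var_env <- ((length(p1) - 1) * stats::var(p1) + (length(p2) - 1) * stats::var(p2)) /
    (length(p1) + length(p2) - 2)
  h2 <- 100 * (var_seg - var_env) / var_seg
  if (h2 < 0) {
    warning("negative heritability estimate (environmental variance exceeds segregant variance)")
    attr(h2, "negative") <- TRUE
  }
  h2
}

#' Correlate every gene's expression with a trait
#'
#' Pearson correlation per gene, a two-sided p-value from the t transform of
#' r, and Benjamini-Hochberg adjustment across genes. Zero-variance genes (or
#' a zero-variance trait) yield \code{NA}.
#'
#' @param x Expression matrix (genes x samples) or \code{expression_matrix}.
#' @param trait Numeric vector, one value per sample.
#' @return data.frame \code{gene}, \code{r}, \code{p}, \code{adjPv}.
#' @export
correlate_with_trait <- function(x, trait) {
  v <- expr_values(x)
  n <- ncol(v)
  if (length(trait) != n) stop("trait length must match sample count")
  if (n < 4) stop("need at least 4 samples")
  sds <- apply(v, 1, stats::sd)
  r <- rep(NA_real_, nrow(v))
  if (stats::sd(trait) > 0) {
    ok <- sds > 0
    r[ok] <- drop(stats::cor(t(v[ok, , drop = FALSE]), trait))
  }
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  data.frame(gene = if (is.null(rownames(v))) seq_len(nrow(v)) else rownames(v),
             r = r, p = p, adjPv = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
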