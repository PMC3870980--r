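#' Simulate heritable quantitative traits for a segregant population
#'
#' Each trait's genetic value is the sum of its planted QTL effects (marker
#' allele coded 0/1). Environmental noise variance is chosen so that the
#' expected broad-sense heritability, computed as
#' 100 (Var_seg - Var_env) / Var_seg with Var_env the pooled parental
#' replicate variance, equals \code{target_H2}. Parental replicate values are
#' drawn with the same noise variance around the pure-parent genetic values.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param truth A \code{cross_truth}; its \code{planted_qtls} slot is filled.
#' @param target_H2 Target heritability in percent, 0 <= H2 < 100.
#' @param parental_reps Replicate measurements per parent (>= 2).
#' @param n_traits Number of traits to simulate.
#' @param n_qtls Number of QTLs planted per trait (ignored when
#'   \code{qtl_loci} is given).
#' @param effect Additive effect per QTL (trait units).
#' @param qtl_loci Optional data.frame \code{chromosome}, \code{pos_kbp},
#'   \code{effect} fixing the planted loci for every trait.
#' @param seed Integer seed.
#' @return A list with \code{traits} (class \code{trait_table}: one entry per
#'   trait, each \code{list(values, parent1, parent2)} with \code{values}
#'   named by segregant id) and the updated \code{truth}.
#' @export
simulate_traits <- function(genotypes, truth, target_H2 = 90,
                            parental_reps = 4, n_traits = 1, n_qtls = 2,
                            effect = 1, qtl_loci = NULL, seed = 1L) {
  if (target_H2 < 0 || target_H2 >= 100)
    stop("target_H2 must be in [0, 100)")
  if (parental_reps < 2) stop("parental_reps must be at least 2")
  set.seed(seed)
  map <- genotypes$map
  x <- genotype_numeric(genotypes)
  x[is.na(x)] <- 0.5
  ids <- genotypes$segregant_ids

  traits <- vector("list", n_traits)
  names(traits) <- sprintf("trait%d", seq_len(n_traits))
  planted <- list()
  for (k in seq_len(n_traits)) {
    if (is.null(qtl_loci)) {
      loci <- data.frame(chromosome = sample(unique(map$chromosome), n_qtls, replace = TRUE),
                         pos_kbp = NA_real_, effect = effect)
      for (j in seq_len(n_qtls)) {
        i <- which(map$chromosome == loci$chromosome[j])
        loci$pos_kbp[j] <- map$pos_kbp[sample(i, 1)]
      }
    } else loci <- qtl_loci
    mi <- vapply(seq_len(nrow(loci)), function(j) {
      i <- which(map$chromosome == loci$chromosome[j])
      if (length(i) == 0) stop("planted QTL locus off the map")
      i[which.min(abs(map$pos_kbp[i] - loci$pos_kbp[j]))]
    }, integer(1))

    if (target_H2 == 0) {
      g <- rep(0, length(ids))
      g_p1 <- g_p2 <- 0
      env_sd <- 1
    } else {
      g <- drop(crossprod(x[mi, , drop = FALSE], loci$effect))
      g_p1 <- sum(loci$effect)   # pure P1 genotype
      g_p2 <- 0                  # pure P2 genotype
      var_g <- stats::var(g)
      if (var_g == 0) stop("planted QTLs produce no genetic variance")
      env_sd <- sqrt(var_g * (100 - target_H2) / target_H2)
    }
    traits[[k]] <- list(
      values = stats::setNames(g + stats::rnorm(length(ids), 0, env_sd), ids),
      parent1 = g_p1 + stats::rnorm(parental_reps, 0, env_sd),
      parent2 = g_p2 + stats::rnorm(parental_reps, 0, env_sd))
    planted[[k]] <- data.frame(trait = names(traits)[k],
                               chromosome = map$chromosome[mi],
                               pos_kbp = map$pos_kbp[mi],
                               effect = if (target_H2 == 0) 0 else loci$effect,
                               stringsAsFactors = FALSE)
  }
  truth$planted_qtls <- do.call(rbind, planted)
  list(traits = structure(traits, class = "trait_table"), truth = truth)
}
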