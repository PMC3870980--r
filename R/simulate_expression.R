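#' Simulate a log2 expression matrix with cis/trans eQTLs and dosage effects
#'
#' Gene coordinates are scattered uniformly across the genome (proportional to
#' chromosome length). A fraction of genes receive a cis eQTL (effect at the
#' marker nearest the gene) and a fraction a trans eQTL (effect at a random
#' marker on another chromosome). Genes inside the disomy region additionally
#' gain \code{dosage_log2} in disomic segregants (1.0 = log2 of two copies).
#' Residual variation is i.i.d. Gaussian noise.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param truth A \code{cross_truth}; the returned copy has
#'   \code{planted_eqtls} and \code{dosage_genes} filled in.
#' @param n_genes Number of genes.
#' @param cis_frac,trans_frac Fractions of genes receiving cis / trans eQTLs.
#' @param effect_size_log2 Mean log2 shift between genotype classes at a
#'   planted eQTL.
#' @param dosage_log2 Mean log2 shift of region genes in disomic segregants.
#' @param noise_sd Residual standard deviation (log2 units).
#' @param baseline_log2 Baseline expression level (log2 intensity scale).
#' @param trans_hubs Optional list of hub loci, each
#'   \code{list(chromosome=, pos_kbp=, n_targets=)}; hub targets are drawn
#'   from the trans-eQTL allocation before random trans loci are assigned.
#' @param seed Integer seed.
#' @return A list with \code{expression} (class \code{expression_matrix}:
#'   \code{values} genes x samples, \code{gene_annot} with \code{gene_id},
#'   \code{chromosome}, \code{pos_kbp}, and \code{sample_ids}) and the updated
#'   \code{truth}.
#' @export
simulate_expression <- function(genotypes, truth, n_genes = 1000,
                                cis_frac = 0.10, trans_frac = 0.05,
                                effect_size_log2 = 1.0, dosage_log2 = 1.0,
                                noise_sd = 0.25, baseline_log2 = 8,
                                trans_hubs = NULL, seed = 1L) {
  stopifnot(cis_frac >= 0, cis_frac <= 1, trans_frac >= 0, trans_frac <= 1,
            cis_frac + trans_frac <= 1, noise_sd > 0)
  set.seed(seed)
  map <- genotypes$map
  lens <- attr(map, "chrom_lengths_kbp")
  chroms <- sort(unique(map$chromosome))
  if (is.null(lens)) lens <- tapply(map$pos_kbp, map$chromosome, max)[as.character(chroms)]

  ch <- sample(chroms, n_genes, replace = TRUE, prob = lens / sum(lens))
  pos <- stats::runif(n_genes, min = 1, max = lens[match(ch, chroms)])
  gene_annot <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                           chromosome = ch, pos_kbp = pos,
                           stringsAsFactors = FALSE)

  x <- genotype_numeric(genotypes)
  x[is.na(x)] <- 0.5
  n_samp <- length(genotypes$segregant_ids)
  values <- matrix(stats::rnorm(n_genes * n_samp, mean = baseline_log2, sd = noise_sd),
                   nrow = n_genes,
                   dimnames = list(gene_annot$gene_id, genotypes$segregant_ids))

  nearest_marker <- function(chrom, kbp) {
    i <- which(map$chromosome == chrom)
    i[which.min(abs(map$pos_kbp[i] - kbp))]
  }

  n_cis <- round(cis_frac * n_genes)
  n_trans <- round(trans_frac * n_genes)
  pool <- sample(n_genes)
  cis_genes <- pool[seq_len(n_cis)]
  trans_genes <- pool[n_cis + seq_len(n_trans)]

  planted <- list()
  for (g in cis_genes) {
    mi <- nearest_marker(gene_annot$chromosome[g], gene_annot$pos_kbp[g])
    values[g, ] <- values[g, ] + effect_size_log2 * x[mi, ]
    planted[[length(planted) + 1L]] <- data.frame(
      transcript = gene_annot$gene_id[g], chromosome = map$chromosome[mi],
      pos_kbp = map$pos_kbp[mi], effect_log2 = effect_size_log2,
      type = "cis", stringsAsFactors = FALSE)
  }
  hub_targets <- integer(0)
  if (!is.null(trans_hubs)) {
    want <- vapply(trans_hubs, function(h) h$n_targets, numeric(1))
    if (sum(want) > n_trans) stop("trans hubs request more targets than trans_frac allows")
    taken <- 0
    for (h in trans_hubs) {
      mi <- nearest_marker(h$chromosome, h$pos_kbp)
      tg <- trans_genes[taken + seq_len(h$n_targets)]
      taken <- taken + h$n_targets
      for (g in tg) {
        values[g, ] <- values[g, ] + effect_size_log2 * x[mi, ]
        planted[[length(planted) + 1L]] <- data.frame(
          transcript = gene_annot$gene_id[g], chromosome = map$chromosome[mi],
          pos_kbp = map$pos_kbp[mi], effect_log2 = effect_size_log2,
          type = "trans", stringsAsFactors = FALSE)
      }
      hub_targets <- c(hub_targets, tg)
    }
  }
  for (g in setdiff(trans_genes, hub_targets)) {
    mi <- nearest_marker(sample(setdiff(chroms, gene_annot$chromosome[g]), 1),
                         stats::runif(1, 1, max(map$pos_kbp)))
    values[g, ] <- values[g, ] + effect_size_log2 * x[mi, ]
    planted[[length(planted) + 1L]] <- data.frame(
      transcript = gene_annot$gene_id[g], chromosome = map$chromosome[mi],
      pos_kbp = map$pos_kbp[mi], effect_log2 = effect_size_log2,
      type = "trans", stringsAsFactors = FALSE)
  }

  dosage_genes <- character(0)
  reg <- truth$disomy_region
  if (!is.null(reg) && dosage_log2 != 0) {
    in_reg <- gene_annot$chromosome == reg$chrom &
      gene_annot$pos_kbp >= reg$start_kbp & gene_annot$pos_kbp <= reg$end_kbp
    dosage_genes <- gene_annot$gene_id[in_reg]
    dis <- genotypes$segregant_ids %in% truth$disomic_segregants
    values[in_reg, dis] <- values[in_reg, dis] + dosage_log2
  }

  truth$planted_eqtls <- if (length(planted)) do.call(rbind, planted) else truth$planted_eqtls
  truth$dosage_genes <- dosage_genes
  expr <- structure(list(values = values, gene_annot = gene_annot,
                         sample_ids = genotypes$segregant_ids),
                    class = "expression_matrix")
  list(expression = expr, truth = truth)
}
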