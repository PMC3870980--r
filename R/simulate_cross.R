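#' Default 8-16 translocation / partial-disomy specification
#'
#' The wine parent (P1) carries a translocation that moved the left arm of
#' chromosome 16 (first 373 kbp) onto chromosome 8 near 20 kbp. Segregants
#' inheriting neither arm copy are inviable; segregants inheriting both are
#' partially disomic.
#'
#' @param chrom Chromosome bearing the duplicated arm.
#' @param start_kbp,end_kbp Arm boundaries in kbp (1-based).
#' @param partner_chrom Chromosome carrying the translocated copy in P1.
#' @param junction_kbp Position of the translocation junction on the partner
#'   chromosome, kbp.
#' @return A list with the five fields above.
#' @export
translocation_spec <- function(chrom = 16, start_kbp = 1, end_kbp = 373,
                               partner_chrom = 8, junction_kbp = 20) {
  list(chrom = chrom, start_kbp = start_kbp, end_kbp = end_kbp,
       partner_chrom = partner_chrom, junction_kbp = junction_kbp)
}

# one batch of meioses for a single chromosome: markers x n matrix of 0/1
# (1 = P1 allele), independent chromosomes, Haldane recombination between
# adjacent markers
meiosis_chromosome <- function(pos_cM, n) {
  m <- length(pos_cM)
  start <- as.integer(stats::runif(n) < 0.5)
  if (m == 1L) return(matrix(start, nrow = 1L))
  r <- haldane_r(diff(pos_cM))
  switches <- matrix(stats::runif((m - 1L) * n) < r, nrow = m - 1L)
  apply(rbind(start, switches), 2, cumsum) %% 2L
}

#' Simulate a haploid segregant population with a translocation-derived disomy
#'
#' Draws gametes from the F1 of a wine (P1) x lab (P2) cross by independent-
#' chromosome meiosis with Haldane recombination. When a translocation is
#' specified, the four junction combinations are equally likely a priori; the
#' class carrying no copy of the translocated arm is inviable and is rejected
#' and redrawn, so roughly one third of the delivered viable segregants are
#' partially disomic. Arm-resident markers report the parental origin of the
#' arm copy carried: P2 for normal segregants, P1 for translocated ones, and
#' P1 for disomic segregants (the duplicated wine-origin copy dominates the
#' array signal, which is what makes the disomy a linkage confounder).
#'
#' @param map A \code{marker_map}.
#' @param n_segregants Number of viable segregants to deliver (>= 2).
#' @param translocation A \code{\link{translocation_spec}} list, or \code{NULL}
#'   for a plain cross with no structural variant.
#' @param missing_rate Fraction of genotype calls set to \code{NA} at random.
#' @param seed Integer seed.
#' @return A list with elements \code{genotypes} (class
#'   \code{genotype_matrix}: \code{map}, \code{calls} markers x segregants in
#'   \{"P1","P2",NA\}, \code{segregant_ids}) and \code{truth} (class
#'   \code{cross_truth}: per-segregant \code{class} labels
#'   normal/translocated/disomic, \code{disomic_segregants},
#'   \code{disomy_region}, and empty \code{planted_eqtls},
#'   \code{planted_qtls}, \code{dosage_genes} slots filled by the expression
#'   and trait simulators).
#' @export
simulate_cross <- function(map, n_segregants,
                           translocation = translocation_spec(),
                           missing_rate = 0.01, seed = 1L) {
  validate_marker_map(map)
  if (n_segregants < 2) stop("n_segregants must be at least 2")
  if (!is.null(translocation) &&
      !all(c(translocation$chrom, translocation$partner_chrom) %in% map$chromosome))
    stop("translocation region must lie on mapped chromosomes")
  set.seed(seed)

  chroms <- sort(unique(map$chromosome))
  idx_by_chrom <- lapply(chroms, function(ch) which(map$chromosome == ch))
  names(idx_by_chrom) <- as.character(chroms)

  draw_batch <- function(n) {
    g <- matrix(0L, nrow = nrow(map), ncol = n)
    for (ch in chroms) {
      i <- idx_by_chrom[[as.character(ch)]]
      g[i, ] <- meiosis_chromosome(map$pos_cM[i], n)
    }
    g
  }

  if (is.null(translocation)) {
    geno <- draw_batch(n_segregants)
    cls <- rep("normal", n_segregants)
  } else {
    tr <- translocation
    arm16 <- which(map$chromosome == tr$chrom &
                   map$pos_kbp >= tr$start_kbp & map$pos_kbp <= tr$end_kbp)
    # junction-defining markers: first marker distal to the arm on the host
    # chromosome, nearest marker to the junction on the partner chromosome
    host <- which(map$chromosome == tr$chrom & map$pos_kbp > tr$end_kbp)
    if (length(host) == 0) stop("no marker distal to the arm on the host chromosome")
    j16 <- host[1]
    p8 <- which(map$chromosome == tr$partner_chrom)
    j8 <- p8[which.min(abs(map$pos_kbp[p8] - tr$junction_kbp))]

    geno <- matrix(0L, nrow = nrow(map), ncol = 0)
    cls <- character(0)
    while (ncol(geno) < n_segregants) {
      need <- n_segregants - ncol(geno)
      batch <- draw_batch(max(8L, ceiling(need * 1.6)))
      has_arm16 <- batch[j16, ] == 0L   # P2 chr16 is intact (carries the arm)
      has_arm8  <- batch[j8, ] == 1L    # P1 chr8 carries the translocated arm
      viable <- has_arm16 | has_arm8
      bcls <- ifelse(has_arm16 & has_arm8, "disomic",
                     ifelse(has_arm8, "translocated", "normal"))
      # the arm segregates as a unit attached to its junction
      if (length(arm16) > 0) {
        batch[arm16, bcls == "normal"] <- 0L
        batch[arm16, bcls != "normal"] <- 1L
      }
      geno <- cbind(geno, batch[, viable, drop = FALSE])
      cls <- c(cls, bcls[viable])
    }
    geno <- geno[, seq_len(n_segregants), drop = FALSE]
    cls <- cls[seq_len(n_segregants)]
  }

  calls <- matrix(ifelse(geno == 1L, "P1", "P2"), nrow = nrow(map))
  if (missing_rate > 0) {
    miss <- stats::runif(length(calls)) < missing_rate
    calls[miss] <- NA_character_
  }
  ids <- sprintf("seg%03d", seq_len(n_segregants))
  dimnames(calls) <- list(map$marker_id, ids)

  genotypes <- structure(list(map = map, calls = calls, segregant_ids = ids),
                         class = "genotype_matrix")
  truth <- structure(list(
    class = stats::setNames(cls, ids),
    disomic_segregants = ids[cls == "disomic"],
    disomy_region = if (is.null(translocation)) NULL else
      translocation[c("chrom", "start_kbp", "end_kbp")],
    planted_eqtls = data.frame(transcript = character(0), chromosome = integer(0),
                               pos_kbp = numeric(0), effect_log2 = numeric(0),
                               type = character(0), stringsAsFactors = FALSE),
    planted_qtls = data.frame(trait = character(0), chromosome = integer(0),
                              pos_kbp = numeric(0), effect = numeric(0),
                              stringsAsFactors = FALSE),
    dosage_genes = character(0)), class = "cross_truth")
  list(genotypes = genotypes, truth = truth)
}

#' Numeric coding of parental-origin calls
#'
#' @param genotypes A \code{genotype_matrix}.
#' @return Numeric matrix markers x segregants: 1 = P1, 0 = P2, NA = missing.
#' @export
genotype_numeric <- function(genotypes) {
  x <- matrix(NA_real_, nrow = nrow(genotypes$calls), ncol = ncol(genotypes$calls),
              dimnames = dimnames(genotypes$calls))
  x[genotypes$calls == "P1"] <- 1
  x[genotypes$calls == "P2"] <- 0
  x
}

#' Restrict a genotype matrix to a subset of segregants
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param ids Segregant ids to keep.
#' @return A \code{genotype_matrix} with the selected columns.
#' @export
subset_genotypes <- function(genotypes, ids) {
  stopifnot(all(ids %in% genotypes$segregant_ids))
  structure(list(map = genotypes$map,
                 calls = genotypes$calls[, ids, drop = FALSE],
                 segregant_ids = ids),
            class = "genotype_matrix")
}
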