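#' Scan all transcripts and collect linkage records
#'
#' Runs the Haley-Knott scan for every transcript and calls linkages at the
#' given threshold (one record per chromosome per transcript).
#'
#' @param probs A \code{genotype_probabilities}.
#' @param x An \code{expression_matrix} (samples must match the probability
#'   columns, possibly a subset).
#' @param lod_threshold LOD threshold for calling.
#' @param drop Support-interval LOD drop.
#' @return data.frame \code{transcript}, \code{gene_chrom}, \code{gene_kbp},
#'   \code{peak_chrom}, \code{peak_kbp}, \code{lod}, \code{ci_lo_kbp},
#'   \code{ci_hi_kbp}.
#' @export
scan_transcriptome <- function(probs, x, lod_threshold, drop = 1.0) {
  stopifnot(inherits(x, "expression_matrix"))
  sub <- match(colnames(probs$probs), x$sample_ids)
  if (anyNA(sub)) stop("probability columns must be a subset of expression samples")
  Y <- x$values[, sub, drop = FALSE]
  lod <- hk_scan_matrix(probs, Y)
  hit <- which(apply(lod, 2, max) >= lod_threshold)
  recs <- vector("list", length(hit))
  for (j in seq_along(hit)) {
    g <- hit[j]
    prof <- probs$grid
    prof$lod <- lod[, g]
    r <- call_linkages(prof, threshold = lod_threshold, drop = drop)
    ann <- x$gene_annot[x$gene_annot$gene_id == rownames(Y)[g], ]
    r <- cbind(transcript = rownames(Y)[g],
               gene_chrom = if (nrow(ann)) ann$chromosome else NA_integer_,
               gene_kbp = if (nrow(ann)) ann$pos_kbp else NA_real_, r)
    recs[[j]] <- r
  }
  empty <- data.frame(transcript = character(0), gene_chrom = integer(0),
                      gene_kbp = numeric(0), peak_chrom = integer(0),
                      peak_kbp = numeric(0), lod = numeric(0),
                      ci_lo_kbp = numeric(0), ci_hi_kbp = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(recs) == 0) empty else
    rbind(empty, do.call(rbind, recs))
}

#' The three-analysis disomy-bypass eQTL design
#'
#' Analysis 1: all segregants, all markers, all transcripts. Analysis 2: the
#' non-disomic segregants only. Analysis 3: all segregants, with
#' duplicated-region genotypes set missing for the disomic segregants (their
#' calls there are ambiguous) and disomy-affected transcripts excluded. Each
#' analysis is scanned at its own threshold: a fixed LOD when
#' \code{lod_threshold} is numeric, otherwise the permutation-FDR threshold
#' at \code{fdr}.
#'
#' @param x An \code{expression_matrix}.
#' @param genotypes A \code{genotype_matrix}.
#' @param disomic_ids Segregant ids carrying the partial disomy.
#' @param region \code{list(chrom, start_kbp, end_kbp)} of the duplication.
#' @param affected_genes Transcripts affected by the disomy (excluded from
#'   analysis 3), e.g. from \code{\link{disomy_affected_transcripts}}.
#' @param lod_threshold Fixed LOD threshold, or \code{NULL} for per-analysis
#'   permutation-FDR thresholds.
#' @param fdr Target transcriptome FDR when thresholds are estimated.
#' @param n_perm Permutation rounds for threshold estimation.
#' @param step_cM Pseudo-marker spacing.
#' @param seed Integer seed for the permutations.
#' @return List \code{analysis1}, \code{analysis2}, \code{analysis3} (linkage
#'   record data.frames as from \code{\link{scan_transcriptome}}) and
#'   \code{thresholds}.
#' @export
run_disomy_bypass <- function(x, genotypes, disomic_ids, region,
                              affected_genes = character(0),
                              lod_threshold = NULL, fdr = 0.10, n_perm = 20,
                              step_cM = 2.5, seed = 1L) {
  normal_ids <- setdiff(genotypes$segregant_ids, disomic_ids)
  subset_expr <- function(x, genes = NULL, samples = NULL) {
    if (!is.null(genes)) {
      keep <- x$gene_annot$gene_id %in% genes
      x$values <- x$values[keep, , drop = FALSE]
      x$gene_annot <- x$gene_annot[keep, , drop = FALSE]
    }
    x
  }
  threshold_for <- function(probs, xx, which_seed) {
    if (!is.null(lod_threshold)) return(lod_threshold)
    sub <- match(colnames(probs$probs), xx$sample_ids)
    tab <- permutation_fdr_transcriptome(
      probs, xx$values[, sub, drop = FALSE], n_perm = n_perm, seed = which_seed)
    fdr_lod_threshold(tab, target = fdr)
  }

  probs1 <- genotype_probabilities(genotypes, step_cM = step_cM)
  th1 <- threshold_for(probs1, x, seed)
  a1 <- scan_transcriptome(probs1, x, th1)

  if (length(normal_ids) == 0) {
    warning("no non-disomic segregants: analysis 2 skipped")
    a2 <- a1[0, ]; th2 <- NA_real_
  } else {
    g2 <- subset_genotypes(genotypes, normal_ids)
    probs2 <- genotype_probabilities(g2, step_cM = step_cM)
    th2 <- threshold_for(probs2, x, seed + 1L)
    a2 <- scan_transcriptome(probs2, x, th2)
  }

  g3 <- genotypes
  in_region <- g3$map$chromosome == region$chrom &
    g3$map$pos_kbp >= region$start_kbp & g3$map$pos_kbp <= region$end_kbp
  g3$calls[in_region, intersect(disomic_ids, colnames(g3$calls))] <- NA_character_
  x3 <- subset_expr(x, genes = setdiff(x$gene_annot$gene_id, affected_genes))
  probs3 <- genotype_probabilities(g3, step_cM = step_cM)
  th3 <- threshold_for(probs3, x3, seed + 2L)
  a3 <- scan_transcriptome(probs3, x3, th3)

  list(analysis1 = a1, analysis2 = a2, analysis3 = a3,
       thresholds = c(analysis1 = th1, analysis2 = th2, analysis3 = th3))
}

#' Merge the three analyses' linkage records with Venn-group labels
#'
#' Records from different analyses are merged when the transcript matches,
#' the peak chromosomes match, and the 1-LOD support intervals overlap
#' (transitively). A merged record keeps the analysis-1 peak when present,
#' else analysis-3, else analysis-2, and carries \code{venn_group}, the
#' sorted set of analyses containing it ("123"-style string).
#'
#' @param analysis1,analysis2,analysis3 Linkage record data.frames.
#' @return Unified data.frame with a \code{venn_group} column.
#' @export
venn_classify <- function(analysis1, analysis2, analysis3) {
  tag <- function(df, k) if (nrow(df)) cbind(df, analysis = k) else
    cbind(df, analysis = integer(0))
  all <- rbind(tag(analysis1, 1L), tag(analysis2, 2L), tag(analysis3, 3L))
  if (nrow(all) == 0) return(cbind(analysis1, venn_group = character(0)))
  out <- list()
  for (tr in unique(all$transcript)) {
    for (ch in unique(all$peak_chrom[all$transcript == tr])) {
      sub <- all[all$transcript == tr & all$peak_chrom == ch, , drop = FALSE]
      # transitive interval-overlap grouping along the chromosome
      o <- order(sub$ci_lo_kbp)
      sub <- sub[o, , drop = FALSE]
      grp <- integer(nrow(sub)); grp[1] <- 1L; hi <- sub$ci_hi_kbp[1]
      for (i in seq_len(nrow(sub))[-1]) {
        if (sub$ci_lo_kbp[i] <= hi) {
          grp[i] <- grp[i - 1L]
          hi <- max(hi, sub$ci_hi_kbp[i])
        } else {
          grp[i] <- grp[i - 1L] + 1L
          hi <- sub$ci_hi_kbp[i]
        }
      }
      for (g in unique(grp)) {
        m <- sub[grp == g, , drop = FALSE]
        keep <- m[order(match(m$analysis, c(1L, 3L, 2L)))[1], , drop = FALSE]
        keep$venn_group <- paste(sort(unique(m$analysis)), collapse = "")
        keep$analysis <- NULL
        out[[length(out) + 1L]] <- keep
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$peak_chrom, res$peak_kbp, res$transcript), , drop = FALSE]
}

#' Classify linkage records as cis (local) or trans (distant)
#'
#' A record is cis when the peak lies on the gene's chromosome within
#' \code{window_kbp} (strictly less than) of the annotated gene start.
#' Records with no gene annotation are classified trans with a warning.
#'
#' @param records Linkage record data.frame with \code{gene_chrom},
#'   \code{gene_kbp}, \code{peak_chrom}, \code{peak_kbp}.
#' @param window_kbp The cis window (40 kbp by convention for this design).
#' @return The records with a \code{local_flag} column ("cis"/"trans").
#' @export
classify_cis_trans <- function(records, window_kbp = 40) {
  missing_ann <- is.na(records$gene_chrom) | is.na(records$gene_kbp)
  if (any(missing_ann))
    warning(sprintf("%d record(s) lack gene annotation; classified trans", sum(missing_ann)))
  cis <- !missing_ann & records$peak_chrom == records$gene_chrom &
    abs(records$peak_kbp - records$gene_kbp) < window_kbp
  records$local_flag <- ifelse(cis, "cis", "trans")
  records
}

#' Detect trans-eQTL hotspots by Poisson binning
#'
#' Trans-eQTL peak positions are binned into \code{bin_kbp} windows per
#' chromosome. A bin is significant when its count exceeds the
#' \code{1 - alpha} quantile of Poisson(total trans eQTLs / total genome
#' bins); adjacent significant bins are merged.
#'
#' @param records Linkage records with \code{local_flag} (only
#'   \code{"trans"} rows are used; if the column is absent, all rows).
#' @param chrom_lengths_kbp Chromosome lengths in kbp (defines the bin
#'   universe).
#' @param bin_kbp Bin width.
#' @param alpha Per-bin significance level.
#' @return data.frame of class \code{hotspot_set}: \code{chrom},
#'   \code{start_kbp}, \code{end_kbp}, \code{count}, \code{members}
#'   (comma-joined transcript ids).
#' @export
detect_hotspots <- function(records, chrom_lengths_kbp = yeast_chromosome_lengths(),
                            bin_kbp = 50, alpha = 0.001) {
  if ("local_flag" %in% names(records))
    records <- records[records$local_flag == "trans", , drop = FALSE]
  empty <- data.frame(chrom = integer(0), start_kbp = numeric(0),
                      end_kbp = numeric(0), count = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(structure(empty, class = c("hotspot_set", "data.frame")))
  total_bins <- sum(ceiling(chrom_lengths_kbp / bin_kbp))
  lambda <- nrow(records) / total_bins
  cutoff <- stats::qpois(1 - alpha, lambda)

  records$bin <- floor((records$peak_kbp - 1e-9) / bin_kbp)
  out <- list()
  for (ch in sort(unique(records$peak_chrom))) {
    sub <- records[records$peak_chrom == ch, , drop = FALSE]
    counts <- table(sub$bin)
    sig <- as.integer(names(counts)[counts > cutoff])
    if (length(sig) == 0) next
    sig <- sort(sig)
    run_id <- cumsum(c(1L, diff(sig) > 1L))
    for (g in unique(run_id)) {
      bins <- sig[run_id == g]
      members <- sub$transcript[sub$bin %in% bins]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_kbp = min(bins) * bin_kbp + 1,
        end_kbp = (max(bins) + 1) * bin_kbp,
        count = length(members),
        members = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  structure(res, class = c("hotspot_set", "data.frame"))
}

#' Write eQTL and hotspot tables to deterministic, sorted TSV files
#'
#' @param records Linkage records (ideally Venn- and cis/trans-annotated).
#' @param hotspots A \code{hotspot_set} (or \code{NULL} to skip).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(records, hotspots, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, "eqtl.tsv")
  if (nrow(records) > 0)
    records <- records[order(records$peak_chrom, records$peak_kbp,
                             records$transcript), , drop = FALSE]
  utils::write.table(records, rec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- rec_path
  if (!is.null(hotspots)) {
    hs_path <- file.path(dir, "hotspots.tsv")
    if (nrow(hotspots) > 0)
      hotspots <- hotspots[order(hotspots$chrom, hotspots$start_kbp), , drop = FALSE]
    utils::write.table(hotspots, hs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, hs_path)
  }
  invisible(paths)
}
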