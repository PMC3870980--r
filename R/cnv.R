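#' Moving-average smoothing of a probe-level signal track
#'
#' Centered moving average over \code{window} probes, computed within each
#' chromosome (no cross-chromosome mixing); probes near chromosome edges use
#' the truncated window.
#'
#' @param track A \code{probe_track} data.frame (\code{chrom}, \code{pos_kbp},
#'   \code{log_signal}, probes in genome order).
#' @param window Number of probes averaged (>= 1; must not exceed the probe
#'   count of any chromosome present).
#' @return The track with \code{log_signal} replaced by the smoothed values.
#' @export
smooth_signal <- function(track, window = 200) {
  stopifnot(window >= 1)
  sig <- track$log_signal
  if (any(!is.finite(sig))) stop("signals must be finite")
  out <- numeric(length(sig))
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    n <- length(i)
    if (window > n) stop(sprintf("window (%d) exceeds probe count (%d) on chromosome %s",
                                 window, n, ch))
    cs <- cumsum(c(0, sig[i]))
    lo <- pmax(seq_len(n) - half_lo, 1L)
    hi <- pmin(seq_len(n) + half_hi, n)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  track$log_signal <- out
  track
}

#' Call segmental amplification (partial disomy) from probe log ratios
#'
#' The per-probe log ratio sample - reference is smoothed over \code{window}
#' probes; maximal runs where the smoothed ratio exceeds
#' \code{call_fraction * gain_log2} and spanning at least
#' \code{min_length_kbp} are emitted. Boundaries are refined to the half-gain
#' crossings by linear interpolation; the copy number is
#' \code{round(2^mean_ratio * base_ploidy)} from the raw (unsmoothed) mean
#' ratio over the segment.
#'
#' @param sample,reference \code{probe_track}s on an identical probe grid
#'   (same chromosomes and positions).
#' @param window Smoothing window in probes.
#' @param gain_log2 Expected log2 gain of a single extra copy.
#' @param call_fraction Fraction of \code{gain_log2} used as the run
#'   threshold.
#' @param min_length_kbp Minimum segment span to report.
#' @param base_ploidy Base ploidy of the strain (1 for haploid segregants).
#' @return data.frame \code{chrom}, \code{start_kbp}, \code{end_kbp},
#'   \code{copy_number}, \code{mean_log2_ratio} (zero rows when no call).
#' @export
call_disomy <- function(sample, reference, window = 200, gain_log2 = 1.0,
                        call_fraction = 0.5, min_length_kbp = 50,
                        base_ploidy = 1) {
  if (nrow(sample) != nrow(reference) ||
      any(sample$chrom != reference$chrom) ||
      any(abs(sample$pos_kbp - reference$pos_kbp) > 1e-9))
    stop("sample and reference must share the probe grid")
  ratio <- sample
  raw <- sample$log_signal - reference$log_signal
  ratio$log_signal <- raw
  sm <- smooth_signal(ratio, window = window)$log_signal
  th <- call_fraction * gain_log2

  calls <- list()
  for (ch in unique(sample$chrom)) {
    i <- which(sample$chrom == ch)
    pos <- sample$pos_kbp[i]
    s <- sm[i]
    above <- s > th
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      # refine boundaries to the threshold crossing between flanking probes
      start_kbp <- if (a == 1L) pos[1] else {
        w <- (th - s[a - 1L]) / (s[a] - s[a - 1L])
        pos[a - 1L] + w * (pos[a] - pos[a - 1L])
      }
      end_kbp <- if (b == length(s)) pos[length(s)] else {
        w <- (s[b] - th) / (s[b] - s[b + 1L])
        pos[b] + w * (pos[b + 1L] - pos[b])
      }
      if (end_kbp - start_kbp < min_length_kbp) next
      mean_ratio <- mean(raw[i][a:b])
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, start_kbp = start_kbp, end_kbp = end_kbp,
        copy_number = as.integer(round(2^mean_ratio * base_ploidy)),
        mean_log2_ratio = mean_ratio)
    }
  }
  if (length(calls) == 0)
    return(data.frame(chrom = integer(0), start_kbp = numeric(0),
                      end_kbp = numeric(0), copy_number = integer(0),
                      mean_log2_ratio = numeric(0)))
  do.call(rbind, calls)
}

#' Median pseudo-reference from a cohort of probe tracks
#'
#' Per-probe median across samples, for use as the euploid reference when no
#' explicit control track is available (a majority-euploid cohort assumed).
#'
#' @param tracks List of \code{probe_track}s on a shared grid.
#' @return A \code{probe_track} with the median log signal.
#' @export
pseudo_reference <- function(tracks) {
  stopifnot(length(tracks) >= 2)
  sig <- vapply(tracks, function(t) t$log_signal, numeric(nrow(tracks[[1]])))
  out <- tracks[[1]]
  out$log_signal <- apply(sig, 1, stats::median)
  out
}

#' Does a set of calls identify a segregant as disomic for a region?
#'
#' @param calls Output of \code{\link{call_disomy}} for one segregant.
#' @param region \code{list(chrom, start_kbp, end_kbp)}.
#' @param min_overlap Minimum fraction of the region a call must cover.
#' @return Logical.
#' @export
is_disomic <- function(calls, region, min_overlap = 0.5) {
  if (nrow(calls) == 0) return(FALSE)
  on_chr <- calls[calls$chrom == region$chrom, , drop = FALSE]
  if (nrow(on_chr) == 0) return(FALSE)
  ov <- pmax(0, pmin(on_chr$end_kbp, region$end_kbp) -
                 pmax(on_chr$start_kbp, region$start_kbp))
  any(ov / (region$end_kbp - region$start_kbp) >= min_overlap)
}

#' Expression consequences of a partial disomy
#'
#' Differential expression between disomic and normal segregants with
#' region-aware reporting: genes inside the called region are reported at
#' \code{alpha} (upregulated set), genes elsewhere at \code{alpha_genomewide}
#' (genome-wide deregulated set). BH adjustment is computed once across all
#' genes.
#'
#' @param x An \code{expression_matrix} (needs \code{gene_annot}).
#' @param disomic,normal Sample id vectors (>= 2 each).
#' @param region \code{list(chrom, start_kbp, end_kbp)} of the amplification.
#' @param alpha Adjusted-p cutoff for in-region genes.
#' @param alpha_genomewide Adjusted-p cutoff for genes outside the region.
#' @return List \code{inside_up} (in-region genes up in disomics),
#'   \code{deregulated} (outside-region genes at the genome-wide cutoff),
#'   \code{affected} (union, for exclusion in downstream analyses),
#'   \code{table} (the full DE table).
#' @export
disomy_affected_transcripts <- function(x, disomic, normal, region,
                                        alpha = 0.05, alpha_genomewide = 0.01) {
  stopifnot(inherits(x, "expression_matrix"))
  de <- differential_expression(x, disomic, normal, alpha = alpha,
                                fc_threshold = 0)
  ann <- x$gene_annot[match(de$gene, x$gene_annot$gene_id), ]
  inside <- ann$chromosome == region$chrom &
    ann$pos_kbp >= region$start_kbp & ann$pos_kbp <= region$end_kbp
  inside_up <- de$gene[inside & de$adjPv < alpha & de$logFC > 0]
  dereg <- de$gene[!inside & de$adjPv < alpha_genomewide]
  list(inside_up = inside_up, deregulated = dereg,
       affected = union(inside_up, dereg), table = de)
}
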