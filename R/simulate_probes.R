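#' Probe grid for array-signal simulation
#'
#' Evenly spaced probes along each chromosome, in genome order.
#'
#' @param chrom_lengths_kbp Chromosome lengths in kbp (named or unnamed;
#'   chromosome numbers are taken as \code{seq_along}).
#' @param probes_per_10kbp Probe density.
#' @return data.frame \code{probe_id}, \code{chrom}, \code{pos_kbp}.
#' @export
probe_grid <- function(chrom_lengths_kbp, probes_per_10kbp = 15) {
  stopifnot(probes_per_10kbp > 0)
  pieces <- lapply(seq_along(chrom_lengths_kbp), function(ch) {
    n <- max(1L, round(chrom_lengths_kbp[ch] * probes_per_10kbp / 10))
    pos <- seq(1, chrom_lengths_kbp[ch], length.out = n)
    data.frame(probe_id = sprintf("p%02d_%05d", ch, seq_len(n)),
               chrom = ch, pos_kbp = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Simulate one sample's probe-level log-signal track
#'
#' Baseline log signal plus Gaussian probe noise; probes inside an amplified
#' region are raised by \code{gain_log2}.
#'
#' @param grid A \code{\link{probe_grid}} data.frame.
#' @param region \code{list(chrom, start_kbp, end_kbp)} of the amplified
#'   segment, or \code{NULL} for a euploid track.
#' @param gain_log2 Log2 gain of the amplified segment (1.0 = doubling).
#' @param noise_sd Per-probe noise standard deviation.
#' @param baseline Baseline log signal.
#' @param seed Integer seed, or \code{NULL} to use the current RNG stream.
#' @return A \code{probe_track} data.frame: grid columns plus
#'   \code{log_signal}.
#' @export
simulate_probe_track <- function(grid, region = NULL, gain_log2 = 1.0,
                                 noise_sd = 0.3, baseline = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sig <- baseline + stats::rnorm(nrow(grid), 0, noise_sd)
  if (!is.null(region)) {
    i <- grid$chrom == region$chrom & grid$pos_kbp >= region$start_kbp &
      grid$pos_kbp <= region$end_kbp
    sig[i] <- sig[i] + gain_log2
  }
  out <- grid
  out$log_signal <- sig
  class(out) <- c("probe_track", "data.frame")
  out
}
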