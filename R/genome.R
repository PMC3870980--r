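#' Chromosome lengths of the S. cerevisiae nuclear genome
#'
#' Standard lengths of the 16 nuclear chromosomes in kilobase pairs, used as
#' the default genome for map and cross simulation. The total is 12,071 kbp.
#'
#' @return Named numeric vector of length 16 (names \code{"chr1"}..\code{"chr16"}),
#'   lengths in kbp.
#' @export
yeast_chromosome_lengths <- function() {
  c(chr1 = 230, chr2 = 813, chr3 = 317, chr4 = 1532, chr5 = 577,
    chr6 = 270, chr7 = 1091, chr8 = 563, chr9 = 440, chr10 = 746,
    chr11 = 667, chr12 = 1078, chr13 = 924, chr14 = 784, chr15 = 1091,
    chr16 = 948)
}

#' Genome-wide marker density
#'
#' Markers per 10 kbp over a set of chromosome lengths.
#'
#' @param n_markers Total marker count.
#' @param chrom_lengths_kbp Chromosome lengths in kbp.
#' @return Density in markers per 10 kbp.
#' @export
marker_density <- function(n_markers, chrom_lengths_kbp = yeast_chromosome_lengths()) {
  n_markers / (sum(chrom_lengths_kbp) / 10)
}

#' Haldane map function
#'
#' Recombination fraction between two loci separated by \code{d_cM}
#' centimorgans under the Haldane (no-interference) model:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM Genetic distance in centimorgans (vectorized, non-negative).
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  0.5 * (1 - exp(-2 * d_cM / 100))
}

# physical -> genetic conversion: 2.5 cM per 7.5 kbp, i.e. 3 kbp per cM
KBP_PER_CM <- 3
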