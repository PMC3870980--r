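#' Simulate a marker map for a haploid cross
#'
#' Places markers uniformly at random along each chromosome at a requested
#' average density. Genetic positions are derived from physical positions by a
#' genome-wide constant of 3 kbp per cM (2.5 cM = 7.5 kbp).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths_kbp Numeric vector of chromosome lengths in kbp
#'   (length \code{n_chrom}). Defaults to the yeast nuclear genome.
#' @param density_per_10kbp Average marker density, markers per 10 kbp.
#' @param seed Integer seed; the map is reproducible given the seed.
#' @return A \code{data.frame} of class \code{marker_map} with columns
#'   \code{marker_id}, \code{chromosome}, \code{pos_kbp}, \code{pos_cM},
#'   sorted by chromosome then position, with the chromosome lengths stored in
#'   \code{attr(, "chrom_lengths_kbp")}.
#' @export
simulate_marker_map <- function(n_chrom = 16,
                                chrom_lengths_kbp = yeast_chromosome_lengths(),
                                density_per_10kbp = 1.81,
                                seed = 1L) {
  if (length(chrom_lengths_kbp) != n_chrom)
    stop("chrom_lengths_kbp must have length n_chrom")
  if (any(chrom_lengths_kbp <= 0)) stop("chromosome lengths must be positive")
  if (density_per_10kbp <= 0) stop("density_per_10kbp must be positive")
  set.seed(seed)
  per_chrom <- pmax(1L, as.integer(round(chrom_lengths_kbp * density_per_10kbp / 10)))
  pieces <- lapply(seq_len(n_chrom), function(ch) {
    n <- per_chrom[ch]
    pos <- sort(stats::runif(n, min = 1, max = chrom_lengths_kbp[ch]))
    # enforce strictly increasing positions (ties have probability zero but
    # guard against them anyway)
    while (anyDuplicated(pos)) pos <- sort(jitter(pos, amount = 1e-6))
    data.frame(marker_id = sprintf("m%02d_%04d", ch, seq_len(n)),
               chromosome = ch, pos_kbp = pos, pos_cM = pos / KBP_PER_CM,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- map$marker_id
  attr(map, "chrom_lengths_kbp") <- unname(chrom_lengths_kbp)
  class(map) <- c("marker_map", "data.frame")
  map
}

validate_marker_map <- function(map) {
  stopifnot(all(c("marker_id", "chromosome", "pos_kbp", "pos_cM") %in% names(map)))
  for (ch in unique(map$chromosome)) {
    p <- map$pos_kbp[map$chromosome == ch]
    if (any(diff(p) <= 0)) stop("marker positions must be strictly increasing within a chromosome")
  }
  invisible(map)
}
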