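translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

is_stop_codon <- function(codon) {
  identical(translate_codon(codon), "*")
}

# Polymorphic codons are scored over the set of distinct variants (spanning
# from the lexicographically smallest one), so counts are independent of
# allele frequencies and of duplicated sequences.
#
# average (synonymous, non-synonymous) step counts over all shortest
# mutational pathways between two codons; pathways passing through a stop
# codon are excluded unless every pathway does
codon_path_counts <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  # depth-first enumeration of complete pathways (one substitution at a time)
  paths <- list()
  walk <- function(cur, remaining, syn, nonsyn, via_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1L]] <<- c(syn = syn, nonsyn = nonsyn,
                                        via_stop = as.numeric(via_stop))
      return(invisible())
    }
    for (i in remaining) {
      nxt <- cur
      substr(nxt, i, i) <- substr(b, i, i)
      step_syn <- identical(translate_codon(cur), translate_codon(nxt))
      walk(nxt, setdiff(remaining, i),
           syn + as.numeric(step_syn), nonsyn + as.numeric(!step_syn),
           via_stop || (is_stop_codon(nxt) && nxt != b))
    }
  }
  walk(a, diffs, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  keep <- m[, "via_stop"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(syn = mean(m[keep, "syn"]), nonsyn = mean(m[keep, "nonsyn"]))
}

#' Read a codon alignment from aligned multi-FASTA
#'
#' @param path Aligned FASTA file; all sequences equal length, divisible by 3.
#' @param outgroup Id (FASTA name) of the outgroup record.
#' @return List of class \code{codon_alignment}: \code{ingroup} (named
#'   character vector of sequences), \code{outgroup} (one sequence).
#' @export
read_codon_alignment <- function(path, outgroup) {
  seqs <- Biostrings::readDNAStringSet(path)
  s <- toupper(as.character(seqs))
  if (length(unique(nchar(s))) != 1) stop("sequences must be aligned (equal length)")
  if (nchar(s[1]) %% 3 != 0) stop("alignment length must be divisible by 3")
  if (!outgroup %in% names(s)) stop("outgroup id not found in the alignment")
  structure(list(ingroup = s[setdiff(names(s), outgroup)],
                 outgroup = unname(s[outgroup])),
            class = "codon_alignment")
}

#' Build a codon alignment from in-memory sequences
#'
#' @param ingroup Named character vector of aligned ingroup sequences (>= 2).
#' @param outgroup One aligned outgroup sequence.
#' @return A \code{codon_alignment}.
#' @export
codon_alignment <- function(ingroup, outgroup) {
  s <- toupper(c(ingroup, .out = outgroup))
  if (length(unique(nchar(s))) != 1) stop("sequences must be aligned (equal length)")
  if (nchar(s[1]) %% 3 != 0) stop("alignment length must be divisible by 3")
  if (length(ingroup) < 2) stop("need at least 2 ingroup sequences")
  structure(list(ingroup = toupper(ingroup), outgroup = toupper(outgroup)),
            class = "codon_alignment")
}

#' McDonald-Kreitman polymorphism and divergence counts
#'
#' Codon-by-codon: changes segregating within the ingroup contribute to
#' Pn/Ps; positions where the ingroup is monomorphic and differs from the
#' outgroup contribute to Dn/Ds. Codons containing gaps or ambiguity
#' characters are skipped, as are codons observed as stops (with a warning).
#' Codons differing at more than one position are scored by averaging the
#' synonymous/non-synonymous step counts over all shortest mutational
#' pathways. Sites both polymorphic and divergent count as polymorphic only
#' by default.
#'
#' @param aln A \code{codon_alignment}.
#' @param divergent_polymorphic \code{"polymorphic"} (default: such codons
#'   count only toward Pn/Ps) or \code{"both"}.
#' @return Named numeric vector \code{Pn}, \code{Ps}, \code{Dn}, \code{Ds}
#'   (possibly fractional from pathway averaging).
#' @export
count_poly_div <- function(aln, divergent_polymorphic = c("polymorphic", "both")) {
  divergent_polymorphic <- match.arg(divergent_polymorphic)
  stopifnot(inherits(aln, "codon_alignment"))
  n_codons <- nchar(aln$outgroup) / 3
  counts <- c(Pn = 0, Ps = 0, Dn = 0, Ds = 0)
  skipped_stop <- FALSE
  for (k in seq_len(n_codons)) {
    at <- 3 * (k - 1) + 1
    cod_in <- substr(aln$ingroup, at, at + 2)
    cod_out <- substr(aln$outgroup, at, at + 2)
    all_cods <- c(cod_in, cod_out)
    if (any(!grepl("^[ACGT]{3}$", all_cods))) next   # gap/ambiguity: skip
    if (any(vapply(unique(all_cods), is_stop_codon, logical(1)))) {
      skipped_stop <- TRUE
      next
    }
    variants <- unique(cod_in)
    if (length(variants) > 1) {
      # frequency-independent counting: changes among the distinct variants,
      # spanning from a deterministic base (so duplicated sequences cannot
      # change the counts)
      base <- sort(variants)[1]
      for (v in setdiff(variants, base)) {
        pc <- codon_path_counts(base, v)
        counts["Ps"] <- counts["Ps"] + pc["syn"]
        counts["Pn"] <- counts["Pn"] + pc["nonsyn"]
      }
      if (divergent_polymorphic == "both" && !cod_out %in% variants) {
        pc <- codon_path_counts(base, cod_out)
        counts["Ds"] <- counts["Ds"] + pc["syn"]
        counts["Dn"] <- counts["Dn"] + pc["nonsyn"]
      }
    } else if (variants != cod_out) {
      pc <- codon_path_counts(variants, cod_out)
      counts["Ds"] <- counts["Ds"] + pc["syn"]
      counts["Dn"] <- counts["Dn"] + pc["nonsyn"]
    }
  }
  if (skipped_stop) warning("stop-containing codon(s) skipped")
  counts
}

#' Neutrality index and Fisher exact significance
#'
#' NI = (Pn/Ps) / (Dn/Ds). The p-value is the two-sided Fisher exact test on
#' the 2x2 table [[Pn, Ps], [Dn, Ds]] (counts rounded to integers, as
#' pathway averaging can produce fractions). NI > 1 is consistent with
#' segregating slightly deleterious or balanced variation, NI < 1 with
#' adaptive divergence.
#'
#' @param counts Named vector with \code{Pn}, \code{Ps}, \code{Dn},
#'   \code{Ds}.
#' @return List \code{NI} (NA when Ps = 0 or Dn = 0), \code{p_value} (NA when
#'   the table is degenerate), \code{interpretation}.
#' @export
neutrality_index <- function(counts) {
  pn <- counts[["Pn"]]; ps <- counts[["Ps"]]
  dn <- counts[["Dn"]]; ds <- counts[["Ds"]]
  if (any(c(pn, ps, dn, ds) < 0)) stop("counts must be non-negative")
  ni <- if (ps > 0 && dn > 0) (pn / ps) / (dn / ds) else NA_real_
  tab <- round(matrix(c(pn, ps, dn, ds), nrow = 2, byrow = TRUE))
  p <- if (any(tab > 0)) stats::fisher.test(tab)$p.value else NA_real_
  interp <- if (is.na(ni)) "undefined" else if (ni > 1)
    "excess polymorphism (negative/balancing selection)" else if (ni < 1)
    "excess divergence (positive selection)" else "neutral expectation"
  list(NI = unname(ni), p_value = unname(p), interpretation = interp)
}
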