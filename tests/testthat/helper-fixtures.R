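# shared fixtures, built once per test run

# hand-built map/genotypes for exact-value tests
make_map <- function(chromosome, pos_kbp) {
  chromosome <- rep(chromosome, length.out = length(pos_kbp))
  map <- data.frame(marker_id = sprintf("m%03d", seq_along(pos_kbp)),
                    chromosome = chromosome, pos_kbp = pos_kbp,
                    pos_cM = pos_kbp / 3, stringsAsFactors = FALSE)
  rownames(map) <- map$marker_id
  attr(map, "chrom_lengths_kbp") <- as.numeric(tapply(pos_kbp, chromosome, max))
  class(map) <- c("marker_map", "data.frame")
  map
}

make_genotypes <- function(map, calls) {
  dimnames(calls) <- list(map$marker_id, sprintf("s%03d", seq_len(ncol(calls))))
  structure(list(map = map, calls = calls, segregant_ids = colnames(calls)),
            class = "genotype_matrix")
}

make_expression <- function(values, chromosome, pos_kbp) {
  ids <- sprintf("g%04d", seq_len(nrow(values)))
  rownames(values) <- ids
  structure(list(values = values,
                 gene_annot = data.frame(gene_id = ids, chromosome = chromosome,
                                         pos_kbp = pos_kbp, stringsAsFactors = FALSE),
                 sample_ids = colnames(values)),
            class = "expression_matrix")
}

# memoized study-scale population (full map, 44 segregants)
.fixture_env <- new.env()
study_population <- function() {
  if (is.null(.fixture_env$pop)) {
    map <- simulate_marker_map(seed = 101)
    .fixture_env$pop <- simulate_cross(map, 44, seed = 202)
  }
  .fixture_env$pop
}

# brute-force oracle for codon pathway counting: enumerate every permutation
# of the differing positions, drop stop-passing paths unless all pass stops
oracle_path_counts <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  paths <- list()
  for (ord in perms(diffs)) {
    cur <- a; steps <- c(syn = 0, nonsyn = 0); via_stop <- FALSE
    for (i in ord) {
      nxt <- cur
      substr(nxt, i, i) <- substr(b, i, i)
      if (code[[cur]] == code[[nxt]]) steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
      if (code[[nxt]] == "*" && nxt != b) via_stop <- TRUE
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- list(steps = steps, via_stop = via_stop)
  }
  ok <- !vapply(paths, `[[`, logical(1), "via_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  kept <- vapply(paths[ok], `[[`, numeric(2), "steps")
  rowMeans(matrix(kept, nrow = 2, dimnames = list(c("syn", "nonsyn"), NULL)))
}

# brute-force MK oracle: per-codon enumeration over the same counting rules
oracle_count_poly_div <- function(aln) {
  code <- Biostrings::GENETIC_CODE
  n_codons <- nchar(aln$outgroup) / 3
  counts <- c(Pn = 0, Ps = 0, Dn = 0, Ds = 0)
  for (k in seq_len(n_codons)) {
    at <- 3 * (k - 1) + 1
    ci <- substr(aln$ingroup, at, at + 2)
    co <- substr(aln$outgroup, at, at + 2)
    if (any(!grepl("^[ACGT]{3}$", c(ci, co)))) next
    if (any(code[unique(c(ci, co))] == "*")) next
    u <- unique(ci)
    if (length(u) > 1) {
      base <- sort(u)[1]
      for (v in setdiff(u, base)) {
        pc <- oracle_path_counts(base, v)
        counts["Ps"] <- counts["Ps"] + pc["syn"]
        counts["Pn"] <- counts["Pn"] + pc["nonsyn"]
      }
    } else if (u != co) {
      pc <- oracle_path_counts(u, co)
      counts["Ds"] <- counts["Ds"] + pc["syn"]
      counts["Dn"] <- counts["Dn"] + pc["nonsyn"]
    }
  }
  counts
}

# random stop-free codon alignment for MK property tests
random_alignment <- function(n_codons, n_ingroup, mut_rate, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  repeat {
    root <- paste(sample(bases, 3 * n_codons, replace = TRUE), collapse = "")
    if (!any(Biostrings::GENETIC_CODE[substring(root, seq(1, nchar(root), 3),
                                                seq(3, nchar(root), 3))] == "*")) break
  }
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in sample(length(v), min(k, length(v))))
      v[i] <- sample(setdiff(bases, v[i]), 1)
    paste(v, collapse = "")
  }
  ing <- vapply(seq_len(n_ingroup),
                function(i) mutate(root, stats::rpois(1, mut_rate * n_codons)),
                character(1))
  names(ing) <- sprintf("in%d", seq_len(n_ingroup))
  out <- mutate(root, stats::rpois(1, 3 * mut_rate * n_codons))
  codon_alignment(ing, out)
}

# explicit least-squares LOD oracle for a single locus
lod_ols_oracle <- function(x, y) {
  fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}
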