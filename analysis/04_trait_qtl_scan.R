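#!/usr/bin/env Rscript
# Phenotypic QTL scans: Haley-Knott regression on the 2.5-cM pseudo-marker
# grid for each simulated trait, with a 1000-permutation genome-wide LOD
# threshold at 0.05 and 1-LOD support intervals.
# Requires 01_simulate_population.R.

suppressMessages(library(wineQTL))
src <- "results/simulated"
out <- "results/trait_qtl"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

map <- read_marker_map(file.path(src, "marker_map.tsv"))
g <- read_genotypes(file.path(src, "genotypes.tsv"), map)
traits <- read_traits(file.path(src, "traits.tsv"))
probs <- genotype_probabilities(g, step_cM = 2.5)

records <- list()
for (nm in names(traits)) {
  y <- traits[[nm]]$values[g$segregant_ids]
  th <- permutation_threshold_trait(probs, y, n_perm = 1000, fdr = 0.05,
                                    seed = 17)
  prof <- hk_scan(probs, y)
  recs <- call_linkages(prof, threshold = th, drop = 1.0)
  cat(sprintf("%s: threshold %.2f, %d QTL(s)\n", nm, th, nrow(recs)))
  if (nrow(recs)) {
    recs <- cbind(trait = nm, recs, threshold = as.numeric(th))
    print(recs[, c("trait", "peak_chrom", "peak_kbp", "lod",
                   "ci_lo_kbp", "ci_hi_kbp")], row.names = FALSE)
    records[[nm]] <- recs
  }
  utils::write.table(cbind(trait = nm, prof),
                     file.path(out, sprintf("lod_profile_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
if (length(records))
  utils::write.table(do.call(rbind, records), file.path(out, "trait_qtls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
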