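#!/usr/bin/env Rscript
# Simulate the reference population: a 2,186-marker map over the 16 yeast
# chromosomes, a 44-segregant haploid cross segregating the 8-16
# translocation (so ~1/3 of viable spores carry the 373-kbp partial disomy
# of the chromosome 16 left arm), a transcriptome with cis/trans eQTLs and
# dosage effects, fermentation-like traits, and probe-level array tracks.
# Writes all tables under results/simulated/.

suppressMessages(library(wineQTL))
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

map <- simulate_marker_map(seed = seed)
cat(sprintf("map: %d markers, %.2f per 10 kbp\n", nrow(map),
            marker_density(nrow(map))))
write_marker_map(map, file.path(out, "marker_map.tsv"))

pop <- simulate_cross(map, n_segregants = 44, seed = seed + 1)
cat("segregant classes:\n")
print(table(pop$truth$class))
write_genotypes(pop$genotypes, file.path(out, "genotypes.tsv"))

sim <- simulate_expression(pop$genotypes, pop$truth, n_genes = 1000,
                           cis_frac = 0.10, trans_frac = 0.05,
                           effect_size_log2 = 1.0, dosage_log2 = 1.0,
                           noise_sd = 0.25,
                           trans_hubs = list(list(chromosome = 14, pos_kbp = 456,
                                                  n_targets = 30)),
                           seed = seed + 2)
cat(sprintf("expression: %d genes, %d planted eQTLs, %d dosage genes\n",
            nrow(sim$expression$values), nrow(sim$truth$planted_eqtls),
            length(sim$truth$dosage_genes)))
write_expression(sim$expression, file.path(out, "expression.tsv"))
utils::write.table(sim$truth$planted_eqtls, file.path(out, "planted_eqtls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tr <- simulate_traits(pop$genotypes, sim$truth, target_H2 = 90,
                      n_traits = 3, seed = seed + 3)
write_traits(tr$traits, file.path(out, "traits.tsv"))

# probe tracks for chromosome 16 (the disomic arm) plus a euploid reference
gr <- probe_grid(yeast_chromosome_lengths()["chr16"], probes_per_10kbp = 15)
gr$chrom <- 16
set.seed(seed + 4)
reg <- sim$truth$disomy_region
for (id in pop$genotypes$segregant_ids) {
  is_d <- id %in% pop$truth$disomic_segregants
  track <- simulate_probe_track(gr, region = if (is_d) reg else NULL,
                                gain_log2 = 1, noise_sd = 0.3)
  write_probe_track(track, file.path(out, sprintf("probes_%s.tsv", id)))
}
ref <- simulate_probe_track(gr, region = NULL, noise_sd = 0.3)
write_probe_track(ref, file.path(out, "probes_reference.tsv"))
writeLines(pop$truth$disomic_segregants, file.path(out, "true_disomic_ids.txt"))
cat("wrote", out, "\n")
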