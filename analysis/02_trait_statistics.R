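#!/usr/bin/env Rscript
# Expression and trait statistics on the simulated population: quantile
# normalization, parental-style differential expression, heritability of the
# simulated traits, trait-expression correlation, and clustering with a
# permutation-derived correlation cutoff. Requires 01_simulate_population.R.

suppressMessages(library(wineQTL))
src <- "results/simulated"
out <- "results/trait_stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr <- read_expression(file.path(src, "expression.tsv"))
expr <- quantile_normalize(expr)
traits <- read_traits(file.path(src, "traits.tsv"))
disomic <- readLines(file.path(src, "true_disomic_ids.txt"))
normal <- setdiff(expr$sample_ids, disomic)

# disomic vs normal contrast (the canonical 13-vs-31 comparison for this design)
de <- differential_expression(expr, disomic, normal, alpha = 0.01,
                              fc_threshold = 0.7)
cat(sprintf("differential expression: %d/%d genes pass adjPv<0.01 & |logFC|>0.7\n",
            sum(de$passes_filter), nrow(de)))
utils::write.table(de, file.path(out, "de_disomic_vs_normal.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# heritability of each simulated trait
h2 <- vapply(traits, function(t) suppressWarnings(heritability(t)), numeric(1))
cat("heritability (%):\n"); print(round(h2, 1))
utils::write.table(data.frame(trait = names(h2), H2 = h2),
                   file.path(out, "heritability.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# correlation of every transcript with the first trait
co <- correlate_with_trait(expr, traits[[1]]$values[expr$sample_ids])
cat(sprintf("trait correlation: %d transcripts at adjPv<0.05\n",
            sum(co$adjPv < 0.05, na.rm = TRUE)))
utils::write.table(co, file.path(out, "trait_correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# clustering with permutation-calibrated all-pairwise cutoff
cl <- cluster_genes(expr, n_permutations = 10, seed = 5)
cat(sprintf("clustering: cutoff r = %.2f, %d clusters of size >= 2\n",
            cl$threshold_r, length(cl$clusters)))
sizes <- vapply(cl$clusters, length, numeric(1))
utils::write.table(
  data.frame(cluster = rep(seq_along(cl$clusters), sizes),
             gene = unlist(cl$clusters)),
  file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

# kinetic-trait extraction on a synthetic logistic fermentation curve
t_h <- seq(0, 120, by = 1 / 3)             # one weighing every 20 min
set.seed(9)
curve <- 94.3 / (1 + exp(-0.12 * (t_h - 40))) + rnorm(length(t_h), 0, 0.2)
kin <- extract_kinetics(t_h, curve, smooth_window = 31)
cat(sprintf("kinetics: Rmax %.2f g/l/h, R70 %.2f g/l/h (at %.0f g/l), lag %.1f h\n",
            kin$Rmax, kin$R70, 0.7 * kin$total_CO2, kin$lag_time))
utils::write.table(as.data.frame(kin), file.path(out, "kinetics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
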