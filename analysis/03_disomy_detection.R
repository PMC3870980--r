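#!/usr/bin/env Rscript
# Detect the partial disomy from probe-level array signals: smooth each
# segregant's chromosome 16 log ratio against the euploid reference over 200
# probes, call amplified segments, and classify segregants. Compares the
# calls to the simulated truth. Requires 01_simulate_population.R.

suppressMessages(library(wineQTL))
src <- "results/simulated"
out <- "results/disomy"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

map <- read_marker_map(file.path(src, "marker_map.tsv"))
g <- read_genotypes(file.path(src, "genotypes.tsv"), map)
truth_ids <- readLines(file.path(src, "true_disomic_ids.txt"))
ref <- read_probe_track(file.path(src, "probes_reference.tsv"))
reg <- translocation_spec()[c("chrom", "start_kbp", "end_kbp")]

calls <- lapply(g$segregant_ids, function(id) {
  track <- read_probe_track(file.path(src, sprintf("probes_%s.tsv", id)))
  cd <- call_disomy(track, ref, window = 200, gain_log2 = 1)
  if (nrow(cd)) cd$segregant <- id
  cd
})
all_calls <- do.call(rbind, calls[vapply(calls, nrow, numeric(1)) > 0])
called_dis <- vapply(calls, function(cd) is_disomic(cd, reg), logical(1))
names(called_dis) <- g$segregant_ids

cat(sprintf("called %d/%d segregants disomic; truth has %d\n",
            sum(called_dis), length(called_dis), length(truth_ids)))
cat(sprintf("classification agreement with truth: %d/%d\n",
            sum(called_dis == (g$segregant_ids %in% truth_ids)),
            length(called_dis)))
if (!is.null(all_calls)) {
  cat(sprintf("mean called boundaries: %.1f - %.1f kbp (truth %d - %d)\n",
              mean(all_calls$start_kbp), mean(all_calls$end_kbp),
              reg$start_kbp, reg$end_kbp))
  utils::write.table(
    all_calls[, c("chrom", "start_kbp", "end_kbp", "segregant",
                  "copy_number", "mean_log2_ratio")],
    file.path(out, "disomy_calls.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
}
writeLines(names(called_dis)[called_dis], file.path(out, "called_disomic_ids.txt"))

# expression consequences: in-region dosage response and genome-wide ripple
expr <- quantile_normalize(read_expression(file.path(src, "expression.tsv")))
dis <- names(called_dis)[called_dis]
nor <- setdiff(expr$sample_ids, dis)
aff <- disomy_affected_transcripts(expr, dis, nor, reg)
cat(sprintf("in-region genes up in disomics (adjPv<0.05): %d\n",
            length(aff$inside_up)))
cat(sprintf("genes deregulated elsewhere (adjPv<0.01): %d\n",
            length(aff$deregulated)))
writeLines(aff$affected, file.path(out, "disomy_affected_genes.txt"))
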