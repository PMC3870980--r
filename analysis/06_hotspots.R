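#!/usr/bin/env Rscript
# Trans-eQTL hotspot detection on the merged eQTL set: peak positions are
# binned into 50-kbp windows and bins exceeding the Poisson 1-alpha quantile
# are reported (adjacent significant bins merged). Requires 05.

suppressMessages(library(wineQTL))
out <- "results/eqtl"
merged <- utils::read.table(file.path(out, "eqtl.tsv"), header = TRUE,
                            sep = "\t", colClasses = c(venn_group = "character"),
                            stringsAsFactors = FALSE)
cat(sprintf("input: %d eQTLs (%d trans)\n", nrow(merged),
            sum(merged$local_flag == "trans")))
hs <- detect_hotspots(merged, bin_kbp = 50, alpha = 0.001)
if (nrow(hs)) {
  cat(sprintf("%d hotspot(s):\n", nrow(hs)))
  print(hs[, c("chrom", "start_kbp", "end_kbp", "count")], row.names = FALSE)
} else cat("no hotspots detected\n")
write_results(merged, hs, out)
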