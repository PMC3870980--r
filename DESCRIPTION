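Package: wineQTL
Title: Genetical Genomics of a Wine Yeast Segregant Population with Partial Disomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis toolkit for eQTL mapping in a haploid yeast
    cross segregating a translocation-derived partial disomy. Provides a
    synthetic-cross generator (Haldane meiosis, viability selection, dosage
    effects), expression and fermentation-trait statistics (quantile
    normalization, differential expression, heritability, kinetic-trait
    extraction, permutation-thresholded clustering), aneuploidy detection from
    probe-level array signals, Haley-Knott interval-mapping genome scans with
    permutation false-discovery-rate control, the three-analysis disomy-bypass
    design with Venn classification, cis/trans annotation and trans-eQTL hotspot
    detection, and McDonald-Kreitman neutrality testing on codon alignments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    signal,
    Biostrings
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
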