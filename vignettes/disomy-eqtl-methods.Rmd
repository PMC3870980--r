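---
title: "Methods: eQTL mapping in a haploid wine-yeast cross with partial disomy"
author: "wineQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping in a haploid wine-yeast cross with partial disomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Wine yeasts commonly carry a reciprocal 8–16 translocation that places the
sulfite exporter *SSU1* under a stronger promoter. When such a strain is
crossed to a laboratory strain, a spore can co-inherit the translocated
chromosome 8 (which carries a copy of the chromosome 16 left arm) together
with an intact chromosome 16. That spore is haploid everywhere except for
the ~373-kbp left arm of chromosome 16, which it carries twice — a *partial
disomy*. A spore inheriting neither copy of the arm is inviable because the
arm carries essential genes. The four junction combinations are equally
likely at meiosis, so among viable spores roughly one third are disomic.

The disomy matters for genetical genomics: the duplicated genes are
expressed at roughly double dose, the dosage ripples into trans effects,
and markers on the arm are ambiguous for disomic segregants. Left
untreated, this contaminates an eQTL scan with spurious linkages.
`wineQTL` implements the full analysis chain for this situation:
simulation of the cross, expression/trait statistics, aneuploidy detection
from array signals, Haley–Knott interval mapping with permutation FDR, a
three-analysis design that bypasses the disomy, hotspot detection, and a
McDonald–Kreitman neutrality test for candidate regulator genes.

Everything is exercised on simulated data; the package downloads nothing.

# The synthetic cross

`simulate_marker_map()` places markers uniformly at an average density of
1.81 markers per 10 kbp (the density of a 2,140 + 46 marker yeast map)
over the 16 yeast chromosomes (12,071 kbp total), giving ~2,186 markers.
Physical and genetic coordinates are linked by a genome-wide constant of
3 kbp/cM, the only conversion the design states (2.5 cM = 7.5 kbp). A
chromosome-specific recombination map would be more realistic but is not
identifiable from the design; the constant is used throughout.

`simulate_cross()` draws gametes by independent-chromosome meiosis under
the Haldane map function, r = (1 − e^(−2d/100))/2, i.e. no crossover
interference. No meiosis model is implied by the interval-mapping method
itself; Haldane is chosen because it is the assumption under which the
Haley–Knott conditional probabilities are exact. Viability selection is
implemented by rejection: spores with no copy of the translocated arm are
redrawn, so the requested population size is always delivered, mirroring
the fact that only viable spores are ever genotyped. Arm-resident markers
report the parental origin of the arm copy actually carried (P2 for
normal, P1 for translocated segregants); for disomic segregants, which
carry both, the calls are set to P1 — the model's stand-in for the
ambiguous mixed hybridization signal of a duplicated region, and the
mechanism that makes the disomy a linkage confounder. Missing calls are
injected at 1% to exercise the genotype-probability code.

Two consequences worth knowing:

* Allele frequencies are 1/2 at all markers *except* those linked to either
  translocation junction. Viability selection removes one of the four
  junction combinations, so both the chromosome 16 arm and the chromosome 8
  junction region settle near 2/3 wine-parent alleles. This is a property
  of the biology, not an artifact.
* Because disomy is the *conjunction* of two junction genotypes, no single
  marker can correlate with disomy status beyond r = 0.5 in this model. A
  pure-dosage spurious linkage is therefore capped near LOD 2.75 at 44
  segregants — real arrays, with their messier call behavior in duplicated
  regions, can do "better". The disomy-bypass property simulations in the
  tests use 120 segregants so the confounded linkage clears the conventional
  LOD-4 operating point; what is asserted is the structural property
  (present in analysis 1, absent in analyses 2 and 3), which does not
  depend on the population size used to expose it.

`simulate_expression()` plants cis eQTLs (effect at the marker nearest the
gene), trans eQTLs (random distant marker, optionally concentrated in
hubs), a dosage effect of +1 log2 unit for duplicated-region genes in
disomic segregants, and i.i.d. Gaussian noise (default sd 0.25 log2
units, a typical residual scale for yeast arrays). `simulate_traits()`
builds trait values as the sum of planted QTL effects plus noise whose
variance is solved from the target heritability,
Var_env = Var_gen (100 − H²)/H², and draws parental replicates (default
four per parent, the usual parental phenotyping depth) with the same noise.

What the generator does *not* emulate: array-specific intensity artifacts,
correlated (batch) noise, segregation distortion beyond the translocation,
chromosome-specific recombination rates, and the horizontally transferred
regions of the wine parent. Tests passing on this generator therefore
certify the statistical machinery, not robustness to array pathology.

# Expression and trait statistics

Quantile normalization equalizes the per-sample distributions (via limma's
implementation). Differential expression defaults to Welch's t per gene on
log2 values with Benjamini–Hochberg adjustment and the joint
filter (adjPv < 0.01 and |logFC| > 0.7); the unspecified "modified t-test"
is additionally available as a variance-moderated mode (limma's
empirical-Bayes shrinkage) for small-replicate designs.

Heritability is H² = 100 (Var_seg − Var_env)/Var_seg, with Var_env the
pooled variance of the parental replicates. Negative estimates are
returned as-is with a warning rather than clipped: a negative value is
diagnostic (environmental variance exceeding among-segregant variance)
and clipping would hide it. Note the estimator is noisy when the parental
replication is small — with 4 + 4 replicates the pooled variance has six
degrees of freedom, so single-trait estimates at low true H² scatter
widely; recovery checks average many traits. Traits with H² below 50% are
conventionally discarded in this design; 50% is treated as a lower bound here.

Kinetic traits come from cumulative CO2 curves sampled every 20 minutes:
the curve is resampled to a uniform grid, smoothed with a Savitzky–Golay
local polynomial (default window 11 points, degree 3 — "polynomial
smoothing" with the window left configurable since no width is stated),
and differentiated. Rmax is the maximal rate; R70 the rate where the curve
crosses 70% of its total release (66 g/l of ~94 g/l); the lag ends when
the rate first exceeds 5% of Rmax (an unstated threshold, chosen so that a
linear curve has zero lag).

Clustering uses centered-Pearson distance (1 − r) with complete linkage,
cut at height 1 − r* so every reported cluster satisfies the all-pairwise
rule. The cutoff r* is calibrated by permuting each gene independently
across samples (ten rounds by default) and taking the smallest grid value
at which fewer than three chance clusters of size ≥ 2 are expected —
per-gene permutation is used because the null being rejected is
correlation between genes, not structure within a gene. On 44-sample data
the calibrated cutoff lands in the 0.6–0.9 range depending on gene count,
bracketing the 0.84 conventionally quoted for 44-sample yeast panels.

# Aneuploidy detection from probe signals

`smooth_signal()` is a centered moving average over 200 probes (the
default window), computed within chromosomes, with the window truncated at
chromosome ends — centering and edge policy are unstated, and truncation
was preferred over padding because it keeps the estimator unbiased for a
locally constant signal. `call_disomy()` smooths the per-probe log ratio
against a euploid reference, takes maximal runs above half the expected
gain, refines boundaries to the half-gain crossings by linear
interpolation, and reports segments of at least 50 kbp (an unstated floor
that suppresses noise runs; at 15 probes/10 kbp and noise sd 0.3 the
false-call rate is below 1%). Copy number is round(2^ratio × base ploidy)
with a haploid base for segregants. When no euploid control is available,
`pseudo_reference()` uses the per-probe median of the cohort, valid while
a minority of samples are aneuploid at any locus.

At the design scale (373-kbp gain, ratio 1.0, probe noise 0.3) boundary
recovery is accurate to a few kbp and classification against the
simulated truth is exact.

# Haley–Knott scans and permutation FDR

`genotype_probabilities()` builds the scan grid — every marker plus
pseudo-markers every 2.5 cM — and computes P(wine allele) per segregant
conditional on the nearest non-missing flanking markers under Haldane;
at a typed marker the probability is exactly 0 or 1. `hk_scan()`
regresses the trait on these probabilities at each locus;
LOD = (n/2) log10(RSS0/RSS1). Perfect fits (possible in small haploid
panels) are capped via RSS1 ≥ 10^−12 RSS0. Ties at the peak resolve to
the leftmost locus, and the 1-LOD support interval is the contiguous
region within one LOD of the peak. One linkage per chromosome per trait
is reported; multi-peak splitting is out of scope.

Trait thresholds use 1,000 permutations of the trait vector (genotypes
fixed) and the 95th percentile of the genome-wide maximum LOD.
Transcriptome FDR uses 20 permutations, each applying *one shared shuffle*
of the sample labels to the whole matrix, preserving transcript–transcript
correlation — the conservative choice where the design is silent — and
FDR(t) = mean null count / observed count of transcripts with max LOD ≥ t,
clipped to [0, 1], with transcripts (not records) as the counting unit.

# The three-analysis disomy bypass

* Analysis 1: all segregants, all markers, all transcripts.
* Analysis 2: non-disomic segregants only — removes the confounder along
  with a third of the detection power.
* Analysis 3: all segregants, but duplicated-region genotypes are set
  missing *for the disomic segregants only* (their calls there are
  ambiguous; the normals' calls are valid, so blanket marker removal would
  discard clean information), and disomy-affected transcripts are
  excluded.

Records from the three analyses are merged when the transcript matches,
the peak chromosomes match, and the 1-LOD intervals overlap — interval
overlap rather than exact peak equality, because the pseudo-marker grids
differ when the segregant subset differs. The merged record keeps the
analysis-1 peak when present (largest population), else analysis-3, else
analysis-2, and carries the Venn label ("123"-style). Deduplication is by
transcript × locus, so a transcript with two distinct loci contributes two
records. eQTLs within 40 kbp of the gene on the same chromosome (strict
inequality, gene annotated start, 1-based kbp) are "cis"/local.

Hotspots are called on trans eQTLs only: peaks are binned into 50-kbp
windows and a bin is significant when its count exceeds the 1 − α quantile
(α = 0.001) of Poisson(total trans / total bins); adjacent significant
bins merge. The rule is this package's own — hotspot reports in this field rarely state
a detection threshold — and the Poisson null is the
natural "no co-localization" reference. It is deliberately conservative:
the hub itself inflates the genome-wide rate and hence the cutoff.

# McDonald–Kreitman test

`count_poly_div()` walks the codon alignment: changes segregating within
the ingroup add to Pn/Ps, codons where the ingroup is monomorphic and
differs from the outgroup add to Dn/Ds. Codons with gaps, ambiguity codes,
or observed stops are skipped. Codons differing at multiple positions are
scored by averaging the synonymous/non-synonymous step counts over all
shortest mutational pathways, excluding pathways through stop codons
unless all of them pass one. Polymorphism is counted over the set of
*distinct* variants (spanning from the lexicographically smallest), so the
counts are invariant to allele frequencies and to duplicated sequences.
Sites both polymorphic and divergent count as polymorphic only (the
ingroup is not fixed there); a switch restores double counting. Pathway
averaging can give fractional counts, so the 2×2 table is rounded for the
Fisher exact test while NI = (Pn/Ps)/(Dn/Ds) uses the raw values. The
NI of a real regulator gene depends on the exact allele set used; the bundled
alignment (`inst/extdata/synthetic_tf_alignment.fasta`) is synthetic,
generated with polymorphism biased toward non-synonymous sites to show the
same qualitative signature (NI ≈ 3.4, p < 0.01).

# Problem sizes used in the tests and acceptance script

The test-suite and `scripts/acceptance.R` run, per check: the full-genome
map (~2,186 markers, ~3,760 grid loci); 20 replicates of a null
44-segregant, 1,000-transcript transcriptome with 20 permutations each for
the FDR calibration; 100 replicates of a 44-track disomy-calling cohort;
one 120-segregant, 400-gene bypass simulation; 1,000 replicates × 25
traits at 200 segregants per heritability target; 200 random 30-codon
alignments against the brute-force oracle plus 500 neutral 100-codon
genes; and one 1,001-eQTL hotspot instance. These sizes keep every
statistical check well-powered while completing on a single CPU in a few
minutes each.

# Known limitations

* Single-QTL scans only; no composite interval mapping or epistasis.
* One linkage per chromosome per transcript.
* The CNV caller is a run-threshold method, not an HMM or circular binary
  segmentation; breakpoints are probe-resolution.
* The meiosis model has no interference and a constant physical↔genetic
  conversion.
* The MK module handles the standard nuclear code and a single outgroup;
  no polarization, no adaptive-substitution (alpha) estimators.
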