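rec <- function(transcript, peak_chrom, peak_kbp, lod = 5,
                ci_lo = peak_kbp - 20, ci_hi = peak_kbp + 20,
                gene_chrom = peak_chrom, gene_kbp = peak_kbp) {
  data.frame(transcript = transcript, gene_chrom = gene_chrom,
             gene_kbp = gene_kbp, peak_chrom = peak_chrom, peak_kbp = peak_kbp,
             lod = lod, ci_lo_kbp = ci_lo, ci_hi_kbp = ci_hi,
             stringsAsFactors = FALSE)
}

test_that("Venn classification merges by transcript, chromosome and interval overlap", {
  e1 <- rec("t1", 2, 100); e2 <- rec("t2", 3, 50); e3 <- rec("t3", 5, 400)
  a <- rbind(e1, e2); b <- e1; c <- rbind(e1, e3)
  v <- venn_classify(a, b, c)
  expect_equal(sort(v$venn_group[match(c("t1", "t2", "t3"), v$transcript)]),
               sort(c("123", "1", "3")))

  # same transcript, non-overlapping intervals: kept distinct
  d1 <- rec("t1", 2, 100, ci_lo = 90, ci_hi = 110)
  d2 <- rec("t1", 2, 300, ci_lo = 290, ci_hi = 310)
  v2 <- venn_classify(d1, d2, d1[0, ])
  expect_equal(nrow(v2), 2)
  expect_setequal(v2$venn_group, c("1", "2"))

  # three identical sets: all "123", union size preserved
  s <- rbind(e1, e2, e3)
  v3 <- venn_classify(s, s, s)
  expect_equal(nrow(v3), 3)
  expect_true(all(v3$venn_group == "123"))

  # merged record keeps the analysis-1 peak when present, else analysis-3
  shift <- rec("t1", 2, 110, ci_lo = 95, ci_hi = 125)
  v4 <- venn_classify(e1, shift, shift)
  expect_equal(v4$peak_kbp, 100)
  v5 <- venn_classify(e1[0, ], shift, rec("t1", 2, 105, ci_lo = 95, ci_hi = 120))
  expect_equal(v5$peak_kbp, 105)
})

test_that("cis/trans classification applies the strict 40-kbp same-chromosome rule", {
  # a self-regulated transporter: peak at its own locus
  tpo1 <- rec("TPO1", 12, 86, gene_chrom = 12, gene_kbp = 86)
  # a distant regulation: gene on chr9, peak on chr12
  qdr2 <- rec("QDR2", 12, 680, gene_chrom = 9, gene_kbp = 250)
  border1 <- rec("b1", 1, 141, gene_chrom = 1, gene_kbp = 100)
  border2 <- rec("b2", 1, 139, gene_chrom = 1, gene_kbp = 100)
  border3 <- rec("b3", 1, 140, gene_chrom = 1, gene_kbp = 100)
  cl <- classify_cis_trans(rbind(tpo1, qdr2, border1, border2, border3))
  expect_equal(cl$local_flag, c("cis", "trans", "trans", "cis", "trans"))

  # missing annotation -> trans with warning
  na_rec <- rec("x", 1, 10); na_rec$gene_chrom <- NA
  expect_warning(cln <- classify_cis_trans(na_rec), "annotation")
  expect_equal(cln$local_flag, "trans")

  # invariant under coordinate translation
  shifted <- rbind(tpo1, qdr2)
  shifted$peak_kbp <- shifted$peak_kbp + 500
  shifted$gene_kbp <- shifted$gene_kbp + 500
  expect_equal(classify_cis_trans(shifted)$local_flag, cl$local_flag[1:2])
})

test_that("hotspot detection flags a trans hub against uniform background", {
  set.seed(81)
  lens <- yeast_chromosome_lengths()
  # a large trans hub: 101 trans eQTLs at chr14:456
  hub <- rec(sprintf("h%03d", 1:101), 14, runif(101, 430, 470),
             gene_chrom = 2, gene_kbp = 100)
  chrom <- sample(1:16, 900, replace = TRUE, prob = lens / sum(lens))
  bg <- rec(sprintf("b%03d", 1:900), chrom,
            vapply(chrom, function(ch) runif(1, 1, lens[ch]), numeric(1)),
            gene_chrom = 1, gene_kbp = 1)
  all <- classify_cis_trans(rbind(hub, bg))
  all$local_flag <- "trans"
  hs <- detect_hotspots(all, bin_kbp = 50, alpha = 0.001)
  on14 <- hs[hs$chrom == 14 & hs$start_kbp <= 456 & hs$end_kbp >= 456, ]
  expect_equal(nrow(on14), 1)
  expect_gte(on14$count, 90)

  # uniform scatter at ~1 eQTL per bin: no hotspots in most runs
  zero <- vapply(1:20, function(s) {
    set.seed(200 + s)
    ch <- sample(1:16, 240, replace = TRUE, prob = lens / sum(lens))
    u <- rec(sprintf("u%03d", 1:240), ch,
             vapply(ch, function(cc) runif(1, 1, lens[cc]), numeric(1)))
    u$local_flag <- "trans"
    nrow(detect_hotspots(u, bin_kbp = 50, alpha = 0.001))
  }, numeric(1))
  expect_gte(mean(zero == 0), 0.95)

  # empty set
  empty <- all[0, ]
  expect_equal(nrow(detect_hotspots(empty)), 0)
})

test_that("result tables round-trip deterministically", {
  recs <- classify_cis_trans(rbind(rec("t2", 3, 50), rec("t1", 2, 100)))
  recs$venn_group <- c("13", "123")
  recs2 <- recs; recs2$local_flag <- "trans"
  hs <- detect_hotspots(recs2, bin_kbp = 50, alpha = 0.5)
  dir <- withr::local_tempdir()
  paths <- write_results(recs, hs, dir)
  back <- utils::read.table(file.path(dir, "eqtl.tsv"), header = TRUE, sep = "\t",
                            colClasses = c(venn_group = "character"),
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), 2)
  expect_true(all(diff(back$peak_chrom) >= 0))
  expect_equal(sort(back$venn_group), c("123", "13"))
  ord <- order(recs$peak_chrom, recs$peak_kbp, recs$transcript)
  expect_equal(back$peak_kbp, recs$peak_kbp[ord])

  # empty input -> header-only file
  write_results(recs[0, ], hs[0, ], dir)
  empty_back <- utils::read.table(file.path(dir, "eqtl.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(empty_back), 0)
  expect_equal(names(empty_back), names(recs))
})

test_that("with no disomic segregants the three analyses coincide", {
  map <- make_map(rep(1:2, each = 40), rep(seq(5, 800, length.out = 40), 2))
  pop <- simulate_cross(map, 40, translocation = NULL, missing_rate = 0, seed = 83)
  sim <- simulate_expression(pop$genotypes, pop$truth, n_genes = 40,
                             cis_frac = 0.25, trans_frac = 0, dosage_log2 = 0,
                             noise_sd = 0.2, seed = 84)
  out <- run_disomy_bypass(sim$expression, pop$genotypes,
                           disomic_ids = character(0),
                           region = list(chrom = 2, start_kbp = 1, end_kbp = 100),
                           affected_genes = character(0), lod_threshold = 4)
  expect_equal(out$analysis1, out$analysis2)
  expect_equal(out$analysis1, out$analysis3)
  expect_gt(nrow(out$analysis1), 0)
  v <- venn_classify(out$analysis1, out$analysis2, out$analysis3)
  expect_true(all(v$venn_group == "123"))
})

test_that("the full pipeline recovers planted eQTLs at the FDR-0.05 threshold", {
  map <- simulate_marker_map(seed = 91)
  pop <- simulate_cross(map, 100, seed = 92)
  # planted effects at twice the noise sd
  sim <- simulate_expression(pop$genotypes, pop$truth, n_genes = 300,
                             cis_frac = 0.07, trans_frac = 0.03,
                             effect_size_log2 = 0.5, dosage_log2 = 0,
                             noise_sd = 0.25, seed = 93)
  pr <- genotype_probabilities(pop$genotypes)
  tab <- permutation_fdr_transcriptome(pr, sim$expression, n_perm = 20, seed = 94)
  th <- fdr_lod_threshold(tab, target = 0.05)
  recs <- scan_transcriptome(pr, sim$expression, th)
  planted <- sim$truth$planted_eqtls
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    r <- recs[recs$transcript == planted$transcript[i] &
              recs$peak_chrom == planted$chromosome[i], , drop = FALSE]
    any(abs(r$peak_kbp - planted$pos_kbp[i]) < 50 |
        (r$ci_lo_kbp <= planted$pos_kbp[i] & r$ci_hi_kbp >= planted$pos_kbp[i]))
  }, logical(1))
  expect_gte(mean(hit), 0.90)
})
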