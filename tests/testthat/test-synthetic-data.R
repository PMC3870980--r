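test_that("simulated marker map hits the requested density and structure", {
  map <- simulate_marker_map(seed = 11)
  expect_gte(nrow(map), 2180)
  expect_lte(nrow(map), 2192)
  expect_lt(abs(marker_density(nrow(map)) - 1.81) / 1.81, 0.02)
  for (ch in 1:16) {
    p <- map$pos_kbp[map$chromosome == ch]
    expect_true(all(diff(p) > 0))
  }
  expect_equal(map$pos_cM, map$pos_kbp / 3)

  one <- simulate_marker_map(n_chrom = 1, chrom_lengths_kbp = 10,
                             density_per_10kbp = 1, seed = 2)
  expect_equal(nrow(one), 1)

  expect_identical(simulate_marker_map(seed = 5), simulate_marker_map(seed = 5))
  expect_error(simulate_marker_map(chrom_lengths_kbp = rep(-1, 16)), "positive")
  expect_error(simulate_marker_map(density_per_10kbp = 0), "positive")
})

test_that("haldane map function has the right limits", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(Inf), 0.5)
  expect_lt(haldane_r(1e6), 0.5 + 1e-12)
  # small distances: r ~ d in Morgans
  expect_equal(haldane_r(1), 0.01, tolerance = 0.02)
})

test_that("cross simulation delivers viable classes with ~1/3 disomic", {
  pop <- study_population()
  expect_equal(length(pop$genotypes$segregant_ids), 44)
  expect_true(all(pop$truth$class %in% c("normal", "translocated", "disomic")))
  expect_identical(names(which(pop$truth$class == "disomic")),
                   pop$truth$disomic_segregants)

  big <- simulate_cross(simulate_marker_map(seed = 3), 4000,
                        missing_rate = 0, seed = 4)
  frac <- mean(big$truth$class == "disomic")
  # binomial(4000, 1/3): 4 SD band
  expect_lt(abs(frac - 1 / 3), 4 * sqrt(1 / 3 * 2 / 3 / 4000))

  expect_error(simulate_cross(simulate_marker_map(seed = 3), 1), "at least 2")
  expect_identical(simulate_cross(simulate_marker_map(seed = 3), 10, seed = 9),
                   simulate_cross(simulate_marker_map(seed = 3), 10, seed = 9))
})

test_that("markers 0 cM apart never recombine", {
  map <- make_map(1, c(30, 30 + 1e-9, 300))
  g <- simulate_cross(map, 200, translocation = NULL, missing_rate = 0, seed = 6)
  x <- genotype_numeric(g$genotypes)
  expect_true(all(x[1, ] == x[2, ]))
})

test_that("allele frequency is ~1/2 away from the translocation junctions", {
  big <- simulate_cross(simulate_marker_map(seed = 3), 1000,
                        missing_rate = 0, seed = 14)
  x <- genotype_numeric(big$genotypes)
  map <- big$genotypes$map
  away <- !(map$chromosome %in% c(8, 16))
  freq <- rowMeans(x[away, ])
  band <- 5 * sqrt(0.25 / 1000)
  expect_gt(mean(abs(freq - 0.5) <= band), 0.995)
  # arm markers deviate (P1 carried by translocated + disomic segregants)
  arm <- map$chromosome == 16 & map$pos_kbp <= 373
  expect_gt(mean(rowMeans(x[arm, ])), 0.55)
})

test_that("breakpoint count per meiosis matches the map length in Morgans", {
  map <- make_map(rep(1, 200), seq(2, 1500, length.out = 200))
  g <- simulate_cross(map, 4000, translocation = NULL, missing_rate = 0, seed = 8)
  x <- genotype_numeric(g$genotypes)
  switches <- colSums(abs(diff(x)))
  morgans <- (max(map$pos_cM) - min(map$pos_cM)) / 100
  expect_equal(mean(switches), morgans, tolerance = 0.05)
})

test_that("expression simulator plants dosage and eQTL effects as configured", {
  pop <- study_population()
  sim <- simulate_expression(pop$genotypes, pop$truth, n_genes = 400,
                             cis_frac = 0.1, trans_frac = 0.05,
                             noise_sd = 0.1, dosage_log2 = 1, seed = 31)
  ex <- sim$expression
  expect_equal(dim(ex$values), c(400, 44))
  expect_true(all(is.finite(ex$values)))
  expect_equal(nrow(ex$gene_annot), 400)
  # dosage genes: disomic - normal mean difference ~ 1.0
  dg <- sim$truth$dosage_genes
  expect_gt(length(dg), 0)
  dis <- ex$sample_ids %in% pop$truth$disomic_segregants
  diffs <- rowMeans(ex$values[dg, dis, drop = FALSE]) -
    rowMeans(ex$values[dg, !dis, drop = FALSE])
  expect_equal(mean(diffs), 1.0, tolerance = 0.05)
  # determinism
  sim2 <- simulate_expression(pop$genotypes, pop$truth, n_genes = 400,
                              cis_frac = 0.1, trans_frac = 0.05,
                              noise_sd = 0.1, dosage_log2 = 1, seed = 31)
  expect_identical(sim$expression$values, sim2$expression$values)
})

test_that("null expression architecture carries no marker association", {
  pop <- study_population()
  sim <- simulate_expression(pop$genotypes, pop$truth, n_genes = 60,
                             cis_frac = 0, trans_frac = 0, dosage_log2 = 0,
                             noise_sd = 0.2, seed = 33)
  expect_equal(nrow(sim$truth$planted_eqtls), 0)
  x <- genotype_numeric(pop$genotypes)
  x[is.na(x)] <- 0.5
  cors <- stats::cor(t(sim$expression$values), t(x[seq(1, nrow(x), by = 40), ]))
  expect_lt(max(abs(cors)), 0.75)
})

test_that("trait simulator reaches the target heritability in expectation", {
  map <- simulate_marker_map(seed = 3)
  pop <- simulate_cross(map, 200, seed = 41)
  h <- vapply(1:60, function(b) {
    tr <- simulate_traits(pop$genotypes, pop$truth, target_H2 = 90, seed = b)
    heritability(tr$traits[[1]])
  }, numeric(1))
  expect_equal(mean(h), 90, tolerance = 3)

  # target 0: estimates center near 0 (the pooled parental variance has few
  # degrees of freedom, so single estimates are noisy; average many traits)
  h0 <- unlist(lapply(1:20, function(b) {
    tr <- simulate_traits(pop$genotypes, pop$truth, target_H2 = 0,
                          n_traits = 20, seed = b)
    vapply(tr$traits, function(t) suppressWarnings(heritability(t)), numeric(1))
  }))
  expect_lt(abs(mean(h0)), 10)

  expect_error(simulate_traits(pop$genotypes, pop$truth, target_H2 = 100), "target_H2")
})

test_that("a disomy-linked trait is bimodal across segregants", {
  pop <- study_population()
  tr <- simulate_traits(pop$genotypes, pop$truth, target_H2 = 95,
                        qtl_loci = data.frame(chromosome = 16, pos_kbp = 100,
                                              effect = 1), seed = 51)
  v <- sort(tr$traits[[1]]$values)
  # two genotype groups: the largest gap between consecutive sorted values
  # is much larger than the typical within-group spacing
  gaps <- diff(v)
  expect_gt(max(gaps), 5 * stats::median(gaps))
})
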