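test_that("hard calls follow Hardy-Weinberg proportions without LD", {
  cfg <- simConfig(n_subjects = 4000L, n_variants = 25L, ld_rho = 0,
                   missing_rate = 0, seed = 101L)
  g <- simulateGenotypes(cfg)
  d <- dosage(g)
  n <- ncol(g)
  for (i in seq_len(nrow(g))) {
    p <- mean(d[i, ]) / 2
    # recover the sampled MAF from the class frequencies themselves is
    # circular; instead check internal HW consistency: freq(het) vs
    # 2 p (1-p) within 3 binomial SE of the implied p
    f_het <- mean(d[i, ] == 1)
    expected <- 2 * p * (1 - p)
    se3 <- 3 * sqrt(expected * (1 - expected) / n)
    expect_lt(abs(f_het - expected), se3 + 3 / n)
  }
  # mean dosage spans the configured MAF range
  expect_true(all(d %in% 0:2))
})

test_that("genotype generator is deterministic and honours degenerate rates", {
  cfg <- simConfig(n_subjects = 50L, n_variants = 30L, seed = 7L)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosage(g1), dosage(g2))
  expect_identical(variantInfo(g1), variantInfo(g2))

  cfg_all_missing <- simConfig(n_subjects = 20L, n_variants = 10L,
                               missing_rate = 1, seed = 3L)
  gm <- simulateGenotypes(cfg_all_missing)
  expect_true(all(missingMask(gm)))
  expect_true(all(is.na(dosage(gm))))
})

test_that("invalid configurations are rejected by name", {
  expect_error(simConfig(missing_rate = 1.5), "missing_rate")
  expect_error(simConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simConfig(ld_rho = 1), "ld_rho")
  expect_error(simConfig(n_subjects = NA), "finite")
  expect_error(simConfig(baseline_scale = -1), "baseline_scale")
})

test_that("within-block LD decays with distance", {
  cfg <- simConfig(n_subjects = 600L, n_variants = 600L,
                   ld_block_size = 10L, ld_rho = 0.7,
                   maf_range = c(0.2, 0.5), missing_rate = 0, seed = 11L)
  g <- simulateGenotypes(cfg)
  d <- t(dosage(g))
  n_blocks <- 60
  r2_at_lag <- vapply(1:5, function(lag) {
    r2 <- c()
    for (b in seq_len(n_blocks)) {
      off <- (b - 1) * 10
      for (k in seq_len(10 - lag))
        r2 <- c(r2, cor(d[, off + k], d[, off + k + lag])^2)
    }
    mean(r2)
  }, numeric(1))
  expect_true(all(diff(r2_at_lag) < 0))
  expect_gt(r2_at_lag[1], 0.2)
})

test_that("event times match the closed-form Weibull survivor function", {
  cfg <- simConfig(n_subjects = 5000L, n_variants = 5L,
                   clinical_effects = numeric(0), causal_effects = numeric(0),
                   dropout_rate = 0, admin_censor_time = 1e9,
                   baseline_shape = 1.3, baseline_scale = 300, seed = 17L)
  d <- simulateDataset(cfg)
  expect_true(all(d$cohort$event == 1))
  ks <- suppressWarnings(
    stats::ks.test(d$cohort$time, stats::pweibull, shape = 1.3, scale = 300))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("near-zero administrative censoring removes essentially all events", {
  cfg <- simConfig(n_subjects = 800L, n_variants = 5L,
                   admin_censor_time = 1e-4, dropout_rate = 0, seed = 19L)
  d <- simulateDataset(cfg)
  expect_lt(mean(d$cohort$event), 0.01)
  expect_true(all(d$cohort$time > 0))
})

test_that("unknown effect terms are rejected", {
  cfg <- simConfig(n_subjects = 30L, n_variants = 5L, seed = 2L,
                   causal_effects = c(not_a_snp = 0.5))
  ann <- simulateGeneAnnotation(cfg)
  g <- simulateGenotypes(cfg)
  clin <- simulateClinical(cfg)
  expect_error(simulateOutcomes(g, clin, cfg), "not_a_snp")

  cfg2 <- simConfig(n_subjects = 30L, n_variants = 5L, seed = 2L,
                    clinical_effects = c(bogus_term = 0.5))
  expect_error(simulateOutcomes(simulateGenotypes(cfg2),
                                simulateClinical(cfg2), cfg2), "bogus_term")
})

test_that("clinical marginals hit their configured targets", {
  cfg <- simConfig(n_subjects = 4000L, n_variants = 5L, seed = 23L)
  clin <- simulateClinical(cfg)
  expect_equal(nrow(clin), 4000)
  expect_false(anyNA(clin[, setdiff(colnames(clin), "ebv_dna")]))
  # T3-T4 target 0.629 within 3 binomial SE
  p_t34 <- mean(clin$t_stage == "T3-T4")
  expect_lt(abs(p_t34 - 0.629), 3 * sqrt(0.629 * 0.371 / 4000))
  expect_identical(clin, simulateClinical(cfg))
  # empty cohort keeps full schema
  clin0 <- simulateClinical(simConfig(n_subjects = 0L, seed = 1L))
  expect_equal(nrow(clin0), 0)
  expect_true(all(colnames(clin) %in% colnames(clin0)))
})

test_that("gene annotation respects packing limits and deafness fractions", {
  cfg0 <- simConfig(n_genes = 20L, deafness_gene_fraction = 0, seed = 5L)
  ann0 <- simulateGeneAnnotation(cfg0)
  expect_length(ann0$deafness, 0)

  cfg1 <- simConfig(n_genes = 20L, deafness_gene_fraction = 1, seed = 5L)
  ann1 <- simulateGeneAnnotation(cfg1)
  expect_length(ann1$deafness, 20)

  expect_error(simulateGeneAnnotation(
    simConfig(n_genes = 100L, genome_length = 1e5,
              gene_length_range = c(5000, 5000), seed = 1L)),
    "packing")

  # non-overlapping intervals
  gr <- regions(ann1$genes)
  o <- order(GenomicRanges::start(gr))
  expect_true(all(GenomicRanges::start(gr)[o][-1] >
                    GenomicRanges::end(gr)[o][-length(gr)]))
})

test_that("planted variant placement hits the target in-region fraction", {
  cfg <- simConfig(n_subjects = 10L, n_variants = 2000L,
                   deafness_variant_fraction = 0.3, seed = 31L,
                   genome_length = 1e8)
  ann <- simulateGeneAnnotation(cfg)
  pos <- sampleVariantPositions(cfg, ann)
  gr <- regions(ann$genes)[ann$deafness]
  inside <- membership_oracle(pos, GenomicRanges::start(gr),
                              GenomicRanges::end(gr), cfg@deafness_flank)
  expect_lt(abs(mean(inside) - 0.3), 0.05)
})
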