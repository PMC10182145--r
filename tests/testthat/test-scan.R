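test_that("scan results are invariant to variant and subject order", {
  td <- make_toy_data(n = 150, m = 6, seed = 21)
  sc <- scanConfig(covariates = clin_covs)
  s1 <- as.data.frame(scanTable(gwasScan(td$genotypes, td$cohort,
                                         config = sc)))
  vperm <- c(4, 1, 6, 2, 5, 3)
  sperm <- sample(seq_len(150))
  g2 <- td$genotypes[vperm, sperm]
  s2 <- as.data.frame(scanTable(gwasScan(g2, td$cohort, config = sc)))
  s2 <- s2[match(s1$variant, s2$variant), ]
  expect_equal(s1$beta, s2$beta, tolerance = 1e-10)
  expect_equal(s1$p, s2$p, tolerance = 1e-10)
  expect_equal(s1$eaf, s2$eaf, tolerance = 1e-12)
})

test_that("Wald p is consistent with beta/se and hr equals exp(beta)", {
  td <- make_toy_data(n = 200, m = 10, seed = 22)
  st <- as.data.frame(scanTable(gwasScan(td$genotypes, td$cohort,
                                         config = scanConfig(covariates = clin_covs))))
  ok <- st$converged
  expect_true(any(ok))
  expect_equal(st$p[ok], 2 * pnorm(-abs(st$beta[ok] / st$se[ok])),
               tolerance = 1e-12)
  expect_equal(st$hr[ok], exp(st$beta[ok]), tolerance = 1e-12)
  expect_true(all(st$ci_low[ok] <= st$ci_high[ok]))
})

test_that("a variant duplicating a covariate is flagged non-converged", {
  td <- make_toy_data(n = 150, m = 4, seed = 23)
  g <- td$genotypes
  des <- clinicalDesign(td$cohort)
  d <- dosage(g)
  d[2, ] <- des[, "t_stage_t34"]  # exact copy of a model covariate
  g2 <- newGenotypeData(dosage = d, variant = rownames(g), chrom = "chr1",
                        pos = variantInfo(g)$pos, subjects = colnames(g))
  st <- as.data.frame(scanTable(gwasScan(g2, td$cohort,
                                         config = scanConfig(covariates = clin_covs))))
  expect_false(st$converged[2])
  expect_true(is.na(st$beta[2]))
})

test_that("missing genotypes drop subjects for that variant only", {
  td <- make_toy_data(n = 150, m = 3, seed = 24)
  d <- dosage(td$genotypes)
  d[2, 1:30] <- NA
  g2 <- newGenotypeData(dosage = d, variant = rownames(td$genotypes),
                        chrom = "chr1", pos = variantInfo(td$genotypes)$pos,
                        subjects = colnames(td$genotypes))
  st <- as.data.frame(scanTable(gwasScan(g2, td$cohort,
                                         config = scanConfig(covariates = clin_covs))))
  expect_equal(st$n_used, c(150L, 120L, 150L))
})

test_that("genomic inflation follows its definition", {
  expect_equal(genomicInflation(rep(0.5, 100)), 1.0)
  set.seed(25)
  p <- runif(10000)
  l1 <- genomicInflation(p)
  expect_gt(l1, 0.97); expect_lt(l1, 1.03)
  # halving all P strictly increases lambda
  expect_gt(genomicInflation(p / 2), l1)
  expect_error(genomicInflation(c(NA_real_, NA_real_)), "valid")
})

test_that("QQ/Manhattan tables have the documented shape", {
  td <- make_toy_data(n = 150, m = 12, seed = 26)
  scan <- gwasScan(td$genotypes, td$cohort,
                   config = scanConfig(covariates = clin_covs))
  tabs <- qqManhattanTables(scan)
  n_valid <- sum(scanTable(scan)$converged & !is.na(scanTable(scan)$p))
  expect_equal(nrow(tabs$qq), n_valid)
  expect_equal(nrow(tabs$manhattan), n_valid)
  expect_true(all(diff(tabs$qq$observed) <= 0))
  one <- make_scan_result(data.frame(variant = "v1", p = 0.2))
  expect_equal(qqManhattanTables(one)$qq$expected, -log10(0.5))
})

test_that("stratified analysis drops the stratifying covariate and matches
           the unstratified fit on a whole-cohort stratum", {
  td <- make_toy_data(n = 250, m = 4, seed = 27)
  co <- td$cohort
  co$t_stage <- "T3-T4"  # single level: stratum = whole cohort
  strat <- stratifiedAnalysis(td$genotypes, co, NULL, "v001",
                              strata = "t_stage_t34",
                              config = scanConfig(covariates = clin_covs))
  expect_equal(nrow(strat), 1)
  # reference: same model with t_stage_t34 removed from covariates
  ref <- as.data.frame(scanTable(gwasScan(
    td$genotypes["v001", ], co,
    config = scanConfig(covariates = setdiff(clin_covs, "t_stage_t34")))))
  expect_equal(strat$hr, ref$hr, tolerance = 1e-10)
  expect_equal(strat$p, ref$p, tolerance = 1e-10)

  # two-level stratification reports every stratum
  strat2 <- stratifiedAnalysis(td$genotypes, td$cohort, NULL, "v001",
                               strata = c("age_ge50", "sex_female"),
                               config = scanConfig(covariates = clin_covs))
  expect_equal(nrow(strat2), 4)
  expect_true(all(strat2$n > 0))
})

test_that("Kaplan-Meier estimates and the log-rank test meet their definitions", {
  # no censoring: survival at t equals the empirical fraction surviving past t
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- rep(1, 8)
  km <- kmLogrank(c(time, time + 0.5), rep(1, 16),
                  rep(c("a", "b"), each = 8))
  a <- km$curves[km$curves$group == "a", ]
  expect_equal(a$survival, 1 - seq_len(8) / 8)
  expect_error(kmLogrank(time, event, rep("a", 8)), "two")

  # log-rank equals the Cox score test for a binary grouping without ties
  set.seed(28)
  n <- 80
  t2 <- runif(n, 1, 50) + seq_len(n) * 1e-7
  e2 <- rbinom(n, 1, 0.6)
  grp <- rbinom(n, 1, 0.5)
  km2 <- kmLogrank(t2, e2, grp)
  fit <- coxFit(matrix(grp, ncol = 1), t2, e2)
  expect_lt(abs(km2$chisq - fit$score), 1e-8)
})
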