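test_that("train/test split sizes, disjointness and reproducibility", {
  co <- data.frame(subject_id = sprintf("S%03d", 1:777), time = rexp(777) + 1,
                   event = rbinom(777, 1, 0.2))
  sp <- splitTrainTest(co, 0.5, seed = 2L)
  expect_equal(nrow(sp$train), 389)
  expect_equal(nrow(sp$test), 388)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  co$subject_id)
  sp2 <- splitTrainTest(co, 0.5, seed = 2L)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  sp3 <- splitTrainTest(co, 0.5, seed = 3L)
  expect_false(identical(sp$train$subject_id, sp3$train$subject_id))
  expect_error(splitTrainTest(co, 1.2, 1L), "ratio")
  expect_error(splitTrainTest(co[1:3, ], 0.5, 1L), "4 subjects")
})

test_that("risk scores are exact linear predictors", {
  td <- make_toy_data(n = 200, m = 5, seed = 41)
  m <- fitRiskModel(td$cohort, td$genotypes, snp_ids = c("v001", "v002"))
  s <- scoreSubjects(m, td$cohort, td$genotypes)
  # hand-computed score for one subject
  cf <- coef(m)
  subj <- td$cohort$subject_id[7]
  hand <- cf[["v001"]] * dosage(td$genotypes)["v001", subj] +
    cf[["v002"]] * dosage(td$genotypes)["v002", subj] +
    sum(cf[c("age_ge50", "t_stage_t34", "concurrent_dose_ge155")] *
          clinicalDesign(td$cohort)[subj,
            c("age_ge50", "t_stage_t34", "concurrent_dose_ge155")])
  expect_equal(unname(s[subj]), unname(hand), tolerance = 1e-12)

  # all-zero terms score zero; linearity in a coefficient
  m0 <- m
  m0@coefficients <- cf * 0
  expect_true(all(scoreSubjects(m0, td$cohort, td$genotypes) == 0))

  # missing genotype flags the subject and reports the exclusion count
  d <- dosage(td$genotypes)
  d["v001", 3] <- NA
  g2 <- newGenotypeData(dosage = d, variant = rownames(td$genotypes),
                        chrom = "chr1", pos = variantInfo(td$genotypes)$pos,
                        subjects = colnames(td$genotypes))
  s2 <- scoreSubjects(m, td$cohort, g2)
  expect_true(is.na(s2[3]))
  expect_equal(attr(s2, "n_excluded"), 1L)
})

test_that("a single clinical term reproduces the univariate Cox coefficient", {
  td <- make_toy_data(n = 250, seed = 42)
  m <- fitRiskModel(td$cohort, td$genotypes, snp_ids = character(0),
                    clinical_terms = "age_ge50")
  u <- univariateCox(td$cohort, "age_ge50")
  expect_equal(unname(coef(m)), u$beta, tolerance = 1e-6)
})

test_that("horizon AUC meets its boundary identities", {
  # identical scores: 0.5 exactly
  time <- c(10, 20, 70, 80, 90, 30)
  event <- c(1, 1, 0, 0, 0, 1)
  expect_equal(aucAtHorizon(rep(1, 6), time, event, horizon = 60), 0.5)
  # perfect ranking, no censoring: 1.0
  expect_equal(aucAtHorizon(c(9, 8, 1, 2, 3, 7), time, event, 60), 1.0)
  expect_error(aucAtHorizon(1:6, time, rep(0, 6), horizon = 5), "cases")
  expect_error(aucAtHorizon(1:6, rep(10, 6), rep(1, 6), horizon = 60),
               "controls")
})

test_that("without censoring before the horizon the AUC is Mann-Whitney", {
  set.seed(43)
  n <- 300
  sc <- rnorm(n)
  t_ev <- rexp(n, 0.02 * exp(0.8 * sc))
  time <- pmin(t_ev, 100)          # censoring only at 100 > horizon
  event <- as.integer(t_ev <= 100)
  auc <- aucAtHorizon(sc, time, event, horizon = 60)
  y <- as.integer(time <= 60 & event == 1)
  mw <- (mean(rank(sc)[y == 1]) - (sum(y) + 1) / 2) / sum(y == 0)
  expect_lt(abs(auc - mw), 1e-10)

  # invariance under a strictly increasing transform of scores
  expect_equal(aucAtHorizon(exp(sc), time, event, 60), auc,
               tolerance = 1e-12)
})

test_that("group hazard ratio handles cutoffs and degenerate groups", {
  set.seed(44)
  n <- 200
  sc <- rnorm(n)
  time <- rexp(n, 0.02 * exp(sc)); event <- rbinom(n, 1, 0.8)
  gh <- groupHazardRatio(sc, median(sc), time, event)
  expect_equal(gh$n_high + gh$n_low, n)
  expect_gt(gh$hr, 1)  # scores drive the hazard by construction
  expect_error(groupHazardRatio(sc, min(sc) - 1, time, event),
               "empty")
})

test_that("clinical-only, genetic-only and combined models share one code path
           and the combined fit dominates in training", {
  cfg <- simConfig(n_subjects = 500L, n_variants = 40L, seed = 45L,
                   causal_effects = c(snp00005 = log(2), snp00020 = log(1.8)))
  d <- simulateDataset(cfg)
  snps <- c("snp00005", "snp00020")
  m_clin <- fitRiskModel(d$cohort, d$genotypes, character(0))
  m_gen <- fitRiskModel(d$cohort, d$genotypes, snps, clinical_terms = character(0))
  m_comb <- fitRiskModel(d$cohort, d$genotypes, snps)
  aucs <- vapply(list(m_clin, m_gen, m_comb), function(m) {
    s <- scoreSubjects(m, d$cohort, d$genotypes)
    aucAtHorizon(s, d$cohort$time, d$cohort$event, 60)
  }, numeric(1))
  expect_gte(aucs[3], max(aucs[1:2]) - 0.01)
})

test_that("evaluateRiskModel populates per-dataset metrics", {
  cfg <- simConfig(n_subjects = 400L, n_variants = 20L, seed = 46L,
                   causal_effects = c(snp00003 = log(2)))
  d <- simulateDataset(cfg)
  sp <- splitTrainTest(d$cohort, 0.5, seed = 1L)
  m <- fitRiskModel(sp$train, d$genotypes, "snp00003")
  m <- evaluateRiskModel(m, list(
    train = list(cohort = sp$train, genotypes = d$genotypes),
    test = list(cohort = sp$test, genotypes = d$genotypes)))
  expect_named(metrics(m), c("train", "test"))
  expect_true(all(vapply(metrics(m), function(x)
    x$auc > 0 && x$auc < 1 && is.finite(x$hr), logical(1))))
})
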