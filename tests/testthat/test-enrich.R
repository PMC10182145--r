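test_that("flank boundary conventions are honoured exactly", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 1000,
                                                        end = 2000))
  names(gr) <- "g1"
  vdf <- data.frame(variant = c("at_flank", "one_before", "one_past_flank",
                                "at_end_flank"),
                    chrom = "chr1",
                    pos = c(1000 - 50, 1000 - 51, 2000 + 51, 2000 + 50))
  m <- mapSnpsToRegions(vdf, geneRegionSet(gr, flank = 50))
  expect_setequal(m$membership, c("at_flank", "at_end_flank"))

  # flank = 0: 1 bp past the gene end is excluded
  vdf0 <- data.frame(variant = c("inside_end", "past_end"), chrom = "chr1",
                     pos = c(2000, 2001))
  m0 <- mapSnpsToRegions(vdf0, geneRegionSet(gr, flank = 0))
  expect_identical(m0$membership, "inside_end")
})

test_that("membership matches the all-pairs brute force on random instances", {
  set.seed(31)
  for (r in 1:5) {
    n_genes <- 20
    starts <- sort(sample.int(5e5, n_genes))
    ends <- starts + sample(1000:20000, n_genes, TRUE)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
    names(gr) <- sprintf("g%02d", seq_len(n_genes))
    fl <- sample(c(0, 500, 20000), 1)
    vdf <- data.frame(variant = sprintf("v%03d", 1:500), chrom = "chr1",
                      pos = sample.int(6e5, 500))
    got <- mapSnpsToRegions(vdf, geneRegionSet(gr, flank = fl))
    want <- vdf$variant[membership_oracle(vdf$pos, starts, ends, fl)]
    expect_setequal(got$membership, want)
    # per-gene lists agree with single-gene brute force
    j <- sample(n_genes, 1)
    expect_setequal(got$per_gene[[j]],
                    vdf$variant[membership_oracle(vdf$pos, starts[j],
                                                  ends[j], fl)])
  }
})

test_that("a variant overlapping several genes is counted once", {
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(start = c(100, 150), end = c(300, 400)))
  names(gr) <- c("g1", "g2")
  vdf <- data.frame(variant = "v1", chrom = "chr1", pos = 200)
  m <- mapSnpsToRegions(vdf, geneRegionSet(gr, flank = 0))
  expect_identical(m$membership, "v1")
  expect_identical(m$per_gene$g1, "v1")
  expect_identical(m$per_gene$g2, "v1")
})

test_that("gene-set subsetting warns on unknown genes and restricts mapping", {
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(start = c(100, 5000), end = c(300, 5400)))
  names(gr) <- c("g1", "g2")
  vdf <- data.frame(variant = c("v1", "v2"), chrom = "chr1",
                    pos = c(200, 5100))
  expect_warning(
    m <- mapSnpsToRegions(vdf, geneRegionSet(gr, flank = 0),
                          gene_subset = c("g1", "ghost")),
    "ghost")
  expect_identical(m$membership, "v1")
})

test_that("significant-count statistic matches a manual tally", {
  sc <- make_scan_result(data.frame(
    variant = c("a", "b", "c", "d", "e", "f"),
    p = c(1e-4, 0.02, NA, 0.5, 1e-6, 0.03),
    converged = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)))
  mem <- c("a", "b", "c", "e")
  expect_equal(countSignificant(sc, mem, 0.05), 2)  # a and b; e not converged
  expect_equal(countSignificant(sc, mem, 1), 2)     # all valid members
  expect_equal(countSignificant(sc, character(0), 0.05), 0)
  expect_error(countSignificant(sc, mem, 0), "threshold")
})

test_that("permutation enrichment: saturation, determinism and budget guard", {
  td <- make_toy_data(n = 100, m = 8, seed = 33)
  mem <- rownames(td$genotypes)[1:4]
  cfg <- scanConfig(covariates = clin_covs)
  er <- permutationEnrichment(td$genotypes, td$cohort, NULL, mem,
                              thresholds = c(1.0 - 1e-12, 1e-8),
                              B = 15L, seed = 4L, config = cfg)
  # threshold ~1: every permutation count equals the observed count
  expect_equal(er@empiricalP[1], 1)
  # observed count 0 at a tiny threshold: empirical P = 1
  expect_equal(er@observed[2], 0L)
  expect_equal(er@empiricalP[2], 1)

  er2 <- permutationEnrichment(td$genotypes, td$cohort, NULL, mem,
                               thresholds = c(1.0 - 1e-12, 1e-8),
                               B = 15L, seed = 4L, config = cfg)
  expect_identical(nullCounts(er), nullCounts(er2))

  expect_error(permutationEnrichment(td$genotypes, td$cohort, NULL, mem,
                                     B = 15L, seed = 1L, config = cfg,
                                     max_fits = 10),
               "max_fits")
  expect_error(permutationEnrichment(td$genotypes, td$cohort, NULL,
                                     character(0), B = 5L, seed = 1L),
               "empty")
})

test_that("permuting the phenotype block only relabels subjects", {
  # the clinical Cox model on a permuted cohort has exactly the original
  # coefficients: permutation changes association with genotypes, not the
  # internal covariate-outcome structure
  td <- make_toy_data(n = 180, seed = 34)
  co <- td$cohort
  fit0 <- multivariateCox(co, clin_covs)
  set.seed(9)
  perm <- sample(nrow(co))
  co_p <- co[perm, ]
  co_p$subject_id <- co$subject_id
  fit_p <- multivariateCox(co_p, clin_covs)
  expect_equal(fit0$beta, fit_p$beta, tolerance = 1e-12)
})

test_that("empirical P is non-increasing in the observed count", {
  td <- make_toy_data(n = 100, m = 6, seed = 35)
  mem <- rownames(td$genotypes)
  er <- permutationEnrichment(td$genotypes, td$cohort, NULL, mem,
                              thresholds = c(0.5), B = 40L, seed = 6L,
                              config = scanConfig(covariates = clin_covs))
  nc <- nullCounts(er)[, 1]
  emp_for <- function(nobs) mean(nc >= nobs)
  expect_true(all(diff(vapply(0:6, emp_for, numeric(1))) <= 0))
})
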