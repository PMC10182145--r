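# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed-form formulas,
# and naive all-pairs scans.

# Explicit Cox partial log-likelihood for distinct event times (no ties),
# single covariate.
partial_loglik_1d <- function(beta, x, time, event) {
  eta <- x * beta
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    s <- s + eta[i] - log(sum(exp(eta[risk])))
  }
  s
}

grid_max_beta <- function(x, time, event, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, partial_loglik_1d, numeric(1), x = x, time = time,
               event = event)
  grid[which.max(ll)]
}

# Closed-form exact HWE two-sided P: probability of heterozygote counts no
# more probable than observed, conditional on allele counts. Uses the exact
# combinatorial normalization (number of allele pairings), no numerical
# renormalization.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  x <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (x == 0 || 2 * n <= 2) return(1)
  h <- seq(x %% 2, min(x, 2 * n - x), by = 2)
  logp <- lfactorial(n) - lfactorial((x - h) / 2) - lfactorial(h) -
    lfactorial((2 * n - x - h) / 2) + h * log(2) +
    lfactorial(x) + lfactorial(2 * n - x) - lfactorial(2 * n)
  p <- exp(logp)
  p_obs <- p[match(n_het, h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Naive all-pairs interval membership: 1-based position q is in a gene iff
# start1 - flank <= q <= end1 + flank.
membership_oracle <- function(pos, starts1, ends1, flank) {
  vapply(pos, function(q)
    any(starts1 - flank <= q & q <= ends1 + flank), logical(1))
}

# Exhaustive Youden cutoff search over observed values, rule x >= c.
roc_oracle <- function(values, outcome) {
  cand <- sort(unique(values))
  best_j <- -Inf
  best_c <- NA_real_
  for (cc in cand) {
    sens <- sum(values >= cc & outcome == 1) / sum(outcome == 1)
    spec <- sum(values < cc & outcome == 0) / sum(outcome == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_c <- cc }
  }
  list(cutoff = best_c, j = best_j)
}

# Mean silhouette width for a 1-d embedding and 2 known groups.
silhouette_1d <- function(x, grp) {
  d <- abs(outer(x, x, "-"))
  mean(vapply(seq_along(x), function(i) {
    same <- grp == grp[i]; same[i] <- FALSE
    a <- mean(d[i, same]); b <- mean(d[i, !same])
    (b - a) / max(a, b)
  }, numeric(1)))
}

# Build a ScanResult from a plain data.frame (for count/threshold tests).
make_scan_result <- function(df) {
  defaults <- data.frame(variant = df$variant, chrom = "chr1",
                         pos = seq_len(nrow(df)), ref = "A", alt = "G",
                         eaf = 0.3, beta = 0, se = 1, hr = 1,
                         ci_low = NA_real_, ci_high = NA_real_,
                         p = NA_real_, n_used = 10L, converged = TRUE)
  for (nm in setdiff(colnames(df), "variant")) defaults[[nm]] <- df[[nm]]
  defaults$hr <- exp(defaults$beta)
  methods::new("ScanResult", results = S4Vectors::DataFrame(defaults),
               covariates = character(0), ties = "efron",
               thresholds = c(genomewide = 5e-8, suggestive = 1e-5))
}

# Small aligned genotype + cohort pair built directly (not via the
# generator) for scan-level tests.
make_toy_data <- function(n = 120, m = 8, seed = 1, maf = 0.3,
                          event_rate = 0.35) {
  set.seed(seed)
  dose <- matrix(rbinom(n * m, 2, maf), nrow = m)
  g <- newGenotypeData(
    dosage = dose * 1.0, variant = sprintf("v%03d", seq_len(m)),
    chrom = "chr1", pos = sort(sample.int(1e6, m)),
    subjects = sprintf("S%03d", seq_len(n)))
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    time = rexp(n, 0.01) + 0.1,
    event = rbinom(n, 1, event_rate),
    age = round(rnorm(n, 45, 10), 1),
    sex = sample(c("male", "female"), n, TRUE),
    t_stage = sample(c("T1-T2", "T3-T4"), n, TRUE),
    n_stage = sample(c("N0-N1", "N2-N3"), n, TRUE),
    overall_stage = sample(c("I-II", "III-IV"), n, TRUE),
    ebv_dna = round(rexp(n, 1e-4)),
    treatment_modality = sample(c("CCRT", "CCRT+IC/AC"), n, TRUE),
    primary_tumor_dose = round(rnorm(n, 70, 0.2), 1),
    induction_cisplatin_dose = round(pmax(0, rnorm(n, 80, 70))),
    concurrent_cisplatin_dose = round(pmax(0, rnorm(n, 160, 60))),
    smoking = rbinom(n, 1, 0.3), drinking = rbinom(n, 1, 0.15),
    hypertension = rbinom(n, 1, 0.05), diabetes = rbinom(n, 1, 0.02),
    stringsAsFactors = FALSE)
  if (sum(cohort$event) == 0) cohort$event[1] <- 1L
  list(genotypes = g, cohort = cohort)
}

clin_covs <- c("age_ge50", "t_stage_t34", "concurrent_dose_ge155")
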