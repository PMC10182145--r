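#' Exact two-sided Hardy-Weinberg equilibrium test
#'
#' Conditional on the allele counts, the number of heterozygotes follows the
#' exact distribution over all pairings of alleles into genotypes; the
#' two-sided P is the total probability of heterozygote counts no more
#' probable than the observed one. Degenerate configurations (total allele
#' count <= 2, or a monomorphic site) give P = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return P in (0, 1].
#' @export
hweExactTest <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  x <- 2 * min(n_hom_ref, n_hom_alt) + n_het  # minor allele count
  if (x == 0 || 2 * n <= 2) return(1)
  h <- seq(x %% 2, min(x, 2 * n - x), by = 2)
  logp <- h * log(2) - lfactorial((x - h) / 2) - lfactorial(h) -
    lfactorial((2 * n - x - h) / 2)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  p_obs <- p[match(n_het, h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Variant-level quality control
#'
#' Removes variants failing any enabled filter: call rate below
#' `call_rate_min`, minor allele frequency below `maf_min` (MAF computed on
#' non-missing dosages as `min(p, 1-p)` with `p = mean(dosage)/2`; folding is
#' used for filtering only, never to re-orient effects), Hardy-Weinberg
#' exact P below `hwe_p_min` (computed on hard calls, i.e. dosages rounded
#' to the nearest integer), and imputation INFO below `info_min` where an
#' INFO score is present. The result does not depend on filter order and a
#' second application removes nothing.
#'
#' @param g a [GenotypeData-class].
#' @param call_rate_min,maf_min,hwe_p_min,info_min thresholds; set any to
#'   `NA` to disable that filter. `info_min` only applies to variants
#'   carrying an INFO score.
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (a [QCReport-class]).
#' @export
variantQC <- function(g, call_rate_min = 0.95, maf_min = 0.01,
                      hwe_p_min = 1e-12, info_min = 0.8) {
  if (nrow(g) == 0L) stop("empty genotype matrix", call. = FALSE)
  d <- dosage(g)
  miss <- missingMask(g)
  call_rate <- rowMeans(!miss)
  p_alt <- rowMeans(d, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- NA_real_
  maf <- pmin(p_alt, 1 - p_alt)
  hard <- round(d)
  hwe <- vapply(seq_len(nrow(g)), function(i) {
    x <- hard[i, ]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hweExactTest(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  info <- variantInfo(g)$info_score

  fails <- function(stat, thr, lower_ok = FALSE) {
    if (is.na(thr)) rep(FALSE, nrow(g))
    else !is.na(stat) & stat < thr | (is.na(stat) & !lower_ok)
  }
  f_call <- fails(call_rate, call_rate_min)
  f_maf <- fails(maf, maf_min)
  f_hwe <- fails(hwe, hwe_p_min)
  f_info <- if (is.na(info_min)) rep(FALSE, nrow(g))
            else !is.na(info) & info < info_min
  any_fail <- f_call | f_maf | f_hwe | f_info

  stats <- S4Vectors::DataFrame(
    variant = rownames(g), call_rate = call_rate, maf = maf, hwe_p = hwe,
    info_score = info, fail_call_rate = f_call, fail_maf = f_maf,
    fail_hwe = f_hwe, fail_info = f_info, removed = any_fail)
  report <- methods::new("QCReport",
    variantStats = stats,
    removed = c(call_rate = sum(f_call), maf = sum(f_maf), hwe = sum(f_hwe),
                info = sum(f_info), any_filter = sum(any_fail)),
    retained = sum(!any_fail),
    thresholds = list(call_rate_min = call_rate_min, maf_min = maf_min,
                      hwe_p_min = hwe_p_min, info_min = info_min),
    notes = c(paste("HWE: two-sided exact test on hard calls",
                    "(dosages rounded to nearest integer)"),
              "MAF folded for filtering only; effect allele remains ALT"))
  if (all(any_fail)) warning("all variants removed by QC", call. = FALSE)
  list(genotypes = g[!any_fail, ], report = report)
}

#' Sample-level QC hook (not implemented)
#'
#' Sample-level filters (sample call rate, heterozygosity outliers, IBD,
#' iterative PC-outlier removal) are deliberately out of scope: the
#' synthetic generator produces clean samples and real pipelines apply these
#' upstream. This stub documents the decision and passes data through.
#'
#' @param g a [GenotypeData-class].
#' @return `g`, unchanged, with attribute `sample_qc = "not applied"`.
#' @export
sampleQCHook <- function(g) {
  attr(g, "sample_qc") <- "not applied"
  g
}
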