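#' Simulation configuration for the synthetic cohort generator
#'
#' Holds every knob of the synthetic-data module: genotype structure
#' (LD-blocked biallelic SNPs under Hardy-Weinberg proportions), gene
#' annotation layout, clinical covariate marginals, and the
#' proportional-hazards outcome model (Weibull baseline, administrative plus
#' dropout censoring). Construct with [simConfig()].
#'
#' @slot n_subjects,n_variants cohort and panel size.
#' @slot maf_range minor (ALT) allele frequency range, each in (0, 0.5].
#' @slot ld_block_size,ld_rho variants per LD block and the AR(1) latent
#'   Gaussian correlation inducing within-block LD.
#' @slot missing_rate per-entry genotype missingness probability.
#' @slot n_genes,genome_length,gene_length_range gene annotation layout on a
#'   single synthetic chromosome (lengths in bp).
#' @slot deafness_gene_fraction fraction of genes assigned to the
#'   hereditary-deafness set.
#' @slot deafness_variant_fraction target fraction of variants placed within
#'   `deafness_flank` bp of a deafness gene (`NA` = uniform placement).
#' @slot deafness_flank flank in bp used when planting variant positions.
#' @slot causal_effects named numeric, variant id -> log hazard ratio per
#'   effect-allele dosage.
#' @slot clinical_effects named numeric, clinical design column (see
#'   [clinicalDesign()]) -> log hazard ratio.
#' @slot baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (scale in months).
#' @slot admin_censor_time administrative censoring time in months.
#' @slot dropout_rate per-month exponential dropout hazard.
#' @slot dosage_noise_sd if > 0, Gaussian noise of this SD is added to hard
#'   calls (clipped to \[0, 2\], quantized to 4 decimals) to emulate imputed
#'   dosages; an INFO-like score of 1 - noise/dosage variance is attached.
#' @slot seed integer seed; fixed seed gives byte-identical output.
#' @export
setClass("SimConfig",
  representation(
    n_subjects = "integer", n_variants = "integer",
    maf_range = "numeric", ld_block_size = "integer", ld_rho = "numeric",
    missing_rate = "numeric",
    n_genes = "integer", genome_length = "numeric",
    gene_length_range = "numeric",
    deafness_gene_fraction = "numeric", deafness_variant_fraction = "numeric",
    deafness_flank = "numeric",
    causal_effects = "numeric", clinical_effects = "numeric",
    baseline_shape = "numeric", baseline_scale = "numeric",
    admin_censor_time = "numeric", dropout_rate = "numeric",
    dosage_noise_sd = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  num1 <- function(x) length(x) == 1L && is.finite(x)
  chk(length(object@n_subjects) == 1L && object@n_subjects >= 0L,
      "n_subjects must be a single non-negative integer")
  chk(length(object@n_variants) == 1L && object@n_variants >= 1L,
      "n_variants must be >= 1")
  chk(length(object@maf_range) == 2L && all(is.finite(object@maf_range)) &&
        all(object@maf_range > 0) && all(object@maf_range <= 0.5) &&
        object@maf_range[1] <= object@maf_range[2],
      "maf_range must be an ordered pair within (0, 0.5]")
  chk(object@ld_block_size >= 1L, "ld_block_size must be >= 1")
  chk(num1(object@ld_rho) && object@ld_rho >= 0 && object@ld_rho < 1,
      "ld_rho must be in [0, 1)")
  for (p in c("missing_rate", "deafness_gene_fraction")) {
    v <- slot(object, p)
    chk(num1(v) && v >= 0 && v <= 1, paste(p, "must be a probability in [0, 1]"))
  }
  dvf <- object@deafness_variant_fraction
  chk(length(dvf) == 1L && (is.na(dvf) || (dvf >= 0 && dvf <= 1)),
      "deafness_variant_fraction must be NA or in [0, 1]")
  chk(object@n_genes >= 1L, "n_genes must be >= 1")
  chk(num1(object@genome_length) && object@genome_length >= 1,
      "genome_length must be positive")
  chk(length(object@gene_length_range) == 2L &&
        all(object@gene_length_range >= 1) &&
        object@gene_length_range[1] <= object@gene_length_range[2],
      "gene_length_range must be an ordered positive pair")
  chk(num1(object@deafness_flank) && object@deafness_flank >= 0,
      "deafness_flank must be >= 0")
  chk(all(is.finite(object@causal_effects)) &&
        (length(object@causal_effects) == 0L ||
           !is.null(names(object@causal_effects))),
      "causal_effects must be a named finite numeric vector")
  chk(all(is.finite(object@clinical_effects)) &&
        (length(object@clinical_effects) == 0L ||
           !is.null(names(object@clinical_effects))),
      "clinical_effects must be a named finite numeric vector")
  chk(num1(object@baseline_shape) && object@baseline_shape > 0,
      "baseline_shape must be > 0")
  chk(num1(object@baseline_scale) && object@baseline_scale > 0,
      "baseline_scale must be > 0")
  chk(num1(object@admin_censor_time) && object@admin_censor_time > 0,
      "admin_censor_time must be > 0")
  chk(num1(object@dropout_rate) && object@dropout_rate >= 0,
      "dropout_rate must be >= 0")
  chk(num1(object@dosage_noise_sd) && object@dosage_noise_sd >= 0,
      "dosage_noise_sd must be >= 0")
  chk(length(object@seed) == 1L && !is.na(object@seed), "seed must be set")
  if (length(msg)) msg else TRUE
})

#' Genotype container: variants by subjects
#'
#' Extends `RangedSummarizedExperiment`. Rows are variants (with positions as
#' `rowRanges` and id/REF/ALT/INFO in `rowData`), columns are subjects.
#' Assays: `dosage` (effect-allele dosage in \[0, 2\], effect allele = ALT)
#' and `missing` (logical mask; dosage is `NA` where missing).
#'
#' @export
setClass("GenotypeData",
  contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("dosage", "missing") %in% an))
    return("assays 'dosage' and 'missing' are required")
  d <- SummarizedExperiment::assay(object, "dosage")
  m <- SummarizedExperiment::assay(object, "missing")
  if (!is.logical(m)) msg <- c(msg, "'missing' assay must be logical")
  obs <- d[!m]
  if (length(obs) && (anyNA(obs) || any(obs < 0 | obs > 2)))
    msg <- c(msg, "observed dosages must lie in [0, 2]")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variant ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "subject ids must be unique")
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
  chr <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object)))
  if (is.unsorted(order(chr, pos), strictly = FALSE) &&
      any(unlist(tapply(pos, chr, is.unsorted))))
    msg <- c(msg, "positions must be non-decreasing within chromosome")
  if (length(msg)) msg else TRUE
})

#' Variant-level QC report
#'
#' Per-variant call rate, MAF, Hardy-Weinberg exact P (computed on rounded
#' hard calls) and INFO, the per-filter failure counts, and the retained
#' variant count. Produced by [variantQC()].
#'
#' @export
setClass("QCReport",
  representation(variantStats = "DFrame", removed = "integer",
                 retained = "integer", thresholds = "list",
                 notes = "character"))

setValidity("QCReport", function(object) {
  n_any <- object@removed[["any_filter"]]
  if (nrow(object@variantStats) != object@retained + n_any)
    return("removal counts inconsistent with retained count")
  TRUE
})

#' Per-variant Cox scan results
#'
#' One row per variant: log hazard ratio per effect-allele dosage (`beta`),
#' its SE, HR with 95% CI, two-sided Wald P, subjects used, effect-allele
#' frequency and a convergence flag. Produced by [gwasScan()].
#'
#' @export
setClass("ScanResult",
  representation(results = "DFrame", covariates = "character",
                 ties = "character", thresholds = "numeric"))

setValidity("ScanResult", function(object) {
  need <- c("variant", "chrom", "pos", "eaf", "beta", "se", "hr",
            "ci_low", "ci_high", "p", "n_used", "converged")
  if (!all(need %in% colnames(object@results)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object@results)), collapse = ", ")))
  r <- object@results
  ok <- r$converged & !is.na(r$p)
  if (any(ok) && (any(r$p[ok] <= 0 | r$p[ok] > 1)))
    return("p must lie in (0, 1]")
  if (any(ok) && any(abs(r$hr[ok] - exp(r$beta[ok])) >
                       1e-8 * pmax(1, r$hr[ok])))
    return("hr must equal exp(beta)")
  if (any(ok & !is.na(r$ci_low) & r$ci_low > r$ci_high))
    return("CI bounds out of order")
  TRUE
})

#' Gene regions with a symmetric flank
#'
#' Gene intervals (stored as standard 1-based closed `GRanges`) plus the
#' flank, in bp, by which each gene is extended on both sides when variants
#' are assigned to genes (50 kb default for the enrichment analysis; 20 kb is
#' the convention for candidate-gene selection). BED input/output is 0-based
#' half-open.
#'
#' @export
setClass("GeneRegionSet",
  representation(regions = "GRanges", flank = "numeric"))

setValidity("GeneRegionSet", function(object) {
  if (length(object@flank) != 1L || !is.finite(object@flank) || object@flank < 0)
    return("flank must be a single value >= 0")
  if (is.null(names(object@regions)) && length(object@regions))
    return("regions must be named by gene")
  TRUE
})

#' Permutation enrichment result
#'
#' Observed counts of gene-set member SNPs below each P threshold, the B x
#' thresholds matrix of permutation-null counts, and the empirical P per
#' threshold (fraction of permutations with a count >= observed). Produced by
#' [permutationEnrichment()].
#'
#' @export
setClass("EnrichmentResult",
  representation(thresholds = "numeric", observed = "integer",
                 nullCounts = "matrix", empiricalP = "numeric",
                 B = "integer", seed = "integer", addOne = "logical"))

setValidity("EnrichmentResult", function(object) {
  if (any(object@empiricalP < 0 | object@empiricalP > 1))
    return("empirical P must lie in [0, 1]")
  if (any(object@nullCounts < 0) || any(object@nullCounts != round(object@nullCounts)))
    return("null counts must be non-negative integers")
  if (nrow(object@nullCounts) != object@B)
    return("nullCounts must have B rows")
  TRUE
})

#' Combined genetic + clinical risk score model
#'
#' Coefficients of a joint Cox fit over SNP dosages and clinical terms, the
#' training-set median score used as the high/low cutoff, the evaluation
#' horizon (months), and per-dataset metrics. Produced by [fitRiskModel()].
#'
#' @export
setClass("RiskModel",
  representation(coefficients = "numeric", snpIds = "character",
                 clinicalTerms = "character", cutoff = "numeric",
                 horizon = "numeric", metrics = "list"))

setValidity("RiskModel", function(object) {
  if (is.null(names(object@coefficients)))
    return("coefficients must be named")
  if (!is.finite(object@cutoff)) return("cutoff must be finite")
  if (!is.finite(object@horizon) || object@horizon <= 0)
    return("horizon must be a positive number of months")
  TRUE
})
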