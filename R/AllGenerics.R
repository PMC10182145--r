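#' @name accessors
#' @title Accessors for otoscan classes
#' @param x an otoscan object.
#' @param ... ignored.
#' @description Slot access for the package's S4 containers.
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x, ...) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x, ...) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x, ...) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("scanTable", function(x, ...) standardGeneric("scanTable"))

#' @rdname accessors
#' @export
setGeneric("variantStats", function(x, ...) standardGeneric("variantStats"))

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(x, ...) standardGeneric("empiricalP"))

#' @rdname accessors
#' @export
setGeneric("nullCounts", function(x, ...) standardGeneric("nullCounts"))

#' @rdname accessors
#' @export
setGeneric("observedCounts", function(x, ...) standardGeneric("observedCounts"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x, ...) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("flank", function(x, ...) standardGeneric("flank"))

#' @rdname accessors
#' @export
setGeneric("riskCutoff", function(x, ...) standardGeneric("riskCutoff"))

#' @rdname accessors
#' @export
setGeneric("modelTerms", function(x, ...) standardGeneric("modelTerms"))

#' @rdname accessors
#' @export
setGeneric("metrics", function(x, ...) standardGeneric("metrics"))

#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeData", function(x, ...)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("missingMask", "GenotypeData", function(x, ...)
  SummarizedExperiment::assay(x, "missing"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeData", function(x, ...) {
  rr <- SummarizedExperiment::rowRanges(x)
  S4Vectors::DataFrame(
    variant = rownames(x),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    SummarizedExperiment::rowData(x))
})

#' @rdname accessors
#' @export
setMethod("subjectIds", "GenotypeData", function(x, ...) colnames(x))

#' @rdname accessors
#' @export
setMethod("scanTable", "ScanResult", function(x, ...) x@results)

#' @rdname accessors
#' @export
setMethod("variantStats", "QCReport", function(x, ...) x@variantStats)

#' @rdname accessors
#' @export
setMethod("empiricalP", "EnrichmentResult", function(x, ...)
  setNames(x@empiricalP, format(x@thresholds, scientific = TRUE)))

#' @rdname accessors
#' @export
setMethod("nullCounts", "EnrichmentResult", function(x, ...) x@nullCounts)

#' @rdname accessors
#' @export
setMethod("observedCounts", "EnrichmentResult", function(x, ...)
  setNames(x@observed, format(x@thresholds, scientific = TRUE)))

#' @rdname accessors
#' @export
setMethod("regions", "GeneRegionSet", function(x, ...) x@regions)

#' @rdname accessors
#' @export
setMethod("flank", "GeneRegionSet", function(x, ...) x@flank)

#' @rdname accessors
#' @export
setMethod("coef", "RiskModel", function(object, ...) object@coefficients)

#' @rdname accessors
#' @export
setMethod("riskCutoff", "RiskModel", function(x, ...) x@cutoff)

#' @rdname accessors
#' @export
setMethod("modelTerms", "RiskModel", function(x, ...)
  list(snps = x@snpIds, clinical = x@clinicalTerms))

#' @rdname accessors
#' @export
setMethod("metrics", "RiskModel", function(x, ...) x@metrics)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_subjects, "subjects x", object@n_variants,
      "variants\n")
  cat("  MAF U(", object@maf_range[1], ", ", object@maf_range[2],
      "), LD blocks of ", object@ld_block_size, " (rho = ", object@ld_rho,
      "), missing rate ", object@missing_rate, "\n", sep = "")
  cat("  ", object@n_genes, " genes on ", object@genome_length,
      " bp; deafness fraction ", object@deafness_gene_fraction, "\n", sep = "")
  cat("  Weibull(shape ", object@baseline_shape, ", scale ",
      object@baseline_scale, " mo), admin censor ", object@admin_censor_time,
      " mo, dropout ", object@dropout_rate, "/mo\n", sep = "")
  cat("  causal SNP effects:", length(object@causal_effects),
      "| clinical effects:", length(object@clinical_effects),
      "| seed:", object@seed, "\n")
})

setMethod("show", "GenotypeData", function(object) {
  d <- dosage(object)
  cat("GenotypeData:", nrow(object), "variants x", ncol(object), "subjects\n")
  cat("  missing:",
      sprintf("%.2f%%", 100 * mean(missingMask(object))), "\n")
  methods::callNextMethod()
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", nrow(object@variantStats), "variants assessed,",
      object@retained, "retained\n")
  cat("  removed by filter (a variant may fail several):\n")
  for (nm in names(object@removed))
    cat(sprintf("    %-12s %d\n", nm, object@removed[[nm]]))
  for (n in object@notes) cat("  note:", n, "\n")
})

setMethod("show", "ScanResult", function(object) {
  r <- object@results
  cat("ScanResult:", nrow(r), "variants;",
      sum(r$converged), "converged\n")
  cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
  cat("  ties:", object@ties, "\n")
  p <- r$p[r$converged & !is.na(r$p)]
  if (length(p))
    cat(sprintf("  min P = %.3g; %d below suggestive (%g), %d genome-wide (%g)\n",
                min(p), sum(p < object@thresholds[["suggestive"]]),
                object@thresholds[["suggestive"]],
                sum(p < object@thresholds[["genomewide"]]),
                object@thresholds[["genomewide"]]))
})

setMethod("show", "GeneRegionSet", function(object) {
  cat("GeneRegionSet:", length(object@regions), "genes, flank",
      object@flank, "bp\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", object@B, "permutations\n")
  df <- data.frame(threshold = object@thresholds, observed = object@observed,
                   empirical_p = object@empiricalP)
  print(df, row.names = FALSE)
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel:", length(object@snpIds), "SNP +",
      length(object@clinicalTerms), "clinical terms; horizon",
      object@horizon, "months\n")
  cat("  training-median cutoff:", signif(object@cutoff, 4), "\n")
  for (nm in names(object@metrics)) {
    m <- object@metrics[[nm]]
    cat(sprintf("  %s: AUC %.3f, high-vs-low HR %.2f (P %.3g)\n",
                nm, m$auc, m$hr, m$p))
  }
})
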