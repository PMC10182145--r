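#' Construct a gene region set
#'
#' @param gr a named `GRanges` of gene bodies (1-based closed, as
#'   conventional for `GRanges`; BED readers/writers convert from 0-based
#'   half-open).
#' @param flank symmetric extension in bp applied when mapping variants
#'   (50 kb is the enrichment convention; 20 kb the candidate-gene one).
#' @return A [GeneRegionSet-class].
#' @export
geneRegionSet <- function(gr, flank = 50000) {
  methods::new("GeneRegionSet", regions = gr, flank = flank)
}

#' Map variants to flank-extended gene regions
#'
#' A variant at 1-based position q belongs to a gene iff
#' `gene_start - flank <= q <= gene_end + flank` (both boundaries included,
#' clipped at position 1); a variant inside several genes appears once in
#' the membership set. Genes restricted via `gene_subset` (e.g. the
#' deafness list) limit the mapping. Chromosomes present in the variants but
#' absent from the regions simply yield no matches; unknown chromosomes in
#' `gene_subset` raise a warning.
#'
#' @param variants a [GenotypeData-class], a [ScanResult-class], or a
#'   `data.frame` with `variant`, `chrom`, `pos`.
#' @param region_set a [GeneRegionSet-class].
#' @param gene_subset optional character vector of gene names to use.
#' @return list with `membership` (unique variant ids) and `per_gene`
#'   (named list of variant ids per gene).
#' @export
mapSnpsToRegions <- function(variants, region_set, gene_subset = NULL) {
  vt <- if (methods::is(variants, "GenotypeData")) {
    as.data.frame(variantInfo(variants)[, c("variant", "chrom", "pos")])
  } else if (methods::is(variants, "ScanResult")) {
    as.data.frame(scanTable(variants)[, c("variant", "chrom", "pos")])
  } else as.data.frame(variants)
  gr <- regions(region_set)
  if (!is.null(gene_subset)) {
    missing_genes <- setdiff(gene_subset, names(gr))
    if (length(missing_genes))
      warning("gene set entries absent from the annotation: ",
              paste(head(missing_genes, 5), collapse = ", "), call. = FALSE)
    gr <- gr[intersect(gene_subset, names(gr))]
  }
  if (length(gr) == 0L || nrow(vt) == 0L)
    return(list(membership = character(0),
                per_gene = setNames(list(), character(0))))
  fl <- flank(region_set)
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(pmax(1, GenomicRanges::start(gr) - fl),
                     GenomicRanges::end(gr) + fl))
  names(ext) <- names(gr)
  vgr <- GenomicRanges::GRanges(vt$chrom, IRanges::IRanges(vt$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(vgr, ext)
  per_gene <- lapply(seq_along(ext), function(j)
    vt$variant[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]])
  names(per_gene) <- names(ext)
  list(membership = unique(vt$variant[S4Vectors::queryHits(ov)]),
       per_gene = per_gene)
}

#' Count gene-set member variants below a P threshold
#'
#' @param scan a [ScanResult-class].
#' @param membership character vector of member variant ids.
#' @param threshold P cutoff in (0, 1]; the comparison is strict (`p <
#'   threshold`).
#' @return integer count of member variants with a valid converged P below
#'   the threshold.
#' @export
countSignificant <- function(scan, membership, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  r <- scanTable(scan)
  sum(r$variant %in% membership & r$converged & !is.na(r$p) &
        r$p < threshold)
}

#' Permutation-based gene-set enrichment
#'
#' Tests whether gene-set member variants are over-represented among the
#' scan's top signals. In each of `B` shuffles one random permutation of
#' subjects is applied jointly to the phenotype block (outcome time/event
#' and the clinical covariates) while genotypes and genotype-derived PCs
#' stay fixed; the adjusted Cox scan is rerun over member variants only
#' (counts are identical to a genome-wide rescan at a fraction of the cost)
#' and the number of member variants below each threshold is recorded. The
#' empirical P per threshold is the fraction of permutations whose count is
#' greater than or equal to the observed count (ties included); with
#' `add_one = TRUE` the (N+1)/(B+1) variant is used.
#'
#' @param g a [GenotypeData-class].
#' @param cohort cohort `data.frame`.
#' @param pcs optional PC matrix (not permuted: PCs travel with genotypes).
#' @param membership member variant ids (non-empty).
#' @param thresholds P cutoffs (default the reported range 5e-2 .. 5e-6).
#' @param B number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param config a [ScanConfig-class].
#' @param add_one use the (N+1)/(B+1) empirical-P estimator.
#' @param max_fits refuse jobs needing more than this many Cox fits.
#' @return An [EnrichmentResult-class].
#' @export
permutationEnrichment <- function(g, cohort, pcs = NULL, membership,
                                  thresholds = c(5e-2, 5e-3, 5e-4, 1e-4,
                                                 5e-5, 1e-5, 5e-6),
                                  B = 1000L, seed = 1L,
                                  config = scanConfig(),
                                  add_one = FALSE, max_fits = 5e6) {
  if (length(membership) == 0L)
    stop("membership set is empty; nothing to test", call. = FALSE)
  stopifnot(B >= 1)
  if (as.numeric(B) * length(membership) > max_fits)
    stop("B x |membership| = ", B * length(membership),
         " Cox fits exceeds max_fits = ", max_fits,
         "; reduce B, prune the member set, or raise max_fits",
         call. = FALSE)
  keep <- rownames(g) %in% membership
  gm <- g[keep, , drop = FALSE]
  obs_scan <- gwasScan(gm, cohort, pcs, config)
  observed <- vapply(thresholds, function(th)
    countSignificant(obs_scan, membership, th), numeric(1))

  idx <- match(colnames(gm), cohort$subject_id)
  cohort <- cohort[idx, , drop = FALSE]
  if (!is.null(pcs)) pcs <- pcs[colnames(gm), , drop = FALSE]
  n <- ncol(gm)
  set.seed(seed)
  null_counts <- matrix(0L, nrow = B, ncol = length(thresholds))
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    # phenotype block (clinical covariates + outcome) permuted jointly;
    # genotypes and PCs keep their subject order
    cohort_b <- cohort[perm, , drop = FALSE]
    cohort_b$subject_id <- cohort$subject_id
    scan_b <- gwasScan(gm, cohort_b, pcs, config)
    pb <- scanTable(scan_b)
    valid <- pb$converged & !is.na(pb$p)
    null_counts[b, ] <- vapply(thresholds, function(th)
      sum(valid & pb$p < th), integer(1L))
  }
  emp <- vapply(seq_along(thresholds), function(j) {
    hits <- sum(null_counts[, j] >= observed[j])
    if (add_one) (hits + 1) / (B + 1) else hits / B
  }, numeric(1))
  methods::new("EnrichmentResult", thresholds = thresholds,
               observed = as.integer(observed), nullCounts = null_counts,
               empiricalP = emp, B = as.integer(B), seed = as.integer(seed),
               addOne = add_one)
}
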