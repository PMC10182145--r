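#' Write genotypes as VCF v4.2
#'
#' Hard calls are written as GT (`0/0`, `0/1`, `1/1`, missing `./.`);
#' non-integer dosages are written as DS with 4 decimals. A per-variant
#' imputation INFO score, when present, is written as `INFO=` in the INFO
#' column. Output is deterministic.
#'
#' @param g a [GenotypeData-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(g, path) {
  d <- dosage(g)
  vi <- variantInfo(g)
  hard <- all(d[!is.na(d)] %in% c(0, 1, 2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=otoscan",
    sprintf("##contig=<ID=%s>", unique(vi$chrom)),
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation information score\">",
    if (hard)
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
    else
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t")), con)
  info_col <- ifelse(is.na(vi$info_score), ".",
                     sprintf("INFO=%.4f", vi$info_score))
  fmt <- if (hard) "GT" else "DS"
  for (i in seq_len(nrow(g))) {
    x <- d[i, ]
    gt <- if (hard) {
      out <- c("0/0", "0/1", "1/1")[x + 1]
      out[is.na(x)] <- "./."
      out
    } else {
      out <- sprintf("%.4f", x)
      out[is.na(x)] <- "."
      out
    }
    writeLines(paste(c(vi$chrom[i], vi$pos[i], vi$variant[i], vi$ref[i],
                       vi$alt[i], ".", "PASS", info_col[i], fmt, gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a biallelic VCF into a GenotypeData object
#'
#' GT is parsed to \{0, 1, 2, missing\}; a DS field, when present, is
#' preferred over GT. An `INFO=` key in the INFO column is captured as the
#' per-variant imputation score. Multiallelic records are rejected.
#'
#' @param path VCF file (v4.2, plain text or bgzipped).
#' @return A [GenotypeData-class].
#' @export
readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multiallelic records are not supported: ",
         paste(head(fix$ID[grepl(",", fix$ALT, fixed = TRUE)], 3),
               collapse = ", "), call. = FALSE)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    known <- !is.na(gt) & !grepl("\\.", gt)
    alleles <- gsub("[|/]", "", gt[known])
    if (any(!grepl("^[01]+$", alleles)))
      stop("non-biallelic allele codes in GT", call. = FALSE)
    d[known] <- vapply(strsplit(alleles, ""),
                       function(a) sum(a == "1"), numeric(1))
  } else stop("VCF has neither GT nor DS in FORMAT", call. = FALSE)
  info <- suppressWarnings(
    vcfR::extract.info(v, element = "INFO", as.numeric = TRUE))
  if (is.null(info)) info <- rep(NA_real_, nrow(fix))
  ids <- fix$ID
  if (anyNA(ids) || anyDuplicated(ids))
    ids <- sprintf("%s_%s", fix$CHROM, fix$POS)
  newGenotypeData(
    dosage = unname(d) * 1.0, missing = unname(is.na(d)),
    variant = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, info_score = info,
    subjects = colnames(d))
}

#' Write / read the phenotype table
#'
#' Tab-separated, one row per subject, columns as documented in
#' [simulateClinical()] plus `time` (months) and `event` (0/1). `NA` encodes
#' missing values.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `path` (writer) or the cohort `data.frame` (reader).
#' @export
writeCohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% colnames(x))
    stop("phenotype table must have a subject_id column", call. = FALSE)
  x$subject_id <- as.character(x$subject_id)
  validateCohort(x)
}

#' Validate the outcome columns of a cohort table
#'
#' @param cohort a cohort `data.frame`.
#' @return the validated table, invisibly usable.
#' @export
validateCohort <- function(cohort) {
  if (anyDuplicated(cohort$subject_id))
    stop("subject ids must be unique", call. = FALSE)
  if (!is.null(cohort$time) && any(cohort$time <= 0, na.rm = TRUE))
    stop("follow-up time must be > 0", call. = FALSE)
  if (!is.null(cohort$event) && !all(cohort$event %in% c(0L, 1L)))
    stop("event must be 0/1", call. = FALSE)
  cohort
}

#' Write / read gene regions as BED
#'
#' BED is 0-based half-open; internal storage is 1-based closed `GRanges`.
#' The 4th column carries the gene name.
#'
#' @param genes a [GeneRegionSet-class] (writer).
#' @param path file path.
#' @param flank flank in bp attached on read (default 50 kb, the enrichment
#'   convention; use 20 kb for candidate-gene mapping).
#' @return `path` (writer) or a [GeneRegionSet-class] (reader).
#' @export
writeGeneBed <- function(genes, path) {
  gr <- regions(genes)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = names(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneBed
#' @export
readGeneBed <- function(path, flank = 50000) {
  gr <- rtracklayer::import(path, format = "BED")
  names(gr) <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr) <- NULL
  geneRegionSet(gr, flank = flank)
}

#' Write / read a newline-delimited gene-set list
#'
#' @param genes character vector of gene names (writer).
#' @param path file path.
#' @return `path` (writer) or a character vector (reader).
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname writeGeneSet
#' @export
readGeneSet <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write a simulated dataset to standard formats
#'
#' Emits `genotypes.vcf` (VCF v4.2), `phenotypes.tsv`, `genes.bed` (0-based
#' half-open) and `deafness_genes.txt` under `out_dir`; a write-then-read
#' round trip reproduces the inputs exactly.
#'
#' @param genotypes a [GenotypeData-class].
#' @param cohort cohort `data.frame`.
#' @param genes a [GeneRegionSet-class].
#' @param deafness character vector of deafness gene names.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
writeDataset <- function(genotypes, cohort, genes, deafness, out_dir) {
  if (!identical(subjectIds(genotypes), cohort$subject_id))
    stop("subject ids of genotypes and cohort do not align", call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             bed = file.path(out_dir, "genes.bed"),
             gene_set = file.path(out_dir, "deafness_genes.txt"))
  writeGenotypeVcf(genotypes, paths[["vcf"]])
  writeCohort(cohort, paths[["phenotypes"]])
  writeGeneBed(genes, paths[["bed"]])
  writeGeneSet(deafness, paths[["gene_set"]])
  paths
}
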