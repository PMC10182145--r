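#' Build a simulation configuration
#'
#' Defaults emulate the statistical structure of a chemoradiotherapy cohort
#' followed for ototoxicity: 777 subjects, right-censored follow-up with a
#' median around 70 months and an event rate near 17%, LD-blocked biallelic
#' SNPs with MAF >= 0.01, and Table-1-like clinical marginals. Clinical
#' log-hazard effects default to the adjusted hazard ratios of the three
#' established risk factors (age >= 50: HR 1.72, T3-T4: HR 1.66, concurrent
#' cisplatin dose >= 155 mg/m2: HR 1.46).
#'
#' @param n_subjects,n_variants cohort and panel size.
#' @param maf_range ALT (minor) allele frequency range in (0, 0.5].
#' @param ld_block_size,ld_rho LD block length and AR(1) latent correlation.
#' @param missing_rate per-entry missingness probability (hard-call path).
#' @param n_genes,genome_length,gene_length_range gene layout (bp) on one
#'   synthetic chromosome.
#' @param deafness_gene_fraction fraction of genes in the deafness set.
#' @param deafness_variant_fraction target fraction of variants within
#'   `deafness_flank` of a deafness gene; `NA` places variants uniformly.
#' @param deafness_flank flank (bp) used when planting variant positions.
#' @param causal_effects named log-HR per variant id.
#' @param clinical_effects named log-HR per clinical design column.
#' @param baseline_shape,baseline_scale Weibull baseline hazard (months).
#' @param admin_censor_time administrative censoring (months).
#' @param dropout_rate exponential dropout hazard per month.
#' @param dosage_noise_sd SD of Gaussian dosage noise (0 = hard calls).
#' @param seed integer seed.
#' @return A validated [SimConfig-class] object.
#' @export
simConfig <- function(n_subjects = 777L, n_variants = 2000L,
                      maf_range = c(0.01, 0.5),
                      ld_block_size = 10L, ld_rho = 0.6,
                      missing_rate = 0.002,
                      n_genes = 60L, genome_length = 5e7,
                      gene_length_range = c(5000, 30000),
                      deafness_gene_fraction = 0.2,
                      deafness_variant_fraction = NA_real_,
                      deafness_flank = 50000,
                      causal_effects = numeric(0),
                      clinical_effects = c(age_ge50 = log(1.72),
                                           t_stage_t34 = log(1.66),
                                           concurrent_dose_ge155 = log(1.46)),
                      baseline_shape = 1.1, baseline_scale = 560,
                      admin_censor_time = 88, dropout_rate = 0.007,
                      dosage_noise_sd = 0, seed = 1L) {
  bad <- vapply(list(n_subjects, n_variants, ld_block_size, n_genes,
                     genome_length, seed),
                function(x) length(x) != 1L || !is.finite(x), logical(1))
  if (any(bad))
    stop("simConfig: scalar config values must be finite", call. = FALSE)
  methods::new("SimConfig",
    n_subjects = as.integer(n_subjects), n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    missing_rate = missing_rate, n_genes = as.integer(n_genes),
    genome_length = as.numeric(genome_length),
    gene_length_range = as.numeric(gene_length_range),
    deafness_gene_fraction = deafness_gene_fraction,
    deafness_variant_fraction = as.numeric(deafness_variant_fraction),
    deafness_flank = deafness_flank,
    causal_effects = causal_effects, clinical_effects = clinical_effects,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    admin_censor_time = admin_censor_time, dropout_rate = dropout_rate,
    dosage_noise_sd = dosage_noise_sd, seed = as.integer(seed))
}

variant_ids <- function(n) sprintf("snp%05d", seq_len(n))
subject_ids_for <- function(n) sprintf("S%04d", seq_len(n))

#' Simulate an LD-blocked genotype matrix
#'
#' Hard-call dosages in \{0, 1, 2\} are drawn per variant from Hardy-Weinberg
#' proportions at a MAF sampled uniformly from `maf_range`. Within each block
#' of `ld_block_size` consecutive variants an AR(1) latent Gaussian with
#' parameter `ld_rho` is thresholded at the HW quantiles, inducing LD that
#' decays with distance in the block. Missingness is applied independently at
#' `missing_rate`. With `dosage_noise_sd > 0`, clipped Gaussian noise
#' (quantized to 4 decimals) emulates imputed dosages and an INFO-like score
#' `1 - noise_var / (2 p (1-p))` is attached per variant.
#'
#' @param cfg a [SimConfig-class].
#' @param positions optional integer vector of 1-based variant positions
#'   (default: uniform draw over the genome, sorted). See
#'   [sampleVariantPositions()].
#' @return A [GenotypeData-class] (variants x subjects).
#' @export
simulateGenotypes <- function(cfg, positions = NULL) {
  methods::validObject(cfg)
  n <- cfg@n_subjects
  m <- cfg@n_variants
  set.seed(cfg@seed + 1L)
  maf <- runif(m, cfg@maf_range[1], cfg@maf_range[2])
  g <- matrix(0L, nrow = n, ncol = m)
  rho <- cfg@ld_rho
  start <- 1L
  while (start <= m) {
    L <- min(cfg@ld_block_size, m - start + 1L)
    z <- matrix(0, n, L)
    if (n > 0L) {
      z[, 1L] <- rnorm(n)
      if (L > 1L)
        for (k in 2:L) z[, k] <- rho * z[, k - 1L] + sqrt(1 - rho^2) * rnorm(n)
    }
    for (k in seq_len(L)) {
      p <- maf[start + k - 1L]
      q1 <- qnorm((1 - p)^2)
      q2 <- qnorm(1 - p^2)
      g[, start + k - 1L] <- (z[, k] > q1) + (z[, k] > q2)
    }
    start <- start + L
  }
  dose <- matrix(as.numeric(g), n, m)
  info <- rep(NA_real_, m)
  if (cfg@dosage_noise_sd > 0 && n > 0L) {
    dose <- pmin(pmax(dose + rnorm(n * m, sd = cfg@dosage_noise_sd), 0), 2)
    dose <- round(dose, 4L)  # 4-decimal quantization keeps VCF round trips exact
    info <- pmax(0, pmin(1, 1 - cfg@dosage_noise_sd^2 / (2 * maf * (1 - maf))))
  }
  mask <- matrix(runif(n * m) < cfg@missing_rate, n, m)
  dose[mask] <- NA_real_
  if (is.null(positions)) {
    if (cfg@genome_length < m)
      stop("genome_length too small for n_variants", call. = FALSE)
    positions <- sort(sample.int(cfg@genome_length, m))
  }
  stopifnot(length(positions) == m, !is.unsorted(positions))
  alleles <- matrix(c("A", "C", "G", "T")[
    cbind(sample.int(4L, m, replace = TRUE),
          sample.int(4L, m, replace = TRUE))], ncol = 2)
  swap <- alleles[, 1] == alleles[, 2]
  alleles[swap, 2] <- ifelse(alleles[swap, 1] == "A", "G", "A")
  newGenotypeData(
    dosage = t(dose), missing = t(mask),
    variant = variant_ids(m), chrom = "chr1", pos = as.integer(positions),
    ref = alleles[, 1], alt = alleles[, 2], info_score = info,
    subjects = subject_ids_for(n))
}

#' Construct a GenotypeData object from parts
#'
#' @param dosage variants x subjects numeric matrix in \[0, 2\] (NA where
#'   missing).
#' @param missing logical mask of the same shape (defaults to `is.na(dosage)`).
#' @param variant,chrom,pos,ref,alt,info_score per-variant metadata.
#' @param subjects subject ids.
#' @return A [GenotypeData-class].
#' @export
newGenotypeData <- function(dosage, missing = is.na(dosage), variant, chrom,
                            pos, ref = "A", alt = "G",
                            info_score = NA_real_, subjects) {
  m <- nrow(dosage)
  rr <- GenomicRanges::GRanges(rep_len(chrom, m),
                               IRanges::IRanges(start = pos, width = 1L))
  names(rr) <- variant
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    ref = rep_len(ref, m), alt = rep_len(alt, m),
    info_score = rep_len(info_score, m))
  dimnames(dosage) <- list(variant, subjects)
  dimnames(missing) <- list(variant, subjects)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage, missing = missing), rowRanges = rr)
  methods::new("GenotypeData", se)
}

#' Simulate a gene annotation and a deafness gene set
#'
#' Places `n_genes` non-overlapping gene intervals on one synthetic
#' chromosome (lengths uniform over `gene_length_range`) and assigns a
#' random subset of `deafness_gene_fraction` of them to the
#' hereditary-deafness set.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `genes` (a [GeneRegionSet-class] with
#'   `flank = cfg@deafness_flank`) and `deafness` (character vector of gene
#'   names; possibly empty).
#' @export
simulateGeneAnnotation <- function(cfg) {
  methods::validObject(cfg)
  set.seed(cfg@seed + 2L)
  len <- round(runif(cfg@n_genes, cfg@gene_length_range[1],
                     cfg@gene_length_range[2]))
  if (sum(len) > cfg@genome_length)
    stop("impossible packing: total gene length exceeds genome_length",
         call. = FALSE)
  slack <- cfg@genome_length - sum(len)
  gaps <- sort(runif(cfg@n_genes, 0, slack))
  starts1 <- floor(gaps + cumsum(c(0, len[-cfg@n_genes]))) + 1L  # 1-based
  nm <- sprintf("gene%03d", seq_len(cfg@n_genes))
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(start = starts1, width = len))
  names(gr) <- nm
  n_deaf <- round(cfg@deafness_gene_fraction * cfg@n_genes)
  deaf <- sort(sample(nm, n_deaf))
  list(genes = geneRegionSet(gr, flank = cfg@deafness_flank), deafness = deaf)
}

#' Sample variant positions with a planted in-region fraction
#'
#' Draws `n_variants` 1-based positions so that approximately
#' `deafness_variant_fraction` of them fall within `deafness_flank` bp of a
#' deafness gene (uniform over the genome when that fraction is `NA` or the
#' deafness set is empty).
#'
#' @param cfg a [SimConfig-class].
#' @param annotation output of [simulateGeneAnnotation()].
#' @return sorted integer positions of length `cfg@n_variants`.
#' @export
sampleVariantPositions <- function(cfg, annotation) {
  set.seed(cfg@seed + 3L)
  m <- cfg@n_variants
  f <- cfg@deafness_variant_fraction
  if (is.na(f) || length(annotation$deafness) == 0L)
    return(sort(sample.int(cfg@genome_length, m)))
  gr <- regions(annotation$genes)
  gr <- gr[annotation$deafness]
  ext <- IRanges::IRanges(
    pmax(1L, GenomicRanges::start(gr) - cfg@deafness_flank),
    pmin(cfg@genome_length, GenomicRanges::end(gr) + cfg@deafness_flank))
  ext <- IRanges::reduce(ext)
  inside_pool <- unlist(lapply(seq_along(ext), function(i)
    IRanges::start(ext)[i]:IRanges::end(ext)[i]))
  n_in <- round(f * m)
  inside <- sample(inside_pool, n_in, replace = n_in > length(inside_pool))
  outside <- integer(0)
  if (m - n_in > 0) {
    cand <- sample.int(cfg@genome_length, min(cfg@genome_length, 4L * m))
    cand <- cand[!overlapsAny_pos(cand, ext)]
    if (length(cand) < m - n_in)
      stop("genome too dense to place variants outside deafness regions",
           call. = FALSE)
    outside <- cand[seq_len(m - n_in)]
  }
  sort(c(inside, outside))
}

overlapsAny_pos <- function(pos, ir) {
  IRanges::overlapsAny(IRanges::IRanges(pos, width = 1L), ir)
}

#' Simulate clinical covariates
#'
#' Draws a complete covariate table with marginals patterned on an advanced
#' nasopharyngeal-carcinoma cohort: age ~ N(43, 9.5) truncated at 18, ~29%
#' female, ~63% T3-T4, ~30% N2-N3, EBV DNA with a point mass at zero and a
#' log-normal positive part, IMRT primary tumor dose ~ N(70.05, 0.15) Gy,
#' induction cisplatin mostly zero, concurrent cisplatin centred near 180
#' mg/m2, and binary comorbidity/lifestyle flags. All columns complete
#' except `ebv_dna`, which carries a small missing fraction (as real
#' pre-treatment load measurements do).
#'
#' @param cfg a [SimConfig-class].
#' @return `data.frame` with one row per subject (no outcome columns yet).
#' @export
simulateClinical <- function(cfg) {
  methods::validObject(cfg)
  set.seed(cfg@seed + 4L)
  n <- cfg@n_subjects
  if (n == 0L) {
    out <- data.frame(subject_id = character(0), age = numeric(0),
                      sex = character(0), t_stage = character(0),
                      n_stage = character(0), overall_stage = character(0),
                      ebv_dna = numeric(0), treatment_modality = character(0),
                      primary_tumor_dose = numeric(0),
                      induction_cisplatin_dose = numeric(0),
                      concurrent_cisplatin_dose = numeric(0),
                      smoking = integer(0), drinking = integer(0),
                      hypertension = integer(0), diabetes = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  age <- round(pmax(18, rnorm(n, 43, 9.5)), 1)
  sex <- ifelse(runif(n) < 0.287, "female", "male")
  t_stage <- ifelse(runif(n) < 0.629, "T3-T4", "T1-T2")
  n_stage <- ifelse(runif(n) < 0.299, "N2-N3", "N0-N1")
  # overall stage correlates with T stage
  overall_stage <- ifelse(t_stage == "T3-T4" | runif(n) < 0.28,
                          "III-IV", "I-II")
  ebv <- ifelse(runif(n) < 0.30, 0, round(exp(rnorm(n, 8.6, 2.0))))
  ebv[runif(n) < 0.036] <- NA
  modality <- ifelse(runif(n) < 0.435, "CCRT+IC/AC", "CCRT")
  dose <- round(rnorm(n, 70.05, 0.15), 1)
  ind_cis <- ifelse(modality == "CCRT+IC/AC",
                    round(pmax(0, rnorm(n, 140, 40))), 0)
  conc_cis <- ifelse(runif(n) < 0.22, 0, round(pmax(0, rnorm(n, 185, 45))))
  data.frame(
    subject_id = subject_ids_for(n), age = age, sex = sex,
    t_stage = t_stage, n_stage = n_stage, overall_stage = overall_stage,
    ebv_dna = ebv, treatment_modality = modality,
    primary_tumor_dose = dose, induction_cisplatin_dose = ind_cis,
    concurrent_cisplatin_dose = conc_cis,
    smoking = as.integer(runif(n) < 0.296),
    drinking = as.integer(runif(n) < 0.130),
    hypertension = as.integer(runif(n) < 0.053),
    diabetes = as.integer(runif(n) < 0.019),
    stringsAsFactors = FALSE)
}

#' Simulate censored time-to-event outcomes
#'
#' Event times follow a proportional-hazards model with Weibull baseline:
#' the survivor function given linear predictor `lp` is
#' `exp(-(t/scale)^shape * exp(lp))`, with
#' `lp = sum(clinical_effects * design) + sum(causal_effects * dosage)`.
#' Observed time is the minimum of the event time, an exponential dropout
#' time and the administrative censoring time; the event indicator is set
#' accordingly and times are strictly positive. Missing dosages contribute
#' through their variant mean (missingness is rare by default).
#'
#' @param genotypes a [GenotypeData-class].
#' @param clinical covariate table from [simulateClinical()].
#' @param cfg a [SimConfig-class].
#' @return `clinical` with `time` (months) and `event` (0/1) columns added.
#' @export
simulateOutcomes <- function(genotypes, clinical, cfg) {
  methods::validObject(cfg)
  if (!identical(subjectIds(genotypes), clinical$subject_id))
    stop("subject ids of genotypes and clinical table do not align",
         call. = FALSE)
  set.seed(cfg@seed + 5L)
  n <- nrow(clinical)
  lp <- rep(0, n)
  if (length(cfg@clinical_effects)) {
    des <- clinicalDesign(clinical)
    missing_terms <- setdiff(names(cfg@clinical_effects), colnames(des))
    if (length(missing_terms))
      stop("unknown clinical effect term(s): ",
           paste(missing_terms, collapse = ", "), call. = FALSE)
    lp <- lp + as.numeric(des[, names(cfg@clinical_effects), drop = FALSE] %*%
                            cfg@clinical_effects)
  }
  if (length(cfg@causal_effects)) {
    unknown <- setdiff(names(cfg@causal_effects), rownames(genotypes))
    if (length(unknown))
      stop("unknown variant id(s) in causal_effects: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    d <- dosage(genotypes)[names(cfg@causal_effects), , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      row <- d[i, ]
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      lp <- lp + cfg@causal_effects[i] * row
    }
  }
  u <- runif(n)
  t_event <- cfg@baseline_scale * (-log(u) / exp(lp))^(1 / cfg@baseline_shape)
  t_drop <- if (cfg@dropout_rate > 0) rexp(n, cfg@dropout_rate) else rep(Inf, n)
  t_cens <- pmin(t_drop, cfg@admin_censor_time)
  time <- pmax(pmin(t_event, t_cens), 1e-6)
  clinical$time <- time
  clinical$event <- as.integer(t_event <= t_cens)
  clinical
}

#' Simulate a complete analysis-ready dataset
#'
#' Orchestrates annotation, variant placement, genotypes, clinical
#' covariates and outcomes under one configuration.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `genotypes`, `cohort` (with time/event), `genes`
#'   (a [GeneRegionSet-class]) and `deafness` (gene names).
#' @export
simulateDataset <- function(cfg) {
  ann <- simulateGeneAnnotation(cfg)
  pos <- sampleVariantPositions(cfg, ann)
  g <- simulateGenotypes(cfg, positions = pos)
  clin <- simulateClinical(cfg)
  cohort <- simulateOutcomes(g, clin, cfg)
  list(genotypes = g, cohort = cohort, genes = ann$genes,
       deafness = ann$deafness)
}
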