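#' Build / read a pipeline configuration
#'
#' A pipeline run is driven by one plain list (optionally loaded from YAML):
#' either a `simulate` block (arguments to [simConfig()]) or an `inputs`
#' block (paths: `vcf`, `phenotypes`, `bed`, `gene_set`), plus optional
#' `qc`, `pca`, `scan`, `enrich` and `risk` blocks overriding stage
#' defaults. Referenced input paths must exist at validation time and every
#' random stage carries an explicit seed.
#'
#' @param config a list, or the path of a YAML file holding one.
#' @return the validated config list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    qc = list(call_rate_min = 0.95, maf_min = 0.01, hwe_p_min = 1e-12,
              info_min = 0.8),
    pca = list(k = 2L),
    scan = list(covariates = c("age_ge50", "t_stage_t34",
                               "concurrent_dose_ge155", "PC1", "PC2")),
    enrich = list(flank = 50000, B = 200L, seed = 1L,
                  thresholds = c(5e-2, 5e-3, 1e-3, 1e-4)),
    risk = list(p_threshold = 1e-3, max_snps = 8L,
                clinical_terms = c("age_ge50", "t_stage_t34",
                                   "concurrent_dose_ge155"),
                horizon = 60, split_ratio = 0.5, split_seed = 1L))
  for (nm in names(defaults))
    config[[nm]] <- modifyList(defaults[[nm]],
                               if (is.null(config[[nm]])) list()
                               else config[[nm]])
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs a 'simulate' block or an 'inputs' block",
         call. = FALSE)
  if (!is.null(config$inputs)) {
    need <- c("vcf", "phenotypes", "bed", "gene_set")
    missing_keys <- setdiff(need, names(config$inputs))
    if (length(missing_keys))
      stop("inputs block is missing: ", paste(missing_keys, collapse = ", "),
           call. = FALSE)
    absent <- !vapply(config$inputs[need], file.exists, logical(1))
    if (any(absent))
      stop("input file(s) not found: ",
           paste(unlist(config$inputs[need][absent]), collapse = ", "),
           call. = FALSE)
  }
  config
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or read inputs), variant QC, genotype PCA,
#' clinical Cox tables, the per-SNP Cox scan with QQ/Manhattan tables and
#' lambda_GC, permutation gene-set enrichment against the deafness gene
#' regions, and the combined risk score with train/test validation. All
#' artifacts are written under `out_dir` and listed in a manifest with MD5
#' content hashes; the returned report summarizes QC removals, lambda_GC,
#' suggestive loci, enrichment empirical P and risk-model metrics. A stage
#' failure aborts with the failing stage named; artifacts already written
#' are preserved.
#'
#' @param config list or YAML path (see [pipelineConfig()]).
#' @param out_dir output directory.
#' @return the run report (list), invisibly; also written as
#'   `report.json`.
#' @export
runPipeline <- function(config, out_dir) {
  config <- pipelineConfig(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(obj, file, writer = function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE)) {
    p <- file.path(out_dir, file)
    writer(obj, p)
    artifacts <<- c(artifacts, p)
    p
  }

  if (!is.null(config$simulate)) {
    dat <- run_stage("simulate", {
      cfg <- do.call(simConfig, config$simulate)
      d <- simulateDataset(cfg)
      writeDataset(d$genotypes, d$cohort, d$genes, d$deafness,
                   file.path(out_dir, "data"))
      d
    })
    genotypes <- dat$genotypes
    cohort <- dat$cohort
    genes <- dat$genes
    deafness <- dat$deafness
    artifacts <- c(artifacts, list.files(file.path(out_dir, "data"),
                                         full.names = TRUE))
  } else {
    genotypes <- run_stage("read", readGenotypeVcf(config$inputs$vcf))
    cohort <- run_stage("read", readCohort(config$inputs$phenotypes))
    genes <- run_stage("read", readGeneBed(config$inputs$bed,
                                           flank = config$enrich$flank))
    deafness <- run_stage("read", readGeneSet(config$inputs$gene_set))
  }

  qc <- run_stage("qc", do.call(variantQC, c(list(genotypes), config$qc)))
  emit(as.data.frame(variantStats(qc$report)), "qc_report.tsv")
  gq <- qc$genotypes

  pca <- run_stage("pca", genotypePCA(gq, config$pca$k))
  emit(data.frame(subject_id = rownames(pca$scores), pca$scores),
       "pcs.tsv")

  clin_tab <- run_stage("clinical", {
    vars <- c("age_ge50", "sex_female", "t_stage_t34", "n_stage_n23",
              "treat_icac", "dose_ge702", "induction_dose_ge162",
              "concurrent_dose_ge155", "smoking", "drinking",
              "hypertension", "diabetes")
    do.call(rbind, lapply(vars, function(v)
      tryCatch(univariateCox(cohort, v), error = function(e) NULL)))
  })
  emit(clin_tab, "clinical_univariate.tsv")

  scan <- run_stage("scan", {
    sc <- scanConfig(covariates = config$scan$covariates)
    gwasScan(gq, cohort, pca$scores, sc)
  })
  emit(as.data.frame(scanTable(scan)), "scan.tsv")
  tabs <- qqManhattanTables(scan)
  emit(tabs$qq, "qq.tsv")
  emit(tabs$manhattan, "manhattan.tsv")
  lambda <- genomicInflation(scanTable(scan)$p[scanTable(scan)$converged])

  enrich <- run_stage("enrich", {
    mem <- mapSnpsToRegions(gq, geneRegionSet(regions(genes),
                                              flank = config$enrich$flank),
                            gene_subset = deafness)
    if (length(mem$membership) == 0L) NULL
    else permutationEnrichment(gq, cohort, pca$scores, mem$membership,
                               thresholds = config$enrich$thresholds,
                               B = config$enrich$B,
                               seed = config$enrich$seed,
                               config = scanConfig(
                                 covariates = config$scan$covariates))
  })
  if (!is.null(enrich)) {
    emit(data.frame(threshold = enrich@thresholds,
                    observed = enrich@observed,
                    empirical_p = enrich@empiricalP),
         "enrichment.tsv")
    emit(as.data.frame(nullCounts(enrich)), "null_counts.tsv")
  }

  risk <- run_stage("risk", {
    rc <- config$risk
    snp_ids <- rc$snp_ids
    if (is.null(snp_ids)) {
      st <- as.data.frame(scanTable(scan))
      st <- st[st$converged & !is.na(st$p) & st$p < rc$p_threshold, ]
      snp_ids <- head(st$variant[order(st$p)], rc$max_snps)
    }
    if (length(snp_ids) == 0L) NULL
    else {
      parts <- splitTrainTest(cohort, rc$split_ratio, rc$split_seed)
      model <- fitRiskModel(parts$train, gq, snp_ids,
                            clinical_terms = rc$clinical_terms,
                            horizon = rc$horizon)
      evaluateRiskModel(model, list(
        train = list(cohort = parts$train, genotypes = gq),
        test = list(cohort = parts$test, genotypes = gq),
        all = list(cohort = cohort, genotypes = gq)))
    }
  })
  if (!is.null(risk))
    emit(list(coefficients = as.list(coef(risk)), cutoff = riskCutoff(risk),
              horizon = risk@horizon, metrics = metrics(risk)),
         "risk_model.json",
         writer = function(o, p) jsonlite::write_json(o, p,
                                                      auto_unbox = TRUE,
                                                      digits = NA))

  st <- as.data.frame(scanTable(scan))
  suggestive <- st[st$converged & !is.na(st$p) &
                     st$p < scan@thresholds[["suggestive"]], ]
  report <- list(
    n_subjects = nrow(cohort), n_events = sum(cohort$event),
    qc = list(assessed = nrow(genotypes), retained = qc$report@retained,
              removed = as.list(qc$report@removed)),
    lambda_gc = lambda,
    suggestive_loci = suggestive$variant[order(suggestive$p)],
    enrichment = if (is.null(enrich)) "absent: empty deafness membership"
                 else list(thresholds = enrich@thresholds,
                           observed = enrich@observed,
                           empirical_p = enrich@empiricalP),
    risk = if (is.null(risk)) "absent: no SNPs selected"
           else list(terms = names(coef(risk)), cutoff = riskCutoff(risk),
                     metrics = metrics(risk)),
    config = config)
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  artifacts <- c(artifacts, rp)
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(report)
}
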