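#' Scan configuration
#'
#' Covariate set, tie handling, convergence control and the significance
#' thresholds used in reporting (genome-wide 5.0e-8, suggestive 1.0e-5).
#' Default covariates are the cohort's three independent clinical risk
#' factors plus the first two genotype principal components.
#'
#' @slot covariates design columns entered alongside each SNP.
#' @slot ties,eps,maxiter Newton-Raphson control (see [coxFit()]).
#' @slot thresholds named numeric: `genomewide`, `suggestive`.
#' @export
setClass("ScanConfig",
  representation(covariates = "character", ties = "character",
                 eps = "numeric", maxiter = "integer",
                 thresholds = "numeric"))

setValidity("ScanConfig", function(object) {
  th <- object@thresholds
  if (!all(c("genomewide", "suggestive") %in% names(th)))
    return("thresholds must name 'genomewide' and 'suggestive'")
  if (any(th <= 0 | th >= 1)) return("thresholds must lie in (0, 1)")
  TRUE
})

#' @param covariates,ties,eps,maxiter,thresholds see slots.
#' @rdname ScanConfig-class
#' @export
scanConfig <- function(covariates = c("age_ge50", "t_stage_t34",
                                      "concurrent_dose_ge155", "PC1", "PC2"),
                       ties = "efron", eps = 1e-9, maxiter = 50L,
                       thresholds = c(genomewide = 5e-8, suggestive = 1e-5)) {
  methods::new("ScanConfig", covariates = covariates, ties = ties,
               eps = eps, maxiter = as.integer(maxiter),
               thresholds = thresholds)
}

# Assemble the fixed covariate matrix: clinicalDesign columns and/or PC
# columns, in the order requested.
scan_covariate_matrix <- function(cohort, pcs, covariates) {
  if (length(covariates) == 0L)
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  des <- clinicalDesign(cohort)
  cols <- lapply(covariates, function(v) {
    if (v %in% colnames(des)) return(des[, v])
    if (!is.null(pcs) && v %in% colnames(pcs)) return(pcs[, v])
    if (v %in% colnames(cohort)) return(as.numeric(cohort[[v]]))
    stop("unknown covariate: ", v, call. = FALSE)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Per-SNP additive Cox proportional-hazards scan
#'
#' Each variant's effect-allele (ALT) dosage enters a Cox model additively
#' alongside the fixed covariates. Subjects missing that variant's genotype
#' (or any covariate) are dropped for that variant only; `n_used` records
#' the analysed count. Monomorphic or collinear variants are emitted with
#' `converged = FALSE`.
#'
#' @param g a [GenotypeData-class] (post-QC).
#' @param cohort cohort `data.frame` with `time`, `event`, aligned to the
#'   subjects of `g` by `subject_id`.
#' @param pcs optional subjects x k PC matrix from [genotypePCA()].
#' @param config a [ScanConfig-class].
#' @return A [ScanResult-class].
#' @export
gwasScan <- function(g, cohort, pcs = NULL, config = scanConfig()) {
  methods::validObject(config)
  idx <- match(colnames(g), cohort$subject_id)
  if (anyNA(idx)) stop("cohort is missing genotyped subjects", call. = FALSE)
  cohort <- cohort[idx, , drop = FALSE]
  if (!is.null(pcs)) pcs <- pcs[colnames(g), , drop = FALSE]
  C <- scan_covariate_matrix(cohort, pcs, config@covariates)
  time <- cohort$time
  event <- as.integer(cohort$event)
  d <- dosage(g)
  base_ok <- complete.cases(C) & !is.na(time) & !is.na(event)
  vi <- variantInfo(g)
  m <- nrow(g)
  eaf <- beta <- se <- p_val <- rep(NA_real_, m)
  n_used <- integer(m)
  converged <- logical(m)
  all_ok <- all(base_ok) && !anyNA(d)
  for (i in seq_len(m)) {
    x <- d[i, ]
    if (all_ok) {
      ok_x <- x; ok_t <- time; ok_e <- event; Ck <- C; n_ok <- length(x)
    } else {
      ok <- base_ok & !is.na(x)
      n_ok <- sum(ok)
      ok_x <- x[ok]; ok_t <- time[ok]; ok_e <- event[ok]
      Ck <- C[ok, , drop = FALSE]
    }
    n_used[i] <- n_ok
    if (n_ok == 0L || sum(ok_e) == 0L) next
    eaf[i] <- mean(ok_x) / 2
    fit <- coxFit(cbind(dose = ok_x, Ck), ok_t, ok_e, ties = config@ties,
                  eps = config@eps, maxiter = config@maxiter)
    if (!fit$converged) next
    beta[i] <- fit$beta[["dose"]]
    se[i] <- fit$se[["dose"]]
    p_val[i] <- fit$p[["dose"]]
    converged[i] <- TRUE
  }
  res <- data.frame(
    variant = vi$variant, chrom = vi$chrom, pos = vi$pos,
    ref = vi$ref, alt = vi$alt, eaf = eaf, beta = beta, se = se,
    hr = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se), p = p_val, n_used = n_used,
    converged = converged, stringsAsFactors = FALSE)
  methods::new("ScanResult", results = S4Vectors::DataFrame(res),
               covariates = config@covariates, ties = config@ties,
               thresholds = config@thresholds)
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`; a value
#' near 1 indicates the observed P distribution matches the global null.
#'
#' @param p_values vector of P values (NA ignored).
#' @return lambda_GC.
#' @export
genomicInflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no valid P values", call. = FALSE)
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' QQ and Manhattan plot tables
#'
#' @param scan a [ScanResult-class].
#' @return list with `qq` (`expected`, `observed` on the -log10 scale,
#'   sorted so observed is non-increasing) and `manhattan`
#'   (`variant`, `chrom`, `pos`, `neglog10p`), covering variants with a
#'   valid converged P.
#' @export
qqManhattanTables <- function(scan) {
  r <- as.data.frame(scanTable(scan))
  r <- r[r$converged & !is.na(r$p), , drop = FALSE]
  if (nrow(r) == 0L) stop("no valid P values in scan", call. = FALSE)
  m <- nrow(r)
  ord <- order(r$p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(r$p[ord]))
  manhattan <- data.frame(variant = r$variant, chrom = r$chrom, pos = r$pos,
                          neglog10p = -log10(r$p))
  list(qq = qq, manhattan = manhattan)
}

#' Stratified association analysis of one variant
#'
#' Refits the adjusted Cox model for a single variant within each level of
#' each stratifying variable, dropping the stratifying variable from the
#' covariates when it is one of them. Strata without events are reported
#' with `converged = FALSE` rather than omitted.
#'
#' @param g a [GenotypeData-class].
#' @param cohort cohort `data.frame`.
#' @param pcs optional PC matrix.
#' @param variant_id variant to test.
#' @param strata character vector of [clinicalDesign()] column names to
#'   stratify on.
#' @param config a [ScanConfig-class].
#' @return `data.frame`: stratum variable, level, n, events, hr, ci, p,
#'   converged.
#' @export
stratifiedAnalysis <- function(g, cohort, pcs = NULL, variant_id,
                               strata, config = scanConfig()) {
  if (!variant_id %in% rownames(g))
    stop("unknown variant: ", variant_id, call. = FALSE)
  idx <- match(colnames(g), cohort$subject_id)
  cohort <- cohort[idx, , drop = FALSE]
  if (!is.null(pcs)) pcs <- pcs[colnames(g), , drop = FALSE]
  des <- clinicalDesign(cohort)
  x <- dosage(g)[variant_id, ]
  out <- list()
  for (sv in strata) {
    sval <- des[, sv]
    for (lev in sort(unique(sval[!is.na(sval)]))) {
      sel <- !is.na(sval) & sval == lev
      covs <- setdiff(config@covariates, sv)
      row <- data.frame(stratum = sv, level = lev, n = sum(sel),
                        events = sum(cohort$event[sel], na.rm = TRUE),
                        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, converged = FALSE)
      if (sum(sel) > 0 && row$events > 0) {
        C <- scan_covariate_matrix(cohort[sel, , drop = FALSE],
                                   if (is.null(pcs)) NULL
                                   else pcs[sel, , drop = FALSE], covs)
        ok <- complete.cases(C) & !is.na(x[sel])
        if (any(ok) && sum(cohort$event[sel][ok]) > 0) {
          fit <- coxFit(cbind(dose = x[sel][ok], C[ok, , drop = FALSE]),
                        cohort$time[sel][ok], cohort$event[sel][ok],
                        ties = config@ties)
          if (fit$converged) {
            row$hr <- fit$hr[["dose"]]; row$ci_low <- fit$ci_low[["dose"]]
            row$ci_high <- fit$ci_high[["dose"]]; row$p <- fit$p[["dose"]]
            row$converged <- TRUE
          }
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group plus the standard log-rank
#' chi-square.
#'
#' @param time,event follow-up and 0/1 event indicator.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `curves` (`group`, `time`, `n_risk`, `n_event`,
#'   `survival`), `chisq`, `df`, `p`.
#' @export
kmLogrank <- function(time, event, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop("at least two non-empty groups are required", call. = FALSE)
  sf <- survfit(Surv(time, event) ~ groups)
  strata_names <- sub("^groups=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(group = strata_names, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       survival = sf$surv)
  sd <- survdiff(Surv(time, event) ~ groups)
  df <- length(sd$n) - 1
  list(curves = curves, chisq = sd$chisq, df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}
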