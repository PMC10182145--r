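#' Binary clinical design coding
#'
#' Codes the cohort's clinical covariates as the binary indicators used in
#' the Cox models: age >= 50 years, female sex, T3-T4, N2-N3, overall stage
#' III-IV, EBV DNA >= 4000 copies/ml, induction + adjuvant chemotherapy,
#' primary tumor dose >= 70.2 Gy, induction cisplatin >= 162 mg/m2,
#' concurrent cisplatin >= 155 mg/m2, plus the raw binary flags. Cutoffs are
#' the ROC-derived values of the cohort analysis; override them via
#' `cutoffs`.
#'
#' @param cohort cohort `data.frame`.
#' @param cutoffs named list overriding any of `age`, `ebv`, `dose`,
#'   `induction`, `concurrent`.
#' @return numeric matrix, one row per subject. `ebv_ge4000` is `NA` where
#'   EBV DNA is missing.
#' @export
clinicalDesign <- function(cohort, cutoffs = list()) {
  cut <- modifyList(list(age = 50, ebv = 4000, dose = 70.2,
                         induction = 162, concurrent = 155), cutoffs)
  n <- nrow(cohort)
  col <- function(nm) if (nm %in% colnames(cohort)) cohort[[nm]] else rep(NA, n)
  m <- cbind(
    age_ge50 = as.numeric(col("age") >= cut$age),
    sex_female = as.numeric(col("sex") == "female"),
    t_stage_t34 = as.numeric(col("t_stage") == "T3-T4"),
    n_stage_n23 = as.numeric(col("n_stage") == "N2-N3"),
    stage_34 = as.numeric(col("overall_stage") == "III-IV"),
    ebv_ge4000 = as.numeric(col("ebv_dna") >= cut$ebv),
    treat_icac = as.numeric(col("treatment_modality") == "CCRT+IC/AC"),
    dose_ge702 = as.numeric(col("primary_tumor_dose") >= cut$dose),
    induction_dose_ge162 = as.numeric(col("induction_cisplatin_dose") >=
                                        cut$induction),
    concurrent_dose_ge155 = as.numeric(col("concurrent_cisplatin_dose") >=
                                         cut$concurrent),
    smoking = as.numeric(col("smoking")),
    drinking = as.numeric(col("drinking")),
    hypertension = as.numeric(col("hypertension")),
    diabetes = as.numeric(col("diabetes")))
  rownames(m) <- cohort$subject_id
  m
}

#' Cohort summary
#'
#' Counts, event proportion, and median/IQR summaries in the conventions of
#' a clinical Table 1: percentages to one decimal, medians and quartiles by
#' linear interpolation of the sorted values.
#'
#' @param cohort cohort `data.frame` with `time` and `event`.
#' @return list with `n`, `events`, `event_percent`, `continuous`
#'   (median/Q1/Q3 per continuous variable) and `categorical` (per-level
#'   counts and percentages).
#' @export
cohortSummary <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)
  events <- sum(cohort$event)
  cont_vars <- intersect(c("time", "age", "ebv_dna", "primary_tumor_dose",
                           "induction_cisplatin_dose",
                           "concurrent_cisplatin_dose"), colnames(cohort))
  cont <- do.call(rbind, lapply(cont_vars, function(v) {
    q <- quantile(cohort[[v]], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(variable = v, median = q[2], q1 = q[1], q3 = q[3])
  }))
  cat_vars <- intersect(c("event", "sex", "t_stage", "n_stage",
                          "overall_stage", "treatment_modality", "smoking",
                          "drinking", "hypertension", "diabetes"),
                        colnames(cohort))
  cat <- do.call(rbind, lapply(cat_vars, function(v) {
    x <- cohort[[v]]
    x[is.na(x)] <- "NA"
    tab <- table(x)
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               percent = round(100 * as.integer(tab) / n, 1))
  }))
  list(n = n, events = events,
       event_percent = round(100 * events / n, 1),
       continuous = cont, categorical = cat)
}

#' ROC-optimal cutoff by Youden's J
#'
#' Scans all observed values as candidate cutoffs under the rule
#' "value >= cutoff is positive" and returns the cutoff maximizing
#' J = sensitivity + specificity - 1; ties are broken by the smaller cutoff.
#'
#' @param values continuous covariate.
#' @param outcome binary outcome (0/1).
#' @return list with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
rocCutoff <- function(values, outcome) {
  ok <- !is.na(values) & !is.na(outcome)
  values <- values[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  if (length(unique(values)) < 2)
    stop("values are constant; no cutoff exists", call. = FALSE)
  cand <- sort(unique(values))
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  j <- vapply(cand, function(cc) {
    sens <- sum(values >= cc & outcome == 1) / n_pos
    spec <- sum(values < cc & outcome == 0) / n_neg
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)  # which.max takes the first = smallest cutoff on ties
  cc <- cand[best]
  list(cutoff = cc, j = j[best],
       sensitivity = sum(values >= cc & outcome == 1) / n_pos,
       specificity = sum(values < cc & outcome == 0) / n_neg)
}

cox_term_table <- function(fit, terms) {
  s <- summary(fit)
  beta <- s$coefficients[, "coef"]
  se <- s$coefficients[, "se(coef)"]
  data.frame(term = terms, beta = beta, se = se, hr = exp(beta),
             ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
             p = 2 * pnorm(-abs(beta / se)),
             converged = rep(is.finite(fit$loglik[2]) &
                               all(is.finite(se)), length(beta)),
             row.names = NULL)
}

resolve_clinical_term <- function(cohort, variable) {
  if (variable %in% colnames(cohort)) {
    x <- cohort[[variable]]
    if (is.character(x)) x <- as.numeric(factor(x)) - 1
    return(x)
  }
  des <- clinicalDesign(cohort)
  if (variable %in% colnames(des)) return(des[, variable])
  stop("unknown clinical variable: ", variable, call. = FALSE)
}

#' Univariate Cox regression of a clinical variable
#'
#' Single-term Cox proportional-hazards fit (Efron ties); the variable may
#' be a raw cohort column or a [clinicalDesign()] indicator name.
#'
#' @param cohort cohort `data.frame` with `time`, `event`.
#' @param variable column name.
#' @return one-row `data.frame`: term, beta, se, hr, ci_low, ci_high,
#'   two-sided Wald p, converged.
#' @export
univariateCox <- function(cohort, variable) {
  x <- resolve_clinical_term(cohort, variable)
  ok <- !is.na(x)
  if (length(unique(x[ok])) < 2)
    stop("variable is constant: ", variable, call. = FALSE)
  fit <- tryCatch(
    coxph(Surv(cohort$time[ok], cohort$event[ok]) ~ x[ok],
          control = coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      f <- suppressWarnings(
        coxph(Surv(cohort$time[ok], cohort$event[ok]) ~ x[ok],
              control = coxph.control(eps = 1e-9, iter.max = 50)))
      attr(f, "nonconverged") <- TRUE
      f
    })
  out <- cox_term_table(fit, variable)
  if (isTRUE(attr(fit, "nonconverged"))) out$converged <- FALSE
  out
}

#' Multivariate Cox regression of clinical variables
#'
#' Joint Cox fit over the requested variables. A rank-deficient design is
#' rejected with the collinear columns named. Use [selectUnivariate()] for
#' the optional screening rule (carry forward variables univariately
#' significant at `alpha`).
#'
#' @param cohort cohort `data.frame`.
#' @param variables character vector of cohort columns or
#'   [clinicalDesign()] indicator names.
#' @return `data.frame` with one row per variable (adjusted HR, CI, Wald P).
#' @export
multivariateCox <- function(cohort, variables) {
  X <- vapply(variables, function(v) resolve_clinical_term(cohort, v),
              numeric(nrow(cohort)))
  ok <- complete.cases(X) & !is.na(cohort$time) & !is.na(cohort$event)
  X <- X[ok, , drop = FALSE]
  qr_x <- qr(cbind(1, scale(X, scale = FALSE)))
  if (qr_x$rank < ncol(X) + 1) {
    dropped <- variables[qr_x$pivot[-seq_len(qr_x$rank)] - 1L]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- coxph(Surv(cohort$time[ok], cohort$event[ok]) ~ X,
               control = coxph.control(eps = 1e-9, iter.max = 50))
  cox_term_table(fit, variables)
}

#' Univariate significance screening
#'
#' @param cohort cohort `data.frame`.
#' @param variables candidate variables.
#' @param alpha screening level (default 0.05).
#' @return character vector of variables with univariate Wald P < alpha.
#' @export
selectUnivariate <- function(cohort, variables, alpha = 0.05) {
  p <- vapply(variables, function(v) univariateCox(cohort, v)$p, numeric(1))
  variables[!is.na(p) & p < alpha]
}
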