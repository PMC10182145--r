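#' Random train/test split
#'
#' Simple random partition without stratification: the training set gets
#' `ceiling(n * ratio)` subjects, the test set the remainder; the parts are
#' disjoint and exhaustive.
#'
#' @param cohort cohort `data.frame` (n >= 4).
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` cohort `data.frame`s.
#' @export
splitTrainTest <- function(cohort, ratio = 0.5, seed = 1L) {
  n <- nrow(cohort)
  if (n < 4) stop("need at least 4 subjects to split", call. = FALSE)
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  n_train <- ceiling(n * ratio)
  idx <- sample.int(n, n_train)
  list(train = cohort[sort(idx), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

# terms matrix: SNP dosages + binary clinical design columns, rows = subjects
risk_term_matrix <- function(cohort, genotypes, snp_ids, clinical_terms) {
  unknown <- setdiff(snp_ids, rownames(genotypes))
  if (length(unknown))
    stop("unknown SNP id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  gidx <- match(cohort$subject_id, colnames(genotypes))
  if (anyNA(gidx))
    stop("genotypes missing for some subjects", call. = FALSE)
  snp_mat <- if (length(snp_ids))
    t(dosage(genotypes)[snp_ids, gidx, drop = FALSE])
  else matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  clin_mat <- if (length(clinical_terms))
    clinicalDesign(cohort)[, clinical_terms, drop = FALSE]
  else matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  X <- cbind(snp_mat, clin_mat)
  rownames(X) <- cohort$subject_id
  X
}

#' Fit the combined genetic + clinical risk model
#'
#' One joint Cox fit over the SNP dosages and clinical indicator terms on
#' the training set; the per-subject risk score is the coefficient-weighted
#' sum of term values, and the training-set median score is stored as the
#' high/low cutoff. Subjects with a missing term value are dropped from the
#' fit (their count is recorded).
#'
#' @param train training cohort `data.frame`.
#' @param genotypes a [GenotypeData-class] covering the training subjects.
#' @param snp_ids SNP terms (entered as additive ALT dosages).
#' @param clinical_terms [clinicalDesign()] column names (default: the three
#'   independent clinical risk factors).
#' @param horizon evaluation horizon in months (default 60 = 5-year risk).
#' @param ties tie handling for the Cox fit.
#' @return A [RiskModel-class].
#' @export
fitRiskModel <- function(train, genotypes, snp_ids,
                         clinical_terms = c("age_ge50", "t_stage_t34",
                                            "concurrent_dose_ge155"),
                         horizon = 60, ties = "efron") {
  X <- risk_term_matrix(train, genotypes, snp_ids, clinical_terms)
  ok <- complete.cases(X) & !is.na(train$time) & !is.na(train$event)
  Xc <- X[ok, , drop = FALSE]
  const <- apply(Xc, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant term(s) in training data: ",
         paste(colnames(Xc)[const], collapse = ", "), call. = FALSE)
  fit <- coxFit(Xc, train$time[ok], train$event[ok], ties = ties)
  if (!fit$converged)
    stop("risk-model Cox fit did not converge (", fit$n_events,
         " events, ", ncol(Xc), " terms)", call. = FALSE)
  scores <- as.numeric(Xc %*% fit$beta)
  methods::new("RiskModel", coefficients = fit$beta,
               snpIds = snp_ids, clinicalTerms = clinical_terms,
               cutoff = median(scores), horizon = horizon,
               metrics = list())
}

#' Score subjects with a fitted risk model
#'
#' Linear predictor: the coefficient-weighted sum of term values,
#' uncentered. Subjects with a missing term value get `NA` and are excluded
#' from downstream metrics; their count is attached as attribute
#' `n_excluded`.
#'
#' @param model a [RiskModel-class].
#' @param cohort cohort `data.frame`.
#' @param genotypes a [GenotypeData-class].
#' @return named numeric vector of risk scores.
#' @export
scoreSubjects <- function(model, cohort, genotypes) {
  X <- risk_term_matrix(cohort, genotypes, model@snpIds, model@clinicalTerms)
  X <- X[, names(model@coefficients), drop = FALSE]
  s <- as.numeric(X %*% model@coefficients)
  s[!complete.cases(X)] <- NA_real_
  names(s) <- cohort$subject_id
  attr(s, "n_excluded") <- sum(is.na(s))
  s
}

# Kaplan-Meier estimate of the censoring survivor function G, evaluated
# with a left limit: G(t-) uses only censoring events strictly before t.
censoring_km <- function(time, event) {
  sf <- survfit(Surv(time, 1 - event) ~ 1)
  function(t, left = FALSE) {
    keep <- if (left) sf$time < t else sf$time <= t
    if (!any(keep)) return(1)
    min_surv <- sf$surv[max(which(keep))]
    max(min_surv, .Machine$double.eps)
  }
}

#' Time-dependent AUC at a horizon (IPCW, cumulative/dynamic)
#'
#' Cases are subjects with an event at or before the horizon; controls are
#' subjects still under observation beyond it. Each case is weighted by
#' `1/G(T_i-)` and each control by `1/G(horizon)`, where G is the
#' Kaplan-Meier estimate of the censoring survivor function; the AUC is the
#' weighted probability that a random case outscores a random control (ties
#' count 1/2). Without censoring before the horizon this reduces exactly to
#' the Mann-Whitney AUC of the binary "event by horizon" outcome.
#'
#' @param scores risk scores (NA excluded).
#' @param time,event follow-up and event indicator.
#' @param horizon months (default 60).
#' @return AUC in \[0, 1\].
#' @export
aucAtHorizon <- function(scores, time, event, horizon = 60) {
  ok <- !is.na(scores) & !is.na(time) & !is.na(event)
  scores <- scores[ok]; time <- time[ok]; event <- event[ok]
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (!any(is_case)) stop("no cases by the horizon", call. = FALSE)
  if (!any(is_ctrl)) stop("no controls beyond the horizon", call. = FALSE)
  G <- censoring_km(time, event)
  w_case <- 1 / vapply(time[is_case], function(t) G(t, left = TRUE),
                       numeric(1))
  w_ctrl <- rep(1 / G(horizon), sum(is_ctrl))
  sc <- scores[is_case]; st <- scores[is_ctrl]
  comp <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
  num <- as.numeric(w_case %*% comp %*% w_ctrl)
  num / (sum(w_case) * sum(w_ctrl))
}

#' High- vs low-risk hazard ratio at a score cutoff
#'
#' Subjects with score strictly above the cutoff form the high-risk group
#' (the median subject falls in the low group); a single-covariate Cox fit
#' gives the HR with Wald CI and P, and Kaplan-Meier tables per group are
#' attached.
#'
#' @param scores risk scores.
#' @param cutoff score cutoff (typically the training median).
#' @param time,event follow-up and event indicator.
#' @return list: `hr`, `ci_low`, `ci_high`, `p`, `beta`, `se`, `n_high`,
#'   `n_low`, `km` (from [kmLogrank()]).
#' @export
groupHazardRatio <- function(scores, cutoff, time, event) {
  ok <- !is.na(scores) & !is.na(time) & !is.na(event)
  scores <- scores[ok]; time <- time[ok]; event <- event[ok]
  high <- scores > cutoff
  if (all(high) || !any(high))
    stop("cutoff ", signif(cutoff, 4), " leaves an empty risk group",
         call. = FALSE)
  if (sum(event) < 1) stop("no events", call. = FALSE)
  fit <- coxFit(matrix(as.numeric(high), ncol = 1,
                       dimnames = list(NULL, "high")), time, event)
  km <- kmLogrank(time, event, ifelse(high, "high", "low"))
  list(hr = unname(fit$hr), ci_low = unname(fit$ci_low),
       ci_high = unname(fit$ci_high), p = unname(fit$p),
       beta = unname(fit$beta), se = unname(fit$se),
       n_high = sum(high), n_low = sum(!high), km = km)
}

#' Evaluate a risk model on one or more datasets
#'
#' Computes the horizon AUC and the high- vs low-risk hazard ratio (at the
#' model's training-median cutoff) for each named dataset and stores them in
#' the model's metrics.
#'
#' @param model a [RiskModel-class].
#' @param datasets named list; each element a list with `cohort` and
#'   `genotypes`.
#' @return the model with populated `metrics`.
#' @export
evaluateRiskModel <- function(model, datasets) {
  met <- lapply(datasets, function(d) {
    s <- scoreSubjects(model, d$cohort, d$genotypes)
    auc <- aucAtHorizon(s, d$cohort$time, d$cohort$event, model@horizon)
    gh <- groupHazardRatio(s, model@cutoff, d$cohort$time, d$cohort$event)
    list(auc = auc, hr = gh$hr, ci_low = gh$ci_low, ci_high = gh$ci_high,
         p = gh$p, n = sum(!is.na(s)), n_excluded = attr(s, "n_excluded"))
  })
  model@metrics <- met
  model
}
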