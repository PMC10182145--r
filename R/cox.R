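#' Cox proportional-hazards fit (Newton-Raphson, Efron ties)
#'
#' The scan engine: maximizes the Efron-adjusted (or Breslow) partial
#' likelihood by Newton-Raphson with step-halving, tolerance `eps` on the
#' largest coefficient change, at most `maxiter` iterations. Standard errors
#' come from the inverse observed information. Degenerate designs (constant
#' column, separation, singular information) are flagged via
#' `converged = FALSE` with `NA` outputs rather than fabricated numbers.
#' The score statistic at beta = 0 is also returned; for a single binary
#' covariate without ties it equals the log-rank chi-square.
#'
#' @param X numeric design matrix (subjects x p), no intercept.
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @param ties "efron" (default) or "breslow".
#' @param eps convergence tolerance on coefficient change.
#' @param maxiter maximum Newton-Raphson iterations.
#' @param init optional initial coefficient vector.
#' @return list: `beta`, `se`, `var`, `hr`, `ci_low`, `ci_high`, `p`
#'   (two-sided Wald), `loglik` (null, fitted), `score` (chi-square at 0),
#'   `iter`, `converged`, `n`, `n_events`.
#' @export
coxFit <- function(X, time, event, ties = c("efron", "breslow"),
                   eps = 1e-9, maxiter = 50L, init = NULL) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  stopifnot(p >= 1, nrow(X) == length(time), length(time) == length(event))
  if (anyNA(X) || anyNA(time) || anyNA(event))
    stop("missing values in the Cox fit inputs; subset to complete cases first",
         call. = FALSE)
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  flagged <- function(score = NA_real_) {
    na <- rep(NA_real_, p)
    list(beta = setNames(na, nm), se = setNames(na, nm),
         var = matrix(NA_real_, p, p), hr = setNames(na, nm),
         ci_low = setNames(na, nm), ci_high = setNames(na, nm),
         p = setNames(na, nm), loglik = c(NA_real_, NA_real_),
         score = score, iter = 0L, converged = FALSE,
         n = nrow(X), n_events = sum(event))
  }
  if (any(apply(X, 2, function(v) diff(range(v)) == 0)))
    return(flagged())
  if (is.null(init)) init <- rep(0, p)
  fit <- tryCatch(
    cox_fit_cpp(X, as.numeric(time), as.integer(event),
                ties == "efron", eps, as.integer(maxiter), as.numeric(init)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged())
  beta <- setNames(as.numeric(fit$beta), nm)
  se <- setNames(as.numeric(fit$se), nm)
  list(beta = beta, se = se, var = fit$var, hr = exp(beta),
       ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
       p = 2 * pnorm(-abs(beta / se)), loglik = as.numeric(fit$loglik),
       score = as.numeric(fit$score), iter = fit$iter,
       converged = isTRUE(fit$converged), n = nrow(X), n_events = sum(event))
}
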