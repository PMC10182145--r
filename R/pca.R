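#' Genotype principal components
#'
#' Missing entries are mean-imputed per variant, columns are centred at
#' `2p` and scaled by `sqrt(2p(1-p))` (the usual variance-standardized
#' genotype scaling), and the top-`k` eigenvectors of the subject covariance
#' matrix are returned. The sign of each component is fixed so its
#' largest-magnitude entry is positive, making results deterministic.
#'
#' @param g a [GenotypeData-class] (post-QC).
#' @param k number of components.
#' @return list with `scores` (subjects x k orthonormal matrix, columns
#'   `PC1..PCk`) and `explained` (variance shares).
#' @export
genotypePCA <- function(g, k) {
  n <- ncol(g)
  if (n < k + 1) stop("need at least k+1 subjects", call. = FALSE)
  X <- t(dosage(g))  # subjects x variants
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  p <- mu / 2
  keep <- p > 0 & p < 1
  if (sum(keep) < k) stop("fewer than k polymorphic variants", call. = FALSE)
  X <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  X <- sweep(X, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  S <- tcrossprod(X) / ncol(X)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (vals[k] <= sum(vals) * 1e-12)
    stop("k exceeds the rank of the genotype matrix", call. = FALSE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(g), paste0("PC", seq_len(k)))
  list(scores = V, explained = vals[seq_len(k)] / sum(vals))
}
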