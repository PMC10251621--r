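# De-regression of an empirical EBV covariance into the covariance of the
# estimation errors of the unscaled EBVs, and diagnostics on the result.

#' Empirical EBV covariance from a published correlation matrix
#'
#' National evaluations usually publish the correlation structure of
#' estimated breeding values rather than their covariance. This helper
#' reconstructs the covariance `H` by combining the correlations with EBV
#' variances. By default the theory-implied variances
#' \eqn{H_{ii} = \rho^2_i \gamma_{ii}} are used (the variance of a scaled
#' EBV under regression to the mean); empirical variances can be supplied
#' instead.
#'
#' @param corr symmetric `m x m` correlation matrix of estimated breeding
#'   values (entries in `[-1, 1]`, unit diagonal), ordered and labelled by
#'   index trait.
#' @param params a [genetic_parameters()] object.
#' @param index_traits index trait labels or an [index_definition()].
#' @param variances optional `m` empirical EBV variances overriding the
#'   theory-implied \eqn{\rho^2_i \gamma_{ii}}.
#' @param n_animals optional count of animals behind the estimate
#'   (documentation only).
#' @return An object of class `ebv_covariance` with elements `matrix` (the
#'   covariance `H`) and `n_animals`.
#' @export
ebv_covariance_from_correlations <- function(corr, params, index_traits,
                                             variances = NULL,
                                             n_animals = NA_integer_) {
  idx <- .index_traits(index_traits)
  corr <- as.matrix(corr)
  if (!all(dim(corr) == length(idx)))
    stop("correlation matrix must be ", length(idx), "x", length(idx))
  .check_labels(corr, idx, "EBV correlation matrix")
  .check_symmetric(corr, "EBV correlation matrix")
  if (any(abs(corr) > 1 + 1e-12))
    stop("EBV correlations must lie in [-1, 1]")
  if (max(abs(diag(corr) - 1)) > 1e-12)
    stop("EBV correlation matrix must have a unit diagonal")
  if (is.null(variances)) {
    r <- .index_reliabilities(params, idx)
    variances <- r * params$genetic_sd[idx]^2
  } else {
    variances <- .named_numeric(variances, idx, "variances")
    if (any(variances <= 0)) stop("EBV variances must be positive")
  }
  H <- corr * sqrt(outer(variances, variances))
  H <- (H + t(H)) / 2
  dimnames(H) <- list(idx, idx)
  structure(list(matrix = H, n_animals = n_animals),
            class = "ebv_covariance")
}

#' Estimate the residual covariance of unscaled EBVs by de-regression
#'
#' Under the scaled-EBV model, an empirical covariance `H` of estimated
#' breeding values has expectation \eqn{R (D \Gamma D' + \Sigma) R}, where
#' \eqn{\Sigma} is the covariance of the estimation errors without the
#' assumption of uncorrelated errors. De-regressing `H` and subtracting the
#' genetic covariance of the index traits exposes the error covariance:
#' \deqn{\hat\Sigma = R^{-1} H R^{-1} - D \Gamma D'.}
#'
#' When `H` was generated from a known error covariance `E` the procedure
#' recovers `E` exactly. With rounded published inputs, \eqn{\hat\Sigma}
#' may be marginally non-positive-semidefinite; this is accepted with a
#' warning because only \eqn{D \Gamma D' + \hat\Sigma} enters the index
#' equations, and that sum is what must be well conditioned.
#'
#' @param H an [ebv_covariance_from_correlations()] result, or a plain
#'   symmetric covariance matrix of scaled EBVs.
#' @inheritParams ebv_covariance_from_correlations
#' @return A [residual_model()] with source `"estimated_from_ebv"`.
#' @export
estimate_residual_covariance <- function(H, params, index_traits) {
  idx <- .index_traits(index_traits)
  Hm <- if (inherits(H, "ebv_covariance")) H$matrix else as.matrix(H)
  if (!all(dim(Hm) == length(idx)))
    stop("H must be ", length(idx), "x", length(idx))
  .check_symmetric(Hm, "H")
  r <- .index_reliabilities(params, idx)
  D <- selection_matrix(params$trait_names, idx)
  Gidx <- D %*% params$Gamma %*% t(D)
  Rinv <- diag(1 / r, length(r))
  Sigma <- Rinv %*% Hm %*% Rinv - Gidx
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(idx, idx)
  if (any(diag(Sigma) <= 0))
    stop("de-regressed residual variance is not positive for: ",
         paste(idx[diag(Sigma) <= 0], collapse = ", "),
         " (reliability inconsistent with the observed EBV variance)")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    warning(sprintf(
      "de-regressed residual covariance is not positive semidefinite (min eigenvalue %.3g); rounded inputs can cause this",
      min(ev)))
  structure(list(matrix = Sigma, source = "estimated_from_ebv"),
            class = "residual_model")
}

#' Residual correlations and sign summary
#'
#' Converts a residual covariance into a correlation matrix and counts the
#' negative correlations among the distinct trait pairs (lower triangle).
#' Because residual covariances are typically derived from correlation
#' tables printed at two decimals, correlations whose magnitude falls below
#' `zero_tol` are not resolvable from the inputs and are counted as zero;
#' set `zero_tol = 0` for a strict sign count.
#'
#' @param residual a [residual_model()].
#' @param zero_tol magnitude below which a correlation is treated as zero
#'   in the sign summary. The default, 0.005, is half the resolution of a
#'   two-decimal input table.
#' @return A list with `correlations` (unit-diagonal `m x m` matrix at full
#'   precision), `n_negative`, `n_pairs` and `negative_pairs` (two-column
#'   character matrix of trait pairs).
#' @export
residual_correlations <- function(residual, zero_tol = 0.005) {
  stopifnot(inherits(residual, "residual_model"))
  Sigma <- residual$matrix
  if (any(diag(Sigma) <= 0))
    stop("residual variances must be positive")
  corr <- stats::cov2cor(Sigma)
  diag(corr) <- 1
  lower <- which(lower.tri(corr), arr.ind = TRUE)
  vals <- corr[lower]
  neg <- vals < -zero_tol
  list(correlations = corr,
       n_negative = sum(neg),
       n_pairs = length(vals),
       negative_pairs = cbind(rownames(corr)[lower[neg, 1]],
                              colnames(corr)[lower[neg, 2]]))
}
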