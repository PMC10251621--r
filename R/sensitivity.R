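# Sensitivity of the genetic-trend composition to marginal changes in the
# economic weights.

#' Perturb one economic weight under the sum-to-one constraint
#'
#' Increases weight `i` by `theta` and reduces all other weights
#' proportionally, \eqn{w_j^i = (1 - \theta/(1 - w_i)) w_j}, so the
#' perturbed vector still sums to 1. A plain first derivative of the trend
#' with respect to `w` would ignore this constraint and mislead: more
#' weight on one trait necessarily means less on the others.
#'
#' @param w numeric weight vector summing to 1 (checked within `1e-9`).
#' @param i position (or name) of the weight to increase; `w[i]` must be
#'   strictly less than 1.
#' @param theta perturbation constant, default `0.001`.
#' @return Perturbed weight vector summing to 1.
#' @export
perturb_weights <- function(w, i, theta = 0.001) {
  if (is.character(i)) {
    i <- match(i, names(w))
    if (is.na(i)) stop("unknown trait in weight perturbation")
  }
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to 1 before perturbation (got ",
         format(sum(w)), ")")
  if (w[i] >= 1)
    stop("cannot perturb a weight of 1: the proportional reduction of the ",
         "other weights is undefined")
  wi <- w
  wi[-i] <- (1 - theta / (1 - w[i])) * w[-i]
  wi[i] <- w[i] + theta
  wi
}

#' Sensitivity of the genetic trend to the economic weights
#'
#' For each index trait in turn, the economic weight is increased by
#' `theta` (others reduced proportionally, see [perturb_weights()]), the
#' index is re-solved and the trend recomputed. Row `i` of the result is
#' the change \eqn{d^i - d} over all goal traits, scaled by the genetic
#' standard deviations and normalised so its absolute values sum to 1 --
#' an approximate, constraint-respecting first derivative. The diagonal
#' (index-trait own column) is the direct change in the modified trait;
#' off-diagonal entries are the correlated changes dragged along in the
#' other traits. Rows are normalised over the traits in `subset` (by
#' default the index traits, the convention under which each displayed
#' line sums to 1 in absolute value); `raw_delta` always covers all goal
#' traits, so correlated changes in non-index traits remain available.
#'
#' Because the unperturbed index is optimal for `w`, the total merit gain
#' under any perturbed index cannot exceed the unperturbed one:
#' \eqn{\Delta G^i \le \Delta G}.
#'
#' @inheritParams genetic_trend
#' @param theta perturbation constant, default `0.001`.
#' @param subset trait labels over which rows are normalised; defaults to
#'   the index traits.
#' @return An object of class `sensitivity_result`: `theta`, `raw_delta`
#'   (`m x n` matrix of trend changes, trait units), `normalized`
#'   (`m x length(subset)`, rows with `sum(abs(.)) == 1`), `delta_G`
#'   (unperturbed),
#'   `delta_G_perturbed` (`m` values \eqn{\Delta G^i = d^{i\prime} w}), and
#'   `mean_direct_share` (mean absolute diagonal of the normalised matrix
#'   over the index-trait columns).
#' @examples
#' sc <- holstein_new()
#' sens <- sensitivity_matrix(sc$params, sc$index_def, sc$residual)
#' round(sens$mean_direct_share, 3)
#' @export
sensitivity_matrix <- function(params, index_def, residual = NULL,
                               theta = 0.001, intensity = 1,
                               subset = NULL) {
  stopifnot(inherits(index_def, "index_definition"))
  if (is.null(residual))
    residual <- diagonal_error_covariance(params, index_def$index_traits)
  base <- genetic_trend(params, index_def, residual, intensity)
  idx <- index_def$index_traits
  if (is.null(subset)) subset <- idx
  m <- length(idx)
  n <- length(params$trait_names)
  raw <- matrix(NA_real_, m, n, dimnames = list(idx, params$trait_names))
  normalized <- matrix(NA_real_, m, length(subset),
                       dimnames = list(idx, subset))
  dGp <- stats::setNames(numeric(m), idx)
  w_goal <- base$solution$system$w_goal
  for (i in seq_len(m)) {
    wi <- perturb_weights(index_def$weights, i, theta)
    def_i <- index_definition(idx, wi)
    tr_i <- genetic_trend(params, def_i, residual, intensity)
    raw[i, ] <- tr_i$d - base$d
    normalized[i, ] <- trend_composition(raw[i, ], params$genetic_sd,
                                         subset = subset)
    dGp[i] <- drop(crossprod(tr_i$d, w_goal))
  }
  direct <- intersect(idx, subset)
  structure(
    list(theta = theta, raw_delta = raw, normalized = normalized,
         delta_G = base$delta_G, delta_G_perturbed = dGp,
         mean_direct_share = mean(abs(normalized[cbind(direct, direct)])),
         base_trend = base),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, digits = 2, ...) {
  cat("Sensitivity of genetic trend to economic weights (theta =",
      x$theta, ")\n")
  cat("  rows: perturbed trait; entries: normalised trend change\n")
  print(round(x$normalized, digits))
  cat("  mean direct share:", format(x$mean_direct_share, digits = 4), "\n")
  invisible(x)
}
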