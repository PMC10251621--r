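# Expected genetic and phenotypic trend under index selection, and the
# observed trend fitted from yearly EBV means.

#' Expected genetic trend under truncation selection on the index
#'
#' When individuals are selected with intensity `i` on the optimum index,
#' the expected change in the true breeding values of all `n` goal traits
#' (index traits directly, other traits via correlated response) is
#' \deqn{d = \frac{i}{\sigma_I} \Gamma D' (D \Gamma D' + \Sigma)^{-1}
#'   D \Gamma w.}
#' The reliability matrix `R` cancels analytically from the unsimplified
#' expression \eqn{(i/\sigma_I)\,\Gamma D' R (R(D\Gamma D'+\Sigma)R)^{-1}
#' R D \Gamma w}, so the solver operates on \eqn{D \Gamma D' + \Sigma}
#' directly. The total merit gain on the economic scale is
#' \eqn{\Delta G = d'w}.
#'
#' @param params a [genetic_parameters()] object.
#' @param index_def an [index_definition()].
#' @param residual a [residual_model()]; defaults to the reliability
#'   diagonal.
#' @param intensity selection intensity `i` (standardised selection
#'   differential of the index), default 1. Every element of `d` and
#'   `delta_G` scale linearly in `i`; compositions are invariant to it.
#' @return An object of class `trend_result`: `d` (length `n`, trait
#'   units), `delta_G`, `composition` (signed shares on the genetic-SD
#'   scale with `sum(abs(.)) == 1`), `intensity`, and the underlying
#'   [solve_index()] `solution`.
#' @examples
#' sc <- holstein_old()
#' tr <- genetic_trend(sc$params, sc$index_def, sc$residual)
#' round(trend_composition(tr$d, sc$params$genetic_sd,
#'                         subset = sc$index_def$index_traits), 3)
#' @export
genetic_trend <- function(params, index_def, residual = NULL, intensity = 1) {
  if (!is.numeric(intensity) || length(intensity) != 1L || intensity <= 0)
    stop("intensity must be a positive scalar")
  sol <- solve_index(params, index_def, residual)
  sys <- sol$system
  mid <- solve(sys$P, sys$D %*% sys$G %*% sys$w_goal)
  d <- drop(intensity / sqrt(sol$sigma_I2) * sys$G %*% t(sys$D) %*% mid)
  names(d) <- params$trait_names
  delta_G <- drop(crossprod(d, sys$w_goal))
  composition <- trend_composition(d, params$genetic_sd)
  structure(
    list(intensity = intensity, d = d, delta_G = delta_G,
         composition = composition, solution = sol, params = params),
    class = "trend_result")
}

#' Composition of a trend vector
#'
#' Shares of a (genetic or observed) trend vector, computed on the
#' genetic-standard-deviation scale: each element is divided by its genetic
#' SD and the result is normalised so that the absolute values sum to 1.
#' Signs are preserved; with possibly negative trend components,
#' absolute-value normalisation is the only convention under which the
#' shares remain comparable.
#'
#' @param d named numeric trend vector (trait units).
#' @param genetic_sd genetic standard deviations, matched to `d` by name
#'   when both are named.
#' @param subset optional trait labels: the composition is computed over
#'   this subset only (shares then sum to 1 within the subset).
#' @return Named numeric vector of signed shares with `sum(abs(.)) == 1`.
#' @export
trend_composition <- function(d, genetic_sd, subset = NULL) {
  if (length(genetic_sd) == 1L) genetic_sd <- rep(genetic_sd, length(d))
  if (!is.null(names(d)) && !is.null(names(genetic_sd)))
    genetic_sd <- genetic_sd[names(d)]
  if (length(genetic_sd) != length(d))
    stop("genetic_sd must match d in length")
  x <- d / genetic_sd
  if (!is.null(subset)) {
    if (is.null(names(x))) stop("d must be named to take a subset")
    missing <- setdiff(subset, names(x))
    if (length(missing))
      stop("subset trait(s) not in d: ", paste(missing, collapse = ", "))
    x <- x[subset]
  }
  tot <- sum(abs(x))
  if (tot == 0) stop("trend is zero on the requested subset")
  x / tot
}

#' Expected phenotypic trend
#'
#' The regression of phenotype on breeding value is 1, so the expected
#' phenotypic change equals the genetic change `d_i`; but traits live on
#' different scales, so compositions are compared in phenotypic standard
#' deviations: \eqn{d_{p_i} = d_i / \sigma_{p_i} = d_i h_i /
#' \sqrt{\gamma_{ii}}}. Low-heritability traits therefore contribute less
#' to the phenotypic than to the genetic trend composition.
#'
#' @param trend a [genetic_trend()] result.
#' @param params a [genetic_parameters()] object (defaults to the one the
#'   trend was computed from).
#' @param subset optional trait labels over which to form the composition;
#'   defaults to the index traits of the trend.
#' @return The `trend_result` with fields `d_p` (phenotypic-SD-scaled
#'   changes for all goal traits) and `phenotypic_composition` added.
#' @export
phenotypic_trend <- function(trend, params = trend$params, subset = NULL) {
  stopifnot(inherits(trend, "trend_result"))
  h2 <- params$heritability
  if (any(h2 <= 0))
    stop("phenotypic SD undefined for zero heritability")
  d_p <- trend$d * sqrt(h2) / params$genetic_sd
  if (is.null(subset)) subset <- trend$solution$index_def$index_traits
  pc <- d_p[subset] / sum(abs(d_p[subset]))
  trend$d_p <- d_p
  trend$phenotypic_composition <- pc
  trend
}

#' Observed genetic trend from yearly mean EBVs
#'
#' Fits the observed genetic trend of each trait as the ordinary
#' least-squares slope of the yearly average estimated breeding values on
#' (birth) year, and returns the composition of the observed trend.
#'
#' @param year numeric vector of years (at least two distinct values).
#' @param mean_ebv numeric matrix or data frame with one row per year and
#'   one column per trait: the average EBV of the animals of that year.
#' @param genetic_sd genetic standard deviations used for the composition;
#'   default 1 for every trait (appropriate when EBVs are already expressed
#'   on a common standardised scale).
#' @return A list with `slope` (named, trait units per year) and
#'   `composition` (signed shares, `sum(abs(.)) == 1`).
#' @export
observed_trend_from_yearly_means <- function(year, mean_ebv,
                                             genetic_sd = 1) {
  year <- as.numeric(year)
  if (length(unique(year)) < 2L)
    stop("at least two distinct years are required")
  mean_ebv <- as.matrix(mean_ebv)
  if (nrow(mean_ebv) != length(year))
    stop("mean_ebv must have one row per year")
  fit <- stats::lm(mean_ebv ~ year)
  cf <- stats::coef(fit)
  slope <- if (is.matrix(cf)) cf["year", ] else cf[["year"]]
  if (is.null(colnames(mean_ebv))) names(slope) <- NULL
  else names(slope) <- colnames(mean_ebv)
  list(slope = slope,
       composition = trend_composition(slope, genetic_sd))
}

#' @export
print.trend_result <- function(x, ...) {
  cat("Expected genetic trend (intensity =", x$intensity, ")\n")
  cat("  delta_G =", format(x$delta_G, digits = 6), "\n")
  out <- data.frame(d = x$d, share = x$composition)
  if (!is.null(x$d_p)) out$d_p <- x$d_p
  print(round(out, 4))
  if (!is.null(x$phenotypic_composition)) {
    cat("  phenotypic composition:\n")
    print(round(x$phenotypic_composition, 4))
  }
  invisible(x)
}
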