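# Packaged German Holstein parameter sets: the total merit indices used
# before ("old", six trait complexes) and after ("new", eight trait
# complexes) April 2021. Trait complexes are standardised breeding values
# (population mean 100, genetic SD 12); high values are favourable.

.holstein_table <- function() {
  utils::read.csv(system.file("extdata", "holstein_traits.csv",
                              package = "meritindex"))
}

#' Genetic parameters of the German Holstein trait complexes
#'
#' Ten trait complexes spanning the old (six-trait) and new (eight-trait)
#' German Holstein total merit index: milk production (RZM), functional
#' herd life (RZN), conformation in its old and new definition
#' (RZEo/RZEn), fertility (RZR), maternal and direct calving traits
#' (RZKm/RZKd), health (RZH), young stock survival (RZC) and somatic cell
#' score (RZS). All complexes are expressed on the standardised scale with
#' genetic standard deviation 12.
#'
#' @return A [genetic_parameters()] object for the ten trait complexes.
#' @export
holstein_parameters <- function() {
  tab <- .holstein_table()
  K <- read_labeled_matrix(
    system.file("extdata", "holstein_genetic_correlations.csv",
                package = "meritindex"),
    symmetric = TRUE)
  genetic_parameters(tab$trait, K, tab$genetic_sd, tab$heritability,
                     tab$reliability)
}

#' Empirical EBV correlations behind the old Holstein index
#'
#' Correlations between the estimated breeding values of the six old-index
#' trait complexes, computed from a large unselected sample of cows of one
#' birth year. Used to de-regress the residual covariance of the
#' estimation errors.
#'
#' @return Symmetric 6 x 6 correlation matrix.
#' @export
holstein_ebv_correlations <- function() {
  read_labeled_matrix(
    system.file("extdata", "holstein_ebv_correlations_old.csv",
                package = "meritindex"),
    symmetric = TRUE)
}

#' The old (pre-2021) and new (post-2021) German Holstein scenarios
#'
#' `holstein_old()` returns the six-trait index (RZM, RZN, RZEo, RZR,
#' RZKm, RZS with weights 0.45, 0.20, 0.15, 0.10, 0.03, 0.07) with the
#' residual covariance de-regressed from the empirical EBV correlations.
#' `holstein_new()` returns the eight-trait index (RZM, RZN, RZEn, RZR,
#' RZKm, RZKd, RZH, RZC with weights 0.36, 0.18, 0.15, 0.07, 0.015,
#' 0.015, 0.18, 0.03); no empirical EBV set exists for all new complexes,
#' so its residual covariance is the reliability diagonal (uncorrelated
#' errors).
#'
#' @param residual for `holstein_old()`: `"estimated"` (default)
#'   de-regresses the packaged EBV correlations; `"diagonal"` uses the
#'   reliability diagonal instead.
#' @return A scenario: list with `params` (all ten trait complexes),
#'   `index_def` and `residual`.
#' @examples
#' sc <- holstein_old()
#' sum(sc$index_def$weights)
#' @export
holstein_old <- function(residual = c("estimated", "diagonal")) {
  residual <- match.arg(residual)
  params <- holstein_parameters()
  tab <- .holstein_table()
  keep <- !is.na(tab$weight_old)
  index_def <- index_definition(tab$trait[keep], tab$weight_old[keep])
  res <- if (residual == "diagonal") {
    diagonal_error_covariance(params, index_def)
  } else {
    H <- ebv_covariance_from_correlations(holstein_ebv_correlations(),
                                          params, index_def,
                                          n_animals = 108458L)
    estimate_residual_covariance(H, params, index_def)
  }
  list(params = params, index_def = index_def, residual = res)
}

#' @rdname holstein_old
#' @export
holstein_new <- function() {
  params <- holstein_parameters()
  tab <- .holstein_table()
  keep <- !is.na(tab$weight_new)
  index_def <- index_definition(tab$trait[keep], tab$weight_new[keep])
  list(params = params, index_def = index_def,
       residual = diagonal_error_covariance(params, index_def))
}
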