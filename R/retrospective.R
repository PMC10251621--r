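# Index in retrospect: invert an observed genetic-trend composition into
# realized index weights and realized economic weights.

#' Realized index weights from an observed trend composition
#'
#' Given the observed composition \eqn{\delta} of the genetic trend
#' (signed shares on the genetic-SD scale, `sum(abs(.)) == 1`), the index
#' weights that would have produced it under strict index selection follow
#' from the trend equation \eqn{d \propto \Gamma D' R b} by dropping the
#' scalar \eqn{i/\sigma_I}:
#' \deqn{\beta = (\Gamma D' R)^{-1} \delta.}
#' A unique solution exists only when every goal trait is an index trait
#' (`m = n`, so `D` is square and full rank); otherwise the inverse does
#' not exist.
#'
#' The result is defined up to a positive scale -- only the relative
#' weights are interpretable.
#'
#' @param delta observed trend composition over the goal traits, on the
#'   genetic-SD scale (it is converted to trait units internally, which
#'   matters only when the genetic SDs are unequal).
#' @param params a [genetic_parameters()] object.
#' @param index_def an [index_definition()] covering all goal traits.
#' @return Named numeric vector `beta` of relative realized index weights.
#' @export
realized_index_weights <- function(delta, params, index_def) {
  sys <- .retrospective_system(delta, params, index_def)
  beta <- drop(solve(sys$G %*% t(sys$D) %*% sys$R, sys$delta_trait))
  stats::setNames(beta, sys$idx)
}

#' Realized economic weights from an observed trend composition
#'
#' The "index in retrospect": the hypothetical economic weights
#' \eqn{\omega} that, used to build the optimum index, would have produced
#' the observed trend composition \eqn{\delta}. Substituting the realized
#' index weights into the normal equations and simplifying gives
#' \deqn{\omega = (D \Gamma)^{-1} (D \Gamma D' + \Sigma)
#'   (\Gamma D')^{-1} \delta.}
#' The result is rescaled so that `sum(abs(omega)) == 1`; signs are
#' preserved, and a negative realized weight is meaningful (selection
#' pressure effectively directed against the trait).
#'
#' @inheritParams realized_index_weights
#' @param residual a [residual_model()]; defaults to the reliability
#'   diagonal.
#' @return An object of class `realized_weights`: `delta` (as supplied,
#'   renormalised), `beta`, and `omega` with `sum(abs(omega)) == 1`.
#' @export
realized_economic_weights <- function(delta, params, index_def,
                                      residual = NULL) {
  if (is.null(residual))
    residual <- diagonal_error_covariance(params, index_def)
  stopifnot(inherits(residual, "residual_model"))
  sys <- .retrospective_system(delta, params, index_def)
  Sigma <- residual$matrix
  if (!all(dim(Sigma) == length(sys$idx)))
    stop("residual matrix dimension does not match the index")
  x <- solve(sys$G %*% t(sys$D), sys$delta_trait)
  y <- (sys$D %*% sys$G %*% t(sys$D) + Sigma) %*% x
  omega <- drop(solve(sys$D %*% sys$G, y))
  omega <- omega / sum(abs(omega))
  names(omega) <- sys$idx
  beta <- realized_index_weights(delta, params, index_def)
  structure(list(delta = sys$delta_sd / sum(abs(sys$delta_sd)),
                 beta = beta, omega = omega),
            class = "realized_weights")
}

#' @export
print.realized_weights <- function(x, ...) {
  cat("Realized weights from the observed trend composition\n")
  print(round(data.frame(delta = x$delta, beta = x$beta, omega = x$omega), 4))
  invisible(x)
}

.retrospective_system <- function(delta, params, index_def) {
  idx <- .index_traits(index_def)
  n <- length(params$trait_names)
  if (length(idx) < n)
    stop("no unique solution: realized weights require every breeding ",
         "goal trait to be an index trait (the selection matrix must have ",
         "rank ", n, ", got ", length(idx), " index traits)")
  D <- selection_matrix(params$trait_names, idx)
  r <- .index_reliabilities(params, idx)
  if (!is.null(names(delta))) {
    missing <- setdiff(params$trait_names, names(delta))
    if (length(missing))
      stop("delta is missing trait(s): ", paste(missing, collapse = ", "))
    delta <- delta[params$trait_names]
  }
  delta <- .named_numeric(delta, params$trait_names, "delta")
  if (all(delta == 0)) stop("delta must be nonzero")
  # delta is a composition on the genetic-SD scale; the trend equations
  # operate in trait units
  delta_trait <- delta * params$genetic_sd
  list(idx = idx, D = D, G = params$Gamma, R = diag(r, length(r)),
       delta_sd = delta, delta_trait = delta_trait)
}
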