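# Selection index normal equations.

#' Solve the selection index normal equations
#'
#' The optimum index weights `b` maximise the correlation between the total
#' merit \eqn{T = w'u} and the index \eqn{I = b'c} of scaled estimated
#' breeding values. They solve
#' \deqn{R (D \Gamma D' + \Sigma) R \, b = R D \Gamma \, w,}
#' i.e. \eqn{C b = Cov(c, u) w}. The system is solved by factorisation,
#' never by explicit inversion.
#'
#' @param params a [genetic_parameters()] object.
#' @param index_def an [index_definition()].
#' @param residual a [residual_model()]; defaults to the reliability
#'   diagonal (uncorrelated errors).
#' @param max_condition condition number of `C` above which the system is
#'   refused as numerically singular. A warning is emitted above `1e8`.
#' @return An object of class `index_solution`: index weights `b`, the
#'   scaled-EBV covariance `C`, the index variance `sigma_I2 = b'Cb`, the
#'   accuracy \eqn{\rho_{TI} = \sigma_I / \sigma_T} with
#'   \eqn{\sigma_T^2 = w' \Gamma w}, and the assembled system matrices
#'   (for downstream use by the trend solver).
#' @examples
#' sc <- holstein_old()
#' sol <- solve_index(sc$params, sc$index_def, sc$residual)
#' sol$accuracy
#' @export
solve_index <- function(params, index_def, residual = NULL,
                        max_condition = 1e12) {
  stopifnot(inherits(index_def, "index_definition"))
  if (is.null(residual))
    residual <- diagonal_error_covariance(params, index_def$index_traits)
  stopifnot(inherits(residual, "residual_model"))
  sys <- .index_system(params, index_def, residual)

  kap <- kappa(sys$C, exact = TRUE)
  if (kap > max_condition)
    stop(sprintf(
      "scaled-EBV covariance is numerically singular (condition number %.3g)",
      kap))
  if (kap > 1e8)
    warning(sprintf(
      "scaled-EBV covariance is ill-conditioned (condition number %.3g)",
      kap))

  rhs <- drop(sys$R %*% sys$D %*% sys$G %*% sys$w_goal)
  b <- drop(solve(sys$C, rhs))
  names(b) <- sys$idx
  sigma_I2 <- max(drop(crossprod(b, sys$C %*% b)), 0)
  sigma_T2 <- drop(crossprod(sys$w_goal, sys$G %*% sys$w_goal))
  accuracy <- sqrt(sigma_I2 / sigma_T2)
  if (accuracy > 1) {
    if (accuracy > 1 + 1e-10)
      stop(sprintf("computed accuracy %.12f exceeds 1; inconsistent inputs",
                   accuracy))
    accuracy <- 1
  }

  structure(
    list(b = b, C = sys$C, sigma_I2 = sigma_I2, accuracy = accuracy,
         sigma_T2 = sigma_T2, condition_number = kap, system = sys,
         index_def = index_def, params = params, residual = residual),
    class = "index_solution")
}

#' Variance of a solved selection index
#'
#' @param solution an [solve_index()] result.
#' @return \eqn{\sigma_I^2 = b' C b \ge 0}. At the optimum this also
#'   equals \eqn{Cov(I, T) = b' R D \Gamma w}.
#' @export
index_variance <- function(solution) {
  stopifnot(inherits(solution, "index_solution"))
  solution$sigma_I2
}

#' @export
print.index_solution <- function(x, ...) {
  cat("Selection index solution (", length(x$b), " index traits)\n", sep = "")
  cat("  sigma_I =", format(sqrt(x$sigma_I2), digits = 6),
      " accuracy rho_TI =", format(x$accuracy, digits = 6), "\n")
  cat("  index weights b:\n")
  print(round(x$b, 6))
  invisible(x)
}
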