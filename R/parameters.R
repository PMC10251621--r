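# Core domain types: genetic parameters, index definitions, residual models,
# and the matrix constructors (D, R, E, C) they give rise to.

#' Genetic parameters of a set of breeding goal traits
#'
#' Bundles the additive genetic parameters of the `n` breeding goal traits:
#' the genetic correlation matrix `K`, the genetic standard deviations, the
#' heritabilities and the reliabilities of the estimated breeding values.
#' The additive genetic covariance matrix is assembled as
#' \eqn{\Gamma = S K S} with \eqn{S = diag(\sigma_g)} and validated for
#' positive semidefiniteness.
#'
#' @param trait_names character vector of `n` unique trait labels. Their
#'   order is authoritative: every matrix produced downstream carries these
#'   labels in this order.
#' @param genetic_corr symmetric `n x n` genetic correlation matrix with
#'   unit diagonal and entries in `[-1, 1]`. Dimnames, if present, must
#'   match `trait_names`.
#' @param genetic_sd `n` positive genetic standard deviations (trait units).
#' @param heritability `n` heritabilities in `(0, 1]`.
#' @param reliability `n` reliabilities of the estimated breeding values in
#'   `(0, 1]`; `NA` is allowed for traits never used as index traits.
#' @param psd_tol relative tolerance for the positive-semidefiniteness
#'   check: the smallest eigenvalue of \eqn{\Gamma} may be no less than
#'   `-psd_tol` times the largest. Published correlation tables are rounded
#'   and can be marginally indefinite, hence a tolerance rather than a
#'   strict check.
#' @param repair if `TRUE`, a \eqn{\Gamma} that fails the tolerance is
#'   repaired by clipping negative eigenvalues to zero instead of raising
#'   an error. Off by default.
#'
#' @return An object of class `genetic_parameters`: a list with elements
#'   `trait_names`, `genetic_corr`, `genetic_sd`, `heritability`,
#'   `reliability` and the assembled covariance `Gamma`.
#' @seealso [genetic_covariance()], [index_definition()],
#'   [holstein_parameters()]
#' @export
genetic_parameters <- function(trait_names, genetic_corr, genetic_sd,
                               heritability, reliability,
                               psd_tol = 1e-8, repair = FALSE) {
  trait_names <- as.character(trait_names)
  n <- length(trait_names)
  if (n < 1L) stop("at least one trait is required")
  if (anyDuplicated(trait_names))
    stop("duplicate trait names: ",
         paste(unique(trait_names[duplicated(trait_names)]), collapse = ", "))

  genetic_corr <- as.matrix(genetic_corr)
  if (!all(dim(genetic_corr) == n))
    stop("genetic_corr must be ", n, "x", n)
  .check_labels(genetic_corr, trait_names, "genetic_corr")
  dimnames(genetic_corr) <- list(trait_names, trait_names)
  .check_symmetric(genetic_corr, "genetic_corr")
  if (max(abs(diag(genetic_corr) - 1)) > 1e-12)
    stop("genetic_corr must have a unit diagonal")
  if (any(abs(genetic_corr) > 1 + 1e-12))
    stop("genetic correlations must lie in [-1, 1]")

  genetic_sd <- .named_numeric(genetic_sd, trait_names, "genetic_sd")
  if (any(!is.finite(genetic_sd)) || any(genetic_sd <= 0))
    stop("genetic_sd must be positive and finite")
  heritability <- .named_numeric(heritability, trait_names, "heritability")
  if (any(!is.finite(heritability)) || any(heritability <= 0) ||
      any(heritability > 1))
    stop("heritability must lie in (0, 1]")
  reliability <- .named_numeric(reliability, trait_names, "reliability")
  bad <- !is.na(reliability) & (reliability <= 0 | reliability > 1)
  if (any(bad))
    stop("reliability must lie in (0, 1] (got ",
         paste(sprintf("%s = %g", trait_names[bad], reliability[bad]),
               collapse = ", "), ")")

  Gamma <- diag(genetic_sd, n) %*% genetic_corr %*% diag(genetic_sd, n)
  Gamma <- (Gamma + t(Gamma)) / 2
  dimnames(Gamma) <- list(trait_names, trait_names)
  ev <- eigen(Gamma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -psd_tol * max(ev)) {
    if (!repair)
      stop("genetic covariance matrix is not positive semidefinite ",
           sprintf("(min eigenvalue %.3g, max %.3g); ", min(ev), max(ev)),
           "set repair = TRUE to clip negative eigenvalues")
    eg <- eigen(Gamma, symmetric = TRUE)
    Gamma <- eg$vectors %*% diag(pmax(eg$values, 0), n) %*% t(eg$vectors)
    Gamma <- (Gamma + t(Gamma)) / 2
    dimnames(Gamma) <- list(trait_names, trait_names)
  }

  structure(
    list(trait_names = trait_names, genetic_corr = genetic_corr,
         genetic_sd = genetic_sd, heritability = heritability,
         reliability = reliability, Gamma = Gamma),
    class = "genetic_parameters")
}

#' @export
print.genetic_parameters <- function(x, ...) {
  cat("Genetic parameters for", length(x$trait_names), "breeding goal traits\n")
  print(data.frame(genetic_sd = x$genetic_sd,
                   heritability = x$heritability,
                   reliability = x$reliability,
                   row.names = x$trait_names))
  invisible(x)
}

#' Additive genetic covariance matrix
#'
#' @param params a [genetic_parameters()] object.
#' @return The `n x n` genetic covariance matrix \eqn{\Gamma}.
#' @export
genetic_covariance <- function(params) {
  stopifnot(inherits(params, "genetic_parameters"))
  params$Gamma
}

#' Phenotypic standard deviations implied by heritability
#'
#' Under \eqn{\sigma_p^2 = \gamma_{ii} / h_i^2}, the phenotypic standard
#' deviation of each trait.
#'
#' @inheritParams genetic_covariance
#' @return Named numeric vector of phenotypic standard deviations.
#' @export
phenotypic_sd <- function(params) {
  stopifnot(inherits(params, "genetic_parameters"))
  params$genetic_sd / sqrt(params$heritability)
}

#' Definition of a selection index
#'
#' An ordered subset of the breeding goal traits together with their
#' relative economic weights. Conventionally the absolute weights sum to 1,
#' but any finite weights with at least one nonzero entry are accepted
#' (accuracy and all trend compositions are invariant to a positive
#' rescaling of the weights).
#'
#' @param index_traits character vector of `m >= 1` trait labels, each of
#'   which must resolve to a breeding goal trait when used.
#' @param weights `m` finite relative economic weights.
#' @return An object of class `index_definition` with elements
#'   `index_traits` and `weights` (named).
#' @export
index_definition <- function(index_traits, weights) {
  index_traits <- as.character(index_traits)
  m <- length(index_traits)
  if (m < 1L) stop("an index needs at least one trait")
  if (anyDuplicated(index_traits))
    stop("duplicate index traits: ",
         paste(unique(index_traits[duplicated(index_traits)]), collapse = ", "))
  weights <- .named_numeric(weights, index_traits, "weights")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (all(weights == 0)) stop("at least one weight must be nonzero")
  structure(list(index_traits = index_traits, weights = weights),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat("Selection index on", length(x$index_traits), "traits\n")
  print(x$weights)
  invisible(x)
}

#' Selection (design) matrix mapping goal traits to index traits
#'
#' Builds the `m x n` 0/1 matrix `D` whose element `(i, j)` is 1 when goal
#' trait `j` is identical to index trait `i`. If the two trait lists are
#' identical, `D` is the identity.
#'
#' @param goal_traits character vector of goal trait labels, or a
#'   [genetic_parameters()] object.
#' @param index_traits character vector of index trait labels, or an
#'   [index_definition()] object.
#' @return `m x n` matrix with dimnames `(index_traits, goal_traits)`;
#'   each row contains exactly one 1.
#' @export
selection_matrix <- function(goal_traits, index_traits) {
  if (inherits(goal_traits, "genetic_parameters"))
    goal_traits <- goal_traits$trait_names
  if (inherits(index_traits, "index_definition"))
    index_traits <- index_traits$index_traits
  goal_traits <- as.character(goal_traits)
  index_traits <- as.character(index_traits)
  if (anyDuplicated(goal_traits))
    stop("duplicate goal trait labels")
  if (anyDuplicated(index_traits))
    stop("duplicate index trait labels")
  pos <- match(index_traits, goal_traits)
  if (anyNA(pos))
    stop("index trait(s) not found among goal traits: ",
         paste(index_traits[is.na(pos)], collapse = ", "))
  D <- matrix(0, length(index_traits), length(goal_traits),
              dimnames = list(index_traits, goal_traits))
  D[cbind(seq_along(pos), pos)] <- 1
  D
}

#' Diagonal reliability matrix of the index traits
#'
#' @param params a [genetic_parameters()] object.
#' @param index_traits index trait labels or an [index_definition()].
#' @return `m x m` diagonal matrix `R` with the reliabilities
#'   \eqn{\rho^2_i} of the index traits on the diagonal.
#' @export
reliability_matrix <- function(params, index_traits) {
  r <- .index_reliabilities(params, index_traits)
  R <- diag(r, length(r))
  dimnames(R) <- list(names(r), names(r))
  R
}

#' Residual (error) covariance model for unscaled estimated breeding values
#'
#' Wraps the `m x m` covariance matrix of the estimation errors of the
#' unscaled estimated breeding values, together with its provenance.
#'
#' @param matrix symmetric `m x m` covariance matrix with strictly positive
#'   diagonal (squared trait units), labelled by index trait.
#' @param source one of `"reliability_diagonal"` (derived from
#'   reliabilities, uncorrelated errors), `"estimated_from_ebv"`
#'   (de-regressed from an empirical EBV covariance) or `"user_supplied"`.
#' @return An object of class `residual_model`.
#' @seealso [diagonal_error_covariance()], [estimate_residual_covariance()]
#' @export
residual_model <- function(matrix,
                           source = c("user_supplied",
                                      "reliability_diagonal",
                                      "estimated_from_ebv")) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("residual matrix must be square")
  .check_symmetric(matrix, "residual matrix")
  matrix <- (matrix + t(matrix)) / 2
  if (any(diag(matrix) <= 0))
    stop("residual matrix must have a strictly positive diagonal")
  structure(list(matrix = matrix, source = source), class = "residual_model")
}

#' @export
print.residual_model <- function(x, ...) {
  cat("Residual covariance of unscaled EBVs (source: ", x$source, ")\n",
      sep = "")
  print(x$matrix)
  invisible(x)
}

#' Diagonal residual covariance implied by the reliabilities
#'
#' Under the uncorrelated-error model, the error variance of the unscaled
#' estimated breeding value of index trait `i` is
#' \eqn{\varepsilon_{ii} = (1 - \rho^2_i)/\rho^2_i \cdot \gamma_{ii}},
#' so that the reliability (the squared correlation between true and
#' estimated breeding value) equals \eqn{\gamma_{ii}/(\gamma_{ii} +
#' \varepsilon_{ii})}.
#'
#' @inheritParams reliability_matrix
#' @return A [residual_model()] with a diagonal matrix and source
#'   `"reliability_diagonal"`. A reliability of 1 gives zero error
#'   variance; perfect knowledge of the breeding value.
#' @export
diagonal_error_covariance <- function(params, index_traits) {
  r <- .index_reliabilities(params, index_traits)
  gam <- params$genetic_sd[names(r)]^2
  eps <- (1 - r) / r * gam
  E <- diag(eps, length(eps))
  dimnames(E) <- list(names(r), names(r))
  out <- structure(list(matrix = E, source = "reliability_diagonal"),
                   class = "residual_model")
  out
}

#' Covariance matrix of the scaled estimated breeding values
#'
#' Estimated breeding values are modelled in two steps: the unscaled value
#' `q = v + e` carries the correct correlation with the true breeding
#' value `v`, and the rescaled value `c = R q` restores the
#' regression-to-the-mean property that `Var(c_i) = rho^2_i gamma_ii`
#' is smaller than the genetic variance. Its covariance is
#' \eqn{C = R (D \Gamma D' + \Sigma) R}.
#'
#' @param params a [genetic_parameters()] object.
#' @param index_def an [index_definition()] (or character vector of index
#'   trait labels).
#' @param residual a [residual_model()]; defaults to the reliability
#'   diagonal.
#' @return Symmetric `m x m` matrix `C`.
#' @export
scaled_ebv_covariance <- function(params, index_def, residual = NULL) {
  idx <- .index_traits(index_def)
  if (is.null(residual)) residual <- diagonal_error_covariance(params, idx)
  pieces <- .index_system(params, idx, residual)
  pieces$C
}

# ---- internal helpers -------------------------------------------------------

.index_traits <- function(index_def) {
  if (inherits(index_def, "index_definition")) index_def$index_traits
  else as.character(index_def)
}

.index_reliabilities <- function(params, index_traits) {
  stopifnot(inherits(params, "genetic_parameters"))
  idx <- .index_traits(index_traits)
  pos <- match(idx, params$trait_names)
  if (anyNA(pos))
    stop("index trait(s) not found among goal traits: ",
         paste(idx[is.na(pos)], collapse = ", "))
  r <- params$reliability[pos]
  if (anyNA(r))
    stop("reliability missing for index trait(s): ",
         paste(idx[is.na(r)], collapse = ", "))
  if (any(r <= 0 | r > 1))
    stop("reliabilities of index traits must lie in (0, 1]")
  names(r) <- idx
  r
}

# Assemble the matrices of the index system for one (params, index, residual)
# triple: D, Gamma, R, P = D Gamma D' + Sigma, C = R P R, and the
# goal-trait economic weight vector when an index_definition is given.
.index_system <- function(params, index_def, residual) {
  idx <- .index_traits(index_def)
  D <- selection_matrix(params$trait_names, idx)
  G <- params$Gamma
  Sigma <- residual$matrix
  if (!all(dim(Sigma) == length(idx)))
    stop("residual matrix dimension (", nrow(Sigma),
         ") does not match the number of index traits (", length(idx), ")")
  if (!is.null(rownames(Sigma)) && !identical(rownames(Sigma), idx))
    stop("residual matrix labels do not match the index traits")
  r <- .index_reliabilities(params, idx)
  R <- diag(r, length(r))
  P <- D %*% G %*% t(D) + Sigma
  P <- (P + t(P)) / 2
  C <- R %*% P %*% R
  dimnames(P) <- dimnames(C) <- list(idx, idx)
  w <- if (inherits(index_def, "index_definition")) index_def$weights else NULL
  w_goal <- NULL
  if (!is.null(w)) {
    w_goal <- stats::setNames(numeric(length(params$trait_names)),
                              params$trait_names)
    w_goal[idx] <- w
  }
  list(idx = idx, D = D, G = G, Sigma = Sigma, r = r, R = R, P = P, C = C,
       w = w, w_goal = w_goal)
}

.named_numeric <- function(x, nms, what) {
  x <- as.numeric(x)
  if (length(x) == 1L && length(nms) > 1L) x <- rep(x, length(nms))
  if (length(x) != length(nms))
    stop(what, " must have length ", length(nms))
  stats::setNames(x, nms)
}

.check_symmetric <- function(M, what, tol = 1e-8) {
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(what, " must be symmetric")
  invisible(TRUE)
}

.check_labels <- function(M, nms, what) {
  for (d in 1:2) {
    lab <- dimnames(M)[[d]]
    if (!is.null(lab) && !identical(lab, nms))
      stop(what, " labels do not match the trait names (",
           paste(setdiff(lab, nms), collapse = ", "), ")")
  }
  invisible(TRUE)
}
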