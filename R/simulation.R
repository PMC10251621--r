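# Random scenario generation and Monte-Carlo population simulation. The
# simulator draws i.i.d. individuals from the model the analytical theory
# assumes (true breeding values u ~ N(0, Gamma), independent estimation
# errors e ~ N(0, Sigma), scaled EBVs c = R(Du + e)) and thereby serves as
# a brute-force oracle for the predicted selection response.

#' Generate a random but valid scenario
#'
#' Draws a random genetic correlation matrix that is positive semidefinite
#' by construction (normalised Gram matrix of a random factor loading
#' matrix, so no generate-and-test loop is needed), random genetic SDs,
#' heritabilities, reliabilities and economic weights on the simplex, and
#' optionally a random full residual covariance.
#'
#' @param n number of breeding goal traits.
#' @param m number of index traits, `1 <= m <= n`.
#' @param seed integer seed; the scenario is fully determined by it.
#' @param reliability_range range the reliabilities are drawn from.
#' @param residual_type `"diagonal"` for reliability-implied uncorrelated
#'   errors, `"full"` for a random correlated (PSD) error covariance with
#'   the same reliability-implied diagonal.
#' @param sd_range range of the genetic standard deviations.
#' @return A scenario: list with `params`, `index_def`, `residual`, `seed`.
#' @export
random_scenario <- function(n, m = n, seed = 1L,
                            reliability_range = c(0.3, 0.9),
                            residual_type = c("diagonal", "full"),
                            sd_range = c(0.5, 2)) {
  residual_type <- match.arg(residual_type)
  if (m < 1 || m > n) stop("need 1 <= m <= n")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  traits <- sprintf("T%02d", seq_len(n))
  # random Gram construction: K = cov2cor(A A' + small ridge), PSD by design
  A <- matrix(stats::rnorm(n * (n + 2)), n)
  K <- stats::cov2cor(A %*% t(A) + diag(1e-6, n))
  K <- (K + t(K)) / 2; diag(K) <- 1
  sds <- stats::runif(n, sd_range[1], sd_range[2])
  h2 <- stats::runif(n, 0.05, 0.9)
  rel <- stats::runif(n, reliability_range[1], reliability_range[2])
  params <- genetic_parameters(traits, K, sds, h2, rel)

  idx <- sort(sample.int(n, m))
  w <- stats::rexp(m)
  w <- w / sum(w)
  index_def <- index_definition(traits[idx], w)

  residual <- diagonal_error_covariance(params, index_def)
  if (residual_type == "full") {
    B <- matrix(stats::rnorm(m * (m + 2)), m)
    Kc <- stats::cov2cor(B %*% t(B) + diag(1e-6, m))
    eps <- diag(residual$matrix)
    M <- Kc * sqrt(outer(eps, eps))
    dimnames(M) <- dimnames(residual$matrix)
    residual <- residual_model(M, "user_supplied")
  }
  list(params = params, index_def = index_def, residual = residual,
       seed = as.integer(seed))
}

#' Simulate a population under the scaled-EBV model
#'
#' Draws `size` independent individuals: true breeding values
#' `u ~ N(0, Gamma)`, estimation errors `e ~ N(0, Sigma)` independent of
#' `u`, unscaled EBVs `q = Du + e` and scaled EBVs `c = Rq`. As the
#' population grows, the sample covariance of `c` converges to
#' `R(D Gamma D' + Sigma)R` and the squared sample correlation between
#' `c_i` and `u_i` to the reliability.
#'
#' @param scenario a scenario (from [random_scenario()], [holstein_old()],
#'   [holstein_new()] or [read_scenario_config()]).
#' @param size number of individuals.
#' @param seed integer seed.
#' @return An object of class `population_draw`: `true_bv` (`size x n`),
#'   `ebv` (`size x m`), `size`.
#' @export
simulate_population <- function(scenario, size, seed = 1L) {
  params <- scenario$params
  index_def <- scenario$index_def
  residual <- scenario$residual
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  D <- selection_matrix(params, index_def)
  r <- .index_reliabilities(params, index_def)
  U <- MASS::mvrnorm(size, rep(0, length(params$trait_names)), params$Gamma)
  E <- MASS::mvrnorm(size, rep(0, length(r)), residual$matrix, tol = 1e-6)
  if (size == 1L) { U <- matrix(U, 1); E <- matrix(E, 1) }
  Cm <- (U %*% t(D) + E) %*% diag(r, length(r))
  colnames(U) <- params$trait_names
  colnames(Cm) <- names(r)
  structure(list(true_bv = U, ebv = Cm, size = size),
            class = "population_draw")
}

#' Empirical selection response under truncation selection
#'
#' Computes the index `I = b'c` for every individual, selects the top
#' fraction `p`, and returns the mean true breeding values of the selected
#' group together with the realized selection intensity (the standardised
#' selection differential of `I`). Feeding the realized intensity back
#' into the analytical trend prediction makes the two directly comparable.
#'
#' @param pop a [simulate_population()] result.
#' @param b index weights (one per index trait).
#' @param p selected fraction, `0 < p < 1`.
#' @return List with `means` (per goal trait), `intensity` (realized),
#'   `n_selected`.
#' @export
empirical_selection_response <- function(pop, b, p) {
  stopifnot(inherits(pop, "population_draw"))
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  I <- drop(pop$ebv %*% b)
  thr <- stats::quantile(I, 1 - p, names = FALSE)
  sel <- I >= thr
  if (!any(sel)) stop("no individuals selected")
  list(means = colMeans(pop$true_bv[sel, , drop = FALSE]),
       intensity = (mean(I[sel]) - mean(I)) / stats::sd(I),
       n_selected = sum(sel))
}

# Preserve the caller's RNG state so that seeded draws inside the package
# never perturb user-level reproducibility.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
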