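# Shared test helpers: small hand-built parameter sets and independent
# brute-force oracles.

# A tiny, fully specified 3-trait parameter set with unequal SDs.
toy_params <- function() {
  K <- matrix(c(1, 0.3, -0.2,
                0.3, 1, 0.4,
                -0.2, 0.4, 1), 3, 3)
  genetic_parameters(c("A", "B", "C"), K,
                     genetic_sd = c(2, 1, 3),
                     heritability = c(0.4, 0.1, 0.25),
                     reliability = c(0.8, 0.6, 0.5))
}

# Parameters with perfect knowledge: reliability 1 everywhere, so the
# index collapses onto the true merit.
perfect_params <- function(n = 3, seed = 7) {
  sc <- random_scenario(n, n, seed = seed)
  p <- sc$params
  genetic_parameters(p$trait_names, p$genetic_corr, p$genetic_sd,
                     p$heritability, reliability = rep(1, n))
}

# Independent oracle for the index solver: maximize corr(I, T) over the
# index weights numerically (correlation is scale-invariant, so optim over
# unconstrained b is enough). Returns the achieved maximum correlation.
brute_force_accuracy <- function(params, index_def, residual) {
  D <- selection_matrix(params, index_def)
  G <- params$Gamma
  r <- params$reliability[index_def$index_traits]
  R <- diag(r, length(r))
  C <- R %*% (D %*% G %*% t(D) + residual$matrix) %*% R
  w_goal <- stats::setNames(numeric(length(params$trait_names)),
                            params$trait_names)
  w_goal[index_def$index_traits] <- index_def$weights
  cov_cu_w <- drop(R %*% D %*% G %*% w_goal)
  sigma_T <- sqrt(drop(crossprod(w_goal, G %*% w_goal)))
  corr_of <- function(b) {
    drop(crossprod(b, cov_cu_w)) /
      (sqrt(drop(crossprod(b, C %*% b))) * sigma_T)
  }
  best <- -Inf
  for (start in seq_len(5)) {
    b0 <- stats::rnorm(length(r))
    opt <- stats::optim(b0, function(b) -corr_of(b), method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- max(best, -opt$value)
  }
  best
}

# Convenience: full goal-trait weight vector of an index definition.
goal_weights <- function(params, index_def) {
  w <- stats::setNames(numeric(length(params$trait_names)),
                       params$trait_names)
  w[index_def$index_traits] <- index_def$weights
  w
}
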