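test_that("EBV covariance reconstruction from correlations", {
  p <- toy_params()
  idx <- c("A", "B")
  H <- ebv_covariance_from_correlations(diag(2), p, idx)
  r <- p$reliability[idx]
  gam <- p$genetic_sd[idx]^2
  expect_equal(diag(H$matrix), r * gam, ignore_attr = TRUE)
  expect_true(all(H$matrix[upper.tri(H$matrix)] == 0))

  unit <- genetic_parameters(c("A", "B"), diag(2), c(1, 1), c(0.5, 0.5),
                             c(1, 1))
  corr <- matrix(c(1, 0.5, 0.5, 1), 2)
  H2 <- ebv_covariance_from_correlations(corr, unit, c("A", "B"))
  expect_equal(unname(H2$matrix), matrix(c(1, 0.5, 0.5, 1), 2))

  sc <- holstein_old()
  H6 <- ebv_covariance_from_correlations(holstein_ebv_correlations(),
                                         sc$params, sc$index_def)
  expect_equal(H6$matrix["RZN", "RZS"],
               0.46 * 144 * sqrt(0.673 * 0.764), tolerance = 1e-12)
  expect_equal(H6$matrix["RZN", "RZS"], 47.498, tolerance = 1e-4)

  expect_error(ebv_covariance_from_correlations(corr * 1.5, unit,
                                                c("A", "B")),
               "\\[-1, 1\\]")
})

test_that("de-regression exactly recovers a known error covariance", {
  for (seed in 1:40) {
    sc <- random_scenario(sample(2:6, 1), seed = seed,
                          residual_type = if (seed %% 2) "full" else "diagonal")
    p <- sc$params
    idx <- sc$index_def$index_traits
    D <- selection_matrix(p, idx)
    r <- p$reliability[idx]
    R <- diag(r, length(r))
    E <- sc$residual$matrix
    H <- R %*% (D %*% p$Gamma %*% t(D) + E) %*% R
    dimnames(H) <- list(idx, idx)
    est <- estimate_residual_covariance(H, p, idx)
    expect_equal(est$matrix, E, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(est$source, "estimated_from_ebv")
  }
})

test_that("an H generated under uncorrelated errors de-regresses back to the reliability diagonal", {
  sc <- holstein_old()
  idx <- sc$index_def$index_traits
  E <- diagonal_error_covariance(sc$params, idx)
  D <- selection_matrix(sc$params, idx)
  r <- sc$params$reliability[idx]
  R <- diag(r, 6)
  H <- R %*% (D %*% sc$params$Gamma %*% t(D) + E$matrix) %*% R
  dimnames(H) <- list(idx, idx)
  est <- estimate_residual_covariance(H, sc$params, idx)
  expect_equal(diag(est$matrix), (1 - r) / r * 144, ignore_attr = TRUE)
  expect_lt(max(abs(est$matrix - diag(diag(est$matrix)))), 1e-10)
  rc <- residual_correlations(est)
  expect_equal(rc$n_negative, 0L)
})

test_that("a reliability inconsistent with the EBV variance is reported", {
  p <- genetic_parameters("A", matrix(1), 12, 0.5, 0.9)
  # observed EBV variance far below rho2^2 * (gamma + eps): de-regressed
  # residual variance goes negative
  H <- matrix(10, 1, 1, dimnames = list("A", "A"))
  expect_error(estimate_residual_covariance(H, p, "A"), "A")
})

test_that("residual correlations have a unit diagonal and a strict sign count", {
  sc <- holstein_old()
  rc <- residual_correlations(sc$residual)
  expect_equal(unname(diag(rc$correlations)), rep(1, 6))
  expect_equal(rc$n_pairs, 15L)
  # full-precision strict count differs by the one near-zero pair
  rc0 <- residual_correlations(sc$residual, zero_tol = 0)
  expect_lte(rc$n_negative, rc0$n_negative)

  d <- residual_model(diag(c(1, 2, 3)), "user_supplied")
  rcd <- residual_correlations(d)
  expect_equal(unname(rcd$correlations), diag(3))
  expect_equal(rcd$n_negative, 0L)
})

test_that("correlated residuals change the index weights, uncorrelated do not", {
  sc <- holstein_old()
  E <- diagonal_error_covariance(sc$params, sc$index_def)
  b_diag <- solve_index(sc$params, sc$index_def, E)$b
  b_est <- solve_index(sc$params, sc$index_def, sc$residual)$b
  expect_gt(max(abs(b_diag - b_est)), 1e-4)

  # a diagonal Sigma recovered by de-regression gives identical weights
  idx <- sc$index_def$index_traits
  D <- selection_matrix(sc$params, idx)
  r <- sc$params$reliability[idx]
  R <- diag(r, 6)
  H <- R %*% (D %*% sc$params$Gamma %*% t(D) + E$matrix) %*% R
  dimnames(H) <- list(idx, idx)
  est <- estimate_residual_covariance(H, sc$params, idx)
  b_est_diag <- solve_index(sc$params, sc$index_def, est)$b
  expect_equal(b_est_diag, b_diag, tolerance = 1e-10)
})
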