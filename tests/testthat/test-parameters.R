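test_that("selection matrix places one 1 per index trait, identity when lists match", {
  D <- selection_matrix(c("A", "B", "C"), "B")
  expect_equal(unname(D), matrix(c(0, 1, 0), 1, 3))

  expect_equal(unname(selection_matrix(c("A", "B"), c("A", "B"))), diag(2))

  sc <- holstein_old()
  D6 <- selection_matrix(sc$params, sc$index_def)
  expect_equal(dim(D6), c(6L, 10L))
  expect_true(all(rowSums(D6) == 1))
  expect_equal(colnames(D6)[apply(D6 == 1, 1, which)],
               c("RZM", "RZN", "RZEo", "RZR", "RZKm", "RZS"))
  # each index trait maps to exactly one goal trait
  expect_equal(unname(D6 %*% t(D6)), diag(6))
})

test_that("selection matrix rejects unknown and duplicated labels", {
  expect_error(selection_matrix(c("A", "B"), "Z"), "Z")
  expect_error(selection_matrix(c("A", "A"), "A"), "duplicate")
  expect_error(selection_matrix(c("A", "B"), c("A", "A")), "duplicate")
})

test_that("reliability matrix is the diagonal of index-trait reliabilities", {
  p <- toy_params()
  R <- reliability_matrix(p, c("B", "C"))
  expect_equal(R, diag(c(0.6, 0.5)), ignore_attr = TRUE)
  expect_equal(rownames(R), c("B", "C"))

  ones <- genetic_parameters("A", matrix(1), 1, 0.5, 1)
  expect_equal(unname(reliability_matrix(ones, "A")), matrix(1))

  sc <- holstein_old()
  expect_equal(unname(diag(reliability_matrix(sc$params, sc$index_def))),
               c(0.743, 0.673, 0.638, 0.541, 0.635, 0.764))
})

test_that("parameter validation rejects malformed inputs", {
  K <- diag(2)
  expect_error(genetic_parameters(c("A", "A"), K, 1, 0.5, 0.5), "duplicate")
  expect_error(genetic_parameters(c("A", "B"), K, c(1, -1), 0.5, 0.5),
               "positive")
  expect_error(genetic_parameters(c("A", "B"), K, 1, c(0.5, 1.2), 0.5),
               "heritability")
  expect_error(genetic_parameters(c("A", "B"), K, 1, 0.5, c(0.5, 0)),
               "reliability")
  Kbad <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
  expect_error(genetic_parameters(c("A", "B"), Kbad, 1, 0.5, 0.5),
               "symmetric")
})

test_that("an indefinite correlation matrix errors unless repaired", {
  K <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.9,
                -0.9, 0.9, 1), 3, 3)
  expect_error(genetic_parameters(c("A", "B", "C"), K, 1, 0.5, 0.5),
               "semidefinite")
  p <- genetic_parameters(c("A", "B", "C"), K, 1, 0.5, 0.5, repair = TRUE)
  ev <- eigen(p$Gamma, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("diagonal error covariance follows (1 - rho2)/rho2 * gamma", {
  one <- genetic_parameters("A", matrix(1), 12, 0.5, 1)
  expect_equal(unname(diagonal_error_covariance(one, "A")$matrix),
               matrix(0))

  half <- genetic_parameters("A", matrix(1), 12, 0.5, 0.5)
  expect_equal(unname(diagonal_error_covariance(half, "A")$matrix),
               matrix(144))

  sc <- holstein_old()
  E <- diagonal_error_covariance(sc$params, sc$index_def)
  expect_equal(E$matrix["RZR", "RZR"], 122.17375, tolerance = 1e-6)
  expect_equal(E$source, "reliability_diagonal")
  expect_true(all(E$matrix[upper.tri(E$matrix)] == 0))
})

test_that("scaled EBV covariance equals R(D Gamma D' + Sigma)R", {
  # R = I, Sigma -> 0: C reduces to the genetic covariance of index traits
  p <- perfect_params(3, seed = 11)
  idf <- index_definition(p$trait_names, rep(1 / 3, 3))
  tiny <- residual_model(diag(1e-12, 3), "user_supplied")
  C <- scaled_ebv_covariance(p, idf, tiny)
  expect_equal(C, p$Gamma, tolerance = 1e-9, ignore_attr = TRUE)

  one <- genetic_parameters("A", matrix(1), 12, 0.5, 0.743)
  expect_equal(drop(scaled_ebv_covariance(one, "A")), 0.743 * 144)

  # with the reliability diagonal, diag(C) = rho2 * gamma exactly, hence
  # shrinkage below the genetic variance
  sc <- holstein_old()
  Cd <- scaled_ebv_covariance(sc$params, sc$index_def,
                              diagonal_error_covariance(sc$params,
                                                        sc$index_def))
  r6 <- sc$params$reliability[sc$index_def$index_traits]
  expect_equal(diag(Cd), r6 * 144, ignore_attr = TRUE)
  expect_true(all(diag(Cd) <= 144))
  expect_equal(Cd, t(Cd))

  # the de-regression-based H keeps the same diagonal by construction
  Ce <- scaled_ebv_covariance(sc$params, sc$index_def, sc$residual)
  expect_equal(diag(Ce), r6 * 144, ignore_attr = TRUE)
})

test_that("residual model validation", {
  expect_error(residual_model(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(residual_model(matrix(c(0, 0, 0, 1), 2)), "positive")
  M <- matrix(c(2, 0.5, 0.5, 1), 2)
  rm_ <- residual_model(M)
  expect_equal(rm_$source, "user_supplied")
})
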