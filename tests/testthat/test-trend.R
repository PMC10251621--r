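test_that("single-trait trend is i * rho * sigma_g", {
  for (rho2 in c(0.3, 0.541, 1)) {
    p <- genetic_parameters("A", matrix(1), 12, 0.5, rho2)
    tr <- genetic_trend(p, index_definition("A", 1), intensity = 2)
    expect_equal(unname(tr$d), 2 * sqrt(rho2) * 12, tolerance = 1e-10)
  }
})

test_that("selection on one perfectly known trait drags other traits along the genetic covariance", {
  p <- perfect_params(3, seed = 21)
  idf <- index_definition(p$trait_names, c(1, 0, 0))
  tiny <- residual_model(diag(1e-12, 3), "user_supplied")
  tr <- genetic_trend(p, idf, tiny)
  g1 <- p$Gamma[, 1]
  expect_equal(unname(tr$d / tr$d[1]), unname(g1 / g1[1]),
               tolerance = 1e-6)
})

test_that("trend composition scales by genetic SD, keeps signs, sums to one in absolute value", {
  expect_equal(trend_composition(c(3, 1), 1), c(0.75, 0.25))
  cc <- trend_composition(c(3, -1), 1)
  expect_equal(cc, c(0.75, -0.25))
  expect_equal(sum(abs(cc)), 1)

  # unequal SDs: shares move onto the SD scale before normalising
  expect_equal(trend_composition(c(a = 4, b = 1), c(a = 4, b = 1)),
               c(a = 0.5, b = 0.5))

  d <- c(x = 1, y = 2, z = -3)
  sub <- trend_composition(d, 1, subset = c("x", "z"))
  expect_equal(sum(abs(sub)), 1)
  expect_error(trend_composition(d, 1, subset = "q"), "q")
  expect_error(trend_composition(c(a = 0, b = 0), 1), "zero")
})

test_that("intensity scales d and delta_G linearly, composition invariant", {
  sc <- holstein_old()
  t1 <- genetic_trend(sc$params, sc$index_def, sc$residual, intensity = 1)
  t2 <- genetic_trend(sc$params, sc$index_def, sc$residual, intensity = 2)
  expect_equal(t2$d, 2 * t1$d, tolerance = 1e-12)
  expect_equal(t2$delta_G, 2 * t1$delta_G, tolerance = 1e-12)
  expect_equal(t2$composition, t1$composition, tolerance = 1e-12)
  expect_equal(sum(abs(t1$composition)), 1, tolerance = 1e-12)
  expect_gte(t1$delta_G, 0)
})

test_that("the simplified trend formula matches the unsimplified one with R kept", {
  for (seed in 1:10) {
    sc <- random_scenario(sample(3:6, 1), sample(2:3, 1), seed = seed,
                          residual_type = "full")
    tr <- genetic_trend(sc$params, sc$index_def, sc$residual)
    sys <- tr$solution$system
    C <- sys$R %*% sys$P %*% sys$R
    d_long <- drop(1 / sqrt(tr$solution$sigma_I2) *
                     sys$G %*% t(sys$D) %*% sys$R %*%
                     solve(C, sys$R %*% sys$D %*% sys$G %*% sys$w_goal))
    expect_equal(unname(tr$d), unname(d_long), tolerance = 1e-10)
  }
})

test_that("the optimal weights maximize delta_G among competing index constructions", {
  sc <- holstein_old()
  base <- genetic_trend(sc$params, sc$index_def, sc$residual)
  w_goal <- goal_weights(sc$params, sc$index_def)
  set.seed(99)
  for (k in 1:10) {
    w_alt <- abs(sc$index_def$weights + rnorm(6, sd = 0.1))
    w_alt <- w_alt / sum(w_alt)
    alt <- genetic_trend(sc$params,
                         index_definition(sc$index_def$index_traits, w_alt),
                         sc$residual)
    dG_alt <- drop(crossprod(alt$d, w_goal))
    expect_lte(dG_alt, base$delta_G + 1e-10)
  }
})

test_that("old-index Holstein genetic trend assigns roughly 28% to milk", {
  sc <- holstein_old()
  tr <- genetic_trend(sc$params, sc$index_def, sc$residual)
  comp <- trend_composition(tr$d, sc$params$genetic_sd,
                            subset = sc$index_def$index_traits)
  expect_equal(unname(comp["RZM"]), 0.28, tolerance = 0.05)
  expect_equal(sum(abs(comp)), 1, tolerance = 1e-12)
})

test_that("phenotypic trend rescales by h/sigma_g", {
  # uniform h2 = 1 and equal SDs: phenotypic equals genetic composition
  p <- genetic_parameters(c("A", "B"), matrix(c(1, 0.2, 0.2, 1), 2),
                          c(3, 3), c(1, 1), c(0.7, 0.7))
  idf <- index_definition(c("A", "B"), c(0.6, 0.4))
  tr <- phenotypic_trend(genetic_trend(p, idf))
  expect_equal(unname(tr$phenotypic_composition),
               unname(trend_composition(tr$d, p$genetic_sd)),
               tolerance = 1e-12)

  p0 <- toy_params()
  p0$heritability["B"] <- 0
  tr0 <- genetic_trend(toy_params(),
                       index_definition(c("A", "B"), c(0.5, 0.5)))
  expect_error(phenotypic_trend(tr0, p0), "heritability")
})

test_that("observed trend regression recovers slopes and composition", {
  yrs <- 2001:2010
  m <- cbind(lin = 2 * yrs + 3, mix = 0.5 * yrs - 7)
  fit <- observed_trend_from_yearly_means(yrs, m)
  expect_equal(unname(fit$slope), c(2, 0.5), tolerance = 1e-12)

  # closed-form OLS on three points
  fit3 <- observed_trend_from_yearly_means(c(1, 2, 3),
                                           matrix(c(0, 1, 1), 3, 1))
  expect_equal(unname(fit3$slope), 0.5, tolerance = 1e-12)

  two <- observed_trend_from_yearly_means(yrs, cbind(a = 2 * yrs,
                                                     b = 2 * yrs + 5))
  expect_equal(two$composition, c(a = 0.5, b = 0.5), tolerance = 1e-12)

  expect_error(observed_trend_from_yearly_means(rep(2000, 3),
                                                matrix(1:3, 3, 1)),
               "distinct")
})
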