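test_that("nb_logpmf matches closed forms, dnbinom and the Poisson limit", {
  # f(0) = (theta/(theta+u))^theta: geometric-type corner
  expect_equal(nb_logpmf(0, u = 1, theta = 1), log(1 / 2), tolerance = 1e-12)
  # direct evaluation for x = 2, u = 2, theta = 1
  expect_equal(nb_logpmf(2, u = 2, theta = 1), log(4 / 27),
               tolerance = 1e-12)
  # large theta collapses to Poisson
  expect_equal(nb_logpmf(3, u = 3, theta = 1e8), dpois(3, 3, log = TRUE),
               tolerance = 1e-6)
  # independent implementation over a parameter grid
  for (u in c(0.3, 2, 17)) {
    for (th in c(0.5, 1, 9)) {
      x <- 0:30
      expect_equal(nb_logpmf(x, u, th),
                   dnbinom(x, mu = u, size = th, log = TRUE),
                   tolerance = 1e-10)
    }
  }
})

test_that("nb_logpmf normalizes and rejects invalid arguments", {
  for (p in list(c(1, 1), c(5, 2), c(20, 0.5))) {
    xmax <- qnbinom(1 - 1e-12, mu = p[1], size = p[2])
    expect_gte(sum(exp(nb_logpmf(0:xmax, p[1], p[2]))), 1 - 1e-8)
  }
  expect_error(nb_logpmf(-1, 1, 1), "non-negative")
  expect_error(nb_logpmf(1.5, 1, 1), "integer")
  expect_error(nb_logpmf(1, 0, 1), "positive")
  expect_error(nb_logpmf(1, 1, -2), "positive")
})

test_that("moments and the (p, gamma) parameterization round-trip", {
  mv <- nb_mean_var(2, 1)
  expect_equal(mv$mean, 2)
  expect_equal(mv$variance, 6)
  expect_equal(nb_mean_var(5, 1e12)$variance, 5, tolerance = 1e-9)
  # round trip is exact
  for (u in c(0.2, 3, 40)) {
    for (th in c(0.7, 2, 90)) {
      pg <- nb_to_pgamma(u, th)
      back <- nb_from_pgamma(pg$p, pg$gamma)
      expect_equal(back$u, u, tolerance = 1e-14)
      expect_equal(back$theta, th, tolerance = 1e-14)
    }
  }
  # sampling agrees with the stated moments
  set.seed(1)
  draws <- rnbinom(1e5, mu = 4, size = 2)
  se_mean <- sqrt(12 / 1e5)
  expect_lt(abs(mean(draws) - 4), 3 * se_mean)
  expect_lt(abs(var(draws) - 12) / 12, 0.1)
})

test_that("cell_mean evaluates the log link and clips overflow", {
  expect_equal(cell_mean(0, c(0, 0), c(3, -1)), 1)
  expect_equal(cell_mean(log(3), c(1, 0), c(0, 5)), 3)
  expect_equal(cell_mean(1, c(0.5, -0.5), c(2, 2)), exp(1),
               tolerance = 1e-12)
  expect_warning(v <- cell_mean(40, c(0), c(0)), "clip")
  expect_equal(v, exp(30))
})

test_that("conditional log-likelihood equals the term-by-term oracle", {
  x <- make_toy_collection(m = 2, nk = c(2, 2), seed = 3)
  Z <- matrix(rnorm(4, sd = 0.5), 2, 2)
  coef <- random_coefficients(c(2, 2), 2, seed = 4)
  disp <- matrix(c(1.5, 3, 2, 0.8), 2, 2)
  expect_equal(conditional_loglik(x, Z, coef, disp),
               oracle_conditional_loglik(x, Z, coef, disp),
               tolerance = 1e-8)

  # single entry collapses to one pmf term
  x1 <- dataset_collection(list(matrix(c(4, 7), 2, 1)))
  Z1 <- matrix(c(0.2, -0.1), 2, 1)
  c1 <- cell_coefficients(alpha = list(1.1), beta = list(matrix(0.4)))
  d1 <- matrix(c(2, 2), 2, 1)
  u_i <- exp(1.1 + 0.4 * Z1[, 1])
  expect_equal(conditional_loglik(x1, Z1, c1, d1),
               sum(nb_logpmf(c(4, 7), u_i, 2)), tolerance = 1e-10)
})

test_that("with zero loadings the likelihood ignores the latent coordinates", {
  x <- make_toy_collection(m = 5, nk = c(4), seed = 5)
  coef <- cell_coefficients(alpha = list(rnorm(4)),
                            beta = list(matrix(0, 4, 2)))
  disp <- matrix(2, 5, 1)
  set.seed(9)
  l1 <- conditional_loglik(x, matrix(rnorm(10), 5, 2), coef, disp)
  l2 <- conditional_loglik(x, matrix(rnorm(10, 5), 5, 2), coef, disp)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("joint likelihood adds the standard-normal prior exactly", {
  x <- make_toy_collection(m = 3, nk = c(2), seed = 6)
  coef <- random_coefficients(c(2), 2, seed = 7)
  disp <- matrix(1.7, 3, 1)
  # all-zero latent coordinates: prior contributes -log(2*pi) per gene
  Z0 <- matrix(0, 3, 2)
  expect_equal(joint_loglik(x, Z0, coef, disp),
               conditional_loglik(x, Z0, coef, disp) + 3 * (-log(2 * pi)),
               tolerance = 1e-10)
  # random coordinates: oracle decomposition
  set.seed(8)
  Z <- matrix(rnorm(6), 3, 2)
  expect_equal(joint_loglik(x, Z, coef, disp),
               conditional_loglik(x, Z, coef, disp) +
                 sum(dnorm(Z, log = TRUE)), tolerance = 1e-10)
})

test_that("penalty subtracts the weighted L1 norm of the loadings", {
  x <- dataset_collection(list(matrix(c(1, 2), 2, 1)))
  Z <- matrix(c(0.1, -0.2, 0.3, 0), 2, 2)
  coef <- cell_coefficients(alpha = list(0.5),
                            beta = list(matrix(c(0.5, -2), 1, 2)))
  disp <- matrix(2, 2, 1)
  jl <- joint_loglik(x, Z, coef, disp)
  expect_equal(penalized_loglik(x, Z, coef, disp, delta = 0), jl)
  expect_equal(penalized_loglik(x, Z, coef, disp, delta = 1), jl - 2.5,
               tolerance = 1e-10)
  expect_lte(penalized_loglik(x, Z, coef, disp, delta = 0.3), jl)
  expect_error(penalized_loglik(x, Z, coef, disp, delta = -1),
               "non-negative")
})

test_that("likelihood is invariant under joint rotation of Z and loadings", {
  x <- make_toy_collection(m = 6, nk = c(3, 2), seed = 10)
  disp <- matrix(runif(12, 0.5, 4), 6, 2)
  for (rep in 1:3) {
    set.seed(20 + rep)
    Z <- matrix(rnorm(12), 6, 2)
    coef <- random_coefficients(c(3, 2), 2, seed = 30 + rep)
    Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
    Zr <- Z %*% Q
    coef_r <- cell_coefficients(coef$alpha,
                                lapply(coef$beta, function(B) B %*% Q))
    expect_equal(conditional_loglik(x, Zr, coef_r, disp),
                 conditional_loglik(x, Z, coef, disp), tolerance = 1e-8)
  }
})

test_that("shape mismatches are rejected with structural errors", {
  x <- make_toy_collection(m = 4, nk = c(3, 2))
  coef <- random_coefficients(c(3, 2), 2)
  disp <- matrix(2, 4, 2)
  expect_error(conditional_loglik(x, matrix(0, 3, 2), coef, disp), "row")
  expect_error(conditional_loglik(x, matrix(0, 4, 3), coef, disp),
               "dimension")
  expect_error(conditional_loglik(x, matrix(0, 4, 2), coef,
                                  matrix(2, 4, 1)), "m x K")
  expect_error(conditional_loglik(x, matrix(0, 4, 2), coef,
                                  matrix(-1, 4, 2)), "positive")
})

test_that("count matrices are validated on construction", {
  expect_error(dataset_collection(list(matrix(c(1, -1, 0, 2), 2))),
               "negative")
  expect_error(dataset_collection(list(matrix(c(1, 0.5, 0, 2), 2))),
               "non-integer")
  expect_error(dataset_collection(list(matrix(0, 2, 2),
                                       matrix(0, 3, 2))), "rows")
  expect_error(dataset_collection(list(a = matrix(0, 2, 2),
                                       a = matrix(0, 2, 2))), "unique")
})
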