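test_that("moment dispersion estimates invert the NB variance formula", {
  # residual variance 6 around a flat fit of 2 gives theta = 4/(6-2) = 1
  x <- dataset_collection(list(matrix(c(0, 0, 3, 5,
                                        1, 1, 1, 1), 2, 4, byrow = TRUE)))
  means <- list(matrix(2, 2, 4))
  th <- estimate_dispersion(x, means)
  expect_equal(th[1, 1], 1, tolerance = 1e-12)

  # under-dispersed genes (variance <= mean) are clamped to the Poisson limit
  x2 <- dataset_collection(list(rbind(rep(2, 4), rep(5, 4))))
  means2 <- list(matrix(rowMeans(x2$datasets[[1]]), 2, 4))
  th2 <- estimate_dispersion(x2, means2)
  expect_equal(unname(th2[, 1]), c(1e8, 1e8))

  # sampling distribution: NB(5, 2) with 2000 cells recovers theta ~ 2
  set.seed(11)
  D <- matrix(rnbinom(3 * 2000, mu = 5, size = 2), 3, 2000)
  x3 <- dataset_collection(list(D))
  th3 <- estimate_dispersion(x3, list(matrix(rowMeans(D), 3, 2000)))
  expect_true(all(th3 >= 1.5 & th3 <= 2.7))
})

test_that("per-cell coordinate descent matches a general-purpose optimizer", {
  set.seed(21)
  for (rep in 1:4) {
    m <- 5
    Z <- matrix(rnorm(m * 2), m, 2)
    theta <- runif(m, 0.8, 4)
    x <- rnbinom(m, mu = exp(1 + Z %*% c(0.7, -0.4)), size = theta)
    for (delta in c(0, 0.5)) {
      fit <- update_cell_coefficients(x, Z, theta, delta)
      obj_cd <- r_cell_objective(c(fit$alpha, fit$beta), x, Z, theta, delta)
      orc <- optim(c(log(mean(x) + 0.1), 0, 0), r_cell_objective,
                   x = x, Z = Z, theta = theta, delta = delta,
                   method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12))
      expect_lte(obj_cd, orc$value + 1e-4)
    }
  }
})

test_that("an infinite penalty zeroes the loadings and leaves the NB intercept", {
  set.seed(22)
  Z <- matrix(rnorm(12), 6, 2)
  x <- rnbinom(6, mu = 6, size = 3)
  theta <- rep(3, 6)   # common dispersion: intercept MLE is the sample mean
  fit <- update_cell_coefficients(x, Z, theta, delta_k = 1e7)
  expect_equal(fit$beta, c(0, 0))
  expect_equal(fit$alpha, log(mean(x)), tolerance = 1e-5)
})

test_that("a cell with no counts gets the floored offset and a warning", {
  Z <- matrix(rnorm(8), 4, 2)
  expect_warning(fit <- update_cell_coefficients(rep(0, 4), Z, rep(2, 4),
                                                 0.1), "no counts")
  expect_equal(fit$alpha, log(1e-4))
  expect_equal(fit$beta, c(0, 0))
})

test_that("a full M-step does not decrease the penalized joint likelihood", {
  x <- make_toy_collection(m = 8, nk = c(6, 5), u = 6, theta = 2, seed = 31)
  set.seed(32)
  Z <- matrix(rnorm(16, sd = 0.7), 8, 2)
  coef0 <- random_coefficients(c(6, 5), 2, seed = 33)
  disp <- matrix(runif(16, 1, 4), 8, 2)
  delta <- c(0.1, 0.2)
  before <- penalized_loglik(x, Z, coef0, disp, delta)
  new_coef <- list(alpha = list(), beta = list())
  for (k in 1:2) {
    a <- numeric(0); B <- NULL
    for (j in seq_len(ncol(x$datasets[[k]]))) {
      f <- update_cell_coefficients(x$datasets[[k]][, j], Z, disp[, k],
                                    delta[k], alpha0 = coef0$alpha[[k]][j],
                                    beta0 = coef0$beta[[k]][j, ])
      a <- c(a, f$alpha); B <- rbind(B, f$beta)
    }
    new_coef$alpha[[k]] <- a
    new_coef$beta[[k]] <- B
  }
  after <- penalized_loglik(x, Z, cell_coefficients(new_coef$alpha,
                                                    new_coef$beta),
                            disp, delta)
  expect_gte(after, before - 1e-8)
})

test_that("the sampler is deterministic under a fixed seed", {
  x <- make_toy_collection(m = 4, nk = c(3), seed = 41)
  coef <- random_coefficients(c(3), 2, seed = 42)
  disp <- matrix(2, 4, 1)
  cfg <- fit_config(2, n_mcmc_samples = 50, mcmc_burnin = 20)
  Z0 <- matrix(0, 4, 2)
  set.seed(7); s1 <- sample_latents(x, coef, disp, Z0, cfg)
  set.seed(7); s2 <- sample_latents(x, coef, disp, Z0, cfg)
  expect_identical(s1$Z, s2$Z)
  expect_identical(s1$accept, s2$accept)
})

test_that("posterior mean from the chain matches 1-D quadrature", {
  # single gene, single cell, lambda = 1: the posterior is tractable by
  # numerical integration of phi(z) * NB(x | exp(a + b z), theta)
  a <- 0.5; b <- 0.8; th <- 2; xval <- 7
  post <- function(z)
    dnorm(z) * exp(nb_logpmf(xval, pmin(exp(a + b * z), 1e12), th))
  norm_const <- integrate(post, -8, 8)$value
  truth <- integrate(function(z) z * post(z), -8, 8)$value / norm_const

  x <- dataset_collection(list(matrix(c(xval, 1), 2, 1)))
  coef <- cell_coefficients(alpha = list(a), beta = list(matrix(b)))
  disp <- matrix(th, 2, 1)
  cfg <- fit_config(1, n_mcmc_samples = 4000, mcmc_burnin = 500,
                    proposal_sd = 0.8)
  set.seed(5)
  s <- sample_latents(x, coef, disp, matrix(0, 2, 1), cfg,
                      keep_samples = TRUE)
  draws <- s$samples[, 1, 1]
  ess_floor <- length(draws) / 20          # generous autocorrelation margin
  mc_se <- sd(draws) / sqrt(ess_floor)
  expect_lt(abs(mean(draws) - truth), 3 * mc_se)
})

test_that("the MCEM fit is reproducible and recovers planted clusters", {
  co <- generate_nb_cohort(n_sets = 2, n_genes = 60, n_clusters = 3,
                           cells_per_dataset = 100, seed = 51)
  x <- co$collections[[2]]
  cfg <- fit_config(3, rng_seed = 9, n_em_iters = 8)
  f1 <- nbcoex(x, cfg)
  f2 <- nbcoex(x, cfg)
  expect_identical(f1$embedding, f2$embedding)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_true(all(is.finite(f1$loglik_trace)))
  a <- cluster_latent(f1$embedding, 3, seed = 1)
  expect_gte(adjusted_rand_index(a$labels, co$true_labels), 0.9)
})

test_that("a single dataset (K = 1) fits without error", {
  co <- generate_nb_cohort(n_sets = 1, n_genes = 30, n_clusters = 3,
                           cells_per_dataset = 40, seed = 52)
  fit <- nbcoex(co$collections[[1]], fit_config(2, rng_seed = 3,
                                                n_em_iters = 4))
  expect_s3_class(fit, "nbcoex_fit")
  expect_equal(dim(fit$embedding), c(30, 2))
})

test_that("permuting dataset order permutes coefficients but not the embedding", {
  co <- generate_nb_cohort(n_sets = 2, n_genes = 24, n_clusters = 3,
                           cells_per_dataset = 30, seed = 53)
  x12 <- co$collections[[2]]
  x21 <- dataset_collection(rev(x12$datasets),
                            gene_ids = x12$gene_ids,
                            dataset_ids = rev(x12$dataset_ids))
  cfg <- fit_config(2, rng_seed = 17, n_em_iters = 4)
  f12 <- nbcoex(x12, cfg)
  f21 <- nbcoex(x21, cfg)
  expect_identical(f12$embedding, f21$embedding)
  expect_identical(f12$coef$alpha[[1]], f21$coef$alpha[[2]])
  expect_identical(f12$coef$beta[[2]], f21$coef$beta[[1]])
  expect_identical(f12$disp[, 1], f21$disp[, 2])
})

test_that("a converged fit is stable under doubling the iteration cap", {
  co <- generate_nb_cohort(n_sets = 1, n_genes = 30, n_clusters = 3,
                           cells_per_dataset = 40, seed = 55)
  x <- co$collections[[1]]
  f1 <- nbcoex(x, fit_config(2, rng_seed = 5, n_em_iters = 30))
  expect_true(f1$converged)
  f2 <- nbcoex(x, fit_config(2, rng_seed = 5, n_em_iters = 60))
  p1 <- tail(f1$loglik_trace, 1)
  p2 <- tail(f2$loglik_trace, 1)
  expect_lt(abs(p1 - p2) / abs(p1), 10 * 1e-4)
})

test_that("BIC table is structurally sound and trivial selection works", {
  co <- generate_nb_cohort(n_sets = 1, n_genes = 30, n_clusters = 3,
                           cells_per_dataset = 40, seed = 54)
  x <- co$collections[[1]]
  cfg <- fit_config(2, rng_seed = 3, n_em_iters = 3)
  sel1 <- select_lambda_bic(x, 2, cfg)
  expect_equal(sel1$best_lambda, 2)
  expect_equal(nrow(sel1$bic_table), 1)
  expect_true(is.finite(sel1$bic_table$bic))
  sel <- select_lambda_bic(x, c(3, 2), cfg)
  expect_equal(sel$bic_table$lambda, c(3, 2))  # candidate order preserved
  expect_true(all(is.finite(sel$bic_table$bic)))
  # BIC formula: -2 loglik + p log N with p = n(1+lambda) + m lambda
  row <- sel$bic_table[sel$bic_table$lambda == 2, ]
  p <- 40 * 3 + 30 * 2
  expect_equal(row$bic, -2 * row$loglik + p * log(30 * 40),
               tolerance = 1e-8)
})
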