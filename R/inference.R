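#' Configuration for the Monte-Carlo EM fit
#'
#' @param lambda_dim dimension of the latent space; also the default number
#'   of gene modules.
#' @param n_mcmc_samples retained Metropolis-Hastings draws per gene per
#'   E-step (posterior means are taken over these).
#' @param mcmc_burnin discarded draws at the start of each chain.
#' @param proposal_sd standard deviation of the Gaussian random-walk proposal.
#' @param n_em_iters maximum EM iterations.
#' @param em_tol relative change in the (smoothed) penalized joint
#'   log-likelihood below which the fit is declared converged.
#' @param delta L1 penalty weight per dataset; `NULL` uses the automatic rule
#'   `sqrt(log(lambda_dim) / m)` for every dataset.
#' @param rng_seed integer seed controlling all randomness in the fit.
#' @return a `fit_config` list.
#' @export
fit_config <- function(lambda_dim, n_mcmc_samples = 200L, mcmc_burnin = 100L,
                       proposal_sd = 0.3, n_em_iters = 30L, em_tol = 1e-4,
                       delta = NULL, rng_seed = 1L) {
  stopifnot(lambda_dim >= 1, n_mcmc_samples >= 1, mcmc_burnin >= 0,
            proposal_sd > 0, n_em_iters >= 1, em_tol > 0)
  if (!is.null(delta) && (any(delta < 0) || any(!is.finite(delta))))
    stop("delta must be non-negative and finite")
  structure(list(lambda_dim = as.integer(lambda_dim),
                 n_mcmc_samples = as.integer(n_mcmc_samples),
                 mcmc_burnin = as.integer(mcmc_burnin),
                 proposal_sd = proposal_sd,
                 n_em_iters = as.integer(n_em_iters),
                 em_tol = em_tol, delta = delta,
                 rng_seed = as.integer(rng_seed)),
            class = "fit_config")
}

.default_delta <- function(lambda_dim, m) sqrt(log(max(lambda_dim, 1)) / m)

# log of the pseudo-mean used for cells with no counts at all
.ZERO_CELL_LOG_MEAN <- log(1e-4)

#' Method-of-moments dispersion estimates per gene and dataset
#'
#' Inverts `Var(x) = u + u^2/theta` using the mean fitted value `u_bar` and
#' the residual variance `s^2` around the fitted means:
#' `theta_hat = u_bar^2 / (s^2 - u_bar)`, clamped to `[0.01, 1e8]`, with
#' `1e8` (effectively Poisson) whenever `s^2 <= u_bar`.
#'
#' @param x a [dataset_collection()].
#' @param means list over datasets of fitted-mean matrices (same shapes as
#'   the count matrices).
#' @return m x K matrix of dispersions.
#' @export
estimate_dispersion <- function(x, means) {
  K <- length(x$datasets)
  m <- n_genes(x)
  theta <- matrix(NA_real_, m, K, dimnames = list(x$gene_ids, x$dataset_ids))
  for (k in seq_len(K)) {
    U <- means[[k]]
    if (any(U <= 0)) stop("fitted means must be strictly positive")
    D <- x$datasets[[k]]
    n <- ncol(D)
    ubar <- rowMeans(U)
    s2 <- if (n > 1) rowSums((D - U)^2) / (n - 1) else rep(0, m)
    th <- ifelse(s2 > ubar, ubar^2 / (s2 - ubar), 1e8)
    theta[, k] <- pmin(pmax(th, 0.01), 1e8)
  }
  theta
}

#' Fit one cell's penalized negative-binomial regression
#'
#' Minimises the per-cell negative NB log-likelihood plus
#' `delta * ||beta||_1` over the offset `alpha` and loading vector `beta`,
#' with the latent coordinates `Z` as fixed covariates.  Solved by iteratively
#' reweighted least squares with coordinate-wise soft-thresholding on `beta`
#' (the offset is never penalized); step-halving keeps the objective
#' non-increasing.
#'
#' @param x_col counts of one cell across the m genes.
#' @param Z m x lambda matrix of latent gene coordinates.
#' @param theta_col dispersion per gene for the cell's dataset.
#' @param delta_k non-negative L1 penalty weight.
#' @param alpha0,beta0 optional warm starts.
#' @param maxit,tol IRLS iteration cap and relative objective tolerance.
#' @return list with `alpha` (scalar) and `beta` (lambda-vector).  A cell
#'   with no counts at all gets `alpha = log(1e-4)`, `beta = 0` and a warning.
#' @export
update_cell_coefficients <- function(x_col, Z, theta_col, delta_k,
                                     alpha0 = NULL, beta0 = NULL,
                                     maxit = 50L, tol = 1e-8) {
  Z <- as.matrix(Z)
  m <- nrow(Z)
  stopifnot(length(x_col) == m, length(theta_col) == m, delta_k >= 0)
  if (is.null(alpha0)) alpha0 <- log(max(mean(x_col), 1e-4))
  if (is.null(beta0)) beta0 <- rep(0, ncol(Z))
  res <- cpp_update_cells(matrix(as.double(x_col), ncol = 1), Z,
                          matrix(theta_col, ncol = 1), 0L, delta_k,
                          alpha0, matrix(beta0, nrow = 1),
                          as.integer(maxit), tol, .ZERO_CELL_LOG_MEAN)
  if (length(res$zero_cells))
    warning("cell has no counts; offset floored at log(1e-4)", call. = FALSE)
  list(alpha = res$alpha[1L], beta = drop(res$beta))
}

# Flatten coefficients (canonical dataset order) into per-cell vectors.
.flat_coef <- function(coef_list) {
  list(alpha = unlist(lapply(coef_list, `[[`, "alpha"), use.names = FALSE),
       beta = do.call(rbind, lapply(coef_list, `[[`, "beta")))
}

#' Sample the latent gene coordinates from their posterior
#'
#' One E-step: for each gene a random-walk Metropolis-Hastings chain targets
#' the unnormalized posterior `phi(z_i) * prod_jk f(x_ijk | z_i, ...)` with
#' the cell coefficients and dispersions held fixed.  The returned `Z` is the
#' mean of the post-burn-in draws (the Monte-Carlo EM expectation).  A gene
#' whose chain accepts nothing is re-run once with the proposal sd halved.
#'
#' @inheritParams conditional_loglik
#' @param Z_current starting coordinates (m x lambda).
#' @param config a [fit_config()].
#' @param keep_samples if `TRUE`, also return the retained draws
#'   (`n_mcmc_samples` x lambda x m array) for diagnostics.
#' @param proposal_sd optional per-gene proposal standard deviations
#'   (recycled to m), overriding `config$proposal_sd`.
#' @return list with `Z` (posterior means), `Zvar` (posterior variances),
#'   `accept` (per-gene acceptance rate), `mean_accept`, and optionally
#'   `samples`.
#' @export
sample_latents <- function(x, coef, disp, Z_current, config,
                           keep_samples = FALSE, proposal_sd = NULL) {
  .check_shapes(x, Z_current, coef, disp)
  fl <- .flatten_collection(x)
  coefc <- lapply(fl$order, function(k)
    list(alpha = coef$alpha[[k]], beta = coef$beta[[k]]))
  fc <- .flat_coef(coefc)
  thetac <- disp[, fl$order, drop = FALSE]
  ps <- rep_len(if (is.null(proposal_sd)) config$proposal_sd
                else proposal_sd, nrow(Z_current))
  res <- cpp_sample_latents(fl$X, fc$alpha, fc$beta, thetac,
                            fl$cell_dataset - 1L, as.matrix(Z_current),
                            config$n_mcmc_samples, config$mcmc_burnin,
                            ps, keep_samples)
  stuck <- which(res$accept == 0)
  if (length(stuck)) {
    warning(length(stuck), " gene chain(s) accepted nothing; re-running ",
            "with halved proposal sd", call. = FALSE)
    res2 <- cpp_sample_latents(fl$X[stuck, , drop = FALSE], fc$alpha,
                               fc$beta, thetac[stuck, , drop = FALSE],
                               fl$cell_dataset - 1L,
                               as.matrix(Z_current)[stuck, , drop = FALSE],
                               config$n_mcmc_samples, config$mcmc_burnin,
                               ps[stuck] / 2, FALSE)
    res$mean[stuck, ] <- res2$mean
    res$var[stuck, ] <- res2$var
    res$accept[stuck] <- res2$accept
  }
  out <- list(Z = res$mean, Zvar = res$var, accept = as.numeric(res$accept),
              mean_accept = mean(res$accept))
  if (keep_samples) out$samples <- res$samples
  out
}

# PCA initialisation of the latent coordinates: log1p of depth-normalised
# counts, genes standardised, first lambda principal scores rescaled to unit
# variance (the scale of the standard-normal prior).
.init_embedding <- function(X, lambda_dim) {
  depth <- pmax(colSums(X), 1)
  M <- log1p(sweep(X, 2L, depth, "/") * 1e4)
  rs <- apply(M, 1L, sd)
  M <- (M - rowMeans(M)) / ifelse(rs > 0, rs, 1)
  r <- min(lambda_dim, nrow(M) - 1L, ncol(M))
  Z <- matrix(0, nrow(M), lambda_dim)
  if (r >= 1) {
    pc <- prcomp(M, center = FALSE, rank. = r)
    Z[, seq_len(r)] <- pc$x[, seq_len(r), drop = FALSE]
  }
  csd <- apply(Z, 2L, sd)
  sweep(Z, 2L, ifelse(csd > 0, csd, 1), "/")
}

.diagnose_divergence <- function(xc, Z, coefc, thetac) {
  for (k in seq_along(xc$datasets)) {
    U <- .dataset_means(Z, coefc$alpha[[k]], coefc$beta[[k]])
    L <- nb_logpmf(xc$datasets[[k]], u = pmax(U, 1e-300),
                   theta = thetac[, k])
    bad <- which(!is.finite(L), arr.ind = TRUE)
    if (nrow(bad))
      stop("divergent fit: non-finite likelihood for gene '",
           xc$gene_ids[bad[1, 1]], "', cell ", bad[1, 2], " of dataset '",
           xc$dataset_ids[k], "'", call. = FALSE)
  }
  stop("divergent fit: non-finite penalized log-likelihood", call. = FALSE)
}

#' Fit the consensus latent-variable NB model by Monte-Carlo EM
#'
#' Alternates Metropolis-Hastings sampling of each gene's latent coordinate
#' (E-step, [sample_latents()]) with coordinate-descent updates of every
#' cell's offset and loadings plus method-of-moments dispersion updates
#' (M-step), until the penalized joint log-likelihood stabilises.  Because
#' the E-step is Monte Carlo, convergence is judged on a 3-iteration moving
#' average of the trace.
#'
#' @param x a [dataset_collection()].
#' @param config a [fit_config()]; `config$lambda_dim` sets the latent
#'   dimension.
#' @return an object of class `nbcoex_fit` with elements `embedding`
#'   (m x lambda posterior-mean coordinates), `coef`
#'   ([cell_coefficients()] in the input dataset order), `disp` (m x K),
#'   `loglik_trace`, `converged`, `mean_accept`, `delta` and `config`.
#' @seealso [cluster_latent()] to turn the embedding into gene modules,
#'   [select_lambda_bic()] to choose the latent dimension.
#' @export
nbcoex <- function(x, config) {
  stopifnot(inherits(x, "dataset_collection"), inherits(config, "fit_config"))
  set.seed(config$rng_seed)
  m <- n_genes(x)
  lam <- config$lambda_dim
  fl <- .flatten_collection(x)
  # canonical-order view of the collection; everything internal uses it
  xc <- dataset_collection(x$datasets[fl$order],
                           gene_ids = x$gene_ids,
                           dataset_ids = x$dataset_ids[fl$order])
  K <- length(xc$datasets)
  nk <- n_cells(xc)
  # penalty per dataset, reordered to the canonical dataset order
  delta <- if (is.null(config$delta)) rep(.default_delta(lam, m), K)
           else rep_len(config$delta, K)[fl$order]

  Z <- .init_embedding(fl$X, lam)
  # flat-fit moment dispersions to start
  means0 <- lapply(xc$datasets, function(D)
    matrix(pmax(rowMeans(D), 1e-4), nrow(D), ncol(D)))
  theta <- estimate_dispersion(xc, means0)
  alpha <- log(pmax(colMeans(fl$X), 1e-4))
  beta <- matrix(0, ncol(fl$X), lam)
  delta_cell <- delta[fl$cell_dataset]

  trace <- numeric(0)
  converged <- FALSE
  mean_accept <- NA_real_
  warned_zero <- FALSE
  # per-gene proposal scales, adapted between E-steps toward ~30% acceptance
  # (each individual chain still uses a fixed kernel)
  prop <- rep(config$proposal_sd, m)
  for (it in seq_len(config$n_em_iters)) {
    # E-step
    e <- cpp_sample_latents(fl$X, alpha, beta, theta, fl$cell_dataset - 1L,
                            Z, config$n_mcmc_samples, config$mcmc_burnin,
                            prop, FALSE)
    stuck <- which(e$accept == 0)
    if (length(stuck)) {
      prop[stuck] <- prop[stuck] / 2
      e2 <- cpp_sample_latents(fl$X[stuck, , drop = FALSE], alpha, beta,
                               theta[stuck, , drop = FALSE],
                               fl$cell_dataset - 1L, Z[stuck, , drop = FALSE],
                               config$n_mcmc_samples, config$mcmc_burnin,
                               prop[stuck], FALSE)
      e$mean[stuck, ] <- e2$mean
      e$accept[stuck] <- e2$accept
    }
    Z <- e$mean
    mean_accept <- mean(e$accept)
    prop <- pmin(pmax(prop * exp(1.5 * (e$accept - 0.3)), 0.02), 3)
    # M-step: per-cell coefficients, then dispersions
    mres <- cpp_update_cells(fl$X, Z, theta, fl$cell_dataset - 1L,
                             delta_cell, alpha, beta, 50L, 1e-8,
                             .ZERO_CELL_LOG_MEAN)
    if (length(mres$zero_cells) && !warned_zero) {
      warning(length(mres$zero_cells), " cell(s) with no counts; offsets ",
              "floored at log(1e-4)", call. = FALSE)
      warned_zero <- TRUE
    }
    alpha <- as.numeric(mres$alpha)
    beta <- mres$beta
    coefc <- .split_coef(alpha, beta, nk)
    means <- lapply(seq_len(K), function(k)
      .dataset_means(Z, coefc$alpha[[k]], coefc$beta[[k]]))
    theta <- estimate_dispersion(xc, means)

    cc <- cell_coefficients(coefc$alpha, coefc$beta)
    pll <- penalized_loglik(xc, Z, cc, theta, delta)
    if (!is.finite(pll)) .diagnose_divergence(xc, Z, coefc, theta)
    trace <- c(trace, pll)
    if (.em_converged(trace, config$em_tol)) {
      converged <- TRUE
      break
    }
  }

  # map coefficients and dispersions back to the user's dataset order
  inv <- match(x$dataset_ids, xc$dataset_ids)
  coefc <- .split_coef(alpha, beta, nk)
  coef_user <- cell_coefficients(coefc$alpha[inv], coefc$beta[inv])
  theta_user <- theta[, inv, drop = FALSE]
  colnames(theta_user) <- x$dataset_ids
  rownames(Z) <- x$gene_ids
  structure(list(embedding = Z, coef = coef_user, disp = theta_user,
                 loglik_trace = trace, converged = converged,
                 mean_accept = mean_accept, delta = delta[inv],
                 config = config, gene_ids = x$gene_ids,
                 dataset_ids = x$dataset_ids),
            class = "nbcoex_fit")
}

.split_coef <- function(alpha, beta, nk) {
  idx <- rep(seq_along(nk), nk)
  list(alpha = split(alpha, idx),
       beta = lapply(split(seq_along(alpha), idx),
                     function(j) beta[j, , drop = FALSE]))
}

# Converged when the 3-iteration moving average of the penalized trace
# changes by < tol in relative terms over two consecutive checks.
.em_converged <- function(trace, tol) {
  n <- length(trace)
  if (n < 5L) return(FALSE)
  ma <- function(i) mean(trace[(i - 2L):i])
  rel <- function(a, b) abs(a - b) / (abs(b) + 1e-12)
  rel(ma(n), ma(n - 1L)) < tol && rel(ma(n - 1L), ma(n - 2L)) < tol
}

#' @export
print.nbcoex_fit <- function(x, ...) {
  cat("nbcoex_fit: ", nrow(x$embedding), " genes in a ",
      ncol(x$embedding), "-dimensional latent space; ",
      length(x$dataset_ids), " dataset(s)\n", sep = "")
  cat("  EM iterations: ", length(x$loglik_trace),
      if (x$converged) " (converged)" else " (iteration cap reached)",
      "\n  final penalized log-likelihood: ",
      format(utils::tail(x$loglik_trace, 1)), "\n", sep = "")
  invisible(x)
}

#' Choose the latent dimension by BIC
#'
#' Fits the model at each candidate dimension and scores it with
#' `BIC = -2 * joint log-likelihood + p * log(N)` where
#' `p = sum_k n_k (1 + lambda) + m * lambda` counts the free cell
#' coefficients plus latent coordinates and `N = m * sum_k n_k` the
#' observations.  The joint (unpenalized) likelihood at the fitted values is
#' used.  Ties break toward the smaller dimension.
#'
#' @param x a [dataset_collection()].
#' @param candidate_lambdas integer vector of dimensions to try (each >= 2
#'   recommended for clustering use).
#' @param config a [fit_config()]; its `lambda_dim` is overridden per
#'   candidate.
#' @return list with `best_lambda`, `bic_table` (one row per candidate, in
#'   the given order) and `fits` (the successful `nbcoex_fit` objects).
#' @export
select_lambda_bic <- function(x, candidate_lambdas, config) {
  stopifnot(length(candidate_lambdas) >= 1)
  m <- n_genes(x)
  nk <- n_cells(x)
  N <- m * sum(nk)
  rows <- vector("list", length(candidate_lambdas))
  fits <- vector("list", length(candidate_lambdas))
  for (i in seq_along(candidate_lambdas)) {
    lam <- candidate_lambdas[i]
    cfg <- config
    cfg$lambda_dim <- as.integer(lam)
    fit <- tryCatch(nbcoex(x, cfg), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fit with lambda = ", lam, " failed: ", conditionMessage(fit),
              call. = FALSE)
      rows[[i]] <- data.frame(lambda = lam, loglik = NA_real_,
                              n_params = NA_real_, bic = NA_real_,
                              converged = NA, ok = FALSE)
      next
    }
    ll <- joint_loglik(x, fit$embedding, fit$coef, fit$disp)
    p <- sum(nk) * (1 + lam) + m * lam
    rows[[i]] <- data.frame(lambda = lam, loglik = ll, n_params = p,
                            bic = -2 * ll + p * log(N),
                            converged = fit$converged, ok = TRUE)
    fits[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$ok & is.finite(tab$bic))
  if (!length(ok)) stop("no candidate latent dimension could be fitted")
  best <- ok[tab$bic[ok] <= min(tab$bic[ok]) + 1e-12]
  best_lambda <- min(tab$lambda[best])
  list(best_lambda = best_lambda, bic_table = tab, fits = fits)
}
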