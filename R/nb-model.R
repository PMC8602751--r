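#' Negative-binomial log probability mass
#'
#' Mean/dispersion parameterisation with `Var(x) = u + u^2 / theta`: the
#' probability of a count x is
#' `Gamma(x + theta) / (Gamma(theta) Gamma(1 + x)) *
#'  (theta / (theta + u))^theta * (u / (theta + u))^x`.
#' Computed on the log scale with `lgamma`, never with raw factorials, so it
#' is stable for large counts and dispersions.
#'
#' @param x vector of non-negative integer counts.
#' @param u mean(s), strictly positive (recycled against `x`).
#' @param theta dispersion(s), strictly positive (recycled).
#' @return vector of log-probabilities.
#' @examples
#' nb_logpmf(0, u = 1, theta = 1)  # log(1/2)
#' @export
nb_logpmf <- function(x, u, theta) {
  if (any(!is.finite(x)) || any(x < 0) || max(abs(x - round(x))) > 0)
    stop("x must be non-negative integers")
  if (any(!is.finite(u)) || any(u <= 0)) stop("u must be positive and finite")
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be positive and finite")
  lgamma(x + theta) - lgamma(theta) - lgamma(1 + x) +
    theta * (log(theta) - log(theta + u)) + x * (log(u) - log(theta + u))
}

#' Moments of the negative binomial in mean/dispersion form
#'
#' @inheritParams nb_logpmf
#' @return list with `mean = u` and `variance = u + u^2 / theta`.
#' @export
nb_mean_var <- function(u, theta) {
  if (any(u <= 0) || any(theta <= 0)) stop("u and theta must be positive")
  list(mean = u, variance = u + u^2 / theta)
}

#' Convert between (mean, dispersion) and (p, gamma) parameterisations
#'
#' `p = u / (u + theta)`, `gamma = theta`; the inverse is
#' `u = p * gamma / (1 - p)`.  The two forms round-trip exactly.
#'
#' @param u,theta mean and dispersion.
#' @param p,gamma success probability in (0,1) and size.
#' @return named list with the other parameterisation.
#' @export
nb_to_pgamma <- function(u, theta) {
  if (any(u <= 0) || any(theta <= 0)) stop("u and theta must be positive")
  list(p = u / (u + theta), gamma = theta)
}

#' @rdname nb_to_pgamma
#' @export
nb_from_pgamma <- function(p, gamma) {
  if (any(p <= 0) || any(p >= 1) || any(gamma <= 0))
    stop("need 0 < p < 1 and gamma > 0")
  list(u = p * gamma / (1 - p), theta = gamma)
}

#' Conditional mean of one count given a gene's latent coordinate
#'
#' The log-linear link `log u = alpha + beta . z`: `alpha` is the cell's
#' offset (library size, capture efficiency), `beta` its loading onto the
#' latent space, and `z` the gene's latent coordinate.  The linear predictor
#' is clipped at 30 (with a warning) to keep degenerate iterates finite.
#'
#' @param alpha scalar cell offset.
#' @param beta numeric loading vector (length = latent dimension).
#' @param z numeric latent coordinate, same length as `beta`.
#' @return the positive conditional mean `exp(alpha + sum(beta * z))`.
#' @export
cell_mean <- function(alpha, beta, z) {
  stopifnot(is.finite(alpha), all(is.finite(beta)), all(is.finite(z)),
            length(beta) == length(z))
  exp(.clip_link(alpha + sum(beta * z)))
}

# ---- structured parameter containers ---------------------------------------

#' Per-cell offsets and loadings
#'
#' @param alpha list over datasets of numeric offset vectors (length n_k).
#' @param beta list over datasets of n_k x lambda loading matrices.
#' @return object of class `cell_coefficients`.
#' @export
cell_coefficients <- function(alpha, beta) {
  stopifnot(is.list(alpha), is.list(beta), length(alpha) == length(beta))
  lam <- ncol(beta[[1L]])
  for (k in seq_along(alpha)) {
    beta[[k]] <- as.matrix(beta[[k]])
    if (length(alpha[[k]]) != nrow(beta[[k]]))
      stop("dataset ", k, ": alpha length and beta rows disagree")
    if (ncol(beta[[k]]) != lam)
      stop("dataset ", k, ": inconsistent latent dimension in beta")
    if (!all(is.finite(alpha[[k]])) || !all(is.finite(beta[[k]])))
      stop("dataset ", k, ": non-finite coefficients")
  }
  structure(list(alpha = alpha, beta = beta, lambda_dim = lam),
            class = "cell_coefficients")
}

.check_shapes <- function(x, Z, coef, disp) {
  m <- n_genes(x)
  K <- length(x$datasets)
  if (nrow(Z) != m) stop("Z must have one row per gene")
  if (length(coef$alpha) != K) stop("coefficients cover ", length(coef$alpha),
                                    " datasets; collection has ", K)
  if (ncol(Z) != coef$lambda_dim)
    stop("latent dimension of Z and coefficients disagree")
  nk <- n_cells(x)
  for (k in seq_len(K))
    if (length(coef$alpha[[k]]) != nk[k])
      stop("dataset ", k, ": ", length(coef$alpha[[k]]),
           " coefficient cells vs ", nk[k], " data cells")
  if (!is.matrix(disp) || nrow(disp) != m || ncol(disp) != K)
    stop("dispersion must be an m x K matrix")
  if (any(!is.finite(disp)) || any(disp <= 0))
    stop("dispersions must be strictly positive and finite")
  invisible(TRUE)
}

# All conditional means for one dataset: m x n_k matrix exp(alpha_j + Z beta_j')
.dataset_means <- function(Z, alpha_k, beta_k) {
  eta <- Z %*% t(beta_k)                       # m x n_k
  eta <- sweep(eta, 2L, alpha_k, "+")
  exp(.clip_link(eta))
}

#' Conditional log-likelihood of the counts given the latent coordinates
#'
#' Sums `nb_logpmf(x_ijk; theta_ik, exp(alpha_jk + beta_jk . z_i))` over all
#' genes i, cells j and datasets k.
#'
#' @param x a [dataset_collection()].
#' @param Z m x lambda matrix of latent gene coordinates.
#' @param coef a [cell_coefficients()] object.
#' @param disp m x K matrix of gene-by-dataset dispersions.
#' @return scalar log-likelihood.
#' @export
conditional_loglik <- function(x, Z, coef, disp) {
  .check_shapes(x, Z, coef, disp)
  ll <- 0
  # canonical dataset order => result invariant to user-supplied ordering
  for (k in order(x$dataset_ids)) {
    U <- .dataset_means(Z, coef$alpha[[k]], coef$beta[[k]])
    ll <- ll + sum(nb_logpmf(x$datasets[[k]], u = U, theta = disp[, k]))
  }
  ll
}

#' Joint log-likelihood: counts plus standard-normal latent prior
#'
#' Adds `sum_i log phi_lambda(z_i)` to [conditional_loglik()], where
#' `phi_lambda` is the standard lambda-variate normal density.
#'
#' @inheritParams conditional_loglik
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(x, Z, coef, disp) {
  conditional_loglik(x, Z, coef, disp) + sum(dnorm(Z, log = TRUE))
}

#' Penalized joint log-likelihood
#'
#' [joint_loglik()] minus the L1 penalty
#' `sum_k sum_j delta_k * ||beta_jk||_1` that shrinks per-cell loadings and
#' guards against over-fitting the latent projection to individual cells.
#'
#' @inheritParams conditional_loglik
#' @param delta non-negative penalty weight per dataset (length K, recycled
#'   from a scalar).
#' @return scalar penalized log-likelihood.
#' @export
penalized_loglik <- function(x, Z, coef, disp, delta) {
  K <- length(x$datasets)
  delta <- rep_len(delta, K)
  if (any(!is.finite(delta)) || any(delta < 0))
    stop("penalty weights must be non-negative and finite")
  pen <- sum(vapply(seq_len(K),
                    function(k) delta[k] * sum(abs(coef$beta[[k]])),
                    numeric(1)))
  joint_loglik(x, Z, coef, disp) - pen
}
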