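# Small simulated fixtures and independent oracles shared across tests.

# K NB datasets with no latent structure (null model), for shape/likelihood
# tests.
make_toy_collection <- function(m = 4, nk = c(3, 2), u = 5, theta = 2,
                                seed = 1) {
  set.seed(seed)
  ds <- lapply(nk, function(n)
    matrix(rnbinom(m * n, mu = u, size = theta), m, n))
  names(ds) <- paste0("d", seq_along(ds))
  dataset_collection(ds)
}

random_coefficients <- function(nk, lambda_dim, seed = 1, scale = 0.3) {
  set.seed(seed)
  cell_coefficients(
    alpha = lapply(nk, function(n) rnorm(n, 1, 0.5)),
    beta = lapply(nk, function(n)
      matrix(rnorm(n * lambda_dim, 0, scale), n, lambda_dim)))
}

# Term-by-term conditional log-likelihood oracle using dnbinom directly.
oracle_conditional_loglik <- function(x, Z, coef, disp) {
  total <- 0
  for (k in seq_along(x$datasets)) {
    D <- x$datasets[[k]]
    for (i in seq_len(nrow(D))) {
      for (j in seq_len(ncol(D))) {
        u <- exp(coef$alpha[[k]][j] + sum(coef$beta[[k]][j, ] * Z[i, ]))
        total <- total + dnbinom(D[i, j], mu = u, size = disp[i, k],
                                 log = TRUE)
      }
    }
  }
  unname(total)
}

# O(n^2) pair-counting adjusted Rand oracle.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(0)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Brute-force sums-of-squares oracles for the validity indices.
oracle_ch <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  cl <- unique(labels)
  grand <- colMeans(points)
  W <- 0; B <- 0
  for (c in cl) {
    P <- points[labels == c, , drop = FALSE]
    ctr <- colMeans(P)
    for (r in seq_len(nrow(P))) W <- W + sum((P[r, ] - ctr)^2)
    B <- B + nrow(P) * sum((ctr - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (length(cl) - 1)) / (W / (n - length(cl)))
}

oracle_dunn <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  dmat <- as.matrix(dist(points))
  inter <- Inf; diam <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) diam <- max(diam, dmat[i, j])
      else inter <- min(inter, dmat[i, j])
    }
  }
  if (diam == 0) return(Inf)
  inter / diam
}

oracle_db <- function(points, labels) {
  points <- as.matrix(points)
  cl <- unique(labels)
  ctrs <- t(sapply(cl, function(c)
    colMeans(points[labels == c, , drop = FALSE])))
  s <- sapply(seq_along(cl), function(ci) {
    P <- points[labels == cl[ci], , drop = FALSE]
    mean(sqrt(rowSums(sweep(P, 2, ctrs[ci, ])^2)))
  })
  mean(sapply(seq_along(cl), function(i) {
    max(sapply(setdiff(seq_along(cl), i), function(j) {
      d <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2))
      if (d == 0) Inf else (s[i] + s[j]) / d
    }))
  }))
}

# Data generated from the latent-variable model itself: genes sit at three
# latent centroids (plus isotropic 3-D scatter, so all three dimensions carry
# signal), cells get random offsets and loadings, counts are NB.
make_model_cohort <- function(m = 60, K = 2, n = 100, seed = 1,
                              sigma = 0.7, beta_sd = 0.6, theta = 3) {
  set.seed(seed)
  lab <- rep(1:3, each = m / 3)
  ctr <- rbind(c(2, 0, 0), c(-2, 1.5, 0), c(0, -2, 0))
  Z <- ctr[lab, ] + matrix(rnorm(m * 3, 0, sigma), m, 3)
  ds <- lapply(seq_len(K), function(k) {
    alpha <- rnorm(n, 0.8, 0.3)
    B <- matrix(rnorm(n * 3, 0, beta_sd), n, 3)
    eta <- pmin(sweep(Z %*% t(B), 2, alpha, "+"), 30)
    matrix(rnbinom(length(eta), mu = exp(eta), size = theta), m, n)
  })
  names(ds) <- paste0("d", seq_len(K))
  list(x = dataset_collection(ds), labels = lab, Z = Z)
}

# Penalized per-cell NB objective in plain R, for optimizer oracles.
r_cell_objective <- function(par, x, Z, theta, delta) {
  a <- par[1]
  b <- par[-1]
  eta <- pmin(a + drop(Z %*% b), 30)
  u <- exp(eta)
  sum((x + theta) * log(theta + u) - x * eta) + delta * sum(abs(b))
}
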