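#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of the two
#' label vectors: `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`.  1 for identical partitions
#' up to relabelling; expectation 0 under independent random labelling.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  if (length(labels_a) < 2) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_a <- ch2(rowSums(tab))
  sum_b <- ch2(colSums(tab))
  expected <- sum_a * sum_b / ch2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (abs(maxidx - expected) < .Machine$double.eps) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

.check_points_labels <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels)) stop("one label per point required")
  groups <- split(seq_len(nrow(points)), labels)
  if (length(groups) < 2) stop("need at least 2 clusters")
  list(points = points, groups = groups)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' `[B/(c-1)] / [W/(n-c)]`, with B and W the between/within sums of squared
#' Euclidean distances to the relevant centroids.  Larger is better.  A
#' configuration with zero within-cluster scatter returns `Inf`.
#'
#' @param points n x d numeric matrix.
#' @param labels cluster labels, one per row.
#' @return the index (possibly `Inf`).
#' @export
calinski_harabasz <- function(points, labels) {
  pl <- .check_points_labels(points, labels)
  points <- pl$points; groups <- pl$groups
  n <- nrow(points); c <- length(groups)
  grand <- colMeans(points)
  W <- 0; B <- 0
  for (g in groups) {
    ctr <- colMeans(points[g, , drop = FALSE])
    W <- W + sum(sweep(points[g, , drop = FALSE], 2L, ctr)^2)
    B <- B + length(g) * sum((ctr - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (c - 1)) / (W / (n - c))
}

#' Davies-Bouldin index
#'
#' For each cluster, the worst-case similarity `(s_i + s_j) / d_ij` to any
#' other cluster is taken (s = mean distance of members to their centroid,
#' d = centroid separation); the index is the mean of these maxima.  Smaller
#' is better; coincident centroids give `Inf`.
#'
#' @inheritParams calinski_harabasz
#' @return the index (possibly `Inf`).
#' @export
davies_bouldin <- function(points, labels) {
  pl <- .check_points_labels(points, labels)
  points <- pl$points; groups <- pl$groups
  c <- length(groups)
  ctrs <- t(vapply(groups, function(g) colMeans(points[g, , drop = FALSE]),
                   numeric(ncol(points))))
  s <- vapply(seq_len(c), function(i) {
    g <- groups[[i]]
    mean(sqrt(rowSums(sweep(points[g, , drop = FALSE], 2L, ctrs[i, ])^2)))
  }, numeric(1))
  r <- numeric(c)
  for (i in seq_len(c)) {
    worst <- -Inf
    for (j in seq_len(c)[-i]) {
      d <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2))
      worst <- max(worst, if (d == 0) Inf else (s[i] + s[j]) / d)
    }
    r[i] <- worst
  }
  mean(r)
}

#' Dunn index
#'
#' Minimum distance between points of different clusters divided by the
#' maximum within-cluster diameter.  Larger is better; all-singleton
#' clusterings (diameter 0) give `Inf`.
#'
#' @inheritParams calinski_harabasz
#' @return the index (possibly `Inf`).
#' @export
dunn_index <- function(points, labels) {
  pl <- .check_points_labels(points, labels)
  points <- pl$points; groups <- pl$groups
  D <- as.matrix(stats::dist(points))
  diam <- max(vapply(groups, function(g)
    if (length(g) > 1) max(D[g, g]) else 0, numeric(1)))
  sep <- Inf
  ng <- length(groups)
  for (i in seq_len(ng - 1L))
    for (j in (i + 1L):ng)
      sep <- min(sep, min(D[groups[[i]], groups[[j]]]))
  if (diam == 0) return(Inf)
  sep / diam
}

#' Hypergeometric gene-set enrichment of a module
#'
#' Upper-tail hypergeometric test of the overlap between a gene module and
#' each set in a collection, over the declared gene universe, with
#' Benjamini-Hochberg correction across the collection.  Rows with adjusted
#' p below `alpha` are flagged significant.
#'
#' @param module character vector of gene ids (non-empty, subset of the
#'   universe).
#' @param collection named list of gene sets (character vectors).
#' @param universe character vector of all assayable genes.
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame with columns `set`, `set_size`, `overlap`, `p`,
#'   `p_adj`, `significant`, ordered as the collection.
#' @export
hypergeom_enrich <- function(module, collection, universe, alpha = 0.05) {
  module <- unique(as.character(module))
  if (!length(module)) stop("module must be non-empty")
  if (!all(module %in% universe))
    stop("module contains genes outside the universe")
  if (!length(collection)) stop("collection must be non-empty")
  N <- length(unique(universe))
  n <- length(module)
  rows <- lapply(seq_along(collection), function(i) {
    set <- unique(intersect(collection[[i]], universe))
    if (!length(set)) stop("set ", i, " has no genes in the universe")
    K <- length(set)
    ov <- length(intersect(module, set))
    # P(X >= ov) for X ~ Hypergeom(N, K, n)
    p <- phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = names(collection)[i] %||% paste0("set", i),
               set_size = K, overlap = ov, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a
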