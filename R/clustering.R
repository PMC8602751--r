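#' Cluster genes in the latent space
#'
#' K-means on the latent coordinates turns the fitted embedding into gene
#' modules.  Centers are seeded k-means++-style (first center uniform, later
#' centers with probability proportional to squared distance from the chosen
#' set); 20 restarts are run and the solution with the lowest total
#' within-cluster sum of squares is kept.  Restarts that produce an empty
#' cluster are re-drawn.
#'
#' @param Z m x lambda matrix of latent gene coordinates (e.g.
#'   `fit$embedding`).
#' @param n_clusters number of modules (>= 2); conventionally equal to the
#'   latent dimension.
#' @param seed integer seed making the clustering deterministic.
#' @param n_restarts number of seeded restarts.
#' @return list of class `module_assignment` with `labels` (m-vector in
#'   `1..n_clusters`), `centers` (n_clusters x lambda) and `tot_withinss`.
#' @export
cluster_latent <- function(Z, n_clusters, seed = 1L, n_restarts = 20L) {
  Z <- as.matrix(Z)
  m <- nrow(Z)
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  if (m < n_clusters) stop("fewer genes than clusters")
  set.seed(seed)
  best <- NULL
  tries <- 0L
  while (tries < n_restarts) {
    centers <- .kmeanspp_centers(Z, n_clusters)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(Z, centers = centers, iter.max = 100L)),
      error = function(e) NULL)
    if (is.null(km) || any(km$size == 0)) next  # empty cluster: redraw
    tries <- tries + 1L
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(labels = as.integer(best$cluster),
                 centers = best$centers,
                 tot_withinss = best$tot.withinss),
            class = "module_assignment")
}

.kmeanspp_centers <- function(Z, k) {
  m <- nrow(Z)
  idx <- integer(k)
  idx[1L] <- sample.int(m, 1L)
  d2 <- rowSums((Z - matrix(Z[idx[1L], ], m, ncol(Z), byrow = TRUE))^2)
  for (c in seq_len(k)[-1L]) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / m, m)
    idx[c] <- sample.int(m, 1L, prob = p)
    d2c <- rowSums((Z - matrix(Z[idx[c], ], m, ncol(Z), byrow = TRUE))^2)
    d2 <- pmin(d2, d2c)
  }
  # jitter exact duplicates so stats::kmeans accepts the center matrix
  C <- Z[idx, , drop = FALSE]
  if (anyDuplicated(C)) C <- C + matrix(rnorm(length(C), 0, 1e-8), nrow(C))
  C
}

#' Per-cell module expression scores
#'
#' For every module and cell, the mean of `log1p(depth-normalised counts)`
#' (counts scaled to 10,000 per cell) over the module's genes — the standard
#' per-cell module summary used downstream of gene clustering.
#'
#' @param x a [dataset_collection()].
#' @param assign a `module_assignment` (or integer label vector) covering all
#'   genes.
#' @return list over datasets of n_modules x n_k score matrices, rows in
#'   module label order.
#' @export
module_means <- function(x, assign) {
  labels <- if (inherits(assign, "module_assignment")) assign$labels
            else as.integer(assign)
  if (length(labels) != n_genes(x)) stop("labels must cover all genes")
  mods <- sort(unique(labels))
  out <- lapply(x$datasets, function(D) {
    depth <- pmax(colSums(D), 1)
    M <- log1p(sweep(D, 2L, depth, "/") * 1e4)
    S <- do.call(rbind, lapply(mods, function(c)
      colMeans(M[labels == c, , drop = FALSE])))
    rownames(S) <- paste0("module", mods)
    S
  })
  names(out) <- x$dataset_ids
  out
}

#' Weighted Jaccard similarity between two weighted gene sets
#'
#' `sum_g min(w_a, w_b) / sum_g max(w_a, w_b)` over the union of genes, with
#' weight 0 for a gene absent from a set.  Equals the plain Jaccard index for
#' 0/1 weights; 1 for identical weighted sets, 0 for disjoint supports.
#'
#' @param w_a,w_b named non-negative weight vectors (names are gene ids).
#' @return similarity in `[0, 1]`; two all-zero sets give 0 with a warning.
#' @export
weighted_jaccard <- function(w_a, w_b) {
  if (any(w_a < 0) || any(w_b < 0)) stop("weights must be non-negative")
  genes <- union(names(w_a), names(w_b))
  if (is.null(names(w_a)) || is.null(names(w_b))) {
    if (length(w_a) != length(w_b))
      stop("unnamed weight vectors must have equal length")
    a <- as.numeric(w_a); b <- as.numeric(w_b)
  } else {
    a <- ifelse(genes %in% names(w_a), w_a[genes], 0); a[is.na(a)] <- 0
    b <- ifelse(genes %in% names(w_b), w_b[genes], 0); b[is.na(b)] <- 0
  }
  den <- sum(pmax(a, b))
  if (den == 0) {
    warning("both weight vectors are all zero; similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  sum(pmin(a, b)) / den
}

#' Default gene weights for module comparison
#'
#' Weights each module gene by its mean raw expression in the module's source
#' dataset, for use with [weighted_jaccard()].
#'
#' @param x a [dataset_collection()].
#' @param labels integer module labels over the genes.
#' @param module module id to extract.
#' @param dataset dataset id or index the module came from.
#' @return named weight vector over the module's genes.
#' @export
module_weights <- function(x, labels, module, dataset = 1L) {
  genes <- which(labels == module)
  if (!length(genes)) stop("module ", module, " is empty")
  D <- x$datasets[[dataset]]
  w <- rowMeans(D[genes, , drop = FALSE])
  names(w) <- x$gene_ids[genes]
  w
}
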