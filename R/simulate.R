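#' Simulate nested sets of per-cluster negative-binomial datasets
#'
#' Emulates a benchmark design for consensus co-expression methods: a cohort
#' of `n_sets` sets D1..Dn where set d contains d datasets ("batches"), each
#' with `n_genes` genes split evenly into `n_clusters` ground-truth
#' co-expression clusters.  Counts for a gene in cluster c of batch n are
#' drawn i.i.d. across cells from `NB(u_cn, theta_cn)`, so clusters differ by
#' their mean/dispersion regime and batches perturb the means.
#'
#' Default means place the clusters at 2, 10 and 40 counts (spanning over an
#' order of magnitude), modulated +/-20% linearly across batches; default
#' dispersions are 1, 2 and 5.
#'
#' @param n_sets number of nested sets (set d holds d datasets).
#' @param n_genes genes per dataset; must be divisible by `n_clusters`.
#' @param n_clusters number of ground-truth gene clusters.
#' @param cells_per_dataset cells in every dataset.
#' @param mean_grid `n_clusters x n_batches` matrix of NB means `u_cn`
#'   (`n_batches = n_sets`); a length-`n_clusters` vector is expanded with
#'   the +/-20% batch modulation.
#' @param disp_grid dispersions `theta_cn`, same shapes accepted.
#' @param seed integer seed.
#' @return list of class `simulated_cohort`: `collections` (one
#'   [dataset_collection()] per set), `true_labels`, `design` metadata.
#' @export
generate_nb_cohort <- function(n_sets = 9L, n_genes = 180L, n_clusters = 3L,
                               cells_per_dataset = 200L,
                               mean_grid = c(2, 10, 40),
                               disp_grid = c(1, 2, 5), seed = 1L) {
  if (n_genes %% n_clusters != 0)
    stop("n_genes must be divisible by n_clusters")
  mean_grid <- .expand_grid_param(mean_grid, n_clusters, n_sets,
                                  batch_mod = TRUE)
  disp_grid <- .expand_grid_param(disp_grid, n_clusters, n_sets,
                                  batch_mod = FALSE)
  if (any(mean_grid <= 0) || any(disp_grid <= 0))
    stop("mean and dispersion grids must be strictly positive")
  set.seed(seed)
  per <- n_genes %/% n_clusters
  labels <- rep(seq_len(n_clusters), each = per)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  # one pool of batches; set d reuses batches 1..d so sets are nested designs
  batches <- lapply(seq_len(n_sets), function(b) {
    D <- matrix(0, n_genes, cells_per_dataset)
    for (c in seq_len(n_clusters)) {
      rows <- which(labels == c)
      D[rows, ] <- rnbinom(length(rows) * cells_per_dataset,
                           mu = mean_grid[c, b], size = disp_grid[c, b])
    }
    rownames(D) <- gene_ids
    D
  })
  collections <- lapply(seq_len(n_sets), function(d) {
    ds <- batches[seq_len(d)]
    names(ds) <- sprintf("batch%02d", seq_len(d))
    dataset_collection(ds, gene_ids = gene_ids)
  })
  names(collections) <- paste0("D", seq_len(n_sets))
  structure(list(collections = collections, true_labels = labels,
                 design = list(style = "nb_cohort", n_sets = n_sets,
                               n_genes = n_genes, n_clusters = n_clusters,
                               cells_per_dataset = cells_per_dataset,
                               mean_grid = mean_grid, disp_grid = disp_grid,
                               seed = seed)),
            class = "simulated_cohort")
}

.expand_grid_param <- function(g, n_clusters, n_batches, batch_mod) {
  if (is.matrix(g)) {
    if (nrow(g) != n_clusters || ncol(g) != n_batches)
      stop("grid must be n_clusters x n_batches")
    return(g)
  }
  if (length(g) != n_clusters)
    stop("grid vector must have one entry per cluster")
  mod <- if (batch_mod && n_batches > 1)
    seq(0.8, 1.2, length.out = n_batches) else rep(1, n_batches)
  outer(as.numeric(g), mod)
}

#' Simulate gamma-Poisson batches with batch factors, DE groups and dropout
#'
#' A reimplementation of the Splat-style generative chain for scRNA-seq
#' counts: gene base means are Gamma draws; each batch multiplies every
#' gene's mean by a lognormal batch factor; genes are partitioned into
#' `n_groups` ground-truth co-expression groups, and a gene is up-regulated
#' by a lognormal DE factor in the cells of its own group (cells are spread
#' evenly over groups); per-cell expected totals follow a lognormal library
#' size; counts are gamma-Poisson (negative binomial with
#' `theta = 1/bcv^2`); finally a logistic dropout mask zeroes entry (i, j)
#' with probability `plogis(dropout_shape * (log mean_ij - dropout_mid))`.
#'
#' With the default `de_prob = 0.25` and 4 groups, the group blocks exactly
#' partition the genes (each group's DE set is a disjoint block of
#' `de_prob * n_genes` genes), which is what makes every gene carry a
#' ground-truth label.
#'
#' Default parameter scales emulate a filtered benchmark panel of expressed
#' genes rather than a whole transcriptome: base means Gamma(4, 1) (moderate
#' spread), marker-scale DE factors (median 50-fold) so that the group
#' programs dominate the deliberately strong batch factors
#' (`batch_facloc = batch_facscale = 1`), and dropout tuned to realistic
#' droplet sparsity (roughly three quarters of entries zero).
#'
#' @param n_batches number of batches to generate.
#' @param cells_per_batch,n_genes dimensions of every batch.
#' @param n_groups number of ground-truth co-expression groups.
#' @param batch_facloc,batch_facscale meanlog / sdlog of the lognormal
#'   per-gene batch factors.
#' @param de_prob fraction of genes that are differentially expressed per
#'   group; `de_prob * n_genes * n_groups` must equal `n_genes` so the DE
#'   blocks partition the gene set.
#' @param de_facloc,de_facscale meanlog / sdlog of the lognormal DE factors.
#' @param mean_shape,mean_rate Gamma parameters of the gene base means.
#' @param lib_loc,lib_scale meanlog / sdlog of the per-cell library size.
#' @param bcv biological coefficient of variation; NB dispersion is
#'   `1/bcv^2`.
#' @param dropout_mid,dropout_shape logistic dropout midpoint (on the log
#'   mean scale) and slope; `dropout_mid = -Inf` disables dropout.
#' @param seed integer seed.
#' @return `simulated_cohort` whose `collections` field holds one
#'   single-dataset [dataset_collection()] per batch (combine batches with
#'   [combine_batches()]), plus `true_labels`, per-cell `cell_groups` and the
#'   full `design` parameter list.
#' @export
generate_splat_cohort <- function(n_batches = 16L, cells_per_batch = 240L,
                                  n_genes = 240L, n_groups = 4L,
                                  batch_facloc = 1, batch_facscale = 1,
                                  de_prob = 0.25, de_facloc = log(50),
                                  de_facscale = 0.25,
                                  mean_shape = 4, mean_rate = 1,
                                  lib_loc = log(5000), lib_scale = 0.2,
                                  bcv = 0.2, dropout_mid = 2.5,
                                  dropout_shape = -1, seed = 1L) {
  stopifnot(n_batches >= 1, cells_per_batch >= 1, n_genes >= n_groups,
            de_prob >= 0, de_prob <= 1, batch_facscale > 0, de_facscale > 0,
            mean_shape > 0, mean_rate > 0, lib_scale > 0, bcv > 0)
  n_de <- round(de_prob * n_genes)
  if (n_de * n_groups != n_genes)
    stop("de_prob * n_genes * n_groups must equal n_genes so the DE blocks ",
         "partition the genes")
  set.seed(seed)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  labels <- rep(seq_len(n_groups), each = n_de)
  base_mean <- rgamma(n_genes, shape = mean_shape, rate = mean_rate)
  base_mean <- pmax(base_mean, 1e-4)
  # one DE factor per gene, applied in the cells of the gene's own group
  de_factor <- rlnorm(n_genes, meanlog = de_facloc, sdlog = de_facscale)
  theta <- 1 / bcv^2
  cell_groups <- vector("list", n_batches)
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    bf <- rlnorm(n_genes, meanlog = batch_facloc, sdlog = batch_facscale)
    grp <- rep_len(seq_len(n_groups), cells_per_batch)
    lib <- rlnorm(cells_per_batch, meanlog = lib_loc, sdlog = lib_scale)
    gm <- base_mean * bf                         # gene means in this batch
    # per-group expression profiles (gene i boosted in its own group)
    prof <- vapply(seq_len(n_groups), function(g) {
      p <- gm
      p[labels == g] <- p[labels == g] * de_factor[labels == g]
      p / sum(p)
    }, numeric(n_genes))
    U <- prof[, grp, drop = FALSE] * rep(lib, each = n_genes)
    X <- matrix(rnbinom(length(U), mu = U, size = theta), n_genes)
    if (is.finite(dropout_mid)) {
      pi_drop <- plogis(dropout_shape * (log(pmax(U, 1e-12)) - dropout_mid))
      keep <- matrix(rbinom(length(U), 1L, 1 - pi_drop), n_genes)
      X <- X * keep
    }
    rownames(X) <- gene_ids
    batches[[b]] <- X
    cell_groups[[b]] <- grp
  }
  names(batches) <- sprintf("batch%02d", seq_len(n_batches))
  collections <- lapply(names(batches), function(nm)
    dataset_collection(batches[nm], gene_ids = gene_ids))
  names(collections) <- names(batches)
  structure(list(collections = collections, true_labels = labels,
                 cell_groups = cell_groups,
                 design = list(style = "splat_cohort", n_batches = n_batches,
                               cells_per_batch = cells_per_batch,
                               n_genes = n_genes, n_groups = n_groups,
                               batch_facloc = batch_facloc,
                               batch_facscale = batch_facscale,
                               de_prob = de_prob, de_facloc = de_facloc,
                               de_facscale = de_facscale,
                               mean_shape = mean_shape,
                               mean_rate = mean_rate, lib_loc = lib_loc,
                               lib_scale = lib_scale, bcv = bcv,
                               dropout_mid = dropout_mid,
                               dropout_shape = dropout_shape, seed = seed)),
            class = "simulated_cohort")
}

#' Combine single-batch collections into one multi-dataset collection
#'
#' @param cohort a `simulated_cohort` from [generate_splat_cohort()].
#' @param which integer indices of the batches to combine.
#' @return a [dataset_collection()] holding the selected batches.
#' @export
combine_batches <- function(cohort, which = seq_along(cohort$collections)) {
  ds <- lapply(cohort$collections[which], function(col) col$datasets[[1L]])
  names(ds) <- names(cohort$collections)[which]
  dataset_collection(ds, gene_ids = cohort$collections[[1L]]$gene_ids)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort (", x$design$style, "): ",
      length(x$collections), " collection(s), ",
      length(x$true_labels), " genes, ",
      length(unique(x$true_labels)), " ground-truth clusters\n", sep = "")
  invisible(x)
}
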