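#' Bundle aligned count matrices from several datasets
#'
#' A `dataset_collection` holds K raw count matrices (genes x cells) that
#' share one gene index, the unit of input for [nbcoex()].  All matrices must
#' have the same genes in the same row order; entries must be finite
#' non-negative integers (raw counts, not normalised values).
#'
#' @param datasets list of K numeric matrices, each `m` genes x `n_k` cells.
#' @param gene_ids character vector of length `m`; defaults to rownames of the
#'   first matrix or `gene1..geneM`.
#' @param dataset_ids unique labels for the K datasets; defaults to list names
#'   or `dataset1..datasetK`.
#' @return An object of class `dataset_collection` with elements `datasets`,
#'   `gene_ids`, `dataset_ids`.
#' @examples
#' x <- dataset_collection(list(a = matrix(rpois(20, 5), 4), b = matrix(rpois(12, 5), 4)))
#' x
#' @export
dataset_collection <- function(datasets, gene_ids = NULL, dataset_ids = NULL) {
  if (!is.list(datasets) || length(datasets) < 1L)
    stop("`datasets` must be a non-empty list of matrices")
  datasets <- lapply(datasets, function(d) {
    d <- as.matrix(d)
    storage.mode(d) <- "double"
    d
  })
  m <- nrow(datasets[[1L]])
  if (m < 2L) stop("need at least 2 genes")
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    if (nrow(d) != m)
      stop("dataset ", k, " has ", nrow(d), " rows; expected ", m)
    if (ncol(d) < 1L) stop("dataset ", k, " has no cells")
    if (!all(is.finite(d))) stop("dataset ", k, " contains non-finite entries")
    if (any(d < 0)) stop("dataset ", k, " contains negative counts")
    if (max(abs(d - round(d))) > 1e-6)
      stop("dataset ", k, " contains non-integer counts")
    datasets[[k]][] <- round(d)
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(datasets[[1L]])
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(m))
  }
  if (length(gene_ids) != m) stop("gene_ids length must equal gene count")
  if (is.null(dataset_ids)) {
    dataset_ids <- names(datasets)
    if (is.null(dataset_ids) || any(!nzchar(dataset_ids)))
      dataset_ids <- paste0("dataset", seq_along(datasets))
  }
  if (anyDuplicated(dataset_ids)) stop("dataset_ids must be unique")
  datasets <- lapply(datasets, function(d) {
    rownames(d) <- gene_ids
    d
  })
  names(datasets) <- dataset_ids
  structure(
    list(datasets = datasets, gene_ids = as.character(gene_ids),
         dataset_ids = as.character(dataset_ids)),
    class = "dataset_collection"
  )
}

#' @export
print.dataset_collection <- function(x, ...) {
  n <- vapply(x$datasets, ncol, integer(1))
  cat("dataset_collection: ", length(x$gene_ids), " genes x ",
      length(x$datasets), " dataset(s) [",
      paste(n, collapse = ", "), " cells]\n", sep = "")
  invisible(x)
}

n_genes <- function(x) length(x$gene_ids)
n_cells <- function(x) vapply(x$datasets, ncol, integer(1))

# Concatenate cells of all datasets into one m x N matrix plus the dataset
# index of each cell.  Datasets are visited in canonical (sorted id) order so
# every likelihood reduction is invariant to the order the user listed them.
.flatten_collection <- function(x) {
  ord <- order(x$dataset_ids)
  mats <- x$datasets[ord]
  X <- do.call(cbind, mats)
  list(X = X,
       cell_dataset = rep(seq_along(mats), vapply(mats, ncol, integer(1))),
       order = ord)
}
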