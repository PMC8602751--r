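#' Read count matrices from disk into an aligned collection
#'
#' Accepts MatrixMarket sparse matrices with companion `genes.tsv` /
#' `barcodes.tsv` files (the 10x convention; pass the `.mtx` path or its
#' directory) or dense delimited files (first column gene ids, header cell
#' ids).  Datasets are aligned to the intersection of their gene ids,
#' keeping the gene order of the first dataset; counts must be integers to
#' within 1e-6.
#'
#' @param paths character vector of file (or, for MatrixMarket, directory)
#'   paths, one per dataset.
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"` or `"tsv"`.
#' @param dataset_ids labels for the datasets; defaults to file base names.
#' @return a [dataset_collection()].
#' @export
read_counts <- function(paths, format = c("auto", "mtx", "csv", "tsv"),
                        dataset_ids = NULL) {
  format <- match.arg(format)
  if (!length(paths)) stop("no input paths given")
  mats <- lapply(paths, function(p) {
    fmt <- if (format != "auto") format else {
      if (dir.exists(p) || grepl("\\.mtx$", p)) "mtx"
      else if (grepl("\\.tsv$", p)) "tsv" else "csv"
    }
    switch(fmt,
           mtx = .read_mtx_dataset(p),
           tsv = .read_dense_dataset(p, sep = "\t"),
           csv = .read_dense_dataset(p, sep = ","))
  })
  if (is.null(dataset_ids))
    dataset_ids <- make.unique(basename(sub("/$", "", paths)))
  shared <- Reduce(intersect, lapply(mats, rownames))
  # preserve the first dataset's gene order
  shared <- rownames(mats[[1L]])[rownames(mats[[1L]]) %in% shared]
  if (!length(shared)) stop("datasets share no gene ids")
  mats <- lapply(mats, function(M) M[shared, , drop = FALSE])
  dataset_collection(mats, gene_ids = shared, dataset_ids = dataset_ids)
}

.read_mtx_dataset <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    dir <- path
  } else {
    mtx <- path
    dir <- dirname(path)
  }
  if (!file.exists(mtx)) stop("no MatrixMarket file at ", mtx)
  genes_f <- file.path(dir, "genes.tsv")
  if (!file.exists(genes_f)) genes_f <- file.path(dir, "features.tsv")
  if (!file.exists(genes_f)) stop("no genes.tsv next to ", mtx)
  M <- as.matrix(Matrix::readMM(mtx))
  genes <- read.delim(genes_f, header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(M))
    stop("gene file ", genes_f, " lists ", length(genes), " genes; matrix ",
         mtx, " has ", nrow(M), " rows")
  rownames(M) <- genes
  bc_f <- file.path(dir, "barcodes.tsv")
  if (file.exists(bc_f)) {
    bcs <- read.delim(bc_f, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (length(bcs) == ncol(M)) colnames(M) <- bcs
  }
  .check_integer_counts(M, mtx)
}

.read_dense_dataset <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e)
      stop("parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE))
  M <- as.matrix(df)
  if (!is.numeric(M))
    stop("parse error in ", path, ": non-numeric count columns ",
         "(malformed header or delimiter?)")
  .check_integer_counts(M, path)
}

.check_integer_counts <- function(M, where) {
  if (any(M < 0)) stop("negative counts in ", where)
  if (max(abs(M - round(M))) > 1e-6)
    stop("non-integer counts in ", where)
  M[] <- round(M)
  M
}

#' Write one dataset as MatrixMarket plus gene/barcode TSVs
#'
#' @param mat genes x cells count matrix (row names = gene ids).
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(mat), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  gids <- rownames(mat)
  if (is.null(gids)) gids <- paste0("gene", seq_len(nrow(mat)))
  writeLines(gids, file.path(dir, "genes.tsv"))
  bcs <- colnames(mat)
  if (is.null(bcs)) bcs <- paste0("cell", seq_len(ncol(mat)))
  writeLines(bcs, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write one dataset as a dense delimited table
#'
#' @param mat genes x cells count matrix.
#' @param path output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_counts_dense <- function(mat, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(gene_id = rownames(mat) %||na% paste0("gene",
                                                         seq_len(nrow(mat))),
                   as.data.frame(mat), check.names = FALSE)
  colnames(df) <- c("gene_id",
                    colnames(mat) %||na% paste0("cell", seq_len(ncol(mat))))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Read gene sets in GMT format
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  sets
}

#' Preprocessing filter thresholds
#'
#' Defaults follow common scRNA-seq practice for multi-sample input: cells
#' need at least 200 expressed genes, a sample (dataset) at least 200
#' retained cells, and a gene must be expressed in at least 300 cells
#' across the retained datasets.
#'
#' @param min_genes_per_cell,min_cells_per_gene,min_cells_per_sample
#'   non-negative integers.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(min_genes_per_cell = 200L,
                          min_cells_per_gene = 300L,
                          min_cells_per_sample = 200L) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0,
            min_cells_per_sample >= 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 min_cells_per_sample = min_cells_per_sample),
            class = "filter_policy")
}

#' Apply quality filters to a collection
#'
#' In order: (1) drop cells expressing fewer than `min_genes_per_cell`
#' genes; (2) drop whole datasets left with fewer than
#' `min_cells_per_sample` cells; (3) drop genes expressed (count > 0) in
#' fewer than `min_cells_per_gene` cells summed across the retained
#' datasets.  Every removal is recorded with the rule that caused it.
#'
#' @param x a [dataset_collection()].
#' @param policy a [filter_policy()].
#' @return list with the filtered `collection` and a `report` data.frame
#'   (`rule`, `dataset`, `item`).  If nothing survives, an error of class
#'   `nbcoex_filter_error` carrying the report is thrown.
#' @export
apply_filters <- function(x, policy = filter_policy()) {
  report <- list()
  note <- function(rule, dataset, item)
    report[[length(report) + 1L]] <<- data.frame(rule = rule,
                                                 dataset = dataset,
                                                 item = item)
  kept <- list()
  for (k in seq_along(x$datasets)) {
    D <- x$datasets[[k]]
    expressed <- colSums(D > 0)
    dropc <- which(expressed < policy$min_genes_per_cell)
    if (length(dropc)) {
      ids <- colnames(D) %||na% as.character(dropc)
      for (j in dropc)
        note("min_genes_per_cell", x$dataset_ids[k],
             (colnames(D) %||na% as.character(seq_len(ncol(D))))[j])
      D <- D[, -dropc, drop = FALSE]
    }
    if (ncol(D) < policy$min_cells_per_sample) {
      note("min_cells_per_sample", x$dataset_ids[k], x$dataset_ids[k])
    } else {
      kept[[x$dataset_ids[k]]] <- D
    }
  }
  fail <- function(msg) {
    rep_df <- if (length(report)) do.call(rbind, report)
              else data.frame(rule = character(), dataset = character(),
                              item = character())
    cond <- structure(class = c("nbcoex_filter_error", "error", "condition"),
                      list(message = msg, call = sys.call(-1),
                           report = rep_df))
    stop(cond)
  }
  if (!length(kept)) fail("all datasets removed by filtering")
  expressed_total <- Reduce(`+`, lapply(kept, function(D) rowSums(D > 0)))
  dropg <- which(expressed_total < policy$min_cells_per_gene)
  if (length(dropg)) {
    for (i in dropg) note("min_cells_per_gene", NA_character_,
                          x$gene_ids[i])
    kept <- lapply(kept, function(D) D[-dropg, , drop = FALSE])
  }
  if (nrow(kept[[1L]]) < 2) fail("fewer than 2 genes survived filtering")
  rep_df <- if (length(report)) do.call(rbind, report)
            else data.frame(rule = character(), dataset = character(),
                            item = character())
  list(collection = dataset_collection(kept,
                                       gene_ids = x$gene_ids[setdiff(
                                         seq_along(x$gene_ids),
                                         if (length(dropg)) dropg else
                                           integer(0))],
                                       dataset_ids = names(kept)),
       report = rep_df)
}
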