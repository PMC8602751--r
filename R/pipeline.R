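#' Run the full analysis pipeline from a declarative config file
#'
#' Reads counts, applies filters, fits the consensus latent-variable model
#' (optionally selecting the latent dimension by BIC), clusters genes into
#' modules, scores the clustering with validity indices, and writes all
#' artifacts plus a JSON run manifest into the output directory.
#'
#' The config (YAML or JSON) has sections:
#' \describe{
#'   \item{inputs}{`paths` (vector) and optional `format`.}
#'   \item{filter}{optional [filter_policy()] fields.}
#'   \item{fit}{[fit_config()] fields; either `lambda_dim` or
#'     `lambda_candidates` (BIC selection).}
#'   \item{seed}{integer; drives every stochastic stage.}
#'   \item{output_dir}{where artifacts go.}
#' }
#'
#' @param config_file path to the YAML/JSON config, or an equivalent list.
#' @return invisibly, a list with the fit, module assignment, index report
#'   and manifest path.  Artifacts written: `modules.tsv`, `embedding.tsv`,
#'   `fit_trace.tsv`, `index_report.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config_file) {
  cfg <- if (is.list(config_file)) config_file else .read_config(config_file)
  .validate_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "nbcoex",
                   version = as.character(utils::packageVersion("nbcoex")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = cfg, stages = list())
  stage <- function(name) message(format(Sys.time(), "[%H:%M:%S] "),
                                  "stage: ", name)
  run_stage <- function(name, expr) {
    stage(name)
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- "failed"
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(res)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- "ok"
    res
  }

  x <- run_stage("read", read_counts(cfg$inputs$paths,
                                     format = cfg$inputs$format %||na%
                                       "auto"))
  pol <- do.call(filter_policy, cfg$filter %||na% list())
  filt <- run_stage("filter", apply_filters(x, pol))
  x <- filt$collection

  fit_args <- cfg$fit %||na% list()
  candidates <- fit_args$lambda_candidates
  fit_args$lambda_candidates <- NULL
  fit_args$rng_seed <- cfg$seed %||na% 1L
  if (is.null(fit_args$lambda_dim))
    fit_args$lambda_dim <- if (!is.null(candidates)) min(candidates) else 2L
  config <- do.call(fit_config, fit_args)

  if (!is.null(candidates)) {
    sel <- run_stage("fit",
                     select_lambda_bic(x, unlist(candidates), config))
    fit <- sel$fits[[match(sel$best_lambda,
                           sel$bic_table$lambda)]]
    manifest$selected_lambda <- sel$best_lambda
    manifest$bic <- sel$bic_table[c("lambda", "bic")]
  } else {
    fit <- run_stage("fit", nbcoex(x, config))
    manifest$selected_lambda <- config$lambda_dim
  }

  assign <- run_stage("cluster",
                      cluster_latent(fit$embedding,
                                     n_clusters = cfg$n_clusters %||na%
                                       ncol(fit$embedding),
                                     seed = cfg$seed %||na% 1L))

  idx <- run_stage("evaluate", {
    Z <- fit$embedding
    data.frame(index = c("calinski_harabasz", "davies_bouldin", "dunn"),
               value = c(calinski_harabasz(Z, assign$labels),
                         davies_bouldin(Z, assign$labels),
                         dunn_index(Z, assign$labels)))
  })

  run_stage("write", {
    write.table(data.frame(gene_id = x$gene_ids, module = assign$labels),
                file.path(out_dir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emb <- data.frame(gene_id = x$gene_ids, fit$embedding)
    colnames(emb) <- c("gene_id", paste0("z", seq_len(ncol(fit$embedding))))
    write.table(emb, file.path(out_dir, "embedding.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(iteration = seq_along(fit$loglik_trace),
                           penalized_loglik = fit$loglik_trace),
                file.path(out_dir, "fit_trace.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(idx, file.path(out_dir, "index_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    NULL
  })
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(list(fit = fit, assignment = assign, indices = idx,
                 manifest = manifest_path))
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.validate_config <- function(cfg) {
  if (is.null(cfg$inputs) || is.null(cfg$inputs$paths))
    stop("config must provide inputs$paths")
  if (is.null(cfg$output_dir)) stop("config must provide output_dir")
  fit <- cfg$fit %||na% list()
  if (is.null(fit$lambda_dim) && is.null(fit$lambda_candidates))
    stop("config fit section needs lambda_dim or lambda_candidates")
  invisible(TRUE)
}
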