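Package: nbcoex
Title: Consensus Gene Co-Expression Modules from Multiple Single-Cell
    Count Datasets via a Negative-Binomial Latent-Variable Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a latent-variable negative-binomial model to several raw
    single-cell RNA-seq count matrices at once, placing each gene at a shared
    low-dimensional latent coordinate while per-cell offsets and loadings
    absorb technical and batch variation. Inference is Monte-Carlo EM:
    Metropolis-Hastings sampling of the gene-level latent variables alternates
    with coordinate-descent fits of L1-penalised per-cell negative-binomial
    regressions, with method-of-moments dispersion updates and BIC selection of
    the latent dimension. K-means on the fitted latent coordinates yields
    consensus co-expression modules. Includes count simulators (per-cluster
    negative-binomial batches and a gamma-Poisson generator with lognormal
    batch factors and logistic dropout), clustering validity indices (ARI,
    Calinski-Harabasz, Davies-Bouldin, Dunn), hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction, weighted Jaccard module
    comparison, count-matrix readers/writers, and preprocessing filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
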