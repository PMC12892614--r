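# Latent-factor gene expression generator: a gene module co-expressed with the
# cohort's noncanonical fragments through the shared latent score, emulating an
# oxidative-stress-like co-expression axis, plus decoy gene sets for null
# enrichment tests.

#' Configuration for the synthetic gene-expression matrix
#'
#' @param n_genes Total number of genes.
#' @param n_pos,n_neg Numbers of genes with positive / negative latent
#'   loadings; the remainder are decoys with loading 0.
#' @param loading Loading magnitude (expression units per latent SD).
#' @param noise_sd SD of the Gaussian expression noise.
#' @param baseline_range Interval for per-gene baseline (log-scale intensity).
#' @param n_decoy_sets,decoy_set_size Decoy gene sets written to the GMT
#'   alongside `POS_PATH` / `NEG_PATH`.
#' @param seed Integer seed.
#' @return A `gene_config` list.
#' @export
gene_config <- function(n_genes = 560L, n_pos = 30L, n_neg = 30L,
                        loading = 2, noise_sd = 1,
                        baseline_range = c(4, 10),
                        n_decoy_sets = 10L, decoy_set_size = 30L,
                        seed = 1L) {
  if (n_pos + n_neg > n_genes) stop("n_genes must cover the loaded genes")
  if (decoy_set_size > n_genes) stop("n_genes smaller than the largest requested set")
  structure(list(n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), loading = loading,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 n_decoy_sets = as.integer(n_decoy_sets),
                 decoy_set_size = as.integer(decoy_set_size),
                 seed = as.integer(seed)),
            class = "gene_config")
}

#' Generate a gene-expression matrix coupled to the cohort's latent factor
#'
#' Gene `g` expression in sample `j` is
#' `baseline_g + loading_g x latent_j + N(0, noise_sd)`. Positive-loading
#' genes form the gene set `POS_PATH`, negative-loading genes `NEG_PATH`;
#' random decoy sets are appended.
#'
#' @param truth A cohort's `truth` element (needs `latent_scores`), or an
#'   `snc_cohort`.
#' @param config A [gene_config()].
#' @return list(`expr` genes x samples matrix, `sets` named list of gene sets,
#'   `loadings` named per-gene loading vector).
#' @export
generate_gene_matrix <- function(truth, config = gene_config()) {
  if (inherits(truth, "snc_cohort")) truth <- truth$truth
  z <- truth$latent_scores
  if (is.null(z)) stop("truth lacks latent_scores")
  local_seed(config$seed, {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    loadings <- stats::setNames(numeric(config$n_genes), genes)
    pos <- genes[seq_len(config$n_pos)]
    neg <- genes[config$n_pos + seq_len(config$n_neg)]
    loadings[pos] <- config$loading
    loadings[neg] <- -config$loading
    base <- stats::runif(config$n_genes, config$baseline_range[1], config$baseline_range[2])
    expr <- base + outer(loadings, z) +
      matrix(stats::rnorm(config$n_genes * length(z), 0, config$noise_sd),
             config$n_genes, length(z))
    rownames(expr) <- genes
    colnames(expr) <- names(z)
    sets <- list(POS_PATH = pos, NEG_PATH = neg)
    for (i in seq_len(config$n_decoy_sets)) {
      sets[[sprintf("DECOY_%02d", i)]] <- sample(genes, config$decoy_set_size)
    }
    list(expr = expr, sets = sets, loadings = loadings)
  })
}
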