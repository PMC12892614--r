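# sncRNA-gene co-expression and pathway scoring: pairwise Spearman
# correlations with BH adjustment over all pairs, the >= 20-family gene
# filter, a local hypergeometric gene-set enrichment test, rank-based
# per-sample pathway scores with exponential weighting, and group comparisons
# of pathway scores.

#' Pairwise Spearman correlations between fragment families and genes
#'
#' rho is the Pearson correlation of average ranks; P comes from the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` df; BH
#' adjustment spans all tested pairs jointly. Constant family or gene vectors
#' are skipped (their pairs are absent from the table) and counted in the
#' `skipped_families` / `skipped_genes` attributes.
#'
#' @param family_expr Families x samples matrix (log-expression; the scale is
#'   irrelevant to ranks as long as it is monotone).
#' @param gene_expr Genes x samples matrix on the same samples (matched by
#'   column name).
#' @return data.frame(family, gene, rho, p, p_adj, sign).
#' @export
spearman_pair_table <- function(family_expr, gene_expr) {
  common <- intersect(colnames(family_expr), colnames(gene_expr))
  if (length(common) < 5) stop("need >= 5 shared samples")
  F <- family_expr[, common, drop = FALSE]
  G <- gene_expr[, common, drop = FALSE]
  n <- length(common)
  const_f <- apply(F, 1, function(x) stats::sd(x) == 0)
  const_g <- apply(G, 1, function(x) stats::sd(x) == 0)
  F <- F[!const_f, , drop = FALSE]
  G <- G[!const_g, , drop = FALSE]
  RF <- t(apply(F, 1, rank))
  RG <- t(apply(G, 1, rank))
  rho <- stats::cor(t(RF), t(RG))                 # families x genes
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  out <- data.frame(
    family = rep(rownames(F), times = ncol(rho)),
    gene = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho), p = as.vector(p))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$sign <- ifelse(out$rho > 0, "pos", ifelse(out$rho < 0, "neg", "zero"))
  attr(out, "skipped_families") <- sum(const_f)
  attr(out, "skipped_genes") <- sum(const_g)
  attr(out, "n") <- n
  out
}

#' Select genes co-expressed with many fragment families
#'
#' A gene is positively co-expressed if at least `min_families` families
#' correlate with it at BH-adjusted P < `alpha` with rho > 0; negatively
#' analogously. A gene satisfying both count thresholds separately is
#' reported in both sets and flagged.
#'
#' @param pair_table Table from [spearman_pair_table()].
#' @param alpha Significance level on adjusted P (default 0.05).
#' @param min_families Minimum number of significant families (default 20).
#' @return list(`positive`, `negative` character vectors, `both` the overlap,
#'   `counts` data.frame(gene, n_pos, n_neg)).
#' @export
select_coexpressed_genes <- function(pair_table, alpha = 0.05, min_families = 20L) {
  sig <- pair_table[pair_table$p_adj < alpha, , drop = FALSE]
  genes <- unique(pair_table$gene)
  n_pos <- table(factor(sig$gene[sig$rho > 0], levels = genes))
  n_neg <- table(factor(sig$gene[sig$rho < 0], levels = genes))
  pos <- genes[n_pos >= min_families]
  neg <- genes[n_neg >= min_families]
  both <- intersect(pos, neg)
  if (length(both)) {
    warning(length(both), " gene(s) qualify in both directions: ",
            paste(utils::head(both, 5), collapse = ", "))
  }
  list(positive = pos, negative = neg, both = both,
       counts = data.frame(gene = genes, n_pos = as.integer(n_pos),
                           n_neg = as.integer(n_neg)))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric P for an overlap at least as large as
#' observed between the gene list and each set (sets are intersected with the
#' universe first); BH adjustment across sets. A local replacement for
#' web-service KEGG enrichment.
#'
#' @param gene_list Character vector, a subset of `universe`.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all testable genes.
#' @return data.frame(set, set_size, overlap, expected, p, p_adj); sets
#'   disjoint from the universe are skipped with a warning.
#' @export
hypergeometric_enrichment <- function(gene_list, sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(gene_list)) stop("empty gene list")
  if (!all(gene_list %in% universe)) stop("gene list must be a subset of the universe")
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    if (!length(set)) {
      warning("set ", nm, " is disjoint from the universe; skipped")
      return(NULL)
    }
    K <- length(set)
    ov <- length(intersect(gene_list, set))
    data.frame(set = nm, set_size = K, overlap = ov,
               expected = n * K / N,
               p = stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(set = character(), set_size = integer(),
                                      overlap = integer(), expected = numeric(),
                                      p = numeric(), p_adj = numeric()))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Rank-based per-sample pathway scores
#'
#' Per sample, genes are ranked by expression descending (average ranks for
#' ties, rank 1 = highest) and weighted `w_g = exp(-rank_g/(0.1 N))`; the set
#' score is `mean(w over set) - mean(w over complement)`. Scores are invariant
#' under any strictly monotone per-sample transform of expression. A higher
#' score implies overall upregulation of the set. Sets with fewer than 2
#' usable genes in or out of the set are skipped with a message.
#'
#' @param gene_expr Genes x samples expression matrix.
#' @param sets Named list of gene sets.
#' @param decay Weight decay constant as a fraction of the gene count
#'   (default 0.1).
#' @return Sets x samples score matrix.
#' @export
faime_scores <- function(gene_expr, sets, decay = 0.1) {
  N <- nrow(gene_expr)
  ranks <- apply(gene_expr, 2, function(x) rank(-x))
  W <- exp(-ranks / (decay * N))
  usable <- vapply(sets, function(s) {
    k <- sum(rownames(gene_expr) %in% s)
    k >= 2 && (N - k) >= 2
  }, logical(1))
  if (any(!usable)) {
    message("skipping ", sum(!usable), " gene set(s) with < 2 genes in or out")
  }
  sets <- sets[usable]
  out <- matrix(NA_real_, length(sets), ncol(gene_expr),
                dimnames = list(names(sets), colnames(gene_expr)))
  for (nm in names(sets)) {
    inset <- rownames(gene_expr) %in% sets[[nm]]
    out[nm, ] <- colMeans(W[inset, , drop = FALSE]) -
      colMeans(W[!inset, , drop = FALSE])
  }
  out
}

#' Group comparison of pathway scores
#'
#' Two-sided Welch t-tests of each set's per-sample scores for each contrast.
#'
#' @param score_matrix Sets x samples matrix from [faime_scores()].
#' @param metadata Sample metadata.
#' @param contrasts Contrast list (`c(reference, case)` pairs).
#' @return data.frame(set, contrast, mean_ref, mean_case, t, df, p).
#' @export
pathway_group_comparison <- function(score_matrix, metadata,
                                     contrasts = DEFAULT_CONTRASTS) {
  check_metadata(metadata, unique(unlist(contrasts)))
  score_matrix <- align_samples(score_matrix, metadata)
  out <- do.call(rbind, lapply(rownames(score_matrix), function(s) {
    cbind(set = s, welch_contrasts(score_matrix[s, ], metadata, contrasts))
  }))
  rownames(out) <- NULL
  out
}
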