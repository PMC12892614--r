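# Family-gene Spearman tables with joint BH adjustment, the >=20-family gene
# filter, hypergeometric enrichment, and rank-based pathway scores.

mk_mat <- function(v, ids, samples) {
  matrix(v, length(ids), length(samples), byrow = TRUE,
         dimnames = list(ids, samples))
}

test_that("Spearman pairs hit the exact extremes and the tied-rank oracle", {
  samples <- sprintf("s%d", 1:8)
  fam <- mk_mat(c(1, 2, 3, 4, 5, 6, 7, 8), "famA", samples)
  genes <- rbind(gUp = log1p(1:8), gDown = 8:1, gTied = c(1, 1, 2, 2, 3, 3, 4, 4))
  colnames(genes) <- samples
  tab <- spearman_pair_table(fam, genes)
  expect_equal(tab$rho[tab$gene == "gUp"], 1)      # monotone transform
  expect_equal(tab$rho[tab$gene == "gDown"], -1)
  # tied data: rank-then-Pearson oracle
  oracle <- cor(rank(fam[1, ]), rank(genes["gTied", ]))
  expect_equal(tab$rho[tab$gene == "gTied"], oracle)
  expect_equal(tab$rho[tab$gene == "gTied"],
               unname(suppressWarnings(
                 cor.test(fam[1, ], genes["gTied", ], method = "spearman")$estimate)))
  # BH is joint across all pairs and preserves the raw-P order
  expect_true(all(tab$p_adj >= tab$p))
  expect_equal(tab$p_adj, p.adjust(tab$p, "BH"))
})

test_that("constant vectors are skipped rather than propagating NaN", {
  samples <- sprintf("s%d", 1:6)
  fam <- rbind(famA = 1:6, famConst = rep(2, 6))
  colnames(fam) <- samples
  genes <- mk_mat(c(2, 4, 6, 8, 10, 12), "g1", samples)
  tab <- spearman_pair_table(fam, genes)
  expect_identical(attr(tab, "skipped_families"), 1L)
  expect_false("famConst" %in% tab$family)
  expect_true(all(is.finite(tab$rho)))
})

test_that("the >=20-family gene filter applies its boundary exactly", {
  # construct a pair table directly: g19 has 19 significant positive families,
  # g20 has 20, gBoth has 20 positive and 20 negative
  mk <- function(gene, n_pos, n_neg) {
    rbind(
      if (n_pos) data.frame(family = sprintf("f%02d", 1:n_pos), gene = gene,
                            rho = 0.8, p = 1e-6, p_adj = 1e-5, sign = "pos"),
      if (n_neg) data.frame(family = sprintf("f%02d", 40 + 1:n_neg), gene = gene,
                            rho = -0.8, p = 1e-6, p_adj = 1e-5, sign = "neg"))
  }
  tab <- rbind(mk("g19", 19, 0), mk("g20", 20, 0), mk("gBoth", 20, 20),
               data.frame(family = "f99", gene = "gNull", rho = 0.1,
                          p = 0.9, p_adj = 0.95, sign = "pos"))
  expect_warning(sel <- select_coexpressed_genes(tab, alpha = 0.05, min_families = 20),
                 "both directions")
  expect_false("g19" %in% sel$positive)
  expect_true("g20" %in% sel$positive)
  expect_true("gBoth" %in% sel$positive && "gBoth" %in% sel$negative)
  expect_identical(sel$both, "gBoth")
  expect_false("gNull" %in% c(sel$positive, sel$negative))
})

test_that("latent-loaded genes are recovered in the correct direction", {
  refs <- small_refs()
  nc_fams <- family_label(refs$class, refs$family)[refs$class != "miRNA"]
  # load a subset of families: a loading on the whole compartment would cancel
  # under the compositional RPM normalisation
  loaded <- nc_fams[seq(1, length(nc_fams), by = 2)]
  coh <- generate_cohort(refs, cohort_config(
    group_sizes = c(HC = 30L, UC = 30L),
    library_size_range = c(20000L, 30000L), n_noise_species = 5L,
    latent_loadings = setNames(rep(0.6, length(loaded)), loaded), seed = 101L))
  gm <- generate_gene_matrix(coh, gene_config(n_genes = 80L, n_pos = 10L,
                                              n_neg = 10L, loading = 2,
                                              noise_sd = 1, seed = 5L))
  fam_log <- log2(family_matrix_from_cohort(coh) + 1)
  fam_log <- fam_log[rownames(fam_log) %in% nc_fams, ]
  tab <- spearman_pair_table(fam_log, gm$expr)
  # loaded genes also anti-correlate with the unloaded families (compositional
  # closure), so they legitimately qualify in both directions; flagged by the
  # selector via a warning
  sel <- suppressWarnings(select_coexpressed_genes(tab, alpha = 0.05, min_families = 10))
  truth_pos <- names(gm$loadings)[gm$loadings > 0]
  truth_neg <- names(gm$loadings)[gm$loadings < 0]
  expect_gte(mean(truth_pos %in% sel$positive), 0.9)
  expect_gte(mean(truth_neg %in% sel$negative), 0.9)
  # unloaded decoys stay out
  decoys <- names(gm$loadings)[gm$loadings == 0]
  expect_lte(sum(decoys %in% c(sel$positive, sel$negative)), 1)
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(SET5 = universe[1:5])
  # list = the whole set: the minimal achievable P is 1/choose(20,5)
  res <- hypergeometric_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(20, 5))
  # exhaustive-enumeration oracle at an intermediate overlap (list g04..g13
  # overlaps the set in exactly {g04, g05})
  res2 <- hypergeometric_enrichment(universe[4:13], sets, universe)
  oracle <- sum(vapply(2:5, function(k)
    choose(5, k) * choose(15, 10 - k) / choose(20, 10), numeric(1)))
  expect_equal(res2$p, oracle)
  # overlap 0 has P = 1
  res3 <- hypergeometric_enrichment(universe[6:10], list(S = universe[1:5]), universe)
  expect_equal(res3$p, 1)
  expect_warning(
    out <- hypergeometric_enrichment(universe[1:3], list(BAD = c("zz1", "zz2")), universe),
    "disjoint")
  expect_identical(nrow(out), 0L)
  expect_error(hypergeometric_enrichment(character(), sets, universe), "empty gene list")
  expect_error(hypergeometric_enrichment(c("notin"), sets, universe), "subset")
})

test_that("decoy-set enrichment P-values are uniform under the null", {
  set.seed(107)
  universe <- sprintf("g%03d", 1:300)
  p <- replicate(400, {
    sets <- list(D = sample(universe, 30))
    hypergeometric_enrichment(sample(universe, 40), sets, universe)$p
  })
  # the hypergeometric P is discrete, hence stochastically >= uniform; it must
  # not be anticonservative at the usual working thresholds
  expect_gt(mean(p), 0.45)
  expect_lt(mean(p), 0.65)
  expect_lte(mean(p < 0.05), 0.07)
  expect_lte(mean(p < 0.25), 0.30)
})

test_that("pathway scores match a spreadsheet-style oracle and its invariances", {
  samples <- c("s1", "s2")
  expr <- matrix(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1,
                   1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                 10, 2, dimnames = list(sprintf("g%02d", 1:10), samples))
  sets <- list(TOP = sprintf("g%02d", 1:3), BOTTOM = sprintf("g%02d", 8:10))
  fs <- faime_scores(expr, sets)
  w <- exp(-(1:10) / (0.1 * 10))       # weights for sample s1 (descending expr)
  expect_equal(fs["TOP", "s1"], mean(w[1:3]) - mean(w[4:10]))
  expect_equal(fs["BOTTOM", "s1"], mean(w[8:10]) - mean(w[c(1:7)]))
  expect_gt(fs["TOP", "s1"], 0)        # top-expressed set scores positive
  # monotone-transform invariance (rank-based)
  fs2 <- faime_scores(expr^3 + 5, sets)
  expect_equal(fs, fs2)
  # all-equal expression gives all-equal weights and score 0
  const <- matrix(7, 10, 1, dimnames = list(rownames(expr), "s"))
  expect_equal(unname(faime_scores(const, sets)[, 1]), c(0, 0))
  # sets without enough genes in/out are skipped
  expect_message(out <- faime_scores(expr, c(sets, list(TINY = "g01"))),
                 "skipping 1")
  expect_identical(rownames(out), c("TOP", "BOTTOM"))
})

test_that("pathway group tests detect a planted latent shift in cases", {
  refs <- small_refs()
  nc_fams <- family_label(refs$class, refs$family)[refs$class != "miRNA"]
  coh <- generate_cohort(refs, cohort_config(
    group_sizes = c(HC = 30L, SC = 2L, UC = 30L),
    library_size_range = c(20000L, 30000L), n_noise_species = 5L,
    latent_loadings = setNames(rep(0.4, length(nc_fams)), nc_fams),
    latent_group_shift = c(UC = 1), seed = 109L))
  gm <- generate_gene_matrix(coh, gene_config(n_genes = 60L, n_pos = 15L,
                                              n_neg = 0L, loading = 1.5,
                                              noise_sd = 1, seed = 7L))
  fs <- faime_scores(gm$expr, gm$sets["POS_PATH"])
  tab <- pathway_group_comparison(fs, coh$metadata, list(c("HC", "UC")))
  expect_gt(tab$t[tab$set == "POS_PATH"], 0)
  expect_lt(tab$p[tab$set == "POS_PATH"], 0.05)
})
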