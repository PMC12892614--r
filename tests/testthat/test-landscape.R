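# Class-total tests and correlations, length distributions, cleavage
# profiles, categorical PCA, and UC/CD fold-change concordance.

make_class_rpm <- function(tsRNA, rsRNA, ysRNA, ids = NULL) {
  m <- rbind(tsRNA = tsRNA, rsRNA = rsRNA, ysRNA = ysRNA,
             miRNA = rep(1, length(tsRNA)))
  colnames(m) <- if (is.null(ids)) sprintf("s%02d", seq_along(tsRNA)) else ids
  m
}

test_that("identical group totals give t = 0 and P = 1; monotone pairs give rho = 1", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   group = rep(c("HC", "UC"), each = 6))
  ts <- rep(100, 12)
  out <- class_total_tests(make_class_rpm(ts, ts * 2, ts / 2), md,
                           contrasts = list(c("HC", "UC")))
  expect_true(all(out$tests$t == 0))
  expect_true(all(out$tests$p == 1))
  # tsRNA totals exactly twice rsRNA totals -> perfect rank correlation
  ts2 <- seq(10, 120, by = 10)
  out2 <- class_total_tests(make_class_rpm(ts2, ts2 / 2, sqrt(ts2)), md,
                            contrasts = list(c("HC", "UC")))
  expect_true(all(out2$correlations$rho == 1))
})

test_that("Spearman rho matches the hand-ranked 1 - 6*sum(d^2)/(n(n^2-1)) formula", {
  x <- c(3.1, 7.2, 1.4, 9.9, 5.5, 2.2)
  y <- c(2.0, 6.1, 3.3, 8.8, 7.7, 1.1)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  md <- data.frame(sample_id = sprintf("s%02d", 1:6),
                   group = rep(c("HC", "UC"), each = 3))
  out <- class_total_tests(make_class_rpm(x, y, runif(6)), md,
                           contrasts = list(c("HC", "UC")))
  got <- out$correlations$rho[out$correlations$class_a == "tsRNA" &
                              out$correlations$class_b == "rsRNA"]
  expect_equal(got, rho_hand)
  expect_equal(got, unname(cor.test(x, y, method = "spearman")$estimate))
})

test_that("missing contrast groups are reported", {
  md <- data.frame(sample_id = c("a", "b", "c", "d"),
                   group = c("HC", "HC", "UC", "UC"))
  expect_error(class_total_tests(make_class_rpm(1:4, 1:4, 1:4, md$sample_id), md),
               "SC")
})

test_that("length histograms concentrate mass at the species lengths and conserve totals", {
  refs <- tiny_refs()
  frag22 <- substr(refs$sequence[1], 22, 43)
  ann <- annotate_reads(data.frame(sequence = frag22), refs)
  counts <- matrix(c(10L, 40L), 1, 2, dimnames = list(frag22, c("s1", "s2")))
  md <- data.frame(sample_id = c("s1", "s2"), group = c("HC", "HC"))
  ld <- length_distribution(ann$species, counts, md)
  ts <- ld[ld$class == "tsRNA", ]
  expect_equal(ts$mean_rpm[ts$length == 22], 1e6)   # all mass in the 22-nt bin
  expect_true(all(ts$mean_rpm[ts$length != 22] == 0))
})

test_that("per-sample histogram bins sum to the class total RPM", {
  refs <- small_refs()
  coh <- generate_cohort(refs, small_cohort_config(seed = 29L))
  ann <- annotate_reads(data.frame(sequence = rownames(coh$counts)), refs)
  agg <- aggregate_families(ann$species, coh$counts)
  ld <- length_distribution(ann$species, coh$counts, coh$metadata, agg$denominator)
  per_sample <- attr(ld, "per_sample")
  for (cl in rownames(agg$class_rpm)) {
    expect_equal(unname(colSums(per_sample[[cl]])), unname(agg$class_rpm[cl, ]),
                 tolerance = 1e-10)
  }
})

test_that("planted cleavage hotspots produce the configured length peaks", {
  refs <- generate_references(reference_config(n_mirna = 5L, seed = 31L))
  coh <- generate_cohort(refs, small_cohort_config(seed = 31L))
  ann <- annotate_reads(data.frame(sequence = rownames(coh$counts)), refs)
  agg <- aggregate_families(ann$species, coh$counts)
  ld <- length_distribution(ann$species, coh$counts, coh$metadata, agg$denominator)
  hc <- ld[ld$class == "tsRNA" & ld$group == "HC", ]
  peaks <- hc$length[hc$mean_rpm > 0]
  expect_setequal(peaks, c(17L, 22L))   # two tRNA-fragment peaks
  ys <- ld[ld$class == "ysRNA" & ld$group == "HC", ]
  expect_setequal(ys$length[ys$mean_rpm > 0], c(27L, 32L))
})

test_that("cleavage profiles conserve RPM x length and add linearly", {
  refs <- tiny_refs()
  fragA <- substr(refs$sequence[1], 22, 41)   # tA positions 21..41 (20 nt)
  fragB <- substr(refs$sequence[1], 50, 71)   # tA positions 49..71 (22 nt)
  ann <- annotate_reads(data.frame(sequence = c(fragA, fragB)), refs)
  counts <- matrix(c(10L, 90L), 2, 1, dimnames = list(c(fragA, fragB), "s1"))
  md <- data.frame(sample_id = "s1", group = "HC")
  denom <- setNames(1e6, "s1")
  prof <- cleavage_profile(ann$species, ann$loci, counts, refs, md,
                           "GtsRNA-Ala-AGC", denom)
  cov <- prof$tA$per_sample[, "s1"]
  expect_equal(sum(cov), 10 * 20 + 90 * 22)
  expect_true(all(cov[22:41] >= 10))
  expect_equal(unname(cov[1]), 0)
  # linearity: the two-species profile is the sum of single-species profiles
  p1 <- cleavage_profile(ann$species[1, ], ann$loci[ann$loci$sequence == fragA, ],
                         counts[1, , drop = FALSE], refs, md, "GtsRNA-Ala-AGC", denom)
  p2 <- cleavage_profile(ann$species[2, ], ann$loci[ann$loci$sequence == fragB, ],
                         counts[2, , drop = FALSE], refs, md, "GtsRNA-Ala-AGC", denom)
  expect_equal(prof$tA$per_sample, p1$tA$per_sample + p2$tA$per_sample)
  expect_warning(
    cleavage_profile(ann$species, ann$loci, counts, refs, md, "GtsRNA-Gly-GCC", denom),
    "no annotated species")
})

test_that("the coverage argmax falls inside the generator's dominant hotspot", {
  refs <- small_refs()
  coh <- generate_cohort(refs, small_cohort_config(seed = 37L))
  ann <- annotate_reads(data.frame(sequence = rownames(coh$counts)), refs)
  agg <- aggregate_families(ann$species, coh$counts)
  hs <- coh$truth$hotspots
  fam <- hs$family[hs$class == "GtRNA"][1]
  pid <- hs$parent_id[hs$family == fam][1]
  prof <- cleavage_profile(ann$species, ann$loci, coh$counts, refs,
                           coh$metadata, fam, agg$denominator)
  m <- rowMeans(prof[[pid]]$mean)
  span <- hs[hs$parent_id == pid, ]
  covered <- unlist(mapply(function(s, l) (s + 1):(s + l), span$start, span$length))
  expect_true(which.max(m) %in% covered)
})

test_that("PCA is an orthogonal centred-scaled SVD matching an eigen oracle", {
  set.seed(41)
  X <- matrix(rnorm(20), 5, 4,
              dimnames = list(sprintf("s%d", 1:5), sprintf("cat%d", 1:4)))
  res <- pca_categories(X)
  # oracle: eigendecomposition of the correlation matrix
  ev <- eigen(cor(X))
  expect_equal(res$explained_variance, ev$values / sum(ev$values))
  sc_oracle <- scale(X) %*% ev$vectors
  for (k in 1:2) {
    expect_equal(abs(cor(res$scores[, k], sc_oracle[, k])), 1)
  }
  # orthogonality and variance ordering
  g <- crossprod(res$scores)
  expect_lt(max(abs(g[upper.tri(g)])) /
              max(sqrt(diag(g) %o% diag(g))), 1e-8)
  expect_true(all(diff(res$explained_variance) <= 1e-12))
  expect_lte(sum(res$explained_variance), 1 + 1e-12)
})

test_that("duplicated samples get identical PC scores; degenerate input errors", {
  set.seed(43)
  X <- matrix(rnorm(24), 6, 4,
              dimnames = list(sprintf("s%d", 1:6), sprintf("cat%d", 1:4)))
  X[2, ] <- X[1, ]
  res <- pca_categories(X)
  expect_equal(res$scores[1, ], res$scores[2, ], ignore_attr = TRUE)
  expect_error(pca_categories(X[1:2, ]), "at least 3 samples")
  Xc <- cbind(X, cat5 = 0)
  expect_warning(pca_categories(Xc), "constant")
})

test_that("fold-change concordance is exact on constructed group means", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   group = rep(c("HC", "UC", "CD"), each = 4))
  fam <- rbind(f1 = c(rep(10, 4), rep(20, 4), rep(20, 4)),
               f2 = c(rep(5, 4), rep(5, 4), rep(5, 4)),
               f3 = c(rep(8, 4), rep(2, 4), rep(2, 4)))
  colnames(fam) <- md$sample_id
  fcc <- fold_change_concordance(fam, md, eps = 0.01)
  expect_equal(fcc$rho, 1)                                # UC means == CD means
  expect_equal(fcc$table$log2fc_uc[fcc$table$family == "f2"], 0)
  expect_equal(fcc$table$log2fc_uc[fcc$table$family == "f1"],
               log2(20.01 / 10.01))
  expect_error(fold_change_concordance(fam, md, eps = 0), "eps")
})

test_that("shared planted effects yield strongly concordant fold changes", {
  refs <- generate_references(reference_config(seed = 47L))
  nc_fams <- family_label(refs$class, refs$family)[refs$class != "miRNA"]
  set.seed(47)
  # per-family effects with SD well above the sampling noise, shared by UC and CD
  effects <- data.frame(family = nc_fams, log2fc = rnorm(length(nc_fams), 0, 1),
                        groups = "UC,CD")
  coh <- generate_cohort(refs, cohort_config(
    group_sizes = c(HC = 15L, UC = 15L, CD = 15L),
    library_size_range = c(50000L, 60000L), n_noise_species = 5L,
    effect_families = effects, seed = 47L))
  fam <- family_matrix_from_cohort(coh)
  fcc <- fold_change_concordance(fam[rownames(fam) %in% nc_fams, ],
                                 coh$metadata, eps = 0.01)
  expect_gt(fcc$rho, 0.8)
})
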