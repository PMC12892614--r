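# Descriptive landscape of the noncanonical small-RNA compartment: class-total
# group tests and cross-class correlations, length distributions, parental-RNA
# cleavage-position profiles, PCA over parental categories, and UC-vs-CD
# fold-change concordance.

DEFAULT_CONTRASTS <- list(c("HC", "SC"), c("HC", "UC"), c("HC", "CD"))

#' Group tests and cross-class correlations of class totals
#'
#' For each fragment class and each contrast, a two-sided Welch t-test on the
#' per-sample class-total RPM; plus Spearman's rank correlation (with the
#' t-approximation P) between the noncanonical class-total pairs
#' (tsRNA-rsRNA, tsRNA-ysRNA, rsRNA-ysRNA). Rank correlations are computed on
#' the raw totals (log axes in plots are presentation only; ranks are
#' invariant).
#'
#' @param class_rpm Fragment classes x samples RPM matrix.
#' @param metadata Sample metadata with `sample_id`, `group`.
#' @param contrasts List of `c(reference, case)` group pairs.
#' @return list(`tests` data.frame(class, contrast, mean_ref, mean_case, t,
#'   df, p), `correlations` data.frame(class_a, class_b, rho, p, n)).
#' @export
class_total_tests <- function(class_rpm, metadata, contrasts = DEFAULT_CONTRASTS) {
  check_metadata(metadata, unique(unlist(contrasts)))
  class_rpm <- align_samples(class_rpm, metadata)
  tests <- do.call(rbind, lapply(rownames(class_rpm), function(cl) {
    tab <- welch_contrasts(class_rpm[cl, ], metadata, contrasts)
    cbind(class = cl, tab)
  }))
  pairs <- list(c("tsRNA", "rsRNA"), c("tsRNA", "ysRNA"), c("rsRNA", "ysRNA"))
  pairs <- Filter(function(p) all(p %in% rownames(class_rpm)), pairs)
  correlations <- do.call(rbind, lapply(pairs, function(p) {
    st <- spearman_t(class_rpm[p[1], ], class_rpm[p[2], ])
    data.frame(class_a = p[1], class_b = p[2], rho = st$rho, p = st$p, n = st$n)
  }))
  list(tests = tests, correlations = correlations)
}

#' Per-class, per-group read-length distributions
#'
#' For each fragment class, each sample contributes a 31-bin vector of summed
#' species RPM per length (15-45 nt); bins are aggregated per group to mean
#' and normal-approximation 95% CI (mean +/- 1.96 SEM).
#'
#' @param species Annotated species table ([annotate_reads()]).
#' @param counts Species x samples count matrix.
#' @param metadata Sample metadata.
#' @param denominator Per-sample totals used for RPM (e.g. from
#'   [aggregate_families()]); defaults to `colSums(counts)`.
#' @return data.frame(class, group, length, mean_rpm, sem, ci_lo, ci_hi), with
#'   the per-sample bin matrix in attribute `per_sample` (list by class).
#' @export
length_distribution <- function(species, counts, metadata, denominator = NULL) {
  check_metadata(metadata)
  counts <- align_samples(counts, metadata)[species$sequence, , drop = FALSE]
  if (is.null(denominator)) denominator <- colSums(counts)
  rpm <- sweep(counts, 2, denominator, "/") * 1e6
  bins <- 15:45
  per_sample <- list()
  rows <- list()
  for (cl in SNC_FRAGMENT_CLASSES) {
    sel <- species$class != "unannotated" & fragment_class(species$class) == cl
    hist_mat <- matrix(0, length(bins), ncol(rpm),
                       dimnames = list(bins, colnames(rpm)))
    if (any(sel)) {
      agg <- rowsum(rpm[sel, , drop = FALSE], species$length[sel])
      hist_mat[rownames(agg), ] <- agg
    }
    per_sample[[cl]] <- hist_mat
    for (g in unique(metadata$group)) {
      cols <- metadata$sample_id[metadata$group == g]
      m <- rowMeans(hist_mat[, cols, drop = FALSE])
      sem <- apply(hist_mat[, cols, drop = FALSE], 1, stats::sd) / sqrt(length(cols))
      rows[[paste(cl, g)]] <- data.frame(class = cl, group = g, length = bins,
                                         mean_rpm = m, sem = sem,
                                         ci_lo = m - 1.96 * sem,
                                         ci_hi = m + 1.96 * sem)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  out
}

#' Cleavage-position profile of a family's parental RNAs
#'
#' Per sample, coverage at position p is the sum over species and matched loci
#' containing p of the species RPM (multi-locus species contribute at every
#' matched locus, preserving positional signal). Coverage is then summarised
#' per group as mean and SEM at each position of the parental sequence.
#'
#' @param species Annotated species table.
#' @param loci Per-species loci table ([annotate_reads()]).
#' @param counts Species x samples count matrix.
#' @param refs Parental reference table.
#' @param metadata Sample metadata.
#' @param family Class-prefixed family label (e.g. `"GtsRNA-Arg-ACG"`).
#' @param denominator Per-sample totals for RPM; defaults to `colSums(counts)`.
#' @return Named list (by parent_id) of lists with `position` (0-based),
#'   per-group `mean` and `sem` matrices (positions x 1), `contributing_species`,
#'   and `per_sample` coverage matrix.
#' @export
cleavage_profile <- function(species, loci, counts, refs, metadata, family,
                             denominator = NULL) {
  check_metadata(metadata)
  counts <- align_samples(counts, metadata)[species$sequence, , drop = FALSE]
  if (is.null(denominator)) denominator <- colSums(counts)
  rpm <- sweep(counts, 2, denominator, "/") * 1e6
  fam_species <- species$sequence[!is.na(species$family) & species$family == family]
  if (!length(fam_species)) {
    warning("family ", family, " has no annotated species; returning zero profiles")
  }
  parents <- refs$parent_id[family_label(refs$class, refs$family) == family]
  out <- list()
  for (pid in parents) {
    L <- nchar(refs$sequence[refs$parent_id == pid])
    cov <- matrix(0, L, ncol(rpm), dimnames = list(NULL, colnames(rpm)))
    loc <- loci[loci$parent_id == pid & loci$sequence %in% fam_species, , drop = FALSE]
    if (nrow(loc)) {
      for (i in seq_len(nrow(loc))) {
        idx <- (loc$start[i] + 1L):loc$end[i]
        cov[idx, ] <- cov[idx, ] + rep(rpm[loc$sequence[i], ], each = length(idx))
      }
    }
    groups <- unique(metadata$group)
    mean_mat <- sem_mat <- matrix(0, L, length(groups), dimnames = list(NULL, groups))
    for (g in groups) {
      cols <- metadata$sample_id[metadata$group == g]
      mean_mat[, g] <- rowMeans(cov[, cols, drop = FALSE])
      sem_mat[, g] <- apply(cov[, cols, drop = FALSE], 1, stats::sd) / sqrt(length(cols))
    }
    out[[pid]] <- list(parent_id = pid, position = seq_len(L) - 1L,
                       mean = mean_mat, sem = sem_mat,
                       contributing_species = length(unique(loc$sequence)),
                       per_sample = cov)
  }
  out
}

#' PCA over parental categories with group tests on PC1
#'
#' Columns (categories) are centred and scaled to unit variance
#' (constant-zero categories are dropped with a warning), then decomposed by
#' SVD. Group contrasts on the first principal component use Welch t-tests.
#'
#' @param category_rpm Samples x categories RPM matrix (or categories x
#'   samples with `samples_in` = "cols").
#' @param metadata Sample metadata; `NULL` skips the PC1 tests.
#' @param contrasts Contrast list for the PC1 Welch t-tests.
#' @param samples_in `"rows"` (default) or `"cols"`.
#' @return list(`scores`, `loadings`, `explained_variance`, `pc1_tests`).
#' @export
pca_categories <- function(category_rpm, metadata = NULL,
                           contrasts = DEFAULT_CONTRASTS,
                           samples_in = c("rows", "cols")) {
  samples_in <- match.arg(samples_in)
  X <- if (samples_in == "cols") t(category_rpm) else category_rpm
  if (nrow(X) < 3) stop("PCA needs at least 3 samples")
  if (ncol(X) < 2) stop("PCA needs at least 2 categories")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant categor",
            if (sum(const) == 1) "y" else "ies", " before PCA")
    X <- X[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  pc1_tests <- NULL
  if (!is.null(metadata)) {
    check_metadata(metadata)
    ord <- match(rownames(X), metadata$sample_id)
    if (anyNA(ord)) stop("PCA matrix rownames must be sample ids present in metadata")
    pc1_tests <- welch_contrasts(pc$x[, 1], metadata[ord, , drop = FALSE], contrasts)
  }
  list(scores = pc$x, loadings = pc$rotation, explained_variance = ev,
       pc1_tests = pc1_tests)
}

#' Fold-change concordance between the UC and CD contrasts
#'
#' Per family, `log2FC = log2((mean_case + eps)/(mean_ref + eps))` for the
#' HC-vs-UC and HC-vs-CD contrasts; concordance is their Spearman correlation.
#' Families with zero mean in every group are excluded.
#'
#' @param family_rpm Families x samples RPM matrix.
#' @param metadata Sample metadata.
#' @param eps Pseudocount in RPM, > 0 (default 0.01).
#' @param ref Reference group; `cases` the two case groups.
#' @return list(`table` data.frame(family, log2fc_uc, log2fc_cd), `rho`, `p`).
#' @export
fold_change_concordance <- function(family_rpm, metadata, eps = 0.01,
                                    ref = "HC", cases = c("UC", "CD")) {
  if (eps <= 0) stop("eps must be > 0")
  check_metadata(metadata, c(ref, cases))
  family_rpm <- align_samples(family_rpm, metadata)
  gm <- vapply(c(ref, cases), function(g)
    rowMeans(family_rpm[, metadata$group == g, drop = FALSE]),
    numeric(nrow(family_rpm)))
  keep <- rowSums(gm) > 0
  gm <- gm[keep, , drop = FALSE]
  fc1 <- log2((gm[, cases[1]] + eps) / (gm[, ref] + eps))
  fc2 <- log2((gm[, cases[2]] + eps) / (gm[, ref] + eps))
  st <- spearman_t(fc1, fc2)
  list(table = data.frame(family = rownames(gm), log2fc_uc = fc1, log2fc_cd = fc2,
                          row.names = NULL),
       rho = st$rho, p = st$p)
}
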