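# Cross-cohort baseline divergence of healthy controls: per-family log2 fold
# change of HC mean expression between cohorts, the miRNA-vs-noncanonical
# comparison of |log2FC| by two-sample KS test, and baseline linearity R^2 on
# the log10 scale.

#' Per-family cohort-divergence log2 fold change
#'
#' `log2FC = log2((mean_B + eps)/(mean_A + eps))` over the intersection of the
#' two family universes; families present in only one cohort are dropped and
#' counted in the `dropped` attribute. Two zero means give exactly 0
#' (pseudocount symmetry).
#'
#' @param mean_a,mean_b Named vectors of per-family HC mean RPM in cohorts A
#'   and B (A is the first-listed/reference cohort, the denominator).
#' @param eps Pseudocount in RPM, > 0 (default 0.01).
#' @return Named log2FC vector over the shared families.
#' @export
divergence_log2fc <- function(mean_a, mean_b, eps = 0.01) {
  if (eps <= 0) stop("eps must be > 0")
  shared <- intersect(names(mean_a), names(mean_b))
  dropped <- length(mean_a) + length(mean_b) - 2L * length(shared)
  if (!length(shared)) stop("no shared families between cohorts")
  out <- log2((mean_b[shared] + eps) / (mean_a[shared] + eps))
  attr(out, "dropped") <- dropped
  out
}

#' KS comparison of miRNA vs noncanonical |log2FC|
#'
#' Two-sample Kolmogorov-Smirnov test (`D = sup |ECDF1 - ECDF2|`, asymptotic
#' two-sided P) of the absolute cohort-divergence fold changes of miRNAs
#' against those of noncanonical families.
#'
#' @param abs_fc_mirna,abs_fc_noncanonical Numeric vectors of |log2FC|, each
#'   of length >= 5.
#' @return list(`D`, `p`).
#' @export
ks_compare <- function(abs_fc_mirna, abs_fc_noncanonical) {
  if (length(abs_fc_mirna) < 5 || length(abs_fc_noncanonical) < 5) {
    stop("both |log2FC| vectors need length >= 5")
  }
  kt <- suppressWarnings(stats::ks.test(abs_fc_mirna, abs_fc_noncanonical,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Baseline linearity between cohorts
#'
#' R^2 of the OLS regression of `log10(mean_B + eps)` on `log10(mean_A + eps)`
#' over the families of one class; for simple regression this equals the
#' squared Pearson correlation of the two log-scale vectors (and is symmetric
#' in the regression direction).
#'
#' @param mean_a,mean_b Named per-family HC mean RPM vectors (intersected).
#' @param eps Pseudocount in RPM.
#' @return R^2.
#' @export
baseline_linearity <- function(mean_a, mean_b, eps = 0.01) {
  if (eps <= 0) stop("eps must be > 0")
  shared <- intersect(names(mean_a), names(mean_b))
  if (length(shared) < 3) stop("need >= 3 shared families")
  x <- log10(mean_a[shared] + eps)
  y <- log10(mean_b[shared] + eps)
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  if (stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Full cohort-divergence table and summaries
#'
#' Builds the per-family divergence table (class, per-cohort HC means,
#' log2FC), the miRNA-vs-noncanonical KS comparison of |log2FC|, and per-class
#' baseline-linearity R^2.
#'
#' @param family_rpm_a,family_rpm_b Families x samples RPM matrices of the
#'   two cohorts.
#' @param metadata_a,metadata_b Their metadata; only `hc_group` samples enter.
#' @param eps Pseudocount in RPM.
#' @param hc_group Group defining the baseline population (default `"HC"`).
#' @return list(`table` data.frame(family, class, mean_a, mean_b, log2fc),
#'   `ks` list(D, p), `r2` named per-class R^2).
#' @export
cohort_divergence <- function(family_rpm_a, family_rpm_b,
                              metadata_a, metadata_b,
                              eps = 0.01, hc_group = "HC") {
  check_metadata(metadata_a, hc_group)
  check_metadata(metadata_b, hc_group)
  ma <- rowMeans(align_samples(family_rpm_a,
                               metadata_a[metadata_a$group == hc_group, ]))
  mb <- rowMeans(align_samples(family_rpm_b,
                               metadata_b[metadata_b$group == hc_group, ]))
  fc <- divergence_log2fc(ma, mb, eps)
  fam <- names(fc)
  cls <- ifelse(grepl("^(GtsRNA|MtsRNA|rsRNA|ysRNA)-", fam), "noncanonical", "miRNA")
  tab <- data.frame(family = fam, class = cls, mean_a = unname(ma[fam]),
                    mean_b = unname(mb[fam]), log2fc = unname(fc),
                    row.names = NULL)
  ks <- ks_compare(abs(tab$log2fc[tab$class == "miRNA"]),
                   abs(tab$log2fc[tab$class == "noncanonical"]))
  r2 <- vapply(c(noncanonical = "noncanonical", miRNA = "miRNA"), function(cl) {
    sel <- tab$class == cl
    if (sum(sel) < 3) return(NA_real_)
    baseline_linearity(stats::setNames(tab$mean_a[sel], tab$family[sel]),
                       stats::setNames(tab$mean_b[sel], tab$family[sel]), eps)
  }, numeric(1))
  list(table = tab, ks = ks, r2 = r2)
}
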