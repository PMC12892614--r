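# Covariate-adjusted differential expression of fragment families and the
# commonly-dysregulated signature. The model is ordinary least squares of RPM
# on [intercept, group indicator (case = 1), age, sex (male = 1)], P two-sided
# from the t distribution with n - 4 df for the group coefficient, Bonferroni
# correction per contrast, and the signature is the intersection of families
# significant in both case contrasts with a concordant direction.

# Design matrix for one two-group contrast; only the two groups involved enter.
contrast_design <- function(metadata, contrast) {
  sel <- metadata$group %in% contrast
  md <- metadata[sel, , drop = FALSE]
  X <- cbind(intercept = 1,
             case = as.numeric(md$group == contrast[2]),
             age = md$age,
             sex = as.numeric(md$sex == "M"))
  if (nrow(X) < 5) stop("contrast ", paste(contrast, collapse = " vs "),
                        ": need at least 5 samples")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    stop("rank-deficient design for contrast ", paste(contrast, collapse = " vs "),
         "; collinear column: ", colnames(X)[q$pivot[(q$rank + 1):ncol(X)]][1])
  }
  list(X = X, qr = q, samples = md$sample_id)
}

#' Fit the covariate-adjusted linear model for one family
#'
#' OLS of the family's RPM on intercept, case indicator, age, and sex
#' (male = 1, female = 0); returns the group coefficient with its two-sided
#' t-test on `n - 4` degrees of freedom. Only samples of the two contrast
#' groups enter the fit.
#'
#' @param rpm Named numeric vector of the family's RPM (names = sample ids),
#'   or unnamed in metadata order.
#' @param metadata Sample metadata with `sample_id`, `group`, `age`, `sex`.
#' @param contrast `c(reference, case)` group pair.
#' @param log_transform Fit on `log2(RPM + 1)` instead of raw RPM (robustness
#'   variant; the primary analysis is on raw RPM).
#' @return list(`coefficient`, `t`, `df`, `p`).
#' @export
fit_family_model <- function(rpm, metadata, contrast = c("HC", "UC"),
                             log_transform = FALSE) {
  check_metadata(metadata, contrast)
  if (!is.null(names(rpm))) rpm <- rpm[metadata$sample_id]
  stopifnot(length(rpm) == nrow(metadata))
  d <- contrast_design(metadata, contrast)
  y <- rpm[metadata$group %in% contrast]
  if (log_transform) y <- log2(y + 1)
  fit <- fit_contrast_matrix(matrix(y, nrow = 1), d)
  list(coefficient = fit$coefficient[1], t = fit$t[1], df = fit$df, p = fit$p[1])
}

# Vectorised OLS of many families (rows of Y) against one contrast design.
# Returns group coefficient, t, raw P per family.
fit_contrast_matrix <- function(Y, design) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, t(Y))        # p x families
  resid <- t(Y) - X %*% B
  df <- n - p
  s2 <- colSums(resid^2) / df
  coef <- B[2, ]
  # numerically exact fits (constant or interpolated data): residual variance
  # at rounding-error level relative to the response scale
  tiny <- 1e-20 * (colMeans(t(Y)^2) + 1)
  exact <- s2 <= tiny
  coef[exact & abs(coef) <= sqrt(tiny)] <- 0
  se <- sqrt(pmax(s2 * XtXi[2, 2], 0))
  t <- ifelse(exact, ifelse(coef == 0, 0, sign(coef) * Inf), coef / se)
  praw <- ifelse(exact, ifelse(coef == 0, 1, 0), 2 * stats::pt(-abs(t), df))
  list(coefficient = coef, t = t, df = df, p = praw)
}

#' Bonferroni adjustment of a raw P-value vector
#'
#' `p_adj = min(1, p x m)` with `m = length(p)`; delegated to
#' [stats::p.adjust()].
#'
#' @param p Raw P-values in \[0, 1\].
#' @return Adjusted P-values.
#' @export
adjust_bonferroni <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Differential table for one contrast across all families
#'
#' @param family_rpm Families x samples RPM matrix.
#' @param metadata Sample metadata.
#' @param contrast `c(reference, case)` group pair.
#' @param log_transform See [fit_family_model()].
#' @return data.frame(family, coefficient, t, df, p, p_adj, direction) with
#'   Bonferroni adjustment over the families tested in this contrast.
#' @export
differential_table <- function(family_rpm, metadata, contrast = c("HC", "UC"),
                               log_transform = FALSE) {
  check_metadata(metadata, contrast)
  family_rpm <- align_samples(family_rpm, metadata)
  d <- contrast_design(metadata, contrast)
  Y <- family_rpm[, d$samples, drop = FALSE]
  if (log_transform) Y <- log2(Y + 1)
  fit <- fit_contrast_matrix(Y, d)
  data.frame(family = rownames(family_rpm),
             coefficient = unname(fit$coefficient), t = unname(fit$t),
             df = fit$df, p = unname(fit$p),
             p_adj = adjust_bonferroni(unname(fit$p)),
             direction = ifelse(fit$coefficient >= 0, "up", "down"),
             row.names = NULL)
}

#' Derive the commonly-dysregulated signature
#'
#' Families with Bonferroni-adjusted P below `alpha` in BOTH contrasts and the
#' same direction of effect in both. Direction is recorded per family and the
#' default (`"both"`) admits either direction, leaving any direction filter to
#' the caller; `"up"` keeps only upregulated survivors.
#'
#' @param tab_a,tab_b Differential tables ([differential_table()]) for the two
#'   case contrasts (HC vs UC, HC vs CD); must cover identical family sets.
#' @param alpha Significance level on adjusted P (default 0.05).
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @return data.frame(family, direction, p_adj_a, p_adj_b) ordered by max
#'   adjusted P; zero rows when no family qualifies.
#' @export
derive_signature <- function(tab_a, tab_b, alpha = 0.05,
                             direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!setequal(tab_a$family, tab_b$family)) {
    stop("the two differential tables must cover identical family sets")
  }
  tab_b <- tab_b[match(tab_a$family, tab_b$family), , drop = FALSE]
  hit <- tab_a$p_adj < alpha & tab_b$p_adj < alpha &
    tab_a$direction == tab_b$direction
  if (direction != "both") hit <- hit & tab_a$direction == direction
  sig <- data.frame(family = tab_a$family[hit],
                    direction = tab_a$direction[hit],
                    p_adj_a = tab_a$p_adj[hit], p_adj_b = tab_b$p_adj[hit],
                    row.names = NULL)
  sig[order(pmax(sig$p_adj_a, sig$p_adj_b), sig$family), , drop = FALSE]
}
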