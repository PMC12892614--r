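# The z-sum risk score and its evaluation: per-family mean/SD baseline on
# log2(RPM + 1), the signed z-score sum, rank-based ROC/AUC, the DeLong test
# for correlated AUCs, and the repeated stratified five-fold cross-validation
# harness with per-fold signature re-derivation.

#' Per-family baseline (mean, SD) of log-expression over a reference population
#'
#' mu and tau are the mean and `n - 1`-denominator SD of `log2(RPM + 1)` per
#' signature family, computed over the stated population samples.
#' Zero-variance families are dropped with a warning.
#'
#' @param family_rpm Families x samples RPM matrix.
#' @param population Sample ids defining the reference population (>= 2).
#' @param signature Signature data.frame (`family`, `direction`) or character
#'   vector of families (all treated as "up").
#' @return data.frame(family, direction, mu, tau) with attribute `population`.
#' @export
compute_baseline <- function(family_rpm, population, signature) {
  if (is.character(signature)) signature <- data.frame(family = signature,
                                                       direction = "up")
  if (length(population) < 2) stop("baseline population needs >= 2 samples")
  miss <- setdiff(signature$family, rownames(family_rpm))
  if (length(miss)) stop("signature families absent from matrix: ",
                         paste(miss, collapse = ", "))
  E <- log2(family_rpm[signature$family, population, drop = FALSE] + 1)
  mu <- rowMeans(E)
  tau <- apply(E, 1, stats::sd)
  keep <- tau > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance famil",
            if (sum(!keep) == 1) "y" else "ies", " from the baseline")
  }
  out <- data.frame(family = signature$family[keep],
                    direction = signature$direction[keep],
                    mu = unname(mu[keep]), tau = unname(tau[keep]),
                    row.names = NULL)
  attr(out, "population") <- population
  out
}

#' z-sum risk score of samples
#'
#' `score = sum_i d_i x (e_i - mu_i)/tau_i` over the signature families, with
#' `e_i = log2(RPM_i + 1)`, `d_i = +1` for upregulated and `-1` for
#' downregulated families. A greater score implies higher likelihood or
#' severity of disease.
#'
#' @param family_rpm Families x samples RPM matrix (columns are scored).
#' @param baseline Baseline from [compute_baseline()].
#' @return Named numeric vector of scores, one per column.
#' @export
risk_score <- function(family_rpm, baseline) {
  if (nrow(baseline) == 0) stop("empty baseline")
  miss <- setdiff(baseline$family, rownames(family_rpm))
  if (length(miss)) stop("missing family value(s): ", paste(miss, collapse = ", "))
  E <- log2(family_rpm[baseline$family, , drop = FALSE] + 1)
  d <- ifelse(baseline$direction == "down", -1, 1)
  colSums((E - baseline$mu) / baseline$tau * d)
}

#' ROC curve and AUC
#'
#' AUC is the concordant-pair fraction: `(concordant + 0.5 x ties)/(n+ x n-)`,
#' computed via the rank (Mann-Whitney) identity. Orientation is fixed - cases
#' are expected to score higher and the AUC may fall below 0.5; there is no
#' automatic flip. Curve points are evaluated at every distinct threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or factor with two levels; the
#'   second level / `TRUE` / `1` is the case class).
#' @return list(`auc`, `roc` data.frame(threshold, fpr, tpr)).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                      # average ranks handle ties as 1/2
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(threshold = thr,
                    fpr = vapply(thr, function(t) mean(scores[y == 0] >= t), 0),
                    tpr = vapply(thr, function(t) mean(scores[y == 1] >= t), 0))
  list(auc = auc, roc = roc)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1)) || length(u) > 2) stop("labels must be binary")
  labels
}

# Placement values of each observation against the opposite class
# (V10: per-case mean of [score > control] + 0.5 [==]; V01 analogous).
delong_placements <- function(scores, y) {
  cs <- scores[y == 1]; ct <- scores[y == 0]
  V10 <- vapply(cs, function(s) mean((s > ct) + 0.5 * (s == ct)), 0)
  V01 <- vapply(ct, function(s) mean((cs > s) + 0.5 * (cs == s)), 0)
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors on the same samples and
#' labels, via placement-value covariance; `z = dAUC/SE(dAUC)`, two-sided P
#' from the standard normal.
#'
#' @param scores_a,scores_b Two score vectors on the same samples.
#' @param labels Binary labels (case = 1).
#' @return list(`auc_a`, `auc_b`, `delta_auc`, `z`, `p`).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$V10, pb$V10))
  s01 <- stats::cov(cbind(pa$V01, pb$V01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- pa$auc - pb$auc
  if (v <= 0 || !is.finite(v)) {
    if (delta != 0) warning("zero variance of the AUC difference; P set to 1")
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, z = 0, p = 1))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

# Stratified-by-group fold assignment: per group, shuffled samples are dealt
# into k folds; remainder samples go one per fold, largest folds first,
# deterministically given the RNG state.
stratified_folds <- function(metadata, k) {
  fold <- integer(nrow(metadata))
  for (g in unique(metadata$group)) {
    idx <- which(metadata$group == g)
    if (length(idx) < k) stop("group ", g, " has fewer samples than folds")
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    rem <- length(idx) %% k
    sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
    fold[idx] <- rep(seq_len(k), sizes)
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the z-sum score
#'
#' In every round, HC/UC/CD samples are split into `k` stratified folds. For
#' each fold, the full signature-derivation procedure (per-contrast
#' covariate-adjusted fits, Bonferroni, common-dysregulation intersection) is
#' re-run on the training folds; the baseline mu/tau is computed on training
#' samples (leakage-free default) or on the full cohort
#' (`baseline_population = "cohort"`); the held-out fold is scored and
#' AUC(HC vs UC) and AUC(HC vs CD) are recorded. Folds whose training split
#' yields an empty signature contribute missing AUCs and are excluded from
#' that round's mean (counted in `empty_folds`).
#'
#' @param family_rpm Families x samples RPM matrix.
#' @param metadata Sample metadata; only `groups` enter the CV.
#' @param k Folds (default 5).
#' @param rounds Number of CV rounds (default 1000).
#' @param alpha Signature significance level on adjusted P.
#' @param seed Integer seed; the report is bit-identical for a fixed seed.
#' @param baseline_population `"training"` (default) or `"cohort"`.
#' @param direction Signature direction filter, as in [derive_signature()].
#' @param groups Groups entering the CV (reference first).
#' @return list(`round_auc` data.frame(round, auc_hc_uc, auc_hc_cd),
#'   `prioritization` named counts of how often each family entered a trained
#'   signature, `empty_folds`, `k`, `rounds`, `seed`).
#' @export
cross_validate <- function(family_rpm, metadata, k = 5L, rounds = 1000L,
                           alpha = 0.05, seed = 1L,
                           baseline_population = c("training", "cohort"),
                           direction = "both",
                           groups = c("HC", "UC", "CD")) {
  baseline_population <- match.arg(baseline_population)
  check_metadata(metadata, groups)
  md <- metadata[metadata$group %in% groups, , drop = FALSE]
  family_rpm <- align_samples(family_rpm, md)
  contrasts <- lapply(groups[-1], function(g) c(groups[1], g))
  freq <- stats::setNames(numeric(nrow(family_rpm)), rownames(family_rpm))
  auc_mat <- matrix(NA_real_, rounds, length(contrasts))
  empty_folds <- 0L
  local_seed(seed, {
    for (r in seq_len(rounds)) {
      fold <- stratified_folds(md, k)
      fold_auc <- matrix(NA_real_, k, length(contrasts))
      for (f in seq_len(k)) {
        tr <- fold != f
        md_tr <- md[tr, , drop = FALSE]
        tabs <- lapply(contrasts, function(ct)
          differential_table(family_rpm[, md_tr$sample_id, drop = FALSE], md_tr, ct))
        sig <- derive_signature(tabs[[1]], tabs[[2]], alpha = alpha,
                                direction = direction)
        if (nrow(sig) == 0) { empty_folds <- empty_folds + 1L; next }
        freq[sig$family] <- freq[sig$family] + 1
        pop <- if (baseline_population == "training") md_tr$sample_id else md$sample_id
        bl <- suppressWarnings(compute_baseline(family_rpm, pop, sig))
        if (nrow(bl) == 0) { empty_folds <- empty_folds + 1L; next }
        md_va <- md[!tr, , drop = FALSE]
        sc <- risk_score(family_rpm[, md_va$sample_id, drop = FALSE], bl)
        for (ci in seq_along(contrasts)) {
          ct <- contrasts[[ci]]
          sel <- md_va$group %in% ct
          lab <- md_va$group[sel] == ct[2]
          if (length(unique(lab)) == 2) {
            fold_auc[f, ci] <- roc_auc(sc[sel], lab)$auc
          }
        }
      }
      auc_mat[r, ] <- colMeans(fold_auc, na.rm = TRUE)
    }
  })
  auc_mat[is.nan(auc_mat)] <- NA_real_
  out <- data.frame(round = seq_len(rounds), auc_mat)
  names(out)[-1] <- paste0("auc_", tolower(groups[1]), "_", tolower(groups[-1]))
  list(round_auc = out, prioritization = freq, empty_folds = empty_folds,
       k = k, rounds = rounds, seed = seed)
}
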