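#' @keywords internal
"_PACKAGE"

# Class labels used throughout. `SNC_CLASSES` are parental-reference classes;
# `SNC_FRAGMENT_CLASSES` are the derived small-RNA class totals reported to users
# (tsRNA pools the genomic and mitochondrial tRNA fragments).
SNC_CLASSES <- c("GtRNA", "MtRNA", "rRNA", "YRNA", "miRNA")
SNC_FRAGMENT_CLASSES <- c("tsRNA", "rsRNA", "ysRNA", "miRNA")
SNC_GROUPS <- c("HC", "SC", "UC", "CD")

# Default annotation precedence: rRNA, the most promiscuous matcher, absorbs last.
DEFAULT_PRECEDENCE <- c("miRNA", "GtRNA", "MtRNA", "YRNA", "rRNA")

#' Evaluate code under a local RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so deterministic generators do not perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All pipeline stages draw their randomness from named substreams of one
#' master seed, so adding a stage never perturbs the streams of earlier
#' stages. The derivation is a small deterministic hash of the stream name
#' folded into the master seed, kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name (e.g. `"simulate"`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (v in utf8ToInt(stream)) h <- (h * 131 + v) %% 1000000007
  as.integer((as.numeric(seed) %% 1000003 + 1) * 1009 %% 2147483647 + h) %% 2147483647L
}

#' Map a parental class and family to the user-facing family label
#'
#' Fragment families carry a class prefix: `GtsRNA-Arg-ACG` (genomic tRNA
#' fragments, anticodon family), `MtsRNA-His-GTG` (mitochondrial),
#' `rsRNA-12S`, `ysRNA-RNY3`. miRNA families keep their own names.
#'
#' @param class Parental class, one of `GtRNA`, `MtRNA`, `rRNA`, `YRNA`, `miRNA`.
#' @param family Family within the class (anticodon family / parental name).
#' @return Character vector of labels.
#' @export
family_label <- function(class, family) {
  prefix <- c(GtRNA = "GtsRNA-", MtRNA = "MtsRNA-", rRNA = "rsRNA-",
              YRNA = "ysRNA-", miRNA = "")[class]
  unname(paste0(prefix, family))
}

#' Fragment-class of a parental class
#' @keywords internal
fragment_class <- function(class) {
  unname(c(GtRNA = "tsRNA", MtRNA = "tsRNA", rRNA = "rsRNA",
           YRNA = "ysRNA", miRNA = "miRNA")[class])
}

#' Welch t-tests of a numeric vector between groups, one row per contrast
#'
#' @param x Numeric vector (one value per sample).
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param contrasts List of 2-vectors `c(reference, case)`.
#' @return data.frame with contrast, group means, t, df, and two-sided P.
#' @keywords internal
welch_contrasts <- function(x, metadata, contrasts) {
  stopifnot(length(x) == nrow(metadata))
  out <- lapply(contrasts, function(ct) {
    a <- x[metadata$group == ct[1]]
    b <- x[metadata$group == ct[2]]
    if (length(a) < 2 || length(b) < 2) {
      stop("contrast ", ct[1], " vs ", ct[2], ": need >= 2 samples per group")
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      # degenerate: identical constant groups
      return(data.frame(contrast = paste0(ct[1], "_vs_", ct[2]),
                        mean_ref = mean(a), mean_case = mean(b),
                        t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    tt <- stats::t.test(b, a)   # case minus reference
    data.frame(contrast = paste0(ct[1], "_vs_", ct[2]),
               mean_ref = mean(a), mean_case = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Spearman correlation with the t-approximation P-value
#'
#' rho is Pearson correlation of average ranks; P comes from
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df. Matches `cor.test`'s rho.
#'
#' @param x,y Numeric vectors.
#' @return list(rho, p, n)
#' @keywords internal
spearman_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Check that metadata has the expected shape
#' @keywords internal
check_metadata <- function(metadata, groups = NULL) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata")
  if (!is.null(groups)) {
    absent <- setdiff(groups, unique(metadata$group))
    if (length(absent)) {
      stop("group(s) absent from metadata: ", paste(absent, collapse = ", "))
    }
  }
  invisible(metadata)
}

#' Align a samples-in-columns matrix with metadata rows
#' @keywords internal
align_samples <- function(mat, metadata) {
  miss <- setdiff(metadata$sample_id, colnames(mat))
  if (length(miss)) stop("samples in metadata missing from matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  mat[, metadata$sample_id, drop = FALSE]
}
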