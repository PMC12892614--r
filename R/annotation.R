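# Exact-match annotation of collapsed small-RNA reads against parental
# references: length filter, zero-mismatch substring assignment with a
# configurable class precedence, and aggregation to family- and class-level
# reads-per-million.

#' Filter collapsed reads by length
#'
#' Retains only species whose length lies in `[min_len, max_len]` (15-45 nt by
#' default); counts are unchanged. The numbers of species and the count mass
#' removed are attached as attributes `n_removed` / `mass_removed`.
#'
#' @param reads data.frame with `sequence` and positive integer `count`.
#' @param min_len,max_len Retained length bounds in nt, inclusive.
#' @return The retained subset of `reads`.
#' @export
filter_reads <- function(reads, min_len = 15L, max_len = 45L) {
  if (nrow(reads) == 0) {
    warning("filter_reads: empty input")
    out <- reads
    attr(out, "n_removed") <- 0L
    attr(out, "mass_removed") <- 0
    return(out)
  }
  if (any(reads$count <= 0) || any(reads$count != round(reads$count))) {
    stop("read counts must be positive integers")
  }
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "mass_removed") <- sum(reads$count[!keep])
  out
}

# All exact-substring loci of `sequence` across `refs`; 0-based half-open.
find_loci <- function(sequence, refs) {
  hit <- which(vapply(refs$sequence, grepl, logical(1),
                      pattern = sequence, fixed = TRUE, USE.NAMES = FALSE))
  if (!length(hit)) {
    return(data.frame(parent_id = character(), class = character(),
                      family = character(), start = integer(), end = integer()))
  }
  w <- nchar(sequence)
  out <- lapply(hit, function(i) {
    starts <- gregexpr(sequence, refs$sequence[i], fixed = TRUE)[[1]]
    data.frame(parent_id = refs$parent_id[i], class = refs$class[i],
               family = refs$family[i],
               start = as.integer(starts) - 1L,
               end = as.integer(starts) - 1L + w)
  })
  do.call(rbind, out)
}

#' Annotate one small-RNA species by exact matching
#'
#' Finds every zero-mismatch substring locus of `sequence` in the references
#' (forward strand; references are mature sense sequences, so the mature-tRNA
#' restriction is inherent) and assigns the species to the first class in the
#' precedence list with at least one locus. If parents within the winning
#' class disagree on family, the species is flagged ambiguous and assigned the
#' lexicographically first family.
#'
#' @param sequence A single DNA string, length 15-45 nt.
#' @param refs Parental reference table.
#' @param precedence Class precedence; default `miRNA > GtRNA > MtRNA > YRNA >
#'   rRNA` so that rRNA, the most promiscuous matcher, absorbs reads last.
#' @return list with `sequence`, `length`, `assigned_class` (or
#'   `"unannotated"`), `family` (class-prefixed label or `NA`), `loci`
#'   (data.frame of 0-based half-open coordinates, restricted to the winning
#'   class), `multimapped` and `ambiguous` flags.
#' @export
annotate_species <- function(sequence, refs, precedence = DEFAULT_PRECEDENCE) {
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 15L, nchar(sequence) <= 45L)
  if (!all(precedence %in% SNC_CLASSES)) stop("unknown class in precedence")
  loci <- find_loci(sequence, refs)
  cls <- precedence[precedence %in% loci$class][1]
  if (is.na(cls) || !length(cls)) {
    return(list(sequence = sequence, length = nchar(sequence),
                assigned_class = "unannotated", family = NA_character_,
                loci = loci[0, ], multimapped = FALSE, ambiguous = FALSE))
  }
  win <- loci[loci$class == cls, , drop = FALSE]
  fams <- sort(unique(win$family))
  list(sequence = sequence, length = nchar(sequence),
       assigned_class = cls,
       family = family_label(cls, fams[1]),
       loci = win, multimapped = nrow(win) > 1L,
       ambiguous = length(fams) > 1L)
}

#' Annotate a table of species
#'
#' Vectorised driver over [annotate_species()] semantics; returns a species
#' table plus the per-species loci of the winning class.
#'
#' @param reads data.frame with `sequence` (unique) and optionally counts.
#' @param refs Parental reference table.
#' @param precedence Class precedence list.
#' @return list(`species` = data.frame(sequence, length, class, family,
#'   n_loci, multimapped, ambiguous), `loci` = data.frame(sequence, parent_id,
#'   start, end)).
#' @export
annotate_reads <- function(reads, refs, precedence = DEFAULT_PRECEDENCE) {
  if (anyDuplicated(reads$sequence)) stop("species sequences must be unique")
  ann <- lapply(reads$sequence, annotate_species, refs = refs, precedence = precedence)
  species <- data.frame(
    sequence = reads$sequence,
    length = nchar(reads$sequence),
    class = vapply(ann, `[[`, "", "assigned_class"),
    family = vapply(ann, `[[`, NA_character_, "family"),
    n_loci = vapply(ann, function(a) nrow(a$loci), 0L),
    multimapped = vapply(ann, `[[`, FALSE, "multimapped"),
    ambiguous = vapply(ann, `[[`, FALSE, "ambiguous"))
  loci <- do.call(rbind, lapply(ann, function(a) {
    if (!nrow(a$loci)) return(NULL)
    cbind(sequence = a$sequence, a$loci[, c("parent_id", "start", "end")])
  }))
  if (is.null(loci)) {
    loci <- data.frame(sequence = character(), parent_id = character(),
                       start = integer(), end = integer())
  }
  rownames(loci) <- NULL
  list(species = species, loci = loci)
}

#' Aggregate annotated species to family-level RPM
#'
#' Family expression = sum of its species counts x 1e6 / denominator, where
#' the denominator is the per-sample total of retained reads
#' (`retained_total`, default) or of annotated reads (`annotated_total`).
#' Multi-locus species contribute their full count once to their assigned
#' family (never once per locus). Class totals pool the fragment classes
#' (tsRNA = genomic + mitochondrial tRNA fragments, rsRNA, ysRNA, miRNA).
#'
#' @param species Species table from [annotate_reads()].
#' @param counts Species x samples integer count matrix (rownames =
#'   sequences).
#' @param denominator_policy `"retained_total"` or `"annotated_total"`.
#' @return list(`family_rpm` families x samples matrix, `class_rpm` fragment
#'   classes x samples, `class_counts` integer read counts per fragment class,
#'   `denominator` per-sample totals).
#' @export
aggregate_families <- function(species, counts,
                               denominator_policy = c("retained_total", "annotated_total")) {
  denominator_policy <- match.arg(denominator_policy)
  stopifnot(all(species$sequence %in% rownames(counts)))
  counts <- counts[species$sequence, , drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  annotated <- species$class != "unannotated"
  denom <- if (denominator_policy == "retained_total") colSums(counts)
           else colSums(counts[annotated, , drop = FALSE])
  if (any(denom == 0)) {
    stop("zero denominator for sample(s): ",
         paste(colnames(counts)[denom == 0], collapse = ", "))
  }
  fam_counts <- rowsum(counts[annotated, , drop = FALSE], species$family[annotated])
  family_rpm <- sweep(fam_counts, 2, denom, "/") * 1e6
  fclass <- fragment_class(species$class[annotated])
  class_counts <- rowsum(counts[annotated, , drop = FALSE], fclass)
  # fragment classes with no species at all appear as zero rows
  missing <- setdiff(SNC_FRAGMENT_CLASSES, rownames(class_counts))
  if (length(missing)) {
    class_counts <- rbind(class_counts,
                          matrix(0L, length(missing), ncol(counts),
                                 dimnames = list(missing, colnames(counts))))
  }
  class_counts <- class_counts[SNC_FRAGMENT_CLASSES, , drop = FALSE]
  class_rpm <- sweep(class_counts, 2, denom, "/") * 1e6
  list(family_rpm = family_rpm, class_rpm = class_rpm,
       class_counts = class_counts, denominator = denom)
}

#' Annotate a directory of per-sample collapsed FASTA files
#'
#' Reads every sample named in the metadata, applies the length filter,
#' annotates the union of species once, and assembles the species x samples
#' count matrix.
#'
#' @param dir Directory holding `<sample_id>.fa` collapsed FASTA files.
#' @param metadata Sample metadata (`sample_id`, ...).
#' @param refs Parental reference table.
#' @param precedence Class precedence list.
#' @param min_len,max_len Length filter bounds.
#' @return list(`species`, `loci`, `counts`) as in [annotate_reads()] plus the
#'   count matrix.
#' @export
annotate_sample_dir <- function(dir, metadata, refs,
                                precedence = DEFAULT_PRECEDENCE,
                                min_len = 15L, max_len = 45L) {
  per_sample <- lapply(metadata$sample_id, function(sid) {
    f <- file.path(dir, paste0(sid, ".fa"))
    if (!file.exists(f)) stop("missing collapsed FASTA for sample ", sid)
    filter_reads(read_collapsed_fasta(f), min_len, max_len)
  })
  seqs <- sort(unique(unlist(lapply(per_sample, `[[`, "sequence"))))
  counts <- matrix(0L, length(seqs), nrow(metadata),
                   dimnames = list(seqs, metadata$sample_id))
  for (j in seq_along(per_sample)) {
    counts[per_sample[[j]]$sequence, j] <- as.integer(per_sample[[j]]$count)
  }
  ann <- annotate_reads(data.frame(sequence = seqs), refs, precedence)
  c(ann, list(counts = counts))
}
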