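# File formats: reference FASTA with `>{class}|{parent_id}|{family}` headers,
# collapsed-read FASTA with `>{read_id}_x{count}` headers, metadata TSV, GMT.

#' Write parental references to FASTA
#'
#' Headers follow the grammar `>{class}|{parent_id}|{family}`.
#'
#' @param refs Reference table (`parent_id`, `class`, `family`, `sequence`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  seqs <- Biostrings::DNAStringSet(refs$sequence)
  names(seqs) <- paste(refs$class, refs$parent_id, refs$family, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read parental references from FASTA
#'
#' @param path FASTA file with `>{class}|{parent_id}|{family}` headers.
#' @return data.frame with `parent_id`, `class`, `family`, `sequence`.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed reference header (need class|parent_id|family): ",
         names(seqs)[bad[1]])
  }
  refs <- data.frame(
    parent_id = vapply(parts, `[`, "", 2L),
    class = vapply(parts, `[`, "", 1L),
    family = vapply(parts, `[`, "", 3L),
    sequence = as.character(seqs)
  )
  validate_references(refs)
  refs
}

#' Validate a parental reference table
#'
#' Enforces the reference invariants: unique parent ids, A/C/G/T alphabet,
#' known classes, nonempty sequences, nuclear tRNAs ending in CCA (mature
#' convention).
#'
#' @param refs Reference data.frame.
#' @return `refs`, invisibly.
#' @export
validate_references <- function(refs) {
  stopifnot(all(c("parent_id", "class", "family", "sequence") %in% names(refs)))
  if (anyDuplicated(refs$parent_id)) stop("duplicated parent_id in references")
  if (!all(refs$class %in% SNC_CLASSES)) {
    stop("unknown reference class: ",
         paste(setdiff(unique(refs$class), SNC_CLASSES), collapse = ", "))
  }
  if (any(nchar(refs$sequence) == 0)) stop("empty reference sequence")
  if (any(grepl("[^ACGT]", refs$sequence))) {
    stop("reference sequences must use the A/C/G/T alphabet only")
  }
  nuc <- refs$sequence[refs$class == "GtRNA"]
  if (length(nuc) && !all(endsWith(nuc, "CCA"))) {
    stop("nuclear tRNA references must end in CCA (mature convention)")
  }
  invisible(refs)
}

#' Write collapsed reads to FASTA
#'
#' One record per unique sequence; header `>{read_id}_x{count}`.
#'
#' @param reads data.frame with `sequence` and integer `count`.
#' @param path Output path.
#' @param prefix Read-id prefix.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path, prefix = "read") {
  stopifnot(all(reads$count == round(reads$count)), all(reads$count > 0))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- sprintf("%s%06d_x%d", prefix, seq_len(nrow(reads)), as.integer(reads$count))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read collapsed reads from FASTA
#'
#' @param path Collapsed FASTA; multiplicities parsed from the trailing
#'   `_x{count}` of each header.
#' @return data.frame with `sequence` and `count` (duplicated sequences are
#'   merged by summing counts).
#' @export
read_collapsed_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  m <- regmatches(names(seqs), regexpr("_x([0-9]+)$", names(seqs)))
  if (length(m) != length(seqs)) {
    stop("collapsed FASTA headers must end in _x{count}: ", path)
  }
  count <- as.integer(sub("^_x", "", m))
  df <- data.frame(sequence = as.character(seqs), count = count)
  if (anyDuplicated(df$sequence)) {
    agg <- rowsum(df$count, df$sequence)
    df <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]))
  }
  df
}

#' Read sample metadata TSV
#'
#' @param path TSV with columns `sample_id, group, age, sex, cohort`.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_metadata(md)
  md
}

#' Write sample metadata TSV
#' @param metadata Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>gene...`.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicated gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), sets, description)
  writeLines(lines, path)
  invisible(path)
}

#' Write a numeric matrix as TSV with a leading id column
#' @param mat Matrix with rownames.
#' @param path Output path.
#' @param id_name Name for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param path TSV path; first column is taken as rownames.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}
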