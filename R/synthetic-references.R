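# Synthetic parental-reference generator. Emulates the category structure of a
# blood small-RNA reference set: nuclear tRNAs labelled by anticodon family
# (mature, 3' CCA), the 22 mitochondrial tRNAs, rRNAs, Y RNAs and miRNA
# hairpins.

# The 22 human mitochondrial tRNA anticodon families.
MITO_TRNA_FAMILIES <- c(
  "Ala-TGC", "Arg-TCG", "Asn-GTT", "Asp-GTC", "Cys-GCA", "Gln-TTG",
  "Glu-TTC", "Gly-TCC", "His-GTG", "Ile-GAT", "Leu-TAA", "Leu-TAG",
  "Lys-TTT", "Met-CAT", "Phe-GAA", "Pro-TGG", "Ser-GCT", "Ser-TGA",
  "Thr-TGT", "Trp-TCA", "Tyr-GTA", "Val-TAC")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

# All sense-codon anticodon families (AA3-anticodon), sorted; the nuclear tRNA
# generator takes the first n.
nuclear_trna_families <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  anticodon <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(names(sense))))
  fam <- paste0(AA3[sense], "-", anticodon)
  fam <- sort(fam)
  if (n > length(fam)) stop("at most ", length(fam), " nuclear tRNA anticodon families")
  fam[seq_len(n)]
}

RRNA_LABELS <- c("12S", "16S", "5S", "5.8S", "18S", "28S", "45S", "ETS")
YRNA_LABELS <- c("RNY1", "RNY3", "RNY4", "RNY5")

#' Configuration for synthetic parental references
#'
#' Defaults mirror the category structure of human blood small-RNA profiling:
#' 48 nuclear (genomic) tRNA anticodon families, the 22 mitochondrial tRNAs,
#' 8 rRNAs and 4 Y RNAs, plus miRNA hairpins.
#'
#' @param n_nuclear_trna_families,n_mito_trna_families,n_rrna,n_yrna,n_mirna
#'   Number of parental references per class.
#' @param trna_length_range,rrna_length_range,yrna_length_range,mirna_length_range
#'   Sequence-length intervals in nt, each within \[50, 2000\].
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#' @return A `reference_config` list.
#' @export
reference_config <- function(n_nuclear_trna_families = 48L,
                             n_mito_trna_families = 22L,
                             n_rrna = 8L, n_yrna = 4L, n_mirna = 50L,
                             trna_length_range = c(70L, 90L),
                             rrna_length_range = c(150L, 600L),
                             yrna_length_range = c(83L, 113L),
                             mirna_length_range = c(60L, 80L),
                             seed = 1L) {
  cfg <- list(n_nuclear_trna_families = as.integer(n_nuclear_trna_families),
              n_mito_trna_families = as.integer(n_mito_trna_families),
              n_rrna = as.integer(n_rrna), n_yrna = as.integer(n_yrna),
              n_mirna = as.integer(n_mirna),
              trna_length_range = as.integer(trna_length_range),
              rrna_length_range = as.integer(rrna_length_range),
              yrna_length_range = as.integer(yrna_length_range),
              mirna_length_range = as.integer(mirna_length_range),
              seed = as.integer(seed))
  counts <- unlist(cfg[1:5])
  if (any(counts < 0)) stop("reference counts must be >= 0")
  if (sum(counts[c("n_nuclear_trna_families", "n_rrna")]) < 1) {
    stop("at least one tRNA or rRNA reference is required")
  }
  for (rng in cfg[6:9]) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 50 || rng[2] > 2000) {
      stop("length ranges must be increasing intervals within [50, 2000] nt")
    }
  }
  class(cfg) <- "reference_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic parental references
#'
#' Draws random A/C/G/T sequences for each parental class. Nuclear tRNAs end in
#' the mature 3' CCA; mitochondrial tRNAs carry the 22 human mt-tRNA anticodon
#' labels; rRNA labels follow the usual subunit names (12S, 16S, 5S, ...); Y RNAs
#' are RNY1/RNY3/RNY4/RNY5. Rejection sampling guarantees that no parental
#' sequence is a substring of another (a hard error names the colliding pair
#' after 1000 failed attempts).
#'
#' @param config A [reference_config()].
#' @return data.frame with `parent_id`, `class`, `family`, `sequence`;
#'   deterministic for a fixed `config$seed`.
#' @export
generate_references <- function(config = reference_config()) {
  stopifnot(inherits(config, "reference_config"))
  local_seed(config$seed, {
    plan <- rbind(
      if (config$n_nuclear_trna_families)
        data.frame(class = "GtRNA",
                   family = nuclear_trna_families(config$n_nuclear_trna_families),
                   lo = config$trna_length_range[1], hi = config$trna_length_range[2]),
      if (config$n_mito_trna_families) {
        fam <- if (config$n_mito_trna_families <= 22L) {
          MITO_TRNA_FAMILIES[seq_len(config$n_mito_trna_families)]
        } else stop("at most 22 mitochondrial tRNA families")
        data.frame(class = "MtRNA", family = fam,
                   lo = config$trna_length_range[1], hi = config$trna_length_range[2])
      },
      if (config$n_rrna) {
        fam <- if (config$n_rrna <= length(RRNA_LABELS)) RRNA_LABELS[seq_len(config$n_rrna)]
               else c(RRNA_LABELS, paste0("rRNA", seq_len(config$n_rrna - length(RRNA_LABELS))))
        data.frame(class = "rRNA", family = fam,
                   lo = config$rrna_length_range[1], hi = config$rrna_length_range[2])
      },
      if (config$n_yrna) {
        fam <- if (config$n_yrna <= 4L) YRNA_LABELS[seq_len(config$n_yrna)]
               else c(YRNA_LABELS, paste0("RNY", 5L + seq_len(config$n_yrna - 4L)))
        data.frame(class = "YRNA", family = fam,
                   lo = config$yrna_length_range[1], hi = config$yrna_length_range[2])
      },
      if (config$n_mirna)
        data.frame(class = "miRNA", family = sprintf("miR-%d", 100L + seq_len(config$n_mirna)),
                   lo = config$mirna_length_range[1], hi = config$mirna_length_range[2])
    )
    seqs <- character(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      len <- sample(plan$lo[i]:plan$hi[i], 1L)
      ok <- FALSE
      for (try in seq_len(1000L)) {
        s <- random_dna(len)
        if (plan$class[i] == "GtRNA") s <- paste0(substr(s, 1, len - 3L), "CCA")
        prev <- seqs[seq_len(i - 1L)]
        clash <- any(vapply(prev, function(p) {
          grepl(s, p, fixed = TRUE) || grepl(p, s, fixed = TRUE)
        }, logical(1)))
        if (!clash) { seqs[i] <- s; ok <- TRUE; break }
      }
      if (!ok) {
        j <- which(vapply(seqs[seq_len(i - 1L)], function(p)
          grepl(s, p, fixed = TRUE) || grepl(p, s, fixed = TRUE), logical(1)))[1]
        stop("substring containment could not be avoided between references ",
             plan$family[i], " and ", plan$family[j], " after 1000 attempts")
      }
    }
    refs <- data.frame(parent_id = paste0(plan$class, "-", plan$family),
                       class = plan$class, family = plan$family, sequence = seqs)
    validate_references(refs)
    refs
  })
}
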