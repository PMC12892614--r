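# Shared fixtures. Hand-built micro-references with known substring structure,
# and small synthetic cohorts reused across test files (generated once per
# test run).

# Seven tiny parental references with frozen aperiodic sequences: the 20-mer
# "probe" occurs exactly once in GtRNA tB and once in rRNA r1 (precedence
# checks); "ambseq" occurs exactly once in GtRNA tA and once in GtRNA tC
# (within-class family ambiguity). No other 15-mer is shared anywhere.
tiny_refs <- function() {
  data.frame(
    parent_id = c("tA", "tB", "tC", "mt1", "r1", "y1", "mir1"),
    class = c("GtRNA", "GtRNA", "GtRNA", "MtRNA", "rRNA", "YRNA", "miRNA"),
    family = c("Ala-AGC", "Arg-ACG", "Gly-GCC", "His-GTG", "12S", "RNY3", "miR-101"),
    sequence = c(
      "TTGACCGGTTAACCGGATCCGGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACCCA",
      "TCGTCACAACGTCCGGGAGCTAGCACGTACGTTGCAACGGTCCAGTCGACGGCGAGCAGTTGAATTTGGAGAACCCA",
      "CTATGGGAACCGTTATTGAATTTCTAATTTGTCTTGACCGGTTAACCGGATCCCAGAACAGAGAGATGCCTGGACCA",
      "GATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATAGAAATAAAGAGTCTAAGTACGTCT",
      paste0("TCCCAGTGATCATCATTTATGCTCTACGTGGGCAGAGTGCCATATGTACTGTCTGTGCGT",
             "ACGTACGTTGCAACGGTCCAACTTACCGCACTTACCTCCAGCGCTCTACCCAAGGATCTT",
             "TGTCTATTGGTGTCCAAAGAACTTAGTGGC"),
      "GGCGGCCCTAGTCTCAGTACGTCTCGGGCCGCACAAGGAGCCTAACAACCTCCGCAGAGAATTATCCTGCGCAGTCCACAGACTA",
      "GTACGGTCTGCGGCTAGTTATCCTCCGAGGGAGCACTGGAGCTGGGTGACCTTCTTACGGCTACTCAC"),
    stringsAsFactors = FALSE)
}

tiny_probe <- function() "ACGTACGTTGCAACGGTCCA"
tiny_ambseq <- function() "TTGACCGGTTAACCGGATCC"

# Small fast cohort for unit tests: reduced groups and library sizes.
small_cohort_config <- function(group_sizes = c(HC = 8L, SC = 8L, UC = 8L, CD = 8L),
                                library_size_range = c(20000L, 30000L),
                                n_noise_species = 10L, ...) {
  cohort_config(group_sizes = group_sizes, library_size_range = library_size_range,
                n_noise_species = n_noise_species, ...)
}

small_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_references(reference_config(
        n_nuclear_trna_families = 10L, n_mito_trna_families = 4L,
        n_rrna = 4L, n_yrna = 4L, n_mirna = 8L, seed = 42L))
    }
    cache
  }
})

# Independent brute-force substring scanner (Biostrings route) used as the
# annotation oracle.
oracle_loci <- function(sequence, refs) {
  hits <- lapply(seq_len(nrow(refs)), function(i) {
    m <- Biostrings::matchPattern(sequence, Biostrings::DNAString(refs$sequence[i]))
    if (!length(m)) return(NULL)
    data.frame(parent_id = refs$parent_id[i], class = refs$class[i],
               start = Biostrings::start(m) - 1L, end = Biostrings::end(m))
  })
  do.call(rbind, hits)
}

# Exhaustive concordant-pair AUC oracle.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Small but complete pipeline configuration for end-to-end runs.
fast_pipeline_config <- function(seed = 1L, ...) {
  pipeline_config(
    reference_config = reference_config(
      n_nuclear_trna_families = 8L, n_mito_trna_families = 4L, n_rrna = 4L,
      n_yrna = 4L, n_mirna = 6L),
    cohort_config_a = cohort_config(
      group_sizes = c(HC = 8L, SC = 8L, UC = 8L, CD = 8L),
      library_size_range = c(15000L, 20000L), n_noise_species = 5L,
      effect_families = data.frame(
        family = c("GtsRNA-Ala-AGC", "rsRNA-12S", "ysRNA-RNY1"),
        log2fc = 1.2, groups = "UC,CD")),
    cohort_config_b = cohort_config(
      group_sizes = c(HC = 8L, UC = 8L), mirna_cohort_shift_sd = 0.5,
      library_size_range = c(15000L, 20000L), n_noise_species = 5L,
      cohort = "cohortB"),
    gene_config = gene_config(n_genes = 40L, n_pos = 6L, n_neg = 6L,
                              n_decoy_sets = 2L, decoy_set_size = 8L),
    cv_rounds = 2L, alpha = 0.3, min_coexpr_families = 5L,
    seed = seed, ...)
}

# Metadata builder for model tests.
toy_metadata <- function(n_per_group, groups = c("HC", "UC"), seed = 1) {
  set.seed(seed)
  n <- n_per_group * length(groups)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             group = rep(groups, each = n_per_group),
             age = round(runif(n, 20, 75), 1),
             sex = sample(c("F", "M"), n, replace = TRUE),
             cohort = "toy")
}
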