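# Canned simulation scenarios: the fixed study conditions under which the
# pipeline's statistical properties (signature recovery, CV calibration,
# co-expression recovery, cohort-divergence detection) are evaluated. Group
# sizes mirror a treatment-naive IBD cohort (30 HC / 65 SC / 58 UC / 52 CD);
# scenario-specific reference sets scale the family universe where a property
# needs it (300 families for the multiple-testing burden of signature
# discovery, >= 100 families per class for distribution comparisons).

#' Signature-recovery scenario
#'
#' A 300-family cohort (the default noncanonical reference set plus miRNAs up
#' to 300 families) with the standard group sizes 30/65/58/52. When `planted`,
#' `n_planted` noncanonical families carry a common UC/CD upregulation of
#' `effect_sd` residual SDs (see [effect_for_sd()]); otherwise the generator
#' is null. Latent loadings are zero here so the planted group effect is the
#' only structured signal.
#'
#' @param seed Integer seed.
#' @param planted Plant the common-up families (`FALSE` for the null).
#' @param n_planted Number of planted families.
#' @param effect_sd Effect size in residual-SD units.
#' @param refs Optional pre-generated references (they are deterministic given
#'   `ref_seed`, so passing them just avoids regeneration in replicate loops).
#' @param ref_seed Seed of the reference set.
#' @return list(`cohort`, `family_rpm` (all 300 families), `planted` family
#'   labels, `refs`).
#' @export
simulate_signature_cohort <- function(seed, planted = TRUE, n_planted = 20L,
                                      effect_sd = 1.5, refs = NULL,
                                      ref_seed = 20240101L) {
  if (is.null(refs)) {
    refs <- generate_references(reference_config(n_mirna = 218L, seed = ref_seed))
  }
  nc <- refs$class != "miRNA"
  nc_fams <- family_label(refs$class[nc], refs$family[nc])
  eff <- NULL
  chosen <- character()
  if (planted) {
    chosen <- local_seed(seed + 1L, sample(nc_fams, n_planted))
    eff <- data.frame(family = chosen,
                      log2fc = effect_for_sd(effect_sd, 10),
                      groups = "UC,CD")
  }
  cohort <- generate_cohort(refs, cohort_config(
    group_sizes = c(HC = 30L, SC = 65L, UC = 58L, CD = 52L),
    library_size_range = c(100000L, 200000L),
    effect_families = eff, noise_fraction = 0, n_noise_species = 0L,
    seed = seed))
  list(cohort = cohort, family_rpm = family_matrix_from_cohort(cohort),
       planted = chosen, refs = refs)
}

#' Co-expression recovery scenario
#'
#' Standard group sizes; 40 of the 82 noncanonical families carry a latent
#' loading of 0.6 log2 units per latent SD (a loading on every family would
#' cancel under the compositional RPM normalisation), and the gene matrix
#' holds 15 positively and 15 negatively loaded genes at a loading of twice
#' the expression noise SD, plus 500 unloaded decoy genes.
#'
#' @param seed Integer seed.
#' @return list(`cohort`, `family_log` (log2(RPM+1), noncanonical only),
#'   `genes` (list from [generate_gene_matrix()])).
#' @export
simulate_coexpression_study <- function(seed) {
  refs <- generate_references(reference_config(seed = 20240102L))
  nc <- refs$class != "miRNA"
  nc_fams <- family_label(refs$class[nc], refs$family[nc])
  loaded <- local_seed(20240104L, sample(nc_fams, 40L))
  cohort <- generate_cohort(refs, cohort_config(
    group_sizes = c(HC = 30L, SC = 65L, UC = 58L, CD = 52L),
    library_size_range = c(100000L, 200000L),
    latent_loadings = stats::setNames(rep(0.6, length(loaded)), loaded),
    noise_fraction = 0, n_noise_species = 0L, seed = seed))
  genes <- generate_gene_matrix(cohort, gene_config(
    n_genes = 530L, n_pos = 15L, n_neg = 15L, loading = 2, noise_sd = 1,
    seed = seed + 7L))
  fam_log <- log2(family_matrix_from_cohort(cohort) + 1)
  list(cohort = cohort,
       family_log = fam_log[rownames(fam_log) %in% nc_fams, , drop = FALSE],
       genes = genes)
}

#' Cohort-divergence scenario
#'
#' Two cohorts of healthy controls over a reference set with at least 100
#' families per class (100 noncanonical: 60 nuclear tRNA + 22 mito + 14 rRNA
#' + 4 Y RNA; 120 miRNA). Cohort B applies a per-miRNA baseline shift of
#' `shift_sd` log2 units; noncanonical families are never shifted.
#'
#' @param seed Integer seed.
#' @param shift_sd SD of the per-miRNA cohort shift (log2).
#' @param refs Optional pre-generated references (see
#'   [simulate_signature_cohort()]).
#' @param ref_seed Seed of the reference set.
#' @return list(`rpm_a`, `rpm_b`, `metadata_a`, `metadata_b`, `refs`).
#' @export
simulate_divergence_pair <- function(seed, shift_sd = 0.5, refs = NULL,
                                     ref_seed = 20240103L) {
  if (is.null(refs)) {
    refs <- generate_references(reference_config(
      n_nuclear_trna_families = 60L, n_mito_trna_families = 22L,
      n_rrna = 14L, n_yrna = 4L, n_mirna = 120L, seed = ref_seed))
  }
  base <- function(shift, cohort, s) cohort_config(
    group_sizes = c(HC = 30L, UC = 2L),
    library_size_range = c(50000L, 80000L),
    mirna_cohort_shift_sd = shift, cohort = cohort,
    noise_fraction = 0, n_noise_species = 0L, seed = s)
  a <- generate_cohort(refs, base(0, "cohortA", seed))
  b <- generate_cohort(refs, base(shift_sd, "cohortB", seed + 1L))
  list(rpm_a = family_matrix_from_cohort(a), rpm_b = family_matrix_from_cohort(b),
       metadata_a = a$metadata, metadata_b = b$metadata, refs = refs)
}
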