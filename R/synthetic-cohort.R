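# Synthetic cohort generator. Emulates a four-group blood small-RNA cohort
# (healthy controls, symptomatic controls, UC, CD) with age/sex covariates,
# planted group effects on chosen fragment families, a single latent factor
# coupling noncanonical fragment abundance to a gene module, class-specific
# read-length peaks via cleavage hotspots, and an optional cohort-specific
# baseline shift applied to miRNAs only.

# Default fragment-length peaks per parental class; these reproduce the
# multi-peak length distributions seen in blood (tRNA fragments at 17/22 nt,
# Y RNA fragments at 27/32 nt, rRNA fragments at 15/17/23/26/33 nt).
CLASS_LENGTH_PEAKS <- list(
  GtRNA = c(17L, 22L), MtRNA = c(17L, 22L),
  rRNA = c(15L, 17L, 23L, 26L, 33L),
  YRNA = c(27L, 32L), miRNA = 22L)

#' Configuration for a synthetic cohort
#'
#' Defaults emulate a treatment-naive IBD cohort design: 30 healthy controls
#' (HC), 65 symptomatic controls (SC), 58 UC and 52 CD patients, with age and
#' sex covariates and overdispersed counts.
#'
#' @param group_sizes Named counts for the groups HC/SC/UC/CD (each >= 2; set a
#'   group to 0 to omit it).
#' @param library_size_range Interval of per-sample totals (reads), >= 10000.
#' @param effect_families data.frame(`family`, `log2fc`, `groups`) of planted
#'   group effects; `groups` is a comma-separated subset of the group names.
#'   `NULL` for the null generator.
#' @param sc_effect_fraction Fraction of each planted UC/CD effect that is also
#'   applied to the SC group (the symptomatic-control attenuation); ignored for
#'   effects whose `groups` already name SC.
#' @param age_slope_log2 Additive log2-abundance slope per year of age
#'   (centred at 49 y), applied to noncanonical families.
#' @param sex_log2 Additive log2 offset for male samples (female = reference),
#'   applied to noncanonical families.
#' @param latent_loadings Named numeric vector of per-family latent-factor
#'   loadings (log2 units per latent SD); families not named get 0. `NULL`
#'   disables the latent factor.
#' @param latent_group_shift Named numeric vector of per-group shifts of the
#'   latent-score mean (e.g. `c(UC = 1)`); used to couple disease state to the
#'   latent gene module.
#' @param mirna_cohort_shift_sd SD (log2) of the per-miRNA-family
#'   cohort-specific baseline offset; 0 disables it. Noncanonical families are
#'   never shifted.
#' @param hotspots_per_parent Number of cleavage hotspots drawn per parental
#'   RNA (miRNA parents always get exactly one mature-arm hotspot).
#' @param dispersion Gamma shape of the count model; the per-species
#'   coefficient of variation is about `1/sqrt(dispersion)`.
#' @param noise_fraction Fraction of the library emitted as unannotatable
#'   random reads (species matching no reference).
#' @param n_noise_species Number of distinct unannotatable species.
#' @param cohort Cohort label written into the metadata.
#' @param seed Integer seed for the cohort draw (samples, counts, covariates).
#' @param structure_seed Integer seed for the biological structure shared
#'   between cohorts - cleavage hotspots and per-family abundance weights.
#'   Two cohorts generated from the same references with the same
#'   `structure_seed` (the default) profile the same species universe with the
#'   same baseline abundances, as two sequencing cohorts of one organism
#'   would.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(HC = 30L, SC = 65L, UC = 58L, CD = 52L),
                          library_size_range = c(100000L, 200000L),
                          effect_families = NULL,
                          sc_effect_fraction = 0.5,
                          age_slope_log2 = 0.004,
                          sex_log2 = 0.08,
                          latent_loadings = NULL,
                          latent_group_shift = NULL,
                          mirna_cohort_shift_sd = 0,
                          hotspots_per_parent = 3L,
                          dispersion = 10,
                          noise_fraction = 0.02,
                          n_noise_species = 50L,
                          cohort = "cohortA",
                          seed = 1L,
                          structure_seed = 20240201L) {
  group_sizes <- unlist(group_sizes)
  group_sizes <- group_sizes[group_sizes > 0]
  if (length(group_sizes) < 2) stop("need at least two nonempty groups")
  if (any(group_sizes < 2)) stop("each group must have >= 2 samples")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% SNC_GROUPS)) {
    stop("group_sizes must be named with groups among ", paste(SNC_GROUPS, collapse = "/"))
  }
  if (library_size_range[1] < 10000) stop("library sizes must be >= 10,000")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (noise_fraction < 0 || noise_fraction >= 1) stop("noise_fraction must be in [0, 1)")
  cfg <- list(group_sizes = group_sizes,
              library_size_range = as.integer(library_size_range),
              effect_families = effect_families,
              sc_effect_fraction = sc_effect_fraction,
              age_slope_log2 = age_slope_log2,
              sex_log2 = sex_log2,
              latent_loadings = latent_loadings,
              latent_group_shift = latent_group_shift,
              mirna_cohort_shift_sd = mirna_cohort_shift_sd,
              hotspots_per_parent = as.integer(hotspots_per_parent),
              dispersion = dispersion,
              noise_fraction = noise_fraction,
              n_noise_species = as.integer(n_noise_species),
              cohort = cohort,
              seed = as.integer(seed),
              structure_seed = as.integer(structure_seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Log2 effect size equivalent to a residual-SD multiple
#'
#' The count model's dominant residual term is the Gamma mixing noise, with
#' coefficient of variation `1/sqrt(dispersion)` on the expression scale. The
#' log2 fold change whose induced mean shift equals `k` residual SDs is
#' therefore `log2(1 + k/sqrt(dispersion))`.
#'
#' @param k Effect size in residual-SD units.
#' @param dispersion Gamma shape of the count model.
#' @return log2 fold change.
#' @export
effect_for_sd <- function(k, dispersion) log2(1 + k / sqrt(dispersion))

# Draw cleavage hotspots for every parental RNA: (start, length, weight) with
# weights summing to 1 per parent. Lengths come from the class's peak set;
# miRNA parents get a single 22-nt mature-arm species.
draw_hotspots <- function(refs, hotspots_per_parent) {
  out <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    L <- nchar(refs$sequence[i])
    cls <- refs$class[i]
    peaks <- CLASS_LENGTH_PEAKS[[cls]]
    k <- if (cls == "miRNA") 1L else hotspots_per_parent
    lens <- peaks[1L + (seq_len(k) - 1L) %% length(peaks)]
    starts <- integer(k)
    for (j in seq_len(k)) {
      if (cls %in% c("GtRNA", "MtRNA") && j == 2L) {
        starts[j] <- L - lens[j]        # 3'-end fragment (covers the CCA tail)
      } else if (j == 1L) {
        starts[j] <- 0L                 # 5'-end fragment
      } else {
        starts[j] <- sample.int(L - lens[j] + 1L, 1L) - 1L
      }
    }
    w <- stats::rgamma(k, shape = 1)
    out[[i]] <- data.frame(parent_id = refs$parent_id[i], class = cls,
                           family = family_label(cls, refs$family[i]),
                           start = starts, length = lens, weight = w / sum(w))
  }
  do.call(rbind, out)
}

validate_hotspots <- function(hotspots, refs) {
  L <- stats::setNames(nchar(refs$sequence), refs$parent_id)
  bad <- hotspots$start < 0 | hotspots$start + hotspots$length > L[hotspots$parent_id]
  if (any(bad)) {
    stop("hotspot outside parental bounds for ",
         paste(unique(hotspots$parent_id[bad]), collapse = ", "))
  }
  ws <- tapply(hotspots$weight, hotspots$parent_id, sum)
  if (any(abs(ws - 1) > 1e-8)) stop("hotspot weights must sum to 1 per parental RNA")
  invisible(hotspots)
}

#' Generate a synthetic cohort of collapsed small-RNA reads
#'
#' Per-sample species counts follow a Gamma-Poisson (negative-binomial)
#' hierarchy conditioned on the drawn library size: each species' rate is
#' `library_size x family weight x hotspot weight x 2^(group effect +
#' covariate terms + latent term + cohort shift if miRNA)` perturbed by Gamma
#' mixing noise, and the per-sample counts are the multinomial allocation of
#' the library total to those rates. Species sequences are exact substrings of
#' the parental references at the hotspot loci; a configurable fraction of
#' unannotatable random species is added on top of the library total.
#'
#' @param refs Parental references from [generate_references()].
#' @param config A [cohort_config()].
#' @param hotspots Optional hotspot table (`parent_id`, `start`, `length`,
#'   `weight` summing to 1 per parent); drawn automatically when `NULL`.
#' @return A `snc_cohort` list: `counts` (species x samples integer matrix),
#'   `species` (sequence, class, family, loci, `is_noise`), `metadata`
#'   (sample_id, group, age, sex, cohort), `library_sizes` (annotatable totals,
#'   before noise reads), and `truth` (planted parameters: effects, latent
#'   scores and loadings, miRNA cohort shifts, family weights, seeds).
#' @export
generate_cohort <- function(refs, config = cohort_config(), hotspots = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  validate_references(refs)
  # biological structure - cleavage hotspots, the species universe and the
  # per-family baseline abundances - is drawn under `structure_seed` so that
  # cohorts sharing it profile the same biology
  structure <- local_seed(config$structure_seed, {
    if (is.null(hotspots)) hotspots <- draw_hotspots(refs, config$hotspots_per_parent)
    validate_hotspots(hotspots, refs)
    refseq <- stats::setNames(refs$sequence, refs$parent_id)
    species <- data.frame(
      sequence = substr(refseq[hotspots$parent_id], hotspots$start + 1L,
                        hotspots$start + hotspots$length),
      length = hotspots$length, class = hotspots$class, family = hotspots$family,
      parent_id = hotspots$parent_id, start = hotspots$start,
      end = hotspots$start + hotspots$length, weight = hotspots$weight,
      is_noise = FALSE)
    # distinct hotspots occasionally yield the same substring; keep one copy,
    # pooling the sampling weight (per parent)
    if (anyDuplicated(species$sequence)) {
      key <- species$sequence
      w <- tapply(species$weight, key, sum)
      keep <- !duplicated(key)
      species <- species[keep, ]
      species$weight <- as.numeric(w[species$sequence])
    }
    rownames(species) <- NULL
    fams <- unique(species$family)
    # per-family abundance weights (log-normal), shared across samples
    fam_w <- stats::setNames(stats::rlnorm(length(fams), meanlog = 0, sdlog = 1), fams)
    list(hotspots = hotspots, species = species, fams = fams, fam_w = fam_w)
  })
  hotspots <- structure$hotspots
  local_seed(config$seed, {
    species <- structure$species
    fams <- structure$fams
    fam_w <- structure$fam_w
    base_w <- fam_w[species$family] * species$weight

    # sample metadata
    md <- data.frame(
      sample_id = sprintf("%s_S%03d", config$cohort, seq_len(sum(config$group_sizes))),
      group = rep(names(config$group_sizes), config$group_sizes))
    n <- nrow(md)
    md$age <- round(stats::runif(n, 18, 80), 1)
    md$sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "M", "F")
    md$cohort <- config$cohort

    # planted log2 effect per species x sample
    eff <- matrix(0, nrow(species), n)
    ef <- config$effect_families
    if (!is.null(ef) && nrow(ef)) {
      unknown <- setdiff(ef$family, fams)
      if (length(unknown)) stop("effect families not generated: ",
                                paste(unknown, collapse = ", "))
      for (i in seq_len(nrow(ef))) {
        rows <- species$family == ef$family[i]
        gset <- strsplit(ef$groups[i], ",", fixed = TRUE)[[1]]
        eff[rows, md$group %in% gset] <- eff[rows, md$group %in% gset] + ef$log2fc[i]
        if (!("SC" %in% gset) && config$sc_effect_fraction != 0) {
          eff[rows, md$group == "SC"] <- eff[rows, md$group == "SC"] +
            config$sc_effect_fraction * ef$log2fc[i]
        }
      }
    }

    noncanon <- species$class != "miRNA"
    # age/sex covariates act on the noncanonical compartment (a multiplier on
    # every species cancels under RPM normalisation)
    eff[noncanon, ] <- eff[noncanon, ] +
      rep(config$age_slope_log2 * (md$age - 49), each = sum(noncanon)) +
      rep(config$sex_log2 * (md$sex == "M"), each = sum(noncanon))

    # latent factor
    latent <- stats::rnorm(n)
    if (!is.null(config$latent_group_shift)) {
      for (g in names(config$latent_group_shift)) {
        latent[md$group == g] <- latent[md$group == g] + config$latent_group_shift[[g]]
      }
    }
    loadings <- stats::setNames(numeric(length(fams)), fams)
    if (!is.null(config$latent_loadings)) {
      known <- intersect(names(config$latent_loadings), fams)
      loadings[known] <- config$latent_loadings[known]
      eff <- eff + outer(loadings[species$family], latent)
    }

    # cohort-specific baseline shift on miRNA families only
    mirna_fams <- unique(species$family[species$class == "miRNA"])
    mirna_shift <- stats::setNames(numeric(length(mirna_fams)), mirna_fams)
    if (config$mirna_cohort_shift_sd > 0 && length(mirna_fams)) {
      mirna_shift[] <- stats::rnorm(length(mirna_fams), 0, config$mirna_cohort_shift_sd)
      eff[!noncanon, ] <- eff[!noncanon, ] + mirna_shift[species$family[!noncanon]]
    }

    # Gamma mixing noise (NB overdispersion), then multinomial allocation of
    # the drawn library size
    G <- matrix(stats::rgamma(nrow(species) * n, shape = config$dispersion,
                              rate = config$dispersion), nrow(species), n)
    rates <- base_w * 2^eff * G
    lib <- sample(config$library_size_range[1]:config$library_size_range[2], n,
                  replace = TRUE)
    counts <- vapply(seq_len(n), function(j)
      stats::rmultinom(1, lib[j], rates[, j])[, 1], integer(nrow(species)))

    # unannotatable random species appended after the annotatable library
    if (config$noise_fraction > 0 && config$n_noise_species > 0) {
      noise_seq <- character(config$n_noise_species)
      for (i in seq_len(config$n_noise_species)) {
        repeat {
          s <- random_dna(sample(15:45, 1L))
          hit <- any(vapply(refs$sequence, grepl, logical(1), pattern = s,
                            fixed = TRUE)) || s %in% species$sequence ||
                 s %in% noise_seq
          if (!hit) { noise_seq[i] <- s; break }
        }
      }
      nw <- stats::rgamma(config$n_noise_species, 1)
      ncounts <- vapply(seq_len(n), function(j)
        stats::rmultinom(1, round(config$noise_fraction * lib[j]), nw)[, 1],
        integer(config$n_noise_species))
      noise_df <- data.frame(sequence = noise_seq, length = nchar(noise_seq),
                             class = "unannotated", family = NA_character_,
                             parent_id = NA_character_, start = NA_integer_,
                             end = NA_integer_, weight = 0, is_noise = TRUE)
      species <- rbind(species, noise_df)
      counts <- rbind(counts, ncounts)
    }
    rownames(counts) <- species$sequence
    colnames(counts) <- md$sample_id

    truth <- list(
      planted_up_families = if (!is.null(ef)) unique(ef$family[ef$log2fc > 0]) else character(),
      planted_effects = ef,
      latent_scores = stats::setNames(latent, md$sample_id),
      latent_loadings = loadings,
      mirna_cohort_shift = mirna_shift,
      family_weights = fam_w,
      hotspots = hotspots,
      seeds_used = config$seed)
    structure(list(counts = counts, species = species, metadata = md,
                   library_sizes = stats::setNames(lib, md$sample_id),
                   truth = truth, config = config),
              class = "snc_cohort")
  })
}

#' Family-level RPM matrix straight from a synthetic cohort's ground truth
#'
#' Aggregates the generator's species counts by their known family labels,
#' bypassing sequence matching. Used as the construction-side route in tests
#' and simulations; [aggregate_families()] recovers the same matrix through
#' actual annotation.
#'
#' @param cohort An `snc_cohort`.
#' @param denominator_policy `"retained_total"` (all retained reads, default)
#'   or `"annotated_total"`.
#' @return Families x samples RPM matrix with a `denominator` attribute.
#' @export
family_matrix_from_cohort <- function(cohort,
                                      denominator_policy = c("retained_total", "annotated_total")) {
  denominator_policy <- match.arg(denominator_policy)
  keep <- !cohort$species$is_noise
  denom <- if (denominator_policy == "retained_total") colSums(cohort$counts)
           else colSums(cohort$counts[keep, , drop = FALSE])
  fam <- rowsum(cohort$counts[keep, , drop = FALSE], cohort$species$family[keep])
  rpm <- sweep(fam, 2, denom, "/") * 1e6
  attr(rpm, "denominator") <- denom
  rpm
}

#' Write a synthetic cohort to disk
#'
#' One collapsed FASTA per sample (headers `>{read_id}_x{count}`), a metadata
#' TSV, and the reference FASTA if supplied.
#'
#' @param cohort An `snc_cohort`.
#' @param dir Output directory (created if needed).
#' @param refs Optional reference table to write alongside.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, refs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (j in seq_len(ncol(cohort$counts))) {
    keep <- cohort$counts[, j] > 0
    f <- file.path(dir, paste0(colnames(cohort$counts)[j], ".fa"))
    write_collapsed_fasta(
      data.frame(sequence = rownames(cohort$counts)[keep],
                 count = cohort$counts[keep, j]), f)
    files <- c(files, f)
  }
  mf <- file.path(dir, "metadata.tsv")
  write_metadata(cohort$metadata, mf)
  files <- c(files, mf)
  if (!is.null(refs)) {
    rf <- file.path(dir, "references.fa")
    write_reference_fasta(refs, rf)
    files <- c(files, rf)
  }
  invisible(files)
}
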