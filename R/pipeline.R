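# Configuration-driven orchestration of the full analysis. Stages run in
# dependency order (simulate -> annotate -> profile -> diff -> score -> cv ->
# coexpress -> diverge) and communicate only through their declared output
# files under the run directory. All randomness flows from one master seed
# via named substreams, so adding a stage never perturbs earlier streams. The
# run manifest (per-stage cache keys, output hashes, seeds, version) makes a
# run reproducible bit-exactly; with caching enabled, a rerun recomputes only
# the stages whose configuration or upstream outputs changed.

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_sorted <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Schema-validated configuration of [run_pipeline()]. In synthetic mode the
#' generator configs below are used; otherwise `reads_dir`, `reference_fasta`
#' and `metadata` must point to existing inputs. Every threshold defaults to
#' the package-wide values (length filter 15-45 nt, precedence with rRNA
#' last, retained-total RPM denominator, alpha 0.05, pseudocount 0.01 RPM,
#' 1000 rounds of 5-fold CV).
#'
#' @param synthetic Generate inputs with the synthetic-cohort module.
#' @param reads_dir,reference_fasta,metadata Paths for real-data mode.
#' @param gene_matrix,gene_sets Optional gene-expression TSV and GMT paths
#'   (real-data mode); their absence skips the co-expression stage.
#' @param second_cohort Synthetic mode: generate a second cohort for the
#'   divergence stage (`FALSE` skips that stage).
#' @param reference_config,cohort_config_a,cohort_config_b,gene_config
#'   Generator configurations for synthetic mode (their seeds are re-derived
#'   from the master seed).
#' @param alpha Significance level for the signature and co-expression calls.
#' @param eps Pseudocount in RPM for fold changes.
#' @param precedence Annotation class precedence.
#' @param denominator_policy RPM denominator policy.
#' @param min_len,max_len Retained read-length bounds (nt).
#' @param min_coexpr_families Gene filter: minimum significant families.
#' @param cv_k,cv_rounds CV folds and rounds.
#' @param baseline_population `"training"` or `"cohort"` (CV baseline mode).
#' @param seed Master seed; stage substreams are derived from it by name.
#' @param cache Skip stages whose inputs are unchanged since the last run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            reads_dir = NULL, reference_fasta = NULL,
                            metadata = NULL, gene_matrix = NULL,
                            gene_sets = NULL, second_cohort = TRUE,
                            reference_config = sncflow::reference_config(),
                            cohort_config_a = sncflow::cohort_config(),
                            cohort_config_b = sncflow::cohort_config(
                              mirna_cohort_shift_sd = 0.5, cohort = "cohortB"),
                            gene_config = sncflow::gene_config(),
                            alpha = 0.05, eps = 0.01,
                            precedence = DEFAULT_PRECEDENCE,
                            denominator_policy = "retained_total",
                            min_len = 15L, max_len = 45L,
                            min_coexpr_families = 20L,
                            cv_k = 5L, cv_rounds = 1000L,
                            baseline_population = "training",
                            seed = 1L, cache = FALSE) {
  cfg <- as.list(environment())
  if (!synthetic) {
    for (p in c("reads_dir", "reference_fasta", "metadata")) {
      if (is.null(cfg[[p]])) stop("non-synthetic mode requires `", p, "`")
      if (!file.exists(cfg[[p]])) stop("input does not exist: ", cfg[[p]])
    }
  }
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (eps <= 0) stop("eps must be > 0")
  if (!all(precedence %in% SNC_CLASSES)) stop("unknown class in precedence")
  if (!denominator_policy %in% c("retained_total", "annotated_total")) {
    stop("unknown denominator_policy")
  }
  if (min_len < 1 || max_len < min_len) stop("invalid length bounds")
  if (cv_k < 2 || cv_rounds < 1) stop("invalid CV settings")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the [pipeline_config()] defaults; generator
#' sub-configs may be given as lists of arguments to the respective
#' `*_config()` constructors.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sub <- list(reference_config = reference_config, cohort_config_a = cohort_config,
              cohort_config_b = cohort_config, gene_config = gene_config)
  for (nm in names(sub)) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- do.call(sub[[nm]], raw[[nm]])
  }
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

# Config fields each stage depends on; part of the stage cache key.
STAGE_CONFIG_FIELDS <- list(
  simulate = c("synthetic", "second_cohort", "reference_config",
               "cohort_config_a", "cohort_config_b", "gene_config", "seed"),
  annotate = c("synthetic", "reads_dir", "reference_fasta", "metadata",
               "precedence", "denominator_policy", "min_len", "max_len"),
  profile = c("eps"),
  diff = c("alpha"),
  score = c("alpha"),
  cv = c("alpha", "cv_k", "cv_rounds", "baseline_population", "seed"),
  coexpress = c("alpha", "min_coexpr_families", "gene_matrix", "gene_sets"),
  diverge = c("eps"))

STAGE_UPSTREAM <- list(
  simulate = character(), annotate = "simulate", profile = "annotate",
  diff = "annotate", score = "diff", cv = "annotate",
  coexpress = c("simulate", "annotate"), diverge = "annotate")

PIPELINE_STAGES <- names(STAGE_CONFIG_FIELDS)

# Fragment-family classification from the label prefix.
is_noncanonical_label <- function(x) grepl("^(GtsRNA|MtsRNA|rsRNA|ysRNA)-", x)

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order, writing every result as
#' TSV/JSON under `out_dir` together with `manifest.json` (package version,
#' master seed, per-stage cache keys and output MD5 hashes) and
#' `pipeline.log`. Stages read nothing but their upstream stages' declared
#' output files. Missing optional inputs (gene matrix, second cohort) cause
#' the dependent stages to be skipped with explicit log lines. With the same
#' configuration and master seed, the manifest is byte-identical across runs;
#' with `cache = TRUE`, stages whose cache key and outputs are unchanged are
#' not recomputed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Subset of `c("simulate", "annotate", "profile", "diff",
#'   "score", "cv", "coexpress", "diverge")`, or `"all"`.
#' @return The manifest, invisibly; its `computed` element names the stages
#'   actually recomputed in this run.
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  if (length(bad <- setdiff(stages, PIPELINE_STAGES))) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$log <- character()
  state$manifest <- list(package = "sncflow",
                         version = as.character(utils::packageVersion("sncflow")),
                         seed = config$seed, stages = list())
  state$computed <- character()
  mf_path <- file.path(out_dir, "manifest.json")
  prev <- if (config$cache && file.exists(mf_path)) {
    jsonlite::read_json(mf_path)
  } else NULL

  log_line <- function(level, ...) {
    line <- paste0("[", level, "] ", paste0(..., collapse = ""))
    state$log <- c(state$log, line)
    message(line)
  }
  record <- function(stage, key, outputs) {
    hashes <- tools::md5sum(file.path(out_dir, outputs))
    names(hashes) <- outputs
    state$manifest$stages[[stage]] <- list(
      key = key, outputs = as.list(hashes[order(names(hashes))]))
  }
  stage_key <- function(stage) {
    up <- unlist(lapply(STAGE_UPSTREAM[[stage]], function(s)
      unlist(state$manifest$stages[[s]]$outputs)))
    cfg_txt <- paste(deparse(config[STAGE_CONFIG_FIELDS[[stage]]]), collapse = "")
    md5_of(paste(stage, cfg_txt, paste(up, collapse = ","), sep = "\n"))
  }
  cache_hit <- function(stage, key) {
    if (is.null(prev)) return(FALSE)
    st <- prev$stages[[stage]]
    if (is.null(st) || !identical(st$key, key)) return(FALSE)
    files <- file.path(out_dir, names(st$outputs))
    all(file.exists(files)) &&
      identical(unname(tools::md5sum(files)), unlist(st$outputs, use.names = FALSE))
  }
  run_stage <- function(stage, fn) {
    key <- stage_key(stage)
    if (cache_hit(stage, key)) {
      log_line("INFO", stage, ": cached, outputs unchanged")
      state$manifest$stages[[stage]] <- prev$stages[[stage]]
      return(invisible())
    }
    outputs <- fn()
    if (is.null(outputs)) return(invisible())   # stage skipped
    state$computed <- c(state$computed, stage)
    record(stage, key, outputs)
  }
  out_file <- function(...) file.path(out_dir, ...)
  have <- function(...) all(file.exists(out_file(c(...))))

  # --- stage bodies ---------------------------------------------------------
  simulate_stage <- function() {
    if (!config$synthetic) {
      log_line("INFO", "simulate: skipped (non-synthetic mode)")
      return(NULL)
    }
    log_line("INFO", "simulate: generating references, cohort(s), gene matrix")
    rc <- config$reference_config
    rc$seed <- substream_seed(config$seed, "references")
    refs <- generate_references(rc)
    write_reference_fasta(refs, out_file("references.fa"))
    ca <- config$cohort_config_a
    ca$seed <- substream_seed(config$seed, "cohortA")
    cohort <- generate_cohort(refs, ca)
    write_matrix_tsv(cohort$counts, out_file("species_counts.tsv"), "sequence")
    write_tsv(cohort$species, out_file("species_table.tsv"))
    write_metadata(cohort$metadata, out_file("metadata.tsv"))
    write_json_sorted(list(planted_up_families = cohort$truth$planted_up_families,
                           planted_effects = cohort$truth$planted_effects,
                           latent_scores = as.list(cohort$truth$latent_scores),
                           seeds_used = cohort$truth$seeds_used),
                      out_file("truth.json"))
    gc_ <- config$gene_config
    gc_$seed <- substream_seed(config$seed, "genes")
    genes <- generate_gene_matrix(cohort, gc_)
    write_matrix_tsv(genes$expr, out_file("gene_matrix.tsv"), "gene")
    write_gmt(genes$sets, out_file("gene_sets.gmt"))
    outs <- c("references.fa", "species_counts.tsv", "species_table.tsv",
              "metadata.tsv", "truth.json", "gene_matrix.tsv", "gene_sets.gmt")
    if (isTRUE(config$second_cohort)) {
      cb <- config$cohort_config_b
      cb$seed <- substream_seed(config$seed, "cohortB")
      cohort_b <- generate_cohort(refs, cb)
      write_matrix_tsv(cohort_b$counts, out_file("species_counts_b.tsv"), "sequence")
      write_metadata(cohort_b$metadata, out_file("metadata_b.tsv"))
      outs <- c(outs, "species_counts_b.tsv", "metadata_b.tsv")
    } else {
      log_line("WARN", "simulate: second cohort disabled; diverge will be skipped")
    }
    outs
  }

  annotate_one <- function(refs, counts, metadata, suffix = "") {
    reads <- filter_reads(data.frame(sequence = rownames(counts),
                                     count = pmax(rowSums(counts), 1)),
                          config$min_len, config$max_len)
    if (attr(reads, "n_removed") > 0) {
      log_line("WARN", "annotate", suffix, ": removed ", attr(reads, "n_removed"),
               " species outside [", config$min_len, ", ", config$max_len, "] nt (",
               attr(reads, "mass_removed"), " reads)")
    }
    ann <- annotate_reads(reads, refs, config$precedence)
    counts <- counts[ann$species$sequence, , drop = FALSE]
    agg <- aggregate_families(ann$species, counts, config$denominator_policy)
    write_tsv(ann$species, out_file(paste0("annotated_species", suffix, ".tsv")))
    write_tsv(ann$loci, out_file(paste0("loci", suffix, ".tsv")))
    write_matrix_tsv(counts, out_file(paste0("retained_counts", suffix, ".tsv")),
                     "sequence")
    write_matrix_tsv(agg$family_rpm, out_file(paste0("family_rpm", suffix, ".tsv")),
                     "family")
    write_matrix_tsv(agg$class_rpm, out_file(paste0("class_rpm", suffix, ".tsv")),
                     "class")
    write_tsv(data.frame(sample_id = names(agg$denominator),
                         denominator = unname(agg$denominator)),
              out_file(paste0("denominators", suffix, ".tsv")))
    paste0(c("annotated_species", "loci", "retained_counts", "family_rpm",
             "class_rpm", "denominators"), suffix, ".tsv")
  }

  annotate_stage <- function() {
    if (config$synthetic) {
      if (!have("references.fa", "species_counts.tsv", "metadata.tsv")) {
        log_line("WARN", "annotate: skipped (simulate outputs unavailable)")
        return(NULL)
      }
      refs <- read_reference_fasta(out_file("references.fa"))
      counts <- read_matrix_tsv(out_file("species_counts.tsv"))
      metadata <- read_metadata(out_file("metadata.tsv"))
      log_line("INFO", "annotate: exact-match annotation of ", nrow(counts),
               " species")
      outs <- annotate_one(refs, counts, metadata)
      if (have("species_counts_b.tsv", "metadata_b.tsv")) {
        counts_b <- read_matrix_tsv(out_file("species_counts_b.tsv"))
        outs <- c(outs, annotate_one(refs, counts_b,
                                     read_metadata(out_file("metadata_b.tsv")), "_b"))
      }
      outs
    } else {
      refs <- read_reference_fasta(config$reference_fasta)
      metadata <- read_metadata(config$metadata)
      file.copy(config$metadata, out_file("metadata.tsv"), overwrite = TRUE)
      log_line("INFO", "annotate: reading collapsed reads from ", config$reads_dir)
      res <- annotate_sample_dir(config$reads_dir, metadata, refs,
                                 config$precedence, config$min_len, config$max_len)
      write_matrix_tsv(res$counts, out_file("species_counts.tsv"), "sequence")
      write_reference_fasta(refs, out_file("references.fa"))
      counts <- res$counts
      c("metadata.tsv", "species_counts.tsv", "references.fa",
        annotate_one(refs, counts, metadata))
    }
  }

  profile_stage <- function() {
    if (!have("annotated_species.tsv", "retained_counts.tsv", "metadata.tsv")) {
      log_line("WARN", "profile: skipped (annotation outputs unavailable)")
      return(NULL)
    }
    log_line("INFO", "profile: landscape statistics")
    species <- utils::read.delim(out_file("annotated_species.tsv"))
    counts <- read_matrix_tsv(out_file("retained_counts.tsv"))
    metadata <- read_metadata(out_file("metadata.tsv"))
    class_rpm <- read_matrix_tsv(out_file("class_rpm.tsv"))
    family_rpm <- read_matrix_tsv(out_file("family_rpm.tsv"))
    denom <- utils::read.delim(out_file("denominators.tsv"))
    denominator <- stats::setNames(denom$denominator, denom$sample_id)[colnames(counts)]
    contrasts <- Filter(function(ct) all(ct %in% metadata$group), DEFAULT_CONTRASTS)
    outs <- character()
    if (length(contrasts)) {
      ctt <- class_total_tests(class_rpm, metadata, contrasts)
      write_tsv(ctt$tests, out_file("class_total_tests.tsv"))
      write_tsv(ctt$correlations, out_file("class_correlations.tsv"))
      outs <- c(outs, "class_total_tests.tsv", "class_correlations.tsv")
    }
    ld <- length_distribution(species, counts, metadata, denominator)
    write_tsv(ld, out_file("length_distribution.tsv"))
    outs <- c(outs, "length_distribution.tsv")
    nc <- family_rpm[is_noncanonical_label(rownames(family_rpm)), , drop = FALSE]
    if (nrow(nc) >= 2 && ncol(nc) >= 3) {
      pca <- pca_categories(t(nc), metadata, contrasts)
      write_matrix_tsv(pca$scores, out_file("pca_scores.tsv"), "sample_id")
      write_json_sorted(list(explained_variance = pca$explained_variance,
                             pc1_tests = pca$pc1_tests),
                        out_file("pca_summary.json"))
      outs <- c(outs, "pca_scores.tsv", "pca_summary.json")
    }
    if (all(c("HC", "UC", "CD") %in% metadata$group)) {
      fcc <- fold_change_concordance(family_rpm, metadata, config$eps)
      write_tsv(fcc$table, out_file("fold_change_concordance.tsv"))
      write_json_sorted(list(rho = fcc$rho, p = fcc$p),
                        out_file("fold_change_summary.json"))
      outs <- c(outs, "fold_change_concordance.tsv", "fold_change_summary.json")
    }
    ts <- nc[grepl("^(GtsRNA|MtsRNA)-", rownames(nc)), , drop = FALSE]
    if (nrow(ts)) {
      refs <- read_reference_fasta(out_file("references.fa"))
      loci <- utils::read.delim(out_file("loci.tsv"))
      top_fam <- rownames(ts)[which.max(rowMeans(ts))]
      prof <- cleavage_profile(species, loci, counts, refs, metadata, top_fam,
                               denominator)
      rows <- do.call(rbind, lapply(prof, function(p) {
        do.call(rbind, lapply(colnames(p$mean), function(g)
          data.frame(parent_id = p$parent_id, start = p$position,
                     end = p$position + 1L, group = g,
                     mean = p$mean[, g], sem = p$sem[, g])))
      }))
      write_tsv(rows, out_file("cleavage_profile.tsv"))
      outs <- c(outs, "cleavage_profile.tsv")
    }
    outs
  }

  diff_stage <- function() {
    if (!have("family_rpm.tsv", "metadata.tsv")) {
      log_line("WARN", "diff: skipped (annotation outputs unavailable)")
      return(NULL)
    }
    metadata <- read_metadata(out_file("metadata.tsv"))
    if (!all(c("HC", "UC", "CD") %in% metadata$group)) {
      log_line("WARN", "diff: skipped (needs HC, UC and CD groups)")
      return(NULL)
    }
    log_line("INFO", "diff: differential families and signature")
    family_rpm <- read_matrix_tsv(out_file("family_rpm.tsv"))
    nc <- family_rpm[is_noncanonical_label(rownames(family_rpm)), , drop = FALSE]
    tab_uc <- differential_table(nc, metadata, c("HC", "UC"))
    tab_cd <- differential_table(nc, metadata, c("HC", "CD"))
    write_tsv(tab_uc, out_file("differential_HC_vs_UC.tsv"))
    write_tsv(tab_cd, out_file("differential_HC_vs_CD.tsv"))
    sig <- derive_signature(tab_uc, tab_cd, config$alpha)
    write_json_sorted(list(alpha = config$alpha,
                           contrasts = c("HC_vs_UC", "HC_vs_CD"),
                           n_families = nrow(sig), entries = sig),
                      out_file("signature.json"))
    log_line("INFO", "diff: signature of ", nrow(sig), " families (",
             sum(sig$direction == "up"), " up)")
    c("differential_HC_vs_UC.tsv", "differential_HC_vs_CD.tsv", "signature.json")
  }

  score_stage <- function() {
    if (!have("signature.json", "family_rpm.tsv", "metadata.tsv")) {
      log_line("WARN", "score: skipped (signature unavailable)")
      return(NULL)
    }
    sig_js <- jsonlite::read_json(out_file("signature.json"), simplifyVector = TRUE)
    if (!sig_js$n_families) {
      log_line("WARN", "score: skipped (empty signature: 0 families)")
      return(NULL)
    }
    log_line("INFO", "score: z-sum risk scores and ROC")
    sig <- as.data.frame(sig_js$entries)
    metadata <- read_metadata(out_file("metadata.tsv"))
    family_rpm <- read_matrix_tsv(out_file("family_rpm.tsv"))
    pop <- metadata$sample_id[metadata$group %in% c("HC", "UC", "CD")]
    bl <- compute_baseline(family_rpm, pop, sig)
    sc <- risk_score(family_rpm, bl)
    write_tsv(data.frame(sample_id = metadata$sample_id, group = metadata$group,
                         score = unname(sc[metadata$sample_id])),
              out_file("risk_scores.tsv"))
    aucs <- list()
    roc_rows <- list()
    for (g in intersect(c("UC", "CD"), unique(metadata$group))) {
      sel <- metadata$group %in% c("HC", g)
      r <- roc_auc(sc[metadata$sample_id[sel]], metadata$group[sel] == g)
      aucs[[paste0("auc_hc_", tolower(g))]] <- r$auc
      roc_rows[[g]] <- cbind(contrast = paste0("HC_vs_", g), r$roc)
    }
    write_json_sorted(aucs, out_file("roc_auc.json"))
    write_tsv(do.call(rbind, roc_rows), out_file("roc_points.tsv"))
    c("risk_scores.tsv", "roc_auc.json", "roc_points.tsv")
  }

  cv_stage <- function() {
    if (!have("family_rpm.tsv", "metadata.tsv")) {
      log_line("WARN", "cv: skipped (annotation outputs unavailable)")
      return(NULL)
    }
    metadata <- read_metadata(out_file("metadata.tsv"))
    if (!all(c("HC", "UC", "CD") %in% metadata$group)) {
      log_line("WARN", "cv: skipped (needs HC, UC and CD groups)")
      return(NULL)
    }
    log_line("INFO", "cv: ", config$cv_rounds, " rounds of ", config$cv_k,
             "-fold cross-validation")
    family_rpm <- read_matrix_tsv(out_file("family_rpm.tsv"))
    nc <- family_rpm[is_noncanonical_label(rownames(family_rpm)), , drop = FALSE]
    cv <- cross_validate(nc, metadata, k = config$cv_k, rounds = config$cv_rounds,
                         alpha = config$alpha,
                         seed = substream_seed(config$seed, "cv"),
                         baseline_population = config$baseline_population)
    if (cv$empty_folds > 0) {
      log_line("WARN", "cv: ", cv$empty_folds, " fold(s) yielded an empty signature")
    }
    write_json_sorted(
      list(k = cv$k, rounds = cv$rounds, seed = cv$seed,
           empty_folds = cv$empty_folds, round_auc = cv$round_auc,
           prioritization = as.list(cv$prioritization[cv$prioritization > 0])),
      out_file("cv_report.json"))
    "cv_report.json"
  }

  coexpress_stage <- function() {
    gm <- if (config$synthetic) out_file("gene_matrix.tsv") else config$gene_matrix
    gs <- if (config$synthetic) out_file("gene_sets.gmt") else config$gene_sets
    if (is.null(gm) || !file.exists(gm)) {
      log_line("WARN", "coexpress: skipped (no gene-expression matrix)")
      return(NULL)
    }
    if (!have("family_rpm.tsv", "metadata.tsv")) {
      log_line("WARN", "coexpress: skipped (annotation outputs unavailable)")
      return(NULL)
    }
    log_line("INFO", "coexpress: family-gene correlation and pathway scores")
    family_rpm <- read_matrix_tsv(out_file("family_rpm.tsv"))
    metadata <- read_metadata(out_file("metadata.tsv"))
    gene_expr <- read_matrix_tsv(gm)
    fam_log <- log2(family_rpm[is_noncanonical_label(rownames(family_rpm)), ,
                               drop = FALSE] + 1)
    pt <- spearman_pair_table(fam_log, gene_expr)
    write_tsv(pt[pt$p_adj < config$alpha, ], out_file("coexpression_pairs.tsv"))
    sel <- select_coexpressed_genes(pt, config$alpha, config$min_coexpr_families)
    write_json_sorted(list(positive = sel$positive, negative = sel$negative,
                           both = sel$both),
                      out_file("coexpressed_genes.json"))
    log_line("INFO", "coexpress: ", length(sel$positive), " positively and ",
             length(sel$negative), " negatively co-expressed genes")
    outs <- c("coexpression_pairs.tsv", "coexpressed_genes.json")
    if (!is.null(gs) && file.exists(gs)) {
      sets <- read_gmt(gs)
      universe <- rownames(gene_expr)
      enr <- list()
      if (length(sel$positive)) {
        enr$positive <- hypergeometric_enrichment(sel$positive, sets, universe)
      }
      if (length(sel$negative)) {
        enr$negative <- hypergeometric_enrichment(sel$negative, sets, universe)
      }
      write_json_sorted(enr, out_file("enrichment.json"))
      fs <- faime_scores(gene_expr, sets)
      write_matrix_tsv(fs, out_file("pathway_scores.tsv"), "set")
      contrasts <- Filter(function(ct) all(ct %in% metadata$group), DEFAULT_CONTRASTS)
      if (length(contrasts)) {
        pg <- pathway_group_comparison(fs, metadata, contrasts)
        write_tsv(pg, out_file("pathway_group_tests.tsv"))
        outs <- c(outs, "pathway_group_tests.tsv")
      }
      outs <- c(outs, "enrichment.json", "pathway_scores.tsv")
    } else {
      log_line("WARN", "coexpress: no gene sets; enrichment and scores skipped")
    }
    outs
  }

  diverge_stage <- function() {
    if (!have("family_rpm.tsv", "family_rpm_b.tsv")) {
      log_line("WARN", "diverge: skipped (no second cohort)")
      return(NULL)
    }
    log_line("INFO", "diverge: cross-cohort baseline divergence")
    dv <- cohort_divergence(read_matrix_tsv(out_file("family_rpm.tsv")),
                            read_matrix_tsv(out_file("family_rpm_b.tsv")),
                            read_metadata(out_file("metadata.tsv")),
                            read_metadata(out_file("metadata_b.tsv")),
                            config$eps)
    write_tsv(dv$table, out_file("divergence.tsv"))
    write_json_sorted(list(ks_D = dv$ks$D, ks_p = dv$ks$p, r2 = as.list(dv$r2)),
                      out_file("divergence_summary.json"))
    c("divergence.tsv", "divergence_summary.json")
  }

  bodies <- list(simulate = simulate_stage, annotate = annotate_stage,
                 profile = profile_stage, diff = diff_stage,
                 score = score_stage, cv = cv_stage,
                 coexpress = coexpress_stage, diverge = diverge_stage)
  for (stage in PIPELINE_STAGES) {
    if (stage %in% stages) run_stage(stage, bodies[[stage]])
  }
  state$manifest$computed <- state$computed
  writeLines(state$log, file.path(out_dir, "pipeline.log"))
  write_json_sorted(state$manifest, mf_path)
  invisible(state$manifest)
}
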