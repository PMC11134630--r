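#' Pipeline configuration
#'
#' Collects all analysis thresholds and simulation settings in one
#' object. The defaults hold the study's stated cutoffs: CPM > 0.1 for
#' expression filtering, FDR 0.05 for divergence calls, and a strict
#' twofold rule for tissue specificity.
#'
#' @param sim A [sim_config()] (or a list of its arguments) driving the
#'   simulate stage.
#' @param cpm_threshold CPM filter cutoff.
#' @param fdr FDR level for divergence and contrast calls.
#' @param lfc_threshold Absolute log2 fold-change for per-replicate
#'   "changed" calls.
#' @param tissue_fold Tissue-specificity fold cutoff.
#' @param clr_zero_strategy Zero handling for the CLR transform.
#' @param n_boot Bootstrap resamples of the heterogeneity comparison.
#' @param n_random Size-matched random sets of the heterogeneity
#'   comparison.
#' @param n_perm Permutations for the crossing-scheme test.
#' @param n_chc_samples_per_group,n_samples_per_replicate,n_ancestral_samples,n_diallel_vials
#'   Simulated sample sizes per stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cpm_threshold = 0.1,
                            fdr = 0.05,
                            lfc_threshold = 1,
                            tissue_fold = 2,
                            clr_zero_strategy = "multiplicative",
                            n_boot = 500L,
                            n_random = 500L,
                            n_perm = 10000L,
                            n_chc_samples_per_group = 15L,
                            n_samples_per_replicate = 3L,
                            n_ancestral_samples = 6L,
                            n_diallel_vials = 5L) {
  if (is.list(sim) && !inherits(sim, "sim_config"))
    sim <- do.call(sim_config, sim)
  stopifnot(cpm_threshold >= 0, fdr > 0, fdr < 1, lfc_threshold >= 0,
            tissue_fold > 0, n_boot > 1, n_random > 0, n_perm > 0)
  structure(list(sim = sim, cpm_threshold = cpm_threshold, fdr = fdr,
                 lfc_threshold = lfc_threshold, tissue_fold = tissue_fold,
                 clr_zero_strategy = clr_zero_strategy,
                 n_boot = as.integer(n_boot),
                 n_random = as.integer(n_random),
                 n_perm = as.integer(n_perm),
                 n_chc_samples_per_group = as.integer(n_chc_samples_per_group),
                 n_samples_per_replicate = as.integer(n_samples_per_replicate),
                 n_ancestral_samples = as.integer(n_ancestral_samples),
                 n_diallel_vials = as.integer(n_diallel_vials)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the `sim` key holds
#' [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown pipeline_config fields in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the simulation-to-report pipeline
#'
#' Executes the requested stages on synthetic data generated from the
#' configuration: `simulate` (writes every modality as TSV), `mating`,
#' `chc`, `cross`, `expression`, `heterogeneity`, `enrich`, or `all`.
#' Results are written as per-stage TSVs plus one machine-readable JSON
#' summary; given the same seed the JSON is byte-identical across runs.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @param out_dir Output directory (created if absent).
#' @param stage Stage name or `"all"`.
#' @param seed Overrides `config$sim$seed` when non-`NULL`.
#' @return Invisibly, the summary list written to
#'   `file.path(out_dir, "summary.json")`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".",
                         stage = "all", seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "mating", "chc", "cross", "expression",
              "heterogeneity", "enrich")
  stage <- match.arg(stage, c(stages, "all"))
  run <- if (stage == "all") stages else stage
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  summary <- list(schema_version = "1.0", seed = cfg$seed, stages = run)
  pathto <- function(f) file.path(out_dir, f)
  msg <- function(...) message("[evoiso] ", ...)

  # every analysis stage needs its inputs; generate them in-memory once
  msg("generating synthetic inputs (seed ", cfg$seed, ")")
  mating_tab <- simulate_choice_assay(cfg, seed = cfg$seed + 1L)
  chc_prof <- simulate_chc(cfg, config$n_chc_samples_per_group,
                           seed = cfg$seed + 2L)
  diallel <- simulate_diallel(cfg, n_vials = config$n_diallel_vials,
                              seed = cfg$seed + 3L)
  sim <- simulate_counts(cfg, config$n_samples_per_replicate,
                         config$n_ancestral_samples, seed = cfg$seed + 4L)

  if ("simulate" %in% run) {
    write_mating_tsv(mating_tab, pathto("mating_pairs.tsv"))
    write_chc_tsv(chc_prof, pathto("chc_profiles.tsv"))
    write_diallel_tsv(diallel, pathto("diallel.tsv"))
    write_counts_tsv(sim$matrix, pathto("counts.tsv"),
                     pathto("sample_meta.tsv"))
    write_gmt(sim$gene_sets, pathto("gene_sets.gmt"))
    summary$simulate <- list(
      n_genes = nrow(sim$matrix$counts),
      n_samples = ncol(sim$matrix$counts),
      n_reproduction_genes = length(sim$gene_sets$reproduction))
  }

  if ("mating" %in% run) {
    msg("mating statistics")
    rep_tab <- assortative_mating_report(mating_tab)
    utils::write.table(rep_tab, pathto("mating_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$mating <- list(yule_Y = rep_tab$yule_Y, yule_Q = rep_tab$yule_Q,
                           fisher_p = rep_tab$fisher_p,
                           n_pairs = rep_tab$n_pairs)
  }

  if ("chc" %in% run) {
    msg("CHC compositional analysis")
    p <- chc_pca(chc_prof, zero_strategy = config$clr_zero_strategy)
    av <- chc_anova_table(chc_prof, zero_strategy = config$clr_zero_strategy)
    utils::write.table(
      data.frame(sample_id = chc_prof$sample_id, sex = chc_prof$sex,
                 group = chc_prof$group,
                 p$scores[, 1:min(4, ncol(p$scores)), drop = FALSE]),
      pathto("chc_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(compound = rownames(p$loadings), p$loadings),
      pathto("chc_loadings.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(av, pathto("chc_anova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$chc <- list(
      pc1_var_pct = 100 * p$var_explained[1],
      pc2_var_pct = 100 * p$var_explained[2],
      n_significant_interactions =
        sum(stats::p.adjust(av$p_interaction, "BH") < config$fdr))
  }

  if ("cross" %in% run) {
    msg("diallel cross analysis")
    ctm <- cross_type_means(diallel)
    mp <- midparent_test(diallel)
    wt <- diallel_wilcoxon(diallel)
    perm <- crossing_scheme_permutation(diallel, config$n_perm,
                                        seed = cfg$seed + 5L)
    utils::write.table(ctm$cross_means, pathto("cross_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(mp, pathto("midparent.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$cross <- list(
      within_mean = ctm$within_mean, between_mean = ctm$between_mean,
      deficit_pct = 100 * ctm$deficit,
      wilcoxon_p = wt$p_value,
      permutation_p = perm$p_value,
      n_hybrid_exceeding_midparent =
        sum(mp$exceeds[mp$direction == "pooled"]))
  }

  div <- NULL; prc <- NULL; disp <- NULL
  if (any(c("expression", "heterogeneity", "enrich") %in% run)) {
    msg("expression divergence (NB GLM LRT)")
    filtered <- cpm_filter(sim$matrix, config$cpm_threshold)
    disp <- estimate_dispersion(filtered)
    div <- divergence_lrt(filtered, disp$common, fdr = config$fdr)
    prc <- per_replicate_change(filtered, disp$common,
                                lfc_threshold = config$lfc_threshold,
                                fdr = config$fdr)
  }

  if ("expression" %in% run) {
    utils::write.table(div, pathto("divergence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = rownames(prc$lfc), prc$lfc, check.names = FALSE),
      pathto("replicate_lfc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    summary$expression <- list(
      n_tested = sum(div$converged),
      n_divergent = sum(div$divergent),
      common_dispersion = disp$common)
  }

  if ("heterogeneity" %in% run) {
    msg("heterogeneity of replicate changes")
    repro <- intersect(sim$gene_sets$reproduction, rownames(prc$lfc))
    cmp <- compare_gene_sets(prc$lfc, repro,
                             n_boot = config$n_boot,
                             n_random = config$n_random,
                             seed = cfg$seed + 6L)
    bias <- direction_bias(prc$direction, repro,
                           background_set = rownames(prc$direction))
    utils::write.table(
      data.frame(set = names(cmp$H), H = as.numeric(cmp$H)),
      pathto("heterogeneity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    summary$heterogeneity <- list(
      H_reproduction = cmp$H[["focal"]],
      H_background = cmp$H[["background"]],
      focal_quantile = cmp$focal_quantile,
      mw_p = cmp$mw_p_vs_background,
      fraction_up = bias$fraction_up,
      direction_binom_p = bias$binom_p)
  }

  if ("enrich" %in% run) {
    msg("gene-set over-representation")
    hits <- div$gene[div$divergent]
    universe <- div$gene[div$converged]
    enr <- overrep_test(hits,
                        list(reproduction =
                               intersect(sim$gene_sets$reproduction,
                                         universe)),
                        universe)
    utils::write.table(enr, pathto("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$enrich <- list(
      odds_ratio = enr$odds_ratio[1], p = enr$p[1], q = enr$q[1])
  }

  jsonlite::write_json(summary, pathto("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
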