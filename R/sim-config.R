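#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every knob of the four data-modality simulators
#' ([simulate_choice_assay()], [simulate_chc()], [simulate_diallel()],
#' [simulate_counts()]) into a single validated object. Defaults mirror
#' the design of a replicated thermal-adaptation experiment in
#' *Drosophila simulans*: 10 evolved replicate populations, mate-choice
#' cages seeded with 50 flies of each sex per population and scored until
#' 25 pairs have formed, and 12 cuticular-hydrocarbon compounds detected
#' in every sample.
#'
#' @param seed Integer seed; a single global seed is threaded to all
#'   simulator substreams so that runs are bit-reproducible.
#' @param n_replicates Number of evolved replicate populations.
#' @param n_flies_per_pop_per_sex Flies of each sex contributed by each
#'   population to a mate-choice cage.
#' @param max_pairs Pair-formation is stopped once this many mating pairs
#'   have been scored (censoring in the assay).
#' @param preference Homotypic mating weight, `>= 1`. A free male of the
#'   same population as the choosing female is picked with probability
#'   proportional to `preference`; heterotypic males have weight 1.
#'   `preference = 1` is random mating.
#' @param n_compounds Number of CHC compounds in a simulated profile.
#' @param sex_effect,evo_effect Per-compound log-scale shifts applied to
#'   male and to evolved samples respectively; length `n_compounds`
#'   (recycled from a scalar, default 0).
#' @param chc_base Per-compound baseline log abundance (length
#'   `n_compounds`); default is a geometric ladder giving one dominant and
#'   several trace compounds, as in real cuticular profiles.
#' @param chc_noise_sd Standard deviation of the per-compound log-normal
#'   noise of a CHC sample.
#' @param n_genes Number of genes in a simulated count matrix.
#' @param frac_reproduction_genes Fraction of genes assigned to the
#'   designated "reproduction" gene set, the only genes that receive
#'   replicate-specific expression shifts.
#' @param shared_lfc_sd Standard deviation (log2 scale) of the adaptive
#'   expression shift shared by all evolved replicates.
#' @param replicate_lfc_sd Standard deviation (log2 scale) of the
#'   replicate-specific shifts injected into reproduction-set genes.
#' @param up_bias Probability in `[0.5, 1]` that a replicate-specific
#'   shift is an up-regulation.
#' @param nb_dispersion Negative-binomial dispersion `phi` (> 0);
#'   variance is `mu + phi * mu^2`.
#' @param diallel_mean Expected viable progeny per vial of a
#'   between-replicate cross.
#' @param diallel_within_advantage Multiplicative progeny advantage of
#'   within-replicate crosses (>= 0): within-cross vials have mean
#'   `diallel_mean * (1 + diallel_within_advantage)`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, preference = 4)
#' cfg$preference
sim_config <- function(seed = 1L,
                       n_replicates = 10L,
                       n_flies_per_pop_per_sex = 50L,
                       max_pairs = 25L,
                       preference = 1,
                       n_compounds = 12L,
                       sex_effect = 0,
                       evo_effect = 0,
                       chc_base = NULL,
                       chc_noise_sd = 0.2,
                       n_genes = 2000L,
                       frac_reproduction_genes = 0.05,
                       shared_lfc_sd = 0.2,
                       replicate_lfc_sd = 1,
                       up_bias = 0.9,
                       nb_dispersion = 0.2,
                       diallel_mean = 24,
                       diallel_within_advantage = 0.09) {
  if (is.null(chc_base)) {
    # one dominant compound plus a tail of minor ones
    chc_base <- seq(3, -2, length.out = n_compounds)
  }
  sex_effect <- rep_len(as.numeric(sex_effect), n_compounds)
  evo_effect <- rep_len(as.numeric(evo_effect), n_compounds)

  cfg <- list(
    seed = as.integer(seed),
    n_replicates = as.integer(n_replicates),
    n_flies_per_pop_per_sex = as.integer(n_flies_per_pop_per_sex),
    max_pairs = as.integer(max_pairs),
    preference = as.numeric(preference),
    n_compounds = as.integer(n_compounds),
    sex_effect = sex_effect,
    evo_effect = evo_effect,
    chc_base = rep_len(as.numeric(chc_base), n_compounds),
    chc_noise_sd = as.numeric(chc_noise_sd),
    n_genes = as.integer(n_genes),
    frac_reproduction_genes = as.numeric(frac_reproduction_genes),
    shared_lfc_sd = as.numeric(shared_lfc_sd),
    replicate_lfc_sd = as.numeric(replicate_lfc_sd),
    up_bias = as.numeric(up_bias),
    nb_dispersion = as.numeric(nb_dispersion),
    diallel_mean = as.numeric(diallel_mean),
    diallel_within_advantage = as.numeric(diallel_within_advantage)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$n_genes) != 1L || is.na(cfg$n_genes))
    stop("n_genes must be a single integer")
  if (cfg$preference < 1)
    stop("preference must be >= 1 (1 = random mating)")
  if (cfg$n_compounds < 1)
    stop("n_compounds must be positive")
  if (length(cfg$sex_effect) != cfg$n_compounds ||
      length(cfg$evo_effect) != cfg$n_compounds)
    stop("per-compound effect vectors must have length n_compounds")
  if (cfg$frac_reproduction_genes <= 0 || cfg$frac_reproduction_genes >= 1)
    stop("frac_reproduction_genes must lie in (0, 1)")
  if (cfg$up_bias < 0.5 || cfg$up_bias > 1)
    stop("up_bias must lie in [0.5, 1]")
  if (cfg$shared_lfc_sd < 0 || cfg$replicate_lfc_sd < 0 ||
      cfg$chc_noise_sd < 0)
    stop("scale parameters must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$diallel_within_advantage < 0)
    stop("diallel_within_advantage must be >= 0")
  if (cfg$diallel_mean <= 0) stop("diallel_mean must be > 0")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Any field of [sim_config()] may be given; missing fields take their
#' defaults.
#'
#' @param path Path to a YAML file whose top-level keys are `sim_config`
#'   argument names.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown sim_config fields in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_replicates, "replicates,",
      x$n_genes, "genes,",
      x$n_compounds, "CHC compounds, seed", x$seed, "\n")
  invisible(x)
}
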