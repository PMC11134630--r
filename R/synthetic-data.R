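#' Simulate a multiple-choice mating assay
#'
#' Sequential pair formation without replacement in a cage seeded with
#' `n_flies_per_pop_per_sex` flies of each sex from each of two
#' populations. At each step a free female is drawn uniformly and a free
#' male is drawn with weight `preference` if he is from the female's
#' population and weight 1 otherwise; the pair is removed from the cage.
#' Scoring stops after `max_pairs` pairs or when either sex is exhausted.
#'
#' @param cfg A [sim_config()]; `preference`, `n_flies_per_pop_per_sex`
#'   and `max_pairs` are used.
#' @param pops Character vector of the two population labels.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A `mating_table`: a 2x2 integer matrix of pair counts with
#'   rows = female population and columns = male population.
#' @export
#' @examples
#' tab <- simulate_choice_assay(sim_config(seed = 7, preference = 4))
#' yules_index(tab, "Q")
simulate_choice_assay <- function(cfg, pops = c("A", "B"), seed = NULL) {
  validate_sim_config(cfg)
  stopifnot(length(pops) == 2L)
  n <- cfg$n_flies_per_pop_per_sex
  if (n <= 0L) stop("empty assay")
  if (!is.null(seed)) set.seed(seed) else set.seed(cfg$seed)

  females <- c(n, n)  # free females per population
  males <- c(n, n)
  counts <- matrix(0L, 2, 2, dimnames = list(female = pops, male = pops))
  pairs <- 0L
  while (pairs < cfg$max_pairs && sum(females) > 0L && sum(males) > 0L) {
    f <- sample.int(2L, 1L, prob = females)
    w <- males * ifelse(seq_len(2L) == f, cfg$preference, 1)
    m <- sample.int(2L, 1L, prob = w)
    females[f] <- females[f] - 1L
    males[m] <- males[m] - 1L
    counts[f, m] <- counts[f, m] + 1L
    pairs <- pairs + 1L
  }
  mating_table(counts)
}

#' Construct a mating-pair count table
#'
#' @param counts 2x2 matrix of nonnegative integer pair counts, rows
#'   indexed by female population and columns by male population.
#' @return The matrix with class `mating_table`.
#' @export
mating_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("a mating table is 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("pair counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(female = c("A", "B"), male = c("A", "B"))
  class(counts) <- c("mating_table", class(counts))
  counts
}

#' Simulate cuticular-hydrocarbon composition profiles
#'
#' Draws logistic-normal compositions: for each sample the per-compound
#' log abundance is `chc_base + sex_effect * [male] + evo_effect *
#' [evolved] + N(0, chc_noise_sd)`, exponentiated and closed to sum 1.
#' Four groups are generated (female/male x ancestral/evolved) with
#' `n_samples_per_group` samples each; evolved samples carry a replicate
#' label cycling through `1..n_replicates`.
#'
#' @param cfg A [sim_config()].
#' @param n_samples_per_group Samples per sex-by-group cell.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A data frame with columns `sample_id`, `sex`, `group`,
#'   `replicate` and one numeric column per compound (`C01`, `C02`, ...);
#'   compound columns sum to 1 in every row.
#' @export
simulate_chc <- function(cfg, n_samples_per_group = 15L, seed = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_compounds < 3L) stop("need at least 3 compounds")
  if (!is.null(seed)) set.seed(seed) else set.seed(cfg$seed)

  K <- cfg$n_compounds
  grid <- expand.grid(sex = c("female", "male"),
                      group = c("ancestral", "evolved"),
                      i = seq_len(n_samples_per_group),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  logab <- matrix(rep(cfg$chc_base, each = n), n, K)
  logab <- logab +
    outer(as.numeric(grid$sex == "male"), cfg$sex_effect) +
    outer(as.numeric(grid$group == "evolved"), cfg$evo_effect) +
    matrix(stats::rnorm(n * K, sd = cfg$chc_noise_sd), n, K)
  comp <- exp(logab)
  comp <- comp / rowSums(comp)
  colnames(comp) <- sprintf("C%02d", seq_len(K))

  repl <- ifelse(grid$group == "evolved",
                 sprintf("R%d", ((grid$i - 1L) %% cfg$n_replicates) + 1L),
                 "anc")
  out <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    sex = grid$sex, group = grid$group, replicate = repl,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(comp))
}

#' Simulate a diallel-cross progeny sheet
#'
#' Full factorial design over `n_pops` populations: every ordered
#' (sire, dam) combination is crossed in `n_vials` vials and the viable
#' progeny count of each vial is Poisson with mean `diallel_mean`,
#' multiplied by `1 + diallel_within_advantage` when sire and dam come
#' from the same population.
#'
#' @param cfg A [sim_config()].
#' @param n_pops Number of populations in the diallel (>= 2).
#' @param n_vials Vials (biological replicates) per cross.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A `diallel_sheet` data frame with columns `sire_pop`,
#'   `dam_pop`, `vial_id`, `progeny_count`.
#' @export
simulate_diallel <- function(cfg, n_pops = 3L, n_vials = 5L, seed = NULL) {
  validate_sim_config(cfg)
  if (n_pops < 2L) stop("a diallel needs at least 2 populations")
  if (!is.null(seed)) set.seed(seed) else set.seed(cfg$seed)

  pops <- sprintf("P%d", seq_len(n_pops))
  design <- expand.grid(sire_pop = pops, dam_pop = pops,
                        vial_id = seq_len(n_vials),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(design$sire_pop == design$dam_pop,
               cfg$diallel_mean * (1 + cfg$diallel_within_advantage),
               cfg$diallel_mean)
  design$progeny_count <- stats::rpois(nrow(design), mu)
  design <- design[order(design$sire_pop, design$dam_pop, design$vial_id), ]
  rownames(design) <- NULL
  class(design) <- c("diallel_sheet", class(design))
  design
}

#' Simulate a replicate-structured RNA-seq count matrix
#'
#' Generates negative-binomial counts for ancestral samples and
#' `n_replicates` evolved replicate populations. Each gene has a log2
#' fold-change shared by all evolved samples (`N(0, shared_lfc_sd)`,
#' the common adaptive response); genes in a designated "reproduction"
#' set additionally receive replicate-specific log2 shifts of scale
#' `replicate_lfc_sd` in 1 or 2 randomly chosen replicates (the number
#' drawn uniformly), with positive sign with probability `up_bias`.
#' Per-sample sequencing depth factors are log-normal, so library sizes
#' differ between samples.
#'
#' @param cfg A [sim_config()].
#' @param n_samples_per_replicate Evolved samples per replicate.
#' @param n_ancestral_samples Ancestral samples.
#' @param depth_sd Standard deviation of the log-normal per-sample depth
#'   factor (0 = equal depths).
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A list of class `sim_counts` with elements
#'   \describe{
#'     \item{matrix}{a [count_matrix()] of NB counts,}
#'     \item{gene_sets}{named list with the `reproduction` gene set,}
#'     \item{truth}{list holding `shared_lfc` (per gene) and
#'       `replicate_lfc` (genes x replicates matrix) of injected shifts.}
#'   }
#' @export
simulate_counts <- function(cfg, n_samples_per_replicate = 3L,
                            n_ancestral_samples = 6L,
                            depth_sd = 0.3, seed = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_genes != round(cfg$n_genes)) stop("n_genes must be an integer")
  if (!is.null(seed)) set.seed(seed) else set.seed(cfg$seed)

  G <- cfg$n_genes
  R <- cfg$n_replicates
  genes <- sprintf("g%04d", seq_len(G))

  repl <- c(rep("anc", n_ancestral_samples),
            rep(sprintf("R%d", seq_len(R)), each = n_samples_per_replicate))
  group <- ifelse(repl == "anc", "ancestral", "evolved")
  samples <- sprintf("%s_s%d", repl, stats::ave(seq_along(repl), repl,
                                                FUN = seq_along))
  S <- length(repl)

  baseline <- exp(stats::rnorm(G, mean = log(100), sd = 1.2))
  shared_lfc <- stats::rnorm(G, sd = cfg$shared_lfc_sd)

  n_repro <- max(3L, round(cfg$frac_reproduction_genes * G))
  repro <- sort(sample.int(G, n_repro))
  replicate_lfc <- matrix(0, G, R,
                          dimnames = list(genes, sprintf("R%d", seq_len(R))))
  for (g in repro) {
    k <- sample(1:2, 1L)                       # affected replicates
    hit <- sample.int(R, k)
    sgn <- ifelse(stats::runif(k) < cfg$up_bias, 1, -1)
    replicate_lfc[g, hit] <- sgn * abs(stats::rnorm(k, sd = cfg$replicate_lfc_sd))
  }

  depth <- exp(stats::rnorm(S, sd = depth_sd))
  lfc <- matrix(0, G, S)
  evolved <- group == "evolved"
  lfc[, evolved] <- shared_lfc +
    replicate_lfc[, match(repl[evolved], colnames(replicate_lfc))]
  mu <- baseline * 2^lfc * rep(depth, each = G)
  counts <- matrix(stats::rnbinom(G * S, mu = mu, size = 1 / cfg$nb_dispersion),
                   G, S, dimnames = list(genes, samples))

  meta <- data.frame(sample_id = samples, replicate = repl, group = group,
                     stringsAsFactors = FALSE)
  out <- list(
    matrix = count_matrix(counts, meta),
    gene_sets = list(reproduction = genes[repro]),
    truth = list(shared_lfc = stats::setNames(shared_lfc, genes),
                 replicate_lfc = replicate_lfc,
                 baseline = stats::setNames(baseline, genes),
                 depth = stats::setNames(depth, samples))
  )
  class(out) <- "sim_counts"
  out
}

#' @export
print.sim_counts <- function(x, ...) {
  cat("sim_counts:", nrow(x$matrix$counts), "genes x",
      ncol(x$matrix$counts), "samples;",
      length(x$gene_sets$reproduction), "reproduction-set genes\n")
  invisible(x)
}
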