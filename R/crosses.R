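#' Read a diallel-cross progeny sheet
#'
#' TSV with columns `sire_pop`, `dam_pop`, `vial_id`, `progeny_count`.
#' Counts averaged over transfers may be non-integer; they must be
#' nonnegative. Full factorial coverage of the population set is
#' required.
#'
#' @param path TSV file path.
#' @return A `diallel_sheet` data frame.
#' @export
read_diallel_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sire_pop", "dam_pop", "vial_id", "progeny_count")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("diallel sheet missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(d$progeny_count < 0)
  if (length(bad))
    stop("negative progeny_count at line(s) ", paste(bad + 1L, collapse = ", "))
  check_diallel_coverage(d)
  class(d) <- c("diallel_sheet", class(d))
  d
}

check_diallel_coverage <- function(d) {
  pops <- sort(unique(c(d$sire_pop, d$dam_pop)))
  have <- unique(paste(d$sire_pop, d$dam_pop, sep = " x "))
  want <- as.vector(outer(pops, pops, paste, sep = " x "))
  miss <- setdiff(want, have)
  if (length(miss))
    stop("missing cross type(s): ", paste(miss, collapse = ", "))
  invisible(pops)
}

#' Per-cross means and the within/between contrast
#'
#' Mean progeny per ordered (sire, dam) cross, the pooled
#' within-replicate and between-replicate means, and the relative
#' deficit of between-replicate crosses,
#' `(between - within) / within` (negative when hybrids do worse).
#'
#' @param d A `diallel_sheet`.
#' @return List with `cross_means` (data frame `sire_pop`, `dam_pop`,
#'   `type`, `mean`, `n_vials`), `within_mean`, `between_mean`,
#'   `deficit`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 3, diallel_within_advantage = 0.09)
#' cross_type_means(simulate_diallel(cfg, n_vials = 200))$deficit
cross_type_means <- function(d) {
  check_diallel_coverage(d)
  key <- interaction(d$sire_pop, d$dam_pop, sep = "\r")
  mn <- tapply(d$progeny_count, key, mean)
  nv <- tapply(d$progeny_count, key, length)
  parts <- do.call(rbind, strsplit(names(mn), "\r", fixed = TRUE))
  cm <- data.frame(sire_pop = parts[, 1], dam_pop = parts[, 2],
                   type = ifelse(parts[, 1] == parts[, 2],
                                 "within", "between"),
                   mean = as.numeric(mn), n_vials = as.integer(nv),
                   stringsAsFactors = FALSE)
  cm <- cm[order(cm$sire_pop, cm$dam_pop), ]
  rownames(cm) <- NULL
  within_mean <- mean(d$progeny_count[d$sire_pop == d$dam_pop])
  between_mean <- mean(d$progeny_count[d$sire_pop != d$dam_pop])
  list(cross_means = cm,
       within_mean = within_mean,
       between_mean = between_mean,
       deficit = (between_mean - within_mean) / within_mean)
}

#' Mid-parent expectation for between-replicate crosses
#'
#' For every unordered pair of populations {A, B}, the mid-parent
#' expectation is the mean of the two pure parental within-cross means,
#' `(mean(AxA) + mean(BxB)) / 2`. The two reciprocal hybrid crosses are
#' reported separately and pooled; `exceeds` flags a hybrid mean above
#' its mid-parent expectation.
#'
#' @param d A `diallel_sheet`.
#' @return Data frame with one row per reciprocal direction plus one
#'   pooled row per pair: `pop1`, `pop2`, `direction`, `observed_mean`,
#'   `midparent`, `exceeds`.
#' @export
midparent_test <- function(d) {
  cm <- cross_type_means(d)$cross_means
  within <- cm[cm$type == "within", ]
  parental <- stats::setNames(within$mean, within$sire_pop)
  pops <- sort(names(parental))
  out <- list()
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i >= j) next
    A <- pops[i]; B <- pops[j]
    if (is.na(parental[A]) || is.na(parental[B]))
      stop("absent parental cross for ", A, " or ", B)
    mp <- (parental[[A]] + parental[[B]]) / 2
    ab <- cm$mean[cm$sire_pop == A & cm$dam_pop == B]
    ba <- cm$mean[cm$sire_pop == B & cm$dam_pop == A]
    rows <- data.frame(
      pop1 = A, pop2 = B,
      direction = c(paste0(A, " x ", B), paste0(B, " x ", A), "pooled"),
      observed_mean = c(ab, ba, mean(c(ab, ba))),
      midparent = mp, stringsAsFactors = FALSE)
    rows$exceeds <- rows$observed_mean > rows$midparent
    out[[length(out) + 1L]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-tailed Wilcoxon rank-sum test (exact by enumeration)
#'
#' Tests the null that `within` values are equal or smaller than
#' `between` values against the alternative that within-replicate
#' crosses produce more progeny. The statistic is the midrank sum of the
#' `within` sample. For `n1 + n2 <= exact_limit` the p-value is computed
#' by complete enumeration of all assignments of the pooled midranks
#' (exact under ties); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param within,between Numeric vectors (progeny counts).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; `NULL`
#'   (default) enumerates when `n1 + n2 <= exact_limit`.
#' @param exact_limit Largest pooled size for enumeration.
#' @param alternative `"greater"` (default; within > between) or
#'   `"less"`.
#' @return List with `statistic` (rank sum W of `within`), `p_value`,
#'   `exact`, `degenerate`.
#' @export
#' @examples
#' # complete separation, 3 vs 6: p = 1/choose(9, 3) = 1/84
#' wilcoxon_one_tailed(c(10, 9, 8), c(7, 6, 5, 4, 3, 2))$p_value
wilcoxon_one_tailed <- function(within, between, exact = NULL,
                                exact_limit = 12L,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(within); n2 <- length(between)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty")
  pooled <- c(within, between)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = n1 * (n1 + n2 + 1) / 2, p_value = 1,
                exact = TRUE, degenerate = TRUE))
  r <- rank(pooled)               # midranks
  W <- sum(r[seq_len(n1)])
  do_exact <- if (is.null(exact)) (n1 + n2) <= exact_limit else exact

  if (do_exact) {
    sets <- utils::combn(n1 + n2, n1)
    Ws <- colSums(matrix(r[sets], nrow = n1))
    eps <- 1e-9
    p <- if (alternative == "greater") mean(Ws >= W - eps)
         else mean(Ws <= W + eps)
  } else {
    N <- n1 + n2
    mu <- n1 * (N + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- if (alternative == "greater") (W - mu - 0.5) / sqrt(sigma2)
         else (W - mu + 0.5) / sqrt(sigma2)
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
  }
  list(statistic = W, p_value = p, exact = do_exact, degenerate = FALSE)
}

#' Within- vs between-replicate Wilcoxon test on a diallel sheet
#'
#' Applies [wilcoxon_one_tailed()] to the within/between contrast,
#' either on vial-level progeny counts or on the nine cross-type means
#' (3 within vs 6 between for a three-population diallel).
#'
#' @param d A `diallel_sheet`.
#' @param unit `"cross_mean"` (default) or `"vial"`.
#' @inheritParams wilcoxon_one_tailed
#' @return As [wilcoxon_one_tailed()], plus `unit`.
#' @export
diallel_wilcoxon <- function(d, unit = c("cross_mean", "vial"),
                             exact = NULL) {
  unit <- match.arg(unit)
  if (unit == "cross_mean") {
    cm <- cross_type_means(d)$cross_means
    w <- cm$mean[cm$type == "within"]
    b <- cm$mean[cm$type == "between"]
  } else {
    w <- d$progeny_count[d$sire_pop == d$dam_pop]
    b <- d$progeny_count[d$sire_pop != d$dam_pop]
  }
  out <- wilcoxon_one_tailed(w, b, exact = exact)
  out$unit <- unit
  out
}

#' Design-respecting permutation test for the crossing scheme
#'
#' Permutation analogue of a mixed-model check for the within/between
#' contrast: the within/between labels are permuted across the cross
#' types (respecting the design's `n` within vs `n(n-1)` between split),
#' the difference of pooled label means is recomputed, and the p-value is
#' the fraction of permutations with a difference at least as large as
#' observed. When the number of distinct assignments (`choose(n^2, n)`)
#' is at most `n_perm`, the complete enumeration is used and the p-value
#' is exact (e.g., 1/84 when the observed assignment is the unique
#' maximum of the 84 assignments of a 3-population diallel).
#'
#' @param d A `diallel_sheet`.
#' @param n_perm Number of permutations (> 0); also the enumeration
#'   threshold.
#' @param seed Optional seed for sampled permutations.
#' @return List with `observed` (within mean - between mean), `p_value`,
#'   `n_used`, `exact`.
#' @export
crossing_scheme_permutation <- function(d, n_perm = 10000L, seed = NULL) {
  if (n_perm <= 0L) stop("n_perm must be positive")
  cm <- cross_type_means(d)$cross_means
  k <- sum(cm$type == "within")
  n <- nrow(cm)
  obs <- mean(cm$mean[cm$type == "within"]) -
    mean(cm$mean[cm$type == "between"])
  n_all <- choose(n, k)
  eps <- 1e-12
  if (n_all <= n_perm) {
    sets <- utils::combn(n, k)
    diffs <- apply(sets, 2L, function(idx)
      mean(cm$mean[idx]) - mean(cm$mean[-idx]))
    p <- mean(diffs >= obs - eps)
    list(observed = obs, p_value = p, n_used = n_all, exact = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    diffs <- replicate(n_perm, {
      idx <- sample.int(n, k)
      mean(cm$mean[idx]) - mean(cm$mean[-idx])
    })
    p <- (1 + sum(diffs >= obs - eps)) / (n_perm + 1)
    list(observed = obs, p_value = p, n_used = n_perm, exact = FALSE)
  }
}
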