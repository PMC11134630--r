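#' Kruskal-Wallis rank test across assay groups
#'
#' Rank-based comparison of chasing times (or any continuous response)
#' across two or more assay setups, with midrank tie correction and a
#' chi-square reference distribution on `k - 1` degrees of freedom.
#' A fully tied input (all values identical) is reported as `H = 0`,
#' `p = 1` and flagged degenerate rather than producing `NaN`.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return A list with `statistic` (H), `df`, `p_value`, `degenerate`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22)))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0L))
    stop("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L,
                p_value = 1, degenerate = TRUE))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, degenerate = FALSE)
}

#' Compact letter display from pairwise Mann-Whitney tests
#'
#' All pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests,
#' Benjamini-Hochberg adjusted, followed by insert-and-absorb letter
#' assignment: two groups share a letter iff their adjusted p-value is
#' above `alpha`.
#'
#' @param groups Named list of numeric vectors; unnamed groups are
#'   labelled `g1`, `g2`, ...
#' @param alpha Significance level applied to BH-adjusted p-values.
#' @return A list with `letters` (named character vector, groups in input
#'   order) and `pairwise` (data frame of group pairs with raw and
#'   adjusted p-values).
#' @export
posthoc_letters <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 1L) stop("need at least one group")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  if (k == 1L)
    return(list(letters = stats::setNames("a", nm),
                pairwise = data.frame()))

  pairs <- utils::combn(k, 2L)
  praw <- apply(pairs, 2L, function(ij) {
    suppressWarnings(stats::wilcox.test(groups[[ij[1]]], groups[[ij[2]]],
                                        exact = FALSE)$p.value)
  })
  praw[is.na(praw)] <- 1  # identical constant groups
  padj <- stats::p.adjust(praw, method = "BH")
  differ <- matrix(FALSE, k, k)
  for (j in seq_len(ncol(pairs))) {
    if (padj[j] <= alpha) {
      differ[pairs[1, j], pairs[2, j]] <- TRUE
      differ[pairs[2, j], pairs[1, j]] <- TRUE
    }
  }

  # order groups by median for conventional a < b < c reading
  ord <- order(vapply(groups, stats::median, 1))
  letters_sets <- cld_insert_absorb(differ, ord)
  lab <- character(k)
  for (i in seq_len(k)) {
    lab[i] <- paste0(letters[which(vapply(letters_sets,
                                          function(s) i %in% s, TRUE))],
                     collapse = "")
  }
  list(letters = stats::setNames(lab, nm),
       pairwise = data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                             p = praw, p_adj = padj,
                             stringsAsFactors = FALSE))
}

# Insert-and-absorb algorithm: maintain letter sets (each a vector of
# group indices) such that a significant pair never shares a set and
# every non-significant pair shares at least one.
cld_insert_absorb <- function(differ, ord) {
  sets <- list(ord)
  k <- nrow(differ)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!differ[i, j]) next
      for (s in seq_along(sets)) {
        if (i %in% sets[[s]] && j %in% sets[[s]]) {
          a <- setdiff(sets[[s]], j)
          b <- setdiff(sets[[s]], i)
          sets[[s]] <- a
          sets[[length(sets) + 1L]] <- b
        }
      }
      # absorb sets contained in another
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] && keep[s] &&
              all(sets[[s]] %in% sets[[t]]) &&
              length(sets[[s]]) < length(sets[[t]]))
            keep[s] <- FALSE
        }
      }
      sets <- sets[keep]
    }
  }
  # stable ordering of letters by the lowest-ranked member
  first <- vapply(sets, function(s) min(match(s, ord)), 1)
  sets[order(first)]
}

#' Yule's association index for a 2x2 mating table
#'
#' Quantifies assortative mating from a 2x2 table of pair counts.
#' With homotypic cells `a` (AA) and `d` (BB) and heterotypic cells `b`
#' (female A x male B) and `c`:
#' \deqn{Q = (ad - bc)/(ad + bc), \qquad
#'       Y = (\sqrt{ad} - \sqrt{bc})/(\sqrt{ad} + \sqrt{bc}).}
#' Both lie in `[-1, 1]`; positive values indicate assortative
#' (homotypic) mating. `Y`, the coefficient of colligation, is the
#' default.
#'
#' @param t A [mating_table()] or plain 2x2 count matrix.
#' @param variant `"Y"` (coefficient of colligation, default) or `"Q"`.
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' yules_index(mating_table(matrix(c(20, 5, 5, 20), 2)), "Q")  # 0.882
#' yules_index(mating_table(matrix(c(20, 5, 5, 20), 2)), "Y")  # 0.6
yules_index <- function(t, variant = c("Y", "Q")) {
  variant <- match.arg(variant)
  t <- as.matrix(t)
  stopifnot(all(dim(t) == 2L), all(t >= 0))
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  ad <- a * d; bc <- b * c
  if (ad + bc == 0) stop("degenerate table: ad + bc = 0")
  if (variant == "Q") (ad - bc) / (ad + bc)
  else (sqrt(ad) - sqrt(bc)) / (sqrt(ad) + sqrt(bc))
}

#' Fisher's exact test for a 2x2 mating table
#'
#' Exact conditional test with fixed margins. The reported odds ratio is
#' the conditional maximum-likelihood estimate (as in
#' [stats::fisher.test()]); the sample odds ratio `ad/bc` is returned
#' alongside. A table with a zero margin carries no information about
#' association and is returned as `p = 1` with undefined odds ratio,
#' flagged degenerate.
#'
#' @param t A [mating_table()] or 2x2 count matrix.
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   association, i.e. assortative mating).
#' @return List with `p_value`, `odds_ratio` (conditional MLE),
#'   `sample_or`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(t, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  t <- as.matrix(t)
  stopifnot(all(dim(t) == 2L))
  if (any(t < 0) || any(t != round(t)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_, sample_or = NA_real_,
                degenerate = TRUE))
  ft <- stats::fisher.test(t, alternative = alternative)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       sample_or = (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1]),
       degenerate = FALSE)
}

#' Assortative-mating report for one population combination
#'
#' Convenience wrapper combining both Yule variants and the Fisher exact
#' test for a mating-pair count table.
#'
#' @param t A [mating_table()].
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return A one-row data frame: populations, pair counts, `yule_Y`,
#'   `yule_Q`, Fisher `odds_ratio` and `p_value`.
#' @export
assortative_mating_report <- function(t, alternative = "two.sided") {
  pops <- rownames(t)
  if (is.null(pops)) pops <- c("A", "B")
  ft <- fisher_exact_2x2(t, alternative)
  data.frame(
    pop1 = pops[1], pop2 = pops[2],
    n_pairs = sum(t),
    n_homotypic = t[1, 1] + t[2, 2],
    yule_Y = yules_index(t, "Y"),
    yule_Q = yules_index(t, "Q"),
    odds_ratio = ft$odds_ratio,
    fisher_p = ft$p_value,
    stringsAsFactors = FALSE
  )
}

#' Read a chasing-time table
#'
#' Expects a TSV with columns `trial_id`, `setup`, `chasing_time`
#' (seconds). Times must be nonnegative and no longer than the assay
#' duration.
#'
#' @param path TSV file path.
#' @param max_seconds Assay duration; 900 s for a 15-minute film.
#' @return A data frame.
#' @export
read_chasing_tsv <- function(path, max_seconds = 900) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "setup", "chasing_time")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("chasing table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(d$chasing_time < 0 | d$chasing_time > max_seconds)
  if (length(bad))
    stop("chasing_time out of [0, ", max_seconds, "] at line(s) ",
         paste(bad + 1L, collapse = ", "))
  d
}

#' Read mating-pair counts
#'
#' Expects a TSV with columns `female_pop`, `male_pop`, `count` covering
#' the four cells of one population combination (extra rows for the same
#' cell, e.g. per cage, are summed).
#'
#' @param path TSV file path.
#' @return A [mating_table()].
#' @export
read_mating_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("female_pop", "male_pop", "count")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("mating table missing column(s): ", paste(miss, collapse = ", "))
  pops <- sort(unique(c(d$female_pop, d$male_pop)))
  if (length(pops) != 2L) stop("expected exactly 2 populations, got ",
                               length(pops))
  tab <- matrix(0L, 2, 2, dimnames = list(female = pops, male = pops))
  for (i in seq_len(nrow(d)))
    tab[d$female_pop[i], d$male_pop[i]] <-
      tab[d$female_pop[i], d$male_pop[i]] + as.integer(d$count[i])
  mating_table(tab)
}
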