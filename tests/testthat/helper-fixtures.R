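# Shared fixture builders. Everything is generated in code; no data files.

# A small count matrix with hand-picked structure: 2 replicates x 2
# samples plus 2 ancestral samples, equal library sizes.
tiny_counts <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- rbind(
      g1 = c(10, 12, 11, 9, 10, 11),
      g2 = c(100, 110, 300, 310, 105, 95),  # shifted in R2
      g3 = c(0, 0, 0, 0, 0, 1)
    )
  }
  meta <- data.frame(
    sample_id = c("R1a", "R1b", "R2a", "R2b", "anc1", "anc2"),
    replicate = c("R1", "R1", "R2", "R2", "anc", "anc"),
    group = c(rep("evolved", 4), rep("ancestral", 2)),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, meta, lib_sizes = rep(1e6, 6))
}

# Balanced 2x2 sex-by-evolution layout with n values per cell.
balanced_design <- function(n) {
  data.frame(
    sex = rep(rep(c("female", "male"), each = n), 2),
    evolution = rep(c("ancestral", "evolved"), each = 2 * n),
    stringsAsFactors = FALSE
  )
}

# Independent enumeration oracle for the one-sided Fisher p-value:
# sum of hypergeometric probabilities over tables with a' >= a.
fisher_greater_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  sum(stats::dhyper(a:hi, m, n, k))
}

# Two-sided oracle: sum of probabilities of all tables with fixed
# margins whose probability does not exceed the observed one.
fisher_twosided_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  pr <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Straight-forward independent re-implementation of the mate-choice
# sampling scheme (used as the oracle for simulate_choice_assay): keeps
# explicit per-fly vectors instead of per-population tallies.
choice_assay_oracle <- function(n_per_pop, max_pairs, preference) {
  fem <- rep(1:2, each = n_per_pop)
  mal <- rep(1:2, each = n_per_pop)
  counts <- matrix(0L, 2, 2)
  while (sum(counts) < max_pairs && length(fem) > 0 && length(mal) > 0) {
    fi <- sample.int(length(fem), 1L)
    f <- fem[fi]
    w <- ifelse(mal == f, preference, 1)
    mi <- sample.int(length(mal), 1L, prob = w)
    m <- mal[mi]
    counts[f, m] <- counts[f, m] + 1L
    fem <- fem[-fi]
    mal <- mal[-mi]
  }
  counts
}

yule_Q_oracle <- function(a, b, c, d) (a * d - b * c) / (a * d + b * c)
yule_Y_oracle <- function(a, b, c, d)
  (sqrt(a * d) - sqrt(b * c)) / (sqrt(a * d) + sqrt(b * c))
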