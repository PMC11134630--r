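test_that("Kruskal-Wallis matches the hand rank formula and handles ties", {
  # untied fixture: ranks known exactly
  g <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  # oracle: H = 12 / (N(N+1)) * sum(R_i^2 / n_i) - 3(N+1)
  H <- 12 / (9 * 10) * (6^2 / 3 + 15^2 / 3 + 24^2 / 3) - 3 * 10
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, stats::pchisq(H, 2, lower.tail = FALSE))

  ident <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  const <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("Kruskal-Wallis holds its nominal level under the null", {
  set.seed(99)
  rej <- mean(replicate(2000, {
    kruskal_wallis(list(rnorm(20), rnorm(20), rnorm(20)))$p_value < 0.05
  }))
  expect_gt(rej, 0.033)
  expect_lt(rej, 0.068)
})

test_that("compact letters reflect the pairwise structure", {
  lo <- 1:12; mid <- lo + 3; hi <- lo + 6

  two <- posthoc_letters(list(low = lo, high = lo + 100))
  expect_equal(unname(two$letters), c("a", "b"))

  same <- posthoc_letters(list(x = lo, y = lo))
  expect_equal(unname(same$letters), c("a", "a"))

  # extremes differ, the middle group differs from neither
  three <- posthoc_letters(list(lo = lo, mid = mid, hi = hi))
  expect_equal(unname(three$letters), c("a", "ab", "b"))
  # oracle: recompute the pairwise BH-adjusted decisions directly
  p <- c(
    stats::wilcox.test(lo, mid, exact = FALSE)$p.value,
    stats::wilcox.test(lo, hi, exact = FALSE)$p.value,
    stats::wilcox.test(mid, hi, exact = FALSE)$p.value
  )
  expect_equal(three$pairwise$p, p, tolerance = 1e-12)
  expect_equal(stats::p.adjust(p, "BH") <= 0.05, c(FALSE, TRUE, FALSE))

  # a clearly graded design gets three distinct letters
  graded <- posthoc_letters(list(a = lo, b = lo + 100, c = lo + 200))
  expect_equal(unname(graded$letters), c("a", "b", "c"))

  one <- posthoc_letters(list(solo = lo))
  expect_equal(unname(one$letters), "a")
})

test_that("Yule's indices match direct arithmetic and the fixtures", {
  perfect <- mating_table(matrix(c(25, 0, 0, 25), 2))
  expect_equal(yules_index(perfect, "Q"), 1)
  expect_equal(yules_index(perfect, "Y"), 1)

  random <- mating_table(matrix(10, 2, 2))
  expect_equal(yules_index(random, "Q"), 0)
  expect_equal(yules_index(random, "Y"), 0)

  mixed <- mating_table(matrix(c(20, 5, 5, 20), 2))
  expect_equal(yules_index(mixed, "Q"), 375 / 425, tolerance = 1e-12)
  expect_equal(yules_index(mixed, "Y"), 15 / 25, tolerance = 1e-12)

  degenerate <- mating_table(matrix(c(3, 0, 0, 0), 2))
  expect_error(yules_index(degenerate), "degenerate")
})

test_that("Yule's indices obey the label-swap symmetries", {
  set.seed(21)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    both <- tab[2:1, 2:1]     # swap rows and columns together
    one <- tab[2:1, ]         # swap only rows
    for (v in c("Q", "Y")) {
      expect_equal(yules_index(tab, v), yules_index(both, v))
      expect_equal(yules_index(tab, v), -yules_index(one, v))
    }
    expect_lte(abs(yules_index(tab, "Y")),
               abs(yules_index(tab, "Q")) + 1e-12)
  }
})

test_that("Fisher exact p-values agree with hypergeometric enumeration", {
  t1 <- mating_table(matrix(1, 2, 2))
  expect_equal(fisher_exact_2x2(t1)$p_value, 1)

  t2 <- mating_table(matrix(c(2, 0, 0, 2), 2))
  expect_equal(fisher_exact_2x2(t2, "greater")$p_value, 1 / 6,
               tolerance = 1e-12)

  set.seed(33)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab, "greater")$p_value,
                 fisher_greater_oracle(tab), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab, "two.sided")$p_value,
                 fisher_twosided_oracle(tab), tolerance = 1e-12)
    # transposition invariance
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 fisher_exact_2x2(t(tab))$p_value, tolerance = 1e-12)
  }

  zero_margin <- mating_table(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  res <- fisher_exact_2x2(zero_margin)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$odds_ratio))
})

test_that("mating tables round-trip through TSV and pool repeated cells", {
  tab <- mating_table(matrix(c(14L, 3L, 2L, 11L), 2,
                             dimnames = list(female = c("A", "H1"),
                                             male = c("A", "H1"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mating_tsv(tab, path)
  back <- read_mating_tsv(path)
  expect_equal(unclass(back)[, ], unclass(tab)[, ])

  # per-cage rows accumulate into the pooled table
  d <- utils::read.delim(path)
  utils::write.table(rbind(d, d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pooled <- read_mating_tsv(path)
  expect_equal(sum(pooled), 2 * sum(tab))
})

test_that("assortative mating report combines the statistics coherently", {
  tab <- mating_table(matrix(c(20L, 5L, 5L, 20L), 2))
  rep_tab <- assortative_mating_report(tab)
  expect_equal(rep_tab$yule_Q, 375 / 425, tolerance = 1e-12)
  expect_equal(rep_tab$n_pairs, 50)
  expect_equal(rep_tab$n_homotypic, 40)
  expect_lt(rep_tab$fisher_p, 0.001)
})

test_that("chasing-time reader enforces the assay bounds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(trial_id = c("t1", "t2"), setup = c("ExE", "AxA"),
                  chasing_time = c(100, 901))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_chasing_tsv(path), "out of")
  d$chasing_time <- c(100, 900)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_chasing_tsv(path)), 2)
})
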