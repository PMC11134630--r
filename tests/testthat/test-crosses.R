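make_sheet <- function(within_counts, between_counts, pops = c("P1", "P2", "P3")) {
  # within_counts / between_counts: one vector of vial counts per cross type
  rows <- list()
  wi <- 0L; bi <- 0L
  for (s in pops) for (d in pops) {
    if (s == d) { wi <- wi + 1L; v <- within_counts[[wi]] }
    else { bi <- bi + 1L; v <- between_counts[[bi]] }
    rows[[length(rows) + 1L]] <- data.frame(
      sire_pop = s, dam_pop = d, vial_id = seq_along(v),
      progeny_count = v, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("diallel_sheet", class(out))
  out
}

test_that("cross-type means reduce to brute-force group averages", {
  d <- simulate_diallel(sim_config(seed = 12), n_vials = 7)
  ctm <- cross_type_means(d)
  for (i in seq_len(nrow(ctm$cross_means))) {
    r <- ctm$cross_means[i, ]
    sel <- d$progeny_count[d$sire_pop == r$sire_pop & d$dam_pop == r$dam_pop]
    expect_equal(r$mean, mean(sel))
    expect_equal(r$n_vials, 7L)
  }
  expect_equal(ctm$within_mean,
               mean(d$progeny_count[d$sire_pop == d$dam_pop]))

  # all counts equal: deficit exactly zero
  eq <- make_sheet(rep(list(rep(9, 5)), 3), rep(list(rep(9, 5)), 6))
  expect_equal(cross_type_means(eq)$deficit, 0)

  # within mean 24, between mean 22: the study's direction, -8.33%
  fix <- make_sheet(rep(list(rep(24, 5)), 3), rep(list(rep(22, 5)), 6))
  expect_equal(cross_type_means(fix)$deficit, -2 / 24, tolerance = 1e-12)

  # deficit is invariant to rescaling every count
  fix2 <- fix; fix2$progeny_count <- fix2$progeny_count * 3.5
  expect_equal(cross_type_means(fix2)$deficit, -2 / 24, tolerance = 1e-12)

  missing <- fix[!(fix$sire_pop == "P1" & fix$dam_pop == "P2"), ]
  expect_error(cross_type_means(missing), "P1 x P2")
})

test_that("mid-parent expectations and flags follow the parental means", {
  sheet <- make_sheet(list(rep(20, 5), rep(10, 5), rep(30, 5)),
                      list(rep(14, 5), rep(26, 5), rep(16, 5),
                           rep(27, 5), rep(18, 5), rep(25, 5)))
  mp <- midparent_test(sheet)
  p12 <- mp[mp$pop1 == "P1" & mp$pop2 == "P2", ]
  expect_equal(unique(p12$midparent), 15)
  pooled <- p12[p12$direction == "pooled", ]
  # reciprocals are P1xP2 = 14 and P2xP1 = 16
  expect_equal(pooled$observed_mean, 15)
  expect_false(p12$exceeds[p12$direction == "P1 x P2"])   # 14 < 15
  expect_true(p12$exceeds[p12$direction == "P2 x P1"])    # 16 > 15
  # pooled observed equals the mean of reciprocal means
  for (pair in split(mp, paste(mp$pop1, mp$pop2))) {
    expect_equal(pair$observed_mean[pair$direction == "pooled"],
                 mean(pair$observed_mean[pair$direction != "pooled"]))
  }
  # vial order must not matter
  shuffled <- sheet[sample(nrow(sheet)), ]
  class(shuffled) <- class(sheet)
  expect_equal(midparent_test(shuffled)$exceeds, mp$exceeds)
})

test_that("exact one-tailed Wilcoxon matches enumeration and wilcox.test", {
  # complete separation 3 vs 6: p = 1 / choose(9, 3)
  res <- wilcoxon_one_tailed(c(10, 9, 8), c(7, 6, 5, 4, 3, 2))
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 84, tolerance = 1e-12)

  # reversed direction on the same data sits at the other end
  res_l <- wilcoxon_one_tailed(c(10, 9, 8), c(7, 6, 5, 4, 3, 2),
                               alternative = "less")
  expect_equal(res_l$p_value, 1, tolerance = 1e-12)

  # untied samples: agree with the exact distribution in wilcox.test
  set.seed(5)
  for (i in 1:25) {
    w <- sample(seq(1, 199, by = 2), 4)   # odd values
    b <- sample(seq(2, 200, by = 2), 6)   # even values: no cross-ties
    ours <- wilcoxon_one_tailed(w, b)$p_value
    ref <- stats::wilcox.test(w, b, alternative = "greater",
                              exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }

  # ties: enumeration over midranks equals a direct permutation scan
  w <- c(5, 5, 4); b <- c(5, 4, 3, 3)
  ours <- wilcoxon_one_tailed(w, b)
  r <- rank(c(w, b))
  sets <- utils::combn(7, 3)
  Ws <- colSums(matrix(r[sets], nrow = 3))
  expect_equal(ours$p_value, mean(Ws >= ours$statistic - 1e-9),
               tolerance = 1e-12)

  expect_true(wilcoxon_one_tailed(c(3, 3), c(3, 3, 3))$degenerate)
  expect_error(wilcoxon_one_tailed(numeric(0), 1:3), "nonempty")

  # large samples switch to the normal approximation coherently
  set.seed(8)
  w2 <- rnorm(30, 0.8); b2 <- rnorm(40)
  appr <- wilcoxon_one_tailed(w2, b2)
  expect_false(appr$exact)
  ref2 <- stats::wilcox.test(w2, b2, alternative = "greater",
                             exact = FALSE, correct = TRUE)$p.value
  expect_equal(appr$p_value, ref2, tolerance = 1e-10)
})

test_that("diallel wilcoxon supports both analysis units", {
  d <- simulate_diallel(sim_config(seed = 44, diallel_within_advantage = 0.5),
                        n_vials = 5)
  by_mean <- diallel_wilcoxon(d, "cross_mean")
  expect_equal(by_mean$unit, "cross_mean")
  expect_true(by_mean$exact)          # 3 + 6 = 9 values
  by_vial <- diallel_wilcoxon(d, "vial")
  expect_false(by_vial$exact)         # 15 + 30 values
  expect_lt(by_mean$p_value, 0.05)
})

test_that("crossing-scheme permutation enumerates the 84 assignments", {
  # observed assignment is the unique maximum: p = 1/84
  sep <- make_sheet(list(rep(30, 4), rep(29, 4), rep(28, 4)),
                    lapply(21:26, function(x) rep(x, 4)))
  perm <- crossing_scheme_permutation(sep, n_perm = 1000)
  expect_true(perm$exact)
  expect_equal(perm$n_used, 84)
  expect_equal(perm$p_value, 1 / 84, tolerance = 1e-12)
  # exact permutation p agrees with the exact rank test decision direction
  expect_equal(perm$p_value,
               diallel_wilcoxon(sep)$p_value, tolerance = 1e-12)

  expect_error(crossing_scheme_permutation(sep, n_perm = 0), "positive")

  # label-invariant data: p is not extreme systematically
  set.seed(71)
  ps <- replicate(300, {
    sheet <- simulate_diallel(sim_config(seed = sample.int(1e6, 1),
                                         diallel_within_advantage = 0),
                              n_vials = 4)
    crossing_scheme_permutation(sheet, n_perm = 1000)$p_value
  })
  expect_gt(mean(ps <= 5 / 84), 0.02)
  expect_lt(mean(ps <= 5 / 84), 0.11)
})
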