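test_that("CPM and the expression filter match a brute-force scan", {
  m <- tiny_counts()
  m$lib_sizes <- c(2e6, rep(1e6, 5))
  cp <- cpm(m)
  expect_equal(cp["g1", 1], 5)                   # 10 reads in 2e6 -> CPM 5
  expect_equal(cp["g2", 3], 300)

  f <- cpm_filter(m, 0.1)
  keep_oracle <- apply(sweep(m$counts, 2, m$lib_sizes, "/") * 1e6 > 0.1,
                       1, all)
  expect_equal(rownames(f$counts), names(which(keep_oracle)))
  expect_false("g3" %in% rownames(f$counts))     # zero-count sample
  expect_error(cpm_filter(m, -1), ">= 0")
})

test_that("count_matrix validates structure", {
  expect_error(tiny_counts(rbind(g1 = c(-1, 0, 0, 0, 0, 0))), "nonnegative")
  meta <- data.frame(sample_id = "s1", replicate = "R1", group = "evolved")
  expect_error(count_matrix(matrix(1, 1, 2), meta), "meta rows")
  expect_error(count_matrix(matrix(1, 1, 1),
                            data.frame(sample_id = "s1", replicate = "R1",
                                       group = "weird")), "group")
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  # Poisson data: dispersion collapses towards zero
  cfg <- sim_config(seed = 2, n_genes = 120, nb_dispersion = 1e-8,
                    replicate_lfc_sd = 0)
  simp <- simulate_counts(cfg, n_samples_per_replicate = 20,
                          n_ancestral_samples = 2)
  dp <- estimate_dispersion(cpm_filter(simp$matrix, 0.1))
  expect_lte(dp$common, 0.01)
  expect_lte(median(dp$shrunk), 0.01)

  # constant counts: no variability at all
  const <- count_matrix(matrix(7L, 5, 6),
                        data.frame(sample_id = paste0("s", 1:6),
                                   replicate = rep(c("R1", "R2"), 3),
                                   group = "evolved"),
                        lib_sizes = rep(1e6, 6))
  dc <- estimate_dispersion(const)
  expect_equal(dc$common, 0)

  # phi = 0.2 recovered at 50 genes x 20 samples
  cfg2 <- sim_config(seed = 9, n_genes = 50, nb_dispersion = 0.2,
                     replicate_lfc_sd = 0)
  sim2 <- simulate_counts(cfg2, n_samples_per_replicate = 2,
                          n_ancestral_samples = 2)
  d2 <- estimate_dispersion(sim2$matrix)
  expect_gt(median(d2$shrunk), 0.1)
  expect_lt(median(d2$shrunk), 0.3)
})

test_that("divergence LRT agrees with edgeR at matched dispersion", {
  cfg <- sim_config(seed = 18, n_genes = 120)
  sim <- simulate_counts(cfg, n_samples_per_replicate = 3)
  f <- cpm_filter(sim$matrix, 0.1)
  phi <- estimate_dispersion(f)$common
  ours <- divergence_lrt(f, phi)

  suppressPackageStartupMessages(library(edgeR))
  evo <- f$meta$group == "evolved"
  y <- f$counts[, evo]
  design <- stats::model.matrix(~ factor(f$meta$replicate[evo]))
  fit <- glmFit(y, design, dispersion = phi,
                offset = log(f$lib_sizes[evo]), prior.count = 0)
  lrt <- glmLRT(fit, coef = 2:ncol(design))
  expect_gt(stats::cor(ours$stat, lrt$table$LR), 0.9999)
  expect_lt(max(abs(ours$p - lrt$table$PValue)), 1e-4)
})

test_that("divergence LRT finds a strongly shifted replicate", {
  # one gene, one replicate shifted 4-fold, low dispersion
  set.seed(30)
  detected <- replicate(40, {
    R <- 4; nper <- 3
    mu <- matrix(100, 1, R * nper + 2)
    mu[1, 1:nper] <- 400
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / 0.05),
                     1, dimnames = list("g1", NULL))
    meta <- data.frame(
      sample_id = paste0("s", seq_len(ncol(counts))),
      replicate = c(rep(paste0("R", 1:R), each = nper), "anc", "anc"),
      group = c(rep("evolved", R * nper), "ancestral", "ancestral"))
    m <- count_matrix(counts, meta, lib_sizes = rep(1e6, ncol(counts)))
    divergence_lrt(m, 0.05)$p < 0.05
  })
  expect_gt(mean(detected), 0.9)
})

test_that("LRT is invariant to sample order and library rescaling", {
  cfg <- sim_config(seed = 77, n_genes = 60)
  sim <- simulate_counts(cfg)
  f <- cpm_filter(sim$matrix, 0.1)
  base <- divergence_lrt(f, 0.2)

  perm <- sample(ncol(f$counts))
  f2 <- count_matrix(f$counts[, perm], f$meta[perm, ], f$lib_sizes[perm])
  expect_equal(divergence_lrt(f2, 0.2)$stat, base$stat, tolerance = 1e-6)

  f3 <- f; f3$lib_sizes <- f$lib_sizes * 7
  expect_equal(divergence_lrt(f3, 0.2)$stat, base$stat, tolerance = 1e-6)
})

test_that("BH q-values follow the step-up construction", {
  p <- c(0.01, 0.02, 0.04, 0.05)
  expect_equal(stats::p.adjust(p, "BH"), c(0.04, 0.04, 0.05, 0.05))
  cfg <- sim_config(seed = 3, n_genes = 80)
  sim <- simulate_counts(cfg)
  div <- divergence_lrt(cpm_filter(sim$matrix, 0.1), 0.2)
  ord <- order(div$p)
  expect_true(all(diff(div$q[ord]) >= -1e-12))   # monotone in sorted p
  expect_true(all(div$q >= div$p - 1e-12))
})

test_that("per-replicate changes quantify shifts against the ancestors", {
  m <- tiny_counts()
  prc <- per_replicate_change(m, dispersion = 0.05, pseudo_cpm = 1e-9)
  # g2: R2 mean 305 vs ancestral mean 100 -> log2FC ~ log2(3.05)
  expect_equal(prc$lfc["g2", "R2"], log2(305 / 100), tolerance = 1e-9)
  expect_lt(abs(prc$lfc["g1", "R1"]), 0.3)
  expect_equal(prc$direction["g2", "R2"], "up")
  expect_equal(prc$direction["g1", "R1"], "none")

  no_anc <- m
  no_anc$meta$group <- "evolved"
  no_anc$meta$replicate <- c("R1", "R1", "R2", "R2", "R3", "R3")
  expect_error(per_replicate_change(no_anc), "ancestral")
})

test_that("injected replicate shifts are recovered with high sensitivity", {
  # enough set genes and strong enough shifts for stable rate estimates
  cfg <- sim_config(seed = 55, n_genes = 4000, replicate_lfc_sd = 2)
  sim <- simulate_counts(cfg)
  f <- cpm_filter(sim$matrix, 0.1)
  disp <- estimate_dispersion(f)
  prc <- per_replicate_change(f, disp$common)
  truth <- sim$truth$replicate_lfc[rownames(f$counts), ]
  called <- prc$direction != "none"
  # sensitivity over injected shifts large enough to clear the lfc gate
  # (call threshold 1 plus ~2 sd of fold-change noise at n = 3)
  strong <- abs(truth) > 2
  expect_gt(mean(called[strong]), 0.8)
  # false-call rate among true-null gene-replicate cells
  null_cells <- truth == 0
  fdr <- sum(called & null_cells) / max(1, sum(called))
  expect_lt(fdr, 0.1)
  # directions match the injected signs where both call and truth exist
  agree <- prc$direction[called & strong] ==
    ifelse(truth[called & strong] > 0, "up", "down")
  expect_gt(mean(agree), 0.95)
})

test_that("count tables round-trip through TSV", {
  sim <- simulate_counts(sim_config(seed = 61, n_genes = 40))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sim$matrix, cpath, mpath)
  back <- read_counts_tsv(cpath, mpath)
  expect_equal(back$counts, sim$matrix$counts)
  expect_equal(back$lib_sizes, sim$matrix$lib_sizes)
  expect_equal(back$meta$replicate, sim$matrix$meta$replicate)
})
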