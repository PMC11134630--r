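# evoiso

Statistical analysis of pre- and postmating reproductive isolation in
replicated evolution experiments.

When ten replicate fly populations adapt independently to the same
novel environment, two questions follow. Do the evolved populations
become reproductively isolated from their ancestors (ecological
speciation: mate discrimination, diverged cuticular-hydrocarbon
profiles)? And do the replicates become isolated from *each other*,
despite identical selection (mutation-order speciation or system
drift: reduced hybrid fitness, replicate-specific evolution of
reproduction genes)? `evoiso` implements the statistical toolkit for
both questions, end to end, for researchers running replicated
experimental evolution with behavioural, chemical and transcriptomic
readouts.

## What it computes

- **Mate choice** — Yule's association indices on 2×2 mating-pair
  tables, `Q = (ad−bc)/(ad+bc)` and the coefficient of colligation
  `Y = (√ad−√bc)/(√ad+√bc)`; Fisher's exact test; Kruskal–Wallis
  chasing-time comparisons with BH-adjusted Mann–Whitney post-hocs and
  compact letter displays.
- **CHC composition** — closure and centred log-ratio transform, PCA
  with a deterministic sign convention, per-compound two-way
  (sex × evolution) type-II ANOVA.
- **Diallel crosses** — per-cross means, within- vs between-replicate
  progeny deficit, mid-parent expectations, an exact tie-aware
  one-tailed Wilcoxon rank-sum test, and a design-respecting
  permutation test for the crossing scheme.
- **Expression divergence** — CPM filtering, negative-binomial GLMs
  with Cox–Reid dispersion estimation, likelihood-ratio tests for an
  among-replicate factor (`expression = replicate + error`), BH FDR,
  and per-replicate log2 fold-change attribution.
- **Heterogeneity** — the replicate-pair statistic
  `H = Σ_{i<j} (1 − cor(x_i, x_j))/N` over per-replicate
  expression-change vectors, with gene-bootstrap and size-matched
  random-set nulls, plus an up-regulation direction-bias test.
- **Enrichment** — Fisher over-representation of GMT-like gene sets
  and strict-twofold tissue-specificity classification.
- **Synthetic data** — seeded generators for all four modalities
  (sequential mate-choice cages, logistic-normal compositions, Poisson
  diallels, NB counts with shared plus replicate-specific shifts), so
  every analysis has parameter-recovery tests with no raw data.

## Worked example

```r
library(evoiso)
cfg <- sim_config(seed = 2024, preference = 4)   # homotypic weight 4

## premating: a mate-choice cage, 50 + 50 flies per sex, 25 pairs
tab <- simulate_choice_assay(cfg)
tab
#>       male
#> female  A B
#>      A 10 4
#>      B  4 7
assortative_mating_report(tab)[, c("yule_Y", "yule_Q", "fisher_p")]
#>   yule_Y  yule_Q  fisher_p
#>    0.353   0.628     0.116

## postmating: 3-population diallel, 5 vials per cross
d <- simulate_diallel(cfg)
ctm <- cross_type_means(d)
c(within = ctm$within_mean, between = ctm$between_mean,
  deficit_pct = 100 * ctm$deficit)
#>   within  between  deficit_pct
#>     27.1     23.6        -12.9
diallel_wilcoxon(d)$p_value        # exact, 3 vs 6 cross means
#> [1] 0.0476

## replicate-divergent expression, 2000 genes, 10 replicates
sim <- simulate_counts(cfg)
f <- cpm_filter(sim$matrix, 0.1)
disp <- estimate_dispersion(f)
div <- divergence_lrt(f, disp$common)
c(tested = sum(div$converged), divergent = sum(div$divergent))
#>    tested divergent
#>      1964        17

## heterogeneity of the reproduction gene set
prc <- per_replicate_change(f, disp$common)
h <- compare_gene_sets(prc$lfc, sim$gene_sets$reproduction,
                       n_boot = 200, n_random = 1000, seed = 1)
round(h$H[c("focal", "background")], 3); h$focal_quantile
#>      focal background
#>      0.752      0.593
#> [1] 1
```

Reading the output: with a homotypic preference of 4 this cage shows
positive but non-significant assortative mating (`Y = 0.35`, Fisher
`p = 0.12` at 25 pairs — the assay is small). The diallel's
between-replicate crosses produced 12.9% fewer progeny than
within-replicate crosses, significant at the exact one-tailed Wilcoxon
resolution limit (`p = 4/84 = 0.0476`). Of 1,964 expressed genes, 17
diverge among replicates at FDR 0.05, and the designated reproduction
set evolved more heterogeneously (`H = 0.75`) than the genome-wide
background (`H = 0.59`), exceeding all 1,000 size-matched random sets.

The full chain (simulate → analyse → report, with TSV/JSON outputs) is
one call, or a shell command via the bundled wrapper:

```r
run_pipeline(pipeline_config(), out_dir = "out", seed = 1)
```

```sh
Rscript inst/cli/evoiso.R all --seed 1 --out out
```

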