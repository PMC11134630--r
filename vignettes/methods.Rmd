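---
title: "Statistical methods for replicated reproductive-isolation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for replicated reproductive-isolation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoiso)
```

## Scope

`evoiso` analyses reproductive isolation in replicated evolution
experiments of the kind run with *Drosophila*: ten or so replicate
populations founded from one polymorphic source, evolving independently
under a common selective regime, assayed against each other and against
reconstituted ancestral populations. Four data modalities are covered —
mate-choice pair counts, cuticular-hydrocarbon (CHC) composition
profiles, diallel-cross progeny counts, and RNA-seq count matrices —
each with its own analysis module and a matching synthetic-data
generator, so that every statistical claim the package makes can be
tested by parameter recovery without any raw data.

The pipeline deliberately starts downstream of instrument-specific
processing: chasing times come from behavioural annotation, CHC
relative abundances from chromatogram deconvolution, and counts from
read quantification. None of those upstream steps is in scope.

## Premating isolation

Mate-choice cages are summarised as 2x2 tables of pair counts indexed
by (female population, male population). Assortative mating is
quantified by Yule's association measures over the homotypic cells
`a, d` and heterotypic cells `b, c`:

$$Q = \frac{ad - bc}{ad + bc}, \qquad
  Y = \frac{\sqrt{ad} - \sqrt{bc}}{\sqrt{ad} + \sqrt{bc}},$$

both in $[-1, 1]$ with positive values meaning homotypic excess. The
field's literature uses "Yule's index (Y)" for the coefficient of
colligation, so `Y` is the default variant; `Q` is always reported
alongside because it is the more widely recognised form. Hypothesis
testing uses Fisher's exact conditional test; tables pooled over cages
are the default, with per-cage breakdowns retained by the reader.

Chasing-time comparisons across assay setups use the Kruskal-Wallis
rank test with midrank tie correction. The post-hoc display is
all-pairwise two-sided Mann-Whitney tests, BH-adjusted at 0.05,
rendered as compact letters by an insert-and-absorb assignment. The
post-hoc procedure is deliberately conventional plumbing: no specific
post-hoc method is canonical for this assay, and any procedure that
shares letters exactly between non-significant pairs would do.

## CHC composition

Relative-abundance profiles are compositions: only ratios carry
information, so all inference runs on centred log-ratios,
$\mathrm{clr}_i = \ln c_i - \overline{\ln c}$. Natural logarithms are
used; the base only rescales the transform. Zeros are handled
multiplicatively — each zero becomes 0.65 times the sample's smallest
positive fraction and the composition is re-closed — because absent
compounds (below detection) are a routine feature of real tables. PCA
is restricted to compounds detected in every sample (a completeness
filter mirroring the usual "detected in all samples" rule), is
column-centred without rescaling, and fixes each component's sign so
its largest-magnitude loading is positive, making scores reproducible
across platforms.

Per-compound inference is a two-way ANOVA (sex, evolution, and their
interaction) with type-II sums of squares. It runs on CLR values by
default for compositional coherence; a raw-percentage mode is retained
because published compound tables are frequently analysed on raw
percentages and the choice is not always documented. The synthetic
generator draws logistic-normal compositions with additive log-scale
sex and evolution effects and no interaction, which makes the expected
pattern checkable: the dominant injected effect owns PC1, the secondary
effect owns PC2, and interaction p-values are uniform. Passing this
says the machinery recovers additive structure from compositional
noise; it does not certify any claim about real chromatograms, where
peak co-elution and detection limits induce structured, non-log-normal
error.

## Diallel crosses

The compatibility assay is a full factorial (diallel) cross of three
replicate populations with five vials per ordered cross. The module
reports per-cross means, the pooled within- versus between-replicate
contrast and its relative deficit $(\bar y_{between} -
\bar y_{within})/\bar y_{within}$, and mid-parent expectations
$\tfrac12(\bar y_{A \times A} + \bar y_{B \times B})$ per unordered
pair, with reciprocal directions kept separate and pooled.

The within/between test is a one-tailed Wilcoxon rank-sum test (null:
within-replicate crosses produce no more progeny). For pooled sizes up
to 12 the p-value comes from complete enumeration of midrank
assignments, which stays exact under ties; the 3-versus-6 cross-mean
layout has $\binom{9}{3} = 84$ assignments, so complete separation
yields $p = 1/84 \approx 0.0119$, the resolution limit of the design.
Larger samples use the normal approximation with tie and continuity
corrections. In place of a mixed-effects model for the crossing-scheme
dependency (crosses sharing a parental population are correlated), the
package uses a design-respecting permutation test: within/between
labels are permuted over cross types, enumerated completely when
feasible. This keeps the same inferential role with assumptions the
design actually satisfies, at the cost of the mixed model's variance
decomposition. Vial-level and cross-mean-level units are both
supported because published analyses are often ambiguous about which
entered the test.

## Expression divergence across replicates

Counts are filtered at CPM > 0.1 in every sample, then modelled per
gene as negative binomial with log link and log-library-size offsets
(variance $\mu + \phi\mu^2$). The divergence test compares a
replicate-factor model against an intercept-only model among evolved
samples by likelihood ratio, $\chi^2$ with $R - 1$ degrees of freedom,
BH-corrected at FDR 0.05. Only evolved male-type samples enter this
test; ancestral samples serve solely as the baseline for per-replicate
log2 fold-changes (pseudo-count 0.5 CPM). A gene is called "changed"
in a replicate when its |log2FC| versus the ancestral mean exceeds 1
and its replicate-versus-rest NB contrast is BH-significant at 0.05 —
an explicit operationalisation of per-replicate attribution, which has
no canonical definition.

Dispersion is estimated in two stages. The common dispersion maximises
the pooled Cox-Reid adjusted profile likelihood; the adjustment
(half the log Fisher information of each fitted group mean) matters —
the unadjusted profile is biased low by roughly a third at ten groups
of three samples, which would inflate the LRT badly. Per-gene
dispersions come from empirical-Bayes weighted-likelihood shrinkage on
a grid around the common value with prior df 10. Inference defaults to
the **common** dispersion: with a dispersion-homogeneous generator it
is the correctly specified model and the LRT holds its nominal size
(measured 0.050 at 10,000 null genes), whereas per-gene shrunk values
buy robustness to dispersion heterogeneity at the price of mild size
inflation. Analyses of real data with visible mean-dispersion trends
should pass `estimate_dispersion(m)$shrunk` explicitly. Normalisation
is by library-size offsets only; trimmed-mean scaling factors are out
of scope and results are therefore invariant to global depth rescaling
but not to severe composition bias.

## Heterogeneity of expression evolution

For a gene set, let $x_i$ be the vector of per-replicate expression
changes over the set's genes. The heterogeneity statistic is the mean
pairwise correlation distance

$$H = \sum_{i<j} \bigl(1 - \mathrm{cor}(x_i, x_j)\bigr) / N,
  \qquad N = \binom{R}{2},$$

with Pearson correlation by default (Spearman available) and $N = 45$
unordered pairs at $R = 10$; ordered pairs would double both numerator
and count and leave $H$ unchanged, so the unordered count is reported.
"Expression change" is the per-replicate log2 fold-change versus the
ancestral mean; a raw-expression mode is retained because both
phrasings circulate for this statistic. $H \in [0, 2]$: 0 for
replicates changing in lockstep, 1 for uncorrelated change, towards 2
for antagonistic change.

A single $H$ per set has no sampling distribution of its own, so
set-level comparison is built from two resampling constructions: a
within-set gene bootstrap (distributional spread of each set's $H$)
and, as the primary evidence, the empirical quantile of the focal
set's $H$ among size-matched random sets drawn from the background.
A focal quantile above 0.99 of 1,000 random sets is the package's
criterion for "evolved more heterogeneously than background".
Direction bias within a set is the fraction of "changed" calls that
are up-regulations, with an exact binomial test against 0.5 and a
Fisher 2x2 against the background set.

## Gene-set over-representation and tissue specificity

Over-representation of annotation sets among divergent genes uses
Fisher's exact test (one-sided by default — over-representation is the
directional question), the sample odds ratio with a Haldane-Anscombe
0.5 correction when a cell is empty, and BH correction across tested
sets. Graph-aware GO decorrelation algorithms are out of scope; sets
are plain GMT-like files so tests run on synthetic ontologies offline.
Tissue-specific sets follow a strict rule: a gene belongs to a
tissue iff its expression there strictly exceeds twice its whole-body
expression.

## The synthetic-data generator

The generator's defaults are the emulated study's conditions: 10
replicate populations; choice cages of 50 flies per sex per population
scored to 25 pairs; 12 CHC compounds; diallel of 3 populations with 5
vials per cross; NB counts with dispersion 0.2 over 2,000 genes with 3
evolved samples per replicate and 6 ancestral samples. Pair formation
is female-initiated: a uniformly drawn free female takes a free male
with weight `preference` (homotypic) versus 1 (heterotypic), without
replacement — the assay defines no mechanism, and any exchangeable
single-weight scheme is equivalent for the statistics computed here.
Progeny counts are Poisson with a multiplicative within-replicate
advantage; the default advantage 0.09 corresponds to a between-cross
deficit of $1 - 1/1.09 \approx 8.3\%$, the magnitude reported for this
kind of assay. Replicate-specific expression shifts hit only the
designated "reproduction" set (5% of genes), in 1 or 2 replicates per
gene (uniform), positive with probability `up_bias` (default 0.9);
shared adaptive shifts are N(0, 0.2) log2 across all evolved samples.
Gaussian log-scale noise, log-normal depth factors and a single global
seed threaded to all substreams complete the model. The generator does
not emulate: courtship dynamics in time (no censoring-time model — the
assay's two-hour cut-off is represented only by `max_pairs`),
mean-dispersion trends, compositional peak co-elution, or linkage
between modalities. Tests passing on this generator demonstrate
correctness of the statistical machinery under the stated model, not
robustness to those unmodelled features.

## Numerical choices and problem sizes

NB group means are fitted by per-gene Newton iterations on the
intercept score equation (steps clamped to ±5, tolerance 1e-10,
empty groups pinned at a log-mean of −30); LRT statistics are floored
at 0, and non-converged genes are flagged and excluded from the BH
family. The dispersion grid spans $2^{\pm 8}$ around the common value
in 25 log-spaced points. CLR zero replacement uses the 0.65 factor
standard in compositional practice. Exact Wilcoxon enumeration is the
default up to a pooled size of 12 (924 assignments at worst).
Permutation tests switch to complete enumeration whenever the number
of assignments is below the requested permutation count, making small
designs exact.

Test-suite problem sizes are chosen to make Monte-Carlo error small
relative to the asserted bands: calibration checks use 10,000
replicates per test (binomial SE ~0.002 at a size of 0.05), parameter
recovery uses 600-simulation grids for mate-choice preference, 4,000
vials per cross for the diallel deficit, and 2,000-4,000-gene count
matrices; the acceptance script runs the full pipeline at the default
study scale in seconds.

## Known limitations

Exact reproduction of any specific published analysis is not the goal:
raw data, normalisation details and post-hoc procedures of individual
studies are generally under-documented, and several of this package's
rules (per-replicate change attribution, the heterogeneity set
comparison, the permutation replacement for a mixed model) are
explicit constructions where the field's practice is ambiguous. The
NB machinery agrees with edgeR's LRT to ~1e-4 in p at matched
dispersion (checked in the test suite) but is not a drop-in numerical
clone; trimmed-mean normalisation, mean-dispersion trends and
quasi-likelihood moderation are deliberately absent.
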