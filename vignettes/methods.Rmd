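---
title: "Methods: factorial soil-ecotoxicology analysis with soilsorb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial soil-ecotoxicology analysis with soilsorb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(soilsorb)
```

## The experimental design

`soilsorb` analyses two-factor greenhouse experiments in which soil is
contaminated with one heavy metal — copper (Cu), nickel (Ni), or zinc
(Zn) — or left uncontaminated (C0), and simultaneously amended with one
of six sorbents (molecular sieve, halloysite, sepiolite, expanded clay,
biochar, zeolite) or left unamended (control). The full cross gives
4 × 7 = 28 treatment cells. Responses span four families: culturable
microbial counts (organotrophic bacteria, actinobacteria, fungi), seven
soil-enzyme activities, sunflower yield (shoots, roots), and leaf
greenness (SPAD).

`experiment_design()` encodes the factor levels, response families, and
per-family replicate counts; `greenhouse_design()` returns the reference
layout (4 replicates for microbial counts, 3 for enzymes and yield, 8
for SPAD). `measurement_table()` validates tidy long data against a
design — unknown levels, non-finite or negative values, and
replicate-count mismatches are all rejected with an error that names the
offending cells, so malformed sheets fail loudly rather than silently
unbalancing the ANOVA.

## Ecological indices

Two indices summarise a 10-day colony-emergence profile
$N_1, \dots, N_{10}$ (colonies first appearing on each day; the
day-$d$ fraction is $p_d = N_d / \sum_i N_i$):

* **Colony development** $CD = 100 \sum_d p_d / d$. It is bounded in
  $[100/D,\ 100]$ for a $D$-day assay and is largest when all colonies
  emerge on day one, i.e. when the community is dominated by
  fast-growing r-strategists. The package deliberately computes it from
  the day fractions, which makes the index scale-invariant in the total
  colony count — only the *timing* of emergence matters.
* **Ecophysiological diversity** $EP = -\sum_d p_d \log_{10} p_d$,
  a Shannon-type evenness of emergence timing bounded in
  $[0,\ \log_{10} D]$ ($= 1$ for $D = 10$). Terms with $p_d = 0$
  contribute zero.

Both are implemented as direct summations; the test suite checks them
against independently coded loop oracles to $10^{-12}$ over 1000 random
profiles, and checks the closed-form values of degenerate profiles
(all colonies on day one, all on day ten, a perfectly uniform profile).

## Impact factors

Treatment effects are expressed as relative impact factors
$IF = a_{\text{treated}} / a_{\text{reference}} - 1$, computed on cell
means:

* $IF_{HM}$ measures the metal effect: the reference is the
  uncontaminated cell *with the same sorbent*.
* $IF_{Ad}$ measures the sorbent effect: the reference is the
  unamended cell *with the same metal*.

`index_matrices()` returns both as 7 × 4 (sorbent × metal) matrices with
`NA` in the reference column/row; multiply by 100 (or pass
`percent = TRUE`) for percentages. A zero or negative reference mean is
an error, not an `Inf` — ratios to a non-positive abundance are
scientifically meaningless here.

## Inference

`ms_anova()` is the core fitting function, following the classic R
modelling idiom: it returns a classed object with `print`, `summary`,
`coef`, `fitted`, `residuals`, `predict`, `plot`, and `simulate`
methods. Internally it wraps `stats::aov(value ~ contaminant * sorbent)`
on a *balanced* table (balance is checked; with equal cell sizes the
sequential decomposition is unique, so no sum-of-squares-type ambiguity
arises). It reports:

* the ANOVA table with **η² effect contributions**, defined as each
  term's share of the total sum of squares in percent; the four shares
  (metal, sorbent, interaction, error) sum to 100 by construction;
* **Tukey HSD compact letter displays** at three levels: the 28
  treatment cells, the 7 sorbent margins, and the 4 metal margins (the
  marginal displays come from one-way ANOVAs on the corresponding
  margin, matching the way such tables are conventionally annotated).

Tukey p-values are computed from the studentized-range distribution
(`stats::ptukey`) on the upper triangle of the pairwise
mean-difference matrix only, then mirrored — with 28 groups this
halves the dominant cost of simulation studies. The letter display is
built by an insert-and-absorb algorithm with the letter "a" anchored on
the largest mean. Its defining contract — two groups share a letter *if
and only if* their difference is non-significant — is verified
exhaustively in the tests against random p-matrices and a brute-force
minimal-clique-cover oracle.

Assumptions are the usual ones for fixed-effects ANOVA: independent,
homoscedastic, approximately normal errors within cells. Residual
diagnostics are available through `residuals()` and `plot()`.

## Multivariate summaries

* `pearson_matrix()` computes the full Pearson correlation matrix with
  t-test p-values and an `alpha`-level significance mask.
* `ms_pca()` wraps `prcomp(center = TRUE, scale. = TRUE)` and reports
  explained-variance percentages. Because the sign of each component is
  arbitrary, loadings are anchored so the largest-magnitude loading of
  each component is positive, making results reproducible across
  platforms.
* `cluster_heatmap()` clusters an impact matrix by Euclidean distance
  and complete linkage (both configurable) on rows and columns, drops
  all-`NA` reference lines first, and optionally renders via
  `pheatmap`.

## The synthetic generator

`generator_config()` + `generate_measurements()` emulate the
measurement process with a deliberately simple multiplicative model:
the median of cell $(m, s)$ is
`baseline × metal_effect[m] × sorbent_effect[s] × interaction[m, s]`,
and replicates are log-normal around that median with coefficient of
variation `cv` (default 0.1, a typical plate-count precision;
`sdlog = sqrt(log(1 + cv^2))` so the configured median is exact).
Multiplicative structure is the natural null for abundance data and
makes the *true* impact factors available in closed form
(`IF_HM = metal_effect − 1` under no interaction), which is what makes
parameter-recovery studies possible. Default effect multipliers are
taken from the shipped organotrophic-bacteria cell-mean ratios, so the
default configuration generates data that look like the reference
experiment.

Colony-emergence profiles are generated as a Poisson total thinned by a
multinomial whose probabilities are Dirichlet-distributed
(`emergence_alpha`, default symmetric with concentration 5): this
produces realistic plate-to-plate variability in emergence timing.

`recovery_experiment()` runs the full pipeline (generate → fit →
indices → letters) `n_sim` times and reports rejection rates per ANOVA
term, bias and RMSE of the recovered impact factors, and the count of
letter-contract violations. Under a null configuration the rejection
rate estimates the type-I error; under a configured effect it estimates
power and recovery bias. These are exactly the quantities written by
`scripts/acceptance.R`.

What the generator does *not* emulate: spatial correlation between
vases, heteroscedasticity across cells, measurement censoring, or any
mechanistic sorption chemistry. It is a calibration instrument for the
statistical machinery, not a soil model.

## Numerical and design choices

* **Reference-value verification.** `verify_reference_values()`
  recomputes the published impact percentages and marginal means from
  the shipped cell means. Tolerances are set from print precision:
  half a final-digit unit for percentages quoted to one decimal
  (0.05 pp; 0.005 for one three-decimal value), and one final-digit
  unit for marginal means (0.01 or 0.001), which allows for rounding of
  the cell means before averaging. A handful of published values fall
  outside these bands; the function reports them as such rather than
  widening the bands — the discrepancies are in the source values, not
  the arithmetic.
* **Replicates.** A design may declare single-replicate families (the
  shipped fixtures are cell means, stored with `replicate = 1`), but
  `ms_anova()` requires at least 2 replicates per cell — there is no
  error term otherwise.
* **Serialisation.** Index matrices round-trip through CSV at 17
  significant digits, with undefined reference cells as blanks.
* **Seeding.** Every stochastic entry point takes an explicit seed;
  given a seed, output is bit-identical across runs.

## Limitations

The inferential layer assumes balance and homoscedasticity and offers
no mixed-effects or repeated-measures extensions. Impact factors are
computed on cell means without propagating replicate uncertainty
(the simulation machinery is the intended route to uncertainty
statements). The letter-display algorithm produces a correct cover but
not always the provably minimal number of letters for adversarial
p-matrices, although it matches the minimal cover in all tested cases.
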