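---
title: "Methods: two-stage testing of rare-event categorical phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage testing of rare-event categorical phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodim)
```

# The problem

A phenotyping screen scores each animal for many binary traits
(abnormal / as expected). Knockout cohorts are small — the working design
throughout this package is seven animals per sex — while control animals
accumulate over time into a large pool (we model two years of weekly
collection, 104 × 7 = 728 per sex). Abnormal outcomes are rare: most traits
have background rates far below 1%. The scientific questions are, per
knockout line and trait:

1. does the knockout change the abnormality rate (a genotype effect)? and
2. if so, does the change differ between the sexes (sexual dimorphism)?

Testing dimorphism only within genotype-significant data sets (a two-stage
design) keeps the second-stage family small, which matters because
interaction tests are intrinsically low-powered.

# Stage-1 tests

All stage-1 tests compare knockout against wild-type, one-sided toward
*more* abnormalities in knockouts. One-sidedness is the package default
(a two-sided flag exists on the Fisher tests) because rare-event screens
monitor for the appearance of abnormality; a knockout that *reduces* an
already-near-zero background rate is undetectable at these sample sizes
anyway.

* **FE / FE_mid** (`fe_stage1()`): a one-sided Fisher exact test per sex;
  the reported p-value is twice the smaller of the two (a Bonferroni over
  sexes), capped at 1. The mid variant uses per-sex mid-P values.
* **MH / MH_mid** (`mh_exact_mid()`): the exact conditional
  Cochran–Mantel–Haenszel test stratified by sex. Conditional on all
  margins the total knockout event count T is the convolution of two
  central hypergeometric laws; p = P(T ≥ t), and the mid variant takes
  P(T > t) + ½·P(T = t). We implement the *exact* conditional law, not the
  asymptotic chi-square, because the mid-P correction is only defined on a
  discrete support, and the cell counts here (0–7 events) are far outside
  asymptotic territory.
* **LR_G** (`lr_g()`): Firth penalized likelihood-ratio test of
  `Y ~ genotype + sex + genotype:sex` against `Y ~ sex` (2 df).

The mid-P correction exists because discrete tests are conservative: the
attainable p-values jump, so a test at nominal 5% often runs at 1–2%
actual size. Subtracting half the point probability of the observed
outcome trades a small, controlled liberality for substantially better
power; the simulations below let one verify that overall size is still
maintained in this design.

# Stage-2 tests

* **LR_KO** (`lr_ko()`, default): within knockouts only, Firth LRT of
  `Y ~ sex` against a constant model (1 df). This reads a *sex difference
  among knockouts* as dimorphism, which is valid when the background rate
  is (near) zero in both sexes — the typical case. It is the only stage-2
  test with power when wild-types show no events at all.
* **Zelen** (`zelen_mid()`): exact test of odds-ratio homogeneity across
  the sex strata, doubly conditional (on margins and on the total knockout
  event count); two-sided by the point-probability method with a mid
  correction.
* **LR_I** (`lr_i()`): Firth LRT of the interaction term on all data (1 df).
* **FE_KO** (`fe_ko()`): knockout-only exact test of male vs female rates,
  two-sided point-probability method, mid-corrected.

Zelen and LR_I condition (exactly or effectively) on the wild-type data;
when wild-types carry zero events the conditional law for the interaction
collapses and these tests cannot reject at 5% regardless of how dimorphic
the knockouts are. For Zelen this is exact (the conditional support has a
single point); for LR_I it follows from the penalized likelihood surface
(the package's tests verify the minimum attainable p over every knockout
allocation is above 0.05). This structural zero-power is why LR_KO is the
default.

# Firth estimation: numerical choices

`firth_fit()` maximizes ℓ(β) + ½·log det I(β) by Newton iteration on the
modified score U*(β) = Xᵀ(y − nπ + h(½ − π)), with step-halving on the
penalized objective. Defaults (`firth_control()`): convergence when both
the maximum absolute penalized score and the maximum coefficient change
are ≤ 1e-8; at most 50 iterations; deterministic start at β = 0.
Observations are aggregated to covariate classes (at most four rows for a
sex × group design), which changes nothing mathematically and makes the
simulations cheap. Rank-deficient designs raise an error; non-convergence
is flagged and the calling test returns p = 1 with a warning rather than
aborting a batch run.

The penalized LRT (`penalized_lrt()`) compares the full fit against a
constrained fit in which the tested coefficients are pinned at zero while
the penalty *retains the full design's information matrix*. The
alternative — refitting the null model with its own smaller penalty — is
available (`null_penalty = "separate"`) but non-default: the two penalties
differ by a constant-free term, and the full-penalty convention is the one
under which the 7+7 stage-2 grid (`alpha_star_grid(7, 7)`) reproduces the
published minimum p-values digit for digit; the separate-penalty variant
can even produce a negative statistic at k = 1. Negative statistics are
truncated to zero (p = 1). The reference distribution is chi-square; with
penalized likelihoods this is an approximation, which is precisely why the
attainability grid is calibrated and reported rather than assumed.

One subtlety of the penalty: with *all-zero* events and unequal group
sizes, the Firth shrinkage (k + ½)/(n + 1) differs between cells, so LR_G
returns a statistic slightly above zero rather than exactly zero; only in
balanced designs is the no-information p exactly 1. This is a property of
the method, not an artifact, and such data sets are removed by the
attainability filter in any realistic configuration.

# Degenerate tables and ties

Uniform conventions, applied before any pipeline filtering:

* One-sided tests on a degenerate conditional support (size 1): standard
  p = 1, mid p = 0.5.
* Two-sided point-probability tests (Zelen, FE_KO) on a support of size 1:
  p = 1, also under the mid variant — there is no information to halve.
* Tie handling in two-sided tails: outcomes whose probability is within
  relative 1e-10 of the observed probability count as ties and are
  included, making the tail stable against floating-point noise in the
  hypergeometric weights.
* All probabilities are computed from `dhyper` (log-gamma arithmetic
  internally) and tails are accumulated from the smallest terms upward.

In pipeline runs these conventions are invisible: a degenerate data set
has α star = 0.5 or 1 and is removed by the filters before testing.

# Attainability filtering

For a discrete conditional test, the margins alone determine the set of
attainable p-values. `mh_alpha_star()` evaluates the MH(-mid) p at the
most extreme attainable allocation (all events on the knockout side, up to
per-stratum capacity); `lrko_alpha_star()` enumerates every split of the
total abnormal knockout count between the sexes and minimizes the LR_KO p
(the enumeration, rather than assuming the all-in-one-sex split, guards
unequal cohorts). Filtering on α star uses margins only — never observed
p-values — so downstream BH/BB inference remains valid after selection.
The α star is always computed with the same mid/standard variant as the
test that will be run.

Thresholds: stage 1 defaults to 0.05 (the working significance level).
Stage 2 also defaults to 0.05: the stage-2 attainability threshold is not
separately specified by the workflow this package implements, and
mirroring the stage-1 level is the choice that makes "cannot reach 5%"
mean the same thing at both stages. Both are configurable in
`pipeline_config()`.

# Multiplicity

`bh()` is the standard step-up procedure (via `stats::p.adjust`). `bb()`
implements two-step average-FDR control over families (gene × zygosity):
within-family BH at level q selects R families; final calls are
within-family BH at level R·q/m inside the selected families only.
Stage-2 FDR is computed over the stage-2 candidate set only, matching the
sequential design. Ties in p-values are kept in stable input order, which
affects reporting order only. The default stage-2 level is 0.20: with at
most 14 knockouts the attainable stage-2 p-values are coarse (minimum
0.00013), and a 5% FDR over any realistic candidate set rejects nothing —
a 20% FDR is the price of being able to flag dimorphism at all, and the
expected fraction of false flags is reported, not hidden.

# Effect sizes

Differences in abnormality proportions with Newcombe method-10 intervals
(`newcombe_diff_ci()`), composed from per-group Wilson score intervals
without continuity correction; z is the standard normal quantile at
(1 + level)/2, level fixed at 0.95 by default. The stage-1 effect is the
mean of the two per-sex knockout-minus-wild-type differences with a
conservative hull interval (min of lowers, max of uppers); the stage-2
effect is the male-minus-female difference among knockouts. No
selective-inference inflation of the intervals is attempted; reports carry
all rows, so the selection applied downstream is visible.

# The synthetic-data generator

`gen_control()` emulates the control stream of a high-throughput pipeline:
independent Bernoulli outcomes per animal and trait, 7 animals per sex per
week, 104 weeks by default. Per-trait rates default to log-uniform on
[1e-5, 0.05] (`trait_rates()`), spanning negligible to clearly-detectable
background rates with most mass at the rare end, as in real control data.
`resample_null_t1e()` relabels 7 + 7 animals as knockouts *without
replacement*, sharing the same drawn animals across all traits within an
iteration (a real cohort is phenotyped for every trait; a per-trait
independent draw is available via `shared_draw = FALSE`).
`stage2_t1e_sim()` adds the same effect to both sexes on the probability
scale (knockout rate = min(1, baseline + effect)) — additive on
probabilities, not odds, because effect grids up to 0.9 against a 0.05
baseline are only meaningful additively. `power_sim()` assigns the
interaction effect to one pre-registered sex (male by default; results are
sex-symmetric by construction).

What the generator does **not** emulate: batch-to-batch variation, litter
structure, correlated traits, drifting background rates. The included
`batch_screen()` exists to check the first assumption on real control
data; the pipeline itself treats batch and litter variation as negligible,
which is the regime in which pooling controls across batches is justified.
Passing simulations therefore demonstrate correctness of the procedures
under independent binomial sampling, not robustness to structured noise.

Randomness: every simulation entry point requires a seed and is
reproducible from it (one seeded stream per call; identical seeds give
identical tables, which the tests assert).

# Problem sizes used for verification

The package's own test suite verifies the exact tests and attainability
against exhaustive enumeration oracles on margins up to 12 per group, the
Firth optimum against a generic optimizer and the add-½ closed form, the
7+7 stage-2 grid against its published values, conservatism of MH_mid
under the global null at 100 traits × 1,000 relabeling iterations, the
structural zero power of Zelen/LR_I at 500 iterations, and the
mid-P/aggregation power ordering at 1,000 iterations — sizes chosen so the
Monte-Carlo standard errors are small relative to the margins being
demonstrated while the whole suite stays fast enough to run routinely.
Paper-scale runs (15,000 iterations) use the same code paths with larger
`iterations` arguments.

# Limitations

* Two sex strata only; the exact stratified machinery does not extend to
  more strata in this implementation.
* No profile-penalized-likelihood confidence intervals or Wald tests for
  Firth coefficients; the fit object exposes the information matrix for
  users who need more.
* The chi-square reference for penalized LRTs is approximate on tiny
  supports; the attainability grid quantifies exactly how coarse the
  stage-2 p-values are.
* FDR is computed per run; a continuously growing screen would need online
  FDR control, which is out of scope.
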