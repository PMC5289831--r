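# phenodim

Two-stage statistical analysis of rare-event categorical phenotypes, with
explicit testing for sexual dimorphism.

High-throughput phenotyping screens (the motivating case: knockout-mouse
pipelines) score hundreds of binary traits — abnormal / as expected — on
small cohorts, typically seven knockout animals per sex compared against a
large pooled control population. Three things make the statistics hard: the
abnormal outcome is rare (most traits show background rates well below 1%),
the per-line sample is tiny, and hundreds of hypotheses are tested at once.
`phenodim` implements a workflow built for exactly this regime:

1. **Stage 1 — genotype effect.** The default test is the exact one-sided
   Cochran–Mantel–Haenszel test stratified by sex with a mid-P correction
   (**MH_mid**): conditional on all margins, the total knockout event count
   T is a convolution of two central hypergeometric laws, and
   p = P(T > t) + ½·P(T = t). Alternatives: per-sex Fisher tests with a
   doubled minimum (FE, FE_mid) and a Firth penalized likelihood-ratio test
   (LR_G).
2. **Stage 2 — sexual dimorphism,** tested only in stage-1 discoveries. The
   default is **LR_KO**: within knockouts only, Firth bias-reduced logistic
   regression `Y ~ sex` against a constant model, with the penalized
   likelihood-ratio statistic 2·(ℓ*₁ − ℓ*₀) referred to χ²(1), where
   ℓ*(β) = ℓ(β) + ½·log det I(β). The Firth penalty keeps estimates finite
   under complete separation (e.g. 7/7 abnormal males, 0/7 females).
   Alternatives: the Zelen exact homogeneity test, LR_I (interaction term on
   all data), FE_KO (knockout-only exact test).
3. **Attainability ("α star") filters.** Exact tests on discrete supports
   have a smallest attainable p-value determined by the margins alone;
   hypotheses that cannot reach the working level even under the most
   extreme outcome are removed *before* testing, shrinking the multiplicity
   burden without biasing selection.
4. **FDR control** by Benjamini–Hochberg over all hypotheses, or by the
   Benjamini–Bogomolov two-step procedure controlling the average FDR over
   gene × zygosity families.
5. **Effect sizes** as differences in abnormality proportions with Newcombe
   method-10 95% intervals (built from Wilson score intervals — odds ratios
   are useless with near-zero denominators).

A simulation module (`gen_control()`, `resample_null_t1e()`,
`stage2_t1e_sim()`, `power_sim()`) reproduces the operating-characteristic
studies used to justify the default choices: type-I error under the global
null by relabeling resampling, stage-2 error in the presence of a genotype
main effect, and power grids across baseline rates, main effects and
one-sex interaction effects.

## Worked example

One knockout line, one trait: 6/7 abnormal male knockouts, 0/7 female
knockouts, against pooled controls (0/721 male, 1/721 female).

```r
library(phenodim)
d <- make_dataset(ko_male = c(6, 7), wt_male = c(0, 721),
                  ko_female = c(0, 7), wt_female = c(1, 721),
                  line_id = "Myo10-like", zygosity = "hom", trait_id = "forepaw")

mh_exact_mid(d)
#>  Exact one-sided Cochran-Mantel-Haenszel test, sex-stratified (MH_mid)
#> data:  Myo10-like:hom:forepaw
#> statistic = 6, p-value = 3.769e-13

lr_ko(d)
#>  LR_KO: Firth penalized LRT for sex within knockouts (Y ~ sex vs constant)
#> data:  Myo10-like:hom:forepaw
#> chi-squared = 10.468, df = 1, p-value = 0.001215

ko_sex_difference(d)
#> Difference in abnormality proportions: 0.8571 [95% CI 0.3446, 0.9743]
```

The stage-1 p-value says the knockout clearly deviates from the controls;
the stage-2 p-value (0.0012) says the effect differs between the sexes; the
male–female knockout difference is 0.86 with a 95% interval [0.34, 0.97].
`run_pipeline(list(d))` wraps the same steps with filtering and FDR calls,
and `write_report()` serializes the result.

Attainability for the 7+7 stage-2 design — at least four abnormal animals
are needed before the 5% level is even reachable:

```r
alpha_star_grid(7, 7)
#>   penetrance n_male n_female n_abnormal alpha_star
#> 1       14.3      7        7          1   0.440593
#> 2       28.6      7        7          2   0.184072
#> 3       42.9      7        7          3   0.069744
#> 4       57.1      7        7          4   0.022993
#> 5       71.4      7        7          5   0.006197
#> 6       85.7      7        7          6   0.001215
#> 7      100.0      7        7          7   0.000126
```

This is also why a fixed p < 0.0001 calling threshold can never declare
sexual dimorphism with seven knockouts per sex: the smallest attainable
stage-2 p-value is 0.00013.

A command-line surface is provided in `inst/cli/phenodim.R`
(`analyze`, `alpha-star`, `simulate-null`, `simulate-stage2-error`,
`simulate-power`, `batch-screen`, `make-fixtures`).

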