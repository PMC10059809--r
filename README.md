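# bcaamr

Two-sample Mendelian randomization (MR) of serum branched-chain amino
acids (BCAA — leucine, isoleucine, valine) on coronary artery disease
(CAD) and related cardiovascular outcomes, from GWAS summary statistics.

Observational studies associate raised circulating BCAA with CAD, but
cannot separate causation from confounding. MR uses genetic variants as
instrumental variables: because alleles are randomly assorted at
conception, a variant that raises serum BCAA and is associated with CAD
only through BCAA provides a confounding-robust estimate of the causal
effect. `bcaamr` implements the complete summary-statistics workflow for
epidemiologists running such analyses: instrument construction, allele
harmonization, six complementary causal estimators, sensitivity
diagnostics, MR mediation, meta-analysis of observational studies,
multiplicity control with cross-trait clustering, and seeded synthetic-data
generators used to validate every stage.

## The model

For variant *i*, let β̂<sub>Xi</sub> (SE σ<sub>Xi</sub>) be its effect on
standardized serum BCAA and β̂<sub>Yi</sub> (SE σ<sub>Yi</sub>) its
log-odds effect on CAD, oriented to a shared effect allele. Each variant
gives a Wald ratio β̂<sub>Yi</sub>/β̂<sub>Xi</sub>; the estimators combine
them under different assumptions about horizontal pleiotropy:

- **IVW** — weighted regression of β̂<sub>Y</sub> on β̂<sub>X</sub>
  through the origin, weights 1/σ<sub>Y</sub>²; multiplicative random
  effects (residual SD floored at 1) by default.
- **MR-Egger** — the same regression with an intercept; the intercept
  estimates average directional pleiotropy (its t-test is the pleiotropy
  test), the slope is the causal effect under the InSiDE assumption.
- **Simple / weighted median** — the (weighted) 50th percentile of the
  Wald ratios; consistent when instruments carrying ≥ 50% of the weight
  are valid. Parametric-bootstrap SEs.
- **MR-RAPS** — root of the profile score
  Σ (β̂<sub>Yi</sub> − bβ̂<sub>Xi</sub>)β̂<sub>Xi</sub>/(σ<sub>Yi</sub>² + b²σ<sub>Xi</sub>²) = 0,
  which models the exposure-side sampling error (robust to weak
  instruments).
- **MR-PRESSO** — leave-one-out residual-sum simulation test that detects
  outlying (pleiotropic) instruments, removes them, and re-estimates.

Heterogeneity is assessed by Cochran's Q on the Wald ratios and a
leave-one-out scan. Mediation through a risk factor M uses the product
method: indirect = β<sub>XM</sub>β<sub>MY</sub>, proportion mediated =
indirect / total, with delta-method SEs. Observational studies are pooled
with DerSimonian–Laird random effects (I² heterogeneity), and cross-trait
locus profiles are clustered with Ward's method on Euclidean distances of
directional Z-scores, with Benjamini–Hochberg and Bonferroni multiplicity
control.

The 17-variant BCAA instrument (exposure betas, outcome odds ratios with
95% CIs, effect-allele frequencies) ships as a plain-text fixture, so the
headline analysis reproduces offline.

## Worked example

```r
library(bcaamr)

res <- reproduce_paper(config = mr_config(seed = 1))
print(res$results)
#>                     method n_snp  beta    se    or or_low or_high   pvalue note
#>  Inverse variance weighted    17 0.074 0.029 1.077  1.018   1.140 9.56e-03
#>            Weighted median    17 0.090 0.038 1.095  1.016   1.180 1.81e-02
#>              Simple median    17 0.090 0.040 1.095  1.012   1.184 2.33e-02
#>                    MR-RAPS    17 0.074 0.029 1.077  1.018   1.140 9.78e-03
#>                  MR-PRESSO    17 0.074 0.018 1.077  1.039   1.117 4.65e-05
#>                   MR-Egger    17 0.009 0.078 1.009  0.854   1.192 9.14e-01

res$variance_explained$total
#> [1] 0.06257617
res$heterogeneity
#> Cochran Q = 6.478 on 16 df, p = 0.982
sum(res$loo$flagged)
#> [1] 0
```

Read: a 1 SD genetically predicted increase in serum BCAA raises the odds
of CAD by about 8% (IVW OR 1.077, 95% CI 1.02–1.14), concordant across
the median, RAPS and PRESSO estimators; the near-null Egger slope with a
small non-significant intercept (0.007, p ≈ 0.4) gives no evidence of
directional pleiotropy; the 17 variants explain 6.26% of exposure
variance; Q shows no heterogeneity and no single variant drives the
estimate (no leave-one-out flags, no PRESSO outliers).

A command-line front-end wraps the same functions:

```sh
inst/cli/bcaamr reproduce-paper --out out/
inst/cli/bcaamr simulate --scenario A --seed 5 --out sim/
inst/cli/bcaamr mr --exposure sim/exposure.tsv --outcome sim/outcome.tsv --seed 5 --out mr_out/
```

## Synthetic validation

`sim_params()` / `scenario_params()` generate paired exposure/outcome
summary statistics with a stated true causal effect, balanced or
directional pleiotropy, planted outliers, and SEs implied by sample sizes
— the statistical structure every stage assumes. The test suite uses them
for parameter-recovery, test-calibration and contamination experiments;
see the methods vignette (`vignettes/bcaamr-methods.Rmd`) for the
generating model and the design decisions behind each numerical
convention.
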