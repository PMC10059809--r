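---
title: "Methods and design notes for bcaamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for bcaamr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcaamr)
```

`bcaamr` estimates the causal effect of genetically predicted serum
branched-chain amino acid (BCAA) concentration on coronary artery disease
(CAD) from two-sample GWAS summary statistics, and carries the
surrounding analyses — mediation, observational meta-analysis,
multiplicity control, cross-trait clustering — in one tested package.
This vignette records the model, the conventions behind every numerical
choice, and what the validation suite does and does not demonstrate.

## The two-sample MR model

For variant $i$, the exposure GWAS supplies $\hat\beta_{Xi}$ (SD units of
standardized serum BCAA per effect allele) with standard error
$\sigma_{Xi}$, and the outcome GWAS supplies $\hat\beta_{Yi}$ (log-odds
of CAD per allele) with $\sigma_{Yi}$, both oriented to a common effect
allele. Under the instrumental-variable assumptions (association with
the exposure; no association with confounders; no effect on the outcome
except through the exposure), each variant identifies the causal effect
$\beta$ through $\beta_{Yi} = \beta\,\beta_{Xi}$, and the per-variant
Wald ratio $\hat\beta_{Yi}/\hat\beta_{Xi}$ estimates it. The estimators
differ in how they pool ratios when the third assumption (no horizontal
pleiotropy) may fail for some variants.

All estimators are invariant to the per-variant sign flip
$(\beta_X,\beta_Y)\to(-\beta_X,-\beta_Y)$, i.e. to the arbitrary choice
of effect allele; this is enforced by construction and checked by
property tests.

## Instrument construction

`select_instruments()` applies, in order: a genome-wide significance
filter ($p < 5\times10^{-8}$ by default, strict inequality); per-variant
deduplication across the three BCAA traits, keeping the strongest
association — operationalized as the smallest p-value, ties broken by
larger $|\beta|$ and then trait label, since the p-value is the only
printed strength measure; removal of variants on a user-supplied
exclusion list of confounder genes/variants (the list is configuration,
not hard-coded); and greedy linkage-disequilibrium pruning. Pruning
visits variants in ascending p-value order (ties by identifier, which
also makes the output independent of input row order) and keeps a
variant only if its $r^2$ with every already-kept variant is below the
protocol threshold — 0.8 for the permissive protocol, 0.001 for the
strict one; the `lead_snp` protocol instead keeps the single lowest-p
variant per locus label. A same-chromosome pair absent from the LD table
is treated as $r^2 = 0$ with a warning (conservative for pruning:
nothing is dropped on unobserved LD); cross-chromosome pairs are always
independent. Note the permissive threshold leaves variants at the same
locus mutually correlated at up to $r^2 = 0.8$; no correlation
correction is applied downstream, so the effective number of instruments
is smaller than the nominal count and heterogeneity statistics should be
read accordingly.

`harmonize()` aligns the outcome record to the exposure's effect allele:
swapped labels flip the sign and complement the frequency; complementary
representations are strand-flipped before comparison. Palindromic (A/T,
C/G) variants cannot be strand-resolved from labels; policy `drop`
removes them, `align_by_frequency` compares both allele frequencies to
0.5 and drops the variant when either lies within $\pm 0.08$ of 0.5 (a
conventional ambiguity band; the alignment is unreliable closer to 0.5),
and `keep` trusts the reported orientation. Irreconcilable allele pairs
always produce an explicit exclusion record.

`variance_explained()` uses $r^2_i = 2 f_i (1-f_i) \beta_{Xi}^2$ for a
standardized exposure (SD = 1); the total over the bundled 17-variant
instrument is 6.26%.

Back-conversion of a published odds ratio with CI to log scale uses
$\hat\beta=\ln(\mathrm{OR})$ and
$\mathrm{SE}=(\ln U-\ln L)/(2z)$ with $z = 1.959964$ (the exact 97.5%
normal quantile, not 1.96 — it moves the fourth digit of the SE).

## Estimator conventions

**IVW.** Weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
through the origin with weights $1/\sigma_Y^2$. The fixed-effects SE
forces the residual variance to 1; the default multiplicative
random-effects SE multiplies it by the residual SD *floored at 1*, so
between-variant heterogeneity widens the interval but an
underdispersed fit never narrows it below the fixed-effects SE.

**MR-PRESSO.** The global test compares the observed (unweighted)
residual sum of squares of leave-one-out IVW predictions with its
parametric null: outcome effects redrawn around the leave-one-out
predictions and exposure effects around their estimates, at the reported
SEs, `n_sim` times (default 1000, seeded). The per-variant outlier test
compares each squared residual with its simulated distribution,
Bonferroni-adjusted across variants at level 0.05. Empirical p-values
use $(1+k)/(1+n_\mathrm{sim})$ so they are never exactly zero. The
corrected estimate is the weighted regression on retained variants with
the plain (sigma-multiplied, unfloored) OLS standard error — the
convention that matches the narrower interval conventionally reported
for the outlier-corrected estimate relative to random-effects IVW. When
outliers are removed, a distortion test compares the corrected estimate
against a null built by removing random same-size subsets.

**MR-Egger.** Variants are first oriented so $\hat\beta_X \ge 0$, then
weighted least squares with an intercept is fitted. Both coefficients
carry the *unfloored* multiplicative residual scaling, and inference
uses $t_{n-2}$. The unfloored choice is deliberate and differs from the
IVW flooring: flooring the residual SD makes the intercept-based
pleiotropy test conservative (measured type-I error ≈ 0.03 at nominal
0.05 in our null simulations versus ≈ 0.05 unfloored), and the unfloored
form is the convention of the widely used implementations. A caveat
established in our design simulations: with a nonzero causal effect and
realistically weak instruments (per-variant F ≈ 8–10), regression
dilution in the Egger fit shifts the intercept away from zero
("NOME" violation), inflating the pleiotropy test's rejection rate to
≈ 0.08–0.09 even without pleiotropy; its size is therefore assessed
under the no-effect, no-pleiotropy null, and Egger intercepts from weak
instruments should be interpreted with this bias in mind.

**Medians.** The weighted median interpolates the ratio against the
cumulative standardized weight $p_j = (\sum_{i\le j} w_i - w_j/2)/\sum
w$ at $p = 0.5$ with inverse-variance weights $\beta_X^2/\sigma_Y^2$;
with equal weights this reduces exactly to the sample median (midpoint
for even counts), which is the simple median estimator. SEs come from a
parametric bootstrap (default 1000 replicates, mandatory seed) redrawing
both effect sides from normal distributions at their SEs; CIs and
p-values are normal approximations of the bootstrap SD (a
percentile-bootstrap option was considered and rejected for
determinism-of-summary reasons; the normal approximation is standard).

**MR-RAPS.** The default is the plain $\ell_2$ profile score without
overdispersion — the simplest published variant and fully deterministic.
The root is found by bracketed bisection from the IVW start (bracket
doubled until a sign change, `uniroot` at tolerance $10^{-12}$), and the
SE is information-based,
$1/\sqrt{\sum \beta_{Xi}^2/(\sigma_{Yi}^2+\hat b^2\sigma_{Xi}^2)}$.
A Huber-loss score and a method-of-moments overdispersion variance are
available behind flags but are not part of the validated default path.
With all exposure SEs zero the score reduces exactly to fixed-effects
IVW — a degeneracy the tests assert.

**Minimum instrument counts.** 1 for IVW (a single variant returns its
Wald ratio), 3 for the medians and Egger, 4 for PRESSO; below these the
estimators raise a structured insufficient-instruments error, and
`mr_run_all()` records the failure on that method's row without
aborting the others.

## Diagnostics

Cochran's Q uses first-order Wald-ratio weights
$\beta_X^2/\sigma_Y^2$ by default, referred to $\chi^2_{n-1}$; the
second-order weighting (adding the exposure-side variance to each
ratio's SE) is available behind a flag. On the bundled instrument the
first-order form gives $p = 0.982$ — consistent, to within the
two-decimal rounding of the published inputs, with the reported absence
of heterogeneity. Leave-one-out re-runs IVW on each $n-1$ subset and
flags a subset whose estimate changes sign or whose CI excludes the
full-set estimate.

## Mediation

`two_step_mediation()` is exact arithmetic on its inputs: indirect
$=\beta_{XM}\beta_{MY}$, proportion $=$ indirect/total, both unclipped
(a noisy or opposing-path analysis can legitimately produce proportions
outside [0, 1]). Delta-method SEs treat the three MR estimates as
independent, justified by their non-overlapping source GWAS; this
assumption is isolated in one function so a correlated-version could be
swapped in. Note the proportion is a ratio estimator: when the total
effect is imprecise (relative SE $\gtrsim$ 25%), the mean recovered
proportion acquires a noticeable positive bias of order
$(\sigma_T/T)^2$, and with a total effect measured at 37% relative SE —
the precision of the real total estimate — that bias is around +20% of
the true proportion. The recovery experiment in the validation suite
therefore fixes the simulated total and exposure–mediator SEs at ~10–15%
relative (matching the relative precision of the published
mediator–outcome estimates) and recovers a true proportion of 0.342 to
within 0.02 over 200 replicates; recovery of the proportion's *mean*
under a much noisier total is not claimed.

## Meta-analysis and multiplicity

Study relative risks are pooled on the log scale (the standard choice;
the ratio scale is not symmetric), with SEs back-computed from the
printed CIs. The default between-study variance is DerSimonian–Laird —
the conventional "random effects" reading — with fixed-effect and REML
alternatives behind flags; fitting is delegated to `metafor::rma()` and
the DL path is verified against an independent implementation of the
textbook formulas to $10^{-10}$ in the tests.
$I^2 = \max(0, 100(Q-\mathrm{df})/Q)$ and $\tau^2 = 0$ whenever
$Q \le \mathrm{df}$.

Benjamini–Hochberg q-values come from `stats::p.adjust` and are verified
against the brute-force step-up definition; the outcome-wide FDR family
is the set of outcome analyses supplied by the caller (the package does
not hard-code a family). The Bonferroni threshold for locus-by-trait
screens is $\alpha/m$ (e.g. $0.05/136 = 3.68\times10^{-4}$ for 17 loci
× 8 traits).

Ward clustering of the locus-by-trait directional Z-score matrix
(effect divided by SE, oriented to the exposure-raising allele) runs the
Lance–Williams Ward update on squared Euclidean distances via
`stats::hclust(method = "ward.D")`; merge heights are non-decreasing,
and the full merge structure is verified against a naive $O(n^3)$
agglomeration oracle in the tests. Missing cells must be resolved before
clustering: a mapped proxy variant fills its sentinel's cell, remaining
cells are zero-filled (a neutral profile) with a provenance flag, and
`NA`s are rejected with a pointer to the policy.

## The synthetic-data generator

`simulate_two_sample()` draws, per variant: an effect-allele frequency
$f$ log-uniform on [0.01, 0.5] — log-uniform so that rare, large-effect
variants occur, mirroring the real instrument whose frequencies span
0.013–0.47; a per-variant exposure variance explained uniform on
[0.001, 0.006], matching the real per-variant range, which fixes
$\beta_{X}=\sqrt{r^2/2f(1-f)}$; SEs $1/\sqrt{2f(1-f)n}$ from the sample
sizes (defaults 25 000 exposure, 180 000 outcome, the scale of the
source GWAS); a direct (pleiotropic) outcome effect
$\alpha\sim N(\mu_\alpha,\sigma_\alpha)$ for the invalid fraction; and
observed effects with normal noise at the stated SEs. Optional planted
outliers shift a chosen variant's observed outcome effect by a stated
number of its SEs. Alleles avoid palindromic pairs unless requested, so
harmonization behaviour is tested separately and deliberately.
Everything is deterministic given the mandatory seed, and the generator
restores the caller's RNG state.

Canonical scenarios: **A** (no pleiotropy, 50 variants, true effect
0.1), **A0** (the same null with zero effect), **B** (balanced
pleiotropy, every variant with $\alpha\sim N(0, 0.005)$), **C** (A plus
one +5-SE outlier), **D** (17 variants — the real instrument's size —
with 30% invalid and directional pleiotropy $\mu_\alpha=0.02$,
$\sigma_\alpha=0.005$). In scenario D the IVW mean estimate sits several
Monte-Carlo SDs above the truth while the weighted median's mean stays
within two MC SDs of it — the contamination contrast the weighted
median exists for. The weighted median does retain a small positive
finite-sample bias under one-sided contamination (of order half the
per-ratio SE); it is robust, not unbiased, and the validation criterion
is phrased in MC SD units for that reason.

What the generator does **not** emulate: linkage disequilibrium between
instruments (draws are independent), allele-frequency-dependent effect
architectures beyond the $r^2$ coupling, binary-trait liability-scale
subtleties (outcome SEs use the same $1/\sqrt{2f(1-f)n}$ form),
selection/winner's-curse in instrument discovery, and sample overlap
between the two GWAS. Passing tests therefore demonstrate correctness of
the estimators under their own generating assumptions, not robustness to
those real-data complications.

## Validation problem sizes

The suite's simulation experiments use: 200 replicates × 50 variants for
estimator bias (all six estimators within 0.01 of the truth); 1000 null
replicates for the Egger intercept test size (within (0.03, 0.07)); 200
replicates of scenario D for the contamination contrast; 100 seeded runs
× 1000 PRESSO simulations for outlier power (≥ 90% detection of a +5-SE
outlier) and global-test size; 500 replicates for Q calibration
(mean $Q/(n-1)$ within 10% of 1); 60 full pipeline replicates for CI
coverage (≥ 90% at nominal 95%); and exhaustive small-case oracles for
BH (n ≤ 10), DerSimonian–Laird (k ≤ 6) and Ward clustering (n ≤ 8).
These sizes keep the whole suite under a minute on one CPU while leaving
Monte-Carlo margins well inside the asserted bands.

## Known limitations

- No correction for residual LD among instruments kept under the
  permissive $r^2<0.8$ protocol.
- Median CIs are normal approximations of a bootstrap SD, not percentile
  intervals.
- The RAPS overdispersion option is a simple method-of-moments
  iteration, not the full maximum-profile-likelihood treatment.
- Mediation SEs assume independent component estimates.
- Multivariable MR, Steiger filtering, and LD estimation from genotype
  panels are out of scope; LD is consumed as a supplied table.
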