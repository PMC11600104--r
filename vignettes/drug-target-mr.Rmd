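---
title: "Drug-target Mendelian randomization with cismr: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with cismr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The analysis this package implements

`cismr` implements the two-sample Mendelian randomization (MR) workflow used
in drug-target studies, where cis-eQTL variants in a drug's target gene proxy
pharmacological modulation of that target. The canonical use case shipped with
the package mirrors a study of GLP-1 receptor agonism: cis-eQTLs for *GLP1R*
expression in blood serve as instruments, binary disease endpoints (on the
log-odds scale) serve as outcomes, indications of the drug class (type 2
diabetes, obesity) serve as positive controls, and two-step MR quantifies how
much of the drug's effect on the endpoint flows through those indications.

Per variant $j$, the instrument carries an exposure association
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ and an outcome association
$\hat\beta_{Yj} \sim N(\theta\,\gamma_j + \alpha_j, \sigma_{Yj}^2)$, where
$\theta$ is the causal effect of interest and $\alpha_j$ is horizontal
pleiotropy (zero for a valid instrument). All estimators consume harmonized
pairs $(\hat\beta_{Xj}, \hat\beta_{Yj})$ aligned to a common effect allele.

## Harmonization

Exposure and outcome tables are matched on rsID and the outcome association
is aligned to the exposure's effect allele: swapped alleles flip the beta
sign and complement the allele frequency; alleles matching only as strand
complements are complemented first. Palindromic variants (A/T, C/G) are
discarded outright — no frequency-based strand inference is attempted,
because allele frequencies near 0.5 make that inference unreliable and the
cis windows involved rarely depend on rescuing a palindrome. Matching is by
rsID only; both source ecosystems (eQTL consortia, national biobanks) key on
rsIDs, and position-based matching adds failure modes without adding matches
here.

## Instrument selection

`select_instruments()` applies five steps in a fixed order, each step a pure
filter so survivor counts are non-increasing:

1. **cis restriction** to the target gene ± a flank (default 1 Mb, the usual
   cis-eQTL window; the gene's coordinates are user-supplied).
2. **Significance**: p < 5e-8 and, when available, an adjusted p < 0.05.
   Both inequalities are strict, so a p-value exactly at 5e-8 is dropped.
   The adjusted p is consumed as a precomputed column (as eQTL consortia
   ship it); `add_bonferroni_adjustment()` provides a fallback.
3. **Exclusion list**: variants known to associate with other genes or
   phenotypes (a static file standing in for a catalogue query) are removed.
4. **LD clumping** at r² ≤ 0.01 against a supplied correlation matrix,
   greedy by ascending p-value with lexicographic rsID tie-breaks — the
   tie-break makes the output deterministic and invariant to row order.
   There is no base-pair window parameter: the candidate set is the cis
   region and the LD matrix defines all the structure needed.
5. **Weak-instrument filter**: F = β²/SE² must be at least 10; a variant
   with F exactly 10 is retained (only values *less than* 10 are excluded).

## Estimators and their conventions

All per-SNP (Wald) ratios use the first-order standard error
$\sigma_{Yj}/|\hat\beta_{Xj}|$; second-order weights that include the
exposure-side variance are available by flag.

* **IVW** — inverse-variance-weighted mean of Wald ratios, equivalently
  zero-intercept weighted regression of outcome on exposure betas with
  weights $1/\sigma_{Yj}^2$. The default model is multiplicative random
  effects: the SE is inflated by $\max(1, \sqrt{Q/(J-1)})$, which reduces to
  the fixed-effect SE in the absence of heterogeneity and never deflates it.
  P-values use the normal reference.
* **MR-Egger** — weighted regression with a free intercept estimating
  directional pleiotropy. Pairs are first oriented so exposure betas are
  non-negative (the regression is not invariant to allele orientation).
  SEs carry the multiplicative overdispersion factor
  $\max(1, \sqrt{RSS_w/(J-2)})$ and p-values use the t reference with J−2
  degrees of freedom, a small-J conservatism.
* **Weighted median** — the Wald ratio at which cumulative normalized
  weight crosses one half, linearly interpolated on the cumulative-weight
  midpoint scale; SE from a parametric bootstrap (default 1000 resamples,
  seeded and reproducible).
* **MR-PRESSO** — the global test compares the observed weighted residual
  sum of squares around leave-one-out IVW slopes to parametric simulations;
  per-SNP residuals give outlier p-values (Bonferroni-flagged); the
  corrected estimate is, definitionally, IVW on the unflagged variants. The
  distortion test compares the raw-minus-corrected shift against shifts
  obtained when the removed set is replaced by resamples of the clean
  variants — the null construction of this test varies across descriptions
  in the literature, so ours is documented here as a convention choice. All
  empirical p-values use the add-one correction $(k+1)/(n_{sim}+1)$ and are
  bit-reproducible under a fixed seed.
* **Cochran's Q, leave-one-out** — standard heterogeneity and influence
  diagnostics; Q uses J−1 degrees of freedom against an IVW reference and
  J−2 against an Egger reference.
* **Multivariable IVW** — weighted multiple regression of outcome betas on
  several exposure-beta columns without intercept; used for the
  difference-in-coefficients mediation sensitivity analysis.

95% intervals use z = 1.959964 throughout, so printed CIs are reproducible
to the last digit.

## Two-step mediation

With $\beta_1$ the exposure→mediator effect, $\beta_2$ the mediator→outcome
effect (estimated with the mediator's own instruments) and $\beta_3$ the
total effect, the indirect effect is $\beta_1\beta_2$ with the first-order
delta variance $\beta_1^2\sigma_2^2 + \beta_2^2\sigma_1^2$. The two
coefficients come from non-overlapping samples, so their covariance is taken
as zero, and the second-order term $\sigma_1^2\sigma_2^2$ is omitted: this
exact convention reproduces published three-decimal intervals, which the
second-order term would not. The mediated proportion is
$\beta_1\beta_2/\beta_3$ with $\beta_3$ treated as fixed in its CI — again
the convention that reconciles with published proportion intervals;
propagating the uncertainty of $\beta_3$ does not. Proportions are reported
as percentages; a flag is raised when a proportion falls outside [0, 1],
where it loses its interpretation as a share. No per-proportion p-value is
reported — the indirect-effect p-value stands in for it.

The **difference-in-coefficients** sensitivity method estimates the direct
effect by multivariable IVW with the mediator adjusted for, and takes
indirect = total − direct. Its variance uses the independence approximation
$\sigma_{total}^2 + \sigma_{direct}^2$, a documented simplification (the two
share outcome data). The multivariable design uses the **union** of exposure
and mediator instruments: with the exposure's cis variants alone the
mediator column has almost no conditional identification. Even with the
union design, standard multivariable IVW carries an errors-in-variables
attenuation of order 1/F: at the instrument strengths simulated here
(F ≈ 50) the direct effect is attenuated by 2–4%, so the difference method
systematically reads a mediated proportion a couple of percentage points
above the product method. The package reports both; they are similar in the
qualitative sense but should not be expected to agree to Monte-Carlo
precision — this is a property of the standard estimator, not of its
implementation.

## Two-step cis-MR confounder adjustment

For each confounder pathway, every instrument's outcome association is
corrected by the product of the variant→confounder effect $b_{gc,j}$ and a
single confounder→outcome estimate $b_{co}$:
$\beta'_{Yj} = \beta_{Yj} - b_{gc,j}\,b_{co}$, with the delta-propagated SE
$\sqrt{\sigma_{Yj}^2 + b_{gc,j}^2\sigma_{co}^2 + b_{co}^2\sigma_{gc,j}^2}$
(the second-order $\sigma_{gc}^2\sigma_{co}^2$ product is omitted, consistent
with the mediation module). Adjusted SEs can therefore only grow. Confounders
are adjusted one at a time — the method is defined per pathway — and the
pipeline reports each adjusted estimate against the unadjusted baseline.

## The synthetic-data generator

`simulate_two_sample()` and `simulate_mediation_chain()` generate
summary-level data (not individual-level: the pipeline consumes only summary
statistics, and summary-level truth is analytically transparent). Defaults
emulate the drug-target setting: J = 22 cis instruments placed in the *GLP1R*
locus, true effects $\gamma_j \sim N(0.14, 0.04)$ with exposure SEs of 0.02
so F-statistics average ≈ 50, outcome SEs of 0.04 (biobank-scale binary
GWAS), and a protective total effect $\theta = \ln(0.493)$. The effect-size
spread across instruments matters: with near-identical $\gamma_j$, MR-Egger
and multivariable MR lose identification entirely, and real cis-eQTL signals
do vary severalfold in effect size. Alleles are non-palindromic by default
(a `palindrome_fraction` switch exists purely to exercise harmonization);
p-values are always consistent with beta/SE; every table passes the
package's own I/O validation; and generation is byte-reproducible under the
mandatory seed without disturbing the session RNG.

The mediation chain draws per-SNP mediator effects
$\beta_1\gamma_j + \delta_j$ with $\delta_j \sim N(0, 0.02)$: SNP-level
mediator pathways that both reflect reality (cis variants rarely act on a
downstream trait through one channel only) and give the mediator column
conditional variation. The mediator's own instruments are drawn stronger
(F ≈ 150), as genome-wide hits from large biobank scans typically are, and
exposure associations at those instruments are truly null. The chain's total
effect is $\theta_{direct} + \beta_1\beta_2$ by construction.

What the generator does **not** emulate: LD-aware effect-size generation
(instruments are post-clumping by construction), liability-scale modelling of
binary traits, sample overlap between cohorts, allele-frequency-dependent
power, or population stratification. Passing calibration tests on these
simulations therefore demonstrates the estimators' correctness and
calibration under the two-sample summary-statistics model — not robustness
to the full messiness of real GWAS data.

## Calibration choices in the test suite

The simulation-backed checks run at sizes chosen to give stable Monte-Carlo
verdicts in seconds: 2000 replicates for type-I error of IVW and Cochran's Q
under the causal null (fixed-effect IVW is the calibrated reference there;
the random-effects SE is conservative by construction), 200 replicates each
for MR-PRESSO's detection of a planted 10×-scale outlier and for its global
test on clean data, 500 for the Egger intercept's false-positive rate, and
500 mediation chains at a 30% true mediated proportion. The Egger intercept
calibration runs under the causal null: with a strong causal effect and
near-homogeneous instrument strength the intercept genuinely absorbs
regression dilution (a known limitation of MR-Egger, worth remembering when
reading its p-value on real cis-instrument data).

## A worked example

```{r example}
cfg <- sim_config(seed = 1)
sim <- simulate_two_sample(cfg)
pairs <- harmonize(sim$exposure, sim$outcome)
mr_ivw(pairs)

med <- two_step_mediation(
  list(beta = -0.167, se = se_from_ci(-0.215, -0.120)),
  list(beta = 0.122, se = se_from_ci(0.064, 0.180)),
  list(beta = log(0.493), se = NA_real_),
  mediator_id = "t2d"
)
med
```

## Known limitations

* Wald-ratio SEs ignore exposure-side noise by default; at F ≈ 50 this is a
  ~1% understatement, and the second-order option is there for weaker
  instruments.
* The difference-in-coefficients method inherits multivariable IVW's
  weak-instrument attenuation (see above).
* The mediated-proportion CI treats the total effect as fixed; when the
  total effect is imprecise the interval understates uncertainty.
* Harmonization never rescues palindromic variants, which costs instruments
  in regions rich in A/T or C/G polymorphisms.
* The TSCMR variance formula is a first-order convention; implementations
  differ in whether they carry the second-order product term.
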