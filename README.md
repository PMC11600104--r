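# cismr

Drug-target Mendelian randomization with cis instruments, two-step
mediation, and confounder adjustment.

## What problem this solves, and for whom

When a drug's target gene has cis-eQTLs, those variants proxy lifelong
pharmacological modulation of the target, and two-sample Mendelian
randomization (MR) against disease GWAS turns that into a causal estimate of
the drug's effect — before or alongside trials. `cismr` is for
epidemiologists and biostatisticians running such drug-target studies end to
end from summary statistics: the motivating design proxies GLP-1 receptor
agonism with *GLP1R* expression instruments, validates them against the drug
class's indications (type 2 diabetes, obesity) as positive controls,
estimates the effect on an endpoint, and asks how much of that effect is
mediated by the indications.

The package covers:

* **I/O and harmonization** — delimited summary-statistics tables (canonical
  or FinnGen-style headers via column maps), LD matrices, exclusion lists;
  effect-allele alignment with sign flips, strand-complement rescue, and
  unconditional discarding of palindromic (A/T, C/G) variants.
* **Instrument selection** — cis-region restriction, p < 5e-8 plus
  adjusted-p screening, exclusion-list removal, greedy LD clumping
  (r² ≤ 0.01), and the F = β²/SE² ≥ 10 weak-instrument filter, with a
  per-step survivor report.
* **Estimators and diagnostics** — Wald ratio, fixed- and
  multiplicative-random-effects IVW, MR-Egger (slope + intercept test),
  weighted median with parametric-bootstrap SEs, MR-PRESSO
  (global/outlier/distortion tests), Cochran's Q, leave-one-out, and
  multivariable IVW.
* **Two-step mediation** — indirect effect β₁β₂ with the first-order delta
  CI, mediated proportion β₁β₂/β₃ (total effect fixed), and the
  difference-in-coefficients sensitivity method via multivariable MR.
* **Two-step cis-MR (TSCMR)** — per-instrument correction of the outcome
  association for a measured confounder pathway
  (β′ = β − b_gc·b_co, with delta-propagated SE), then re-estimation.
* **Synthetic data with known truth** — a fully seeded generator for
  two-sample datasets, mediation chains, confounder pathways, planted
  outliers, and block LD, so every stage is testable offline.

The core quantities, in the field's notation: per SNP *j* the Wald ratio is
β̂_Yj/β̂_Xj; IVW pools them with weights 1/se(β̂_Yj/β̂_Xj)²; the indirect
effect of a mediator is β₁ × β₂ with Var = β₁²σ₂² + β₂²σ₁², and the mediated
proportion is (β₁ × β₂)/β₃.

## A worked example

```r
library(cismr)

# a synthetic drug-target study: 22 cis instruments at F ~ 50,
# true protective effect OR = 0.493
sim <- simulate_two_sample(sim_config(seed = 1))
pairs <- harmonize(sim$exposure, sim$outcome)
mr_ivw(pairs)
#> IVW (22 SNPs, multiplicative random)
#>   beta -0.6538 (se 0.0596), 95% CI -0.7707 to -0.5369, p = 5.76e-28
#>   OR 0.520, 95% CI 0.463 to 0.585
```

The IVW log-odds estimate (−0.654) recovers the simulated truth
(ln 0.493 = −0.707) within its standard error; the OR row is the same
estimate exponentiated, the scale on which binary-outcome results are
reported.

Two-step mediation from published coefficient tables — exposure→mediator
β₁ = −0.167 (95% CI −0.215 to −0.120), mediator→outcome β₂ = 0.122 (0.064 to
0.180), total effect β₃ = ln(0.493) — with SEs back-derived from the CIs:

```r
med <- two_step_mediation(
  list(beta = -0.167, se = se_from_ci(-0.215, -0.120)),
  list(beta = 0.122,  se = se_from_ci(0.064, 0.180)),
  list(beta = log(0.493), se = NA_real_),
  mediator_id = "t2d"
)
med
#> Mediation through t2d (product-of-coefficients)
#>   beta1 -0.1670 (se 0.0242), beta2 0.1220 (se 0.0296)
#>   total -0.7072, direct -0.6869
#>   indirect -0.0204, 95% CI -0.0317 to -0.0091, p = 0.000403
#>   mediated proportion 2.88% (95% CI 1.28% to 4.48%)
```

The indirect effect −0.020 (−0.032 to −0.009) is the part of the protective
total effect flowing through the mediator; the mediated proportion says it
accounts for about 2.9% of the total.

`run_full_study()` orchestrates the whole design (selection → positive
controls → main MR → sensitivity → mediation → TSCMR) from one config list
and one seed; `write_study_report()` serializes every table as TSV plus a
JSON bundle. See the vignette (`vignettes/drug-target-mr.Rmd`) for the
models, conventions, and limitations.

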