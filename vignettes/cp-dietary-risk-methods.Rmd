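---
title: "Methods: dietary exposure and MOE risk characterization for chlorinated paraffins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary exposure and MOE risk characterization for chlorinated paraffins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpexposure)
```

## The problem

Chlorinated paraffins (CPs) are industrial polychlorinated n-alkanes,
quantified analytically as congener groups — one (carbon, chlorine) pair per
group. Short-chain CPs (SCCPs, C10–C13) and medium-chain CPs (MCCPs,
C14–C17) bio-accumulate in lipid-rich animal foods, and chicken meat is a
major dietary vector. The package implements the standard food-safety
workflow over congener-resolved concentration tables and an individual-level
consumption survey:

1. occurrence statistics per region (detection rates, means, ranges, pooled
   means, nonparametric regional comparisons with BH-FDR correction,
   SCCP–MCCP correlations);
2. homologue composition profiles (carbon-chain, chlorination-degree, class
   shares);
3. probabilistic estimated daily intake (EDI) via Monte Carlo over fitted
   parametric distributions, with rank-regression contribution-to-variance
   sensitivity analysis; and
4. margin-of-exposure (MOE) risk characterization against EFSA BMDL10 points
   of departure.

The core identities are

$$\mathrm{EDI} = \frac{C \times F}{BW}
\qquad\qquad
\mathrm{MOE} = \frac{\mathrm{POD}}{\mathrm{Exp}}$$

with $C$ the concentration in chicken (ng/g wet weight), $F$ daily chicken
consumption (g/d), $BW$ body weight (kg), so EDI is in ng/kg bw/d; POD is
the BMDL10 (2.3 mg/kg bw/d for SCCPs, 36 mg/kg bw/d for MCCPs), converted by
$10^6$ to ng/kg bw/d before division. MOE > 1000 is read as no significant
health concern. Reported MOEs are rounded half away from zero to integers;
classification always uses the unrounded ratio.

## Domain model and censoring

Each analyte class comprises exactly 24 congener groups: 4 carbon chain
lengths × chlorination degrees Cl5–Cl10. The chlorine range is an assumption
(the quantification convention reports 24 + 24 groups without stating it);
it is centralized in one enumeration so a different convention is a one-line
change.

Concentrations below the method detection limit (MDL: 3 ng/g ww for SCCPs,
5.0 ng/g ww for MCCPs) are left-censored. The reader substitutes them by
policy: `lower` → 0, `middle` → MDL/2 (default, the common dietary-exposure
convention), `upper` → MDL, and flags every imputed cell. The choice never
binds on the reproduction targets because the underlying survey had 100%
detects; the policies are ordered (lower ≤ middle ≤ upper cell-wise), which
is tested as a property.

## Synthetic data generator

No raw data are deposited with the underlying survey, so the package ships a
seeded generator whose defaults *are* the published study conditions — they
are a stated world, not tunable knobs:

* **Concentrations.** Eight regions with the published sample counts (n =
  126 total) and per-class mean/range targets. Class totals are lognormal —
  positive, right-skewed, consistent with mean ≪ max in every region — with
  the log-sd set so the central 99% interval matches the published min–max
  range, the log-mean set so the untruncated mean equals the published mean,
  then truncation to the range (inverse-CDF). This is a calibration device,
  not a claim about the study's data. Each sample's total is split across
  the 24 congener groups by a Dirichlet draw (concentration parameter 150)
  around a mean profile built as an outer product of carbon and chlorine
  margins chosen inside the published homologue bands (SCCP: C10 45%
  within the 29–63% band, C11 26% within 22–29%, Cl6 35% within 23–55%, Cl7
  28% within 22–34%, so C10–11Cl6–7 predominate; MCCP: C14+C15 = 62% within
  58–66%, Cl7–8 = 50% within 46–57%). The margins were additionally chosen
  so the 4th/5th-ranked group shares are separated by about 4 sd of the
  regional Dirichlet noise, making the stated "top four = C10–11Cl6–7"
  ordering robust rather than knife-edge. The last congener is set by
  difference so class totals equal the sum of their congeners exactly.
* **Survey.** Eight sex–age subgroups totalling 55,678 respondents
  (children's groups pooled across sexes, as published), each with three
  recall days. A day is a consumption day with probability 0.31; positive
  amounts are lognormal with log-sd 0.85 and subgroup medians calibrated so
  the pooled mean daily consumption is ≈ 16.8 g/d, the consumer-only
  (consumed on every recall day) mean is ≈ 54.7 g/d, and the
  exposure ordering puts children 3–6 y highest. Body weights are lognormal
  with subgroup medians from standard Chinese reference anthropometry
  (18–66 kg; the published study reports none — only the F/BW ratio matters
  for EDI). Subgroup sizes follow the population's age–sex structure.
* **Seeding.** One master seed; each region/subgroup draws from a named
  substream derived by hashing, so adding a region never perturbs another
  region's values (tested).

What a green test on synthetic data establishes: that the pipeline's
estimators recover the generating structure. What it does not establish:
anything about real inter-individual correlation between consumption and
body weight (not modeled beyond subgroup structure), real congener
covariance (Dirichlet is the simplest simplex noise), or the study's exact
sample-level values.

### A numerical caveat made explicit

Because the generator ties the lognormal log-sd to the published range
(central-99% match) and then truncates, refitting an untruncated lognormal
to truncated draws shrinks the log-sd deterministically by
$\sqrt{1 - 2c\,\varphi(c)/(2\Phi(c)-1)} \approx 0.9615$ with $c =
\Phi^{-1}(0.995)$ — far outside a 3-Monte-Carlo-SE band at n = 10,000. The
parameter-recovery property is therefore tested on untruncated draws
(`region_conc_spec(..., truncate = FALSE)`), and the truncated default is
tested against that theoretical shrinkage factor instead of pretending the
bias away.

## Occurrence statistics

Pooled means are sample-size weighted: $\sum_i n_i \bar{x}_i / \sum_i n_i$,
which equals the mean of the concatenated samples when the regional means
are exact. Applied to the published regional table this reproduces the
printed 95.8 (SCCP) and 156.6 (MCCP) ng/g ww overall means and the East
China / Northeast China pools at one decimal; North China SCCP pools to 73.5
against a printed 73.4, an artifact of the inputs being printed at one
decimal, and is deliberately not asserted.

Regional comparisons use the tie-corrected Kruskal–Wallis H with a
chi-square reference (k − 1 df); for total n ≤ 10 an exact permutation
p-value is computed by full enumeration. Enumeration over all 4+4 rank
splits shows the chi-square approximation is good in the rejection-relevant
tail (absolute error ≤ 0.031 for H ≥ 3) but off by up to 0.122 near the
null — the tests assert both facts rather than sampling around them.
Pairwise comparisons are two-sided Wilcoxon rank-sum tests (exact when both
groups ≤ 25 without ties, otherwise tie-corrected normal approximation with
continuity correction), adjusted by an own implementation of the
Benjamini–Hochberg step-up, cross-checked against `stats::p.adjust`. BH is
order-preserving, dominates the raw p-values, and is capped at 1; it is
*not* idempotent (re-adjusting adjusted p-values can raise them), so that
folk invariant is not asserted.

Correlations (Spearman by default — the published correlation panel is
Spearman, though the methods text says Pearson; both are implemented and the
method is recorded in the output) get 95% CIs via the Fisher z transform
with variance $1/(n-3)$ (Pearson) or $1.06/(n-3)$ (Spearman). Whether the
published CIs are Fisher-z or bootstrap is unstated; Fisher-z is the
documented choice. $|r| = 1$ collapses the CI to a flagged point.

## Congener profiles

Fractions are computed within class (carbon margins, chlorine margins, and
group-level shares) plus the class share of total CPs. Regional profiles are
concentration-weighted (sum, then normalize) by default; averaging
per-sample fractions is available because the published aggregation is
unspecified and the two differ whenever totals vary across samples (shown in
the tests with a two-sample toy). Zero class totals yield flagged missing
fractions rather than NaNs. Dominant groups rank by share with
deterministic (carbon, chlorine) tie-breaks and an explicit tie flag when
the cut lands inside a tied run.

## Exposure engine

`fit_distribution()` fits lognormal (closed-form MLE), gamma and Weibull
(numerical MLE via MASS) and selects by AIC = 4 − 2 logL. Zeros are never
fitted: consumption is zero-inflated, with the per-day consumer probability
estimated as the fraction of positive person-days and only positive amounts
fitted. Constant data are refused (`point_mass()` represents degeneracy
explicitly, and makes the Monte Carlo engine reduce *exactly* to the
deterministic EDI — a conservation law in the test suite).

`simulate_exposure()` draws 10,000 (default, as published) independent
(C, F, BW) triples and summarizes the EDI iterates by mean, P95 (type-7
linear-interpolation quantile), and a batch-means 95% CI half-width (20
equal batches, $1.96\,\mathrm{sd}(\text{batch means})/\sqrt{20}$). The
published tables' "95% CI" columns are internally inconsistent in magnitude
(e.g. 89.0 ± 1.8 next to 93.9 ± 22.0) and the estimator behind them is
undefined, so CI half-widths are reported but not reproduction targets.
Fewer than 1000 iterations are refused (unstable P95). C, F and BW are
independent in the simulation, as implied by separate distribution fitting;
`empirical_exposure()` offers the per-individual alternative that preserves
each respondent's (F, BW) pair and resamples concentrations from the
empirical totals.

P95 ≥ mean is *not* asserted anywhere (false for left-skewed inputs);
P95 ≥ median and monotonicity of P95 in the concentration scale are.

Sensitivity follows the rank-regression approximation of the proprietary
contribution-to-variance metric: rank-transform inputs and output, OLS,
then $100 \cdot \beta_i^{*2}/\sum_j \beta_j^{*2} \cdot R^2$ per input with
standardized coefficients $\beta^*$. The published 16.8%/2.3% figures
approximate a proprietary metric on undeposited data and are treated as
non-targets; the implementation is validated on constructions with known
answers (single active driver ≈ 100%, symmetric additive inputs equal
within Monte Carlo error, constants flagged at 0).

### Known bias of the whole-population parametric route

The pooled concentration sample is a cross-regional lognormal mixture with
one heavy region; a single min-AIC lognormal understates its arithmetic mean
by roughly 10% (the fit matches log-moments, not the mean). Consequently the
parametric whole-population SCCP EDI mean lands ~10–15% below the
generator's arithmetic value, while MCCP (more homogeneous regions) matches
closely. This is a property of the method, reported as such;
`empirical_exposure()` reproduces the arithmetic value.

## Risk characterization

`moe_table()` emits MOE^a (mean basis) and MOE^b (P95 basis) per group and
class. Against the published exposure statistics the computed integers
reproduce every printed MOE range endpoint exactly: 25,843–103,139 (SCCP
MOE^a, sex–age), 8358–33,675 (MOE^b), 271,493–1,084,337 / 87,379–357,143
(MCCP), and 14,456–333,333 / 4736–107,981 (SCCP regional), 426,540–4,736,842
/ 137,562–1,773,399 (MCCP regional). The $10^6$ mg→ng conversion is
hard-coded once, with both units carried in the result, and the conservation
$\mathrm{MOE}\cdot\mathrm{Exp}/\mathrm{POD} = 10^6$ is tested.

## Pipeline and reproducibility

`run_pipeline()` stages data → occurrence → profiles → exposure → risk,
writes CSVs (each with a units comment line) plus a JSON manifest (seed,
config digest, input digests, package version), and is a pure function of
(inputs, config, seed) — asserted by re-running and comparing bytes. The
CLI (`inst/cli/cp-pipeline.R`) fronts the same functions with subcommands
`simulate-data`, `occurrence`, `profile`, `exposure`, `risk`, `run-all` and
exit codes 0/1/2. Run configuration is JSON (no YAML parser in the
supported dependency set).

## Limitations

* Chicken only; no aggregation across food groups, no cooking/processing
  factors.
* No LCCPs (not measured in the underlying survey).
* Synthetic defaults reproduce published aggregates, not sample-level
  reality; exact published correlations (e.g. r = 0.721) require the
  undeposited raw data and are out of reach by construction.
* The consumption/body-weight joint structure is subgroup-level only.
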