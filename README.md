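# cpexposure

Dietary exposure and margin-of-exposure (MOE) risk assessment for short- and
medium-chain chlorinated paraffins (SCCPs, C10–C13; MCCPs, C14–C17) in
chicken meat.

Chlorinated paraffins are persistent industrial polychlorinated n-alkanes
that accumulate in lipid-rich foods. Risk assessors characterize dietary
risk from them in three steps, all implemented here as a tested, seedable
pipeline:

1. **Occurrence** — congener-group-resolved concentration tables
   (ng/g wet weight) summarized per region: detection rates against the
   method detection limits (3 ng/g SCCP, 5.0 ng/g MCCP; below-MDL cells
   substituted by a configurable 0 / MDL/2 / MDL policy), sample-size-weighted
   pooled means, tie-corrected Kruskal–Wallis and pairwise Wilcoxon tests
   with Benjamini–Hochberg FDR adjustment, and SCCP–MCCP correlations with
   Fisher-z confidence intervals. Homologue composition profiles (carbon
   chain, chlorination degree, class shares) are decomposed per sample or
   per region.
2. **Exposure** — the estimated daily intake of each individual in a 3-day
   dietary-recall survey,

   EDI = C × F / BW   (ng/kg bw/d),

   propagated probabilistically: concentrations, zero-inflated daily
   consumption amounts and body weights are fitted by maximum likelihood
   (lognormal/gamma/Weibull, AIC-selected) and combined by Monte Carlo
   simulation (10,000 iterations by default), per sex–age subgroup, with
   rank-regression contribution-to-variance sensitivity analysis.
3. **Risk** — MOE = POD / Exp, with the EFSA BMDL10 values (2.3 mg/kg bw/d
   for SCCPs, 36 mg/kg bw/d for MCCPs) as the point of departure, converted
   to ng/kg bw/d; MOE > 1000 means no significant health concern. MOE^a uses
   the mean exposure, MOE^b the 95th percentile (high consumers).

Because the underlying national survey deposits no raw data, the package
ships a seeded synthetic-data generator (`default_study_specs()`,
`gen_concentrations()`, `gen_survey()`) that emulates the published
structure: eight regions (126 samples) with the published class-total means
and ranges, congener profiles inside the published homologue bands, and a
55,678-respondent consumption survey in eight sex–age subgroups calibrated
to the published consumption means (16.8 g/d overall, 54.7 g/d for daily
consumers). See the methods vignette
(`vignettes/cp-dietary-risk-methods.Rmd`) for every modeling choice and its
rationale.

## Worked example

```r
library(cpexposure)

# pooled mean from the published regional occurrence table
occ <- reported_table("occurrence")
pooled_mean(occ[occ$analyte_class == "SCCP", ])   # 95.8 ng/g ww

# MOE for the published children-3-6 mean SCCP exposure
moe(2.3, 89.0, basis = "mean", label = "3-6", analyte_class = "SCCP")
#>   label basis exposure moe_reported risk_flag
#>     3-6  mean       89        25843      TRUE

# end to end on synthetic data (5% scale survey for speed)
specs  <- default_study_specs(survey_scale = 0.05)
conc   <- gen_concentrations(specs$regions, seed = 1)
survey <- assign_subgroups(gen_survey(specs$subgroups, seed = 1))
tot    <- class_totals(conc)
fitc   <- fit_distribution(tot$total_ng_g[tot$analyte_class == "SCCP"])
fitc$family                                        # "lognormal"
days   <- unlist(survey[, c("day1", "day2", "day3")])
s <- simulate_exposure(
  fitc,
  cons_model(mean(days > 0), fit_distribution(days[days > 0])),
  fit_distribution(survey$body_weight),
  n_iter = 10000, seed = 2, subgroup = "All", analyte_class = "SCCP"
)
c(s$mean, s$ci_half_width, s$p95)  # 31.0 3.4 153.7  (ng/kg bw/d)
moe_table(list(s))
#>   label analyte_class basis  exposure moe_reported risk_flag
#>     All          SCCP  mean  31.04672        74082      TRUE
#>     All          SCCP   p95 153.72800        14961      TRUE
```

The simulated whole-population mean (31.0 ng/kg bw/d) sits near the
published 32.8 ng/kg bw/d, and both MOEs clear the 1000 threshold by orders
of magnitude — the study's central finding. The full pipeline with output
CSVs and a run manifest:

```r
run_pipeline(default_run_config(seed = 1), out_dir = "cp_out")
```

or from the command line (subcommands `simulate-data`, `occurrence`,
`profile`, `exposure`, `risk`, `run-all`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cp-pipeline.R", package = "cpexposure"))') \
  run-all --seed 1 --out-dir cp_out
```

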