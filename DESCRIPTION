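Package: cpexposure
Title: Dietary Exposure and Margin-of-Exposure Risk Assessment for
    Chlorinated Paraffins in Chicken Meat
Version: 0.1.0
Authors@R:
    person("CP", "Exposure Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for occurrence statistics, congener-group profiling,
    probabilistic dietary exposure estimation, and margin-of-exposure (MOE)
    risk characterization of short- and medium-chain chlorinated paraffins
    (SCCPs, C10-C13; MCCPs, C14-C17) in chicken meat. Implements readers and
    validators for congener-resolved concentration tables and dietary-recall
    consumption surveys, left-censored (below-MDL) substitution policies,
    regional summaries with Kruskal-Wallis and pairwise Wilcoxon (BH-FDR)
    comparisons, homologue composition decomposition, per-kilogram-bodyweight
    estimated daily intake (EDI = C x F / BW) by Monte Carlo simulation over
    fitted parametric distributions with rank-regression sensitivity
    analysis, and BMDL10-based MOE classification. A seeded synthetic-data
    generator emulates the regional concentration structure and the sex-age
    consumption-survey structure of a national chicken-meat survey so the
    full pipeline is testable without raw measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
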