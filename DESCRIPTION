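Package: ppcpscreen
Title: Screening and Prioritization of Pharmaceuticals and Personal Care
    Products in Wastewater Treatment Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening-level hazard and risk
    assessment of pharmaceuticals and personal care products (PPCPs)
    observed in wastewater treatment plant (WWTP) influents and effluents.
    Literature-style monitoring records are quality-scored (0-6 quality
    index) and filtered; removal efficiency (RE) is computed per record
    from influent/effluent concentrations or a sludge mass balance,
    binned into classes, and reduced to a worst-case consensus class per
    chemical and plant type (secondary-only WWTP1 vs tertiary/advanced
    WWTP2). Per-model QSAR property predictions are aggregated with
    applicability-domain gating and experimental-value priority, then
    compared to regulatory screening thresholds (REACH Annex XIII, CLP
    mobility criteria) to flag persistent, mobile and toxic (PMT),
    persistent, bioaccumulative and toxic (PBT), vPvM/vPvB and endocrine
    disruption candidates. Risk quotients (effluent concentration over a
    PNEC derived from minimum predicted acute toxicity with an assessment
    factor) support final prioritization. A seeded synthetic-data
    generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
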