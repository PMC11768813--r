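---
title: "Methods: screening and prioritizing PPCPs in wastewater treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and prioritizing PPCPs in wastewater treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcpscreen)
```

## The procedure and its assumptions

`ppcpscreen` chains four screening-level stages. Each stage is a pure
function of tabular inputs, so intermediate results can be inspected,
replaced or re-run in isolation.

**Quality indexing.** Literature monitoring records are heterogeneous;
before any arithmetic, each record gets three 0–2 sub-scores
(molecule identification, RE-data quantifiability, general plant
information). Their 0–6 sum maps to Low (0–1), Moderate (2–3),
Good (4–5), Excellent (6), and Low records are excluded everywhere
downstream. The package hard-codes only this total-to-class mapping;
how a data curator arrives at each 0–2 sub-score is inherently
rubric-dependent and therefore stays an input rather than a
computation. The shipped defaults in the generator emulate a mostly
moderate-to-good corpus with a configurable share of Low records.

**Plant typology.** Treatment trains are reduced to a binary typology:
WWTP1 (primary and/or secondary treatment only) and WWTP2 (any
tertiary/advanced stage). A declared treatment level decides directly.
Otherwise free-text technology tokens are matched against a
configurable tertiary-keyword list (`tertiary_keywords()`); an
explicit "tertiary" token or at least two distinct tertiary
technologies count as firm evidence, while a single ambiguous token
falls back to WWTP1. This worst-case fallback deliberately biases the
typology toward the less capable plant class, which is the
conservative choice for a screening exercise. The two-token rule and
the keyword list are our operationalization of prose classification
guidance and are exposed as arguments rather than constants.

**Removal efficiency.** Per-record RE uses a fixed precedence:
a source-reported RE wins; otherwise the sludge mass balance
`RE% = (Ci·F − (Ce·F + Cs·TSP))/(Ci·F)·100` when all five parameters
are present (loads in ng/d: Ci, Ce in ng/L, F in L/d, Cs in ng/g wet
weight, TSP in g/d); otherwise the concentration ratio
`(1 − c_effl/c_infl)·100` on medians (means only when no median
exists). The mass balance reduces exactly to the ratio when the sludge
term is zero — a tested identity. RE may be negative (apparent
in-plant formation by de-conjugation or metabolite
back-transformation) and is bounded above by 100.

Classes partition the real line with upper-closed bins — Other (≤ 0),
Low (0, 50], Moderate (50, 75], High (75, 95], Excellent (> 95) — and
the computed percent is binned without prior rounding, so boundary
behavior is exact. Censored concentrations (below the limit of
quantification or detection) yield NoData under the default policy;
the alternative `"formation"` policy maps a censored influent with a
detected effluent to class Other, reading such records as in-plant
formation. Both policies are explicit options because non-detect
handling is a genuine judgment call on which reasonable curators
differ.

**Consensus.** When a chemical has several records in one plant type,
the most represented class wins; NoData is set aside whenever any
quantified class exists (equivalently: if NoData is modal, the next
most populated class is taken); ties resolve to the *worst* class
under Other < Low < Moderate < High < Excellent. Placing Other below
Low is the worst-case reading — a chemical that is sometimes formed in
the plant is a bigger concern than one merely poorly removed. The
implementation is verified against an independent brute-force oracle
on every multiset of up to five records over the six classes
(461 cases, exhaustive).

**Hazard screening.** Per-model predictions enter as data — the
package deliberately does not reimplement BIOWIN, KOWWIN, KOCWIN,
OPERA or similar QSAR models, nor their applicability-domain (AD)
calculations. Aggregation per partitioning endpoint: an experimental
value, when present, pre-empts predictions; otherwise the arithmetic
mean of in-domain regulatory-level (L1) predictions; for Log Koc only,
the Soil-Koc model alone is used when KOCWIN (MCI) is out of domain
(when both are in domain their mean is used — the fallback rule
governs only the out-of-domain case). Out-of-domain predictions are
inert: tests perturb them arbitrarily and require identical output.

Screening flags use strict inequalities throughout:

| Flag | Rule | Default |
|------|------|---------|
| pP (joint pP/pvP) | BIOWIN3 < 2.25 and (BIOWIN2 < 0.5 or BIOWIN6 < 0.5) | `p_rule = "or"` |
| pB | Log Kow > 4.5 or Log BCF > 3.3 | — |
| pvB | Log BCF > 3.7 | — |
| pM / pvM | Log Koc < 4 / < 3 (conservative) or < 3 / < 2 (EU 2023) | both profiles evaluated |
| pT | min acute EC50/LC50 < 0.1 mg/L (strict variant 0.01) | 0.1 mg/L |
| pED | ER, AR or hTTR binding at any strength | — |

Molar toxicity predictions (−log10 mol/L or mmol/L) convert via the
molecular weight; minima are taken per basis (lethal LC50 endpoints
from fish models; effect EC50 endpoints from algae and *Daphnia*),
only over in-domain values.

Labels: PBT = pP∧pB∧pT, PMT = pP∧pM∧pT. The BIOWIN rule yields a joint
"pP or pvP" flag that cannot affirm *very* persistent on its own, so
vPvB/vPvM labels require an explicit `pvP` assertion; by default the
label set is a subset of {PBT, PMT} and pvB/pvM travel as flags. This
matches published screening practice, where a chemical with pvM and
joint persistence is classified PMT, with very-mobility reported at
the flag level. Choosing the "or" combination of the two
fast-biodegradation probabilities (with "and" selectable) is likewise
the worst-case screening reading of a rule whose prose lists the
criteria jointly. Level-2 (non-regulatory) models such as a global
half-life index or a composite PBT index annotate the verdict's
provenance but never enter label logic.

**Risk.** `PNEC [ng/L] = min(EC50 or LC50) [mg/L] · 10^6 / AF` with
assessment factor AF = 1000 (acute data, three trophic levels, per the
EU technical guidance; configurable). `PR = CA/PNEC` per measured
effluent concentration and per basis; a chemical is flagged when any
PR exceeds 1 strictly — PR = 1.0 exactly is not a flag. Chemicals with
no measured concentration are excluded from the risk stage entirely
rather than imputed. The prioritized list intersects
hazard-labelled with risk-flagged chemicals; the intersection is by
construction a subset of both, which is property-tested.

## The synthetic study generator

`generator_config()` defines the study conditions; `generate_study_data()`
emits the record, prediction, ED-flag and concentration tables plus the
ground truth. Design choices:

- **Archetypes.** Chemicals are drawn from four archetypes (PMT-like,
  PBT-like, ED-only, benign; default mix 0.25/0.25/0.2/0.3). Each true
  property value is sampled from a truncated normal whose support
  keeps it at least three prediction-noise standard deviations away
  from every threshold the archetype addresses (e.g. PMT-like
  Log Koc centred at 1.2 and clamped to ≤ 1.55 against the strictest
  very-mobility cut-off of 2; BIOWIN3 centred at 1.6, clamped to
  ≤ 1.8 against 2.25). This margin is what makes near-perfect label
  recovery at the default noise level a designed property rather than
  luck, and it is asserted directly in the tests.
- **True labels** are whatever `assess()` returns on the noiseless
  truth — the generator never encodes label logic of its own.
- **Concentrations.** Influents are log-normal (median 1000 ng/L,
  sdlog 0.8 — the ng/L-to-µg/L span typical of effluent monitoring);
  effluent = influent · (1 − RE/100) · (1 + ε) with ε ~ N(0, cv),
  cv = 0.05 by default. True REs sit at class-interior values
  (−25, 25, 65, 85, 98), far from bin edges relative to the induced
  RE noise; WWTP2 performance is sampled to be at least as good as
  WWTP1. At high cv the multiplicative noise produces genuinely
  negative computed REs, which the tests require.
- **Censoring** applies independently to influent and effluent below
  the LOQ (default 5 ng/L), exercising both non-detect policies.
- **AD dropout** defaults to 0: domain membership is a property of the
  external QSAR models, not a stochastic feature of a monitoring
  study; the knob exists to exercise gating (tests drive it to 1 for
  the Koc models and verify that mobility becomes unassessable and no
  PMT label can fire).
- **Determinism.** A single integer seed fixes everything; identical
  configs produce byte-identical CSVs (tested).

What passing recovery tests show — and do not show: they demonstrate
that the pipeline's logic inverts the generator's data model exactly
(zero noise) and robustly (default noise, label recovery ≥ 0.99 at
n = 200). They do not show that real literature corpora satisfy the
generator's assumptions: real QSAR errors are correlated across
models, real concentration noise is not i.i.d. multiplicative, real
quality scores correlate with laboratories, and real chemicals sit
near thresholds (indeed the published borderline cases — e.g. a
triclocarban-like Log Koc of 3.25 between the two mobility profiles —
are exactly the chemicals archetypes avoid). Threshold-boundary
behavior is therefore pinned by direct worked-example tests, not by
recovery statistics.

## Numerical and interface choices

- All threshold comparisons are strict (`<`, `>`) as printed in the
  regulatory screening criteria; no tolerance is added.
- RE percents are classified without rounding; report tables round
  only at render time (`render_percent()`, integer style for the
  plant-type distribution, two decimals for the risk cross-tab), and
  underlying tables keep full precision.
- Degenerate inputs are values, not errors, wherever the screening
  semantics define them: a zero/censored influent gives a NoData RE;
  a missing endpoint gives an unassessable flag (`NA`), which
  combines as "not flagged"; an empty risk table summarizes to zero
  rows. Validation errors are reserved for structural problems
  (sub-scores outside 0–2, unknown units or classes, missing columns —
  reported with the table and column name).
- Ionizable chemicals are assessed as neutral species; no speciation
  correction is attempted. This is a stated limitation of
  Kow/Koc-based screening for the many ionizable PPCPs.
- Test and example problem sizes (up to 200 chemicals, ~16 plants,
  exhaustive consensus enumeration at multiset size ≤ 5) were chosen
  so the whole suite runs in well under a minute while still giving
  the binomial margin arguments force.

The interface is the R function surface plus `scripts/acceptance.R`;
the stages are meant to be composed in scripts and notebooks
(`run_pipeline()` is itself just that composition), so no separate
shell executable is provided.

## Known limitations

- The quality-index sub-score rubrics are inputs; the package cannot
  detect an inconsistent rubric.
- Consensus treats records as exchangeable; no weighting by study
  size, year or analytical method.
- The PMT/PBT screening is a threshold engine over externally supplied
  predictions; prediction uncertainty enters only through the AD flag,
  not as a distribution.
- PNECs derive from predicted acute toxicity with a fixed assessment
  factor; chronic endpoints and species-sensitivity distributions are
  out of scope.
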