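---
title: "Modelling preanalytical and analytical variability of plasma microRNA quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preanalytical and analytical variability of plasma microRNA quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvar)
```

## The problem

Circulating microRNAs are attractive plasma biomarkers, but their measured
levels are notoriously sensitive to how the plasma was prepared
(centrifugation protocol, residual platelets, hemolysis), how the RNA was
purified, and which quantification platform and normalization strategy was
used. mirvar implements a complete analysis pipeline for the canonical study
design that dissects these sources: a 30-tube single-donor
centrifugation-protocol comparison, a 50-patient two-material cohort, a
single-assay vs low-density-array comparison, and a pooled-sample precision
experiment run as 15 independent analyses x duplicate reverse transcription
x duplicate PCR on qPCR and droplet digital PCR, with the assays miR-92a,
miR-126, miR-16 and the spike-in cel-miR-39.

## Quantification model

**qPCR / TLDA.** Replicate wells are averaged on the Ct scale, then
normalized: `delta_ct = ct_target - r` with `r` the reference Ct
(cel-miR-39 for the spike strategy, miR-16 for the endogenous strategy, or
their arithmetic mean for the combined strategy), and the relative level is
`2^-delta_ct`. Averaging reference Cts is equivalent, on the level scale,
to taking the geometric mean of the two single-reference levels — an exact
identity that the test suite asserts. Determined Cts above 40 cycles are
demoted to the explicit undetermined state (`NA`), since the protocols run
40 cycles; undetermined wells are excluded from replicate means, and a
sample whose wells are all undetermined is an error rather than a silent
gap. How the original study handled undetermined wells is not documented;
exclusion is this package's own rule.

**ddPCR.** Each well's concentration follows the Poisson occupancy model:
with `k` of `n` droplets positive, `lambda = -ln(1 - k/n)` copies per
droplet and `concentration = lambda / volume` with the droplet volume
defaulting to 0.85 nL (the QX100-class constant). Duplicate wells are
converted to concentrations first and then averaged (pooling raw counts
across wells is available as `pool_counts = TRUE` but is not the default,
matching a workflow that normalizes the mean of duplicate measurements).
A fully positive well is flagged saturated and refuses conversion: the
estimator diverges there, and `lambda >= 20` drives wells to saturation
with near certainty. Normalization divides by the reference concentration,
or by the geometric mean of the two references for the combined strategy.

A reference is never its own target: miR-16 cannot be normalized to itself,
and the spike is only ever a reference, so the endogenous and combined
strategies produce levels for miR-92a and miR-126 only.

## Precision statistics

The precision experiment yields, per run, one duplicate pair of final
normalized levels (the two RT replicates, each already averaged over its
PCR wells). From the `k` complete pairs:

* **repeatability (intra-assay CV)** uses the pooled within-run duplicate
  SD in Dahlberg form, `100 * sqrt(sum(d_i^2) / (2k)) / grand_mean`;
* **precision (inter-assay CV)** is the CV (`(SD/mean)*100`, sample SD) of
  the `k` run means.

A duplicate design does not uniquely dictate this split, and published
tables rarely say which reading was used; the alternative — the CV of all
`2k` individual values — is exposed as `inter_method = "all_values"` so
either convention can be reproduced. Runs missing one pair member are
dropped with a warning; fewer than three complete runs is an error. Note
the commonly stated rule of thumb that the within-run CV is bounded by the
pooled CV of all values holds when between-run variation dominates but can
invert when it is absent (the pooled estimator's `2k - 1` denominator
undercuts the Dahlberg `2k`); the test suite therefore checks the ordering
under between-run-dominant configurations only.

**Attribution.** The whole-procedure CVs of the centrifugation experiment
include plasma preparation, purification and measurement; the repeatability
CV of the pooled-sample experiment isolates the measurement. Their
comparison,

```
cv_total = (cv_single + cv_dual) / 2
fraction = 100 * (cv_total - cv_rt_qpcr) / cv_total
```

assigns the excess intra-assay variation to centrifugation + purification.
The fraction is reported unclamped (a negative value flags estimation noise
with a warning), and rounding — half away from zero, integers for
fractions, one decimal for CVs — happens only at presentation.

## Comparison statistics

Protocol comparison uses the Student t-test, by default the unpaired
equal-variance two-sample form matching a per-protocol group presentation;
because all 30 tubes came from one venipuncture a paired reading is equally
defensible, so `pairing = "paired_by_adjacent_tube"` pairs each dual tube
with the following single tube in draw order. The order-of-draw check
compares the first and last third of the draw sequence (10 vs 10 tubes in
the full design). Degenerate inputs are handled explicitly: identical
groups report `t = 0, p = 1` (no evidence), constant data in the standalone
order-of-draw test is an error, while the pipeline maps it to `p = 1` so a
zero-variance configuration flows through end-to-end.

Agreement between materials and platforms uses Spearman's rank correlation
with average ranks; the two-sided p-value comes from the exhaustive
permutation null for `n <= 8` without ties and from the t-approximation on
`n - 2` df otherwise (at the study's `n = 50` the approximation is
standard). The qualitative labels (|rho| < 0.3 "none", 0.3–0.7
"intermediate", > 0.7 "good") are a presentation convention of this
package, not a statistical test.

The paired sample-size calculation converts a relative difference, a
relative SD and a within-pair correlation into the effect size
`d = diff / (sd * sqrt(2 (1 - rho)))` and solves
`n = (t_{1-a/2, n-1} + t_{power, n-1})^2 / d^2` to a fixed point (damped
iteration — near one degree of freedom the raw map oscillates), rounding
up. At a 10% difference, 20% SD, correlation 0.85, two-sided alpha 0.05 and
power 0.8 this gives 12 pairs; very large effects floor at 2–4 pairs,
where the t-quantiles' blow-up at one degree of freedom dominates.

## The synthetic-data generator

Every downstream stage is testable without any download because the
generators emulate the full hierarchical variance structure. Noise is
additive on the Ct (log2) scale; contamination is added to copy numbers in
the linear domain and converted via `ct = mu - log2(level)`. This matches
the exponential chemistry of PCR and makes every normalized level exactly
lognormal, so closed-form CVs exist for any configuration and the test
suite can compare estimates against analytic values rather than against
other simulations.

A well's Ct decomposes as baseline + run effect + aliquot terms + RT effect
+ well noise. Two structural choices matter:

* The overall **extraction efficiency** of an aliquot (`sigma_extraction`)
  is shared by all assays including the spike, so it cancels in every
  Delta-Ct — that cancellation is exactly what spike-in normalization is
  for, and the generator makes it visible.
* The **purification term** (`sigma_prep`) is drawn independently per assay
  within the aliquot: each microRNA's recovery through the column varies
  individually. A fully shared purification term would cancel in every
  normalization and make purification noise invisible, contradicting the
  central observation that preparation and purification dominate
  intra-assay variation. The spike receives an additional per-aliquot
  dispensing term (`sigma_spike_pipette`), the one technical term that
  spike normalization *adds*.

The centrifugation experiment assigns odd draw positions to dual and even
positions to prolonged single centrifugation, one aliquot and one RT per
tube, duplicate wells. The patient cohort draws per-subject true log2
levels (`biological_sd`), measures both materials, and gives standard
plasma a linear-domain platelet term `c_s * platelet_load[assay]` (with a
per-subject lognormal residual-platelet index `c_s`) plus a hemolysis term
for miR-16 — so material agreement degrades under spike normalization but
partially survives endogenous normalization, since the shared platelet
index cancels in the target/miR-16 ratio. TLDA is qPCR plus a per-assay,
per-card pre-amplification effect (`sigma_preamp`); ddPCR shares the
cohort aliquot's RT products and samples droplet counts binomially via the
occupancy model. The precision experiment nests RT effects within run
effects and shares both across platforms, mirroring one cDNA feeding both
instruments.

**Defaults.** Baseline Cts (miR-92a 17.7, miR-126 23.0, miR-16 14.3,
cel-miR-39 21.0) encode the reported fold structure: miR-16 ~8 cycles
(256-fold) above miR-126, 3–4 cycles above miR-92a, cel-miR-39 ~2 cycles
above miR-126. Variance components (`sigma_day` 0.30, `sigma_prep` 0.15,
`sigma_rt` 0.06, `sigma_pcr` 0.05, `sigma_extraction` 0.50,
`sigma_spike_pipette` 0.20, `sigma_preamp` 3.0 cycles; `biological_sd`
0.8 log2 units) were chosen once so that whole-procedure CVs land near
20%, qPCR repeatability near 5–7%, precision near 25–30%, and the
attribution fraction in the 55–70% range — the magnitudes typical of this
kind of study — and so that pre-amplification noise removes single-assay
vs TLDA correlation. Component-level variances are not published anywhere,
so the day/RT split in particular is illustrative: only its sum is
identifiable from a duplicate design. ddPCR baselines (`conc0`) put
occupancies in the informative Poisson range (lambda 0.02–0.45 at 0.85 nL
and 15 000 droplets/well).

**Determinism.** All randomness flows from one seed; equal configurations
give bitwise-identical tables. A configuration with every SD and load at
zero is a strict fixed point: Cts equal `mu_ct` exactly, and droplet
occupancy is then set to its expectation instead of being sampled, so the
zero-variance property holds end-to-end for ddPCR too (any nonzero
component restores binomial sampling). This is a deliberate discontinuity:
Poisson counting noise is physically irreducible, and the deterministic
branch exists for verification, not realism.

**What the generator does not emulate** — and hence what green tests do
not establish about real data: amplification-efficiency differences between
assays (the 2-fold-per-cycle model is exact here), droplet "rain" and
threshold ambiguity, inhibitors, degradation during storage, batch effects
in reagent lots, and any correlation between biological levels across
microRNAs. Passing the recovery tests shows the estimators are correct
under the stated lognormal hierarchy, not that real plasma data obey it.

## Problem sizes and numerical choices

Closed-form recovery tests run the precision design at 400 runs, where the
sampling error of a CV estimate is a few percent relative — comfortably
inside the ±10% acceptance band; Monte-Carlo calibration checks use
50–200 replicate simulations at the study's own design sizes. CSV
round-trips serialise doubles at 17 significant digits so read-after-write
is exact. Ties in ranks use average ranks; the exact Spearman null is
enumerated only for `n <= 8`. XLSX input is supported (via readxl); output
is CSV only. Report files contain no timestamps, so a re-run with the same
configuration and seed is byte-identical.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
study <- run_study(cfg)
study$attribution
paired_sample_size()          # 12
fold_difference(8)            # 256
estimate_concentration(10000, 20000)  # lambda = ln 2, 815.5 copies/uL
```

## Known limitations

Reproducing the source study's published summary tables exactly requires
its deposited raw measurement workbook; this package ships the schema and a
reader, but mapping that workbook's layout onto the schema is left to the
user. The inter-assay CV convention and the paired-vs-unpaired protocol
test are both ambiguous in typical reports; both readings are implemented
and the defaults documented above. The attribution statistic compares CVs
estimated on different materials (fresh single-donor plasma vs a frozen
pool) and inherits that design's assumptions.
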