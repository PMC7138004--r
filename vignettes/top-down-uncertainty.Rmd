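---
title: "Top-down measurement uncertainty from routine QC data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-down measurement uncertainty from routine QC data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labmu)
```

## The model

A clinical laboratory result carries a measurement uncertainty (MU) that a
top-down analysis estimates directly from quality-control performance data,
treating random and systematic effects as components with similar statistical
properties:

* **Imprecision** is the long-term within-laboratory coefficient of variation,
  `CV_WL`: each internal QC level contributes `100 * SD / mean` over its
  result series, and `CV_WL` is the unweighted arithmetic mean across levels.
* **Bias** is the relative deviation from an accepted reference, estimated
  from any of three sources: proficiency-test (PT) rounds against the
  peer-group assigned value, certified reference calibrators (CRC) against
  their certified value, and inter-laboratory internal QC scheme (IQCS)
  monthly peer comparisons. Individual biases
  `b_i = 100 (x_i - a_i) / a_i` are aggregated as the root mean square,
  `RMS_bias = sqrt(mean(b_i^2))`, which dominates the absolute mean and keeps
  sign-cancelling biases visible.
* Only satisfactory PT results enter: rounds with z-scores strictly beyond
  ±2 are discarded. The boundary |z| = 2 is kept. Rounds missing a provider
  z-score are, by default, rescored from the assigned value and peer CV.

The uncertainty *of the bias* depends on which published formulation is used:

| Approach | PT | CRC | IQCS |
|---|---|---|---|
| Nordtest | `sqrt(RMS^2 + u(PT)^2)` | `sqrt(RMS^2 + u(CRC)^2 + u(Cal)^2)` | `sqrt(RMS^2 + u(IQCS)^2)` |
| Eurolab  | `sqrt(RMS^2 + u(PT)^2 + (CV_rep/sqrt(n_rep))^2)` | identical to Nordtest | ND |
| Cofrac   | `sqrt((range/2/sqrt(3))^2 + s_b^2)` | NE | same as PT |

where `u(PT) = sqrt(mean(CV_PT,i^2 / n_lab,i))` pools the standard errors of
the peer assigned values over rounds (analogously `u(CRC)` over a
calibrator's replicate series and `u(IQCS)` over peer comparisons), and
`u(Cal)` is the certificate's expanded uncertainty divided by its coverage
factor, expressed relative to the assigned value. The two structurally empty
cells are fixed: Eurolab needs duplicate measurements that IQCS reports do
not carry (ND), and the Cofrac formula has no bias term for calibrator data
(NE). A third status, NC, is data-driven: an analyte without a peer group
simply has no records for that source.

Imprecision and bias uncertainty combine in quadrature,
`u_c = sqrt(CV_WL^2 + u(Bias)^2)`, and the expanded uncertainty is
`U = k * u_c` with `k = 2` (~95% coverage) by default. Everything is carried
as relative uncertainty in percent, which makes every statistic invariant
under concentration unit rescaling.

## Design choices in the ambiguous corners

Several pieces of the published formulations are stated loosely; the package
fixes them as follows and records the choices in the JSON report's
`settings` block.

* **Pooling across rounds (the `u(PT)`/`u(CRC)`/`u(IQCS)` aggregations)**
  uses root-mean-square pooling of the per-item `CV/sqrt(n)` terms rather
  than their arithmetic mean, for consistency with the RMS bias aggregation
  and quadrature propagation. For homogeneous rounds the two differ by less
  than reporting precision.
* **The Eurolab bias term** is the RMS bias when several rounds are
  aggregated (`eurolab_bias_term = "rms"`), with `"mean"` available for the
  literal mean-deviation reading. When no PT round carries replicate
  measurements the replicate term is omitted (zero) and the cell remains
  computed; the data-driven ND is reserved for IQCS.
* **The Cofrac dispersion term** is the sample SD of the item biases in
  percentage points, not a literal CV of the biases: signed, near-zero mean
  biases make a CV explode and would be non-reproducible.
* **Sample SDs** use the n−1 denominator throughout, the QC convention.
* **Rounding** happens only at the reporting edge, half away from zero to
  the configured decimals; all arithmetic is at full precision, and the JSON
  report keeps full precision alongside the rounded TSV.
* **Degenerate inputs** are errors, not guesses: fewer than two results per
  QC level, fewer than two replicate series per calibrator, fewer than two
  bias items for a half-range, peer groups of fewer than two laboratories,
  non-positive assigned values.

## Quality goals

Two families of analytical performance specifications are supported:

* **Westgard desirable allowable total error** from biological variation:
  `TEa = 1.65 * (0.5 CV_I) + 0.25 * sqrt(CV_I^2 + CV_G^2)` (z = 1.65, 95%
  one-sided, configurable). CV_I and CV_G are user-supplied: the package
  deliberately bundles no biological-variation database, since database
  revisions shift the goals.
* **Permissible uncertainty from the reference interval** (the Haeckel-style
  non-linear relation). The empirical reference-interval CV assumes the
  interval spans the central 95% of a log-normal population,
  `CV_E = 100 * sqrt(exp(s^2) - 1)` with `s = ln(UL/LL)/3.92`; when the
  lower limit is unknown it is set to 15% of the upper limit. `CV_E` is then
  mapped through two power laws, `pU = 2.7723 * CV_E^0.4452` for routine
  results and `pU_PT = 4.4871 * CV_E^0.4489` for single PT results. The
  original relation is available only as printed input→output pairs at
  one-decimal precision, so the constants here are least-squares calibrated
  (in log space) to four published reference-interval → limit pairs
  (creatinine 44–97 → 10.6/17.3; testosterone 8.8–30.6 → 13.1/21.6; ALP
  <128 and CA 19-9 <37, both of relative interval width 0.7391, → 16.0/26.2),
  which they reproduce within 0.2 percentage points. Because the mapping
  depends on the limits only through their ratio, it is scale invariant, and
  intervals of equal relative width receive identical limits by construction.
  The PT limit is the wider companion (the ratio pU_PT/pU is ≈1.64
  throughout the calibrated range).

`verdict()` flags a budget against `permissible_u` and `allowable_te`, and
optionally the observed total error `TE = |bias| + 1.65 * CV_WL` against its
allowable goal; which bias source feeds that TE is left to the caller, since
the three sources legitimately disagree.

## What the synthetic generator emulates

`simulation_config()` describes a creatinine-like analyte under typical
verification conditions, and those defaults are the conditions every
recovery test runs under: two QC levels (80 and 400 µmol/L) with 250 results
each, true CV_WL 2.0%, a persistent method bias of +5.2%, 13 PT rounds of 30
laboratories at 3% peer CV with the PT sample measured in duplicate, one
certified calibrator (724.9 ± 11.6, k = 2) measured in 10 analytical series,
six monthly IQCS comparisons of 49 laboratories (20 IQC results behind each
monthly mean, no duplicates — so the Eurolab IQCS cell exercises its ND
path), and a 5% rate of gross-error PT rounds injected beyond |z| = 3.

Two generator choices deserve justification:

* **Noise is Gaussian everywhere.** The CV-based statistics of the method
  presuppose approximately Gaussian QC dispersion; heavy-tailed or
  log-normal behaviour of low-concentration tumour markers is not simulated.
* **The simulated PT provider scores z against a prescribed evaluation SD**
  (`z_eval_cv`, default 6% of the target — a deviation limit of ±12%,
  typical of clinical-chemistry schemes), the ISO 13528 convention, rather
  than against the observed peer SD of the round. This matters: with a true
  bias of 5.2% and a 3% peer CV, scoring against the raw peer SD puts the
  honest laboratory at z ≈ 1.7 and the |z| ≤ 2 filter would systematically
  discard its worst-looking rounds, truncating the very bias the simulation
  is supposed to carry — a laboratory whose scheme scored that way could not
  have 13 retained rounds at that bias. Peer-SD scoring remains available
  (`z_eval_cv = NULL`) for studying exactly that truncation effect.

Under the default conditions the seed-median Nordtest-PT expanded
uncertainty over 200 seeds is ≈11.6%, close to the analytic
`2 * sqrt(2^2 + 5.2^2) = 11.1%` (the excess is the peer-noise contribution to
the per-round biases), and the estimated CV_WL at 1000 results per level is
within 10% relative of truth in essentially all seeds. These are the problem
sizes used throughout the test suite and the acceptance script; they were
chosen to mirror the data volumes a laboratory accumulates in two to five
years of routine QC.

What passing these tests does **not** show about real data: peer groups are
simulated as unbiased and method-homogeneous (no method-specific peer-group
bias), calibrator replicates are independent across series (no calibration
drift or lot changes), and PT materials are assumed commutable. With real
data those effects fold silently into the bias component.

## Limitations

* The bottom-up (GUM cause-and-effect) budget and preanalytical uncertainty
  are out of scope.
* The Cofrac formula reflects only the spread of biases, not their
  magnitude; with a large, stable bias it can report a smaller uncertainty
  than Nordtest does from the same data. That is a property of the formula,
  not of this implementation.
* The permissible-uncertainty constants are a calibrated approximation of a
  relation published only as printed pairs; outside the calibrated CV_E
  range (roughly 20–52%) they extrapolate.
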