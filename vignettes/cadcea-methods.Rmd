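---
title: "Methods: a decision-analytic model of two CAD diagnostic strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-analytic model of two CAD diagnostic strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadcea)
```

## The decision problem

Two work-ups for suspected coronary artery disease both deliver the
information current guidelines ask for before revascularization — evidence
of hemodynamically significant ischemia plus full coronary anatomy:

1. **CMR + CXA**: perfusion cardiovascular magnetic resonance first;
   ischemia-positive patients go on to invasive coronary angiography.
2. **CXA + FFR**: angiography in everyone; fractional flow reserve in
   patients with a ≥50% diameter stenosis. This invasive combination is
   treated as the diagnostic reference with perfect accuracy.

The model is expectation-based, built on Bayes' theorem: for a cohort with
pre-test likelihood `p` of significant disease, each branch of the decision
tree has a probability given by the test-performance parameters, and each
branch accrues a cost. Effectiveness is the expected fraction of patients
correctly diagnosed as diseased (true positives, with anatomy); the
cost-effectiveness ratio (CER) is expected cost per patient tested divided
by effectiveness — cost per patient correctly diagnosed. Only payer-visible
diagnostic costs enter: treatment and "downstream" costs, pre-test work-up
("upstream") costs, radiation-induced malignancy, and intangible costs of
cardiac death are all outside the model, and no QALY weighting is applied.

## Parameters

| Parameter | Meaning | Default | Unit |
|---|---|---|---|
| `sn_cmr`, `sp_cmr` | per-patient CMR accuracy vs FFR ≤ 0.75 | 0.88, 0.90 | probability |
| `ndx` | non-diagnostic CMR rate | 0.05 | probability |
| `sn_cxa`, `sp_cxa`, `sn_ffr`, `sp_ffr` | reference-test accuracy | 1 | probability |
| `r_cxa` | major complication per angiography | 0.0005 | probability |
| `r_f` | complication per 10-year follow-up in false negatives | 0.15 | probability |
| `f_cmr`, `f_cxa_*`, `f_ffr` | fees (FFR incremental on angiography) | user | money |
| `c_complication` | cost of one myocardial infarction (PCI, 1 week hospital, 4 weeks rehabilitation) | user | money |
| `discount_rate` | annual discounting of future complication costs | 0.03 | 1/year |
| `horizon_years` | false-negative follow-up horizon | 10 | years |

The accuracy and complication defaults are the literature values commonly
used for this comparison; fees are always user-supplied because they are
payer-specific. The shipped `inst/extdata/synthetic_country.yaml` schedule
is synthetic and labelled as such in its mandatory `provenance_note`; the
package never presents synthetic fees as a real payer's schedule.

## Cost taxonomy and its reconstruction

The per-patient cost equations are assembled from the stated cost taxonomy
— first-line fee, unnecessary angiographies after false-positive CMR,
procedural complications, cross-over of non-diagnostic examinations, and
discounted false-negative complications — rather than copied from a
published formula sheet. `strategy1_cost_components()` therefore reports
the decomposition term by term, so any alternative reconstruction can be
compared component-wise. Structural choices embedded in the equations:

* Non-diagnostic CMR patients pay the full CMR fee plus the full invasive
  strategy cost and are diagnosed with perfect accuracy (they contribute
  `p` to effectiveness). They are not exposed to the false-negative risk
  pathway.
* After a positive CMR no FFR is performed — ischemia is already
  established, angiography supplies anatomy only.
* A false positive incurs exactly one unnecessary angiography (fee plus
  procedural risk), with no further cascade.
* Procedural complications are costed undiscounted (they occur at test
  time); both complication types are a myocardial infarction with the
  single cost `c_complication`.

**Timing of false-negative complications.** Only a 10-year complication
rate and annual discounting are specified, not an event-time distribution.
The package assumes the event year is uniform over years 1..H and
discounts each year, giving the annuity-average factor
`A(r, H) = mean((1 + r)^{-t})`, equal to 0.85302 at the defaults. This is
the simplest assumption consistent with a per-horizon rate and annual
discounting; with `discount_rate = 0` the term collapses exactly to
`c_complication * r_f` per false negative.

## The ischemia–stenosis link

Costing the invasive arm requires the fraction of patients sent to FFR,
i.e. the prevalence of ≥50% stenosis `P_sten` at each ischemia prevalence
`P_isch`. The package models this as a monotone map `L` applied as
`P_sten = L(P_isch)`, calibrated by weighted least squares
(`stats::lm`) to study-level points, in two forms: `linear_clipped`
(linear, clipped to the unit interval) and `logit_linear` (linear in
logit–logit space, boundary points excluded from the fit). Monotonicity is
enforced: a negative fitted slope is a calibration error, not a warning.
The default link is the identity — every flow-limiting lesion is an
anatomic stenosis and vice versa — which is the conservative floor for the
FFR referral fraction; users opt in to any non-identity calibration.

Two open interpretation questions were resolved as follows. First, the
referral fraction for FFR is taken to be exactly `L(p)` even though FFR is
clinically performed for "intermediate" stenoses — a sub-fraction would
only scale the FFR fee term down, and a single consistent knob is
preferable to an unidentifiable second parameter. Second, the map's
direction is fixed as `P_isch → P_sten`; the same calibration points would
support the inverse tabulation, but this direction is the one the cost
equation needs. The FFR positivity threshold (0.75 vs 0.80) is carried as
a label on the calibration set: a 0.80-threshold analysis is simply the
same machinery with the alternative link object, which is how the
threshold scenario of the sensitivity analysis is expressed
(`sensitivity_scenario(..., perturbation = "swap_link")`).

## Crossing points and numerical choices

`find_ce_crossing()` and `find_cost_crossing()` locate the prevalence at
which the two strategies' CER (or per-patient cost) curves cross. The
difference curve is scanned on a grid of step `1e-3` over the search
domain (default `[0.01, 1]`; the lower bound excludes the singularity of
the CER at `p = 0`), and any sign change is bisected to a bracket of
`1e-6`. Relative tolerance `1e-6` on the difference decides exact-zero and
everywhere-equal (degenerate) cases. Published crossings in this problem
family are reported to whole percentage points, so these tolerances are
comfortably finer; shifts are rounded only at the reporting layer, never
internally. If the scan reveals several sign changes — impossible for the
well-behaved configurations studied here but not forbidden by the model —
the smallest root is returned with a warning. Absence of a crossing is a
status (`none_in_domain`), not an error, because it is a substantive
finding (one strategy dominates at every prevalence).

One-way sensitivity analysis recomputes the crossing from scratch for each
perturbed configuration; no incremental shortcuts are taken, so scenario
order cannot matter. Perturbations may scale a parameter
(`relative_scale`), set it (`absolute_set`), swap the link, or swap the
angiography setting. The conventional "CMR sensitivity reduced by 10%"
scenario is implemented as an absolute set to 0.80 — the perturbed value
usually quoted — rather than exact relative scaling of 0.88; both styles
are available. A perturbation that pushes a probability outside `[0, 1]`
is clipped with a warning; one that invalidates the configuration marks
the scenario `invalid` and the run continues.

## The microsimulation and what it does (not) show

`simulate_cohort()` is the minimal stochastic model whose expectations
equal the closed forms, used as an independent oracle: disease is
Bernoulli at the pre-test likelihood; stenosis is certain in diseased
patients and sampled in the rest so the marginal stenosis rate equals
`L(p)` (requiring `L(p) ≥ p`, since ischemia implies stenosis); the CMR
result is non-diagnostic with probability `ndx` independently of disease —
an assumption, as the dependence is unspecified — and otherwise positive
with the sensitivity/one-minus-specificity probabilities; complications
and their uniformly timed, discounted costs follow the cost rules above.
All draws come from one seeded stream and the seed is recorded in every
estimate, so patient tables are bit-reproducible.

Agreement between simulation and closed forms validates the internal
algebra, not the model's realism: the generator has no correlated test
errors, no per-patient cost heterogeneity, no covariates, and no
time-to-event structure beyond the uniform complication year, and real
cohorts have all of these. Passing tests therefore demonstrate that the
equations and the sampler implement the same model, and nothing about how
well that model describes any particular patient population or payer.

**Oracle test design.** The acceptance suite compares closed forms and
simulation over 3 parameter sets × 5 prevalences × 2 strategies at
N = 200,000 (chosen so each run takes well under a minute on one CPU, with
Monte Carlo standard errors near 0.1% of the quantities checked). Each of
the 60 comparisons yields an approximately standard-normal z-score under
agreement. Checking every cell against a fixed 3-standard-error band would
reject a correct implementation in roughly one seed in seven purely by
chance, so the suite instead controls the family-wise error at the same
stringency as a single 3-SE check: a Bonferroni bound on the maximum |z|
and a chi-square bound on the mean z² — the latter strictly more sensitive
to a small systematic bias spread across cells than per-cell banding.

## Limitations

* Fees drive every headline number, and the shipped fee schedules are
  synthetic; conclusions about any real health-care system require that
  system's transcribed fees.
* The reference arm is axiomatically perfect; any real-world imperfection
  of angiography + FFR biases the comparison against the CMR-first arm.
* Average CERs are compared, not incremental ratios between strategies,
  and only two strategies are modelled.
* The five-study calibration behind a realistic ischemia–stenosis link is
  not bundled; the identity default understates the FFR referral fraction
  whenever non-flow-limiting stenoses exist.
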