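---
title: "Methods: a decision-tree cost-effectiveness model for IBD care during a pandemic"
author: "ibdcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree cost-effectiveness model for IBD care during a pandemic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdcea)
```

## The decision problem

During the COVID-19 pandemic a substantial fraction of chronic-disease
outpatients avoided routine care, and IBD clinics faced the question of
whether a weekly telemonitoring programme could offset the resulting harm.
This package evaluates that question with a one-year decision-tree cohort
model: a hypothetical cohort of adult IBD outpatients, split between
ulcerative colitis and Crohn's disease, flows through
hospitalization → surgery → survival/death branches, accruing direct
medical cost (USD, provider perspective) and quality-adjusted life-years.
With a one-year horizon there is no discounting and no within-year state
transition: the year is a single Bernoulli cascade per patient, which is
exactly what the patient-level oracle (`simulate_cohort()`) draws and what
the analytic engine (`expected_outcomes()`) integrates in expectation.

## Model structure and assumptions

For disease $d \in \{\mathrm{UC}, \mathrm{CD}\}$ with hospitalization
probability $h_d$, surgery-per-admission $s_d$, in-hospital mortality $m_d$
and a strategy-specific hospitalization multiplier $f$:

$$\mathrm{QALY}_d = (1 - f h_d)\,u_{out} + f h_d (1-s_d)(1-m_d)\,u_{hosp}
  + f h_d\, s_d (1-m_d)\,u_{surg}$$

Decedents accrue zero utility for the whole year and survivors their single
state utility for the full year; mortality applies uniformly to surgical and
non-surgical admissions (the input table provides a single per-disease
mortality). Cohort outcomes are the disease-mix weighted average with weight
$p_{uc}$.

The multipliers are population averages over the subgroups that actually
experience an effect:

* avoidance: $f_{avoid} = p_{avoid}\,rr_{avoid} + (1 - p_{avoid})$,
* telemonitoring: $f_{tm} = p_{comply}\,rr_{tm} + (1 - p_{comply})$,

applied multiplicatively ($f = f_{avoid} f_{tm}$ for the SC-TM arm, which is
always evaluated during the pandemic, i.e. on top of avoidance). The engine
refuses any $f h_d > 1$ rather than clipping.

**Cost assembly.** The input table lists per-patient-year costs without
stating which tree branch each row feeds. The package uses the unique simple
assembly consistent with the strategy totals it reproduces: outpatient
visits, medications and non-invasive imaging accrue to *all* patients;
endoscopy, ward stay, surgery (for the surgical fraction) and terminal care
(for the decedent fraction) accrue only with admission. Avoidance reduces
the visit cost of the avoider subgroup only
($\times\,(1 - p_{avoid}\,visit\_reduction)$ on average); telemonitoring
scales imaging for the compliant fraction only
($\times\,(1 + p_{comply}(rr_{imaging}-1))$) but its programme cost
(maintenance + encounters × duration × wage ≈ USD 170/patient-year) accrues
to every enrollee, compliant or not — the programme is deployed per patient
while compliance gates only the clinical effect.

## Parameters

`canonical_parameters()` ships the complete base-case table: 37 inputs, each
with base value, low/high sensitivity range and distribution family
(Beta for probabilities and utilities, Gamma for costs, Lognormal for
relative risks and the visit-cost reduction, Normal for encounter counts and
durations, point masses for the WTP threshold of USD 46,450/QALY — 1× local
GDP per capita — the one-year horizon, and the USD→HKD conversion kept as
metadata). The table is also bundled as `inst/extdata/ibd_model_inputs.csv`
and round-trips through CSV, JSON and YAML via `load_parameters()` /
`write_parameters()`. Validation is collective: all missing names are
reported at once, unknown names are rejected, and each row is checked
against both its family constraints and its measurement kind (probabilities
in $[0,1]$, costs $\ge 0$, relative risks $> 0$).

## Incremental analysis

`compare()` classifies dominance before any division: a comparator that
gains QALYs at lower cost is *dominant*, the reverse *dominated*, and only
in the trade-off quadrants is the ICER $\Delta C / \Delta Q$ computed and
judged against the willingness-to-pay. The net monetary benefit
$\mathrm{NMB} = \lambda\,\Delta Q - \Delta C$ is always reported. Boundary
cases (one increment exactly zero) are folded into the adjacent weak
dominance verdict; exact ties in both dimensions are *indifferent*.

## One-way sensitivity analysis

`sweep_parameter()` evaluates the incremental quantities on a 101-point grid
over each input's published range, all other inputs at base.
`find_threshold()` locates sign changes by bisection with an absolute
parameter tolerance of $10^{-6}$ and at most 200 iterations — every
incremental quantity in this tree is monotone (affine in most single
parameters), so bisection is unconditionally robust, and the affine cases
are cross-checked against closed-form roots in the test suite. Where a
crossing lies outside the published range the search interval is extended
(probabilities to $(0,1)$, relative risks and costs to a wide positive
span), with the ends shrunk back toward base whenever the extension would
push an effective probability past 1. Because the telemonitoring base case
is dominant, the ICER is undefined there; the tornado ranking
(`tornado()`) therefore uses the NMB at the WTP threshold as its default
quantity, ranking parameters by the span of NMB between their range ends.

## Probabilistic sensitivity analysis

Each published low/high range is read as a 95% interval, the standard
health-economics convention when a paper provides ranges without standard
errors: $sd = (high - low)/3.92$. Beta and Gamma are fitted by method of
moments to (mean = base, sd); Normal directly; Lognormal is anchored at
natural-scale *median* = base with $\sigma_{\log} = (\ln high - \ln
low)/3.92$, since relative-risk point estimates conventionally sit at the
geometric mean. Zero-width ranges (the UC in-hospital mortality) degenerate
to point masses. Draws are made parameter-by-parameter in canonical table
order under a single seed; both (or all three) strategy arms are evaluated
on the *same* draw, because per-simulation quadrant counting requires paired
parameters. Draws that would push an effective hospitalization probability
past 1 are rejected and redrawn, never clipped, with the rejection count
recorded.

Two numerical consequences of this parameterization are worth stating
plainly. First, a median-anchored lognormal has mean
$base \cdot e^{\sigma^2/2}$, so sampled relative risks recover their base
value in median, not in mean; the mean-recovery tests treat lognormal inputs
accordingly. Second, the proportions of draws on one side of a sign boundary
are sensitive to the relative-risk spreads: with
$\sigma_{\log}(rr_{avoid}) \approx 0.060$ the avoidance arm loses QALYs in
$\Phi(\ln 1.156/0.060) \approx 99.2\%$ of draws and is costlier in roughly
$82\%$, whereas proportions of 100% and 96.82% would require a log-scale
spread about half as large as any reading of the published range supports.
Ranges alone do not pin the convention down, and the package keeps the one
documented here rather than reverse-engineering a tighter spread; the
deterministic results and the PSA *means* are insensitive to this choice.

## Microsimulation oracle

`simulate_cohort()` draws individual trajectories — disease, avoider and
compliance flags, then hospitalization with the patient's own multiplier,
surgery, death — and accrues cost and QALYs with exactly the cohort engine's
assembly rules. Its per-patient expectations equal the analytic expressions
by construction, so agreement within Monte Carlo error is a genuine
cross-validation of the implementation (especially of the cost assembly),
not a tautology: the acceptance suite checks all four outcome fields for all
three strategies within 3 standard errors at 200,000 patients, and the
module tests at 100,000. `write_fixture()` emits the canonical table plus
each input moved to its low and high end, for harness use.

## Problem sizes and determinism

Default analysis sizes: 10,000 PSA draws and a deterministic cohort. Unit tests use smaller draws (200–4,000) where only
structural properties are asserted, and the full 10,000/200,000 in the
end-to-end suite. All stochastic entry points (`run_psa()`,
`simulate_cohort()`, the report runners) take an explicit integer seed and
restore the caller's RNG state; identical seed and inputs reproduce results
and report files bit-for-bit, and report headers echo the seed and
configuration while containing no timestamps.

## Known limitations

* Single-cycle tree: no relapse states, no within-year event timing, no
  age/sex stratification or age-specific technology acceptance.
* Patients who avoid care but stay out of hospital accrue full outpatient
  utility, likely understating the QALY loss of avoidance.
* The PSA proportions near certainty boundaries depend on the
  distribution-parameterization convention, as discussed above.
* Avoider and compliance flags are drawn independently of disease type, as
  no disease-specific rates are available.
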