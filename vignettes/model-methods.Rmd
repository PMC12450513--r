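---
title: "A Markov cohort model for decision support in AF anticoagulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for decision support in AF anticoagulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcea)
```

## The decision problem

Up to a third of patients with atrial fibrillation (AF) who qualify for
oral anticoagulation under guideline criteria are not prescribed it, despite
the large stroke-risk reduction the treatment offers. A clinical decision
support (CDS) system embedded in the electronic health record can nudge
prescribers and raise adherence to guideline-recommended anticoagulation by
a small absolute amount. `afcea` asks whether buying that adherence gain is
good value: it compares a CDS strategy against standard of care (SoC) in a
hypothetical AF cohort, estimating lifetime clinical events, discounted
costs and quality-adjusted life years (QALYs), and summarising the
comparison as an incremental cost-effectiveness ratio (ICER) judged against
a willingness-to-pay threshold of €50 000 per QALY.

## Model structure

The engine is a discrete-time Markov cohort model with yearly cycles. The
cohort enters at a given age split across three AF states — untreated, on
warfarin, or on a non-vitamin-K oral anticoagulant (NOAC) — according to the
arm-specific adherence. The SoC-level adherent patients are divided between
warfarin and NOAC by `warfarin_fraction`; the entire CDS-minus-SoC
adherence increment (the trial treatment effect, 0.016 with 95% CI
0.003–0.028 by default) is placed in the NOAC state, reflecting NOACs being
first-line therapy at the time the effect was measured.

Each year, patients in AF states face competing risks of five clinical
events — ischaemic stroke (IS), intracranial haemorrhage (ICH), extracranial
systemic embolism (SE), myocardial infarction (MI) and major bleeding (MB) —
plus background death from an age-indexed life table. Event risks are
untreated annual rates multiplied by treatment-specific relative risks
(efficacy RRs below one for IS/SE, bleeding RRs at or above one). Annual
rates become annual probabilities through the constant-hazard conversion
$p = 1 - e^{-r}$.

The year after an event is a *transient* acute state occupied for exactly
one cycle. Acute-year mortality combines the event's case fatality with
background mortality ($1-(1-\mathrm{cf})(1-q)$); survivors of IS, ICH, SE
and MI move to a matching post-event state where only the first event is
modelled: those four risks are switched off, a mortality multiplier
($\ge 1$) scales background death, and an annual post-event cost and
utility decrement apply for life. Major bleeding is different: it can occur
from any alive state, may recur without limit, and after the acute year the
survivor either permanently discontinues anticoagulation (probability
`mb_discontinue_prob`) or resumes the same drug. MB acute states therefore
carry the underlying chronic condition, so a bleeding survivor returns to
exactly the state they bled from (with or without their anticoagulant).

Three structural choices deserve explicit statement because they were
genuinely open:

* **Treatment persists after events.** Post-event and acute states keep
  their treatment stratum, and drug cost plus the anticoagulation utility
  decrement keep accruing there. Lifetime anticoagulation costs of several
  million euros per 1000 patients are only attainable under this reading;
  stopping therapy at the first event would roughly halve them.
* **Unlimited MB recurrence.** Nothing in the clinical logic caps the
  number of bleeds; each recurrence re-applies the acute cost, decrement
  and discontinuation lottery.
* **Resumption returns to the same drug.** No warfarin↔NOAC switching is
  modelled anywhere.

### Competing risks and numerical closure

Each cause is converted to a probability independently. If, at some age,
the event probabilities plus background death exceed one (this happens only
at extreme ages or under extreme sensitivity draws), the event
probabilities are rescaled proportionally into the remaining mass and a
warning names the affected states and ages. Transition rows sum to one
within $10^{-12}$ and occupancy is conserved within $10^{-10}$ at every
cycle. The life table forces the death probability to one at `max_age`
(110 by default), which closes the lifetime horizon: the final occupancy
row is fully absorbed in Dead, so "lifetime" results are exact sums, not
truncations.

### Accounting

Costs and QALYs are discounted at 3%/yr with cycle 0 undiscounted,
$(1+r)^{-t}$. State occupancy is half-cycle corrected (the mean of
start-of-cycle and end-of-cycle occupancy), which places the corrected
person-time strictly between the start- and end-counted sums. Half-cycle
correction applies to QALYs, annual drug costs and annual post-event
costs; one-off quantities — the cycle-0 CDS fee and acute event costs
attached to incident flows — are not half-cycle corrected, and acute costs
are discounted at the cycle the flow arrives. Utilities are age-specific
population weights minus additive decrements (anticoagulation, acute,
post-event; a bleeding year on top of a post-stroke state subtracts both),
floored at zero with a warning. Undiscounted event counts are raw sums of
incident flows, with no half-cycle adjustment.

The one-time CDS development cost is excluded from the base case. The
development-cost scenario spreads it over the trial AF population
(14 134 patients by default, configurable) and adds the cohort's share to
the cycle-0 CDS fee.

## Parameters and the synthetic generator

All inputs live in one validated parameter object, loadable from a YAML
config (life table and utilities inline or as two-column CSV). Each
uncertain input carries a distribution family used by the probabilistic
analysis. `generate_synthetic_parameters()` produces a complete set with no
external data. Values reported directly by the source trial are used as-is:
arm adherences 0.712/0.728, treatment effect 0.016 (CI 0.003–0.028), start
age 75, cohort 1000, 3%/yr discounting, €50 000/QALY threshold, CDS fee
€2996 per 1000 patients, development cost €185 000. The remainder are
synthetic stand-ins chosen once from the stroke-prevention literature and
not tuned afterwards:

* untreated IS rate 4.8%/yr (CHA2DS2-VASc ≈ 4; 0.6%/yr and 9.7%/yr for the
  score-1 and score-6 scenario profiles), SE 0.7%, MI 1.7%, ICH 0.2%,
  MB 1.0%;
* warfarin RRs: IS 0.36 (≈64% risk reduction), SE 0.36, MI 0.85, ICH 2.0,
  MB 2.0; NOAC RRs: IS/SE 0.29 (a further ≈19% beyond warfarin), MI 0.90,
  ICH 1.0, MB 1.4;
* case fatality IS 18%, ICH 45%, SE 8%, MI 15%, MB 5%; post-event
  mortality multipliers 2.2/2.5/1.5/1.8 (IS/ICH/SE/MI);
* a Gompertz life table anchored at 3%/yr at age 75 with hazard doubling
  roughly every 7 years, closed at 110; population utilities declining
  linearly from ≈0.80 at 75 (0.92 − 0.005·(age − 50), floored at 0.45);
* anticoagulation decrement 0.012/yr for both drugs; acute decrements
  0.25/0.30/0.12/0.15/0.10 and post-event decrements 0.18/0.25/0.08/0.10;
* annual warfarin €450 (drug plus INR monitoring), NOAC €1000; acute costs
  €12 000/€18 000/€9 000/€9 000/€6 000 and annual post-event costs
  €4 000/€6 000/€1 800/€1 500 (IS/ICH/SE/MI, MB acute-only), in
  2023-price euro magnitudes for a Swedish setting.

The generator emulates the *shape and scale* of a real input set — under
these defaults a 1000-patient lifetime run yields event counts of the same
order as published AF cohort models (≈212 ischaemic strokes per 1000). It
does not emulate the exact proprietary input tables of any particular
study: incremental results (differences between two ≈€13M cost totals and
two ≈6 600-QALY totals) are highly sensitive to percent-level input
differences, so a green property suite on synthetic data demonstrates that
the machinery is correct, not that any particular published ICER is
reproduced. The deterministic generator ignores its seed beyond recording
it, so identical calls are bit-identical.

## Probabilistic sensitivity analysis

Each of the (by default) 10 000 draws resamples every uncertain input
independently: relative risks lognormal with log-scale spread solved from
their 95% CIs (location at the log point estimate); rates, costs and
mortality multipliers gamma; proportions and utility decrements beta; the
treatment effect normal from its CI, truncated so both adherences stay in
[0, 1]. Where no standard error is reported, SE = mean/4. Gamma and beta
shapes are solved by moment matching; the beta variance is capped just
below $m(1-m)$ to keep the parameterization valid; sampled mortality
multipliers are floored at 1. Structural settings, the life table and the
population utility curve stay fixed.

The mean ICER is reported as the *ratio of means* of incremental costs and
incremental QALYs — per-draw ratios are unstable when a draw's QALY gain is
near zero — and the output metadata says so. A draw counts as
cost-effective when it is dominant or buys a positive QALY gain at no more
than the threshold; the per-draw net monetary benefit
$\lambda\,\Delta Q - \Delta C$ is exported for acceptability-curve use.
Everything is reproducible bit-for-bit from one seed.

## One-way, scenario and threshold analyses

The tornado analysis halves and doubles each uncertain leaf in turn
(proportions clipped to [0, 1]; moving the treatment effect moves the
CDS-arm adherence with it) and ranks parameters by the width of the
resulting ICER interval. "Increased by 200%" in the source description is
read as multiplication by 2, the reading consistent with its pairing with
"reduced by 50%"; both multipliers are arguments. The development cost is
not varied (the base case excludes it entirely).

Time-horizon analyses truncate both arms at 5/10/15/20 years; events
incident at the boundary cycle are counted. The treatment-effect sweep
varies the adherence gain over 0.001–0.1 and shows the ICER falling while
the incremental anticoagulation cost rises linearly. The
maximum-acceptable-CDS-price analysis exploits that the ICER is affine in
the cycle-0 fee, $c^* = \lambda\,\Delta Q - \Delta C_{-CDS}$, and
cross-checks the closed form against a bisection that reruns the model
(1e-6 relative tolerance). Risk-profile scenarios re-run the model for a
low-embolic-risk population (entry at 65, IS/SE rates fixed at the
score-1 level for the whole run, MI/ICH/MB rates cut to one third —
background mortality still ages normally) and a high-risk population
(IS/SE raised to the score-6 level only).

## Verification strategy and problem sizes

The test suite validates the cohort engine against independent oracles
rather than against itself: a fine-time-step (daily) competing-risk
propagation for single transition rows, and an individual-level
microsimulation using the same per-cycle transition rules, run at $10^6$
individuals on three seeds, whose occupancy must match the cohort trace
within Monte-Carlo error. That agreement is checked with exact binomial
bands per (cycle, state) cell at a family-wise two-sided 3-sigma level:
with ~1700 cells a naive per-cell ±3·SE rule would be expected to fail by
chance for a perfectly correct model, and near-empty cells need exact
(Poisson-regime) quantiles rather than a normal approximation. QALY
accumulation is re-derived by a deliberately naive loop in the tests, the
tornado table against brute-force single-parameter reruns, and PSA
summaries by recounting exported draws. Routine test runs use a
200 000-individual microsimulation and PSA sizes of tens to hundreds of
draws; the full-scale checks (10 000 draws, $10^6$ individuals) live in
the acceptance suite.

## Limitations

Adherence is fixed after the first model year; treatment discontinuation
is modelled only after major bleeding; there is no drug switching, no
individual-level risk heterogeneity within a run, no correlation between
sampled parameters, and no societal-perspective costs. The synthetic
default inputs are literature-plausible but are not the input tables of
any specific published evaluation, so absolute results under the defaults
characterise the method, not a particular health system; supply your own
YAML config to evaluate a concrete setting.
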