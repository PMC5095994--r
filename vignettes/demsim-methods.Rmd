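---
title: "demsim: model, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{demsim: model, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demsim)
```

`demsim` projects the population burden of dementia with a continuous-time
dynamic microsimulation over an open population, paired with a deterministic
cohort-component twin used for validation. This vignette documents the model
and its assumptions, the tunable parameters, the synthetic-parameter
generator, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The lifecourse model

The unit of simulation is the actor: one synthetic person with a sex, a
continuous birth date, an entry mode (born or immigrant) and a sampling
weight equal to total represented persons divided by the number of actors.
Actors are drawn multinomially across every birth-cohort and immigration
cell in proportion to scheduled counts, so desk-scale runs (tens of
thousands of actors) stand in for national populations (tens of millions of
persons); every aggregate multiplies by the weight.

Within each calendar year, events are resolved in a fixed order:

1. **Onset draw (January 1).** A dementia-free actor at or above the minimum
   incidence age onsets with probability $p = 1 - e^{-i(a,s,t)}$, where $i$
   is the incidence hazard per person-year. On success, the onset date is
   uniform within the year. Dementia is absorbing: no remission.
2. **Mortality.** The within-year death hazard is piecewise constant:
   $m_0(a,s,t)$ before onset and $m_0 \cdot HR$ after, changing exactly at
   the onset date. Death is determined by a single per-actor Exponential(1)
   threshold $E$ tested against the accumulated hazard; the death date is
   the exact piecewise inversion of $\int_0^{t^*} h(u)\,du = E$.
3. **Emigration.** A competing constant hazard with its own Exponential(1)
   threshold; emigration censors the factual lifecourse (no return).
4. **HUI3 assignment.** The annual health-utility value is a truncated
   normal around the age/sex/status mean, clipped to $[-0.36, 1]$; in the
   onset year the annual value time-averages the dementia-free and dementia
   cell values over the pre- and post-onset portions actually lived. The
   same noise draw serves both statuses and both twins.
5. **Caregiving (year end).** Receipt of informal care for the *following*
   year is Bernoulli with probability indexed by age group, dementia status
   and HUI3 band at assignment time; recipients draw a weekly-hours bin and
   are assigned a caregiver HUI3 and caregiver out-of-pocket cost.
6. **Costs.** Persons with dementia accrue sector costs at incident-phase
   rates for the 12 months following onset (prorated across the two calendar
   years the window straddles) and prevalent-phase rates for the rest of
   their dementia person-time.

Baseline mortality improves over calendar time,
$m_0(a,s,t) = m_\mathrm{ref}(a,s)\, e^{-\rho(a,s)\,\kappa\,(t - t_0)}$ — a
reduced form of the Lee–Carter projections national statistical agencies
publish. The low/mid/high life-expectancy variants act only through the
multiplier $\kappa$ (0.5/1/1.5 by default), for actors with and without
dementia alike. The full $a_x + b_x k_t$ machinery is deliberately not
estimated here: projected mortality is an *input* to this kind of model, and
only the qualitative contract (mortality declines smoothly over time, never
increases) matters for the downstream results.

### Counterfactual twins and YLL/HYLL

Every actor is simulated twice with identical random draws: factually, and
as a twin who never develops dementia ($HR \equiv 1$). YLL is the
counterfactual minus factual death age (zero without onset; censored — NA —
if emigration ends observation first). HYLL is the difference in
HUI3-weighted lifetimes, $\sum u^{cf}_y \ell^{cf}_y - \sum u_y \ell_y$, with
$\ell_y$ the fraction of year $y$ lived.

Whether the twin also escapes the dementia HUI3 decrement is genuinely
ambiguous in the literature this design follows. Both modes are implemented:

- `counterfactual = "full"` (default): the twin follows the dementia-free
  HUI3 path — "did not develop dementia" taken at face value, so HYLL
  includes the quality-of-life loss of lived dementia years.
- `counterfactual = "hr_only"`: the twin keeps the dementia HUI3 path and
  only the excess mortality is removed, so HYLL reduces to the
  utility-weighted longevity loss.

Under the full mode, HYLL can exceed YLL when the decrement times the years
lived with dementia outweighs the utility discount on the longevity gap;
under the hr-only mode HYLL is always at most YLL. Both are legitimate
definitions; the flag makes the choice explicit and testable.

### Common random numbers

Every draw is a pure function of (master seed, actor id, stream id, calendar
year), computed by a splitmix64-based counter hash in C++. Nothing is
sequential, so results are independent of actor processing order, identical
across repeated runs, and — crucially — identical across scenarios. This
turns scenario comparisons into per-actor couplings with provable
orderings:

- delayed incidence ($i'(a) = i(a - 5)$, zero below the minimum age, with
  $i$ non-decreasing in age) can never advance an onset, because the same
  uniform is compared against a smaller probability in every year;
- a hazard-ratio multiplier below 1 lowers the hazard path pointwise, so the
  same threshold is reached later: no actor dies earlier;
- with an effective HR of exactly 1 the factual and counterfactual hazard
  paths are evaluated by *the same floating-point expressions* (the engine
  collapses the two within-year segments whenever the post-onset hazard
  equals the pre-onset one, and carries the exact onset fraction rather than
  reconstructing it from absolute dates), so YLL and HYLL vanish exactly,
  not just to rounding.

One ordering claimed by intuition does **not** hold per actor: annual
prevalence under delayed incidence. The baseline twin onsets earlier and can
therefore die earlier, so an individual actor can be prevalent in the
delayed world while already dead in the baseline world. The package
guarantees (and tests) the per-actor onset ordering exactly, and the
prevalence ordering at the aggregate level, which is what the coupling
actually implies at realistic sizes. Similarly, the direction of dementia
*deaths* under a lower hazard ratio is a composition effect — fewer deaths
per prevalent person, but more and older prevalent persons — and is an
expectation, not a per-actor fact; it is checked on the deterministic oracle
rather than on one noisy draw of a few dozen single-year deaths.

## The cohort-component oracle

`run_oracle()` evolves expected occupancy $N(a, s, d)$ at each January 1 by
difference equations that integrate the engine's within-year mechanics
exactly. With $A = m_0 + e$ (pre-onset total hazard), $B = m_0 HR + e$
(post-onset) and $f(x) = (1 - e^{-x})/x$, a dementia-free person who draws
onset survives the year with probability $e^{-B} f(A-B)$ (the onset time is
uniform), materialises the onset with probability $f(A)$, dies before it
with probability $\tfrac{m_0}{A}(1 - f(A))$, and so on — the same
memoryless-threshold algebra the engine uses, integrated in closed form.
Newborns (birth dates uniform in the year) and January-1 immigrants get the
matching partial-exposure terms. Because the discretisation is *identical*,
the microsimulation equals the oracle in expectation cell by cell, and
`compare_to_oracle()` can use tight standardised discrepancies
($SE = \sqrt{w\mu(1 - \mu/T)}$, the two-stage sampling variance implied by
multinomial actor allocation with common weight $w$ out of $T$ represented
persons) without any asymptotic hand-waving: a 200,000-actor run is expected
to land within $|z| \le 3$ in ~99.7% of year-by-measure cells, and a
systematic discrepancy of even a fraction of a percent would flag
immediately.

The oracle also powers the calibration harness: `calibration_check()`
compares projected to "observed" prevalence by stratum and declares
calibration unnecessary when all ratios fall in a configured band (0.9–1.1
by default), mirroring the projected-versus-observed validation step such
models undergo. Since the repository has no access to observed registry
prevalence, the shipped reference is oracle-generated and therefore
synthetic; the harness applies unchanged to a real reference table.

**A power note.** The default strata are {65–79, 80+} × sex. At 200,000
actors the synthetic world holds on the order of a thousand simulated
dementia cases in 2009, so each stratum ratio carries ~5–6% Monte-Carlo
error and the 0.9–1.1 band is only about 1.7 SE wide: an arbitrary seed
clears all four strata roughly two times in three. That is a sample-size
property of the check, not an engine bias (the oracle-equivalence test is
the instrument with actual power). The acceptance script therefore runs its
calibration pass on a larger dedicated population (500,000 actors,
records kept for the calibration year only).

## The synthetic-parameter generator

No national incidence/mortality/cost tables ship with the package;
`synthesize_parameter_set()` builds bundles with the right *shape* from
closed-form curves, and `synth_config()` exposes every knob. Defaults were
chosen once to describe a Canada-like population and are not tuned
thereafter:

| parameter | default | units / rationale |
|---|---|---|
| Gompertz mortality $\alpha e^{\beta a}$ | $\alpha = 2\times10^{-5}$, $\beta = 0.1$ | per person-year; life expectancy in the low 80s, hazard capped at 1/yr |
| mortality improvement $\rho$ | 0.01 | per year; typical modern secular decline, variants 0.5×/1×/1.5× |
| incidence anchor | 0.004 at age 65 | per person-year; diagnosed (not total) dementia incidence |
| incidence doubling time | 6 years | classic late-life doubling, plateau cap 0.25/yr at the oldest ages |
| minimum incidence age | 40 | diagnosed dementia below 40 is negligible; reports use the 40+ stratum |
| hazard ratio | 2.5 | excess mortality with dementia, within the published 2–3 range |
| HUI3 dementia-free | 0.95 at 40, −0.0025/yr | index scale; gentle age decline |
| HUI3 dementia decrement | 0.30 | constant; qualitative mean-HUI3-by-status pattern |
| HUI3 noise sd | 0.05 | truncated normal, clipped to [−0.36, 1]; 0 gives deterministic means |
| care receipt (dementia) | 0.77 | the reported 2011 receipt level among people with dementia |
| hour-bin distribution | mass on 15–70 and ≥71 h/week | matches the reported bin pattern; representative hours 0/3.5/10.5/40/80 |
| sector costs | long-term care ≈ 46%, hospitalization ≈ 27% of total | per prevalent person-year, proportioned to published 2011 sector totals; incident phase 1.5× |
| cohorts | births growing ~0.77%/yr from 1872 | immigration ramping to 250,000/yr by 2011; emigration 0.002/yr |

What the generator emulates: Gompertz-like adult mortality with secular
improvement, late-life-rising diagnosed incidence, age-declining HUI3 with a
status decrement, care receipt concentrated in heavy-hour bins, long-term
care dominating costs, and an open population with realistic turnover. What
it does not: cohort-specific mortality history, age/sex structure in the
hazard ratio (supported by the type, constant by default — the source design
is silent on whether it varies), time trends in HUI3 or care behaviour
(explicitly held constant), regional stratification, and the under-diagnosis
adjustment. Passing tests therefore demonstrate internal correctness of the
machinery — sampling, coupling, accounting, aggregation — on realistic
*shapes*, not agreement with any country's registry values.

Test worlds use birth cohorts from 1900 rather than 1872: deep enough that
the elderly population before 2015 is natives plus immigrants (cohorts
starting at 1950 would leave nobody over 65 except immigrants, which skews
early-horizon age structure), shallow enough to keep a 200,000-actor run
around half a minute on one CPU. Problem sizes in the test suite — 200,000
actors for oracle equivalence and calibration, 100,000 for the closed-form
YLL check, 15–30,000 for coupling and receipt properties — were chosen as
the package's own validation design.

## Numerical choices

- **Age grid and lookups.** Whole years 0–110; the last row is open-ended
  (ages clamp to 110), years clamp to the table span, and there is no
  interpolation — rates are step functions, which keeps every run exactly
  reproducible from the table cells alone.
- **Age cap.** An actor whose January-1 age reaches `max_age` (default 110)
  lives that final year and dies at its end. The cap is metadata:
  closed-form validation worlds raise it to 250 so that truncation (worth
  ~0.08 years at a 0.05 hazard) cannot bias the constant-hazard identity
  E[YLL] = 1/m − 1/(m·HR).
- **Within-year inversion.** The death date solves the piecewise cumulative
  hazard equation segment by segment; when the post-onset hazard equals the
  pre-onset hazard the segments are collapsed so the arithmetic is
  bit-identical to the single-segment twin (this is what makes the null-HR
  identities exact rather than approximate).
- **Bundle IO.** Tables are written as `%.17g` CSV cells, so a save/load
  round trip reproduces every double bit-exactly; the manifest carries
  metadata and structural configuration in YAML.
- **Degenerate inputs.** Zero hazards yield infinite waiting times (no
  division-by-zero paths); `0/0` flow splits in the oracle are defined as 0;
  an all-zero demographic schedule is an explicit "empty population" error;
  a scenario shift that zeroes the whole incidence table warns rather than
  errors.
- **Determinism of reports.** Aggregation orders records by (year, id)
  before summing, so report files are byte-identical across runs and actor
  permutations with the same seed.

## Design decisions on open points

- **Prevalence reference date** is July 1 (mid-year), the demographic
  convention; it also makes the mortality-rate arithmetic
  (deaths / point prevalence × 1000) internally consistent.
- **Mortality-rate denominator** is point prevalence, not person-years.
- **"Working age"** is 25–65 inclusive at mid-year, read literally from the
  caregiving-per-person measure it serves.
- **Caregiving percentages** are over all persons with dementia in the year,
  community-dwelling or not; the "none" hour bin exists in the distribution
  (probability 0 by default) and is folded into "receiving no care".
- **Incident cases dying in the onset year** count as both an onset and a
  dementia death; they appear in prevalence only if alive at the reference
  date.
- **Immigrants** enter dementia-free on January 1 of the arrival year
  (prevalent-at-arrival is left to future work); onset risk begins at the
  first January 1 at or after entry.
- **Out-of-pocket costs** are tabulated by age group and dementia status but
  accrued, like sector costs, over dementia person-time — the report is "among
  people with dementia".

## Limitations

No dementia risk factors (incidence depends on age, sex and year only); no
severity stages beyond the HUI3 continuum; no remission or misdiagnosis
dynamics; no regional stratification; no monetary discounting or inflation;
no parameter-uncertainty propagation (scenarios are deterministic
transformations, not posterior draws). The hazard-ratio table supports
age/sex/year variation but defaults to a constant. Caregiver attributes are
population constants rather than sampled characteristics. These boundaries
are inherited from the modelling tradition the package implements and are
the natural extension points.
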