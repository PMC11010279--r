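---
title: "Methods: the chronic-pain cohort model behind starcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the chronic-pain cohort model behind starcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starcea)
```

## The decision problem

Roughly one in five people who undergo a total knee replacement (TKR)
report chronic post-surgical pain. The STAR care pathway — a three-month
clinical assessment with personalised onward referral and follow-up calls
during the first year — aims to move these patients out of chronic pain
faster than usual postoperative care. The model in this package asks what
that is worth to the NHS over five years, in QALYs and in £.

## Model structure and assumptions

The model is a deterministic cohort Markov simulation with exactly two
health states, chronic pain (CP) and no chronic pain (NCP), defined by the
Oxford Knee Score pain subscale: OKS-PS ≤ 14 is CP. Cycles are annual —
the evidence informing the transitions is collected yearly, and
interpolating shorter cycles would add assumptions, not information. The
horizon is five years, long enough that most people who will leave chronic
pain have done so. There is no death state: the horizon is short relative
to life expectancy, and the intervention is assumed not to affect
mortality; this overstates person-time slightly but does so equally in
both arms.

Everyone enters the model in CP (`initial_distribution = c(CP = 1, NCP =
0)`). Transition matrices are time-dependent: year 1 is arm-specific
(trial evidence, the only year the intervention is active); years 2–5 are
shared between arms (cohort evidence), a conservative choice that confines
the intervention's effect to its active year while letting anyone who
escaped CP keep that advantage. The year-1 NCP row is structural — nobody
occupies NCP at entry — and is stored as (0, 1) so every row is a valid
distribution.

### Accrual conventions

Payoffs are attributed by **end-of-cycle** state membership with no
half-cycle correction, and discounting at 3.5% starts in year 2 (factor
$(1.035)^{-(t-1)}$, year 1 undiscounted). These two conventions are not
arbitrary: they are the unique pair among the standard candidates
(start-of-cycle, half-cycle, discounting from year 1) that reproduces the
published comparator totals — 3.09 QALYs and £3,563 — and both arms' QALY
totals from the published inputs to printed precision. The one-off £191
intervention cost enters year 1 of the STAR arm undiscounted, regardless
of state membership.

### The intervention-arm cost gap

One published cell is *not* reconstructable under those conventions: the
STAR arm's total cost (£3,188.86 in the base case). From the published
per-state inputs the model yields ≈£2,981 — a gap of ≈£208. The same gap,
to within ten pence, appears in the scenario that changes year-1 hospital
costs (£207.5 vs £207.6), so it behaves like a constant year-1 arm-level
cost whose source is not given in the published inputs. We deliberately do
**not** hard-code a correction. The parameter `extra_arm_year1_cost`
(default 0) makes the discrepancy explicit; `calibrate_extra_year1_cost()`
computes the value that closes any target gap (year-1 costs enter
undiscounted, so the mapping is exactly one-to-one). Incremental costs and
the iNMB therefore differ from the published values by this constant
unless the knob is set; incremental QALYs are unaffected.

## Parameter derivation

The model inputs are derived from patient-level data in three stages,
implemented exactly as they would be run on the restricted sources and
exercised here on synthetic panels.

**Transitions.** Row-wise relative frequencies between paired OKS-PS
classifications (`estimate_transition_matrix()`). Patients missing either
observation are dropped for that transition (available-case) and counted;
no imputation. An empty risk set is an error unless the origin state is
structural (trial baseline NCP), where the row is the identity.

**Year-1 QALYs.** Per-patient area under the utility-time curve from
utilities at 0, 6 and 12 months (`auc_qaly()`: trapezoids, $0.25(u_0 +
u_6) + 0.25(u_6 + u_{12})$), then regression-adjusted for baseline utility
(`adjust_qalys_for_baseline()`): a linear model of QALYs on group
indicators plus a single pooled baseline slope, with group means predicted
at the pooled mean baseline. A pooled slope is the standard
covariate-adjustment choice; per-group slopes would let the adjustment
itself differ by arm, which the design does not support.

**Years 2–5 utilities: the PoPC projection.** Later-year utilities are
projected from the year-1 anchors by the change observed in a reference
cohort, as a *percentage of potential change*. For a cohort improvement
from $g_t$ to $g_{t+1}$ on a scale with ceiling 1:

$$u_{t+1} = u_t + \frac{g_{t+1} - g_t}{1 - g_t}\,(1 - u_t)$$

i.e. the cohort's gain, expressed as a fraction of its remaining headroom,
is applied to the anchor's own headroom. Algebraically this preserves each
trajectory's relative distance to full health. For cohort
*deteriorations* the implemented rule is multiplicative on the level,
$u_{t+1} = u_t\,g_{t+1}/g_t$. The choice between "signed PoPC" (same
headroom denominator with a negative numerator) and the level-ratio rule
is empirically decidable: the published projected series, in their
declining years, match the level-ratio rule exactly at printed precision
(e.g. NCP 0.742 → 0.739 → 0.728 → 0.714), while signed PoPC yields 0.739 /
0.729 / 0.716. Both rules agree that an anchor equal to the cohort start
reproduces the cohort series, and neither can push an on-scale value above
the ceiling. Two projected CP cells (years 4–5) differ from their printed
values by ≤ 0.0008 under either rule — consistent with the original
projection having used unrounded cohort values — so projection checks are
asserted to within 0.001.

**Costs.** Year-1 anchors per arm, component and state from trial means;
later years apply the cohort's annual percent changes multiplicatively
(`pct_change_project()`), which is equivariant under rescaling of the
anchor. Prescriptions and consultations share one schedule across arms;
hospital admissions differ by arm in year 1 only.

## Scenarios

Scenarios are declarative overrides on the built-in fixture
(`apply_scenario()`), so shared values stay single-sourced, and are
idempotent. Scenario 1 pools the QALY payoffs across arms, isolating the
transition pathway as the only source of QALY difference. Scenario 2 moves
the classification point to 10 weeks: year-1 transitions change and the
cohort enters with a non-degenerate NCP fraction. That entry split is not
published; the default `s2_initial_ncp = 0.10` is an explicit assumption,
so scenario 2's published results are illustrative rather than
reproduction targets. Scenario 3 equalises year-1 hospital costs across
arms (CP £1,935, NCP £1,237), the scenario under which dominance is lost
and an ICER (~£400/QALY from the published inputs, ~£2,800 in the
published table whose incremental costs include the arm-level gap above)
becomes the summary.

## Probabilistic sensitivity analysis

Every sampled input gets a distribution moment-matched to its point
estimate: **beta** for quantities bounded in (0, 1) — transition
probabilities and utilities — and **gamma** for costs, each with standard
deviation `dispersion × mean`. The published analysis's hyperparameters
live in unpublished supplementary tables, so the dispersion is a package
parameter, default 0.15: with means spanning 0.3–0.95 (probabilities,
utilities) and £20–£3,000 (costs) this produces coefficient-of-variation
uncertainty comparable to what the published interval for the iNMB
implies, without pretending to reproduce unseen hyperparameters. The
published probability of cost-effectiveness (0.62 at £20,000) is therefore
a guide; the default configuration yields ≈0.66.

Two-state transition rows are sampled as a single beta on the
probability of moving to CP with the complement filling the row —
equivalent to a Dirichlet for two states. Structural constants are never
sampled: zero/one probabilities (the year-1 NCP row), the one-off cost,
the discount rate, the horizon. Beta standard deviations are capped just
inside the support bound where the requested dispersion would leave it.
Parameters are sampled independently across arms and years; any
correlation structure in the original analysis is unpublished.

One RNG stream is seeded once per run; draws are vectorised per parameter
in a stable order, so a seed fully determines the output. Each draw
rebuilds a parameter set and runs both arms through the same engine as
the deterministic analysis.

**CEAC shape.** The acceptability curve starts at $P(\Delta C < 0)$ at
$\lambda = 0$ and tends to $P(\Delta Q > 0)$ as $\lambda \to \infty$. For
a mostly-dominant intervention the former exceeds the latter (≈0.96 vs
≈0.62 here), so the CEAC *declines* with the threshold. It is provably
non-decreasing only when every draw gains QALYs, and the test suite
asserts exactly that conditional property.

The 95% ellipse on the (ΔQ, ΔC) plane is the bivariate-normal region from
the draw mean and covariance scaled by the $\chi^2_2$ quantile
(`confidence_ellipse()`); empirical coverage on normal draws is verified
to Monte-Carlo precision.

## Synthetic data

`simulate_trial()` and `simulate_cohort()` generate panels with the
structure the derivation assumes, and only that structure: states first
(Markov, per the configured probabilities), then OKS-PS scores, utilities
and costs conditional on state. OKS-PS supports are disjoint across states
by construction, so classification recovers the generating states exactly.
Utilities are Gaussian around state means, capped at 1, negative values
allowed; costs are gamma with configurable coefficient of variation
(default 0.5, typical of right-skewed healthcare costs) and an optional
point mass at zero. The trial design observes utilities at 0/6/12 months
with the interim visit sharing the 12-month state (one transition is
modelled per year, so the interim state is not separately generated);
the cohort is assessed yearly for five years.

Default sizes are 2,000 patients per trial arm and 5,000 in the cohort —
large enough that derivation checks are sharp, small enough to run in
seconds. Generator means default to the built-in fixture's comparator
values, so the infinite-sample derivation (`implied_parameters()`)
reproduces the fixture's comparator arm exactly — a closed loop the test
suite exploits. What the generator does **not** emulate: demographics,
informative missingness, measurement error correlated over time, or any
difference between the three real data sources' populations. Passing the
recovery tests therefore shows the pipeline is consistent, not that the
real sources are exchangeable.

## Numerical choices and test scale

Row-stochasticity and distribution sums are checked to 1e-9; mass
conservation and engine-vs-oracle agreement to 1e-12 (the oracle is an
independently hand-unrolled five-step scalar recursion). Reported CSVs are
rounded only at the reporting boundary (2 decimals for money and QALY
totals, 3 for incremental QALYs); JSON carries full precision. The test
suite runs the PSA at 10,000 draws (matching the published analysis, ~15
s) and the recovery checks at n = 2,000 × 20 seeds and one n = 10,000
derive-and-run pipeline; these sizes give Monte-Carlo error well inside
every asserted tolerance.

## Known limitations

* Published inputs are stored at printed precision; quantities that
  difference two similar totals (notably the base-case ΔQALY, 0.085 from
  printed inputs vs 0.086 published) amplify that rounding beyond their
  own printed precision.
* The intervention-arm cost constant (≈£208) is documented and
  calibratable but unexplained by the published inputs.
* No mortality, no social-care costs, no within-cycle timing, two states
  only — structural simplifications inherited from the modelled design.
* PSA hyperparameters and cross-parameter correlations are assumptions
  controlled by `dispersion`, not reproductions.
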