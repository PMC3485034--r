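---
title: "Rule-based immunization coverage estimation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based immunization coverage estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wuenicr)
```

## The estimation problem

Annual national immunization coverage — the share of surviving infants
receiving a vaccine dose — is observed twice, badly: administrative
reports (doses given over an estimated birth cohort) are timely but
distorted by denominator error and double counting, and household
surveys are accurate for a birth cohort but arrive years later, with
sampling and recall error. The official estimate must pick one number
per country/vaccine/year, be reproducible, and be *explainable*: an
auditor must be able to see which rule or which expert decision produced
every figure.

`wuenicr` treats this as deterministic rule evaluation over a relational
knowledge base of five tables (reported data, survey results, survey
metadata, working-group decisions, required keys). Expert decisions are
data, not code: each carries an action (`assignWUENIC`,
`ignoreReported`, `acceptReported`, `ignoreSurvey`, `acceptSurvey`,
`interpolate`, `comment`) and a mandatory written explanation that is
propagated verbatim into the output. The closed-world convention — a
rule engages only when no overriding decision exists — is realized as
fixed if/else precedence, which makes the system decidable, fast, and
independent of the order in which rules or rows are written.

## The four levels

**Level 1 — grading.** Every data point is accepted, modified or
excluded, and every exclusion carries a reason. Reported coverage
≥ 100 % is excluded as implausible. A one-year spike — consecutive-year
changes larger than the jump threshold in *both* directions — is
attributed to the outlying year and excluded; a sustained shift (no
recovery) is only flagged, because a real programme collapse looks
exactly like that and the decision to exclude belongs to the working
group. Surveys need n ≥ 300 (strict: 299 is out, 300 is in) and an age
cohort inside the configured window. Decisions are evaluated after all
filters so that they dominate in both directions. Accepted reported
points are completed into a series by exact linear interpolation and
nearest-neighbour extrapolation.

**Level 2 — anchors.** Years with both accepted reported data and at
least one accepted survey are anchor points. The support test is
`|Psurv − Prpt| < 10` (strict, in percentage points): supported means the
reported value stands (`AP:R`), unsupported means the survey value
stands (`AP:S`). Several same-year surveys are combined by unweighted
mean before the test (sample-size weighting is available in the
configuration). An `assignWUENIC` decision makes its year an anchor by
fiat (`AP:W`).

**Level 3 — completion.** Between two `AP:R` anchors the surveys have
certified the reported series, which passes through unchanged. In every
other segment the reported series is *calibrated*: each end's ratio
(anchor estimate ÷ reported value at that year) is blended linearly in
time and multiplies the series, so the output passes exactly through the
anchor estimates while preserving the reported shape. Beyond the
outermost anchors a single constant ratio applies. A `W:I` decision
replaces a segment with straight-line interpolation between the anchor
estimates. Years with no reported data at all take the temporally
nearest estimate (`E`).

**Level 4 — reconciliation.** DTP1 (first dose) is sometimes
under-reported because it is not the "final" dose of the series. Where
the DTP1 estimate is missing or falls below DTP3, it is replaced by the
modelled value

$$P_{1} = P_{3} + aP_{3}^2 + bP_{3} + c, \qquad
  (a, b, c) = (-0.0066,\; 0.4799,\; 16.67),$$

clamped to [0, 100], rule code `RMF`. The polynomial's positive root is
at ≈ 98.4: below it the modelled DTP1 always lies above DTP3, above it
the raw polynomial dips slightly below DTP3. We keep the raw value
rather than forcing DTP1 ≥ DTP3, and the property suite documents the
breakeven. Decision-assigned estimates are exempt: an expert assignment
is never overridden by any rule, including this one.

## Parameters

| setting | default | units | role |
|---|---|---|---|
| `support_threshold` | 10 | % points | strict survey-vs-report support window |
| `min_sample_size` | 300 | children | survey exclusion bound (strict `<`) |
| `jump_threshold` | 20 | % points | year-over-year change treated as a jump |
| `exclude_sustained_jumps` | `FALSE` | — | exclude (vs flag) non-recovering jumps |
| `cohort_min/max_months` | 12–59 | months | valid survey age cohort |
| `survey_weighting` | `"none"` | — | same-year survey combination |
| `dtp1_poly` | (−0.0066, 0.4799, 16.67) | — | DTP1/DTP3 model coefficients |
| `calibration` | `"multiplicative"` | — | ratio vs additive-shift calibration |
| `source_precedence` | reported > gov > admin | — | coexisting report sources |

The support threshold, the 300-child bound, the interpolation formula
and the polynomial coefficients are the published operational values of
the method; the jump threshold is stated only qualitatively ("large
changes") in its public description, so 20 points is this package's
default, chosen to be well clear of ordinary year-to-year programme
variation (a few points) while catching the halving-and-recovery
patterns typical of denominator errors. It is a configuration entry, not
a constant.

## Numerical choices

* Coverage is carried in percentage points at full precision throughout;
  clamping to [0, 100] and rounding (half away from zero, so 96.5 → 97)
  happen once, at final output. The estimates table exposes both
  `coverage` (published integer) and `coverage_raw`.
* Calibration by ratios preserves zero and ordering; when a reported
  value of 0 at an anchor year would make a ratio undefined, the segment
  falls back to an additive shift and the audit records the method.
  Anchor fidelity — output equals the anchor estimate exactly at anchor
  years, before rounding — holds under either form.
* Whether two-anchor calibration blends the endpoint ratios linearly or
  steps at the midpoint is not pinned down by the method's public
  description; we blend, which is continuous in time and reduces to the
  constant-ratio case when the ratios agree.
* The jump filter compares consecutive *calendar* years; across a
  reporting gap no jump is assessed (an apparent large change over a
  multi-year gap is not evidence of a reporting artefact in either
  specific year).
* The recall-bias correction needs a card-only dose-k figure and both
  dose-1 figures from the same survey; the survey table therefore
  accepts an optional `evidence` column (`card`/`either`), defaulting to
  the survey's confirmation method. Without the needed figures, the
  result is accepted unchanged and the missing-data reason recorded. The
  exact production correction is not published; the dose-1
  card/history-ratio method used here is the conventional EPI-survey
  correction and is isolated behind one operation so it can be swapped.
* Tie-breaks are deterministic everywhere: equidistant
  nearest-neighbour fills take the earlier year; coexisting report
  sources resolve by configured precedence.

## Override semantics

For any key, an `assignWUENIC` decision fixes the final estimate — the
data-driven anchor rules, the segment logic and the DTP1 reconciliation
all carry the implicit "no overriding decision" guard. `accept*` /
`ignore*` decisions dominate the grading filters in their direction.
A decision-fixed anchor does **not** certify the reported series: for
segment logic it behaves like a survey anchor, so neighbouring years are
calibrated to it rather than passed through. Keys whose only information
is an assigned estimate still produce it (and neighbours extrapolate
from it); keys with no accepted data of any kind produce a logged gap,
never a silent hole and never an invented number.

## What the synthetic generator emulates — and what it does not

`random_kb()` draws latent true coverage trajectories as bounded random
walks in [5, 98], then corrupts them the way the real data streams do:
reported = truth + systematic over-reporting bias + noise (occasionally
crossing 100, so the exclusion filter is exercised), surveys = truth +
noise with sample sizes straddling the 300 boundary and occasional
invalid cohorts, and decisions of every action sprinkled at a
configurable rate. It does *not* emulate real-world features such as
correlated multi-year denominator drift, country-specific survey
availability patterns, or politically-timed reporting artefacts — so
green property tests demonstrate the rules' internal guarantees
(uniqueness, dominance, fidelity, order-invariance), not calibration
against real country data. The worked-example fixtures pin the
arithmetic to published values; the twelve-year scenario fixture pins
*which rule fires when* across all behaviours simultaneously, with
synthetic numbers.

Every fixture is also evaluated by a second, deliberately naive
reference implementation of the rules (flat year-by-year loops, no
shared code), and the engine must agree with it exactly; problem sizes
in the test suite (hundreds of knowledge bases of 1–2 countries, 2–3
vaccines, 8–15 years) keep the full suite under a minute while covering
every rule path.

## Known limitations

* No uncertainty intervals: the method is point-estimation by design.
* The support test ignores survey confidence intervals and design
  effects; the threshold is a hard 10 points.
* Only the DTP1/DTP3 pair is reconciled across vaccines.
* Reports and surveys for the same key are reconciled, but multiple
  conflicting *reported* sources resolve by precedence, not by
  evidence-weighing.
* Whether production systems additionally floor DTP1 at DTP3 after the
  polynomial near 100 % is unknown; this package does not.
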