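# wuenicr

A deterministic, fully explainable rule engine for estimating national
immunization coverage from conflicting data sources, in the style of the
WHO & UNICEF joint estimates (WUENIC).

## The problem

National immunization programmes report annual coverage — the percentage
of surviving infants who received a given vaccine dose (DTP3, measles,
polio, ...) — to WHO and UNICEF. These administrative figures are cheap
and timely but suffer from denominator problems, double counting and
missing reports; independent household surveys (DHS, MICS, EPI cluster
surveys) measure the same quantity years later, with their own biases
(small samples, caretaker recall). Producing one official estimate per
country, vaccine and year therefore requires reconciling the two sources
under a documented set of heuristics, plus explicit expert ("working
group") decisions for exceptional events such as vaccine stock-outs or
civil unrest.

`wuenicr` implements this reconciliation as a rule engine with
closed-world override semantics: for every rule, the expert decision
dominates when present and the data-driven rule engages only in its
absence. Every output estimate carries a rule code and a generated
explanation, so each number can be traced back to the data and decisions
it came from.

## The method

Estimation proceeds in four levels, per country and vaccine:

1. **Data grading.** Reported values ≥ 100 % are excluded; one-year
   spikes larger than a configurable jump threshold (default 20 points)
   are excluded; surveys with sample size < 300 or an age cohort outside
   the valid range are excluded; multi-dose survey results measured by
   card only are adjusted for recall bias using the dose-1 card/history
   ratio. Working-group `accept*`/`ignore*` decisions are applied last
   and dominate every filter. The accepted reported points are completed
   into a full time series by linear interpolation,

   *P*(y) = *P*₁ + (y − y₁) · (*P*₂ − *P*₁)/(y₂ − y₁),

   with nearest-neighbour extrapolation outside the observed range.
2. **Anchor points.** At years with both accepted reported data and
   accepted survey results, the estimate is the reported value when
   |*P*ₛᵤᵣᵥ − *P*ᵣₚₜ| < 10 (rule `AP:R`), otherwise the survey value
   (`AP:S`); an assigned working-group estimate always wins (`AP:W`).
3. **Series completion.** Between two `AP:R` anchors the estimates are
   the reported series itself; otherwise the reported series is
   calibrated — scaled by anchor-estimate/reported ratios blended
   linearly in time — so it passes exactly through the anchor estimates
   (`C`). The same logic, with a constant ratio, applies beyond the
   earliest and latest anchors; report-less years take the value closest
   in time (`E`).
4. **Reconciliation.** Where the DTP1 estimate is missing or falls below
   DTP3, it is re-derived from DTP3 via the modelled second-degree
   polynomial *P*₁ = *P*₃ − 0.0066 *P*₃² + 0.4799 *P*₃ + 16.67
   (rule `RMF`).

All thresholds and coefficients live in a YAML configuration
(`wuenic_config()`), so refining a rule is a config edit.

## Worked example

```r
library(wuenicr)
kb <- egypt_fixture()        # reported 97/96, surveys 93.5/95 (2004/2005)
res <- wuenic_run(kb)
res$estimates[, c("vaccine", "year", "coverage", "rule_code", "explanation")]
#>   vaccine year coverage rule_code                              explanation
#> 1    dtp3 2004       97      AP:R Reported coverage is supported by survey
#> 2    dtp3 2005       96      AP:R Reported coverage is supported by survey
```

The surveys fall within 10 points of the reports in both years, so both
years are anchor points resolved to the reported data: the estimates are
97 % and 96 % with rule code `AP:R`. Had the 2004 survey found 85 %
instead, the 2004 estimate would have been 85 with code `AP:S`; a
working-group decision assigning a value would override either outcome
(`AP:W`) and propagate its written justification verbatim.

The same run from the shell, using the CSV knowledge base shipped under
`inst/extdata/egypt/`:

```sh
exec/wuenic run --data inst/extdata/egypt --out out/
#> 2 estimates, 0 gaps -> out/
```

which writes `estimates.csv`, a grading audit log, anchor and gap tables,
and an HTML country report with per-vaccine plots.

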