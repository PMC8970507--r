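---
title: "Disaggregating fishery variable costs from fleet segment to métier"
author: "metiercost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disaggregating fishery variable costs from fleet segment to métier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metiercost)
```

## The model and its assumptions

Variable costs (fuel cost, fuel consumption, labour cost) are observed
annually per vessel, while activity is observed per trip and métier. The
method rests on three assumptions:

1. **Proportional attribution.** A vessel-year's costs can be attributed to
   its prevalent métier in proportion to that métier's share of the
   vessel-year's activity. If the prevalent métier accounts for 75 % of the
   monitored activity, 75 % of each variable cost is treated as the cost of
   fishing under that métier. The remaining 25 % is discarded rather than
   attributed to the minor métiers, because a handful of observations per
   minor métier cannot support a stable per-métier estimate — that is the
   same reasoning behind the coverage filter below.
2. **Linearity through the origin (exploratory stage).** Each cost is
   proportional to one transversal variable: no activity, no variable cost.
   The null intercept is what makes phase 2 a multiplication: the fitted
   slope can be applied directly to a métier-level transversal total.
3. **Gaussian errors, identity link (inference stage).** The candidate
   GLMs for an adjusted cost $y$ with transversal $x$ and métier factor $m$
   are the nested family

   $$\mathrm{EQ3}:\; y = \alpha x + \varepsilon \quad\subset\quad
     \mathrm{EQ1}:\; y = \alpha_m + \beta x + \varepsilon \quad\subset\quad
     \mathrm{EQ2}:\; y = \alpha_m + (\beta + \gamma_m)x + \varepsilon,$$

   with $\varepsilon$ Gaussian. The métier factor is coded as **cell means**
   (no global intercept), so each métier carries its own coefficient
   $\alpha_m$ that phase 2 can use directly; in EQ2 the interaction is coded
   as slope offsets against the first métier ($\gamma_{\text{ref}} = 0$).

Within each observation, the activity share multiplies the transversal
totals as well as the costs. Only costs are mentioned by the attribution
rule, but scaling one side and not the other would distort every per-unit
rate (cost per hour, crew share of revenue); the run log flags that both
sides are scaled.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `activity_metric` | `hours_at_sea` | — | "Most frequent in terms of fishing activity" needs a metric; hours at sea is the effort unit used throughout. `fishing_days` and `trip_count` are available (trip counts suit passive gears, where soak time decouples effort from hours). |
| `coverage_threshold` | 0.8 | share of observations | Métiers covering the top 80 % of a segment's observations are retained; per-segment overrides (e.g. 0.95 for a segment with three evenly represented métiers) via `coverage_overrides`. |
| `min_n` | 30 | observations | Minimum sample for any emitted regression row. |
| `alpha` | 0.05 | — | Significance level, strict inequality everywhere (`p < alpha`). |
| `fallback` | `"skip"` | — | What phase 2 does with métiers present in the transversal table but absent from the fitted model; see below. |
| `scale_intercepts_by_vessel_count` | off | — | Intercept-scale correction in phase 2; see below. |

## The decision flow and its significance rules

The selection logic per fleet segment and cost variable:

1. **Exploratory gate.** If no candidate transversal shows a significant
   *Pearson correlation* with the cost, no disaggregation approach makes
   sense and the result is `"none"`. The gate deliberately uses the
   correlation test, not the through-origin slope test: two strictly
   positive variables regressed through the origin produce a "significant"
   slope almost regardless of association (the line must pass through the
   data cloud), which would make the `"none"` branch unreachable. The
   centred correlation measures association proper.
2. **EQ2** if at least one métier level, the common slope, and at least one
   interaction offset are significant; else
3. **EQ1** if at least one métier level and the slope are significant; else
4. **EQ3** if the through-origin slope is significant; else `"none"`.
5. Among several qualifying transversals (labour typically has revenue and
   effort), the lowest AIC wins.

**Why "any level significant" for the factor?** The factor test is
deliberately permissive: a segment in which a single métier differs
detectably from zero already justifies métier-level coefficients, and
published applications retain models whose weakest métier level sits near
p ≈ 0.1. A joint F-test of the factor against a common-intercept model is
available (`metier_significant(..., joint = TRUE)`) but off by default.
Exact ties with `alpha` are not significant.

With a single prevalent métier in a segment, EQ1/EQ2 are not estimable (the
métier factor is confounded with a global intercept) and the flow proceeds
directly to EQ3 — the single-métier fleet segment is the canonical EQ3 case.

## Phase 2: disaggregation and its known scale limitation

Phase 2 evaluates the selected equation on métier-level transversal totals
$X_m$: $\alpha_m + \beta X_m$, $\alpha_m + (\beta+\gamma_m) X_m$, or
$\alpha X_m$. Two deliberate policies:

* **Unmodelled métiers** (below the coverage threshold in phase 1) are
  *skipped* by default, leaving them unallocated. This reproduces the
  baseline behaviour, where part of the reconciliation gap is exactly this
  coverage loss. `fallback = "pooled"` instead applies the segment's pooled
  zero-intercept slope as an EQ3-style estimate.
* **Intercept scale.** $\alpha_m$ is estimated per vessel-year but added
  once per métier to a fleet-level product $\beta X_m$. The baseline method
  does exactly that, and the default reproduces it; the consequence is a
  systematic shortfall whenever intercepts carry a substantial part of the
  cost, visible in the consistency check. For users who want scale
  consistency, `scale_intercepts_by_vessel_count = TRUE` multiplies
  $\alpha_m$ by the number of active vessels (supplied per year × segment ×
  métier). The package reports the gap rather than repairing it: no
  residual reallocation forces métier costs to sum to the official total.

The consistency check reports, per (year, segment, cost variable), the
signed relative difference between the métier sum and the official total,
and overall the mean of the absolute relative differences in percent. Rows
with an official value of zero are flagged and excluded from the overall
mean.

## The synthetic fleet generator

`simulate_fleet()` emulates what the method needs from confidential trip and
cost records:

* **Activity.** Each vessel has a designed prevalent métier; its activity is
  split across métiers by a Dirichlet draw concentrated on that métier
  (expected share `prevalence_concentration`, default 0.8, precision 150).
  Trip hours are gamma distributed (shape 4) around `mean_trip_hours` (48 h)
  with `trips_per_vessel` (13) trips per year on average, and are rescaled
  within métier so realised hour shares equal the drawn shares exactly.
* **Costs on the attributed scale.** The generating law is written where
  the GLM is defined: attributed fuel $= \alpha_m + (\beta+\gamma_m)\,h_m$
  with $h_m$ the hours on the prevalent métier; the recorded vessel-year
  total is that amount divided by the activity share. Dividing rather than
  multiplying makes phase 1's proportional attribution *exact by
  construction*, so recovery experiments measure estimator properties and
  not an extra, uncontrolled attribution error. It also embodies the same
  assumption that justifies proportional attribution in the first place:
  cost per unit of activity is the same across the vessel's métiers. Labour
  is `crew_share × revenue` (default 0.3, the crew-share remuneration
  system) and needs no such construction — proportional relationships
  survive scaling untouched.
* **Noise.** Default is multiplicative lognormal with mean 1 and
  coefficient of variation `noise_cv`: costs are positive and right-skewed,
  and the deliberate mismatch with the Gaussian fitting assumption probes
  robustness. `noise = "gaussian"` adds homoscedastic noise with
  sd = `noise_cv` × the segment mean cost — the exact-recovery mode in
  which OLS standard errors are textbook-valid, used for the coverage
  experiments.
* **Aggregates.** Segment cost totals and métier transversal totals are
  exact marginal sums of the micro-data, so end-to-end conservation can be
  asserted to machine precision.

Default scenario scale: four segments (three trawler length classes with
2–3 otter-trawl métiers, one single-métier hooks segment), ~450 vessels,
two pooled years, fuel intercepts 10 000–20 000 per métier-year, slope 25
per hour, crew share 0.3 — magnitudes in the range reported for
Mediterranean demersal fleets. A full simulate-fit-disaggregate-check cycle
runs in about a second.

**What the generator does not emulate:** spatial fishing-ground structure,
effort displacement between years, vessel-level random effects or serial
dependence from repeated observation of the same vessel, métier-dependent
trip-length distributions, and price dynamics (fuel price is a constant
converting cost to consumption). Passing tests on synthetic fleets
therefore show that the estimators and the selection flow work *when the
model family contains the truth and observations are independent*; they do
not certify performance on real fleets, where pooling years violates
independence and cost processes are richer.

## Experiment sizes and numerical choices

The replication studies use fleets of 120–200 vessels over one simulated
year, with 100 replicates for selection rates and 200 for coverage — sizes
at which the Monte-Carlo error of a selection rate is about 2–3 percentage
points and a full study runs in a couple of minutes on one CPU.

* Ties in prevalent-métier activity are broken toward the lexicographically
  smaller métier code (deterministic) and flagged.
* The coverage filter defines shares against the totals of the dataset it
  first saw (recorded on the filtered result), making re-application a
  no-op rather than a further cut.
* Explained deviance is $100(1 - D_{\text{res}}/D_{\text{null}})$ with the
  intercept-only null model; with no-intercept formulas R's own
  `null.deviance` would reference the empty model and inflate the figure.
* Zero-intercept slope inference uses $n-1$ degrees of freedom
  ($\hat\sigma^2 = \mathrm{RSS}/(n-1)$, $t = \hat\beta/\mathrm{se}$).
  Perfect fits (noiseless fixtures) yield $p = 0$ for a non-zero slope and
  $p = 1$ for a zero one, rather than NaN.
* Written CSVs format doubles with 17 significant digits so a write–read
  cycle reproduces values bit-for-bit; result tables are sorted on all
  columns for byte-identical reruns.
* A métier with fewer than 2 (EQ1) or 3 (EQ2) observations makes the
  design effectively rank-deficient; the error names the métier. Rows with
  missing values enter only the analyses that do not need them (a trip
  without landings value still supports fuel~effort).

## Known limitations

* The intercept-scale gap in phase 2 (above) is inherent to applying
  vessel-level intercepts at fleet level; the consistency check is the
  honest report of its size.
* The decision flow inherits the multiple-testing behaviour of the
  any-level rule: with $k$ métiers, the chance of a spurious EQ2 upgrade
  grows with $k$ at rate roughly $1-(1-\alpha)^{k-1}$.
* Transversals derived from costs (revenue minus variable costs, revenue
  minus fuel) are available in the exploratory stage but cannot drive
  phase 2, because they are not observable at métier level in the official
  transversal tables; the selection stage therefore only offers revenue and
  effort as candidates.
* Currency and consumption units are carried as labels and never converted;
  pooled years are treated as independent observations.
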