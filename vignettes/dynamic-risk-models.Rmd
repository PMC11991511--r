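---
title: "Dynamic risk models from wearable event logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic risk models from wearable event logs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynrisk)
```

## The problem

Older cancer survivors wear an activity tracker for about three months
and answer two short questionnaires once a month: the VES-13 (vulnerable
elders screen, 0–10, positive at 3 or more) and the PHQ-4
(anxiety/depression screen, 0–12, positive at 3 or more). The question a
dynamic risk model answers is: *which time-varying behaviour patterns —
not static covariates — carry excess risk of a patient ever reporting a
positive screen?*

The pipeline has five stages:

1. **Discretization.** Daily step counts become `sedentary` (< 5000),
   `medium` (5000–10000, both ends included) or `active` (> 10000);
   nightly sleep efficiency becomes `insufficient` (< 0.80), `normal`
   ([0.80, 0.90)) or `beneficial` (>= 0.90). The interval convention is
   left-closed, so every value maps to exactly one state; 0.80 is
   `normal` and 0.90 is `beneficial`.
2. **Run collapsing.** Consecutive observed days in the same state merge
   into a *visit* with a duration in observed days. A calendar gap of at
   most `max_gap` days (default 2) inside a same-state run is bridged; a
   longer gap ends the visit and starts a new segment, and no transition
   is counted across the break.
3. **Process discovery.** Each segment contributes a path
   `@Start -> v1 -> ... -> vk -> @End` to a directly-follows graph whose
   edges count transitions and whose state nodes carry the median visit
   duration. Heat scores min–max normalise medians (nodes) and counts
   (edges) per model, with an all-equal fallback of 0.5, and export to
   Graphviz DOT (green–red fill) and versioned JSON.
4. **Trace clustering.** Pairwise dissimilarities between patients'
   daily state sequences are computed by global alignment: substitution
   costs the ordinal gap `|i − j| / (K − 1)`, an insertion/deletion
   costs 0.75, and the optimal alignment cost is normalised by the
   longer sequence. Quality Threshold Clustering (QTC) then repeatedly
   accepts the largest greedily grown cluster whose diameter (maximum
   pairwise distance) stays within a threshold; patients never assigned
   are outliers. The threshold is selected from a candidate grid (by
   default the deciles of the off-diagonal distance distribution) to
   maximise the Pearson chi-square separation between the resulting
   strata (clusters plus one outlier stratum) and the outcome labels,
   with ties broken toward the smallest threshold.
5. **Relative risks.** For each behaviour stratum (and for categorical
   exposures such as cancer type), a 2×2 table against the outcome gives
   `RR = (a/(a+b)) / (c/(c+d))` with a 95% interval from the log-method
   (Katz) standard error `sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`. Both the
   event and its complement are tabulated (their tables are cell swaps
   of each other), printed as `X (Y; Z)`, and a row is flagged when the
   whole interval exceeds 1.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| step cut-offs | 5000, 10000 | steps/day | sedentary / medium / active bands in common clinical use |
| sleep cut-offs | 0.80, 0.90 | fraction | insufficient / normal / beneficial sleep efficiency |
| `max_gap` | 2 | days | bridges isolated missing days without welding separate episodes |
| gap cost | 0.75 | per day | between the adjacent (0.5) and extreme (1.0) substitution costs, so alignments use gaps but not freely |
| `min_size` | 5 | patients | clusters smaller than this are not clinically interpretable strata; unassigned cases become outliers |
| CI level | 0.95 | – | conventional; the normal quantile is computed, not hard-coded |
| zero-cell policy | error | – | an undefined RR is reported as such; the Haldane–Anscombe +0.5 correction is available behind an explicit flag, never silent |

## What the synthetic generator emulates

Real study data of this kind are restricted, so the package ships a
first-class generator whose defaults encode the study conditions: 121
patients, 90 monitored days, five activity behaviour groups in
proportions 42:25:24:19:11, three sleep groups plus outliers in
proportions 35:22:16:48, three VES-13 and four PHQ-4 questionnaires per
patient, 5% of days missing independently per stream, ages
normal(71.63, 5.93) truncated to [65, 95] (the truncation raises the
realised mean to about 73), melanoma recruited in Sweden and
breast/prostate cases in Greece, Spain and Scotland with per-country sex
ratios.

The questionnaire schedule ("monthly, plus one at the beginning")
suggests four of each; the study text states three VES-13 were
collected, so the defaults are 3 VES-13 and 4 PHQ-4.

Each behaviour group is a first-order Markov chain over the three daily
states. The transition matrices are the package's own design, calibrated
once, by simulation, against the requirement that the groups be
*numerically distinct under the alignment distance* (so that clustering
can recover them) as well as plausible daily dynamics:

* `active` and `long_sedentary` (and `insufficient` for sleep) are
  near-corner chains: one state dominates (occupancy 0.85–0.92);
  `long_sedentary` keeps a 0.92 self-stay on the sedentary state, giving
  multi-day sedentary runs and stationary sedentary occupancy above 0.8.
* `medium_to_active`, `sedentary`, `insufficient_with_dynamism` and
  `balanced` are near-alternating chains (off-diagonal mass ≈ 0.85–0.9
  between their two main states). Alternation is the one first-order
  dynamic that is intrinsically *tight* under the alignment distance: two
  alternating sequences synchronise up to a single gap, so within-group
  distances stay small while composition differences to other groups
  remain visible. Mixture chains with 30% minority days, by contrast,
  have within-group spreads (≈ 0.25–0.28) comparable to their distance
  from neighbouring groups on the sedentary–medium axis (whose
  substitution cost is only 0.5), which makes five groups unrecoverable.
* `medium_to_sedentary` is a fast-mixing medium-dominant mixture with
  ~25% sedentary days — the one deliberately diffuse group.
* Sleep `outlier` patients each get an idiosyncratic high-temperature
  chain (transition rows drawn per patient from a Dirichlet with
  concentration 2). Such near-uniform chains produce high-entropy
  sequences that sit 0.28+ apart from each other and from the structured
  groups, so outliers resist clustering instead of forming spurious
  groups. `balanced` is consequently *not* near-uniform (it alternates
  normal/beneficial nights — stable adequate sleep); a near-uniform
  balanced group would be statistically indistinguishable from the
  outliers.

States map back to numbers by uniform draws strictly inside each
category's interval (steps: 0–4999, 5000–10000, 10001–20000; sleep
efficiency: 0.50–0.799, 0.80–0.899, 0.90–0.99), so discretization
inverts the mapping exactly.

### Planted outcomes

Outcomes are planted at the patient level. The probability of *ever*
reporting a positive screen is a baseline multiplied by the relative
risk of each exposure the patient carries: long-sedentary activity
(RR 2.58) and prostate-metastatic cancer (RR 3.28) for vulnerability,
insufficient-with-dynamism sleep (RR 2.02) for anxiety/depression.
Joint effects multiply on the probability scale — independence is the
simplest testable assumption — with a hard cap at 0.95 that warns when
it binds. With `k` questionnaires, each is positive independently with
probability `q = 1 − (1 − p_any)^(1/k)`, which makes the any-positive
probability exactly `p_any`; positive VES-13 totals are uniform on 3–10,
negative on 0–2 (PHQ-4: 3–12 / 0–2).

The vulnerability baseline defaults to `p_vuln_base = 0.11`: it is the
largest round value keeping the strongest joint cell below the cap
(0.11 × 2.58 × 3.28 = 0.93 < 0.95). A higher baseline such as 0.18
would make the cap truncate the long-sedentary × prostate-metastatic
cell and bias the planted marginal RR downward by about 6%, defeating
parameter-recovery checks. The anxiety baseline is 0.25 (no joint
factor). The cancer mix (54 breast-curative, 36 prostate-curative, 21
melanoma, 5 breast-metastatic, 5 prostate-metastatic per 121) keeps the
metastatic-prostate group small, consistent with the width of the
published interval for that stratum.

### What the generator does *not* emulate

Calendar structure (weekday/weekend rhythms, seasonal drift), gradual
trajectories (recovery or decline over the study), informative
missingness (sicker patients wearing the tracker less), within-patient
correlation between activity and sleep, and measurement error in the
tracker itself. Passing recovery tests therefore shows the *pipeline*
is correct and well-calibrated under first-order stationary dynamics
with independent missingness — not that real cohorts satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Boundary values: 5000 and 10000 steps are `medium`; 0.80 is `normal`
  and 0.90 `beneficial` (the ambiguous [0.89, 0.90) band is `normal`).
* Medians of even-length duration sets take the midpoint of the central
  pair; durations count observed days, not calendar days.
* QTC is fully deterministic: greedy growth adds the point minimising
  the resulting diameter with ties broken toward the smallest case id;
  the largest candidate wins with ties toward the smallest seed id.
  Growth is a heuristic — tests compare its first accepted cluster with
  a brute-force maximum subset at n ≤ 7 and pin any divergence.
* Threshold selection drops strata with zero row totals before the
  chi-square and returns 0 when fewer than two strata (or an empty
  outcome margin) remain; ties choose the smallest threshold.
* `RR` with no unexposed events is an explicit error, never `Inf`;
  strata equal to the whole universe are emitted with a degenerate
  marker and no estimate; displayed tables round to 2 decimals but all
  computation is full precision.
* All randomness flows from a single integer seed; the pipeline derives
  a named substream per stage, and repeated runs are byte-identical.

## Problem sizes used by the test-suite

Unit examples run on hand-enumerable inputs. The parameter-recovery
checks use: mixture shares at n = 121 000 patients × 2 days; cluster
recovery on ten independent 121-patient, 90-day cohorts (modal cluster
count and mean adjusted Rand index across the ten seeds); planted-RR
recovery and the acceptance script on one 5000-patient cohort, where
the Monte-Carlo standard error of the estimated RR is about 6%;
interval coverage on 2000 replicated binomial 2×2 tables with true
RR = 2 at 200 per arm. These sizes give stable checks at a few minutes
of total runtime.

## Known limitations

* The recovered *number* of behaviour groups is the modal outcome over
  seeds, not a per-seed guarantee: at n = 121 the chi-square selection
  is itself noisy (the planted association contributes a chi-square of
  roughly 8–12, against a null mean of k − 1), and per-seed adjusted
  Rand indices range from ≈ 0.35 to ≈ 1.0.
* The alignment distance compresses the sedentary–medium axis (cost
  0.5), so behaviours differing only in the *run structure* of the same
  composition (e.g. "sedentary" vs "long sedentary" at equal sedentary
  share) are near-indistinguishable; the defaults separate them by
  composition and alternation instead.
* Relative risks are crude (unadjusted) and carry no multiplicity
  correction; with 121 patients the intervals are wide, and the dual
  event/complement columns are descriptive, not independent tests.
* QTC's greedy growth can in principle accept a sub-maximal cluster;
  observed divergence from the brute-force optimum at n ≤ 7 is rare and
  pinned in the tests.
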