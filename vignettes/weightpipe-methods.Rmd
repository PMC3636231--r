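---
title: "Methods: screening self-reported weights and modelling engagement effects"
author: "weightpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening self-reported weights and modelling engagement effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightpipe)
```

## The problem

Free online weight-loss programs accumulate event logs: date-stamped
self-reported weight entries and log-ins, plus undated per-member totals
for food and exercise diary use, points, forum posts, and friend links.
Two obstacles stand between those logs and an interpretable
engagement–weight-change association. First, self-reported weights carry
data-entry errors — omitted, added, or transposed digits — that can turn a
185-lb entry into 18 lb or 815 lb and wreck any trajectory-based outcome.
Second, most usage events are undated, so without care a member could have
used a feature *after* the last weigh-in, breaking the temporal ordering an
associational claim needs.

`weightpipe` implements the full chain: automated error screening with a
two-reviewer adjudication workflow, cohort construction under a
temporality rule, per-30-day usage coding, and the regression stage
(confounder screen, BMI-adjusted univariable models, backward stepwise
selection). A synthetic-data generator with ground-truth labels makes every
stage testable: filter sensitivity is measured against known injected
errors, and the regression stage is checked for recovery of known injected
effects.

## Screening rules

Entries are first collapsed to one per member-day (the last entry of the
day), so the unit throughout is the weight-entry *day*. Members with an
implausible recorded baseline are excluded outright: age above 100 years,
height above 120 inches, or a baseline weight under 100 lb / over 800 lb
*with no follow-up entries* — a lone implausible baseline is unverifiable,
while one followed by more entries can be adjudicated by the trajectory
filters instead.

Four filters then flag suspicious entries; all thresholds live in
`qc_thresholds()` with these defaults:

* **F1** (≥ 3 entry days): fit `weight ~ day + day²` by OLS per member;
  flag entries with `|residual| > 3·SD(residuals)` *and*
  `|residual| > 10 lb`. The SD uses the n−1 denominator — with tiny
  per-member records the sample SD is the conservative choice. With
  exactly three entry days the quadratic interpolates and nothing can be
  flagged. A further caveat worth knowing: on an otherwise smooth record a
  *single* gross spike inflates the residual SD itself, so with fewer than
  about 13 points the 3·SD conjunct cannot fire no matter how large the
  spike; F1 earns its keep on longer records and on records with ordinary
  measurement noise, while F2–F4 cover short ones.
* **F2** (≥ 3 entry days): flag both members of any consecutive pair whose
  change exceeds 2% of the earlier weight per day, whether the interval is
  one day or one year (strict inequality, so exactly 2.0%/day does not
  flag). The earlier weight is the natural denominator; an all-pairs
  version would double-count trends.
* **F3** (≥ 3 entry days): flag both members of *any* pair — not only
  consecutive — differing by 50 lb or more (inclusive). Both entries are
  flagged because the rule cannot tell which one is wrong; review decides.
* **F4** (≥ 2 entry days): member-level flag when the whole record's range
  (max − min) reaches 100 lb. Max − min rather than last − first, because
  an interior spike would otherwise hide. The flag carries the argmax and
  argmin entries so review has something concrete to look at.

Flagged entries go to two independent reviewers; disagreements require a
consensus verdict. Agreement is summarized as raw percent agreement and
Cohen's kappa `(p_o − p_e)/(1 − p_e)` with `p_e` from the observed verdict
margins. Only confirmed-erroneous entries are removed; the ledger reports
the removal as a percentage of all entries. On synthetic data the two
reviewers are simulated as ground truth plus independent verdict flips
(default probability 0.025 per reviewer, giving ≈ 95% raw agreement); note
that kappa is strongly driven by the erroneous base rate among flagged
entries, so a low-prevalence flag set yields a much lower kappa than the
same reviewers would earn on a balanced set.

## Cohort and outcomes

The analyzable cohort requires (i) at least two distinct weight-entry days
after cleaning, and (ii) the temporality rule: the member's last log-in
day falls on or before the last weight-entry day. Because every website
activity generates a log-in, this guarantees all feature use happened
between the first and last weigh-in — usage precedes the measured outcome.
A flow ledger records entering/excluded/retained counts per stage and
refuses to chain if the counts do not conserve.

Per member: baseline weight is the first cleaned entry (weight change is
defined from entries, so the roster weight is only used for baseline
exclusions); span is days between first and last entry; net change (kg) is
last − baseline; the per-30-day change divides net change by span/30
(baseline 108 kg, last 100 kg, span 60 days → −8/2 = −4 kg per 30 days);
BMI uses the imperial formula 703·lb/in². Span strata use the printed bins
with inclusive upper bounds (a 30-day span is "Up to 30 days") plus an
overflow bin.

## Usage coding

Binary flags are ever/never indicators for the five features a member can
plausibly never touch (food days, exercise days, exercise minutes, forum
posts, friends); log-ins, weigh-ins, and points are excluded because the
cohort definition forces the former two and nearly everyone has a point.
Categorical coding divides each count by the member's weight-entry span in
30-day units — the same exposure window as the outcome — with thresholds
at 4 events (≈ weekly), 120 exercise minutes, and 20 points per 30 days;
"0" always means an exactly zero count, "≥" boundaries are inclusive, and
friends stay on raw counts (0 / 1 / ≥2) since a friend link is a state,
not a repeated event.

## Regression stage

All inference is classical homoskedastic OLS; multi-level categoricals are
tested as blocks via `drop1` F tests so variables enter and leave models
whole. The confounder screen fits one univariable model of net change on
each of baseline BMI, age, gender, registration source, region, and span,
retaining candidates with overall P < .05. Univariable usage models adjust
for baseline BMI and use net kg for binary flags and kg per 30 days for
categorical variables — the two analyses deliberately use different
outcome scales. Backward stepwise selection starts from baseline BMI plus
all categorical usage variables, repeatedly removes the largest-p block at
or above P = .20 (refitting each time; ties broken toward the later term
in the declared order for determinism), and records the removal trace.
Baseline BMI is eligible for removal like any other term. Note a selection
rule with retention P < .20 keeps a pure-noise covariate in roughly 15–25%
of datasets by construction; that is a property of the threshold, not a
bug.

## The synthetic-data generator

`sim_config()` holds every tunable. The defaults describe a large free
online program circa its 2008 intake: ~90.7% female, age 33.6 (SD 11),
BMI 31.6 (SD 7.7), registrations over a 89-day window, follow-up through
day 829. A single latent engagement score per member drives log-in
frequency, attrition, and weigh-in propensity, which produces the
characteristic funnel: most members log a single weigh-in, usage totals
are right-skewed with point masses at zero, and an interacting "stops
weighing but keeps logging in" process generates the members the
temporality rule later excludes. A separate social latent drives forum
posts and friends so that social-feature use is not confounded with
weighing behaviour. Under the default configuration ~26.6k simulated
members funnel to a final cohort in the 1.2–1.8k range, matching the scale
of the motivating design.

Mechanics worth knowing:

* **Log-in process.** Log-in-day counts are `1 + Geometric(p)` with `p`
  shrunk for engaged members; gaps between log-in days are lognormal with
  a per-member median (engaged members return on a faster, more regular
  rhythm — the dispersion sits mostly *between* members) and a 4-day
  minimum turnaround. Weigh-in eligibility ends after a geometric number
  of log-ins (self-monitoring attrition).
* **Trajectories.** True weight is linear between first and last weigh-in.
  The per-30-day slope is
  `drift + β_weigh·I(rate ≥ 4/30d) + η`, `η ~ N(0, 0.9)` kg/30d, plus
  per-30-day accrual of the forum and BMI effects (below). Accrual noise
  with SD `0.8·√(span/30)` kg and i.i.d. 1-lb measurement noise per entry
  complete the observation model. Members whose trajectory would cross a
  physical floor (loss beyond 60 kg or true weight below ~38 kg) leave the
  program the day the floor is reached — a "goal reached" drop-out — so
  the linear slope holds exactly over every observed span instead of being
  clamped (clamping would bias slope recovery).
* **Injected effects.** The frequent-weigher effect is a per-30-day slope
  difference (default −5.09 kg/30d) keyed to the member's *realized*
  weigh-in rate. The forum (−1.55 kg) and BMI (−0.28 kg/unit) effects are
  specified on the net-kg scale and implemented as per-30-day accrual
  rates divided by a reference span (`span30_ref`, calibrated once to the
  default cohort's mean span of ≈ 4.2 span-30 units), so the marginal
  net-kg regression slopes equal the configured values while short-span
  members are not assigned instantaneous level shifts they could not have
  accumulated.
* **Errors.** Exactly `round(error_rate·n)` entries (default rate 0.002)
  are corrupted by omitting the last digit, appending a digit, transposing
  the first two digits, or an unexplained ±50–150 lb jump; every
  corruption is recorded in the ground truth. Baseline outliers are
  digit-slip typos of the *recorded* first entry over a sane true
  trajectory, so a typo with follow-up entries is exactly what the
  trajectory filters exist to catch.

What the generator does *not* emulate: within-window usage timing (the
undated totals are genuinely undated in the motivating data), weight
plateaus and regain cycles (trajectories are linear between endpoints),
seasonal or day-of-week behaviour, and any dependence of weight change on
demographics beyond BMI. Consequently, passing tests demonstrate that the
pipeline's logic is correct and that its models recover known effects
under the stated generative assumptions — not that those effects are
causally identified in real program data, where engagement and outcome
share unmeasured causes. One visible divergence: because the injected
frequent-weigher slope is sustained, synthetic long-span frequent weighers
legitimately lose 50–100 lb, so F3/F4 flag far more (valid) entries than a
real cohort would produce; the review stage exists precisely to pass such
entries through.

## Numerical and design choices

* Weights are stored in pounds end to end; kilograms appear only in
  outcomes and reports (1 lb = 0.45359237 kg). Dates are integer day
  offsets from the study epoch; ISO-8601 rendering happens only at CSV
  I/O.
* Same-day entries collapse to the last of the day before anything else
  runs, which also removes the Δday = 0 case from F2.
* All randomness flows from one seed; per-stage sub-streams are derived
  deterministically, and identical configurations produce byte-identical
  CSV output.
* F1 centers the day covariate before solving the quadratic — a
  conditioning measure only; residuals are unchanged.
* F1's residual SD includes the candidate point itself (plain residuals,
  not deletion residuals); the alternative is noted as an open choice and
  would only strengthen flagging.
* The filter union's sensitivity is reported both over all injected errors
  and over the filters' applicable domain (members with ≥ 2 entry days);
  a single-entry member cannot be screened by any trajectory rule, and
  such members never reach the cohort.
* Classical CI coverage for the frequent-weigher contrast is the most
  delicate recovery property: members with short spans have per-30-day
  noise amplified by 30/span, they concentrate in the frequent-weigher
  group, and homoskedastic OLS standard errors undercover under that
  variance pattern. The generator's attrition design keeps such "burst"
  members realistic but not dominant; measured coverage sits at, not
  comfortably above, the nominal level.

## Problem sizes used in tests

The test suite exercises the full pipeline at the study's sampled-cohort
scale (26,582 members per replicate; 20 replicates in the Monte-Carlo
recovery checks) and verifies the filters against brute-force oracles on
1,000 random series of up to 50 entries. A full pipeline run takes a few
seconds; the complete recovery Monte-Carlo runs in about a minute.

## Reproducing the headline numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes
the worked outcome example, the QC arithmetic, the flow accounting, the
kappa closed form, one full synthetic pipeline (cohort size, filter
sensitivity, removal percentage, recovered coefficients), and the
20-replicate CI-coverage summary, writing one flat JSON object.
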