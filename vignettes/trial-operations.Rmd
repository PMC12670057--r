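---
title: "Operating a remote weight-management trial: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operating a remote weight-management trial: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialops)
library(dplyr)
```

## The problem this package addresses

Fully remote weight-management trials replace clinic visits with consumer
devices: a cellular scale transmits every weigh-in, a diet app uploads daily
calorie logs, and the trial platform turns those streams into weekly
contingency-management decisions ("did this participant earn their incentive
this week?") and text messages. Between the devices and the decisions sit a
series of small but consequential rules — what counts as a plausible weight,
what counts as a logged day, when a Monday message moves to Tuesday — and
operational statistics that staff watch to keep the trial honest.

`trialops` implements that middle layer: ingestion of device-style streams,
automated anomalous-weight screening with manual reference resets, weekly
per-arm incentive adjudication across trial phases, holiday- and
timezone-aware message scheduling with delivery accounting, operational
reporting, and a synthetic-cohort simulator so the entire pipeline can be
exercised, tested, and demonstrated without any participant data.

## Study structure

The program runs 78 weeks in three 26-week phases: phase I targets weight
loss, phase II maintenance, phase III is observational (no incentives).
Weeks are anchored **per participant** at enrollment — a rolling cohort —
so week 1 begins on each participant's enrollment date and `study_calendar()`
produces their personal 546-day window. Participants are randomized to four
arms: `COMBINED` (rewarded for diet logging and weight progress, with a
partial award when exactly one criterion is met), `DIET_ONLY`,
`WEIGHT_ONLY`, and `CONTROL` (devices and messages, no money).

A participant is active from enrollment up to, but not including, any
withdrawal date; nothing is scheduled or adjudicated for the withdrawal day
itself. This exclusive boundary is a deliberate choice: a withdrawal
recorded in the morning should not generate an afternoon message.

## Weight screening

Scales in a household produce errant readings — another person stepping on,
an untared scale, a scale against a baseboard. Screening is a chained rule:
a transmission is **rejected** when its relative deviation from the
*reference weight* exceeds 3% (strictly; exactly 3% passes), where the
reference is the most recent accepted weight, seeded from the enrollment
baseline. Accepted weights become the new reference; rejected weights never
do, and rejected weights never reach the incentive engine.

Numerical choices worth stating:

* The deviation denominator is the reference, and the rule is symmetric in
  direction — gains and losses are screened identically.
* The threshold (0.03) is an argument everywhere it appears.
* A **manual reference reset** — a coordinator-verified weight entered after,
  say, a long scale hiatus — replaces the reference from its date forward and
  is itself exempt from screening. Without resets, a legitimately changed
  weight would be rejected forever; `flag_repeat_rejections()` (default: 3
  consecutive rejections, configurable because the run length defining a
  "pattern" is an operational judgement) exists to surface exactly those
  participants.
* The daily representative is the **mean of the day's accepted weights**,
  damping close-succession re-weighs; first-of-day or minimum were rejected
  as representative choices because they re-introduce sensitivity to the
  unreasonable first reading the re-weigh was meant to correct.

A property worth knowing: threshold monotonicity (a looser threshold never
rejects a weight it previously accepted) holds for a single measurement
against a fixed reference, but **not** through the chain — a looser
threshold can accept an excursion that then drags the reference with it.
The test suite checks the per-measurement property and checks the chain
against an independent brute-force re-walk instead.

## Incentive adjudication

Each completed phase I/II week, for each active incentivized-arm
participant:

* **Diet criterion** — at least `diet_days_required` (default 5) days with
  ≥1 food entry and ≥ `min_kcal_per_logging_day` (default 500 kcal). The
  calorie floor filters token single-entry days.
* **Phase I weight criterion** — at least `weighins_required_phase1`
  (default 2) accepted weigh-in days, and the weekly representative (mean of
  daily representatives) strictly below the lowest weekly representative to
  date — a *ratchet*. The ratchet prevents oscillation gaming (lose the same
  kilogram every other week); `phase1_rule = "prior_week"` switches to a
  simple decrease against the prior week for deployments that prefer it.
  For week 1 the baseline weight serves as the week-0 representative, so the
  first week must undercut baseline.
* **Phase II weight criterion** — at least `weighins_required_phase2`
  (default 1) weigh-in day, weekly representative within the anchor
  ± `maintenance_band_fraction` (default 2%). The anchor is the lowest
  phase I weekly representative. A participant with no accepted phase I
  weights has no anchor; their phase II weeks route to `MANUAL` rather than
  auto-deny, because an automated denial from missing data is precisely the
  case coordinators are meant to review.

`decide_week()` then applies the payout table: control and phase III always
zero; single-criterion arms pay `amount_full` when their criterion is met;
the combined arm pays full for both, `amount_partial` for exactly one. The
default amounts (20/10 units) are illustrative placeholders — protocols set
their own — and the engine only requires `amount_partial < amount_full`.

Manual adjudication (`mark_manual()`) is append-only: the original decision
is preserved in an audit attribute, the justification note is mandatory, and
control-arm overrides are refused outright.

## Message scheduling and delivery accounting

Every participant receives two motivational messages per week (Tuesday and
Friday) for all 78 weeks. Incentivized-arm participants also receive one
incentive-status message per phase I/II week on Monday — shifted to Tuesday
when Monday is a holiday (default calendar: observed US federal holidays;
the calendar is injected configuration). Motivational messages do not shift:
only the Monday incentive message carries the holiday rule.

Send times are drawn uniformly in [08:00, 11:00) in the participant's
**enrollment** time zone — travel never re-anchors the zone — and are
reproducible under a seed; changing the seed changes only the within-window
times, never dates or counts. Local wall-clock times are stored alongside
their UTC instants, so a schedule crossing a daylight-saving transition
stays inside the window by construction and the UTC offsets simply change.

Incentive message bodies are fixed templates per (arm, criteria pattern),
deliberately free of digits and currency symbols: carriers flag messages
with dollar amounts as likely spam, and removing numerals restores
delivery. Delivery is tracked as a small state machine
(`QUEUED → ACCEPTED_BY_CARRIER → DELIVERED`, with `FAILED` reachable from
the first two states); failed messages are retried up to 3 attempts except
for opt-outs and landlines, which are never retried. The **delivery rate**
is accepted/attempted and the **success rate** delivered/accepted, both
counting unique messages rather than retry attempts (a message's final
state, not its history, enters the statistics).

## The simulator

The generator exists to exercise the platform, not to model physiology. Its
defaults describe the cohort the pipeline is designed around:

| parameter | default | meaning |
|---|---|---|
| `weighin_rate_phase1/2` | 2 / 1 days·week⁻¹ | the weighing schedule participants are asked to follow |
| `errant_weight_prob` | 0.05 | fraction of transmissions that are errant |
| `errant_deviation_range` | [0.08, 0.15] | multiplicative deviation of errant weights (sign random) |
| `logging_start_prob` | 0.85 | daily logging probability at enrollment |
| `logging_decay_halflife_days` | 90 | adherence half-life: logging halves by day 90 |
| `kcal_mean`, `kcal_sd` | 1900, 350 | kilocalories per logged day (truncated at 0) |
| `delivery_failure_prob` | 0.006 | per-message carrier refusal probability |
| `withdrawal_hazard_per_week` | 0.002 | constant weekly withdrawal hazard |
| `trueloss_kg_per_week_phase1` | 0.35 kg | latent linear loss during phase I |
| `weight_noise_sd_kg` | 0.4 kg | measurement noise |

The latent weight model is piecewise linear (loss through phase I, plateau
after) plus Gaussian noise. Errant deviations start at 8%, comfortably
above the 3% screening band given 0.4 kg noise on ~98 kg bodies, so the
post-screening rejected fraction is an estimator of `errant_weight_prob` —
a parameter-recovery property the test suite checks to within three
binomial standard errors over a 200-participant cohort.

What the generator deliberately does **not** emulate: close-succession
re-weighs (each weigh-in day carries one transmission, so the simulated
weigh-ins-per-weighing-day statistic is exactly 1; doubling errant days
would bias the recovery check), energy-balance physiology, and any
behavioral response to the incentives themselves — arm effects on behavior
are the trial's scientific question, not the platform's. Passing tests
therefore demonstrate that the plumbing is correct under realistic volumes
and failure modes, not that any behavioral conclusion holds.

`inject_scenario()` adds deterministic failure modes on top — a household
member's ~20%-off block of weights, a cellular coverage gap, a spam wave
failing a Monday's incentive sends, a diet-API cutover with a logging gap —
each paired with the defense it is meant to trip (screening, the weigh-in
frequency gate, retry logic, source tracking).

## Reporting

`ops_summarize()` computes the statistics staff watch: message counts by
weekday and type (tallied on the scheduled *local* date), delivery and
success rates, weight and acceptance totals, weigh-ins per weighing day
(a *weighing day* is a participant-day with ≥1 transmission, accepted or
rejected), diet-day totals, and the automatic/manual processing split.
Percentages are rounded half-up to one decimal, matching how such tables
are conventionally printed. The weigh-ins statistic is computed per
participant then averaged (`weighins_stat = "pooled"` pools all weighing
days instead; the two differ when weighing frequency varies across
participants). Every statistic is checked in the test suite against an
independent brute-force recomputation over raw records.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 30, n_weeks = 30, seed = 7)
res <- run_pipeline(cfg)
res$summary
glance(res$weights)     # screening totals
tidy(res$decisions)     # per-arm award totals
autoplot(res$summary)   # message volume by weekday
```

Problem sizes in the shipped tests were chosen to make every property
measurable at comfortable statistical resolution — the screening oracle
runs 1,000 random streams, parameter recovery uses 200 participants over
26 weeks (~10,000 transmissions, binomial SE ≈ 0.2 percentage points) —
while the whole suite completes in well under a minute.

## Known limitations

* The incentive criteria's numeric defaults (5 logging days, 500 kcal,
  2/1 weigh-ins, 2% band) are configurable placeholders; deployments must
  set them from their protocol.
* The delivery statistics classify a message by its final state, so a
  message that was accepted and later failed counts as not accepted.
* Screening assumes the enrollment baseline is trustworthy; a wrong
  baseline requires a manual reset to recover, which is by design.
* The simulator's behavioral streams are stationary within phase except for
  logging decay; real cohorts show seasonality and re-engagement waves the
  generator does not produce.
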