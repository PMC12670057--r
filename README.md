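# trialops

Operations engine for fully remote weight-management trials that pay
contingency-management incentives: ingestion of cellular-scale and diet-app
data streams, automated anomalous-weight screening, weekly per-arm incentive
adjudication, holiday-aware text-message scheduling with delivery
accounting, operational reporting, and a synthetic-cohort simulator that
exercises the whole pipeline without participant data.

## Who it is for

Teams running (or building software for) remote behavioral trials where a
platform — not a clinic — collects daily weights and dietary logs, decides
weekly whether each participant earned a financial incentive, and tells
them by SMS. The package implements the rules layer between devices and
decisions, with every threshold exposed as configuration and every
statistic checkable against raw records.

## The core rules

**Weight screening.** A transmission is rejected when its relative
deviation from the reference weight exceeds a threshold *t* (default 3%,
strict):

    reject  ⇔  |w − r| / r > t

where the reference *r* chains through the stream: it starts at the
enrollment baseline, each accepted weight becomes the new reference,
rejected weights never do, and a coordinator-verified *reference reset*
replaces it from its date forward. Rejected weights are excluded from all
incentive decisions.

**Weekly adjudication.** For each active participant-week in the
incentivized phases, a diet criterion (≥ d days with ≥ 1 entry and
≥ k kcal; defaults d = 5, k = 500) and a weight criterion — phase I:
≥ 2 accepted weigh-in days and a weekly representative strictly below the
lowest weekly representative to date (a ratchet); phase II: ≥ 1 weigh-in
day and the weekly representative within ±2% of the phase I low — feed a
payout table: full award for all applicable criteria, a partial award in
the combined arm for exactly one, zero for the control arm and phase III.

**Messaging.** Two motivational messages per week (Tue/Fri) for 78 weeks;
one incentive-status message (Mon, shifted to Tue on holidays) per
phase I/II week for incentivized arms; send times uniform in
[08:00, 11:00) in the participant's enrollment time zone. Delivery rate =
accepted/attempted, success rate = delivered/accepted, over unique
messages.

## Worked example

```r
library(trialops)

cfg <- sim_config(n_participants = 30, n_weeks = 30, seed = 7)
res <- run_pipeline(cfg)
res$summary
```

```
Operational summary
===================
  messages_total                   2406
  delivery_rate                    0.99334995843724
  success_rate                     1
  weights_total                    1659
  weights_accepted                 1581
  acceptance_pct                   95.3
  mean_weighins_per_weighing_day   1
  sd_weighins_per_weighing_day     0
  diet_days_total                  2612
  incentives_total                 642
  incentives_auto                  642
  auto_pct                         100
  incentives_manual                0
  manual_pct                       0
  messages by weekday and type:
    Monday       INCENTIVE      568
    Tuesday      INCENTIVE      74
    Tuesday      MOTIVATIONAL   882
    Friday       MOTIVATIONAL   882
```

Reading it: 30 simulated participants over 30 weeks produced 1,659 weight
transmissions of which 95.3% passed the 3% screening chain (the generator
injects 5% errant weights, so the rejected fraction recovers that rate);
2,406 messages were scheduled, 99.3% accepted by the simulated carrier
(failure probability 0.006); 642 participant-weeks were adjudicated, all
automatically. The 74 Tuesday incentive messages are Monday-holiday shifts.

```r
glance(res$weights)     # screening totals as a one-row tibble
tidy(res$decisions)     # per-arm decision and award totals
autoplot(res$summary)   # message volume by weekday and type
```

```
# A tibble: 3 × 5
  arm         n_decisions n_paid total_amount manual_fraction
  <chr>             <int>  <int>        <dbl>           <dbl>
1 COMBINED            270    174         2020               0
2 DIET_ONLY           180     42          840               0
3 WEIGHT_ONLY         192     94         1880               0
```

A thin command-line front end over the same functions lives at
`inst/cli/trialops.R` (`simulate`, `ingest`, `screen`, `incentives`,
`schedule`, `report`, `pipeline` subcommands).

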