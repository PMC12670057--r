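test_that("diet criterion counts qualifying days against the requirement", {
  cfg <- incentive_config()
  expect_true(evaluate_diet_criterion(make_diet_week(d = 5), cfg))
  # a 300-kcal day falls under the 500-kcal floor and does not count
  week <- make_diet_week(d = 5)
  week$total_kcal[3] <- 300
  expect_false(evaluate_diet_criterion(week, cfg))
  expect_false(evaluate_diet_criterion(week[0, ], cfg))
  expect_false(evaluate_diet_criterion(NULL, cfg))
  # zero-entry days never qualify even with kcal recorded upstream
  week <- make_diet_week(d = 5)
  week$n_entries[1] <- 0L
  expect_false(evaluate_diet_criterion(week, cfg))
  # requirement is configurable
  expect_true(evaluate_diet_criterion(make_diet_week(d = 3),
                                      incentive_config(diet_days_required = 3)))
})

test_that("phase I weight criterion is a ratchet on the weekly representative", {
  cfg <- incentive_config()
  # week 2 at 99.4 undercuts the prior representative 100.0
  expect_true(evaluate_weight_criterion_phase1(c(99.5, 99.3), c(100.5, 100.0), cfg))
  # no change fails: strict decrease required
  expect_false(evaluate_weight_criterion_phase1(c(100.0, 100.0), c(100.5, 100.0), cfg))
  # enough loss but only one weigh-in day when two are required
  expect_false(evaluate_weight_criterion_phase1(99.0, c(100.5, 100.0), cfg))
  # ratchet: must undercut the *lowest* prior week, not just the last
  expect_false(evaluate_weight_criterion_phase1(c(99.5, 99.5), c(99.0, 101.0), cfg))
  expect_true(evaluate_weight_criterion_phase1(c(98.5, 98.9), c(99.0, 101.0), cfg))
  # alternative rule: decrease versus the immediately prior week
  alt <- incentive_config(phase1_rule = "prior_week")
  expect_true(evaluate_weight_criterion_phase1(c(99.5, 99.5), c(99.0, 101.0), alt))
})

test_that("phase II maintenance band is symmetric around the anchor", {
  cfg <- incentive_config()
  # anchor 90: band [88.2, 91.8]
  expect_true(evaluate_weight_criterion_phase2(91.0, 90, cfg))
  expect_false(evaluate_weight_criterion_phase2(92.0, 90, cfg))
  expect_true(evaluate_weight_criterion_phase2(88.2, 90, cfg))
  expect_false(evaluate_weight_criterion_phase2(88.1, 90, cfg))
  expect_false(evaluate_weight_criterion_phase2(numeric(), 90, cfg))
  # missing anchor defers adjudication
  expect_true(is.na(evaluate_weight_criterion_phase2(90, NA, cfg)))
})

test_that("weekly decision matches the arm-by-phase-by-criteria truth table", {
  cfg <- incentive_config(amount_full = 20, amount_partial = 10)
  cases <- expand.grid(
    arm = c("COMBINED", "DIET_ONLY", "WEIGHT_ONLY", "CONTROL"),
    week = c(3L, 30L, 60L),  # one week in each phase
    diet = c(TRUE, FALSE),
    weight = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expected_amount <- function(arm, week, diet, weight) {
    if (arm == "CONTROL" || week > 52) return(0)
    switch(arm,
      DIET_ONLY = if (diet) 20 else 0,
      WEIGHT_ONLY = if (weight) 20 else 0,
      COMBINED = c(0, 10, 20)[diet + weight + 1]
    )
  }
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    d <- decide_week("P001", cs$week, cs$arm, cs$diet, cs$weight, cfg)
    expect_equal(d$amount, expected_amount(cs$arm, cs$week, cs$diet, cs$weight),
                 info = paste(cs$arm, cs$week, cs$diet, cs$weight))
    expect_equal(d$processing_mode, "AUTO")
    # criteria inapplicable to the arm are recorded as NA
    if (cs$arm == "DIET_ONLY") expect_true(is.na(d$weight_criterion_met))
    if (cs$arm == "WEIGHT_ONLY") expect_true(is.na(d$diet_criterion_met))
  }
})

test_that("meeting more criteria never lowers the combined-arm amount", {
  cfg <- incentive_config()
  a00 <- decide_week("P", 3, "COMBINED", FALSE, FALSE, cfg)$amount
  a10 <- decide_week("P", 3, "COMBINED", TRUE, FALSE, cfg)$amount
  a01 <- decide_week("P", 3, "COMBINED", FALSE, TRUE, cfg)$amount
  a11 <- decide_week("P", 3, "COMBINED", TRUE, TRUE, cfg)$amount
  expect_true(a00 <= a10 && a10 <= a11)
  expect_true(a00 <= a01 && a01 <= a11)
})

test_that("a deferred criterion routes the decision to manual review", {
  d <- decide_week("P001", 30, "WEIGHT_ONLY", NA, NA)
  expect_equal(d$processing_mode, "MANUAL")
  expect_equal(d$amount, 0)
})

test_that("manual adjudication documents, overrides, and preserves the audit trail", {
  d <- decide_week("P001", 3, "COMBINED", FALSE, FALSE)
  m <- mark_manual(d, "verified weight by phone; award full", amount = 20)
  expect_equal(m$processing_mode, "MANUAL")
  expect_equal(m$amount, 20)
  expect_equal(m$note, "verified weight by phone; award full")
  expect_length(attr(m, "audit"), 2)
  expect_equal(attr(m, "audit")[[1]]$amount, 0)  # original preserved
  expect_error(mark_manual(d, ""), class = "trialops_validation_error")
  ctrl <- decide_week("P002", 3, "CONTROL")
  expect_error(mark_manual(ctrl, "note"), class = "trialops_validation_error")
})

test_that("batch adjudication skips control and withdrawn participants and is deterministic", {
  roster <- make_roster(3, arms = c("COMBINED", "WEIGHT_ONLY", "CONTROL"))
  roster$withdrawal_date[2] <- as.Date("2021-01-06")  # mid first week
  weights <- dplyr::bind_rows(
    make_weights("P001", c(0, 3, 7, 10), c(100, 99.8, 99.0, 98.8)),
    make_weights("P002", c(0, 3, 7, 10), c(100, 99.8, 99.0, 98.8))
  )
  screened <- screen_weights(weights, roster)
  diet <- make_diet_week("P001", d = 7)
  batch <- run_weekly_batch(roster, screened, diet, week_ending = "2021-01-10")
  # control arm never decided; withdrawn participant produces no decision
  expect_equal(batch$decisions$participant_id, "P001")
  expect_equal(batch$decisions$week_index, 1L)
  rerun <- run_weekly_batch(roster, screened, diet, week_ending = "2021-01-10")
  expect_identical(as.data.frame(batch$decisions), as.data.frame(rerun$decisions))
  # conservation: queue total equals the sum of decision amounts
  expect_equal(sum(batch$queue$amount), sum(batch$decisions$amount))
})

test_that("rejected weights never influence a decision", {
  roster <- make_roster(1, arms = "WEIGHT_ONLY")
  base <- dplyr::bind_rows(
    make_weights("P001", c(0, 3), c(100.0, 99.9)),
    make_weights("P001", c(7, 10), c(99.0, 98.9))
  )
  # inject a burst of wildly errant weights into week 2
  junk <- make_weights("P001", c(8.1, 8.2, 9.3), c(130, 131, 65))
  diet <- make_diet_week("P001", d = 0)[0, ]
  dec_clean <- adjudicate_weeks(roster, screen_weights(base, roster), diet,
                                weeks = 1:2)
  dec_junk <- adjudicate_weeks(
    roster,
    screen_weights(dplyr::arrange(dplyr::bind_rows(base, junk), timestamp_utc),
                   roster),
    diet, weeks = 1:2
  )
  expect_identical(
    as.data.frame(dec_clean[c("week_index", "weight_criterion_met", "amount")]),
    as.data.frame(dec_junk[c("week_index", "weight_criterion_met", "amount")])
  )
})

test_that("phase II anchors to the lowest phase I weekly representative", {
  roster <- make_roster(1, arms = "WEIGHT_ONLY")
  # a weekly weigh-in drifting down 0.3 kg/week through phase I (each step
  # well inside the screening band) to a 92.5 kg floor at week 26
  w1 <- make_weights("P001", 7 * (0:25), 100 - 0.3 * (0:25))
  w_in <- make_weights("P001", 26 * 7 + c(0, 3), c(93.0, 93.2))   # week 27, within 2%
  w_out <- make_weights("P001", 27 * 7 + c(0, 3), c(95.0, 95.2))  # week 28, outside
  screened <- screen_weights(
    dplyr::arrange(dplyr::bind_rows(w1, w_in, w_out), timestamp_utc),
    roster
  )
  expect_true(all(screened$status == "ACCEPTED"))
  dec <- adjudicate_weeks(roster, screened, make_diet_week(d = 0)[0, ],
                          weeks = c(27, 28))
  expect_equal(dec$weight_criterion_met, c(TRUE, FALSE))
  expect_equal(dec$amount > 0, c(TRUE, FALSE))
})

test_that("a participant with no phase I weights defers phase II adjudication", {
  roster <- make_roster(1, arms = "WEIGHT_ONLY")
  w <- make_weights("P001", 26 * 7 + c(0, 3), c(93.0, 93.2))
  dec <- adjudicate_weeks(roster, screen_weights(w, roster),
                          make_diet_week(d = 0)[0, ], weeks = 27)
  expect_equal(dec$processing_mode, "MANUAL")
  expect_equal(dec$amount, 0)
})
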