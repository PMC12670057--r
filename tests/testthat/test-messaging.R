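test_that("weekly cadence: two motivational always, one incentive in phase I/II", {
  roster <- make_roster(4)  # one arm of each
  # a week with no Monday holiday
  msgs <- schedule_week(roster, 2, seed = 5)
  counts <- dplyr::count(msgs, participant_id, mtype)
  for (pid in roster$participant_id) {
    expect_equal(counts$n[counts$participant_id == pid &
                            counts$mtype == "MOTIVATIONAL"], 2L)
  }
  # control receives no incentive message; incentivized arms exactly one
  inc <- counts[counts$mtype == "INCENTIVE", ]
  expect_setequal(inc$participant_id, c("P001", "P002", "P003"))
  expect_true(all(inc$n == 1L))
  # phase III weeks carry no incentive messages for anyone
  m3 <- schedule_week(roster, 60, seed = 5)
  expect_equal(sum(m3$mtype == "INCENTIVE"), 0)
  expect_equal(nrow(m3), 8)  # 4 participants x 2 motivational
})

test_that("motivational messages fall on Tuesday and Friday, incentives on Monday", {
  roster <- make_roster(2, arms = c("COMBINED", "CONTROL"))
  # weeks whose Mondays (Jan 11, Jan 25, Feb 1 2021) are not holidays
  msgs <- schedule_messages(roster, weeks = c(2, 4, 5), seed = 5)
  wd <- lubridate::wday(msgs$scheduled_date, week_start = 1)
  expect_true(all(wd[msgs$mtype == "MOTIVATIONAL"] %in% c(2, 5)))
  expect_true(all(wd[msgs$mtype == "INCENTIVE"] == 1))
})

test_that("a Monday holiday shifts the incentive message to Tuesday", {
  roster <- make_roster(1, arms = "COMBINED")  # enrolled Mon 2021-01-04
  # week 22 starts Monday 2021-05-31, Memorial Day
  msgs <- schedule_week(roster, 22, seed = 5)
  inc <- msgs[msgs$mtype == "INCENTIVE", ]
  expect_equal(inc$scheduled_date, as.Date("2021-06-01"))
  expect_equal(lubridate::wday(inc$scheduled_date, week_start = 1), 2)
  # motivational messages do not shift
  expect_equal(sort(msgs$scheduled_date[msgs$mtype == "MOTIVATIONAL"]),
               as.Date(c("2021-06-01", "2021-06-04")))
})

test_that("send times land in the 8-11 am local window, across DST changes", {
  roster <- make_roster(2, tz = c("America/New_York", "America/Chicago"))
  # weeks spanning the March 2021 spring-forward and November fall-back
  msgs <- schedule_messages(roster, weeks = c(9:11, 44:45), seed = 11)
  hrs <- as.integer(substr(msgs$scheduled_local, 12, 13))
  expect_true(all(hrs >= 8 & hrs < 11))
  # and the UTC instants convert back into the same local window
  local_back <- purrr::map2_chr(msgs$scheduled_utc, msgs$timezone,
                                ~format(lubridate::with_tz(.x, .y), "%H"))
  expect_true(all(as.integer(local_back) >= 8 & as.integer(local_back) < 11))
  # DST shifts the UTC offset between early March and late March
  utc_h <- lubridate::hour(msgs$scheduled_utc)
  expect_true(length(unique(utc_h - hrs)) > 1)
})

test_that("scheduling is deterministic; seeds vary times but never dates or counts", {
  roster <- make_roster(3)
  a <- schedule_messages(roster, weeks = 1:4, seed = 1)
  b <- schedule_messages(roster, weeks = 1:4, seed = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- schedule_messages(roster, weeks = 1:4, seed = 2)
  expect_identical(a$message_id, c$message_id)
  expect_identical(a$scheduled_date, c$scheduled_date)
  expect_false(identical(a$scheduled_local, c$scheduled_local))
})

test_that("incentive bodies are digit- and currency-free and deterministic", {
  cfg <- incentive_config()
  for (arm in c("COMBINED", "DIET_ONLY", "WEIGHT_ONLY")) {
    for (d in c(TRUE, FALSE)) for (w in c(TRUE, FALSE)) {
      dec <- decide_week("P001", 10, arm, d, w, cfg)
      body <- compose_incentive_body(dec)
      expect_false(grepl("[0-9$]", body), info = paste(arm, d, w))
      expect_identical(body, compose_incentive_body(dec))
    }
  }
  # earned and unearned variants differ
  expect_false(identical(
    compose_incentive_body(decide_week("P1", 2, "DIET_ONLY", TRUE, NA, cfg)),
    compose_incentive_body(decide_week("P1", 2, "DIET_ONLY", FALSE, NA, cfg))
  ))
  expect_error(compose_incentive_body(decide_week("P1", 2, "CONTROL")),
               class = "trialops_validation_error")
})

test_that("the delivery state machine refuses illegal transitions", {
  roster <- make_roster(1)
  m <- schedule_week(roster, 1, seed = 3)[1, ]
  expect_equal(m$status, "QUEUED")
  m1 <- record_receipt(m, "accepted")
  expect_equal(m1$status, "ACCEPTED_BY_CARRIER")
  m2 <- record_receipt(m1, "delivered")
  expect_equal(m2$status, "DELIVERED")
  expect_error(record_receipt(m2, "accepted"), class = "trialops_state_error")
  expect_error(record_receipt(m2, "delivered"), class = "trialops_state_error")
  expect_error(record_receipt(m, "delivered"), class = "trialops_state_error")
  f <- record_receipt(m, "failed", reason = "SPAM_FLAGGED")
  expect_equal(f$status, "FAILED")
  expect_equal(f$failure_reason, "SPAM_FLAGGED")
  expect_error(record_receipt(m, "failed"), class = "trialops_validation_error")
})

test_that("random event sequences never reach an illegal state", {
  roster <- make_roster(1)
  base <- schedule_week(roster, 1, seed = 3)[1, ]
  set.seed(77)
  legal <- list(
    QUEUED = c("ACCEPTED_BY_CARRIER", "FAILED"),
    ACCEPTED_BY_CARRIER = c("DELIVERED", "FAILED")
  )
  for (rep in 1:200) {
    m <- base
    for (step in 1:5) {
      ev <- sample(c("accepted", "delivered", "failed"), 1)
      prev <- m$status
      res <- tryCatch(
        record_receipt(m, ev, reason = "OTHER"),
        error = function(e) NULL
      )
      if (!is.null(res)) {
        expect_true(res$status %in% c(legal[[prev]], prev))
        m <- res
      }
    }
    expect_true(m$status %in% c("QUEUED", "ACCEPTED_BY_CARRIER", "DELIVERED",
                                "FAILED"))
  }
})

test_that("retry requeues transient failures but respects opt-outs and caps", {
  roster <- make_roster(1)
  msgs <- schedule_week(roster, 1, seed = 3)
  msgs$status <- "FAILED"
  msgs$failure_reason <- c("SPAM_FLAGGED", "OPTED_OUT", "UNREACHABLE")
  msgs$attempt <- c(1L, 1L, 3L)
  out <- retry_failed(msgs, max_attempts = 3)
  expect_equal(out$status, c("QUEUED", "FAILED", "FAILED"))
  expect_equal(out$attempt, c(2L, 1L, 3L))
  ll <- msgs
  ll$failure_reason <- "LANDLINE"
  expect_true(all(retry_failed(ll)$status == "FAILED"))
})

test_that("delivery statistics follow the accepted/attempted definitions", {
  mk <- function(n, status) tibble::tibble(
    message_id = sprintf("%s-%d", status, seq_len(n)),
    status = status, attempt = 1L
  )
  msgs <- dplyr::bind_rows(mk(96, "DELIVERED"), mk(2, "ACCEPTED_BY_CARRIER"),
                           mk(2, "FAILED"))
  ds <- compute_delivery_stats(msgs)
  expect_equal(ds$attempted, 100L)
  expect_equal(ds$accepted, 98L)
  expect_equal(ds$delivered, 96L)
  expect_equal(ds$delivery_rate, 0.98)
  expect_equal(ds$success_rate, 96 / 98)
  # retried messages count once, at their final state
  retried <- dplyr::bind_rows(
    tibble::tibble(message_id = "m1", status = "FAILED", attempt = 1L),
    tibble::tibble(message_id = "m1", status = "DELIVERED", attempt = 2L)
  )
  ds2 <- compute_delivery_stats(retried)
  expect_equal(ds2$attempted, 1L)
  expect_equal(ds2$delivered, 1L)
  # empty log yields zero rates, not NaN
  empty <- compute_delivery_stats(msgs[0, ])
  expect_equal(empty$delivery_rate, 0)
  expect_equal(empty$success_rate, 0)
})
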