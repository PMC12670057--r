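#' Schedule one study week of text messages
#'
#' Every participant receives two motivational messages per week (Tuesday
#' and Friday) for all 78 weeks. Participants in incentivized arms
#' additionally receive one incentive-status message in each phase I/II
#' week, sent on Monday -- or the following day when Monday is a holiday.
#' Send times are drawn uniformly between 08:00 and 11:00 in the
#' participant's enrollment time zone (travel never re-anchors the zone),
#' reproducibly under the seed: changing the seed changes only the
#' within-window times, never the dates or counts.
#'
#' @param roster a validated roster.
#' @param week_index study week (1..78).
#' @param holidays `Date` vector of holidays (default: US federal
#'   holidays covering the scheduled years).
#' @param seed integer seed for the send-time draw.
#' @return a message tibble: `message_id`, `participant_id`, `mtype`,
#'   `week_index`, `scheduled_date`, `scheduled_local` (local wall-clock
#'   datetime, character), `timezone`, `scheduled_utc`, `status`
#'   (`QUEUED`), `failure_reason`, `attempt`, `body`.
#' @export
schedule_week <- function(roster, week_index, holidays = NULL, seed = 1L) {
  schedule_messages(roster, weeks = week_index, holidays = holidays, seed = seed)
}

#' Schedule messages for many weeks
#'
#' Vectorised form of [schedule_week()] over a span of study weeks.
#'
#' @inheritParams schedule_week
#' @param weeks integer vector of study weeks.
#' @return a message tibble (see [schedule_week()]).
#' @export
schedule_messages <- function(roster, weeks = 1:78, holidays = NULL, seed = 1L) {
  roster <- validate_roster(roster)
  weeks <- sort(unique(as.integer(weeks)))
  stopifnot(all(weeks >= 1 & weeks <= 78))
  if (is.null(holidays)) {
    yrs <- unique(lubridate::year(c(roster$enrollment_date,
                                    roster$enrollment_date + 78 * 7)))
    holidays <- us_federal_holidays(seq(min(yrs), max(yrs) + 1))
  }
  holidays <- as.Date(holidays)

  # one row per participant-week-message with its calendar date
  grid <- tidyr::crossing(
    roster |> select("participant_id", "arm", "timezone", "enrollment_date"),
    week_index = weeks
  ) |>
    mutate(
      phase = week_phase(.data$week_index),
      week_start = .data$enrollment_date + 7L * (.data$week_index - 1L)
    )

  day_in_week <- function(week_start, wday_target) {
    # date of the given weekday (1 = Mon .. 7 = Sun) within the 7-day window
    offset <- (wday_target - lubridate::wday(week_start, week_start = 1)) %% 7
    week_start + offset
  }

  motivational <- grid |>
    tidyr::crossing(tibble(.wday = c(2L, 5L))) |>  # Tuesday, Friday
    mutate(
      mtype = "MOTIVATIONAL",
      scheduled_date = day_in_week(.data$week_start, .data$.wday)
    ) |>
    select(-".wday")

  incentive <- grid |>
    filter(.data$arm %in% INCENTIVIZED_ARMS, .data$phase %in% c("I", "II")) |>
    mutate(
      mtype = "INCENTIVE",
      .monday = day_in_week(.data$week_start, 1L),
      scheduled_date = if_else(.data$.monday %in% holidays,
                               .data$.monday + 1L, .data$.monday)
    ) |>
    select(-".monday")

  out <- bind_rows(incentive, motivational) |>
    arrange(.data$participant_id, .data$week_index, .data$scheduled_date,
            .data$mtype) |>
    mutate(
      message_id = sprintf("%s-w%02d-%s-%s", .data$participant_id,
                           .data$week_index, substr(.data$mtype, 1, 3),
                           format(.data$scheduled_date, "%Y%m%d"))
    )

  # send times: uniform in [08:00, 11:00) local, reproducible under seed
  secs <- withr::with_seed(seed, runif(nrow(out), 0, 3 * 3600))
  out <- out |>
    mutate(
      .time = hms_chr(8 * 3600 + secs),
      scheduled_local = paste(format(.data$scheduled_date, "%Y-%m-%d"), .data$.time),
      scheduled_utc = local_to_utc(.data$scheduled_local, .data$timezone),
      status = "QUEUED",
      failure_reason = NA_character_,
      attempt = 1L,
      body = ""
    ) |>
    select("message_id", "participant_id", "mtype", "week_index",
           "scheduled_date", "scheduled_local", "timezone", "scheduled_utc",
           "status", "failure_reason", "attempt", "body")
  class(out) <- c("message_log", class(out))
  out
}

hms_chr <- function(seconds) {
  seconds <- floor(seconds)
  sprintf("%02d:%02d:%02d", seconds %/% 3600, (seconds %% 3600) %/% 60,
          seconds %% 60)
}

# Convert local wall-clock strings to UTC instants across mixed zones.
local_to_utc <- function(local_chr, tz) {
  tz <- rep_len(tz, length(local_chr))
  out <- lubridate::as_datetime(rep(NA_real_, length(local_chr)), tz = "UTC")
  for (z in unique(tz)) {
    idx <- tz == z
    out[idx] <- lubridate::with_tz(
      lubridate::ymd_hms(local_chr[idx], tz = z), "UTC"
    )
  }
  out
}

#' Compose the body of an incentive-status message
#'
#' Bodies are fixed templates keyed by arm and criteria pattern, never
#' personalized, and deliberately free of digits and currency symbols:
#' carriers flag messages with dollar amounts or numerals as likely spam,
#' and removing them restores delivery.
#'
#' @param decision a one-row incentive decision (phase I/II, incentivized
#'   arm).
#' @return a single string.
#' @export
compose_incentive_body <- function(decision) {
  stopifnot(nrow(decision) == 1)
  if (decision$arm == "CONTROL") {
    abort("Control-arm participants receive no incentive messages.",
          class = "trialops_validation_error")
  }
  if (decision$phase == "III") {
    abort("Phase III weeks are non-incentivized.",
          class = "trialops_validation_error")
  }
  d <- isTRUE(decision$diet_criterion_met)
  w <- isTRUE(decision$weight_criterion_met)
  body <- switch(decision$arm,
    COMBINED = if (d && w) {
      "Great work this week. You met both your food logging and your weight goal, and your full reward is on its way."
    } else if (d) {
      "Nice job logging your food this week. You met one of your two goals, so a partial reward is on its way. Keep working toward your weight goal."
    } else if (w) {
      "Nice progress on your weight this week. You met one of your two goals, so a partial reward is on its way. Keep up your food logging too."
    } else {
      "You did not meet your goals this week, so no reward was earned. A fresh week starts now. You can do this."
    },
    DIET_ONLY = if (d) {
      "Great work logging your food this week. You met your goal and your reward is on its way."
    } else {
      "You did not meet your food logging goal this week, so no reward was earned. A fresh week starts now."
    },
    WEIGHT_ONLY = if (w) {
      "Great work on your weight this week. You met your goal and your reward is on its way."
    } else {
      "You did not meet your weight goal this week, so no reward was earned. A fresh week starts now."
    }
  )
  body
}

#' Record a carrier event against a message
#'
#' Delivery accounting is a small state machine: a queued message is first
#' accepted (or refused) by the downstream carrier, and an accepted
#' message later yields a positive delivery receipt or a failure. Illegal
#' transitions -- any event after `DELIVERED`, or a receipt for a message
#' never accepted -- are refused.
#'
#' @param message a one-row message tibble.
#' @param event one of `"accepted"`, `"delivered"`, `"failed"`.
#' @param reason failure reason, required when `event = "failed"`: one of
#'   `SPAM_FLAGGED`, `OPTED_OUT`, `UNREACHABLE`, `LANDLINE`, `OTHER`.
#' @return the updated one-row message tibble.
#' @export
record_receipt <- function(message, event = c("accepted", "delivered", "failed"),
                           reason = NULL) {
  event <- match.arg(event)
  stopifnot(nrow(message) == 1)
  from <- message$status
  if (from == "DELIVERED") {
    abort("Message already delivered; no further events are legal.",
          class = "trialops_state_error")
  }
  if (from == "FAILED") {
    abort("Failed message must be re-queued (see retry_failed) before new events.",
          class = "trialops_state_error")
  }
  if (event == "accepted") {
    if (from != "QUEUED") {
      abort("Only queued messages can be accepted by the carrier.",
            class = "trialops_state_error")
    }
    message$status <- "ACCEPTED_BY_CARRIER"
  } else if (event == "delivered") {
    if (from != "ACCEPTED_BY_CARRIER") {
      abort("Delivery receipts are only legal after carrier acceptance.",
            class = "trialops_state_error")
    }
    message$status <- "DELIVERED"
  } else {
    if (is.null(reason) || !reason %in% FAILURE_REASONS) {
      abort(paste0("Failure requires a reason in: ",
                   paste(FAILURE_REASONS, collapse = ", ")),
            class = "trialops_validation_error")
    }
    message$status <- "FAILED"
    message$failure_reason <- reason
  }
  message
}

#' Apply a stream of carrier receipts to a message log
#'
#' @param messages a message tibble.
#' @param receipts tibble with `message_id`, `event` (`accepted` /
#'   `delivered` / `failed`), optional `reason`, applied in row order.
#' @return the updated message tibble.
#' @export
apply_receipts <- function(messages, receipts) {
  if (!"reason" %in% names(receipts)) receipts$reason <- NA_character_
  idx <- match(receipts$message_id, messages$message_id)
  if (any(is.na(idx))) {
    warn(sprintf("%d receipt(s) reference unknown messages; ignored.",
                 sum(is.na(idx))))
  }
  # fold the events over plain vectors; same transition rules as
  # record_receipt, enforced per message
  status <- messages$status
  reason <- messages$failure_reason
  keep <- which(!is.na(idx))
  for (r in keep) {
    i <- idx[r]
    from <- status[i]
    ev <- receipts$event[r]
    if (from == "QUEUED" && ev == "accepted") {
      status[i] <- "ACCEPTED_BY_CARRIER"
    } else if (from == "ACCEPTED_BY_CARRIER" && ev == "delivered") {
      status[i] <- "DELIVERED"
    } else if (ev == "failed" && from %in% c("QUEUED", "ACCEPTED_BY_CARRIER")) {
      rs <- receipts$reason[r]
      if (is.na(rs) || !rs %in% FAILURE_REASONS) {
        abort(paste0("Failure requires a reason in: ",
                     paste(FAILURE_REASONS, collapse = ", ")),
              class = "trialops_validation_error")
      }
      status[i] <- "FAILED"
      reason[i] <- rs
    } else {
      abort(sprintf("Illegal receipt event '%s' for message %s in state %s.",
                    ev, messages$message_id[i], from),
            class = "trialops_state_error")
    }
  }
  messages$status <- status
  messages$failure_reason <- reason
  messages
}

#' Re-queue failed messages for another attempt
#'
#' Failed messages are retried automatically up to `max_attempts`, except
#' when retrying would be wrong: a participant who opted out stays opted
#' out, and a landline will never receive a text.
#'
#' @param messages a message tibble.
#' @param max_attempts maximum total attempts per message (default 3).
#' @return the message tibble with eligible failures re-queued
#'   (`status = "QUEUED"`, `attempt` incremented, reason cleared).
#' @export
retry_failed <- function(messages, max_attempts = 3) {
  eligible <- messages$status == "FAILED" &
    messages$attempt < max_attempts &
    !messages$failure_reason %in% c("OPTED_OUT", "LANDLINE")
  messages |>
    mutate(
      attempt = if_else(eligible, .data$attempt + 1L, .data$attempt),
      status = if_else(eligible, "QUEUED", .data$status),
      failure_reason = if_else(eligible, NA_character_, .data$failure_reason)
    )
}

#' Delivery statistics for a message log
#'
#' The delivery rate is the number of messages accepted by the downstream
#' carrier divided by the number attempted; the success rate is the
#' proportion of accepted messages that received a positive delivery
#' receipt. Both count unique messages, not retry attempts, and both are
#' zero when their denominator is zero.
#'
#' @param messages a message tibble.
#' @return a one-row tibble: `attempted`, `accepted`, `delivered`,
#'   `delivery_rate`, `success_rate`.
#' @export
#' @examples
#' # 126,082 of 126,283 attempted messages accepted by the carrier
#' m <- tibble::tibble(
#'   message_id = as.character(1:10), status = rep(c("DELIVERED", "FAILED"), c(9, 1)),
#'   attempt = 1L
#' )
#' compute_delivery_stats(m)
compute_delivery_stats <- function(messages) {
  if (nrow(messages) == 0) {
    return(tibble(attempted = 0L, accepted = 0L, delivered = 0L,
                  delivery_rate = 0, success_rate = 0))
  }
  final <- if (anyDuplicated(messages$message_id)) {
    messages |>
      arrange(.data$message_id, dplyr::desc(.data$attempt)) |>
      distinct(.data$message_id, .keep_all = TRUE)
  } else {
    messages
  }
  attempted <- nrow(final)
  accepted <- sum(final$status %in% c("ACCEPTED_BY_CARRIER", "DELIVERED"))
  delivered <- sum(final$status == "DELIVERED")
  tibble(
    attempted = attempted,
    accepted = accepted,
    delivered = delivered,
    delivery_rate = if (attempted > 0) accepted / attempted else 0,
    success_rate = if (accepted > 0) delivered / accepted else 0
  )
}

#' Write a message log CSV
#' @param messages a message tibble.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_message_log <- function(messages, file) {
  readr::write_csv(as_tibble(messages), file, progress = FALSE)
  invisible(file)
}
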