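# Shared fixtures, built in code.

make_roster <- function(n = 4,
                        arms = rep_len(c("COMBINED", "DIET_ONLY", "WEIGHT_ONLY",
                                         "CONTROL"), n),
                        enrollment = as.Date("2021-01-04"),
                        tz = "America/New_York",
                        baseline = 100) {
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    site = rep_len(c("WI", "NC"), n),
    arm = arms,
    timezone = rep_len(tz, n),
    baseline_weight_kg = rep_len(baseline, n),
    enrollment_date = rep_len(as.Date(enrollment), n),
    scale_device_id = sprintf("DEV%03d", seq_len(n)),
    withdrawal_date = as.Date(NA)
  )
}

# UTC timestamps n days after an anchor, at a fixed morning hour
ts_days <- function(days, anchor = as.Date("2021-01-04"), hour = 12) {
  lubridate::as_datetime(anchor, tz = "UTC") + lubridate::dhours(hour) +
    lubridate::ddays(days)
}

make_weights <- function(pid, days, weights, tz = "UTC",
                         anchor = as.Date("2021-01-04")) {
  tibble::tibble(
    participant_id = pid,
    timestamp_utc = ts_days(days, anchor),
    weight_kg = weights,
    timezone = tz
  )
}

# Independent re-walk of the chained screening rule, written as a plain
# accumulator so it shares no code with screen_stream().
brute_force_screen <- function(weights_kg, timestamps, baseline, threshold = 0.03,
                               reset_times = NULL, reset_weights = NULL) {
  ref <- baseline
  out <- character(length(weights_kg))
  for (i in seq_along(weights_kg)) {
    if (!is.null(reset_times)) {
      due <- which(reset_times <= timestamps[i])
      if (length(due)) {
        ref <- reset_weights[max(due)]
        reset_times <- reset_times[-due]
        reset_weights <- reset_weights[-due]
      }
    }
    rejected <- abs(weights_kg[i] - ref) > threshold * ref
    out[i] <- if (rejected) "REJECTED" else "ACCEPTED"
    if (!rejected) ref <- weights_kg[i]
  }
  out
}

# A fully-adherent diet week: d qualifying days
make_diet_week <- function(pid = "P001", start = as.Date("2021-01-04"),
                           d = 5, kcal = 1800, entries = 3L) {
  tibble::tibble(
    participant_id = pid,
    date = start + seq_len(d) - 1,
    total_kcal = rep_len(kcal, d),
    n_entries = rep_len(as.integer(entries), d),
    source = "FITBIT_DIRECT"
  )
}
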