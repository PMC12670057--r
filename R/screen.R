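#' Screen one weight against a reference
#'
#' A transmitted weight is rejected when its relative deviation from the
#' reference weight (the most recent accepted weight, or a manually
#' verified reset) exceeds the threshold. The rule is strict -- a deviation
#' of exactly the threshold is accepted -- and symmetric in direction:
#' gains and losses are screened identically, with the reference as the
#' denominator.
#'
#' @param weight_kg numeric vector of candidate weights (kg).
#' @param reference_kg numeric vector of reference weights (kg), recycled.
#' @param threshold maximum accepted relative deviation (default 0.03,
#'   i.e. weights deviating by more than 3% are rejected).
#' @return character vector of `"ACCEPTED"` / `"REJECTED"`.
#' @export
#' @examples
#' screen_weight(c(103.2, 103.0, 97.1), 100)
screen_weight <- function(weight_kg, reference_kg, threshold = 0.03) {
  if (any(is.na(reference_kg)) || any(reference_kg <= 0)) {
    abort("reference_kg must be positive.", class = "trialops_invalid_reference")
  }
  dev <- abs(weight_kg - reference_kg) / reference_kg
  if_else(dev > threshold, "REJECTED", "ACCEPTED")
}

#' Screen a participant's time-ordered weight stream
#'
#' Walks the chained screening rule over one participant's transmissions:
#' the first reference is the baseline weight, each accepted weight becomes
#' the new reference, and rejected weights never update it. A manual
#' reference reset -- a coordinator-verified weight, recorded when e.g. a
#' long scale hiatus put the participant legitimately outside the band --
#' replaces the reference from its date forward and is itself exempt from
#' screening.
#'
#' @param weights tibble for a single participant with columns
#'   `timestamp_utc` (POSIXct) and `weight_kg`, sorted by timestamp.
#'   Additional columns are carried through.
#' @param baseline_kg the participant's baseline weight (kg), seeding the
#'   reference chain.
#' @param resets optional tibble of manual resets with columns `date`
#'   (a reset applies to all records from that calendar date, UTC, onward)
#'   and `verified_weight_kg`; an `operator_note` column is carried into
#'   the record's `reason`.
#' @param threshold relative-deviation threshold (default 0.03).
#' @return the input tibble with `status`, `reference_weight_kg` (the
#'   reference each record was screened against), and `reason` columns.
#' @export
screen_stream <- function(weights, baseline_kg, resets = NULL, threshold = 0.03) {
  if (is.na(baseline_kg) || baseline_kg <= 0) {
    abort("baseline_kg must be positive.", class = "trialops_invalid_reference")
  }
  n <- nrow(weights)
  if (n == 0) {
    return(weights |> mutate(
      status = character(), reference_weight_kg = numeric(), reason = character()
    ))
  }
  if (is.unsorted(weights$timestamp_utc)) {
    abort("Weight stream must be sorted by timestamp.",
          class = "trialops_ordering_error")
  }
  if (!is.null(resets) && nrow(resets) > 0) {
    if (any(resets$verified_weight_kg <= 0)) {
      abort("Reset verified_weight_kg must be positive.",
            class = "trialops_validation_error")
    }
    resets <- resets |> arrange(.data$date)
    reset_ts <- lubridate::as_datetime(as.Date(resets$date), tz = "UTC")
  } else {
    resets <- NULL
  }
  status <- character(n)
  ref_used <- numeric(n)
  reason <- rep(NA_character_, n)
  ref <- baseline_kg
  next_reset <- 1L
  for (i in seq_len(n)) {
    while (!is.null(resets) && next_reset <= nrow(resets) &&
           reset_ts[next_reset] <= weights$timestamp_utc[i]) {
      ref <- resets$verified_weight_kg[next_reset]
      next_reset <- next_reset + 1L
    }
    ref_used[i] <- ref
    dev <- abs(weights$weight_kg[i] - ref) / ref
    if (dev > threshold) {
      status[i] <- "REJECTED"
      reason[i] <- sprintf("deviation %.1f%% from reference %.1f kg exceeds %.0f%%",
                           100 * dev, ref, 100 * threshold)
    } else {
      status[i] <- "ACCEPTED"
      ref <- weights$weight_kg[i]
    }
  }
  weights |> mutate(status = status, reference_weight_kg = ref_used, reason = reason)
}

#' Screen all participants' weights
#'
#' Applies [screen_stream()] per participant, seeding each chain from the
#' roster baseline weight.
#'
#' @param weights bound weight records (see [bind_devices()]) with
#'   `participant_id`, `timestamp_utc`, `weight_kg`; unbound records
#'   (NA participant) are dropped with a warning.
#' @param roster a validated roster.
#' @param resets optional tibble of manual resets with `participant_id`,
#'   `date`, `verified_weight_kg`.
#' @param threshold relative-deviation threshold (default 0.03).
#' @return a `screened_weights` tibble with screening columns added.
#' @export
screen_weights <- function(weights, roster, resets = NULL, threshold = 0.03) {
  roster <- validate_roster(roster)
  if (any(is.na(weights$participant_id))) {
    warn(sprintf("Dropping %d unbound weight record(s).",
                 sum(is.na(weights$participant_id))))
    weights <- weights |> filter(!is.na(.data$participant_id))
  }
  baselines <- setNames(roster$baseline_weight_kg, roster$participant_id)
  unknown <- setdiff(unique(weights$participant_id), roster$participant_id)
  if (length(unknown)) {
    abort(paste0("Weights for participants absent from roster: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- weights |>
    arrange(.data$participant_id, .data$timestamp_utc) |>
    group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      pid <- key$participant_id
      pr <- if (is.null(resets)) NULL else resets |> filter(.data$participant_id == pid)
      screen_stream(df, baselines[[pid]], resets = pr, threshold = threshold)
    }) |>
    ungroup()
  class(out) <- c("screened_weights", class(out))
  out
}

#' Flag participants with runs of consecutive rejections
#'
#' A run of rejected weights usually means the reference has drifted (a
#' scale hiatus, or a household member using the scale) and a coordinator
#' should verify the participant's weight and reset the reference.
#'
#' @param records screened weight records with `participant_id` and
#'   `status`, in time order within participant.
#' @param k minimum run length to flag (default 3).
#' @return character vector of flagged participant IDs.
#' @export
flag_repeat_rejections <- function(records, k = 3) {
  records |>
    group_by(.data$participant_id) |>
    summarise(.flag = {
      r <- rle(.data$status == "REJECTED")
      any(r$values & r$lengths >= k)
    }, .groups = "drop") |>
    filter(.data$.flag) |>
    pull("participant_id")
}

#' Collapse weight records to one representative per day
#'
#' Participants were asked to re-weigh in close succession when a first
#' reading looked unreasonable, so days often carry several transmissions.
#' The daily representative is the mean of that day's accepted weights
#' (damping close-succession re-weighs); days with only rejected records
#' yield no representative. Dates are the participant's local calendar
#' dates when a `timezone` column is present, UTC otherwise.
#'
#' @param records screened weight records.
#' @return tibble with `participant_id`, `date`, `weight_kg`, `n_accepted`.
#' @export
collapse_daily <- function(records) {
  tz <- if ("timezone" %in% names(records)) records$timezone else "UTC"
  records |>
    mutate(.local_date = local_date(.data$timestamp_utc, tz)) |>
    filter(.data$status == "ACCEPTED") |>
    group_by(.data$participant_id, date = .data$.local_date) |>
    summarise(weight_kg = mean(.data$weight_kg), n_accepted = n(), .groups = "drop")
}

# Local calendar date of a UTC instant, vectorised over mixed time zones.
local_date <- function(timestamp_utc, tz) {
  tz <- rep_len(tz, length(timestamp_utc))
  out <- as.Date(rep(NA_integer_, length(timestamp_utc)), origin = "1970-01-01")
  for (z in unique(tz)) {
    idx <- tz == z
    out[idx] <- as.Date(timestamp_utc[idx], tz = z)
  }
  out
}

#' Weekly representative weights
#'
#' Averages a participant's daily representative weights over each study
#' week (anchored at enrollment). The weekly representative drives both
#' the phase I weight-loss criterion and the phase II maintenance band.
#'
#' @param daily output of [collapse_daily()].
#' @param roster a validated roster (for enrollment anchoring).
#' @return tibble with `participant_id`, `week_index`, `phase`,
#'   `weight_kg` (weekly representative), `n_weighin_days`.
#' @export
weekly_representatives <- function(daily, roster) {
  enroll <- setNames(roster$enrollment_date, roster$participant_id)
  daily |>
    mutate(week_index = date_to_week(.data$date, enroll[.data$participant_id])) |>
    filter(!is.na(.data$week_index)) |>
    group_by(.data$participant_id, .data$week_index) |>
    summarise(weight_kg = mean(.data$weight_kg), n_weighin_days = n(),
              .groups = "drop") |>
    mutate(phase = week_phase(.data$week_index)) |>
    select("participant_id", "week_index", "phase", "weight_kg", "n_weighin_days")
}

#' Write a screening report CSV
#' @param records screened weight records.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_screening_report <- function(records, file) {
  records |>
    select(dplyr::any_of(c("participant_id", "timestamp_utc", "weight_kg",
                           "status", "reference_weight_kg", "reason"))) |>
    readr::write_csv(file, progress = FALSE)
  invisible(file)
}
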