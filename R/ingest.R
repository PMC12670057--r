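#' Parse a cellular-scale transmission stream
#'
#' Scale payloads arrive as JSON lines, one transmission per line, with a
#' device ID, an epoch-millisecond UTC timestamp, and a weight in grams
#' (the wire dialect used throughout this package). Malformed lines are
#' skipped with a warning; weights outside the physiological plausibility
#' gate of 20-300 kg (a scale transmitting with nothing human on it, an
#' untared scale) are dropped with a warning. The gate is deliberately
#' distinct from the downstream >3% screening rule: gated payloads never
#' enter the record at all, whereas screened weights are kept and marked
#' rejected.
#'
#' @param file path to a JSON-lines file, or a character vector of lines
#'   (anything with an embedded newline is treated as literal text).
#' @return a tibble with `device_id`, `timestamp_utc` (POSIXct, UTC),
#'   `weight_kg`, sorted by timestamp, with attributes `n_skipped`
#'   (malformed lines) and `n_gated` (implausible weights).
#' @export
#' @examples
#' read_scale_stream('{"device_id":"I1","timestamp_utc":1609459200000,"weight_g":90000}')
read_scale_stream <- function(file) {
  looks_like_path <- length(file) == 1 && !grepl("\n", file) &&
    !startsWith(trimws(file), "{")
  lines <- if (looks_like_path) {
    if (!file.exists(file)) {
      abort(paste0("Cannot read scale stream: ", file), class = "trialops_io_error")
    }
    readr::read_lines(file, progress = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(lines, function(l) {
    x <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(x) || !is.list(x) ||
        !all(c("device_id", "timestamp_utc", "weight_g") %in% names(x))) {
      return(NULL)
    }
    w <- suppressWarnings(as.numeric(x$weight_g))
    ts <- suppressWarnings(as.numeric(x$timestamp_utc))
    if (is.na(w) || is.na(ts)) return(NULL)
    tibble(device_id = as.character(x$device_id), timestamp_ms = ts, weight_g = w)
  })
  n_skipped <- sum(vapply(parsed, is.null, logical(1)))
  if (n_skipped > 0) {
    warn(sprintf("Skipped %d malformed scale payload line(s).", n_skipped))
  }
  out <- bind_rows(parsed)
  if (nrow(out) == 0) {
    out <- tibble(device_id = character(), timestamp_ms = numeric(), weight_g = numeric())
  }
  gated <- out$weight_g < PLAUSIBLE_WEIGHT_G[1] | out$weight_g > PLAUSIBLE_WEIGHT_G[2]
  if (any(gated)) {
    warn(sprintf("Dropped %d payload(s) outside the 20-300 kg plausibility gate.",
                 sum(gated)))
  }
  out <- out[!gated, , drop = FALSE]
  out <- out |>
    mutate(
      timestamp_utc = lubridate::as_datetime(.data$timestamp_ms / 1000, tz = "UTC"),
      weight_kg = .data$weight_g / 1000
    ) |>
    arrange(.data$timestamp_utc) |>
    select("device_id", "timestamp_utc", "weight_kg")
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_gated") <- sum(gated)
  out
}

#' Write scale payloads back to the JSON-lines wire format
#'
#' Inverse of [read_scale_stream()]: round-tripping a parsed stream
#' reproduces the same records.
#'
#' @param payloads tibble with `device_id`, `timestamp_utc`, `weight_kg`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_scale_stream <- function(payloads, file) {
  lines <- sprintf(
    '{"device_id":"%s","timestamp_utc":%.0f,"weight_g":%.0f}',
    payloads$device_id,
    as.numeric(payloads$timestamp_utc) * 1000,
    payloads$weight_kg * 1000
  )
  readr::write_lines(lines, file)
  invisible(file)
}

#' Bind scale payloads to participants by device ID
#'
#' Each scale's device ID is recorded at enrollment and linked to the
#' participant ID; binding is a pure function of the device ID. Payloads
#' from unregistered devices are kept, flagged unbound, for staff review.
#'
#' @param payloads output of [read_scale_stream()].
#' @param roster a validated roster.
#' @return a tibble of weight records: `participant_id` (NA when unbound),
#'   `device_id`, `timestamp_utc`, `weight_kg`, `timezone`, `bound`.
#' @export
bind_devices <- function(payloads, roster) {
  roster <- validate_roster(roster)
  payloads |>
    left_join(
      roster |> select("participant_id", "scale_device_id", "timezone"),
      by = c(device_id = "scale_device_id")
    ) |>
    mutate(bound = !is.na(.data$participant_id)) |>
    select("participant_id", "device_id", "timestamp_utc", "weight_kg",
           "timezone", "bound")
}

#' Read a daily dietary log
#'
#' One row per participant-day of food logging: total kilocalories and the
#' number of entries. Duplicate participant-date rows (a known artifact of
#' chained third-party syncing) are merged by summing kilocalories and
#' entry counts, with a warning. A day with zero entries must carry zero
#' kilocalories; negative kilocalories are a validation error.
#'
#' @param file path to a CSV with columns `participant_id`, `date`
#'   (ISO 8601), `total_kcal`, `n_entries`, and optionally `source`
#'   (`MFP_VIA_FITBIT` or `FITBIT_DIRECT`).
#' @return a tibble of diet days, one per participant-date.
#' @export
read_diet_log <- function(file) {
  df <- readr::read_csv(
    file,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      date = readr::col_date(),
      total_kcal = readr::col_double(),
      n_entries = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (!"source" %in% names(df)) df$source <- "FITBIT_DIRECT"
  if (any(df$total_kcal < 0, na.rm = TRUE)) {
    abort("Negative total_kcal in diet log.", class = "trialops_validation_error")
  }
  if (any(df$n_entries == 0 & df$total_kcal != 0, na.rm = TRUE)) {
    abort("Diet day with zero entries but nonzero kcal.",
          class = "trialops_validation_error")
  }
  n_dup <- sum(duplicated(df[c("participant_id", "date")]))
  if (n_dup > 0) {
    warn(sprintf("Merged %d duplicate participant-date diet row(s).", n_dup))
  }
  df |>
    group_by(.data$participant_id, .data$date) |>
    summarise(
      total_kcal = sum(.data$total_kcal),
      n_entries = sum(.data$n_entries),
      source = first(.data$source),
      .groups = "drop"
    ) |>
    arrange(.data$participant_id, .data$date)
}

#' Write a diet log to CSV
#' @param diet a diet-day tibble.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_diet_log <- function(diet, file) {
  readr::write_csv(diet, file, progress = FALSE)
  invisible(file)
}
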