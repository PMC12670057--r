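#' Read and validate an enrollment roster
#'
#' The roster is the registry binding each participant to a site, a
#' randomized arm, a time zone, a baseline weight, and a cellular-scale
#' device ID (the scale's IMEI, recorded at enrollment). All downstream
#' modules key on it.
#'
#' @param file path to a CSV with columns `participant_id`, `site`,
#'   `arm`, `timezone`, `baseline_weight_kg`, `enrollment_date`
#'   (ISO 8601), `scale_device_id`, and optionally `withdrawal_date`.
#' @return a validated roster tibble.
#' @export
read_roster <- function(file) {
  df <- readr::read_csv(
    file,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      site = readr::col_character(),
      arm = readr::col_character(),
      timezone = readr::col_character(),
      baseline_weight_kg = readr::col_double(),
      enrollment_date = readr::col_date(),
      scale_device_id = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (!"withdrawal_date" %in% names(df)) df$withdrawal_date <- as.Date(NA)
  df$withdrawal_date <- as.Date(df$withdrawal_date)
  validate_roster(as_tibble(df))
}

#' Validate a roster data frame
#'
#' Enforces the registry invariants: known site and arm labels, valid IANA
#' time zones, positive baseline weights, withdrawal on or after enrollment,
#' and scale device IDs unique across simultaneously active participants
#' (a device shared by two concurrently enrolled participants is a hard
#' error -- weight payloads could not be attributed).
#'
#' @param roster a data frame shaped like [read_roster()] output.
#' @return the roster as a tibble, invisibly validated.
#' @export
validate_roster <- function(roster) {
  roster <- as_tibble(roster)
  required <- c(
    "participant_id", "site", "arm", "timezone", "baseline_weight_kg",
    "enrollment_date", "scale_device_id"
  )
  missing <- setdiff(required, names(roster))
  if (length(missing)) {
    abort(paste0("Roster is missing columns: ", paste(missing, collapse = ", ")),
          class = "trialops_roster_error")
  }
  if (!"withdrawal_date" %in% names(roster)) roster$withdrawal_date <- as.Date(NA)
  roster$enrollment_date <- as.Date(roster$enrollment_date)
  roster$withdrawal_date <- as.Date(roster$withdrawal_date)
  if (anyDuplicated(roster$participant_id)) {
    abort("Duplicate participant_id in roster.", class = "trialops_roster_error")
  }
  if (!all(roster$site %in% SITES)) {
    abort(paste0("Unknown site; expected one of ", paste(SITES, collapse = ", ")),
          class = "trialops_roster_error")
  }
  if (!all(roster$arm %in% ARMS)) {
    abort(paste0("Unknown arm; expected one of ", paste(ARMS, collapse = ", ")),
          class = "trialops_roster_error")
  }
  if (!all(roster$timezone %in% OlsonNames())) {
    abort("timezone must be a valid IANA zone name.", class = "trialops_roster_error")
  }
  if (any(is.na(roster$baseline_weight_kg)) || any(roster$baseline_weight_kg <= 0)) {
    abort("baseline_weight_kg must be positive.", class = "trialops_roster_error")
  }
  bad_wd <- !is.na(roster$withdrawal_date) &
    roster$withdrawal_date < roster$enrollment_date
  if (any(bad_wd)) {
    abort("withdrawal_date precedes enrollment_date.", class = "trialops_roster_error")
  }
  # device uniqueness among participants whose active windows overlap
  dup <- roster |>
    mutate(.end = dplyr::coalesce(.data$withdrawal_date, as.Date("9999-12-31"))) |>
    group_by(.data$scale_device_id) |>
    filter(n() > 1) |>
    arrange(.data$enrollment_date, .by_group = TRUE) |>
    filter(any(as.numeric(.data$enrollment_date[-1]) <
                 cummax(as.numeric(.data$.end))[-n()])) |>
    ungroup()
  if (nrow(dup) > 0) {
    abort(
      paste0("scale_device_id shared by concurrently active participants: ",
             paste(unique(dup$scale_device_id), collapse = ", ")),
      class = "trialops_roster_error"
    )
  }
  roster
}

#' Write a roster to CSV
#' @param roster a roster tibble.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_roster <- function(roster, file) {
  readr::write_csv(roster, file, progress = FALSE)
  invisible(file)
}
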