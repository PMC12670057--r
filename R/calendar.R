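#' Map a study week to its trial phase
#'
#' The 78-week program is divided into three 26-week phases: phase I
#' (weight-loss initiation, weeks 1-26), phase II (maintenance within a
#' band, weeks 27-52), and phase III (non-incentivized maintenance,
#' weeks 53-78).
#'
#' @param week_index integer vector of study weeks, each in 1..78.
#' @return character vector of `"I"`, `"II"`, `"III"`.
#' @export
#' @examples
#' week_phase(c(1, 26, 27, 52, 53, 78))
week_phase <- function(week_index) {
  week_index <- as.integer(week_index)
  if (any(is.na(week_index)) || any(week_index < 1L) || any(week_index > 78L)) {
    abort("`week_index` must be an integer in 1..78.", class = "trialops_invalid_week")
  }
  c("I", "II", "III")[findInterval(week_index, c(1L, 27L, 53L))]
}

#' Build a participant's 78-week study calendar
#'
#' Weeks are anchored per participant: week 1 begins on the enrollment date
#' and each week is a consecutive 7-day window, so the calendar covers
#' exactly 546 days with no gaps or overlaps.
#'
#' @param enrollment_date a `Date` (or string coercible to one).
#' @return a tibble with columns `week_index`, `phase`, `start_date`,
#'   `end_date` (inclusive).
#' @export
#' @examples
#' study_calendar("2021-01-04")
study_calendar <- function(enrollment_date) {
  enrollment_date <- as.Date(enrollment_date)
  if (length(enrollment_date) != 1 || is.na(enrollment_date)) {
    abort("`enrollment_date` must be a single valid date.")
  }
  start <- enrollment_date + 7L * (0:77)
  tibble(
    week_index = 1:78,
    phase = week_phase(1:78),
    start_date = start,
    end_date = start + 6L
  )
}

#' Which study week does a date fall in?
#'
#' @param date Date vector.
#' @param enrollment_date the participant's enrollment date.
#' @return integer week index (NA outside the 78-week window).
#' @export
date_to_week <- function(date, enrollment_date) {
  idx <- as.integer(floor(as.numeric(as.Date(date) - as.Date(enrollment_date)) / 7)) + 1L
  idx[idx < 1L | idx > 78L] <- NA_integer_
  idx
}

#' Is a participant active on a given date?
#'
#' A participant is active from their enrollment date up to, but not
#' including, their withdrawal date: no services are rendered on the
#' withdrawal day itself.
#'
#' @param roster a roster data frame (see [read_roster()]).
#' @param on a single `Date`.
#' @return logical vector, one element per roster row.
#' @export
is_active <- function(roster, on) {
  on <- as.Date(on)
  enrolled <- on >= as.Date(roster$enrollment_date)
  wd <- as.Date(roster$withdrawal_date)
  not_withdrawn <- is.na(wd) | on < wd
  enrolled & not_withdrawn
}

#' US federal holidays
#'
#' Computes observed US federal holidays for a span of years (fixed-date
#' holidays falling on a Saturday are observed the preceding Friday, on a
#' Sunday the following Monday). Used as the default holiday calendar when
#' scheduling Monday incentive messages.
#'
#' @param years integer vector of calendar years.
#' @param observed shift weekend holidays to the observed weekday?
#' @return a `Date` vector, sorted.
#' @export
#' @examples
#' us_federal_holidays(2021)
us_federal_holidays <- function(years, observed = TRUE) {
  nth_weekday <- function(year, month, wday, n) {
    # wday: 1 = Monday .. 7 = Sunday; n = -1 means last
    d <- seq(as.Date(sprintf("%d-%02d-01", year, month)), by = "day", length.out = 31)
    d <- d[as.integer(format(d, "%m")) == month & lubridate::wday(d, week_start = 1) == wday]
    if (n == -1) d[length(d)] else d[n]
  }
  one_year <- function(y) {
    fixed <- as.Date(sprintf(
      "%d-%s", y,
      c("01-01", "06-19", "07-04", "11-11", "12-25")
    ))
    floating <- c(
      nth_weekday(y, 1, 1, 3),   # Martin Luther King Jr. Day
      nth_weekday(y, 2, 1, 3),   # Washington's Birthday
      nth_weekday(y, 5, 1, -1),  # Memorial Day
      nth_weekday(y, 9, 1, 1),   # Labor Day
      nth_weekday(y, 10, 1, 2),  # Columbus Day
      nth_weekday(y, 11, 4, 4),  # Thanksgiving
      as.Date(character())
    )
    if (observed) {
      wd <- lubridate::wday(fixed, week_start = 1)
      fixed[wd == 6] <- fixed[wd == 6] - 1L
      fixed[wd == 7] <- fixed[wd == 7] + 1L
    }
    c(fixed, floating)
  }
  sort(unique(do.call(c, lapply(unique(as.integer(years)), one_year))))
}
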