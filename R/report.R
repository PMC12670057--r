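#' Operational summary of a trial's data streams
#'
#' Computes the descriptive statistics study staff monitor: message counts
#' by weekday and type (on the scheduled local date), delivery and success
#' rates, weight transmission and acceptance counts, weigh-ins per weighing
#' day, diet-day totals, and the automatic/manual split of incentive
#' processing. Percentages are rounded half-up to one decimal. Empty
#' inputs yield a summary of zeros, never an error.
#'
#' A *weighing day* is a participant-day with at least one transmission,
#' accepted or rejected: close-succession re-weighs (including an
#' unreasonable first reading) all count, which is why the mean exceeds 1.
#'
#' @param weights screened weight records (may be `NULL`).
#' @param diet diet-day tibble (may be `NULL`).
#' @param messages message tibble (may be `NULL`).
#' @param decisions incentive decisions (may be `NULL`).
#' @param weighins_stat `"per_participant"` (default): compute each
#'   participant's mean weigh-ins per weighing day, then take the mean and
#'   SD across participants; `"pooled"`: pool all weighing days.
#' @return an `ops_summary` object (a named list; see [tidy.ops_summary()]
#'   and [glance.ops_summary()]).
#' @export
ops_summarize <- function(weights = NULL, diet = NULL, messages = NULL,
                          decisions = NULL,
                          weighins_stat = c("per_participant", "pooled")) {
  weighins_stat <- match.arg(weighins_stat)

  if (!is.null(messages) && nrow(messages) > 0) {
    ds <- compute_delivery_stats(messages)
    weekday <- lubridate::wday(as.Date(messages$scheduled_date),
                               label = TRUE, abbr = FALSE, week_start = 1,
                               locale = "C")
    by_wd <- tibble(weekday = as.character(weekday), mtype = messages$mtype) |>
      count(.data$weekday, .data$mtype, name = "n") |>
      arrange(match(.data$weekday, WEEKDAYS), .data$mtype)
    messages_total <- ds$attempted
  } else {
    ds <- tibble(delivery_rate = 0, success_rate = 0)
    by_wd <- tibble(weekday = character(), mtype = character(), n = integer())
    messages_total <- 0L
  }

  if (!is.null(weights) && nrow(weights) > 0) {
    weights_total <- nrow(weights)
    weights_accepted <- sum(weights$status == "ACCEPTED")
    tz <- if ("timezone" %in% names(weights)) weights$timezone else "UTC"
    per_day <- weights |>
      mutate(weigh_date = local_date(.data$timestamp_utc, tz)) |>
      count(.data$participant_id, .data$weigh_date, name = "n_weighins")
    if (weighins_stat == "per_participant") {
      per_part <- per_day |>
        group_by(.data$participant_id) |>
        summarise(m = mean(.data$n_weighins), .groups = "drop")
      mean_wi <- mean(per_part$m)
      sd_wi <- if (nrow(per_part) > 1) sd(per_part$m) else 0
    } else {
      mean_wi <- mean(per_day$n_weighins)
      sd_wi <- if (nrow(per_day) > 1) sd(per_day$n_weighins) else 0
    }
  } else {
    weights_total <- 0L
    weights_accepted <- 0L
    mean_wi <- 0
    sd_wi <- 0
  }

  if (!is.null(decisions) && nrow(decisions) > 0) {
    incentives_total <- nrow(decisions)
    incentives_auto <- sum(decisions$processing_mode == "AUTO")
  } else {
    incentives_total <- 0L
    incentives_auto <- 0L
  }
  incentives_manual <- incentives_total - incentives_auto

  pct <- function(num, den) {
    if (den > 0) round_half_up(100 * num / den, 1) else 0
  }
  out <- list(
    messages_total = messages_total,
    messages_by_weekday_and_type = by_wd,
    delivery_rate = ds$delivery_rate,
    success_rate = ds$success_rate,
    weights_total = weights_total,
    weights_accepted = weights_accepted,
    acceptance_pct = pct(weights_accepted, weights_total),
    mean_weighins_per_weighing_day = mean_wi,
    sd_weighins_per_weighing_day = sd_wi,
    diet_days_total = if (is.null(diet)) 0L else nrow(diet),
    incentives_total = incentives_total,
    incentives_auto = incentives_auto,
    auto_pct = pct(incentives_auto, incentives_total),
    incentives_manual = incentives_manual,
    manual_pct = pct(incentives_manual, incentives_total)
  )
  structure(out, class = "ops_summary")
}

WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")

#' Busiest day of a record stream
#'
#' @param dates a `Date` vector (e.g. weight transmission dates or
#'   message send dates).
#' @return a one-row tibble `date`, `n` for the day with the largest
#'   count (earliest date on ties), or a zero-row tibble when empty.
#' @export
peak_day <- function(dates) {
  dates <- as.Date(dates)
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0) {
    return(tibble(date = as.Date(character()), n = integer()))
  }
  tab <- tibble(date = dates) |>
    count(.data$date, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$date)
  tab[1, ]
}

#' Render an operational summary
#'
#' Serializes an `ops_summary` losslessly to a staff-facing text table, a
#' long CSV, or JSON. CSV and JSON renderings round-trip through
#' [parse_report()] back to an equal summary.
#'
#' @param summary an `ops_summary`.
#' @param format `"text"`, `"csv"`, or `"json"`.
#' @return a single string (the rendered document).
#' @export
render_report <- function(summary, format = c("text", "csv", "json")) {
  if (!inherits(summary, "ops_summary")) {
    abort("`summary` must be an ops_summary.", class = "trialops_usage_error")
  }
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(paste0("Unknown report format: ", format[1]),
          class = "trialops_usage_error")
  })
  scalars <- summary[setdiff(names(summary), "messages_by_weekday_and_type")]
  wd <- summary$messages_by_weekday_and_type
  if (format == "json") {
    return(jsonlite::toJSON(
      c(scalars, list(messages_by_weekday_and_type = wd)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    ))
  }
  if (format == "csv") {
    rows <- c(
      "field,value",
      sprintf("%s,%s", names(scalars),
              vapply(scalars, format_num, character(1))),
      sprintf("messages_by_weekday_and_type:%s:%s,%d", wd$weekday, wd$mtype, wd$n)
    )
    return(paste(rows, collapse = "\n"))
  }
  # text
  lines <- c(
    "Operational summary",
    "===================",
    sprintf("  %-32s %s", names(scalars),
            vapply(scalars, format_num, character(1))),
    "  messages by weekday and type:",
    if (nrow(wd) > 0) sprintf("    %-12s %-14s %d", wd$weekday, wd$mtype, wd$n)
    else "    (none)"
  )
  paste(lines, collapse = "\n")
}

format_num <- function(x) {
  if (is.integer(x) || (is.numeric(x) && all(x == round(x)))) {
    format(x, scientific = FALSE)
  } else {
    format(x, digits = 15, scientific = FALSE)
  }
}

#' Parse a rendered report back into an `ops_summary`
#'
#' @param text the output of [render_report()] (csv or json formats).
#' @param format `"csv"` or `"json"`.
#' @return an `ops_summary`.
#' @export
parse_report <- function(text, format = c("csv", "json")) {
  format <- match.arg(format)
  int_fields <- c("messages_total", "weights_total", "weights_accepted",
                  "diet_days_total", "incentives_total", "incentives_auto",
                  "incentives_manual")
  if (format == "json") {
    x <- jsonlite::fromJSON(text)
    wd <- as_tibble(x$messages_by_weekday_and_type)
    if (nrow(wd) == 0) {
      wd <- tibble(weekday = character(), mtype = character(), n = integer())
    }
    wd$n <- as.integer(wd$n)
    scalars <- x[setdiff(names(x), "messages_by_weekday_and_type")]
  } else {
    df <- readr::read_csv(I(text), col_types = "cc", progress = FALSE,
                          show_col_types = FALSE)
    is_wd <- startsWith(df$field, "messages_by_weekday_and_type:")
    parts <- stringr::str_split_fixed(df$field[is_wd], ":", 3)
    wd <- tibble(weekday = parts[, 2], mtype = parts[, 3],
                 n = as.integer(df$value[is_wd]))
    scalars <- as.list(as.numeric(df$value[!is_wd]))
    names(scalars) <- df$field[!is_wd]
  }
  scalars[int_fields] <- lapply(scalars[int_fields], as.integer)
  canonical <- c(
    "messages_total", "messages_by_weekday_and_type", "delivery_rate",
    "success_rate", "weights_total", "weights_accepted", "acceptance_pct",
    "mean_weighins_per_weighing_day", "sd_weighins_per_weighing_day",
    "diet_days_total", "incentives_total", "incentives_auto", "auto_pct",
    "incentives_manual", "manual_pct"
  )
  structure(c(scalars, list(messages_by_weekday_and_type = wd))[canonical],
            class = "ops_summary")
}

#' @export
print.ops_summary <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}

#' Run the full simulate-to-report pipeline
#'
#' Exercises every module end to end: simulates a cohort, writes its
#' streams to the interchange formats, re-reads them through the ingestion
#' module, screens the weights, adjudicates all completed phase I/II
#' weeks, applies the carrier receipts to the message log, and summarizes.
#' Deterministic under the config seed: two runs with the same config
#' write byte-identical artifacts.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all intermediate streams,
#'   the screening report, the incentive report, and the rendered summary
#'   (CSV and JSON) are written there.
#' @return a list: `summary` (an `ops_summary`), `roster`, `weights`
#'   (screened), `diet`, `decisions`, `messages`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  sim <- simulate_cohort(config)
  stage_dir <- out_dir %||% tempfile("trialops-stage-")
  paths <- write_cohort(sim, stage_dir)

  roster <- read_roster(paths[["roster"]])
  payloads <- read_scale_stream(paths[["scale"]])
  diet <- read_diet_log(paths[["diet"]])
  bound <- bind_devices(payloads, roster)
  screened <- screen_weights(bound, roster)
  decisions <- adjudicate_weeks(roster, screened, diet,
                                weeks = seq_len(min(config$n_weeks, 52)))
  messages <- apply_receipts(sim$messages, sim$receipts)
  summary <- ops_summarize(screened, diet, messages, decisions)

  if (!is.null(out_dir)) {
    write_screening_report(screened, file.path(out_dir, "screening_report.csv"))
    write_incentive_report(decisions, file.path(out_dir, "incentive_report.csv"))
    write_message_log(messages, file.path(out_dir, "message_log.csv"))
    writeLines(render_report(summary, "csv"), file.path(out_dir, "summary.csv"))
    writeLines(render_report(summary, "json"), file.path(out_dir, "summary.json"))
  }
  list(summary = summary, roster = roster, weights = screened, diet = diet,
       decisions = decisions, messages = messages)
}
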