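#' Simulator configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults describe a
#' plausible remote weight-management cohort: participants weigh in about
#' twice weekly while losing weight and weekly while maintaining; roughly
#' one weight in twenty is errant (someone else on the scale, an untared
#' scale) and lands 8-15% away from truth; food logging starts near-daily
#' and decays with a 90-day half-life; message delivery fails rarely
#' (0.6% of sends); withdrawal is a small constant weekly hazard. The
#' latent weight model is intentionally simple -- linear loss in phase I,
#' plateau afterwards, Gaussian measurement noise -- because the platform,
#' not human physiology, is what the simulator exists to exercise.
#'
#' @param n_participants cohort size.
#' @param site_weights sampling weights over the WI and NC sites.
#' @param seed integer seed; the whole simulation is reproducible under it.
#' @param n_weeks number of study weeks to simulate (default 78).
#' @param first_enrollment earliest enrollment date; participants enroll
#'   uniformly within `enrollment_span_days` of it.
#' @param enrollment_span_days rolling-enrollment window (default 28).
#' @param weighin_rate_phase1 expected weigh-in days per week in phase I
#'   (default 2).
#' @param weighin_rate_phase2 expected weigh-in days per week in phases
#'   II/III (default 1).
#' @param errant_weight_prob probability a transmission is errant
#'   (default 0.05).
#' @param errant_deviation_range multiplicative deviation range of errant
#'   weights (default `c(0.08, 0.15)`, sign random).
#' @param logging_start_prob daily probability of food logging at week 1
#'   (default 0.85).
#' @param logging_decay_halflife_days half-life of the logging
#'   probability decay (default 90 days).
#' @param kcal_mean,kcal_sd kilocalories per logged day, Gaussian
#'   truncated at zero (defaults 1900, 350).
#' @param delivery_failure_prob per-message probability the carrier
#'   refuses the send (default 0.006).
#' @param withdrawal_hazard_per_week weekly withdrawal probability
#'   (default 0.002).
#' @param trueloss_kg_per_week_phase1 latent weight loss per phase I week
#'   (default 0.35 kg).
#' @param weight_noise_sd_kg measurement noise SD (default 0.4 kg).
#' @param baseline_mean_kg,baseline_sd_kg baseline-weight distribution
#'   (defaults 98, 14, floored at 60 kg).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 50,
                       site_weights = c(WI = 0.5, NC = 0.5),
                       seed = 20210104L,
                       n_weeks = 78,
                       first_enrollment = as.Date("2021-01-04"),
                       enrollment_span_days = 28,
                       weighin_rate_phase1 = 2,
                       weighin_rate_phase2 = 1,
                       errant_weight_prob = 0.05,
                       errant_deviation_range = c(0.08, 0.15),
                       logging_start_prob = 0.85,
                       logging_decay_halflife_days = 90,
                       kcal_mean = 1900,
                       kcal_sd = 350,
                       delivery_failure_prob = 0.006,
                       withdrawal_hazard_per_week = 0.002,
                       trueloss_kg_per_week_phase1 = 0.35,
                       weight_noise_sd_kg = 0.4,
                       baseline_mean_kg = 98,
                       baseline_sd_kg = 14) {
  cfg <- as.list(environment())
  probs <- c(cfg$errant_weight_prob, cfg$logging_start_prob,
             cfg$delivery_failure_prob, cfg$withdrawal_hazard_per_week)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].", class = "trialops_config_error")
  }
  if (cfg$n_participants < 1) {
    abort("n_participants must be at least 1.", class = "trialops_config_error")
  }
  if (length(cfg$errant_deviation_range) != 2 ||
      cfg$errant_deviation_range[1] > cfg$errant_deviation_range[2]) {
    abort("errant_deviation_range must be an increasing interval.",
          class = "trialops_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Daily logging probability under the decay model
#'
#' Food logging adherence decays exponentially: the probability of logging
#' on study day `d` is `logging_start_prob * 2^(-d / halflife)`, so at the
#' half-life (90 days by default) it is exactly half the starting rate.
#'
#' @param day study day (0 = enrollment day).
#' @param config a [sim_config()].
#' @return numeric vector of probabilities.
#' @export
logging_probability <- function(day, config = sim_config()) {
  config$logging_start_prob * 2^(-day / config$logging_decay_halflife_days)
}

#' Simulate a synthetic cohort
#'
#' Generates, reproducibly under the config seed, all the streams the
#' platform ingests: an enrollment roster, a cellular-scale transmission
#' stream (with errant weights injected), a daily diet log with decaying
#' adherence, a scheduled message log, and a carrier receipt stream with
#' rare delivery failures. The streams use exactly the ingestion module's
#' interchange formats, so a simulated cohort doubles as format
#' documentation.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list with tibbles `roster`, `scale_stream`
#'   (device_id, timestamp_utc in epoch ms, weight_g), `diet_log`,
#'   `messages` (the scheduled log), `receipts`, and `truth` (per-
#'   participant latent parameters, for parameter-recovery checks).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  tz_by_site <- c(WI = "America/Chicago", NC = "America/New_York")
  site <- sample(names(config$site_weights), n, replace = TRUE,
                 prob = config$site_weights)
  arm <- sample(ARMS, n, replace = TRUE)
  baseline <- pmax(60, rnorm(n, config$baseline_mean_kg, config$baseline_sd_kg))
  enroll <- config$first_enrollment +
    sample.int(config$enrollment_span_days, n, replace = TRUE) - 1L

  # weekly withdrawal: geometric hazard over the simulated span
  wd_week <- apply(
    matrix(rbinom(n * config$n_weeks, 1, config$withdrawal_hazard_per_week),
           nrow = n) == 1, 1,
    function(z) if (any(z)) which(z)[1] else NA_integer_
  )
  withdrawal <- enroll + 7L * wd_week  # inactive from start of next week
  roster <- tibble(
    participant_id = ids,
    site = site,
    arm = arm,
    timezone = unname(tz_by_site[site]),
    baseline_weight_kg = round(baseline, 1),
    enrollment_date = enroll,
    scale_device_id = sprintf("IMEI%06d", seq_len(n)),
    withdrawal_date = withdrawal
  )

  per_participant <- function(i) {
    p <- roster[i, ]
    last_day <- if (is.na(wd_week[i])) config$n_weeks * 7L - 1L else
      (wd_week[i] * 7L - 1L)
    days <- 0:last_day
    week_of_day <- days %/% 7 + 1L
    phase <- week_phase(pmin(week_of_day, 78L))

    # latent trajectory: linear loss through phase I, plateau after
    loss_weeks <- pmin((days + 1) / 7, 26)
    true_wt <- p$baseline_weight_kg -
      config$trueloss_kg_per_week_phase1 * loss_weeks

    rate <- if_else(phase == "I", config$weighin_rate_phase1,
                    config$weighin_rate_phase2) / 7
    weigh <- rbinom(length(days), 1, pmin(rate, 1)) == 1
    wdays <- days[weigh]
    n_w <- length(wdays)
    scale <- NULL
    if (n_w > 0) {
      measured <- true_wt[weigh] + rnorm(n_w, 0, config$weight_noise_sd_kg)
      errant <- rbinom(n_w, 1, config$errant_weight_prob) == 1
      dev <- runif(n_w, config$errant_deviation_range[1],
                   config$errant_deviation_range[2]) *
        sample(c(-1, 1), n_w, replace = TRUE)
      measured[errant] <- measured[errant] * (1 + dev[errant])
      # morning weigh-in, local time converted to a UTC instant
      tod <- 6.5 * 3600 + runif(n_w, 0, 3 * 3600)
      local <- paste(format(p$enrollment_date + wdays, "%Y-%m-%d"),
                     hms_chr(tod))
      ts <- local_to_utc(local, p$timezone)
      scale <- tibble(
        device_id = p$scale_device_id,
        timestamp_ms = as.numeric(ts) * 1000,
        weight_g = round(measured * 1000),
        errant = errant
      )
    }

    logs <- rbinom(length(days), 1, logging_probability(days, config)) == 1
    ldays <- days[logs]
    diet <- NULL
    if (length(ldays) > 0) {
      diet <- tibble(
        participant_id = p$participant_id,
        date = p$enrollment_date + ldays,
        total_kcal = round(pmax(0, rnorm(length(ldays), config$kcal_mean,
                                         config$kcal_sd))),
        n_entries = 1L + rpois(length(ldays), 2),
        source = if_else(p$enrollment_date + ldays < as.Date("2021-12-15"),
                         "MFP_VIA_FITBIT", "FITBIT_DIRECT")
      )
    }
    list(scale = scale, diet = diet)
  }

  streams <- lapply(seq_len(n), per_participant)
  scale_all <- bind_rows(lapply(streams, `[[`, "scale"))
  if (nrow(scale_all) == 0) {
    scale_all <- tibble(device_id = character(), timestamp_ms = numeric(),
                        weight_g = numeric(), errant = logical())
  }
  scale_all <- scale_all |> arrange(.data$timestamp_ms, .data$device_id)
  diet_all <- bind_rows(lapply(streams, `[[`, "diet"))

  messages <- schedule_messages(
    roster |> mutate(withdrawal_date = as.Date(NA)),  # schedule, then drop
    weeks = seq_len(min(config$n_weeks, 78)),
    seed = (config$seed + 1L) %% .Machine$integer.max
  )
  # messages are only sent to active participants
  wd <- roster$withdrawal_date[match(messages$participant_id, roster$participant_id)]
  keep <- is.na(wd) | messages$scheduled_date < wd
  messages <- messages[keep, ]

  fail <- rbinom(nrow(messages), 1, config$delivery_failure_prob) == 1
  reasons <- sample(c("SPAM_FLAGGED", "UNREACHABLE", "OTHER"), sum(fail),
                    replace = TRUE, prob = c(0.6, 0.3, 0.1))
  receipts <- bind_rows(
    tibble(message_id = messages$message_id[!fail], event = "accepted", ord = 1L),
    tibble(message_id = messages$message_id[!fail], event = "delivered", ord = 2L),
    tibble(message_id = messages$message_id[fail], event = "failed", ord = 1L,
           reason = reasons)
  )
  if (!"reason" %in% names(receipts)) receipts$reason <- NA_character_
  receipts <- receipts |>
    arrange(.data$message_id, .data$ord) |>
    select("message_id", "event", "reason")

  structure(
    list(
      roster = roster,
      scale_stream = scale_all |>
        select("device_id", "timestamp_ms", "weight_g") |>
        rename(timestamp_utc = "timestamp_ms"),
      diet_log = diet_all |> arrange(.data$participant_id, .data$date),
      messages = messages,
      receipts = receipts,
      truth = tibble(
        participant_id = ids,
        errant_weight_prob = config$errant_weight_prob,
        delivery_failure_prob = config$delivery_failure_prob,
        n_errant = vapply(streams, function(s) {
          if (is.null(s$scale)) 0L else sum(s$scale$errant)
        }, integer(1)),
        n_weights = vapply(streams, function(s) {
          if (is.null(s$scale)) 0L else nrow(s$scale)
        }, integer(1))
      ),
      config = config
    ),
    class = "sim_cohort"
  )
}

#' Inject an operational failure scenario into simulated streams
#'
#' Deterministically perturbs a simulated cohort to reproduce a known
#' failure mode so downstream defenses can be exercised:
#' * `HOUSEHOLD_MEMBER` -- a block of one participant's weights shifted
#'   about 20%, as when someone else uses the scale; screening should
#'   reject the block.
#' * `CARRIER_GAP` -- scale payloads dropped over a window, as when the
#'   scale sits outside cellular coverage.
#' * `SPAM_WAVE` -- all Monday incentive sends fail one week with
#'   `SPAM_FLAGGED`; retry logic should requeue them.
#' * `API_CUTOVER` -- the diet source switches from MyFitnessPal-via-
#'   Fitbit syncing to direct Fitbit logging with a gap of missing days.
#'
#' @param sim a `sim_cohort`.
#' @param scenario one of the scenario names above.
#' @param participant_id target participant (default: the first).
#' @param start_day first affected study day (default 30).
#' @param duration_days length of the affected window (default 7).
#' @return the perturbed `sim_cohort`.
#' @export
inject_scenario <- function(sim, scenario = c("HOUSEHOLD_MEMBER", "CARRIER_GAP",
                                              "SPAM_WAVE", "API_CUTOVER"),
                            participant_id = NULL, start_day = 30,
                            duration_days = 7) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(sim, "sim_cohort"))
  pid <- participant_id %||% sim$roster$participant_id[1]
  p <- sim$roster[sim$roster$participant_id == pid, ]
  dev <- p$scale_device_id
  win_start <- p$enrollment_date + start_day
  win_end <- win_start + duration_days
  ms <- function(d) as.numeric(lubridate::as_datetime(d, tz = "UTC")) * 1000
  in_window <- sim$scale_stream$device_id == dev &
    sim$scale_stream$timestamp_utc >= ms(win_start) &
    sim$scale_stream$timestamp_utc < ms(win_end)

  if (scenario == "HOUSEHOLD_MEMBER") {
    sim$scale_stream$weight_g[in_window] <-
      round(sim$scale_stream$weight_g[in_window] * 0.8)
  } else if (scenario == "CARRIER_GAP") {
    sim$scale_stream <- sim$scale_stream[!in_window, ]
  } else if (scenario == "SPAM_WAVE") {
    wk <- date_to_week(win_start, p$enrollment_date)
    hit <- sim$messages$mtype == "INCENTIVE" & sim$messages$week_index == wk
    hit_ids <- sim$messages$message_id[hit]
    sim$receipts <- sim$receipts |>
      filter(!.data$message_id %in% hit_ids) |>
      bind_rows(tibble(message_id = hit_ids, event = "failed",
                       reason = "SPAM_FLAGGED"))
  } else if (scenario == "API_CUTOVER") {
    d_in <- sim$diet_log$participant_id == pid &
      sim$diet_log$date >= win_start & sim$diet_log$date < win_end
    sim$diet_log <- sim$diet_log[!d_in, ]
    after <- sim$diet_log$participant_id == pid & sim$diet_log$date >= win_end
    sim$diet_log$source[after] <- "FITBIT_DIRECT"
    before <- sim$diet_log$participant_id == pid & sim$diet_log$date < win_start
    sim$diet_log$source[before] <- "MFP_VIA_FITBIT"
  }
  sim
}

#' Write a simulated cohort to the interchange formats
#'
#' Emits the roster CSV, scale JSON-lines stream, diet-log CSV, message
#' log CSV, and receipts CSV that the ingestion module reads.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    roster = file.path(dir, "roster.csv"),
    scale = file.path(dir, "scale_stream.jsonl"),
    diet = file.path(dir, "diet_log.csv"),
    messages = file.path(dir, "messages.csv"),
    receipts = file.path(dir, "receipts.csv")
  )
  write_roster(sim$roster, paths["roster"])
  readr::write_lines(sprintf(
    '{"device_id":"%s","timestamp_utc":%.0f,"weight_g":%.0f}',
    sim$scale_stream$device_id, sim$scale_stream$timestamp_utc,
    sim$scale_stream$weight_g
  ), paths["scale"])
  write_diet_log(sim$diet_log, paths["diet"])
  write_message_log(sim$messages, paths["messages"])
  readr::write_csv(sim$receipts, paths["receipts"], progress = FALSE)
  invisible(paths)
}
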