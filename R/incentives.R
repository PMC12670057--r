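#' Incentive adjudication configuration
#'
#' Bundles the tunable rules for weekly incentive adjudication. The rule
#' *structure* (a required logging frequency, a per-day calorie minimum,
#' phase-specific weigh-in schedules, a maintenance band around the
#' end-of-phase-I anchor, and a partial award in the combined arm when
#' exactly one criterion is met) is fixed; every numeric value is a
#' configurable default that a deployment should set from its protocol.
#' Award amounts are illustrative placeholders, in arbitrary currency
#' units.
#'
#' @param diet_days_required days per week of qualifying food logging
#'   required to meet the diet criterion (default 5).
#' @param min_kcal_per_logging_day a day counts as logged only when its
#'   total reaches this many kilocalories (default 500) -- a floor that
#'   filters token entries.
#' @param weighins_required_phase1,weighins_required_phase2 accepted
#'   weigh-in days required per week in phases I and II (defaults 2 and 1,
#'   matching the weighing schedule participants are asked to follow).
#' @param maintenance_band_fraction half-width of the symmetric phase II
#'   maintenance band around the anchor weight (default 0.02, i.e. stay
#'   within 2%).
#' @param amount_full weekly award when all applicable criteria are met.
#' @param amount_partial combined-arm award when exactly one of the two
#'   criteria is met; must be less than `amount_full`.
#' @param screening_threshold relative-deviation threshold used upstream
#'   by weight screening (default 0.03), carried here so one config object
#'   describes the whole weekly run.
#' @param phase1_rule `"ratchet"` (default): the phase I weight criterion
#'   requires a new all-time weekly low, preventing oscillation gaming;
#'   `"prior_week"`: any decrease versus the immediately prior weekly
#'   representative qualifies.
#' @return an `incentive_config` list.
#' @export
incentive_config <- function(diet_days_required = 5,
                             min_kcal_per_logging_day = 500,
                             weighins_required_phase1 = 2,
                             weighins_required_phase2 = 1,
                             maintenance_band_fraction = 0.02,
                             amount_full = 20,
                             amount_partial = 10,
                             screening_threshold = 0.03,
                             phase1_rule = c("ratchet", "prior_week")) {
  phase1_rule <- match.arg(phase1_rule)
  if (amount_partial >= amount_full) {
    abort("amount_partial must be less than amount_full.",
          class = "trialops_config_error")
  }
  if (amount_partial < 0 || amount_full < 0) {
    abort("Award amounts must be nonnegative.", class = "trialops_config_error")
  }
  if (maintenance_band_fraction <= 0 || maintenance_band_fraction >= 1) {
    abort("maintenance_band_fraction must be in (0, 1).",
          class = "trialops_config_error")
  }
  structure(
    list(
      diet_days_required = diet_days_required,
      min_kcal_per_logging_day = min_kcal_per_logging_day,
      weighins_required_phase1 = weighins_required_phase1,
      weighins_required_phase2 = weighins_required_phase2,
      maintenance_band_fraction = maintenance_band_fraction,
      amount_full = amount_full,
      amount_partial = amount_partial,
      screening_threshold = screening_threshold,
      phase1_rule = phase1_rule
    ),
    class = "incentive_config"
  )
}

weighins_required <- function(config, phase) {
  if_else(phase == "I", config$weighins_required_phase1,
          config$weighins_required_phase2)
}

#' Evaluate the weekly dietary-logging criterion
#'
#' A week meets the diet criterion when it contains at least
#' `diet_days_required` days with at least one food entry and a total of
#' at least `min_kcal_per_logging_day` kilocalories.
#'
#' @param diet_days tibble of one participant-week's diet days with
#'   `total_kcal` and `n_entries`.
#' @param config an [incentive_config()].
#' @return logical scalar.
#' @export
evaluate_diet_criterion <- function(diet_days, config = incentive_config()) {
  if (is.null(diet_days) || nrow(diet_days) == 0) return(FALSE)
  qualifying <- diet_days$n_entries >= 1 &
    diet_days$total_kcal >= config$min_kcal_per_logging_day
  sum(qualifying) >= config$diet_days_required
}

#' Evaluate the phase I weight-loss criterion
#'
#' Phase I rewards interim weight loss. Under the default ratchet rule the
#' criterion is met when (a) the week has at least the required number of
#' accepted weigh-in days and (b) the weekly representative weight is
#' strictly below the lowest prior weekly representative (the baseline
#' weight counts as the week-0 representative, so week 1 must undercut
#' baseline). The ratchet means oscillating around a plateau never pays.
#'
#' @param daily_weights numeric vector of this week's daily representative
#'   weights (one per accepted weigh-in day).
#' @param prior_reps numeric vector of weekly representatives observed so
#'   far, with the baseline weight first; weeks without weigh-ins simply
#'   contribute nothing.
#' @param config an [incentive_config()].
#' @return logical scalar.
#' @export
evaluate_weight_criterion_phase1 <- function(daily_weights, prior_reps,
                                             config = incentive_config()) {
  if (length(daily_weights) < config$weighins_required_phase1) return(FALSE)
  if (length(prior_reps) == 0) return(FALSE)
  comparator <- if (config$phase1_rule == "ratchet") {
    min(prior_reps)
  } else {
    prior_reps[length(prior_reps)]
  }
  mean(daily_weights) < comparator
}

#' Evaluate the phase II maintenance criterion
#'
#' Phase II rewards holding weight within a symmetric band around the
#' anchor -- the lowest weekly representative achieved in phase I. A
#' missing anchor (no accepted phase I weights) cannot be auto-adjudicated
#' and returns `NA`, which the weekly batch routes to manual review.
#'
#' @param daily_weights numeric vector of this week's daily representative
#'   weights.
#' @param anchor_kg the phase II anchor weight (kg), or `NA`.
#' @param config an [incentive_config()].
#' @return logical scalar, or `NA` when adjudication must be deferred.
#' @export
evaluate_weight_criterion_phase2 <- function(daily_weights, anchor_kg,
                                             config = incentive_config()) {
  if (is.na(anchor_kg)) return(NA)
  if (length(daily_weights) < config$weighins_required_phase2) return(FALSE)
  rep_wt <- mean(daily_weights)
  band <- anchor_kg * config$maintenance_band_fraction
  rep_wt >= anchor_kg - band && rep_wt <= anchor_kg + band
}

#' Decide one participant-week's incentive
#'
#' Applies the arm and phase payout rules to already-evaluated criteria:
#' the control arm and all phase III weeks pay nothing; the diet-only and
#' weight-only arms pay the full amount when their single criterion is
#' met; the combined arm pays in full when both criteria are met and a
#' partial amount when exactly one is. A criterion that could not be
#' auto-evaluated (`NA`) routes the decision to manual processing.
#'
#' @param participant_id participant identifier.
#' @param week_index study week (1..78).
#' @param arm one of `COMBINED`, `DIET_ONLY`, `WEIGHT_ONLY`, `CONTROL`.
#' @param diet_met,weight_met logical (or `NA` for deferred / not
#'   applicable per arm).
#' @param config an [incentive_config()].
#' @return a one-row `incentive_decision` tibble: `participant_id`,
#'   `week_index`, `phase`, `arm`, `diet_criterion_met`,
#'   `weight_criterion_met`, `amount`, `processing_mode`, `note`.
#' @export
#' @examples
#' decide_week("P001", 3, "COMBINED", diet_met = TRUE, weight_met = FALSE)
decide_week <- function(participant_id, week_index, arm,
                        diet_met = NA, weight_met = NA,
                        config = incentive_config()) {
  stopifnot(arm %in% ARMS)
  phase <- week_phase(week_index)
  diet_app <- arm %in% c("COMBINED", "DIET_ONLY")
  weight_app <- arm %in% c("COMBINED", "WEIGHT_ONLY")
  diet_met <- if (diet_app) diet_met else NA
  weight_met <- if (weight_app) weight_met else NA
  mode <- "AUTO"
  note <- ""
  amount <- 0
  if (arm == "CONTROL" || phase == "III") {
    note <- if (arm == "CONTROL") "control arm: no incentive" else
      "phase III: non-incentivized"
  } else {
    deferred <- (diet_app && is.na(diet_met)) || (weight_app && is.na(weight_met))
    if (deferred) {
      mode <- "MANUAL"
      note <- "criterion could not be auto-adjudicated; deferred to coordinator"
    } else {
      amount <- switch(arm,
        DIET_ONLY = if (isTRUE(diet_met)) config$amount_full else 0,
        WEIGHT_ONLY = if (isTRUE(weight_met)) config$amount_full else 0,
        COMBINED = {
          n_met <- sum(isTRUE(diet_met), isTRUE(weight_met))
          c(0, config$amount_partial, config$amount_full)[n_met + 1]
        }
      )
    }
  }
  out <- tibble(
    participant_id = participant_id,
    week_index = as.integer(week_index),
    phase = phase,
    arm = arm,
    diet_criterion_met = diet_met,
    weight_criterion_met = weight_met,
    amount = amount,
    processing_mode = mode,
    note = note
  )
  class(out) <- c("incentive_decision", class(out))
  out
}

#' Adjudicate all completed phase I/II weeks for a cohort
#'
#' The batch engine behind the weekly run: evaluates the diet and weight
#' criteria for every active, incentivized-arm participant for each
#' requested week and applies [decide_week()]. Only weights already marked
#' `ACCEPTED` by screening ever influence a decision. Deterministic given
#' its inputs.
#'
#' @param roster a validated roster.
#' @param screened screened weight records ([screen_weights()]).
#' @param diet diet-day tibble ([read_diet_log()]).
#' @param weeks integer vector of study weeks to adjudicate (phase I/II
#'   weeks only, i.e. 1..52; others are skipped).
#' @param config an [incentive_config()].
#' @param as_of only adjudicate weeks fully elapsed by this date
#'   (default: no limit).
#' @return an `incentive_decisions` tibble sorted by participant then
#'   week.
#' @export
adjudicate_weeks <- function(roster, screened, diet, weeks = 1:52,
                             config = incentive_config(), as_of = NULL) {
  roster <- validate_roster(roster)
  weeks <- intersect(as.integer(weeks), 1:52)
  daily <- collapse_daily(screened)
  weekly <- weekly_representatives(daily, roster)
  enroll <- setNames(roster$enrollment_date, roster$participant_id)

  diet <- diet |>
    mutate(week_index = date_to_week(.data$date, enroll[.data$participant_id]))

  decide_participant <- function(p) {
    cal <- study_calendar(p$enrollment_date)
    wk_tab <- weekly |> filter(.data$participant_id == p$participant_id)
    reps <- setNames(wk_tab$weight_kg, wk_tab$week_index)
    nd <- setNames(wk_tab$n_weighin_days, wk_tab$week_index)
    phase1_reps <- wk_tab |> filter(.data$week_index <= 26)
    anchor <- if (nrow(phase1_reps) > 0) min(phase1_reps$weight_kg) else NA_real_
    p_diet <- diet |> filter(.data$participant_id == p$participant_id)
    p_daily <- daily |> filter(.data$participant_id == p$participant_id) |>
      mutate(week_index = date_to_week(.data$date, p$enrollment_date))

    map_dfr(weeks, function(w) {
      week_end <- cal$end_date[w]
      if (!is.null(as_of) && week_end > as.Date(as_of)) return(NULL)
      if (!is_active(p, week_end)) return(NULL)
      phase <- week_phase(w)
      dw <- p_daily$weight_kg[p_daily$week_index == w & !is.na(p_daily$week_index)]
      diet_met <- evaluate_diet_criterion(
        p_diet |> filter(.data$week_index == w), config
      )
      weight_met <- if (phase == "I") {
        prior <- c(p$baseline_weight_kg,
                   unname(reps[as.integer(names(reps)) < w]))
        length(dw) >= config$weighins_required_phase1 &&
          evaluate_weight_criterion_phase1(dw, prior, config)
      } else {
        evaluate_weight_criterion_phase2(dw, anchor, config)
      }
      decide_week(p$participant_id, w, p$arm, diet_met, weight_met, config)
    })
  }

  active_incent <- roster |> filter(.data$arm %in% INCENTIVIZED_ARMS)
  out <- map_dfr(seq_len(nrow(active_incent)), function(i) {
    decide_participant(active_incent[i, ])
  })
  if (nrow(out) == 0) {
    out <- decide_week("x", 1, "CONTROL")[0, ]
  }
  out <- out |> arrange(.data$participant_id, .data$week_index)
  class(out) <- c("incentive_decisions", class(out))
  out
}

#' Run one weekly incentive batch
#'
#' Adjudicates the single study week ending on (or most recently before)
#' the given date for every active incentivized-arm participant, and
#' returns the decisions together with the payment queue -- the positive
#' awards, sorted by participant ID, ready for staff to load onto debit
#' cards.
#'
#' @param roster,screened,diet,config as in [adjudicate_weeks()].
#' @param week_ending calendar date; each participant's most recent study
#'   week ending on or before this date is adjudicated.
#' @return list with `decisions` (one per adjudicated participant-week)
#'   and `queue` (rows with `amount > 0`, sorted by `participant_id`).
#' @export
run_weekly_batch <- function(roster, screened, diet, week_ending,
                             config = incentive_config()) {
  roster <- validate_roster(roster)
  week_ending <- as.Date(week_ending)
  decisions <- map_dfr(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    if (!p$arm %in% INCENTIVIZED_ARMS) return(NULL)
    elapsed <- floor(as.numeric(week_ending - p$enrollment_date + 1) / 7)
    if (elapsed < 1 || elapsed > 52) return(NULL)
    adjudicate_weeks(p, screened |> filter(.data$participant_id == p$participant_id),
                     diet |> filter(.data$participant_id == p$participant_id),
                     weeks = elapsed, config = config, as_of = week_ending)
  })
  if (nrow(decisions) == 0) decisions <- decide_week("x", 1, "CONTROL")[0, ]
  decisions <- decisions |> arrange(.data$participant_id)
  class(decisions) <- c("incentive_decisions", class(decisions))
  list(
    decisions = decisions,
    queue = decisions |> filter(.data$amount > 0) |> arrange(.data$participant_id)
  )
}

#' Manually adjudicate a decision
#'
#' Coordinator override of an automated decision (for example after
#' verifying a disputed weight). The decision is re-marked `MANUAL`, the
#' justification is recorded, and the prior version is appended to the
#' decision's audit trail; the original is never destroyed. Overriding a
#' control-arm decision is refused -- the control arm is never paid.
#'
#' @param decision a one-row incentive decision.
#' @param note non-empty justification (adjudication must be documented).
#' @param amount optional overridden award.
#' @return the decision with `processing_mode = "MANUAL"` and an `audit`
#'   attribute (list of prior versions, oldest first).
#' @export
mark_manual <- function(decision, note, amount = NULL) {
  stopifnot(nrow(decision) == 1)
  if (missing(note) || !nzchar(trimws(note))) {
    abort("Manual adjudication requires a documented note.",
          class = "trialops_validation_error")
  }
  if (decision$arm == "CONTROL") {
    abort("Control-arm participants are never paid; override refused.",
          class = "trialops_validation_error")
  }
  audit <- c(attr(decision, "audit") %||% list(), list(as_tibble(decision)))
  out <- decision
  out$processing_mode <- "MANUAL"
  out$note <- note
  if (!is.null(amount)) out$amount <- amount
  attr(out, "audit") <- c(audit, list(as_tibble(out)))
  out
}

#' Write a weekly incentive report CSV
#' @param decisions incentive decisions.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_incentive_report <- function(decisions, file) {
  readr::write_csv(as_tibble(decisions), file, progress = FALSE)
  invisible(file)
}
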