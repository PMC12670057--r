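#' Tidy an operational summary
#'
#' Returns the scalar statistics as a long two-column tibble, one row per
#' statistic.
#'
#' @param x an `ops_summary`.
#' @param ... unused.
#' @return a tibble with columns `statistic`, `value`.
#' @method tidy ops_summary
#' @export
tidy.ops_summary <- function(x, ...) {
  scalars <- x[setdiff(names(x), "messages_by_weekday_and_type")]
  tibble(statistic = names(scalars), value = as.numeric(unlist(scalars)))
}

#' One-row glance at an operational summary
#'
#' @param x an `ops_summary`.
#' @param ... unused.
#' @return a one-row tibble of the scalar statistics.
#' @method glance ops_summary
#' @export
glance.ops_summary <- function(x, ...) {
  scalars <- x[setdiff(names(x), "messages_by_weekday_and_type")]
  as_tibble(scalars)
}

#' Tidy screened weight records
#'
#' @param x a `screened_weights` tibble.
#' @param ... unused.
#' @return per-participant screening counts: transmissions, accepted,
#'   rejected, acceptance fraction.
#' @method tidy screened_weights
#' @export
tidy.screened_weights <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$participant_id) |>
    summarise(
      n_weights = n(),
      n_accepted = sum(.data$status == "ACCEPTED"),
      n_rejected = sum(.data$status == "REJECTED"),
      acceptance = .data$n_accepted / .data$n_weights,
      .groups = "drop"
    )
}

#' Glance at screened weight records
#' @param x a `screened_weights` tibble.
#' @param ... unused.
#' @return a one-row tibble: totals and the overall acceptance fraction.
#' @method glance screened_weights
#' @export
glance.screened_weights <- function(x, ...) {
  tibble(
    n_weights = nrow(x),
    n_accepted = sum(x$status == "ACCEPTED"),
    n_rejected = sum(x$status == "REJECTED"),
    acceptance = if (nrow(x) > 0) sum(x$status == "ACCEPTED") / nrow(x) else NA_real_
  )
}

#' Tidy incentive decisions
#' @param x an `incentive_decisions` tibble.
#' @param ... unused.
#' @return per-arm totals: decisions, awards paid, total amount, manual
#'   fraction.
#' @method tidy incentive_decisions
#' @export
tidy.incentive_decisions <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$arm) |>
    summarise(
      n_decisions = n(),
      n_paid = sum(.data$amount > 0),
      total_amount = sum(.data$amount),
      manual_fraction = mean(.data$processing_mode == "MANUAL"),
      .groups = "drop"
    )
}

#' Glance at incentive decisions
#' @param x an `incentive_decisions` tibble.
#' @param ... unused.
#' @return a one-row tibble with totals and the auto-processing fraction.
#' @method glance incentive_decisions
#' @export
glance.incentive_decisions <- function(x, ...) {
  tibble(
    n_decisions = nrow(x),
    n_auto = sum(x$processing_mode == "AUTO"),
    n_manual = sum(x$processing_mode == "MANUAL"),
    total_amount = sum(x$amount),
    auto_fraction = if (nrow(x) > 0) mean(x$processing_mode == "AUTO") else NA_real_
  )
}

#' Plot message volume by weekday and type
#'
#' @param object an `ops_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ops_summary
#' @export
autoplot.ops_summary <- function(object, ...) {
  wd <- object$messages_by_weekday_and_type |>
    mutate(weekday = factor(.data$weekday, levels = WEEKDAYS))
  ggplot2::ggplot(wd, ggplot2::aes(x = .data$weekday, y = .data$n,
                                   fill = .data$mtype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "messages sent", fill = "type",
                  title = "Message volume by weekday") +
    ggplot2::theme_minimal()
}

#' Plot screened weight trajectories
#'
#' Accepted weights as connected trajectories, rejected transmissions as
#' crosses -- the view a coordinator uses to spot reference drift or a
#' household member on the scale.
#'
#' @param object a `screened_weights` tibble.
#' @param participants optional subset of participant IDs.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot screened_weights
#' @export
autoplot.screened_weights <- function(object, participants = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(participants)) {
    df <- df |> filter(.data$participant_id %in% participants)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp_utc,
                                   y = .data$weight_kg)) +
    ggplot2::geom_line(
      data = df |> filter(.data$status == "ACCEPTED"),
      color = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$status, shape = .data$status)) +
    ggplot2::scale_shape_manual(values = c(ACCEPTED = 16, REJECTED = 4)) +
    ggplot2::scale_color_manual(values = c(ACCEPTED = "#2c7fb8",
                                           REJECTED = "#d95f02")) +
    ggplot2::facet_wrap(~participant_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "weight (kg)") +
    ggplot2::theme_minimal()
}

#' Plot weekly award totals
#'
#' @param decisions an `incentive_decisions` tibble.
#' @return a ggplot of total awarded amount per study week, by arm.
#' @export
plot_weekly_awards <- function(decisions) {
  df <- as_tibble(decisions) |>
    group_by(.data$week_index, .data$arm) |>
    summarise(total = sum(.data$amount), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$week_index, y = .data$total,
                                   color = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "study week", y = "amount awarded", color = "arm") +
    ggplot2::theme_minimal()
}
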