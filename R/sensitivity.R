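# Sensitivity transforms on fitted dose events: spreading each bolus over a
# window of hours, and shifting bolus times, with difference metrics between
# the resulting prediction series.

#' Spread bolus doses over a time window
#'
#' For 2- and 8-hr spreads, each event is replaced by equal 15-min
#' sub-boluses, half of the window before and half after the event time. For
#' the 24-hr spread, all events of a subject's calendar day are summed and
#' distributed evenly over that day's 96 grid steps. Total daily dose is
#' conserved exactly.
#'
#' @param events Data frame of dose events (`time_min`, `dose_ug_kg`,
#'   optionally `subject_id`).
#' @param hours Spread duration: 2, 8 or 24.
#' @param grid_min Grid step in minutes (sub-bolus spacing).
#' @return A tibble of sub-bolus events (`subject_id` if present, `time_min`,
#'   `dose_ug_kg`, `spread_min = 0`), times clamped at 0.
#' @examples
#' ev <- tibble::tibble(time_min = 600, dose_ug_kg = 8)
#' spread_doses(ev, hours = 2)
#' @export
spread_doses <- function(events, hours, grid_min = 15) {
  if (!hours %in% c(2, 8, 24)) rlang::abort("hours must be 2, 8 or 24")
  has_id <- "subject_id" %in% names(events)
  if (!has_id) events$subject_id <- "s1"
  if (hours == 24) {
    daily <- events |>
      dplyr::mutate(day = event_day(.data$time_min)) |>
      dplyr::group_by(.data$subject_id, .data$day) |>
      dplyr::summarise(total = sum(.data$dose_ug_kg), .groups = "drop")
    n <- 1440 / grid_min
    out <- tibble::tibble(
      subject_id = rep(daily$subject_id, each = n),
      time_min = rep((daily$day - 1) * 1440, each = n) +
        rep(seq(0, 1440 - grid_min, by = grid_min), times = nrow(daily)),
      dose_ug_kg = rep(daily$total / n, each = n)
    )
  } else {
    n <- hours * 60 / grid_min
    out <- tibble::tibble(
      subject_id = rep(events$subject_id, each = n),
      time_min = rep(events$time_min, each = n) - hours * 30 +
        rep(seq_len(n) - 1, times = nrow(events)) * grid_min,
      dose_ug_kg = rep(events$dose_ug_kg / n, each = n)
    )
  }
  out <- out |>
    dplyr::mutate(time_min = pmax(.data$time_min, 0), spread_min = 0) |>
    dplyr::arrange(.data$subject_id, .data$time_min)
  if (!has_id) out$subject_id <- NULL
  out
}

#' Shift bolus dose times
#'
#' Moves every event time by `offset_min` minutes (e.g. +/- 120 to probe a
#' 2-hr uncertainty in exposure timing), clamping to the study bounds rather
#' than wrapping.
#'
#' @inheritParams spread_doses
#' @param offset_min Shift in minutes (positive = later).
#' @param bounds Study time bounds in minutes, `c(start, end)`.
#' @return The events with shifted `time_min`.
#' @export
shift_doses <- function(events, offset_min, bounds = c(0, Inf)) {
  dplyr::mutate(
    events,
    time_min = pmin(pmax(.data$time_min + offset_min, bounds[1]), bounds[2])
  )
}

#' Difference metrics between two predicted void series
#'
#' Compares two prediction series over matched voids (same times) and reports
#' the maximum and mean relative concentration difference per metabolite,
#' with the denominator floored to avoid 0/0. The metric is symmetric and
#' zero exactly when the series are identical.
#'
#' @param pred_a,pred_b Prediction tibbles from [pk_simulate()] over the same
#'   void schedule.
#' @param floor_ug_L Denominator floor in µg/L.
#' @return A tibble `metabolite`, `max_rel_diff`, `mean_rel_diff`,
#'   `max_abs_diff`.
#' @export
series_difference <- function(pred_a, pred_b, floor_ug_L = 1) {
  if (nrow(pred_a) != nrow(pred_b) ||
      any(pred_a$time_min != pred_b$time_min)) {
    rlang::abort("prediction series must cover the same voids")
  }
  mets <- sub("^conc_", "", grep("^conc_", names(pred_a), value = TRUE))
  purrr::map(mets, function(m) {
    a <- pred_a[[paste0("conc_", m)]]
    b <- pred_b[[paste0("conc_", m)]]
    rel <- abs(a - b) / pmax((a + b) / 2, floor_ug_L)
    tibble::tibble(metabolite = m, max_rel_diff = max(rel),
                   mean_rel_diff = mean(rel), max_abs_diff = max(abs(a - b)))
  }) |>
    purrr::list_rbind()
}
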