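# Person-day intake summaries of reconstructed (or true) exposure events.
# Events carry time_min (minutes from study start, where study start is local
# midnight of day 1), so clock time = time_min mod 1440 and calendar day =
# floor(time_min / 1440) + 1.

NIGHT_START_MIN <- 22 * 60 # 2200
NIGHT_END_MIN <- 5 * 60    # 0500 (half-open: 0500 itself is daytime)

clock_min <- function(time_min) time_min %% 1440

event_day <- function(time_min) floor(time_min / 1440) + 1

is_night <- function(time_min) {
  cm <- clock_min(time_min)
  cm >= NIGHT_START_MIN | cm < NIGHT_END_MIN
}

intake_bin <- function(intake) {
  cut(intake, breaks = c(-Inf, 0, 5.5, 10, 20, Inf),
      labels = c("0", "1-5", "6-10", "10-20", ">20"), right = TRUE)
}

#' Person-day intake table
#'
#' Sums event doses into daily intakes (µg/kg-day) per subject and calendar
#' day, including zero-exposure person-days, and bins each person-day into
#' the standard exposure ranges (0, 1–5, 6–10, 10–20, > 20 µg/kg-day).
#'
#' @param events Data frame of dose events with `time_min` and `dose_ug_kg`
#'   (and optionally `subject_id`).
#' @param n_days Number of study days per subject (person-days = subjects x
#'   days; days without events count as zero-exposure).
#' @param subject_ids Subjects to include (defaults to those present in
#'   `events`); subjects with no events contribute `n_days` zero days.
#' @return A tibble `subject_id`, `day`, `intake_ug_kg_day`, `bin`.
#' @examples
#' ev <- tibble::tibble(time_min = c(540, 1980), dose_ug_kg = c(5, 5))
#' daily_summary(ev, n_days = 2)
#' @export
daily_summary <- function(events, n_days, subject_ids = NULL) {
  if (!"subject_id" %in% names(events)) events$subject_id <- "s1"
  if (is.null(subject_ids)) subject_ids <- unique(events$subject_id)
  if (!length(subject_ids)) subject_ids <- "s1"
  grid <- tidyr::expand_grid(subject_id = as.character(subject_ids),
                             day = seq_len(n_days))
  per_day <- events |>
    dplyr::mutate(day = event_day(.data$time_min)) |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(intake_ug_kg_day = sum(.data$dose_ug_kg),
                     .groups = "drop")
  grid |>
    dplyr::left_join(per_day, by = c("subject_id", "day")) |>
    dplyr::mutate(
      intake_ug_kg_day = tidyr::replace_na(.data$intake_ug_kg_day, 0),
      bin = intake_bin(.data$intake_ug_kg_day)
    )
}

#' Cohort-level intake summary
#'
#' Collapses a [daily_summary()] table to the headline statistics: the mean
#' over all person-days, the average of per-subject medians, the count of
#' zero-exposure person-days, and the person-day counts per exposure bin.
#'
#' @param daily A tibble from [daily_summary()].
#' @return A one-row tibble: `n_person_days`, `mean_daily`, `median_daily`,
#'   `n_zero_days`, and `bin_*` counts.
#' @export
summarize_intake <- function(daily) {
  med <- daily |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(med = stats::median(.data$intake_ug_kg_day),
                     .groups = "drop")
  bins <- table(daily$bin)
  tibble::tibble(
    n_person_days = nrow(daily),
    mean_daily = mean(daily$intake_ug_kg_day),
    median_daily = mean(med$med),
    n_zero_days = sum(daily$intake_ug_kg_day == 0),
    bin_0 = unname(bins["0"]),
    bin_1_5 = unname(bins["1-5"]),
    bin_6_10 = unname(bins["6-10"]),
    bin_10_20 = unname(bins["10-20"]),
    bin_gt20 = unname(bins[">20"])
  )
}

#' Average hourly intake profile
#'
#' Assigns each event's dose to its clock hour and averages over person-days,
#' giving the mean intake attributable to each hour of the day. The 24 values
#' sum to the cohort's mean daily intake.
#'
#' @inheritParams daily_summary
#' @param n_person_days Total person-days of observation.
#' @return A tibble `hour` (0–23), `intake_ug_kg` (µg/kg per person-day).
#' @examples
#' ev <- tibble::tibble(time_min = 570, dose_ug_kg = 10) # 0930
#' hourly_profile(ev, n_person_days = 1)
#' @export
hourly_profile <- function(events, n_person_days) {
  if (n_person_days <= 0) rlang::abort("n_person_days must be positive")
  by_hour <- events |>
    dplyr::mutate(hour = floor(clock_min(.data$time_min) / 60)) |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(total = sum(.data$dose_ug_kg), .groups = "drop")
  tibble::tibble(hour = 0:23) |>
    dplyr::left_join(by_hour, by = "hour") |>
    dplyr::mutate(intake_ug_kg = tidyr::replace_na(.data$total, 0) /
                    n_person_days) |>
    dplyr::select("hour", "intake_ug_kg")
}

#' Nighttime exposure summary
#'
#' Events with clock time in the half-open window \[2200, 0500) count as
#' nighttime. Returns the nighttime event count, the average nighttime intake
#' per person-day, and the nighttime fraction of total intake.
#'
#' @inheritParams hourly_profile
#' @return A one-row tibble: `n_events`, `n_night_events`,
#'   `night_ug_kg_day`, `night_fraction`.
#' @examples
#' ev <- tibble::tibble(time_min = c(23.5 * 60, 2.75 * 60 + 1440),
#'                      dose_ug_kg = c(20, 10))
#' nighttime_summary(ev, n_person_days = 2)
#' @export
nighttime_summary <- function(events, n_person_days) {
  night <- is_night(events$time_min)
  total <- sum(events$dose_ug_kg)
  tibble::tibble(
    n_events = nrow(events),
    n_night_events = sum(night),
    night_ug_kg_day = sum(events$dose_ug_kg[night]) / n_person_days,
    night_fraction = if (total > 0) sum(events$dose_ug_kg[night]) / total else 0
  )
}

#' Concordance of exposure events with diary entries
#'
#' Flags each event as food-concordant when any food or beverage diary entry
#' of the same subject lies within the closed window of +/- `window_min`
#' minutes of the event time, and labels events as day or night.
#'
#' @inheritParams daily_summary
#' @param diary Data frame of diary entries: `time_min`, `category` (entries
#'   with category `"food"` or `"beverage"` count for concordance), and
#'   optionally `subject_id`.
#' @param window_min Half-width of the concordance window in minutes
#'   (closed: an entry exactly `window_min` away is concordant).
#' @return The events with added columns `night`, `concordant`, and
#'   `nearest_food_min` (signed minutes to the nearest food/beverage entry,
#'   `NA` when the subject has none).
#' @export
diary_concordance <- function(events, diary, window_min = 60) {
  if (!"subject_id" %in% names(events)) events$subject_id <- "s1"
  if (!"subject_id" %in% names(diary)) diary$subject_id <- "s1"
  food <- diary[diary$category %in% c("food", "beverage"), ]
  events |>
    dplyr::mutate(
      night = is_night(.data$time_min),
      nearest_food_min = purrr::map2_dbl(
        .data$subject_id, .data$time_min,
        function(id, t) {
          ft <- food$time_min[food$subject_id == id]
          if (!length(ft)) return(NA_real_)
          ft[which.min(abs(ft - t))] - t
        }
      ),
      concordant = !is.na(.data$nearest_food_min) &
        abs(.data$nearest_food_min) <= window_min
    )
}
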