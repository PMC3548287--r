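#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reconstruction: the fitted event table
#'
#' @param x A `dehp_recon` from [reconstruct_subject()].
#' @param ... Unused.
#' @return A tibble of fitted events: `subject_id`, `time_min`, `dose_ug_kg`,
#'   `spread_min`, `loss`, `window_open`, `window_close`, `kept` (`FALSE` for
#'   events pruned below the threshold).
#' @export
tidy.dehp_recon <- function(x, ...) {
  x$events
}

#' @rdname tidy.dehp_recon
#' @export
tidy.dehp_recon_cohort <- function(x, ...) {
  purrr::list_rbind(purrr::map(x$fits, tidy))
}

#' Glance at a reconstruction: one-row fit summary
#'
#' @param x A `dehp_recon` or `dehp_recon_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: number of kept and pruned events, mean and
#'   median daily intake (µg/kg-day), per-metabolite observed-vs-predicted
#'   Pearson correlations, and the log-scale RMSE.
#' @export
glance.dehp_recon <- function(x, ...) {
  s <- summarize_intake(x$daily)
  out <- tibble::tibble(
    subject_id = x$subject_id,
    n_events = sum(x$events$kept),
    n_pruned = sum(!x$events$kept),
    mean_daily = s$mean_daily,
    median_daily = s$median_daily,
    rmse_log = x$rmse_log
  )
  for (m in names(x$correlations)) {
    out[[paste0("r_", m)]] <- unname(x$correlations[m])
  }
  out
}

#' @rdname glance.dehp_recon
#' @export
glance.dehp_recon_cohort <- function(x, ...) {
  s <- summarize_intake(x$daily)
  rs <- purrr::map(x$fits, "correlations")
  cors <- purrr::map_dbl(names(rs[[1]]), function(m) {
    mean(purrr::map_dbl(rs, m), na.rm = TRUE)
  })
  out <- tibble::tibble(
    n_subjects = length(x$fits),
    n_events = nrow(x$events),
    n_person_days = s$n_person_days,
    mean_daily = s$mean_daily,
    median_daily = s$median_daily,
    n_zero_days = s$n_zero_days
  )
  for (i in seq_along(cors)) {
    out[[paste0("r_", names(rs[[1]])[i])]] <- cors[i]
  }
  out
}

#' @export
print.dehp_recon <- function(x, ...) {
  cat("DEHP dose reconstruction -- subject", x$subject_id, "\n")
  cat(sprintf("  %d voids over %d day(s); %d events kept, %d pruned (< %g ug/kg)\n",
              nrow(x$observed), x$n_days, sum(x$events$kept),
              sum(!x$events$kept), x$config$prune_threshold))
  s <- summarize_intake(x$daily)
  cat(sprintf("  daily intake: mean %.2f, median %.2f ug/kg-day\n",
              s$mean_daily, s$median_daily))
  cat("  observed-vs-predicted r:",
      paste(sprintf("%s %.3f", names(x$correlations), x$correlations),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.dehp_recon_cohort <- function(x, ...) {
  g <- glance(x)
  cat("DEHP dose reconstruction -- cohort of", g$n_subjects, "subjects\n")
  cat(sprintf("  %d events over %d person-days; mean %.2f, median %.2f ug/kg-day\n",
              g$n_events, g$n_person_days, g$mean_daily, g$median_daily))
  invisible(x)
}

#' @export
print.dehp_cohort <- function(x, ...) {
  cat("Synthetic DEHP biomonitoring cohort\n")
  cat(sprintf("  %d subjects x %d days = %d person-days; %d voids, %d true events (seed %s)\n",
              nrow(x$subjects), x$config$n_days,
              nrow(x$subjects) * x$config$n_days,
              nrow(x$voids), nrow(x$events), format(x$seed)))
  invisible(x)
}

long_conc <- function(df, value_name, mets) {
  df |>
    dplyr::select("time_min", dplyr::all_of(paste0("conc_", mets))) |>
    tidyr::pivot_longer(dplyr::starts_with("conc_"),
                        names_to = "metabolite", names_prefix = "conc_",
                        values_to = value_name)
}

#' Plot observed vs. predicted concentration series
#'
#' One panel per metabolite: observed void concentrations (points) and the
#' reconstructed model predictions (line) over the study period.
#'
#' @param object A `dehp_recon`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dehp_recon <- function(object, ...) {
  mets <- names(object$correlations)
  obs <- long_conc(object$observed, "observed", mets)
  pred <- long_conc(object$predictions, "predicted", mets)
  df <- dplyr::left_join(obs, pred, by = c("time_min", "metabolite"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min / 1440)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::labs(x = "Study day", y = "Urinary concentration (µg/L)",
                  title = paste("Observed (points) vs predicted (line) --",
                                object$subject_id))
}

#' Plot the average hourly intake profile
#'
#' @param profile A tibble from [hourly_profile()].
#' @return A ggplot bar chart of mean intake by clock hour.
#' @export
plot_hourly_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$hour,
                                        y = .data$intake_ug_kg)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "Hour of day",
                  y = "Mean intake (µg/kg per person-day)")
}
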