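# Inverse problem: reconstruct the timing and magnitude of DEHP intake events
# from measured void concentrations. The procedure automates what was
# historically done by trial and error: find concentration rises, postulate an
# exposure in the preceding inter-void interval, and fit its time and
# magnitude against the observed series.

#' Reconstruction configuration
#'
#' Tuning parameters of the automated dose reconstruction. The loss is a
#' weighted sum of squared errors on `log1p`-transformed concentrations over
#' all voids from the window opening to a look-ahead horizon. MEHP is
#' down-weighted by default: it carries the smallest share of the dose, is
#' eliminated fastest, and the calibrated model is known to overpredict it,
#' so the fit favours the oxidative metabolites (MEHHP, MEOHP, MECPP).
#'
#' @param weights Named non-negative loss weights per metabolite.
#' @param search_res_min Time-grid resolution of the event-time search (min).
#' @param dose_bounds Magnitude search bounds, µg/kg (lower bound must sit
#'   below `prune_threshold` so that spurious windows resolve to prunable
#'   events).
#' @param n_dose_grid Number of log-spaced magnitudes in the coarse search.
#' @param prune_threshold Events fitted below this dose (µg/kg) are pruned
#'   from the final solution (default 1, the stepwise-exclusion cut that
#'   leaves central-tendency estimates essentially unchanged).
#' @param lookahead_hr Fit horizon after the window opens (hours); the
#'   horizon is also truncated at the opening of the next candidate window so
#'   that later, not-yet-fitted exposures do not contaminate the loss.
#' @param rise_fold,rise_increment,rise_min_metabolites A window opens between
#'   consecutive voids when at least `rise_min_metabolites` metabolites rise
#'   by more than `rise_increment` µg/L and to more than `rise_fold` times the
#'   previous concentration (floored at `baseline_floor` µg/L).
#' @param baseline_floor Floor (µg/L) applied to the previous concentration in
#'   the fold test, so rises from near-zero baselines are detectable.
#' @param window_back_min Because metabolite appearance peaks ~2 hr after a
#'   dose, the first qualifying rise can land one void after the inter-void
#'   interval that actually contains the event; the time search therefore
#'   extends before the window opening by up to this many minutes (never past
#'   the previous void).
#' @param start_window Should a first void with concentrations above
#'   `rise_increment` open a window anchored at study start?
#' @param chain_tail_min Rises at voids opening within this many minutes of a
#'   cluster's first rising void are attributed to the same event's absorption
#'   tail (excretion peaks ~2 hr post dose, so an exposure keeps raising
#'   concentrations for several voids); one event is fitted per cluster, in
#'   its first window.
#' @param n_refine Number of refinement passes: each fitted event is re-fitted
#'   in its window with all other events held fixed and an untruncated
#'   look-ahead horizon, removing the bias the sequential first pass incurs
#'   when later events fall inside a fit horizon.
#' @param max_events Safety cap on the number of events fitted per subject.
#' @param lod Named limits of detection (µg/L); censored observations are
#'   imputed at `lod / sqrt(2)` for loss evaluation.
#' @param grid_min Simulation grid step (min).
#' @return A named list of class `fit_config`.
#' @export
fit_config <- function(weights = c(MEHP = 0.25, MEHHP = 1, MEOHP = 1, MECPP = 1),
                       search_res_min = 15,
                       dose_bounds = c(0.1, 200),
                       n_dose_grid = 25,
                       prune_threshold = 1,
                       lookahead_hr = 24,
                       rise_fold = 1.2,
                       rise_increment = 5,
                       window_back_min = 240,
                       rise_min_metabolites = 2,
                       baseline_floor = 5,
                       start_window = TRUE,
                       chain_tail_min = 240,
                       n_refine = 2,
                       max_events = 100,
                       lod = c(MEHP = 0.5, MEHHP = 0.5, MEOHP = 0.5, MECPP = 0.5),
                       grid_min = 15) {
  if (any(weights < 0) || all(weights == 0)) {
    rlang::abort("weights must be non-negative and not all zero")
  }
  if (prune_threshold < 0) rlang::abort("prune threshold must be >= 0")
  if (length(dose_bounds) != 2 || dose_bounds[1] <= 0 ||
      dose_bounds[2] <= dose_bounds[1]) {
    rlang::abort("dose_bounds must be positive and increasing")
  }
  structure(
    list(weights = weights, search_res_min = search_res_min,
         dose_bounds = dose_bounds, n_dose_grid = n_dose_grid,
         prune_threshold = prune_threshold, lookahead_hr = lookahead_hr,
         rise_fold = rise_fold, rise_increment = rise_increment,
         window_back_min = window_back_min,
         rise_min_metabolites = rise_min_metabolites,
         baseline_floor = baseline_floor, start_window = start_window,
         chain_tail_min = chain_tail_min, n_refine = n_refine,
         max_events = max_events, lod = lod, grid_min = grid_min),
    class = "fit_config"
  )
}

conc_matrix <- function(voids, metabolites) {
  cols <- paste0("conc_", metabolites)
  missing <- setdiff(cols, names(voids))
  if (length(missing)) {
    rlang::abort(paste0("voids lack concentration columns: ",
                        paste(missing, collapse = ", ")))
  }
  m <- as.matrix(voids[cols])
  colnames(m) <- metabolites
  m
}

# Impute censored observations at LOD/sqrt(2) where below_lod_* flags are set.
impute_lod <- function(voids, lod) {
  for (m in names(lod)) {
    flag_col <- paste0("below_lod_", m)
    conc_col <- paste0("conc_", m)
    if (flag_col %in% names(voids) && conc_col %in% names(voids)) {
      cens <- !is.na(voids[[flag_col]]) & voids[[flag_col]]
      voids[[conc_col]][cens] <- lod[[m]] / sqrt(2)
    }
  }
  voids
}

#' Detect candidate exposure windows from concentration rises
#'
#' Scans consecutive void pairs of each subject and opens a candidate window
#' (previous void time, rising void time) whenever enough metabolites rise by
#' more than the configured increment and fold. A sufficiently concentrated
#' first void may open a window anchored at study start. Because metabolite
#' appearance peaks hours after a dose, one exposure keeps concentrations
#' rising over several consecutive voids; chained rises opening within
#' `chain_tail_min` of a cluster's first rising void are therefore collapsed
#' to the cluster's first window, so one event yields one window. An exposure
#' event is then assumed to have occurred inside each returned window.
#'
#' @param voids A data frame of voids with `time_min`, `volume_L` and
#'   `conc_<metabolite>` columns; an optional `subject_id` column groups
#'   subjects.
#' @param config A [fit_config()].
#' @return A tibble with columns `subject_id`, `open_min`, `close_min`,
#'   `n_rising`, `trigger` (comma-separated rising metabolites). Empty when
#'   no rises qualify.
#' @export
detect_windows <- function(voids, config = fit_config()) {
  if (!"subject_id" %in% names(voids)) voids$subject_id <- "s1"
  voids |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    purrr::map(function(v) {
      cluster_windows(detect_windows_one(v, config), config$chain_tail_min)
    }) |>
    purrr::list_rbind()
}

detect_windows_one <- function(voids, config) {
  voids <- dplyr::arrange(voids, .data$time_min)
  mets <- names(config$weights)
  conc <- conc_matrix(voids, mets)
  n <- nrow(voids)
  out <- list()

  if (config$start_window && n >= 1) {
    first <- conc[1, ]
    rising <- !is.na(first) & first >= config$rise_increment
    if (sum(rising) >= config$rise_min_metabolites) {
      out[[length(out) + 1]] <- tibble::tibble(
        subject_id = voids$subject_id[1],
        open_min = 0, close_min = voids$time_min[1],
        n_rising = sum(rising),
        trigger = paste(mets[rising], collapse = ",")
      )
    }
  }
  if (n >= 2) {
    for (i in 2:n) {
      prev <- conc[i - 1, ]
      cur <- conc[i, ]
      ok <- !is.na(prev) & !is.na(cur)
      rising <- ok &
        (cur - prev) >= config$rise_increment &
        cur >= config$rise_fold * pmax(prev, config$baseline_floor)
      if (sum(rising) >= config$rise_min_metabolites) {
        out[[length(out) + 1]] <- tibble::tibble(
          subject_id = voids$subject_id[1],
          open_min = voids$time_min[i - 1], close_min = voids$time_min[i],
          n_rising = sum(rising),
          trigger = paste(mets[rising], collapse = ",")
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(subject_id = character(), open_min = numeric(),
                          close_min = numeric(), n_rising = integer(),
                          trigger = character()))
  }
  purrr::list_rbind(out)
}

# Group chained windows: a window whose opening void lies within
# chain_tail_min of the cluster's first rising void is the same event's
# absorption tail. Returns one row per cluster: the first window, which is
# where the event is fitted.
cluster_windows <- function(windows, chain_tail_min) {
  if (!nrow(windows)) return(windows)
  windows <- dplyr::arrange(windows, .data$open_min)
  cluster <- integer(nrow(windows))
  cluster[1] <- 1L
  anchor_close <- windows$close_min[1]
  for (i in seq_len(nrow(windows))[-1]) {
    if (windows$open_min[i] < anchor_close + chain_tail_min) {
      cluster[i] <- cluster[i - 1]
    } else {
      cluster[i] <- cluster[i - 1] + 1L
      anchor_close <- windows$close_min[i]
    }
  }
  windows[!duplicated(cluster), , drop = FALSE]
}

# Flag voids whose observed concentrations exceed the model prediction by
# the rise rule: excess >= rise_increment and obs >= rise_fold * prediction
# (floored), in at least rise_min_metabolites metabolites.
flag_unexplained <- function(obs_m, pred_m, config) {
  excess <- obs_m - pred_m
  hit <- !is.na(obs_m) &
    excess >= config$rise_increment &
    obs_m >= config$rise_fold * pmax(pred_m, config$baseline_floor)
  rowSums(hit) >= config$rise_min_metabolites
}

# Weighted SSE on log1p concentrations between predicted and observed
# matrices (voids x metabolites); NAs in obs are skipped.
recon_loss <- function(pred, obs, weights) {
  d <- log1p(pmax(pred, 0)) - log1p(obs)
  w <- matrix(weights, nrow(obs), length(weights), byrow = TRUE)
  sum(w * d^2, na.rm = TRUE)
}

#' Fit one exposure event inside a candidate window
#'
#' Grid search over event times on the search grid inside the window crossed
#' with a coarse log-spaced magnitude grid, followed by 1-D refinement of the
#' magnitude (via [stats::optimize()] on log-dose) at each candidate time.
#' The loss is the weighted `log1p` SSE over all voids from the window opening
#' to `horizon_end_min`. Earlier fitted events enter through `prior_events`
#' and are held fixed. Deterministic; ties break to the smaller dose, then
#' the earlier time.
#'
#' @param voids Single-subject voids with observed concentrations.
#' @param window One row of [detect_windows()] output (list or one-row tibble
#'   with `open_min`, `close_min`).
#' @param prior_events Data frame of already-fitted events (possibly empty).
#' @inheritParams pk_simulate
#' @param config A [fit_config()].
#' @param horizon_end_min Last void time included in the loss (defaults to
#'   `open_min + lookahead_hr`).
#' @return A one-row tibble: `time_min`, `dose_ug_kg`, `spread_min = 0`,
#'   `loss`, `window_open`, `window_close`.
#' @export
fit_window <- function(voids, window, prior_events, specs,
                       config = fit_config(), body_weight_kg = 70,
                       horizon_end_min = NULL) {
  open <- window$open_min
  close <- window$close_min
  if (is.null(horizon_end_min)) {
    horizon_end_min <- open + config$lookahead_hr * 60
  }
  horizon_end_min <- min(horizon_end_min, open + config$lookahead_hr * 60)

  # extend the search before the window opening (appearance lag can push the
  # first qualifying rise one void late), but never past the previous void
  prev_voids <- voids$time_min[voids$time_min < open]
  ext_open <- max(if (length(prev_voids)) max(prev_voids) else 0,
                  open - config$window_back_min)
  ext_open <- max(ext_open, 0)

  res <- config$search_res_min
  cand <- seq(snap_to_grid(ext_open, res), close - res, by = res)
  if (!length(cand)) cand <- snap_to_grid(ext_open, res)
  cand <- unique(pmax(cand, 0))
  if (!length(cand)) rlang::abort("empty feasible time grid for window")

  mets <- names(config$weights)
  in_horizon <- voids$time_min > ext_open & voids$time_min <= horizon_end_min
  if (!any(in_horizon)) in_horizon <- voids$time_min >= close
  obs <- conc_matrix(voids[in_horizon, ], mets)
  w <- config$weights[mets]

  sched <- voids[c("time_min", "volume_L")]
  base <- pk_simulate(sched, prior_events, specs, body_weight_kg,
                      config$grid_min)
  base_m <- conc_matrix(base, mets)[in_horizon, , drop = FALSE]

  lb <- log(config$dose_bounds[1])
  ub <- log(config$dose_bounds[2])
  coarse <- seq(lb, ub, length.out = config$n_dose_grid)

  best <- list(loss = Inf, dose = Inf, time = Inf)
  for (tc in cand) {
    unit <- pk_simulate(
      sched, tibble::tibble(time_min = tc, dose_ug_kg = 1, spread_min = 0),
      specs, body_weight_kg, config$grid_min
    )
    u <- conc_matrix(unit, mets)[in_horizon, , drop = FALSE]
    f <- function(ld) recon_loss(base_m + exp(ld) * u, obs, w)
    losses <- vapply(coarse, f, numeric(1))
    j <- which.min(losses)
    lo <- coarse[max(1L, j - 1L)]
    hi <- coarse[min(length(coarse), j + 1L)]
    opt <- stats::optimize(f, interval = c(lo, hi), tol = 1e-7)
    cand_loss <- opt$objective
    cand_dose <- exp(opt$minimum)
    # also consider the exact bounds (optimize never returns the endpoints)
    for (ld in c(lb, ub)) {
      fl <- f(ld)
      if (fl < cand_loss) {
        cand_loss <- fl
        cand_dose <- exp(ld)
      }
    }
    if (cand_loss < best$loss - 1e-12 ||
        (abs(cand_loss - best$loss) <= 1e-12 && cand_dose < best$dose - 1e-9)) {
      best <- list(loss = cand_loss, dose = cand_dose, time = tc)
    }
  }

  tibble::tibble(
    time_min = best$time, dose_ug_kg = best$dose, spread_min = 0,
    loss = best$loss, window_open = open, window_close = close
  )
}

#' Prune small fitted exposure events
#'
#' Removes events with dose below the threshold, preserving order. Small
#' fitted events are plausible artifacts of second-phase metabolism from
#' earlier exposures rather than genuine new intakes, and removing those
#' below 1 µg/kg leaves central-tendency intake estimates essentially
#' unchanged.
#'
#' @param events A data frame of dose events with a `dose_ug_kg` column.
#' @param threshold Pruning threshold in µg/kg (>= 0); events with
#'   `dose_ug_kg >= threshold` are retained.
#' @return The retained events (same columns, original order).
#' @examples
#' ev <- tibble::tibble(time_min = c(0, 60, 120), dose_ug_kg = c(0.5, 1.2, 3))
#' prune_events(ev, 1)
#' @export
prune_events <- function(events, threshold = 1) {
  if (threshold < 0) rlang::abort("threshold must be >= 0")
  events[events$dose_ug_kg >= threshold, , drop = FALSE]
}

#' Reconstruct the exposure history of one subject
#'
#' Runs the full inverse procedure: impute censored observations, detect
#' candidate windows, fit one event per window in time order (each fitted
#' event joins the baseline for later windows), prune events below the
#' threshold, and re-simulate the retained events to produce final
#' predictions, residual summaries, observed-vs-predicted correlations, and
#' person-day intakes.
#'
#' @param voids Single-subject void records: `time_min`, `volume_L`,
#'   `conc_<metabolite>` columns (optionally `below_lod_<metabolite>` flags).
#' @inheritParams fit_window
#' @param diary Optional diary entries (`time_min`, `category`) carried into
#'   the result for concordance reporting.
#' @param subject_id Subject label; taken from the data when present.
#' @return An object of class `dehp_recon`; see [tidy.dehp_recon()],
#'   [glance.dehp_recon()] and [autoplot.dehp_recon()].
#' @examples
#' \donttest{
#' specs <- metabolite_specs()
#' voids <- tibble::tibble(time_min = seq(120, 1380, by = 120), volume_L = 0.25)
#' truth <- tibble::tibble(time_min = 540, dose_ug_kg = 12, spread_min = 0)
#' obs <- pk_simulate(voids, truth, specs)
#' fit <- reconstruct_subject(obs, specs)
#' tidy(fit)
#' }
#' @export
reconstruct_subject <- function(voids, specs = metabolite_specs(),
                                config = fit_config(), body_weight_kg = 70,
                                diary = NULL, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- if ("subject_id" %in% names(voids)) {
      as.character(voids$subject_id[1])
    } else "s1"
  }
  voids <- dplyr::arrange(voids, .data$time_min)
  if (any(voids$volume_L <= 0)) rlang::abort("void volumes must be positive")
  voids <- impute_lod(voids, config$lod)

  windows <- detect_windows_one(
    dplyr::mutate(voids, subject_id = subject_id), config
  )

  # Sequential residual detection and fitting: simulate the events fitted so
  # far, find the earliest void whose observed concentrations exceed that
  # prediction by the rise rule, fit one event in the preceding inter-void
  # interval, and repeat. Referencing rises to the running model (rather
  # than to the previous void) keeps explained rises -- overnight bladder
  # accumulation, absorption tails of already-fitted events -- from spawning
  # spurious events.
  sched <- voids[c("time_min", "volume_L")]
  mets <- names(config$weights)
  obs_m <- conc_matrix(voids, mets)
  fitted <- tibble::tibble(
    time_min = numeric(), dose_ug_kg = numeric(), spread_min = numeric(),
    loss = numeric(), window_open = numeric(), window_close = numeric()
  )
  last_idx <- 0L
  repeat {
    if (nrow(fitted) >= config$max_events) break
    pred <- pk_simulate(sched, fitted[c("time_min", "dose_ug_kg",
                                        "spread_min")],
                        specs, body_weight_kg, config$grid_min)
    pred_m <- conc_matrix(pred, mets)
    flags <- flag_unexplained(obs_m, pred_m, config)
    if (!config$start_window) flags[1] <- FALSE
    nxt <- which(flags & seq_along(flags) > last_idx)
    if (!length(nxt)) break
    nxt <- nxt[1]
    open <- if (nxt == 1) 0 else voids$time_min[nxt - 1]
    close <- voids$time_min[nxt]
    # truncate the fit horizon before the next distant unexplained rise,
    # which most likely belongs to a later, not-yet-fitted event
    later <- which(flags & voids$time_min >= close + config$chain_tail_min)
    horizon_end <- if (length(later)) {
      max(close, voids$time_min[later[1] - 1])
    } else {
      open + config$lookahead_hr * 60
    }
    ev <- fit_window(voids, list(open_min = open, close_min = close),
                     fitted[c("time_min", "dose_ug_kg", "spread_min")],
                     specs, config, body_weight_kg, horizon_end)
    fitted <- dplyr::bind_rows(fitted, ev)
    last_idx <- nxt
  }

  # Refinement: re-fit each event in its window with every other event fixed
  # and the full look-ahead horizon.
  if (nrow(fitted)) {
    for (pass in seq_len(config$n_refine)) {
      for (i in seq_len(nrow(fitted))) {
        others <- fitted[-i, c("time_min", "dose_ug_kg", "spread_min")]
        ev <- fit_window(voids,
                         list(open_min = fitted$window_open[i],
                              close_min = fitted$window_close[i]),
                         others, specs, config, body_weight_kg)
        fitted[i, names(ev)] <- ev
      }
    }
  }
  fitted$kept <- fitted$dose_ug_kg >= config$prune_threshold
  kept <- fitted[fitted$kept, c("time_min", "dose_ug_kg", "spread_min")]

  pred <- pk_simulate(voids[c("time_min", "volume_L")], kept, specs,
                      body_weight_kg, config$grid_min)
  mets <- names(config$weights)
  obs_m <- conc_matrix(voids, mets)
  pred_m <- conc_matrix(pred, mets)
  correlations <- vapply(seq_along(mets), function(j) {
    ok <- !is.na(obs_m[, j])
    if (sum(ok) < 3 || stats::sd(obs_m[ok, j]) == 0 ||
        stats::sd(pred_m[ok, j]) == 0) {
      return(NA_real_)
    }
    stats::cor(obs_m[ok, j], pred_m[ok, j])
  }, numeric(1))
  names(correlations) <- mets
  rmse_log <- sqrt(mean((log1p(pred_m) - log1p(obs_m))^2, na.rm = TRUE))

  n_days <- max(1, ceiling(max(voids$time_min) / 1440))
  events <- dplyr::mutate(fitted, subject_id = subject_id, .before = 1)

  structure(
    list(
      subject_id = subject_id,
      events = events,
      windows = windows,
      predictions = pred,
      observed = voids,
      correlations = correlations,
      rmse_log = rmse_log,
      daily = daily_summary(events[events$kept, ], n_days = n_days,
                            subject_ids = subject_id),
      diary = diary,
      config = config,
      body_weight_kg = body_weight_kg,
      n_days = n_days
    ),
    class = "dehp_recon"
  )
}

#' Reconstruct a multi-subject cohort
#'
#' Applies [reconstruct_subject()] to each subject and collects per-subject
#' fits plus a combined event table for cohort summaries
#' ([daily_summary()], [hourly_profile()], [nighttime_summary()],
#' [diary_concordance()]).
#'
#' @param voids Void records for all subjects (must carry `subject_id`).
#' @param subject_tbl A tibble from [subjects()] giving sex and body weight
#'   per subject; defaults to 70-kg males for unknown ids.
#' @inheritParams reconstruct_subject
#' @return An object of class `dehp_recon_cohort` with elements `fits` (named
#'   list of `dehp_recon`), `events` (kept events, all subjects), `daily`,
#'   `n_person_days`.
#' @export
reconstruct_cohort <- function(voids, subject_tbl = NULL,
                               specs = metabolite_specs(),
                               config = fit_config(), diary = NULL) {
  if (!"subject_id" %in% names(voids)) {
    rlang::abort("cohort voids must carry subject_id")
  }
  ids <- unique(voids$subject_id)
  if (is.null(subject_tbl)) subject_tbl <- subjects(ids)
  fits <- purrr::map(ids, function(id) {
    bw <- subject_tbl$body_weight_kg[match(id, subject_tbl$subject_id)]
    if (is.na(bw)) bw <- 70
    d <- if (!is.null(diary)) diary[diary$subject_id == id, ] else NULL
    reconstruct_subject(voids[voids$subject_id == id, ], specs, config,
                        body_weight_kg = bw, diary = d, subject_id = id)
  })
  names(fits) <- ids
  events <- purrr::map(fits, function(f) f$events[f$events$kept, ]) |>
    purrr::list_rbind()
  n_days <- max(purrr::map_dbl(fits, "n_days"))
  daily <- daily_summary(events, n_days = n_days, subject_ids = ids)
  structure(
    list(fits = fits, events = events, daily = daily,
         subjects = subject_tbl, n_days = n_days,
         n_person_days = n_days * length(ids)),
    class = "dehp_recon_cohort"
  )
}
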