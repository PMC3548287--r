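specs <- metabolite_specs()

test_that("no windows open on a strictly decreasing concentration series", {
  voids <- tibble::tibble(
    time_min = seq(120, 1200, by = 120), volume_L = 0.25,
    conc_MEHP = seq(200, 20, length.out = 10),
    conc_MEHHP = seq(300, 30, length.out = 10),
    conc_MEOHP = seq(250, 25, length.out = 10),
    conc_MECPP = seq(280, 28, length.out = 10)
  )
  cfg <- fit_config(start_window = FALSE)
  expect_equal(nrow(detect_windows(voids, cfg)), 0)
})

test_that("a concordant multi-metabolite jump opens one window between those voids", {
  conc <- c(12, 10, 10, 230, 180)
  voids <- tibble::tibble(
    time_min = c(120, 300, 480, 600, 780), volume_L = 0.25,
    conc_MEHP = conc * 0.2, conc_MEHHP = conc,
    conc_MEOHP = conc * 0.8, conc_MECPP = conc * 1.1
  )
  w <- detect_windows(voids, fit_config(start_window = FALSE))
  expect_equal(nrow(w), 1)
  expect_equal(w$open_min, 480)
  expect_equal(w$close_min, 600)
  expect_match(w$trigger, "MEHHP")
})

test_that("an injected event is detected as exactly one window spanning the right voids", {
  voids <- tibble::tibble(time_min = seq(120, 1440, by = 120), volume_L = 0.25)
  doses <- tibble::tibble(time_min = 400, dose_ug_kg = 15, spread_min = 0)
  pred <- pk_simulate(voids, doses, specs, 70)
  # the event lies between voids 3 (t=360) and 4 (t=480)
  w <- detect_windows(pred, fit_config(start_window = FALSE))
  expect_equal(nrow(w), 1)
  expect_equal(w$open_min, 360)
  expect_equal(w$close_min, 480)
})

test_that("fitting a flat series lands on the lower dose bound, which is then pruned", {
  voids <- tibble::tibble(
    time_min = seq(120, 1440, by = 120), volume_L = 0.25,
    conc_MEHP = 0, conc_MEHHP = 0, conc_MEOHP = 0, conc_MECPP = 0
  )
  cfg <- fit_config()
  ev <- fit_window(voids, list(open_min = 360, close_min = 480),
                   prior_events = NULL, specs, cfg)
  expect_equal(ev$dose_ug_kg, cfg$dose_bounds[1])
  expect_equal(nrow(prune_events(ev, cfg$prune_threshold)), 0)
})

test_that("fit_window recovers a noise-free event exactly and is deterministic", {
  voids <- tibble::tibble(time_min = seq(120, 1440, by = 120), volume_L = 0.25)
  truth <- tibble::tibble(time_min = 405, dose_ug_kg = 9, spread_min = 0)
  obs <- pk_simulate(voids, truth, specs, 70)
  cfg <- fit_config()
  ev <- fit_window(obs, list(open_min = 360, close_min = 480), NULL, specs, cfg)
  expect_equal(ev$time_min, 405) # within +/- one 15-min grid step (exact here)
  expect_equal(ev$dose_ug_kg, 9, tolerance = 0.05)
  ev2 <- fit_window(obs, list(open_min = 360, close_min = 480), NULL, specs, cfg)
  expect_identical(ev, ev2)
})

test_that("MEHP down-weighting keeps fits accurate when the MEHP channel is corrupted", {
  voids <- tibble::tibble(time_min = seq(120, 1440, by = 120), volume_L = 0.25)
  truth <- tibble::tibble(time_min = 405, dose_ug_kg = 9, spread_min = 0)
  obs <- pk_simulate(voids, truth, specs, 70)
  obs$conc_MEHP <- obs$conc_MEHP * 2
  ev <- fit_window(obs, list(open_min = 360, close_min = 480), NULL, specs,
                   fit_config())
  expect_equal(ev$dose_ug_kg, 9, tolerance = 0.10)
})

test_that("prune_events filters by threshold and preserves order", {
  ev <- tibble::tibble(time_min = c(0, 60, 120), dose_ug_kg = c(0.5, 1.2, 3))
  expect_equal(prune_events(ev, 1)$dose_ug_kg, c(1.2, 3))
  expect_identical(prune_events(ev, 0), ev)
  expect_error(prune_events(ev, -1), ">= 0")
})

test_that("stepwise pruning monotonically reduces event count and mean daily intake", {
  withr::local_seed(5)
  ev <- tibble::tibble(
    time_min = sort(sample(0:(7 * 96 - 1), 40)) * 15,
    dose_ug_kg = stats::rlnorm(40, log(3), 1)
  )
  counts <- intakes <- numeric(4)
  for (i in seq_along(0:3)) {
    kept <- prune_events(ev, c(0, 1, 2, 3)[i])
    counts[i] <- nrow(kept)
    intakes[i] <- summarize_intake(daily_summary(kept, 7))$mean_daily
  }
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(intakes) <= 0))
  expect_lt(counts[4], counts[1])
})

test_that("an all-zero concentration series reconstructs to zero intake", {
  voids <- tibble::tibble(
    time_min = seq(120, 2880, by = 240), volume_L = 0.3,
    conc_MEHP = 0, conc_MEHHP = 0, conc_MEOHP = 0, conc_MECPP = 0
  )
  fit <- reconstruct_subject(voids, specs)
  expect_equal(sum(fit$events$kept), 0)
  expect_equal(sum(fit$daily$intake_ug_kg_day), 0)
})

test_that("noise-free reconstruction recovers every well-separated event", {
  rs <- recovery_subject()
  obs <- pk_simulate(rs$voids, rs$truth, specs, 70)
  fit <- reconstruct_subject(obs, specs)
  kept <- dplyr::filter(tidy(fit), kept)
  expect_equal(nrow(kept), nrow(rs$truth))
  for (i in seq_len(nrow(rs$truth))) {
    j <- which.min(abs(kept$time_min - rs$truth$time_min[i]))
    expect_lte(abs(kept$time_min[j] - rs$truth$time_min[i]), 15)
    expect_equal(kept$dose_ug_kg[j], rs$truth$dose_ug_kg[i], tolerance = 0.05)
  }
  # self-consistency: near-perfect observed-vs-predicted correlation
  expect_true(all(fit$correlations > 0.99))
  # determinism: identical rerun
  fit2 <- reconstruct_subject(obs, specs)
  expect_identical(tidy(fit), tidy(fit2))
  # sequential-fit consistency: re-simulating the kept events reproduces the
  # reported predictions exactly
  resim <- pk_simulate(rs$voids, kept[c("time_min", "dose_ug_kg", "spread_min")],
                       specs, 70)
  expect_identical(fit$predictions$conc_MECPP, resim$conc_MECPP)
})

test_that("glance and tidy expose the fit summary", {
  rs <- recovery_subject()
  obs <- pk_simulate(rs$voids, rs$truth[1:4, ], specs, 70)
  fit <- reconstruct_subject(obs, specs)
  g <- glance(fit)
  expect_equal(g$n_events, sum(tidy(fit)$kept))
  expect_true(all(c("mean_daily", "median_daily", "r_MECPP") %in% names(g)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("daily_summary totals, bins and zero days follow the conventions", {
  ev <- tibble::tibble(time_min = c(540, 600), dose_ug_kg = c(5, 5))
  d <- daily_summary(ev, n_days = 2)
  expect_equal(d$intake_ug_kg_day, c(10, 0))
  expect_equal(as.character(d$bin), c("6-10", "0"))
  s <- summarize_intake(d)
  expect_equal(s$n_zero_days, 1)
  expect_equal(s$mean_daily, 5)
})

test_that("hourly profile assigns doses to clock hours and sums to the daily mean", {
  ev <- tibble::tibble(time_min = c(570, 570 + 1440), dose_ug_kg = c(10, 14))
  hp <- hourly_profile(ev, n_person_days = 2)
  expect_equal(hp$intake_ug_kg[hp$hour == 9], 12)
  expect_equal(sum(hp$intake_ug_kg), 12)
  expect_equal(sum(hp$intake_ug_kg),
               summarize_intake(daily_summary(ev, 2))$mean_daily)
})

test_that("nighttime window 2200-0500 is half-open", {
  ev <- tibble::tibble(
    time_min = c(23.5 * 60, 1440 + 2.75 * 60, 5 * 60, 12 * 60),
    dose_ug_kg = c(20, 10, 5, 5)
  )
  ns <- nighttime_summary(ev, n_person_days = 2)
  expect_equal(ns$n_night_events, 2) # 2330 and 0245 yes; 0500 exactly is daytime
  expect_equal(ns$night_ug_kg_day, 15)
  expect_equal(ns$night_fraction, 30 / 40)
  noon <- nighttime_summary(tibble::tibble(time_min = 720, dose_ug_kg = 3), 1)
  expect_equal(noon$night_fraction, 0)
})

test_that("diary concordance uses a closed +/- 60 min window on food and beverage", {
  ev <- tibble::tibble(time_min = c(720, 1440 + 180, 2880 + 600),
                       dose_ug_kg = c(5, 8, 2))
  diary <- tibble::tibble(
    time_min = c(750, 2880 + 540, 2880 + 660),
    category = c("food", "driving", "food"),
    label = c("lunch", "commute", "brunch")
  )
  cc <- diary_concordance(ev, diary)
  expect_equal(cc$concordant, c(TRUE, FALSE, TRUE))
  expect_true(cc$night[2]) # 0300 event, empty nighttime diary: unmatched
  # boundary: exactly 60 min away is concordant
  cc2 <- diary_concordance(tibble::tibble(time_min = 690, dose_ug_kg = 1), diary)
  expect_true(cc2$concordant)
})
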