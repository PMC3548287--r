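test_that("the default cohort has the study's design shape", {
  coh <- generate_cohort(cohort_config(), seed = 101)
  expect_equal(nrow(coh$subjects), 8)
  expect_equal(sum(coh$subjects$sex == "M"), 4)
  expect_equal(unique(coh$subjects$body_weight_kg[coh$subjects$sex == "M"]), 70)
  expect_equal(unique(coh$subjects$body_weight_kg[coh$subjects$sex == "F"]), 60)
  expect_equal(nrow(coh$subjects) * coh$config$n_days, 56)
  # expected ~427 voids; stays within 15% across seeds
  for (s in c(101, 202, 303)) {
    n <- nrow(generate_cohort(cohort_config(), seed = s)$voids)
    expect_gt(n, 427 * 0.85)
    expect_lt(n, 427 * 1.15)
  }
  expect_true(all(coh$events$dose_ug_kg >= 1 & coh$events$dose_ug_kg <= 60))
})

test_that("generation is reproducible from the seed", {
  a <- generate_cohort(cohort_config(n_subjects = 2, n_days = 3), seed = 7)
  b <- generate_cohort(cohort_config(n_subjects = 2, n_days = 3), seed = 7)
  expect_identical(a$voids, b$voids)
  expect_identical(a$events, b$events)
  expect_identical(a$diary, b$diary)
  c <- generate_cohort(cohort_config(n_subjects = 2, n_days = 3), seed = 8)
  expect_false(identical(a$voids, c$voids))
})

test_that("noise-free, uncensored observations equal the model prediction exactly", {
  cfg <- cohort_config(n_subjects = 2, n_days = 3, noise_cv = 0,
                       lod = c(MEHP = 0, MEHHP = 0, MEOHP = 0, MECPP = 0))
  coh <- generate_cohort(cfg, seed = 5)
  for (m in c("MEHP", "MEHHP", "MEOHP", "MECPP")) {
    expect_identical(coh$voids[[paste0("conc_", m)]],
                     coh$voids[[paste0("true_conc_", m)]])
    expect_false(any(coh$voids[[paste0("below_lod_", m)]]))
  }
})

test_that("ground-truth events summarise to the generator's daily intakes", {
  coh <- generate_cohort(cohort_config(n_subjects = 3, n_days = 4), seed = 42)
  daily <- daily_summary(coh$events, n_days = 4,
                         subject_ids = coh$subjects$subject_id)
  expect_equal(nrow(daily), 12)
  expect_equal(sum(daily$intake_ug_kg_day), sum(coh$events$dose_ug_kg))
  # per-subject check against direct aggregation
  direct <- tapply(coh$events$dose_ug_kg, coh$events$subject_id, sum)
  agg <- tapply(daily$intake_ug_kg_day, daily$subject_id, sum)
  expect_equal(unname(agg[names(direct)]), unname(direct))
})

test_that("event counts per person-day follow the configured distribution", {
  cfg <- cohort_config(n_subjects = 8, n_days = 25) # 200 person-days
  coh <- generate_cohort(cfg, seed = 13)
  ev_day <- dplyr::count(
    dplyr::mutate(coh$events, day = floor(time_min / 1440) + 1),
    .data$subject_id, .data$day
  )
  counts <- table(factor(ev_day$n, levels = 0:4))
  counts["0"] <- 200 - nrow(ev_day)
  gof <- stats::chisq.test(as.vector(counts), p = cfg$events_per_day_probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort fixtures round-trip through the text formats", {
  coh <- generate_cohort(cohort_config(n_subjects = 2, n_days = 2), seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  voids <- read_voids(file.path(dir, "voids.tsv"))
  events <- read_dose_events(file.path(dir, "events.tsv"))
  diary <- read_diary(file.path(dir, "diary.tsv"))
  expect_equal(voids$time_min, coh$voids$time_min)
  expect_equal(voids$volume_L, coh$voids$volume_L)
  for (m in c("MEHP", "MEHHP", "MEOHP", "MECPP")) {
    expect_equal(voids[[paste0("conc_", m)]], coh$voids[[paste0("conc_", m)]])
    expect_equal(voids[[paste0("below_lod_", m)]],
                 coh$voids[[paste0("below_lod_", m)]])
  }
  expect_equal(events$dose_ug_kg, coh$events$dose_ug_kg)
  expect_equal(events$time_min, coh$events$time_min)
  expect_equal(diary$category, coh$diary$category)

  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 3)
  coh2 <- generate_cohort(cohort_config(n_subjects = 2, n_days = 3), seed = 3)
  dir2 <- withr::local_tempdir()
  write_cohort(coh2, dir2)
  manifest2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  expect_false(identical(manifest$config_hash, manifest2$config_hash))
})

test_that("a generated fixture feeds the reconstruction end to end", {
  cfg <- cohort_config(n_subjects = 1, n_days = 2,
                       events_per_day_probs = c(`0` = 0, `1` = 1, `2` = 0,
                                                `3` = 0, `4` = 0))
  coh <- generate_cohort(cfg, seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  voids <- read_voids(file.path(dir, "voids.tsv"))
  fit <- reconstruct_subject(voids, metabolite_specs())
  expect_s3_class(fit, "dehp_recon")
  expect_true(all(tidy(fit)$dose_ug_kg > 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(events_per_day_probs = c(`0` = 0.5, `1` = 0.4)),
               "probability")
  expect_error(cohort_config(night_fraction = 1.2), "fractions")
  expect_error(cohort_config(noise_cv = -1), "invalid")
})
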