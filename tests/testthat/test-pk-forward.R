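test_that("package molecular weights agree with hand-computed formula masses", {
  specs <- metabolite_specs()
  expect_equal(specs$mw[match(names(MW_HAND), specs$metabolite)],
               unname(MW_HAND), tolerance = 1e-6)
  # MW_DEHP enters dose_input_mass as dose/MW_DEHP; recover and check it
  m <- dose_input_mass(specs, 10, 70)
  implied_mw_dehp <- 10 * 70 * specs$f * specs$mw / m$mass_ug
  expect_equal(implied_mw_dehp, rep(MW_DEHP_HAND, 4), tolerance = 1e-6)
})

test_that("dose_input_mass matches hand arithmetic, is zero at zero, and is linear", {
  specs <- metabolite_specs()
  m <- dose_input_mass(specs, 10, 70)
  # hand oracle: f * (dose*bw / MW_DEHP) * MW_m, from independent atomic masses
  expect_equal(m$mass_ug[m$metabolite == "MEHP"],
               0.059 * (700 / MW_DEHP_HAND) * MW_HAND["MEHP"],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m$mass_ug[m$metabolite == "MEHP"], 29.434, tolerance = 1e-3)

  expect_equal(dose_input_mass(specs, 0, 70)$mass_ug, rep(0, 4))
  expect_equal(dose_input_mass(specs, 20, 70)$mass_ug, 2 * m$mass_ug)
  expect_error(dose_input_mass(specs, -1, 70), "non-negative")
})

test_that("pk_step conserves mass and matches the single-exponential closed form", {
  specs <- instant_specs()
  st <- pk_state(specs)
  st <- pk_step(st, 15)
  expect_equal(unname(st$P), rep(0, 4))
  expect_equal(unname(st$B), rep(0, 4))

  input <- c(MEHP = 10, MEHHP = 5, MEOHP = 2, MECPP = 1)
  st <- pk_step(st, 15, input_ug = input)
  for (i in 1:200) st <- pk_step(st, 15)
  # total mass conserved, and B -> I as t grows
  expect_equal(unname(st$P + st$B), unname(input), tolerance = 1e-12)
  t_hr <- 200 * 15 / 60
  k <- metabolite_specs()$k_per_hr
  expect_equal(unname(st$B),
               unname(input * (1 - exp(-k * t_hr))), tolerance = 1e-12)
  st <- pk_void(st)
  expect_equal(unname(st$B), rep(0, 4))
  expect_equal(unname(st$excreted + st$P), unname(input), tolerance = 1e-12)
})

test_that("simulate with no dose events predicts zero everywhere", {
  voids <- tibble::tibble(time_min = c(60, 240, 600), volume_L = c(0.2, 0.4, 0.1))
  pred <- pk_simulate(voids, NULL, metabolite_specs())
  expect_equal(unlist(pred[grep("^conc_", names(pred))]),
               rep(0, 12), ignore_attr = TRUE)
})

test_that("simulate validates its inputs", {
  specs <- metabolite_specs()
  voids <- tibble::tibble(time_min = c(240, 120), volume_L = 0.2)
  expect_error(pk_simulate(voids, NULL, specs), "sorted")
  voids2 <- tibble::tibble(time_min = c(120, 240), volume_L = c(0.2, -0.1))
  expect_error(pk_simulate(voids2, NULL, specs), "positive")
  voids3 <- tibble::tibble(time_min = 240, volume_L = 0.2)
  bad <- tibble::tibble(time_min = 0, dose_ug_kg = -5, spread_min = 0)
  expect_error(pk_simulate(voids3, bad, specs), "positive")
})

test_that("discrete simulation matches the closed-form bladder accumulation", {
  specs <- instant_specs()
  withr::local_seed(11)
  for (rep in 1:20) {
    t0 <- sample(0:40, 1) * 15
    dose <- stats::runif(1, 1, 60)
    void_min <- sort(sample(seq(15, 72 * 60, by = 15), sample(5:30, 1)))
    voids <- tibble::tibble(time_min = void_min,
                            volume_L = stats::runif(length(void_min), 0.05, 0.6))
    doses <- tibble::tibble(time_min = t0, dose_ug_kg = dose, spread_min = 0)
    pred <- pk_simulate(voids, doses, specs, 70)
    inputs <- dose_input_mass(specs, dose, 70)
    for (j in seq_len(nrow(specs))) {
      m <- specs$metabolite[j]
      oracle <- oracle_voided_mass(inputs$mass_ug[j], specs$k_per_hr[j],
                                   t0, void_min)
      expect_equal(pred[[paste0("mass_", m)]], oracle, tolerance = 1e-9)
      expect_equal(pred[[paste0("conc_", m)]],
                   pred[[paste0("mass_", m)]] / voids$volume_L)
    }
  }
})

test_that("mass conservation, linearity, and schedule invariance hold", {
  specs <- metabolite_specs()
  withr::local_seed(23)
  for (rep in 1:25) {
    n_ev <- sample(1:4, 1)
    doses <- tibble::tibble(
      time_min = sort(sample(0:200, n_ev)) * 15,
      dose_ug_kg = stats::runif(n_ev, 0.5, 60),
      spread_min = sample(c(0, 0, 120, 480), n_ev, replace = TRUE)
    )
    void_min <- sort(sample(seq(15, 96 * 60, by = 15), sample(8:40, 1)))
    voids <- tibble::tibble(time_min = void_min,
                            volume_L = stats::runif(length(void_min), 0.05, 0.6))
    pred <- pk_simulate(voids, doses, specs, 70)
    total_in <- sum(vapply(doses$dose_ug_kg, function(d) {
      sum(dose_input_mass(specs, d, 70)$mass_ug)
    }, numeric(1)))
    expect_equal(total_excreted(pred) + residual_mass(pred), total_in,
                 tolerance = 1e-9)

    # homogeneity of degree 1 in dose
    pred2 <- pk_simulate(voids, dplyr::mutate(doses, dose_ug_kg = 2 * dose_ug_kg),
                         specs, 70)
    expect_equal(pred2$conc_MECPP, 2 * pred$conc_MECPP, tolerance = 1e-9)

    # additivity over dose events
    if (n_ev >= 2) {
      pa <- pk_simulate(voids, doses[1, ], specs, 70)
      pb <- pk_simulate(voids, doses[-1, ], specs, 70)
      expect_equal(pa$conc_MEHHP + pb$conc_MEHHP, pred$conc_MEHHP,
                   tolerance = 1e-9)
    }

    # total excreted mass is independent of the void schedule
    single <- pk_simulate(tibble::tibble(time_min = max(void_min), volume_L = 1),
                          doses, specs, 70)
    expect_equal(total_excreted(single), total_excreted(pred), tolerance = 1e-9)
  }
})

test_that("a second void at the same grid time collects nothing", {
  specs <- metabolite_specs()
  voids <- tibble::tibble(time_min = c(240, 480, 480), volume_L = c(0.2, 0.3, 0.1))
  doses <- tibble::tibble(time_min = 0, dose_ug_kg = 10, spread_min = 0)
  pred <- pk_simulate(voids, doses, specs)
  expect_gt(pred$conc_MEHP[2], 0)
  expect_equal(pred$conc_MEHP[3], 0)
  expect_equal(pred$mass_MECPP[3], 0)
})

test_that("terminal MEHP kinetics reproduce the calibrated 5-hr half-life", {
  specs <- metabolite_specs()
  voids <- tibble::tibble(time_min = seq(60, 48 * 60, by = 60), volume_L = 0.1)
  doses <- tibble::tibble(time_min = 0, dose_ug_kg = 10, spread_min = 0)
  pred <- pk_simulate(voids, doses, specs, 70)
  sel <- pred$time_min >= 360 & pred$time_min <= 1440
  slope <- stats::coef(stats::lm(log(pred$mass_MEHP[sel]) ~
                                   I(pred$time_min[sel] / 60)))[2]
  expect_equal(unname(log(2) / -slope), 5, tolerance = 0.02)
})

test_that("cumulative molar fractions approach the configured excretion fractions", {
  specs <- metabolite_specs()
  expect_equal(cumulative_molar_fraction(specs, "MEHP", 72), 0.059,
               tolerance = 1e-3 / 0.059)
  # short horizon: fraction small; long horizon with instantaneous appearance
  # matches f * (1 - exp(-k T)) exactly
  expect_lt(cumulative_molar_fraction(specs, "MECPP", 0.25), 0.005)
  si <- instant_specs()
  for (Thr in c(6, 24)) {
    j <- which(si$metabolite == "MEHHP")
    expect_equal(cumulative_molar_fraction(si, "MEHHP", Thr),
                 si$f[j] * (1 - exp(-si$k_per_hr[j] * Thr)), tolerance = 1e-12)
  }
  expect_error(cumulative_molar_fraction(specs, "MEHP", 72, dose_ug_kg = 0),
               "zero dose")
})

test_that("second-phase metabolism releases the configured delayed fraction", {
  specs2 <- metabolite_specs(g = 0.1, tau_hr = 24)
  # long-horizon molar fraction approaches f * (1 + g)
  expect_equal(cumulative_molar_fraction(specs2, "MEHP", 24 * 14),
               0.059 * 1.1, tolerance = 1e-3)
  # nothing extra is excreted before the lag
  voids <- tibble::tibble(time_min = 23 * 60, volume_L = 0.5)
  doses <- tibble::tibble(time_min = 0, dose_ug_kg = 10, spread_min = 0)
  p1 <- pk_simulate(voids, doses, metabolite_specs())
  p2 <- pk_simulate(voids, doses, specs2)
  expect_equal(p2$mass_MEHP, p1$mass_MEHP, tolerance = 1e-12)
})

test_that("spread doses are delivered half before and half after the event time", {
  specs <- metabolite_specs()
  # voids bracket the 2-hr spread window of an event at t = 600
  voids <- tibble::tibble(time_min = c(539, 660, 1440), volume_L = 0.2)
  doses <- tibble::tibble(time_min = 600, dose_ug_kg = 8, spread_min = 120)
  pred <- pk_simulate(voids, doses, specs)
  # sub-boluses start at 540; nothing can be in the bladder at the 539 void
  expect_equal(pred$conc_MEHHP[1], 0)
  expect_gt(pred$conc_MEHHP[2], 0)
  # total mass is conserved under spreading
  bolus <- pk_simulate(voids, dplyr::mutate(doses, spread_min = 0), specs)
  expect_equal(total_excreted(pred) + residual_mass(pred),
               total_excreted(bolus) + residual_mass(bolus), tolerance = 1e-9)
})
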