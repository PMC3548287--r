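# Shared fixtures: all built in code at test time.

# Atomic masses for independent formula-mass arithmetic (hand oracle).
AM <- c(C = 12.011, H = 1.008, O = 15.999)
formula_mass <- function(nC, nH, nO) nC * AM["C"] + nH * AM["H"] + nO * AM["O"]
MW_DEHP_HAND <- unname(formula_mass(24, 38, 4))
MW_HAND <- c(
  MEHP  = unname(formula_mass(16, 22, 4)),
  MEHHP = unname(formula_mass(16, 22, 5)),
  MEOHP = unname(formula_mass(16, 20, 5)),
  MECPP = unname(formula_mass(16, 20, 6))
)

# Specs with instantaneous appearance and no second phase: the regime with a
# closed-form solution.
instant_specs <- function() metabolite_specs(k_a_per_hr = Inf)

# Closed-form oracle (independent of the simulator): mass voided at each void
# for a single bolus delivering `input_ug` to the body pool at time t0 with
# instantaneous appearance: the bladder collects
# I * (exp(-k (t_prev - t0)) - exp(-k (t_i - t0))) between consecutive voids.
oracle_voided_mass <- function(input_ug, k_per_hr, t0_min, void_min) {
  prev <- t0_min
  out <- numeric(length(void_min))
  for (i in seq_along(void_min)) {
    ti <- void_min[i]
    if (ti > t0_min) {
      lo <- max(prev, t0_min)
      out[i] <- input_ug * (exp(-k_per_hr * (lo - t0_min) / 60) -
                              exp(-k_per_hr * (ti - t0_min) / 60))
    }
    prev <- ti
  }
  out
}

# The reference recovery subject: 7 days, wake void at 0630 plus 2-hourly
# daytime voids, two well-separated events per day (0900 and 1700, >= 3 µg/kg).
recovery_subject <- function() {
  voids <- tibble::tibble(
    time_min = unlist(lapply(0:6, function(d) {
      d * 1440 + c(390, seq(480, 1320, by = 120))
    })),
    volume_L = 0.25
  )
  truth <- tibble::tibble(
    time_min = unlist(lapply(0:6, function(d) d * 1440 + c(540, 1020))),
    dose_ug_kg = c(8, 4, 15, 3, 6, 20, 5, 10, 4, 12, 3.5, 7, 9, 5),
    spread_min = 0
  )
  list(voids = voids, truth = truth)
}

# Multiplicative lognormal measurement noise with unit mean.
add_conc_noise <- function(pred, cv, seed) {
  withr::local_seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  for (cc in grep("^conc_", names(pred), value = TRUE)) {
    pred[[cc]] <- pred[[cc]] * stats::rlnorm(nrow(pred), -sdlog^2 / 2, sdlog)
  }
  pred
}

total_excreted <- function(pred) {
  sum(as.matrix(pred[grep("^mass_", names(pred), value = TRUE)]))
}

residual_mass <- function(pred) {
  fs <- attr(pred, "final_state")
  sum(fs$A) + sum(fs$P) + sum(fs$B)
}
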