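# Two-compartment urinary excretion kinetics.
#
# Per metabolite, a dose contributes mass to an appearance pool A (rate k_a;
# absorption plus metabolic formation), which feeds the body pool P (the mass
# destined for urine), which drains into the bladder B at the first-order
# elimination rate k. Voids empty B. All pool updates use the exact
# exponential (Bateman) solution over each interval, so there is no
# integration step error: the grid only discretises event times.

# Exact update of pools over dt hours; A, P, k, ka are equal-length vectors.
# Returns list(A, P, delivered) where `delivered` is the mass moved into the
# bladder during the interval. Mass is conserved by construction.
advance_pools <- function(A, P, k, ka, dt_hr) {
  if (dt_hr < 0) rlang::abort("cannot advance pools by negative time")
  if (dt_hr == 0) {
    return(list(A = A, P = P, delivered = numeric(length(A))))
  }
  decP <- exp(-k * dt_hr)
  newA <- numeric(length(A))
  newP <- P * decP
  fin <- is.finite(ka) & A > 0
  if (any(fin)) {
    kaf <- ka[fin]
    kf <- k[fin]
    decA <- exp(-kaf * dt_hr)
    newA[fin] <- A[fin] * decA
    gap <- kaf - kf
    # Bateman transfer A -> P; series limit when k_a ~ k
    transfer <- ifelse(
      abs(gap) > 1e-9 * kf,
      A[fin] * kaf / gap * (decP[fin] - decA),
      A[fin] * kf * dt_hr * decP[fin]
    )
    newP[fin] <- newP[fin] + transfer
  }
  newA[is.finite(ka) & A <= 0] <- 0
  delivered <- (A + P) - (newA + newP)
  list(A = newA, P = newP, delivered = delivered)
}

#' Initialise a simulation state
#'
#' The state tracks, per metabolite, the appearance-pool mass `A`, the body
#' pool `P` (mass destined for urine), the bladder mass `B`, and the running
#' total of excreted (voided) mass, all in µg of the metabolite.
#'
#' @inheritParams dose_input_mass
#' @param t_min Starting time in minutes from study start.
#' @return An object of class `pk_state`.
#' @examples
#' st <- pk_state(metabolite_specs())
#' st <- pk_step(st, dt_min = 15, input_ug = c(MEHP = 10))
#' @export
pk_state <- function(specs, t_min = 0) {
  validate_specs(specs)
  zero <- stats::setNames(numeric(nrow(specs)), specs$metabolite)
  structure(
    list(t_min = t_min, A = zero, P = zero, B = zero, excreted = zero,
         k = stats::setNames(specs$k_per_hr, specs$metabolite),
         ka = stats::setNames(specs$k_a_per_hr, specs$metabolite)),
    class = "pk_state"
  )
}

#' Advance the simulation state by one grid step
#'
#' Applies the exact first-order update over `dt_min` minutes, then adds
#' `input_ug` (µg of each metabolite, e.g. from [dose_input_mass()]) to the
#' appearance pool (or directly to the body pool when the appearance rate is
#' infinite). Total mass (pools + bladder + previously excreted) is conserved.
#'
#' @param state A `pk_state`.
#' @param dt_min Step length in minutes.
#' @param input_ug Named numeric vector of metabolite masses entering at the
#'   end of the step; names must match the state's metabolites.
#' @return The updated `pk_state`.
#' @export
pk_step <- function(state, dt_min = 15, input_ug = NULL) {
  stopifnot(inherits(state, "pk_state"))
  adv <- advance_pools(state$A, state$P, state$k, state$ka, dt_min / 60)
  state$A[] <- adv$A
  state$P[] <- adv$P
  state$B <- state$B + adv$delivered
  state$t_min <- state$t_min + dt_min
  if (!is.null(input_ug)) {
    idx <- names(input_ug)
    if (is.null(idx) || !all(idx %in% names(state$A))) {
      rlang::abort("input_ug must be named by metabolite")
    }
    fin <- is.finite(state$ka[idx])
    state$A[idx][fin] <- state$A[idx][fin] + input_ug[fin]
    state$P[idx][!fin] <- state$P[idx][!fin] + input_ug[!fin]
  }
  state
}

#' Empty the bladder (a void) in a simulation state
#'
#' @param state A `pk_state`.
#' @return The state with every bladder mass reset to 0; the voided mass is
#'   added to the `excreted` accumulator.
#' @export
pk_void <- function(state) {
  stopifnot(inherits(state, "pk_state"))
  state$excreted <- state$excreted + state$B
  state$B[] <- 0
  state
}

# Snap times to the simulation grid, rounding down.
snap_to_grid <- function(time_min, grid_min) {
  floor(time_min / grid_min) * grid_min
}

# Expand dose events (time_min, dose_ug_kg, spread_min) into a per-metabolite
# input schedule: tibble(time_min) + matrix of masses (columns = metabolites).
# Spread doses become equal sub-boluses on the grid, half the window before
# and half after the event time; second-phase fractions are released tau_hr
# after each (sub-)bolus.
expand_dose_inputs <- function(doses, specs, body_weight_kg, grid_min) {
  m <- nrow(specs)
  if (is.null(doses) || nrow(doses) == 0) {
    return(list(time = numeric(0),
                mass = matrix(0, 0, m, dimnames = list(NULL, specs$metabolite))))
  }
  if (!all(c("time_min", "dose_ug_kg") %in% names(doses))) {
    rlang::abort("dose events need columns time_min and dose_ug_kg")
  }
  if (!"spread_min" %in% names(doses)) doses$spread_min <- 0
  if (any(doses$dose_ug_kg <= 0)) rlang::abort("dose magnitudes must be positive")
  if (any(doses$time_min < 0)) rlang::abort("dose times must be non-negative")
  if (any(doses$spread_min %% grid_min != 0)) {
    rlang::abort("spread_min must be a multiple of the grid step")
  }

  times <- numeric(0)
  sub_dose <- numeric(0) # µg/kg per sub-bolus
  for (i in seq_len(nrow(doses))) {
    t0 <- doses$time_min[i]
    sp <- doses$spread_min[i]
    if (sp > 0) {
      n <- sp / grid_min
      tt <- t0 - sp / 2 + (seq_len(n) - 1) * grid_min
      tt <- pmax(tt, 0)
      times <- c(times, tt)
      sub_dose <- c(sub_dose, rep(doses$dose_ug_kg[i] / n, n))
    } else {
      times <- c(times, t0)
      sub_dose <- c(sub_dose, doses$dose_ug_kg[i])
    }
  }
  times <- snap_to_grid(times, grid_min)

  per_umol <- sub_dose * body_weight_kg / MW_DEHP # µmol DEHP per sub-bolus
  mass1 <- outer(per_umol, specs$f * specs$mw) # first phase, µg metabolite
  colnames(mass1) <- specs$metabolite

  has2 <- specs$g > 0
  if (any(has2)) {
    # second-phase releases: one per sub-bolus per metabolite with g > 0,
    # at time + tau_hr; masses only in that metabolite's column
    extra_t <- numeric(0)
    extra_m <- NULL
    for (j in which(has2)) {
      tj <- snap_to_grid(times + specs$tau_hr[j] * 60, grid_min)
      mj <- matrix(0, length(tj), nrow(specs),
                   dimnames = list(NULL, specs$metabolite))
      mj[, j] <- specs$g[j] * per_umol * specs$f[j] * specs$mw[j]
      extra_t <- c(extra_t, tj)
      extra_m <- rbind(extra_m, mj)
    }
    times <- c(times, extra_t)
    mass1 <- rbind(mass1, extra_m)
  }

  ord <- order(times)
  list(time = times[ord], mass = mass1[ord, , drop = FALSE])
}

#' Forward-simulate urinary metabolite concentrations at voids
#'
#' Runs the two-compartment excretion model on a 15-min grid from study start
#' through the last void (and through any later scheduled inputs, so that mass
#' accounting stays complete). Each dose event delivers
#' [dose_input_mass()] µg of each metabolite into the appearance pool at its
#' grid-snapped time (spread doses as equal 15-min sub-boluses, half the
#' window before and half after the event time). At each void the bladder
#' masses are divided by the void volume to give concentrations, and the
#' bladder is emptied.
#'
#' @param voids A data frame with columns `time_min` (minutes from study
#'   start, non-decreasing) and `volume_L` (> 0).
#' @param doses A data frame with columns `time_min`, `dose_ug_kg` and
#'   optionally `spread_min` (default 0 = single-step bolus). `NULL` or empty
#'   means no exposure.
#' @inheritParams dose_input_mass
#' @param grid_min Simulation grid step in minutes (default 15); all event
#'   times snap down to this grid.
#' @return A tibble with one row per void: `time_min`, `volume_L`, and per
#'   metabolite `mass_<m>` (µg excreted in that void) and `conc_<m>` (µg/L,
#'   exactly mass/volume). The attribute `final_state` holds the residual
#'   pool masses after the last event, for mass accounting.
#' @examples
#' specs <- metabolite_specs()
#' voids <- tibble::tibble(time_min = c(240, 480, 720), volume_L = 0.2)
#' doses <- tibble::tibble(time_min = 60, dose_ug_kg = 10, spread_min = 0)
#' pk_simulate(voids, doses, specs, body_weight_kg = 70)
#' @export
pk_simulate <- function(voids, doses, specs, body_weight_kg = 70,
                        grid_min = 15) {
  validate_specs(specs)
  if (!all(c("time_min", "volume_L") %in% names(voids))) {
    rlang::abort("voids need columns time_min and volume_L")
  }
  if (nrow(voids) == 0) rlang::abort("need at least one void")
  if (is.unsorted(voids$time_min)) {
    rlang::abort("voids must be sorted by time")
  }
  if (any(voids$volume_L <= 0)) rlang::abort("void volumes must be positive")
  if (body_weight_kg <= 0) rlang::abort("body weight must be positive")

  nm <- nrow(specs)
  void_t <- snap_to_grid(voids$time_min, grid_min)
  inputs <- expand_dose_inputs(doses, specs, body_weight_kg, grid_min)

  # Event stream: voids and dose inputs in time order; voids first at ties
  # (a dose in the same grid step lands after the bladder is emptied).
  ev_time <- c(void_t, inputs$time)
  ev_kind <- c(rep(1L, length(void_t)), rep(2L, length(inputs$time)))
  ev_idx <- c(seq_along(void_t), seq_along(inputs$time))
  ord <- order(ev_time, ev_kind, ev_idx)

  A <- P <- B <- numeric(nm)
  k <- specs$k_per_hr
  ka <- specs$k_a_per_hr
  t_cur <- 0
  voided <- matrix(0, length(void_t), nm,
                   dimnames = list(NULL, specs$metabolite))

  for (e in ord) {
    te <- ev_time[e]
    if (te > t_cur) {
      adv <- advance_pools(A, P, k, ka, (te - t_cur) / 60)
      A <- adv$A
      P <- adv$P
      B <- B + adv$delivered
      t_cur <- te
    }
    if (ev_kind[e] == 1L) {
      voided[ev_idx[e], ] <- B
      B[] <- 0
    } else {
      add <- inputs$mass[ev_idx[e], ]
      fin <- is.finite(ka)
      A[fin] <- A[fin] + add[fin]
      P[!fin] <- P[!fin] + add[!fin]
    }
  }

  conc <- voided / voids$volume_L
  out <- tibble::tibble(time_min = voids$time_min, volume_L = voids$volume_L)
  for (j in seq_len(nm)) {
    out[[paste0("mass_", specs$metabolite[j])]] <- voided[, j]
    out[[paste0("conc_", specs$metabolite[j])]] <- conc[, j]
  }
  attr(out, "final_state") <- list(
    A = stats::setNames(A, specs$metabolite),
    P = stats::setNames(P, specs$metabolite),
    B = stats::setNames(B, specs$metabolite)
  )
  out
}
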