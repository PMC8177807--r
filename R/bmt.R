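# Body-mass trajectories: the energy-budget recursion and the
# counterfactual foraging scenarios.

#' One step of the body-mass recursion
#'
#' Surplus metabolizable energy is stored with efficiency `store_eff`
#' (default 0.8); deficits are covered from stores with efficiency
#' `burn_eff` (default 1). Energy and mass convert at the tissue energy
#' density (29 kJ/g).
#'
#' @param w_prev_g Mass before the step (g), positive.
#' @param intake_kj Metabolized energy over the step (kJ).
#' @param cost_kj Total energy cost over the step (kJ).
#' @param params [energetics_params()].
#' @return Mass after the step (g).
#' @examples
#' step_mass(1600, 129, 100) # surplus 29 kJ -> +0.8 g
#' @export
step_mass <- function(w_prev_g, intake_kj, cost_kj,
                      params = energetics_params()) {
  if (any(w_prev_g <= 0)) stop("mass must be positive")
  s <- intake_kj - cost_kj
  ed <- params$energy_density_kj_g
  w_prev_g + ifelse(s >= 0, params$store_eff * s / ed,
                    s / (ed * params$burn_eff))
}

#' Day-of-year of the January source night for a later night
#'
#' The maximum-foraging scenario replaces each night after January's first
#' moon cycle (day-of-year > 30) by the night of the same position in a
#' 30-day cycle anchored at January 1: source = `((doy - 1) mod 30) + 1`.
#' Nights with day-of-year <= 30 map to themselves.
#'
#' @param doy Integer day-of-year of the night (date of its sunset).
#' @return Integer day-of-year of the source night (1-30).
#' @examples
#' scenario_source_doy(61) # night of Mar 2-3 -> Jan 1-2
#' @export
scenario_source_doy <- function(doy) {
  ((doy - 1) %% 30) + 1
}

#' No-nighttime-foraging scenario
#'
#' Sets the behavior of every night fix to inactive; day fixes are
#' untouched.
#'
#' @param fixes Resampled fixes with `slot_start`, `dt_min`, `behavior`.
#' @param lat,lon Location for day/night assignment (degrees).
#' @return The transformed fixes, with attribute `scenario = "no_night"`.
#' @export
apply_no_night_scenario <- function(fixes, lat, lon) {
  dn <- assign_day_night(fixes$slot_start + fixes$dt_min * 30, lat, lon)
  fixes$behavior[dn$daynight == "night"] <- "inactive"
  attr(fixes, "scenario") <- "no_night"
  fixes
}

#' Maximum-foraging scenario (January-night substitution)
#'
#' Replaces the time budget (behavior and habitat) of every night after the
#' first January moon cycle by the same bird's night from that first cycle,
#' matched through a 30-day cycle anchored at January 1
#' ([scenario_source_doy()]): e.g. the nights of Jan 31/Feb 1, Mar 2/3,
#' Apr 1/2 and May 1/2 all receive the budget of the night of Jan 1/2.
#' Slots are matched by position from the start of the night; where the
#' (shorter) target night runs out of source slots the source is truncated,
#' and a missing source night falls back to the nearest available January
#' night (noted in the `substitutions` attribute).
#'
#' @param fixes Resampled fixes with `bird`, `slot_start`, `dt_min`,
#'   `behavior`, `habitat`.
#' @param lat,lon Location for day/night assignment (degrees).
#' @return The transformed fixes, attribute `scenario = "max_foraging"`.
#' @export
apply_max_foraging_scenario <- function(fixes, lat, lon) {
  dn <- assign_day_night(fixes$slot_start + fixes$dt_min * 30, lat, lon)
  fixes$.night <- dn$night_date
  is_night <- dn$daynight == "night" & !is.na(fixes$.night)
  jan1 <- as.Date(format(max(fixes$.night, na.rm = TRUE), "%Y-01-01"))
  subs <- list()
  for (b in unique(fixes$bird)) {
    bsel <- fixes$bird == b & is_night
    nd <- fixes$.night[bsel]
    doy <- as.integer(nd - jan1) + 1L
    src_available <- sort(unique(doy[doy >= 1 & doy <= 30]))
    for (d in sort(unique(doy[doy > 30]))) {
      want <- scenario_source_doy(d)
      if (!(want %in% src_available)) {
        if (length(src_available) == 0) next
        got <- src_available[which.min(abs(src_available - want))]
        subs[[length(subs) + 1]] <- data.frame(bird = b, night_doy = d,
                                               wanted = want, used = got)
        want <- got
      }
      tgt_idx <- which(bsel)[doy == d]
      src_idx <- which(bsel)[doy == want]
      tgt_idx <- tgt_idx[order(fixes$slot_start[tgt_idx])]
      src_idx <- src_idx[order(fixes$slot_start[src_idx])]
      k <- min(length(tgt_idx), length(src_idx))
      if (k == 0) next
      fixes$behavior[tgt_idx[seq_len(k)]] <- fixes$behavior[src_idx[seq_len(k)]]
      fixes$habitat[tgt_idx[seq_len(k)]] <- fixes$habitat[src_idx[seq_len(k)]]
    }
  }
  fixes$.night <- NULL
  attr(fixes, "scenario") <- "max_foraging"
  attr(fixes, "substitutions") <- if (length(subs)) do.call(rbind, subs) else NULL
  fixes
}

#' Starting body mass
#'
#' Either an explicit mass, a linear size-to-mass rule, or a population
#' default constant.
#'
#' @param explicit_g Explicit starting mass (g), passed through.
#' @param size Optional biometric predictor (e.g. head length).
#' @param coef `c(intercept, slope)` of a linear size-to-mass rule (g).
#' @param default_g Population default (g) when nothing else is given.
#' @return Starting mass (g).
#' @export
start_mass_from_size <- function(explicit_g = NULL, size = NULL,
                                 coef = NULL, default_g = 1600) {
  if (!is.null(explicit_g)) return(explicit_g)
  if (!is.null(size)) {
    if (is.null(coef)) stop("size given but no size-to-mass coefficients")
    return(coef[1] + coef[2] * size)
  }
  if (is.null(default_g)) stop("no starting mass, size rule or default given")
  default_g
}

#' Simulate body-mass trajectories
#'
#' Runs the per-fix energy-budget recursion for every bird in `fixes`:
#' existence energy uses the mass-dependent BMR (mass at the previous fix),
#' thermoregulation is evaluated at the fixed reference mass, intake comes
#' from the habitat-specific PI-GDD model times foraging-plus-active time on
#' suitable habitat, flight intervals carry flight cost instead of
#' existence energy, and the mass steps through [step_mass()]. Apply a
#' scenario transformation to `fixes` first for counterfactual runs.
#'
#' @param fixes Resampled fixes (`bird`, `t`, `lat`, `lon`, `slot_start`,
#'   `dt_min`, `behavior`, `habitat`), already scenario-transformed if
#'   desired.
#' @param weather 6-hourly weather table ([generate_weather()] schema).
#' @param pim A `pi_model`.
#' @param gdd [growing_degree_days()] table covering every fix date.
#' @param start_mass_g Starting mass (g), recycled over birds.
#' @param params [energetics_params()].
#' @param scenario Label stored with the trajectory.
#' @return data.frame `bird`, `scenario`, `t`, `mass_g` (mass after the
#'   fix's interval), `intake_kj`, `cost_kj`; attribute `start_mass_g`, and
#'   `unrealistic` listing birds whose mass hit zero.
#' @export
simulate_bmt <- function(fixes, weather, pim, gdd,
                         start_mass_g = 1600,
                         params = energetics_params(),
                         scenario = attr(fixes, "scenario") %||% "baseline") {
  stopifnot(all(c("bird", "slot_start", "dt_min", "behavior", "habitat") %in%
                names(fixes)))
  fixes <- fixes[order(fixes$bird, fixes$slot_start), ]
  n <- nrow(fixes)
  dt_s <- fixes$dt_min * 60

  # weather matched to the latest record at or before the fix
  wi <- findInterval(as.numeric(fixes$slot_start), as.numeric(weather$t))
  if (any(wi == 0) ||
      any(as.numeric(fixes$slot_start) >
          as.numeric(weather$t[nrow(weather)]) + 6 * 3600)) {
    bad <- range(fixes$slot_start[wi == 0 |
      as.numeric(fixes$slot_start) > as.numeric(weather$t[nrow(weather)]) + 6 * 3600])
    stop("weather table does not cover fixes between ",
         bad[1], " and ", bad[2])
  }
  wrec <- weather[wi, ]
  et <- thermoregulation_cost(wrec, params$fixed_thermo_mass_g, dt_s, params)

  date <- as.Date(fixes$slot_start, tz = "UTC")
  gi <- match(date, gdd$date)
  if (anyNA(gi)) {
    stop("GDD series does not cover fix dates: ",
         paste(unique(date[is.na(gi)]), collapse = ", "))
  }
  suitable <- fixes$habitat %in% SUITABLE_HABITATS
  feeding <- fixes$behavior %in% c("foraging", "active") & suitable
  pi_rate <- numeric(n)
  pi_rate[feeding] <- potential_intake(fixes$habitat[feeding],
                                       gdd$gdd[gi[feeding]], pim)
  intake_kj <- pi_rate * dt_s / 3600

  # flight: accelerometer class or displacement speed between fixes
  flying <- fixes$behavior == "flying"
  if (all(c("lat", "lon", "t") %in% names(fixes))) {
    same_bird <- c(fixes$bird[-n] == fixes$bird[-1], FALSE)
    dts <- c(as.numeric(diff(as.numeric(fixes$slot_start))), NA)
    ok <- same_bird & !is.na(dts) & dts > 0
    det <- rep(FALSE, n)
    if (any(ok)) {
      df <- detect_flight(fixes$lon[which(ok)], fixes$lat[which(ok)],
                          fixes$lon[which(ok) + 1], fixes$lat[which(ok) + 1],
                          dts[ok], params)
      det[which(ok)] <- df$flight
    }
    flying <- flying | det
  }

  mult <- numeric(n)
  mult[!flying] <- params$multipliers[fixes$behavior[!flying]]
  # per-gram coefficients: Ee = ke * w ; Ef = kf * w (J per step)
  ke <- mult * dt_s * params$bmr_ref_w / params$w_ref_g
  kf <- ifelse(flying, params$flight_bmr_multiple, 0) * dt_s *
    params$bmr_ref_w / params$w_ref_g

  start_mass_g <- rep_len(start_mass_g, length(unique(fixes$bird)))
  names(start_mass_g) <- unique(fixes$bird)
  mass <- numeric(n); cost_kj <- numeric(n)
  unrealistic <- character(0)
  ed <- params$energy_density_kj_g
  for (b in unique(fixes$bird)) {
    idx <- which(fixes$bird == b)
    w <- start_mass_g[[b]]
    for (i in idx) {
      es <- max(et[i], ke[i] * w) + kf[i] * w # J
      ck <- es / 1000
      s <- intake_kj[i] - ck
      w <- w + if (s >= 0) params$store_eff * s / ed else s / (ed * params$burn_eff)
      if (w <= 0) {
        unrealistic <- c(unrealistic, b)
        w <- .Machine$double.eps
      }
      mass[i] <- w
      cost_kj[i] <- ck
    }
  }
  out <- data.frame(bird = fixes$bird, scenario = scenario,
                    t = fixes$slot_start, mass_g = mass,
                    intake_kj = intake_kj, cost_kj = cost_kj,
                    stringsAsFactors = FALSE)
  attr(out, "start_mass_g") <- start_mass_g
  attr(out, "unrealistic") <- unique(unrealistic)
  out
}

#' Departure metrics of one trajectory
#'
#' Maximum ("departure") body mass and when it is first reached, the first
#' time a reference mass is attained (for comparing scenarios against the
#' baseline departure mass), and the energy-deposition period against a
#' supplied fueling-onset breakpoint.
#'
#' @param bmt Trajectory rows for one bird ([simulate_bmt()] output).
#' @param breakpoint_day Fueling-onset day-of-year (from
#'   [fit_breakpoint()]); optional.
#' @param reference_mass_g Optional reference mass whose first attainment
#'   time is wanted.
#' @return list `max_mass_g`, `t_max_mass`, `doy_max_mass`,
#'   `t_reach_reference` (`NA` if never reached), `deposition_period_days`
#'   (`NA` without a breakpoint).
#' @export
departure_metrics <- function(bmt, breakpoint_day = NULL,
                              reference_mass_g = NULL) {
  stopifnot(nrow(bmt) > 0, length(unique(bmt$bird)) == 1)
  bmt <- bmt[order(bmt$t), ]
  imax <- which.max(bmt$mass_g) # which.max takes the first on ties
  t_max <- bmt$t[imax]
  doy_max <- fractional_doy(t_max)
  t_ref <- NA
  if (!is.null(reference_mass_g)) {
    hit <- which(bmt$mass_g >= reference_mass_g)
    t_ref <- if (length(hit)) bmt$t[hit[1]] else NA
  }
  dep <- if (!is.null(breakpoint_day)) doy_max - breakpoint_day else NA_real_
  list(max_mass_g = bmt$mass_g[imax], t_max_mass = t_max,
       doy_max_mass = doy_max, t_reach_reference = t_ref,
       deposition_period_days = dep)
}
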