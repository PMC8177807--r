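# Bioenergetics: existence energy, thermoregulation, flight, total cost.

#' Energetic parameter set
#'
#' Bundles all constants of the energy model: the reference basal metabolic
#' rate and body mass used for proportional BMR scaling, behavior-specific
#' existence multipliers, the lower critical temperature, the biophysical
#' anchors of the thermoregulation model, tissue energy density, storage and
#' burning efficiencies, and flight handling.
#'
#' @param bmr_ref_w Reference basal metabolic rate (W) at `w_ref_g`.
#' @param w_ref_g Reference body mass (g).
#' @param multipliers Named multipliers of BMR for existence energy;
#'   flying is costed separately and contributes 0 existence energy.
#' @param lct_c Lower critical temperature (deg C).
#' @param bird_height_m Characteristic height of the standing bird (m), the
#'   reference height for wind experienced by the bird and the characteristic
#'   dimension of its boundary layer.
#' @param plumage_resistance_s_m Coat (plumage) resistance to sensible heat
#'   loss (s/m).
#' @param energy_density_kj_g Energy density of deposited tissue (kJ/g).
#' @param store_eff Efficiency of converting surplus metabolizable energy to
#'   stores (dimensionless, <= 1).
#' @param burn_eff Efficiency of mobilising stores to cover a deficit.
#' @param flight_speed_kmh Minimum ground speed (km/h) used to flag a
#'   displacement between fixes as flight.
#' @param flight_bmr_multiple Default flight power as a multiple of BMR; a
#'   different power curve can be plugged in via `flight_power`.
#' @param flight_power Optional function `(airspeed_m_s, bmr_w)` returning
#'   power in W; overrides `flight_bmr_multiple`.
#' @param thermo_model Optional function
#'   `(weather_row, mass_g, dt_s, params)` returning thermoregulation cost in
#'   J; replaces the built-in parameterization (plug-in point for an exact
#'   published model).
#' @param fixed_thermo_mass_g Body mass (g) at which thermoregulation is
#'   evaluated throughout (the model holds this fixed while existence energy
#'   tracks the simulated mass).
#' @return An object of class `energetics_params` (a named list).
#' @examples
#' p <- energetics_params()
#' bmr(1600, p) # 4.853 W
#' @export
energetics_params <- function(bmr_ref_w = 5.536,
                              w_ref_g = 1825,
                              multipliers = c(inactive = 1.5, active = 1.9,
                                              foraging = 1.6),
                              lct_c = 10,
                              bird_height_m = 0.15,
                              plumage_resistance_s_m = 150,
                              energy_density_kj_g = 29,
                              store_eff = 0.8,
                              burn_eff = 1,
                              flight_speed_kmh = 20,
                              flight_bmr_multiple = 12.5,
                              flight_power = NULL,
                              thermo_model = NULL,
                              fixed_thermo_mass_g = 1600) {
  stopifnot(bmr_ref_w > 0, w_ref_g > 0, all(multipliers > 0),
            energy_density_kj_g > 0, store_eff > 0, store_eff <= 1,
            burn_eff > 0, burn_eff <= 1, flight_speed_kmh > 0,
            bird_height_m > 0, plumage_resistance_s_m > 0)
  structure(list(
    bmr_ref_w = bmr_ref_w, w_ref_g = w_ref_g, multipliers = multipliers,
    lct_c = lct_c, bird_height_m = bird_height_m,
    plumage_resistance_s_m = plumage_resistance_s_m,
    energy_density_kj_g = energy_density_kj_g,
    store_eff = store_eff, burn_eff = burn_eff,
    flight_speed_kmh = flight_speed_kmh,
    flight_bmr_multiple = flight_bmr_multiple,
    flight_power = flight_power, thermo_model = thermo_model,
    fixed_thermo_mass_g = fixed_thermo_mass_g
  ), class = "energetics_params")
}

#' Mass-scaled basal metabolic rate
#'
#' BMR scales proportionally with body mass relative to a reference bird:
#' `BMR = (W / W_ref) * BMR_ref`.
#'
#' @param mass_g Body mass (g), positive.
#' @param params [energetics_params()].
#' @return BMR in watts.
#' @examples
#' bmr(1600, energetics_params()) # 4.853
#' @export
bmr <- function(mass_g, params = energetics_params()) {
  if (any(mass_g <= 0)) stop("body mass must be positive")
  (mass_g / params$w_ref_g) * params$bmr_ref_w
}

#' Existence energy for one fix interval
#'
#' Activity-dependent maintenance cost: `BMR * b * t` with a
#' behavior-specific multiplier `b`. Flying contributes 0 here because
#' flight is costed separately.
#'
#' @param behavior Character vector of behavior labels.
#' @param bmr_w BMR in watts (scalar or vector).
#' @param dt_s Interval length in seconds, positive.
#' @param params [energetics_params()].
#' @return Energy in joules.
#' @export
existence_energy <- function(behavior, bmr_w, dt_s,
                             params = energetics_params()) {
  check_behavior(behavior)
  if (any(dt_s <= 0)) stop("dt must be positive")
  b <- rep(0, length(behavior))
  known <- behavior != "flying"
  b[known] <- params$multipliers[behavior[known]]
  bmr_w * b * dt_s
}

# Default biophysical thermoregulation parameterization.
#
# Heat loss is modelled as a conductance in series: a wind-dependent
# boundary-layer resistance r_b = 307 * sqrt(d / u) (s/m, flat-plate/cylinder
# convection with characteristic dimension d = bird height) plus the plumage
# resistance. Wind at 10 m is scaled to bird height with a logarithmic
# profile (roughness length 0.01 m). Absorbed shortwave radiation raises the
# operative temperature linearly, T_op = T_air + gamma * S with
# gamma = 0.015 K per W m^-2 (a few degrees of warming in full sun). Costs
# accrue only below the lower critical temperature:
# rate = rho * c_p * A / r_e * (LCT - T_op), with surface area from a Meeh
# rule A = 0.1 * (m_kg)^(2/3).
default_thermo_rate_w <- function(t_air_c, wind10_m_s, radiation_w_m2,
                                  mass_g, params) {
  rho_cp <- 1200 # J m^-3 K^-1, volumetric heat capacity of air
  z0 <- 0.01
  u_bird <- pmax(0.1, wind10_m_s * log(params$bird_height_m / z0) / log(10 / z0))
  r_b <- 307 * sqrt(params$bird_height_m / u_bird)
  r_e <- r_b + params$plumage_resistance_s_m
  t_op <- t_air_c + 0.015 * pmax(0, radiation_w_m2)
  area <- 0.1 * (mass_g / 1000)^(2 / 3)
  pmax(0, rho_cp * area / r_e * (params$lct_c - t_op))
}

#' Thermoregulation cost for one fix interval
#'
#' Cost of keeping warm below the lower critical temperature, as a function
#' of air temperature, 10-m wind and shortwave radiation. Zero at or above
#' thermoneutrality. The parameterization is pluggable via
#' `params$thermo_model`; the built-in default is a documented
#' operative-temperature / series-resistance model anchored at the
#' configured LCT, bird height and plumage resistance.
#'
#' @param weather A data.frame row (or vectorised columns) with `t_air_c`,
#'   `u10_m_s`, `v10_m_s`, `radiation_w_m2`.
#' @param mass_g Body mass (g) at which to evaluate the model.
#' @param dt_s Interval length (s).
#' @param params [energetics_params()].
#' @return Energy in joules (>= 0).
#' @export
thermoregulation_cost <- function(weather, mass_g, dt_s,
                                  params = energetics_params()) {
  if (is.null(weather) ||
      !all(c("t_air_c", "u10_m_s", "v10_m_s", "radiation_w_m2") %in%
           names(weather))) {
    stop("weather record with t_air_c, u10_m_s, v10_m_s, radiation_w_m2 ",
         "is required (no silent default)")
  }
  if (any(dt_s <= 0)) stop("dt must be positive")
  if (!is.null(params$thermo_model)) {
    return(params$thermo_model(weather, mass_g, dt_s, params))
  }
  wind <- sqrt(weather$u10_m_s^2 + weather$v10_m_s^2)
  default_thermo_rate_w(weather$t_air_c, wind, weather$radiation_w_m2,
                        mass_g, params) * dt_s
}

#' Detect flight between consecutive fixes from displacement speed
#'
#' Great-circle distance between fixes divided by the interval; speeds above
#' the configured minimum ground speed flag the interval as flight.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates of the two fixes (degrees).
#' @param dt_s Interval (s), positive.
#' @param params [energetics_params()].
#' @return data.frame `distance_m`, `speed_kmh`, `flight` (logical).
#' @export
detect_flight <- function(lon1, lat1, lon2, lat2, dt_s,
                          params = energetics_params()) {
  if (any(dt_s <= 0)) stop("dt must be positive")
  d <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
  v <- d / dt_s * 3.6
  data.frame(distance_m = d, speed_kmh = v,
             flight = v > params$flight_speed_kmh)
}

#' Energetic cost of a flight interval
#'
#' Airspeed is the ground velocity minus the 10-m wind vector; energy is a
#' pluggable power curve times flight duration. The default power curve is a
#' constant multiple of BMR (airspeed-independent); a U-shaped aerodynamic
#' curve can be supplied via `params$flight_power`.
#'
#' @param ground_u,ground_v Ground velocity components (m/s, east/north).
#' @param wind_u,wind_v 10-m wind components (m/s).
#' @param dt_flying_s Time in flight (s), non-negative.
#' @param bmr_w BMR (W) of the bird, used by the default power model.
#' @param params [energetics_params()].
#' @return list `airspeed_m_s`, `energy_j`.
#' @export
flight_cost <- function(ground_u, ground_v, wind_u = 0, wind_v = 0,
                        dt_flying_s, bmr_w, params = energetics_params()) {
  if (any(dt_flying_s < 0)) stop("flight duration must be non-negative")
  airspeed <- sqrt((ground_u - wind_u)^2 + (ground_v - wind_v)^2)
  pw <- if (!is.null(params$flight_power)) {
    params$flight_power(airspeed, bmr_w)
  } else {
    params$flight_bmr_multiple * bmr_w + 0 * airspeed
  }
  list(airspeed_m_s = airspeed, energy_j = pw * dt_flying_s)
}

#' Total energy cost of an interval
#'
#' Heat generated by activity substitutes for thermoregulation, so the bird
#' pays `max(Et, Ee)`; flight cost is added on top (flight intervals carry
#' zero existence energy).
#'
#' @param ee_j Existence energy (J), >= 0.
#' @param et_j Thermoregulation cost (J), >= 0.
#' @param ef_j Flight cost (J), >= 0.
#' @return Total cost `Es` in joules.
#' @export
total_cost <- function(ee_j, et_j, ef_j = 0) {
  if (any(ee_j < 0) || any(et_j < 0) || any(ef_j < 0)) {
    stop("energy components must be non-negative")
  }
  pmax(ee_j, et_j) + ef_j
}
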