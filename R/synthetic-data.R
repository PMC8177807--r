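# Seeded synthetic-data generator: tracks, accelerometer bursts, weather,
# field intake observations. Emulates the statistical structure the analysis
# assumes (diel/lunar behavior structure, seasonal ramps, habitat split) so
# every downstream stage is testable without external data.

#' Configuration of the synthetic study
#'
#' Defaults emulate the study design: ~23 birds tracked at 30-min fixes from
#' January 1 to mid-May at a Wadden Sea wintering site, a calibration set of
#' 945 labeled bursts (796/57/44/48), daytime grazing occupying about
#' two-thirds of daylight, and nocturnal grazing concentrated in moonlit
#' winter nights and decaying over the season.
#'
#' @param n_birds Number of birds.
#' @param start_date,end_date Study period (UTC calendar dates).
#' @param fix_interval Minutes between fixes.
#' @param site_lat,site_lon Site coordinates (degrees).
#' @param burst_class_counts Named counts of calibration bursts per class.
#' @param day_forage_frac Probability a daylight slot is foraging.
#' @param day_active_frac Probability a non-foraging daylight slot is active.
#' @param night_forage_base Night foraging target at zero moonlight on
#'   January 1 (minutes per night).
#' @param night_forage_moon_gain Additional minutes of night foraging per
#'   moonlit hour.
#' @param night_forage_decay_days e-folding time (days) of the seasonal
#'   decay of the night-foraging target.
#' @param night_noise_sd SD (minutes) of night-level noise on the target.
#' @param temp_winter,temp_spring Seasonal temperature ramp endpoints
#'   (deg C) at `start_date` and `end_date`.
#' @param habitat_switch_doy Day-of-year when switching birds move from
#'   agricultural to natural habitat.
#' @param switch_frac Fraction of birds that switch habitat.
#' @param departure_doy Mean day-of-year of the last fix (migratory
#'   departure).
#' @param departure_jitter_sd SD (days) of per-bird departure jitter.
#' @param dropout_prob Probability that any fix is dropped (data gaps).
#' @param water_prob Probability that a daylight slot is a wave-artifact fix
#'   (recorded as foraging on water; the water correction repairs these).
#' @param fly_prob Probability that a daylight slot is a flight (commuting).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return `sim_config` object (named list).
#' @export
sim_config <- function(n_birds = 23,
                       start_date = "2015-01-01", end_date = "2015-05-15",
                       fix_interval = 30,
                       site_lat = 53.87, site_lon = 7.3,
                       burst_class_counts = c(inactive = 796, active = 57,
                                              foraging = 44, flying = 48),
                       day_forage_frac = 0.66, day_active_frac = 0.25,
                       night_forage_base = 45, night_forage_moon_gain = 3.6,
                       night_forage_decay_days = 60, night_noise_sd = 0,
                       temp_winter = 3, temp_spring = 14,
                       habitat_switch_doy = 90, switch_frac = 0.5,
                       departure_doy = 134, departure_jitter_sd = 2,
                       dropout_prob = 0, water_prob = 0.005,
                       fly_prob = 0.01, seed = 42) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (!(start_date < end_date)) stop("invalid date range: start must precede end")
  stopifnot(n_birds >= 1, day_forage_frac >= 0, day_forage_frac <= 1,
            all(burst_class_counts >= 0), fix_interval > 0,
            night_noise_sd >= 0, dropout_prob >= 0, dropout_prob < 1)
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Seasonal (de-noised) mean temperature of the generator
#'
#' Linear ramp from `temp_winter` at `start_date` to `temp_spring` at
#' `end_date`.
#'
#' @param config [sim_config()].
#' @param t POSIXct or Date vector.
#' @return deg C.
#' @export
seasonal_temp <- function(config, t) {
  frac <- as.numeric(difftime(as_utc(as.POSIXct(t, tz = "UTC")),
                              as.POSIXct(paste(config$start_date, "00:00:00"),
                                         tz = "UTC"), units = "days")) /
    as.numeric(config$end_date - config$start_date)
  config$temp_winter + (config$temp_spring - config$temp_winter) * frac
}

#' Generate the 6-hourly weather table
#'
#' Temperature is the seasonal ramp plus a 2 deg C diel cycle and AR(1)
#' noise; winds are AR(1) around zero; shortwave radiation follows the solar
#' elevation under the generated cloud cover (zero at night).
#'
#' @param config [sim_config()].
#' @return data.frame `t`, `date`, `t_air_c`, `temp_trend_c`, `u10_m_s`,
#'   `v10_m_s`, `cloud`, `radiation_w_m2`.
#' @export
generate_weather <- function(config) {
  with_seed(config$seed + 3L, {
    t <- seq(as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
             as.POSIXct(paste(config$end_date, "18:00:00"), tz = "UTC"),
             by = 6 * 3600)
    n <- length(t)
    ar1 <- function(n, phi, sd) {
      x <- numeric(n)
      x[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
      for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1, 0, sd)
      x
    }
    trend <- seasonal_temp(config, t)
    hour <- as.numeric(format(t, "%H"))
    diel <- -2 * cos(2 * pi * (hour - 14) / 24)
    t_air <- trend + diel + ar1(n, 0.8, 1.2)
    u10 <- ar1(n, 0.85, 1.6); v10 <- ar1(n, 0.85, 1.6)
    cloud <- pmin(1, pmax(0, 0.6 + ar1(n, 0.7, 0.25)))
    # solar elevation at the site for the radiation diel cycle
    jc <- (julian_day(t) - 2451545) / 36525
    g <- sun_geometry(jc)
    tst_min <- (hour * 60) + 4 * config$site_lon + g$eqtime # true solar time
    ha <- (tst_min / 4 - 180) * DEG
    sin_elev <- sin(config$site_lat * DEG) * sin(g$decl * DEG) +
      cos(config$site_lat * DEG) * cos(g$decl * DEG) * cos(ha)
    radiation <- pmax(0, 750 * sin_elev) * (1 - 0.7 * cloud)
    data.frame(t = t, date = as.Date(t, tz = "UTC"),
               t_air_c = t_air, temp_trend_c = trend,
               u10_m_s = u10, v10_m_s = v10, cloud = cloud,
               radiation_w_m2 = radiation)
  })
}

#' Daily mean temperatures from a weather table
#'
#' @param weather Output of [generate_weather()] (or any table with `date`
#'   and `t_air_c`).
#' @return data.frame `date`, `t_mean_c`.
#' @export
weather_daily_means <- function(weather) {
  agg <- aggregate(t_air_c ~ date, data = weather, FUN = mean)
  names(agg)[2] <- "t_mean_c"
  agg[order(agg$date), ]
}

# Night-foraging target in minutes for a night: seasonal exponential decay
# of a base plus a moonlight bonus. The decay reflects that the longest
# nocturnal foraging happens in the first (January) moon cycle.
night_forage_target_min <- function(config, doy, moonlit_h) {
  (config$night_forage_base +
     config$night_forage_moon_gain * moonlit_h) *
    exp(-(doy - 1) / config$night_forage_decay_days)
}

#' Generate per-bird GPS/behavior tracks
#'
#' One fix per `fix_interval` from `start_date` to each bird's departure.
#' Daylight slots are foraging with probability `day_forage_frac`, otherwise
#' active or inactive (rare flight and wave-artifact water fixes mixed in).
#' Each night gets a foraging target of
#' `(base + gain * moonlit_h) * exp(-(doy-1)/decay)` minutes, filled from
#' the start of the night; remaining night slots are inactive. Habitat is a
#' per-bird label stream (agricultural, with a configurable fraction of
#' birds switching to natural habitat in spring).
#'
#' @param config [sim_config()].
#' @param nights Optional precomputed [night_table()] for the period.
#' @return data.frame `bird`, `t`, `lat`, `lon`, `behavior`, `habitat`.
#' @export
generate_track <- function(config, nights = NULL) {
  dates <- seq(config$start_date, config$end_date, by = 1)
  if (is.null(nights)) {
    nights <- night_table(dates, config$site_lat, config$site_lon)
  }
  slots <- seq(as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
               as.POSIXct(paste(config$end_date, "23:59:59"), tz = "UTC"),
               by = config$fix_interval * 60)
  dn <- assign_day_night(slots + config$fix_interval * 30,
                         config$site_lat, config$site_lon)
  slot_doy <- fractional_doy(as.Date(slots, tz = "UTC"))
  night_doy <- as.numeric(format(dn$night_date, "%j"))
  moonlit <- nights$moonlit_h[match(dn$night_date, nights$date)]
  moonlit[is.na(moonlit)] <- 0

  with_seed(config$seed + 1L, {
    out <- vector("list", config$n_birds)
    switches <- seq_len(config$n_birds) <= round(config$switch_frac * config$n_birds)
    for (b in seq_len(config$n_birds)) {
      depart <- round(config$departure_doy +
                        rnorm(1, 0, config$departure_jitter_sd))
      depart <- min(max(depart, 32), max(slot_doy))
      keep <- slot_doy <= depart
      tt <- slots[keep]
      is_day <- dn$daynight[keep] == "day"
      nd <- dn$night_date[keep]
      n_doy <- night_doy[keep]
      moon <- moonlit[keep]
      n <- length(tt)
      behavior <- rep("inactive", n)

      # daylight slots
      di <- which(is_day)
      u <- runif(length(di))
      behavior[di] <- ifelse(u < config$day_forage_frac, "foraging",
                      ifelse(u < config$day_forage_frac +
                               (1 - config$day_forage_frac) * config$day_active_frac,
                             "active", "inactive"))
      fly <- runif(length(di)) < config$fly_prob
      behavior[di[fly]] <- "flying"

      # night slots: fill each night's target from the start of the night
      ni <- which(!is_day & !is.na(nd))
      if (length(ni)) {
        for (d in unique(nd[ni])) {
          sel <- ni[nd[ni] == d]
          doy_d <- n_doy[sel[1]]
          target <- night_forage_target_min(config, doy_d, moon[sel[1]])
          if (config$night_noise_sd > 0) {
            target <- target + rnorm(1, 0, config$night_noise_sd)
          }
          k <- min(length(sel),
                   max(0L, as.integer(round(target / config$fix_interval))))
          if (k > 0) behavior[sel[seq_len(k)]] <- "foraging"
        }
      }

      habitat <- rep("agricultural", n)
      if (switches[b]) {
        habitat[slot_doy[keep] >= config$habitat_switch_doy] <- "natural"
      }
      # wave-artifact fixes: daylight, recorded as foraging on water
      wa <- di[runif(length(di)) < config$water_prob]
      behavior[wa] <- "foraging"; habitat[wa] <- "water"

      drop <- if (config$dropout_prob > 0) {
        runif(n) < config$dropout_prob
      } else rep(FALSE, n)
      out[[b]] <- data.frame(
        bird = sprintf("bird%02d", b), t = tt,
        lat = config$site_lat + rnorm(n, 0, 0.005),
        lon = config$site_lon + rnorm(n, 0, 0.008),
        behavior = behavior, habitat = habitat,
        stringsAsFactors = FALSE)[!drop, ]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# per-class burst signal models: rows are 10 samples, columns x, y, z (g)
burst_signal <- function(class) {
  tgrid <- (0:9) / 20
  noise <- function(sd) matrix(rnorm(30, 0, sd), ncol = 3)
  pitch_vec <- function(p) c(sin(p * pi / 180), 0, cos(p * pi / 180))
  base <- switch(class,
    inactive = {
      p <- rnorm(1, 0, 5)
      matrix(pitch_vec(p), nrow = 10, ncol = 3, byrow = TRUE) + noise(0.01)
    },
    foraging = {
      p <- rnorm(1, -40, 8) # head-down grazing posture
      matrix(pitch_vec(p), nrow = 10, ncol = 3, byrow = TRUE) + noise(0.08)
    },
    active = {
      p <- rnorm(1, 15, 6) # upright walking posture
      matrix(pitch_vec(p), nrow = 10, ncol = 3, byrow = TRUE) + noise(0.08)
    },
    flying = {
      p <- rnorm(1, 5, 5)
      amp <- rnorm(1, 0.6, 0.1); f <- rnorm(1, 4, 0.4)
      m <- matrix(pitch_vec(p), nrow = 10, ncol = 3, byrow = TRUE)
      m[, 3] <- m[, 3] + amp * sin(2 * pi * f * tgrid + runif(1, 0, 2 * pi))
      m + noise(0.12)
    },
    stop("unknown burst class: ", class))
  base
}

#' Generate the labeled calibration burst set
#'
#' Draws `burst_class_counts` bursts per class from per-class signal models
#' chosen to be separable in the four-feature space: inactive bursts are a
#' static gravity vector with near-zero dynamics, foraging bursts a
#' head-down pitch offset with moderate dynamics, active bursts an upright
#' pitch with moderate dynamics, and flying bursts a high-amplitude periodic
#' heave.
#'
#' @param config [sim_config()].
#' @return data.frame with `burst_id`, `class`, `x1..x10`, `y1..y10`,
#'   `z1..z10` (units g, 20 Hz).
#' @export
generate_bursts <- function(config) {
  counts <- config$burst_class_counts
  if (sum(counts) == 0) stop("burst class counts sum to zero: empty set")
  with_seed(config$seed + 2L, {
    classes <- rep(names(counts), counts)
    mats <- lapply(classes, burst_signal)
    flat <- t(vapply(mats, function(m) c(m[, 1], m[, 2], m[, 3]),
                     numeric(30)))
    colnames(flat) <- c(paste0("x", 1:10), paste0("y", 1:10), paste0("z", 1:10))
    data.frame(burst_id = seq_along(classes), class = classes, flat,
               stringsAsFactors = FALSE)
  })
}

#' Generate field intake observations
#'
#' Observations of metabolizable intake rate scattered around habitat-true
#' lines in growing degree days, emulating the field feeding-rate data that
#' the PI regressions are fitted to.
#'
#' @param config [sim_config()].
#' @param pi_true A `pi_model` holding the true lines.
#' @param n_per_habitat Observations per habitat.
#' @param noise_sd Residual SD (kJ/h), >= 0.
#' @param gdd_range Range of GDD over which observations are spread.
#' @return data.frame `habitat`, `gdd`, `intake_kj_h`.
#' @export
generate_intake_obs <- function(config, pi_true = pi_model(),
                                n_per_habitat = 60, noise_sd = 8,
                                gdd_range = c(0, 1100)) {
  if (noise_sd < 0) stop("noise SD must be non-negative")
  stopifnot(all(vapply(pi_true$habitats,
                       function(h) is.finite(h$intercept) && is.finite(h$slope),
                       logical(1))))
  with_seed(config$seed + 4L, {
    habs <- names(pi_true$habitats)
    do.call(rbind, lapply(habs, function(h) {
      cf <- pi_true$habitats[[h]]
      gdd <- runif(n_per_habitat, gdd_range[1], gdd_range[2])
      data.frame(habitat = h, gdd = gdd,
                 intake_kj_h = cf$intercept + cf$slope * gdd +
                   rnorm(n_per_habitat, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
}
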