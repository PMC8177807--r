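# Solar and lunar ephemeris: day length, night windows, moonlit hours.
#
# Solar events follow the NOAA solar calculator algorithm (position of the
# sun from Julian-century polynomials, sunrise/sunset at solar altitude
# -0.833 degrees). Lunar altitude uses a truncated low-precision series for
# ecliptic longitude/latitude/parallax (accuracy a few tenths of a degree),
# which is ample for deciding whether the moon is above the horizon during
# a night. All timestamps are UTC.

DEG <- pi / 180

julian_day <- function(t) as.numeric(as_utc(t)) / 86400 + 2440587.5

# Sun geometry at Julian centuries jc since J2000: declination (deg) and
# equation of time (minutes). Vectorised.
sun_geometry <- function(jc) {
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  mr <- m * DEG
  csun <- sin(mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * mr) * (0.019993 - 0.000101 * jc) + sin(3 * mr) * 0.000289
  true_long <- l0 + csun
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * DEG)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * DEG)
  decl <- asin(sin(eps * DEG) * sin(app_long * DEG)) / DEG
  y <- tan(eps / 2 * DEG)^2
  l0r <- l0 * DEG
  eqtime <- 4 / DEG * (y * sin(2 * l0r) - 2 * ecc * sin(mr) +
    4 * ecc * y * sin(mr) * cos(2 * l0r) -
    0.5 * y^2 * sin(4 * l0r) - 1.25 * ecc^2 * sin(2 * mr))
  list(decl = decl, eqtime = eqtime)
}

#' Sunrise, sunset and day length for a date and location
#'
#' Computes solar events with the NOAA solar calculator algorithm
#' (sunrise/sunset at solar altitude -0.833 degrees, i.e. the standard
#' refraction + solar radius convention). Polar day and polar night are
#' flagged instead of returning events.
#'
#' @param date `Date` vector (events are computed for the UTC calendar day).
#' @param lat,lon Latitude and longitude in degrees (east positive).
#' @return A data.frame with one row per date: `date`, `lat`, `lon`,
#'   `sunrise`, `sunset` (POSIXct UTC, `NA` when no event), `day_length_h`,
#'   and `polar` (`"day"`, `"night"` or `NA`).
#' @examples
#' solar_events(as.Date("2015-03-15"), 53.87, 7.3)
#' @export
solar_events <- function(date, lat, lon) {
  stopifnot(abs(lat) <= 90)
  date <- as.Date(date)
  jd_noon <- as.numeric(date) + 2440587.5 + 0.5 # 12:00 UTC of that day
  jc <- (jd_noon - 2451545) / 36525
  g <- sun_geometry(jc)
  cos_ha <- cos(90.833 * DEG) / (cos(lat * DEG) * cos(g$decl * DEG)) -
    tan(lat * DEG) * tan(g$decl * DEG)
  noon_min <- 720 - 4 * lon - g$eqtime
  ha_deg <- ifelse(abs(cos_ha) <= 1, acos(pmin(1, pmax(-1, cos_ha))) / DEG, NA_real_)
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunrise <- midnight + 60 * (noon_min - 4 * ha_deg)
  sunset  <- midnight + 60 * (noon_min + 4 * ha_deg)
  polar <- ifelse(cos_ha < -1, "day", ifelse(cos_ha > 1, "night", NA_character_))
  day_length <- ifelse(is.na(polar), 8 * ha_deg / 60,
                       ifelse(polar == "day", 24, 0))
  data.frame(date = date, lat = lat, lon = lon,
             sunrise = sunrise, sunset = sunset,
             day_length_h = day_length, polar = polar,
             stringsAsFactors = FALSE)
}

# Topocentric lunar altitude (degrees) at POSIXct times. Truncated
# low-precision series for the geocentric position, first-order parallax
# correction for the observer.
moon_altitude <- function(t, lat, lon) {
  d <- julian_day(t) - 2451545
  tc <- d / 36525
  s <- function(a, b) sin((a + b * tc) * DEG)
  cc <- function(a, b) cos((a + b * tc) * DEG)
  lam <- 218.32 + 481267.8813 * tc +
    6.29 * s(134.9, 477198.85) - 1.27 * s(259.2, -413335.38) +
    0.66 * s(235.7, 890534.23) + 0.21 * s(269.9, 954397.70) -
    0.19 * s(357.5, 35999.05) - 0.11 * s(186.6, 966404.05)
  bet <- 5.13 * s(93.3, 483202.03) + 0.28 * s(228.2, 960400.87) -
    0.28 * s(318.3, 6003.18) - 0.17 * s(217.6, -407332.20)
  parallax <- 0.9508 + 0.0518 * cc(134.9, 477198.85) +
    0.0095 * cc(259.2, -413335.38) + 0.0078 * cc(235.7, 890534.23) +
    0.0028 * cc(269.9, 954397.70)
  eps <- (23.4393 - 0.0130 * tc) * DEG
  lamr <- lam * DEG; betr <- bet * DEG
  xe <- cos(betr) * cos(lamr)
  ye <- cos(eps) * cos(betr) * sin(lamr) - sin(eps) * sin(betr)
  ze <- sin(eps) * cos(betr) * sin(lamr) + cos(eps) * sin(betr)
  ra <- atan2(ye, xe)
  dec <- asin(ze)
  gmst <- (280.46061837 + 360.98564736629 * d) %% 360
  h <- (gmst + lon) * DEG - ra
  alt <- asin(sin(lat * DEG) * sin(dec) +
              cos(lat * DEG) * cos(dec) * cos(h)) / DEG
  alt - parallax * cos(alt * DEG)
}

#' Night window following a date's sunset
#'
#' The night belonging to `date` runs from that date's sunset to the next
#' day's sunrise (civil twilight is not subtracted; day length is defined
#' sunrise-to-sunset).
#'
#' @param date `Date` scalar or vector.
#' @param lat,lon Location in degrees.
#' @return data.frame with `date`, `night_start`, `night_end`,
#'   `night_length_h`. Polar-day nights have zero length.
#' @export
night_window <- function(date, lat, lon) {
  date <- as.Date(date)
  s0 <- solar_events(date, lat, lon)
  s1 <- solar_events(date + 1, lat, lon)
  start <- s0$sunset
  end <- s1$sunrise
  # polar day: empty night anchored at local midnight; polar night: full 24 h
  mid <- as.POSIXct(paste(date, "23:59:59"), tz = "UTC")
  polar_day <- !is.na(s0$polar) & s0$polar == "day"
  polar_night <- !is.na(s0$polar) & s0$polar == "night"
  start[polar_day] <- mid[polar_day]
  end[polar_day] <- mid[polar_day]
  if (any(polar_night)) {
    start[polar_night] <- as.POSIXct(paste(date[polar_night], "12:00:00"),
                                     tz = "UTC")
    end[polar_night] <- start[polar_night] + 86400
  }
  data.frame(date = date, night_start = start, night_end = end,
             night_length_h = as.numeric(difftime(end, start, units = "hours")))
}

#' Intervals during a night when the moon is above the horizon
#'
#' Either computes lunar altitude on a 1-minute grid with the built-in
#' low-precision lunar series, or clips moonrise/moonset intervals from an
#' injected ephemeris table (`date`, `moonrise`, `moonset`; timestamps UTC)
#' to the night window. The injected-table path is the reference path for
#' testing interval bookkeeping.
#'
#' @param night_start,night_end POSIXct night bounds (sunset to next sunrise).
#' @param lat,lon Location in degrees (ignored in table mode).
#' @param table Optional injected data.frame with POSIXct columns `moonrise`
#'   and `moonset` (one row per lunar pass; a pass may span midnight).
#' @return data.frame with columns `start`, `end` (possibly 0 rows), clipped
#'   to the night window.
#' @export
moon_intervals <- function(night_start, night_end, lat = NULL, lon = NULL,
                           table = NULL) {
  night_start <- as_utc(night_start); night_end <- as_utc(night_end)
  stopifnot(length(night_start) == 1, length(night_end) == 1,
            night_start <= night_end)
  if (is.null(table)) {
    if (is.null(lat) || is.null(lon)) {
      stop("moon_intervals() needs either lat/lon for the lunar algorithm ",
           "or an injected ephemeris table")
    }
    if (night_end - night_start < as.difftime(1, units = "mins")) {
      return(data.frame(start = night_start[0], end = night_end[0]))
    }
    grid <- seq(night_start, night_end, by = 60)
    up <- moon_altitude(grid, lat, lon) > 0
    runs <- rle(up)
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    keep <- runs$values
    out <- data.frame(start = grid[starts[keep]],
                      end = pmin(grid[pmin(ends[keep] + 1, length(grid))], night_end))
    return(out)
  }
  if (!all(c("moonrise", "moonset") %in% names(table))) {
    stop("injected ephemeris table must have 'moonrise' and 'moonset' columns")
  }
  rs <- as_utc(table$moonrise); st <- as_utc(table$moonset)
  ok <- !is.na(rs) & !is.na(st)
  a <- pmax(rs[ok], night_start)
  b <- pmin(st[ok], night_end)
  keep <- a < b
  data.frame(start = a[keep], end = b[keep])
}

#' Total moonlit hours in a night
#'
#' Merges overlapping intervals, clips them to the night window and sums
#' their lengths.
#'
#' @param intervals data.frame with `start`, `end` POSIXct columns.
#' @param night_start,night_end Night bounds; intervals are clipped to them.
#' @return Hours (numeric scalar), between 0 and the night length.
#' @export
moonlit_hours <- function(intervals, night_start, night_end) {
  night_start <- as_utc(night_start); night_end <- as_utc(night_end)
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  a <- as.numeric(pmax(as_utc(intervals$start), night_start))
  b <- as.numeric(pmin(as_utc(intervals$end), night_end))
  keep <- a < b
  if (!any(keep)) return(0)
  a <- a[keep]; b <- b[keep]
  o <- order(a)
  a <- a[o]; b <- b[o]
  tot <- 0; cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] <= cur_b) {
      cur_b <- max(cur_b, b[i])
    } else {
      tot <- tot + (cur_b - cur_a)
      cur_a <- a[i]; cur_b <- b[i]
    }
  }
  (tot + (cur_b - cur_a)) / 3600
}

#' Moonlit hours for every night in a date range
#'
#' Convenience wrapper producing, per date, the night window after that
#' date's sunset and its moonlit hours (algorithmic lunar mode).
#'
#' @param dates `Date` vector.
#' @param lat,lon Location in degrees.
#' @return data.frame `date`, `night_start`, `night_end`, `night_length_h`,
#'   `moonlit_h`.
#' @export
night_table <- function(dates, lat, lon) {
  nw <- night_window(dates, lat, lon)
  nw$moonlit_h <- vapply(seq_len(nrow(nw)), function(i) {
    iv <- moon_intervals(nw$night_start[i], nw$night_end[i], lat, lon)
    moonlit_hours(iv, nw$night_start[i], nw$night_end[i])
  }, numeric(1))
  nw
}

#' Classify a timestamp as day or night
#'
#' Day is `sunrise <= t < sunset` of the fix's date; everything else is
#' night, attributed to the night that starts at the most recent sunset.
#'
#' @param t POSIXct vector (UTC).
#' @param lat,lon Location in degrees.
#' @return data.frame `t`, `daynight` (`"day"`/`"night"`), `night_date`
#'   (date of the sunset opening the night; `NA` for day fixes).
#' @export
assign_day_night <- function(t, lat, lon) {
  t <- as_utc(t)
  d <- as.Date(t, tz = "UTC")
  sol <- solar_events(unique(d), lat, lon)
  idx <- match(d, sol$date)
  sunrise <- sol$sunrise[idx]; sunset <- sol$sunset[idx]
  polar <- sol$polar[idx]
  is_day <- !is.na(sunrise) & t >= sunrise & t < sunset
  is_day[!is.na(polar) & polar == "day"] <- TRUE
  is_day[!is.na(polar) & polar == "night"] <- FALSE
  # night attribution: after sunset -> this date's night; before sunrise ->
  # previous date's night
  night_date <- d
  pre_dawn <- !is_day & !is.na(sunrise) & t < sunrise
  night_date[pre_dawn] <- d[pre_dawn] - 1
  night_date[is_day] <- NA
  data.frame(t = t, daynight = ifelse(is_day, "day", "night"),
             night_date = night_date)
}
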