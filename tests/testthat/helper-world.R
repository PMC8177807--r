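# Shared fixtures, generated in code and cached for the test session.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

SITE_LAT <- 53.87
SITE_LON <- 7.3

test_nights <- function(start = "2015-01-01", end = "2015-05-15") {
  cached(paste0("nights_", start, "_", end),
         night_table(seq(as.Date(start), as.Date(end), by = 1),
                     SITE_LAT, SITE_LON))
}

# two birds, January-February: enough structure for budget/BMT unit tests
small_world <- function() {
  cached("small_world", {
    cfg <- sim_config(n_birds = 2, end_date = "2015-03-01",
                      departure_doy = 59, seed = 11)
    nights <- test_nights("2015-01-01", "2015-03-01")
    tracks <- generate_track(cfg, nights = nights)
    weather <- generate_weather(cfg)
    fixes <- water_correction(resample_fixes(tracks, cfg$fix_interval))
    gdd <- growing_degree_days(weather_daily_means(weather))
    list(cfg = cfg, nights = nights, tracks = tracks, weather = weather,
         fixes = fixes, gdd = gdd, pim = pi_model())
  })
}

# four birds over the full season, all three scenarios simulated
season_world <- function() {
  cached("season_world", {
    cfg <- sim_config(n_birds = 4, seed = 5)
    nights <- test_nights()
    tracks <- generate_track(cfg, nights = nights)
    weather <- generate_weather(cfg)
    fixes <- water_correction(resample_fixes(tracks, cfg$fix_interval))
    gdd <- growing_degree_days(weather_daily_means(weather))
    pim <- pi_model()
    base <- simulate_bmt(fixes, weather, pim, gdd, 1600)
    nn <- simulate_bmt(apply_no_night_scenario(fixes, SITE_LAT, SITE_LON),
                       weather, pim, gdd, 1600, scenario = "no_night")
    mf <- simulate_bmt(apply_max_foraging_scenario(fixes, SITE_LAT, SITE_LON),
                       weather, pim, gdd, 1600, scenario = "max_foraging")
    list(cfg = cfg, nights = nights, fixes = fixes, weather = weather,
         gdd = gdd, pim = pim, baseline = base, no_night = nn,
         max_foraging = mf)
  })
}

default_bursts <- function() {
  cached("default_bursts", generate_bursts(sim_config()))
}

default_burst_features <- function() {
  cached("default_burst_features", burst_features(default_bursts()))
}
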