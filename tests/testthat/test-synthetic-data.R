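# Generators: determinism, configured structure, recoverability.

test_that("configuration is validated", {
  expect_error(sim_config(start_date = "2015-05-01", end_date = "2015-02-01"),
               "invalid date range")
  expect_error(sim_config(n_birds = 0))
  expect_error(sim_config(day_forage_frac = 1.2))
  expect_error(generate_bursts(sim_config(burst_class_counts =
    c(inactive = 0, active = 0, foraging = 0, flying = 0))), "empty")
  expect_error(generate_intake_obs(sim_config(), noise_sd = -1),
               "non-negative")
})

test_that("generators are bit-reproducible given the seed", {
  cfg <- sim_config(n_birds = 2, end_date = "2015-01-20", seed = 123)
  nights <- test_nights("2015-01-01", "2015-01-20")
  expect_identical(generate_track(cfg, nights), generate_track(cfg, nights))
  expect_identical(generate_bursts(cfg), generate_bursts(cfg))
  expect_identical(generate_weather(cfg), generate_weather(cfg))
  expect_identical(generate_intake_obs(cfg), generate_intake_obs(cfg))
  # a different seed changes the draw
  cfg2 <- sim_config(n_birds = 2, end_date = "2015-01-20", seed = 124)
  expect_false(identical(generate_track(cfg2, nights),
                         generate_track(cfg, nights)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(77)
  a <- rnorm(1)
  set.seed(77)
  invisible(generate_bursts(sim_config(n_birds = 1)))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("burst set matches the calibration counts and is separable", {
  bursts <- default_bursts()
  expect_equal(nrow(bursts), 945)
  counts <- table(bursts$class)
  expect_equal(counts[["inactive"]], 796)
  expect_equal(counts[["active"]], 57)
  expect_equal(counts[["foraging"]], 44)
  expect_equal(counts[["flying"]], 48)
  feats <- default_burst_features()
  # inactive bursts sit below the foraging ODBA distribution
  expect_lt(max(feats$odba[feats$class == "inactive"]),
            quantile(feats$odba[feats$class == "foraging"], 0.01))
  # head-down grazing vs upright activity separates in pitch
  expect_lt(max(feats$pitch_deg[feats$class == "foraging"]),
            min(feats$pitch_deg[feats$class == "active"]))
})

test_that("daytime foraging occupies the configured fraction of daylight", {
  cfg <- sim_config() # study conditions: 23 birds, full season
  tracks <- cached("default_tracks", generate_track(cfg, test_nights()))
  fixes <- resample_fixes(tracks, cfg$fix_interval)
  dn <- assign_day_night(fixes$slot_start + 900, cfg$site_lat, cfg$site_lon)
  frac <- mean(fixes$behavior[dn$daynight == "day"] == "foraging")
  expect_lt(abs(frac - 0.66), 0.05)
})

test_that("night foraging tracks moonlight, and not when the gain is off", {
  nights <- test_nights()
  # moonlight effect net of the seasonal decline shared by both series
  partial_cor <- function(nb) {
    doy <- as.numeric(format(nb$night_date, "%j"))
    cor(resid(lm(nb$forage_night_min ~ doy)),
        resid(lm(nb$moonlit_h ~ doy)))
  }
  cfg <- sim_config(n_birds = 2, seed = 21)
  tr <- generate_track(cfg, nights)
  nb <- nightly_budget(resample_fixes(tr, 30), cfg$site_lat, cfg$site_lon,
                       nights = nights)
  expect_gt(partial_cor(nb), 0.5)

  cfg0 <- sim_config(n_birds = 2, seed = 21, night_forage_moon_gain = 0)
  tr0 <- generate_track(cfg0, nights)
  nb0 <- nightly_budget(resample_fixes(tr0, 30), cfg$site_lat, cfg$site_lon,
                        nights = nights)
  expect_lt(abs(partial_cor(nb0)), 0.15)
})

test_that("weather has the configured seasonal and diel structure", {
  flat <- generate_weather(sim_config(n_birds = 1, temp_winter = 5,
                                      temp_spring = 5))
  expect_true(all(abs(flat$temp_trend_c - 5) < 1e-9))

  w <- generate_weather(sim_config(n_birds = 1))
  jan <- mean(w$t_air_c[format(w$date, "%m") == "01"])
  apr <- mean(w$t_air_c[format(w$date, "%m") == "04"])
  expect_lt(jan, apr)
  # local midnight (00:00 UTC is 29 min before local solar midnight): no sun
  expect_true(all(w$radiation_w_m2[format(w$t, "%H") == "00"] == 0))
  expect_true(all(w$radiation_w_m2 >= 0))
  expect_true(all(w$cloud >= 0 & w$cloud <= 1))
})

test_that("intake observations recover the true PI lines", {
  cfg <- sim_config(seed = 31)
  truth <- pi_model(agricultural = c(85, 0.06), natural = c(75, 0.06))
  exact <- generate_intake_obs(cfg, truth, n_per_habitat = 30, noise_sd = 0)
  fit0 <- fit_pi_regression(exact)
  for (h in c("agricultural", "natural")) {
    expect_equal(fit0$habitats[[h]]$intercept, truth$habitats[[h]]$intercept,
                 tolerance = 1e-9)
    expect_equal(fit0$habitats[[h]]$slope, truth$habitats[[h]]$slope,
                 tolerance = 1e-9)
  }
  noisy <- generate_intake_obs(cfg, truth, n_per_habitat = 200, noise_sd = 8)
  fit <- fit_pi_regression(noisy)
  for (h in c("agricultural", "natural")) {
    sub <- noisy[noisy$habitat == h, ]
    se <- summary(lm(intake_kj_h ~ gdd, data = sub))$coefficients[, 2]
    expect_lt(abs(fit$habitats[[h]]$intercept - truth$habitats[[h]]$intercept),
              3 * se[1])
    expect_lt(abs(fit$habitats[[h]]$slope - truth$habitats[[h]]$slope),
              3 * se[2])
  }
})

test_that("fix drop-out produces missing time in budgets", {
  nights <- test_nights("2015-01-01", "2015-01-15")
  cfg <- sim_config(n_birds = 1, end_date = "2015-01-15", seed = 8,
                    dropout_prob = 0.2, departure_doy = 15)
  fx <- resample_fixes(generate_track(cfg, nights), 30)
  bud <- daily_time_budget(fx, cfg$site_lat, cfg$site_lon, nights = nights)
  inner <- bud[bud$date > as.Date("2015-01-01") &
               bud$date < as.Date("2015-01-14"), ]
  expect_gt(mean(inner$missing_min), 0)
})
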