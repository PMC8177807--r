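# Body-mass recursion, scenarios, departure metrics.

test_that("mass steps follow the storage/burning efficiencies", {
  p <- energetics_params()
  expect_equal(step_mass(1600, 100, 100, p), 1600)
  expect_equal(step_mass(1600, 129, 100, p), 1600.8) # +29 kJ -> +0.8 g
  expect_equal(step_mass(1600, 71, 100, p), 1599)    # -29 kJ -> -1 g
  expect_error(step_mass(0, 1, 1, p), "positive")
})

test_that("the 30-day night mapping reproduces the printed correspondences", {
  # nights of Jan 31/Feb 1, Mar 2/3, Apr 1/2, May 1/2 -> night of Jan 1/2
  expect_equal(scenario_source_doy(c(31, 61, 91, 121)), rep(1, 4))
  # nights of Feb 1/2, Mar 3/4, Apr 2/3, May 2/3 -> night of Jan 2/3
  expect_equal(scenario_source_doy(c(32, 62, 92, 122)), rep(2, 4))
  # January nights map to themselves
  expect_equal(scenario_source_doy(1:30), 1:30)
})

test_that("the no-night scenario silences nocturnal behavior only", {
  w <- small_world()
  nn <- apply_no_night_scenario(w$fixes, SITE_LAT, SITE_LON)
  dn <- assign_day_night(w$fixes$slot_start + 900, SITE_LAT, SITE_LON)
  night <- dn$daynight == "night"
  expect_true(all(nn$behavior[night] == "inactive"))
  expect_identical(nn$behavior[!night], w$fixes$behavior[!night])
  expect_identical(attr(nn, "scenario"), "no_night")
})

test_that("the maximum-foraging scenario copies January night budgets", {
  w <- small_world()
  mx <- apply_max_foraging_scenario(w$fixes, SITE_LAT, SITE_LON)
  dn <- assign_day_night(w$fixes$slot_start + 900, SITE_LAT, SITE_LON)
  doy <- as.integer(dn$night_date - as.Date("2015-01-01")) + 1L
  night <- dn$daynight == "night" & !is.na(doy)
  # January nights (doy <= 30) untouched
  jan <- night & doy >= 1 & doy <= 30
  expect_identical(mx$behavior[jan], w$fixes$behavior[jan])
  # day fixes untouched
  expect_identical(mx$behavior[dn$daynight == "day"],
                   w$fixes$behavior[dn$daynight == "day"])
  # a February night receives the opening slots of its January source night
  b <- w$fixes$bird[1]
  for (d in c(35L, 40L)) {
    tgt <- which(w$fixes$bird == b & night & doy == d)
    src <- which(w$fixes$bird == b & night & doy == scenario_source_doy(d))
    tgt <- tgt[order(w$fixes$slot_start[tgt])]
    src <- src[order(w$fixes$slot_start[src])]
    k <- min(length(tgt), length(src))
    expect_identical(mx$behavior[tgt[seq_len(k)]],
                     w$fixes$behavior[src[seq_len(k)]])
    expect_identical(mx$habitat[tgt[seq_len(k)]],
                     w$fixes$habitat[src[seq_len(k)]])
  }
})

test_that("starting mass resolves explicit, size-rule and default paths", {
  expect_equal(start_mass_from_size(explicit_g = 1500), 1500)
  expect_equal(start_mass_from_size(), 1600)
  expect_equal(start_mass_from_size(size = 110, coef = c(200, 12.5)),
               200 + 12.5 * 110)
  expect_error(start_mass_from_size(default_g = NULL), "no starting mass")
  expect_error(start_mass_from_size(size = 110), "coefficients")
})

test_that("zero intake and vanishing costs leave mass constant", {
  w <- small_world()
  p0 <- energetics_params(multipliers = c(inactive = 1e-12, active = 1e-12,
                                          foraging = 1e-12),
                          flight_bmr_multiple = 1e-12,
                          thermo_model = function(wx, m, dt, p) 0 * dt)
  zero_pi <- pi_model(agricultural = c(0, 0), natural = c(0, 0))
  tr <- simulate_bmt(w$fixes[w$fixes$bird == w$fixes$bird[1], ], w$weather,
                     zero_pi, w$gdd, 1600, p0)
  expect_true(all(abs(tr$mass_g - 1600) < 1e-6))
})

test_that("a constant surplus grows mass exactly linearly", {
  t0 <- as.POSIXct("2015-01-05 00:00:00", tz = "UTC")
  fx <- resample_fixes(data.frame(bird = "b1", t = t0 + 1800 * (0:99),
                                  behavior = "foraging",
                                  habitat = "agricultural",
                                  stringsAsFactors = FALSE), 30)
  w <- small_world()
  p0 <- energetics_params(multipliers = c(inactive = 1e-12, active = 1e-12,
                                          foraging = 1e-12),
                          thermo_model = function(wx, m, dt, p) 0 * dt)
  flat_pi <- pi_model(agricultural = c(58, 0), natural = c(58, 0))
  tr <- simulate_bmt(fx, w$weather, flat_pi, w$gdd, 1600, p0)
  s <- 58 * 0.5 # kJ per 30-min step
  expect_equal(tr$mass_g, 1600 + 0.8 * s / 29 * seq_len(100),
               tolerance = 1e-9)
})

test_that("trajectories satisfy the mass-conservation identity", {
  w <- season_world()
  for (sc in c("baseline", "no_night", "max_foraging")) {
    tr <- w[[sc]]
    for (b in unique(tr$bird)) {
      sub <- tr[tr$bird == b, ]
      s <- sub$intake_kj - sub$cost_kj
      expected_delta <- (0.8 * sum(s[s >= 0]) + sum(s[s < 0])) / 29
      expect_equal(sub$mass_g[nrow(sub)] - 1600, expected_delta,
                   tolerance = 1e-9)
    }
  }
})

test_that("missing weather or GDD coverage raises a named error", {
  w <- small_world()
  short_weather <- w$weather[w$weather$date < as.Date("2015-02-01"), ]
  expect_error(simulate_bmt(w$fixes, short_weather, w$pim, w$gdd, 1600),
               "weather table does not cover")
  short_gdd <- w$gdd[w$gdd$date < as.Date("2015-02-01"), ]
  expect_error(simulate_bmt(w$fixes, w$weather, w$pim, short_gdd, 1600),
               "GDD series does not cover")
})

test_that("departure metrics find maxima, ties and threshold crossings", {
  t0 <- as.POSIXct("2015-03-01 00:00:00", tz = "UTC")
  up <- data.frame(bird = "b", t = t0 + 1800 * (0:99),
                   mass_g = 1500 + 2 * (0:99))
  m <- departure_metrics(up)
  expect_equal(m$t_max_mass, up$t[100]) # strictly increasing: max at the end
  expect_equal(m$max_mass_g, 1698)

  flat <- data.frame(bird = "b", t = t0 + 1800 * (0:9), mass_g = 1500)
  expect_equal(departure_metrics(flat)$t_max_mass, t0) # tie: first timestamp

  # linear ramp 1500 + 1 g per step: analytic crossing of 1550 at step 50
  ramp <- data.frame(bird = "b", t = t0 + 1800 * (0:99),
                     mass_g = 1500 + (0:99))
  mm <- departure_metrics(ramp, reference_mass_g = 1550)
  expect_lt(abs(as.numeric(mm$t_reach_reference - (t0 + 1800 * 50),
                           units = "secs")), 1800)
  # never reached -> flagged absent
  m2 <- departure_metrics(ramp, reference_mass_g = 1e6)
  expect_true(is.na(m2$t_reach_reference))

  m3 <- departure_metrics(up, breakpoint_day = 60)
  expect_equal(m3$deposition_period_days,
               m3$doy_max_mass - 60, tolerance = 1e-9)
})

test_that("scenarios order pathwise when night feeding pays", {
  w <- season_world()
  expect_true(all(w$no_night$mass_g <= w$baseline$mass_g + 1e-9))
  expect_true(all(w$max_foraging$mass_g >= w$baseline$mass_g - 1e-9))
})

test_that("cutting PI drives baseline mass monotonically down", {
  w <- small_world()
  tiny_pi <- pi_model(agricultural = c(5, 0), natural = c(5, 0))
  tr <- simulate_bmt(w$fixes[w$fixes$bird == w$fixes$bird[1], ], w$weather,
                     tiny_pi, w$gdd, 1600)
  expect_true(all(diff(tr$mass_g) <= 1e-12))
})
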