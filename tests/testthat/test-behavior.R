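# Burst features, classifier, kappa, resampling, corrections, budgets.

test_that("burst features recover posture and dynamics", {
  level <- matrix(rep(c(0, 0, 1), each = 10), ncol = 3) # static, level
  f <- acc_features(level)
  expect_equal(unname(f), c(0, 0, 0, 0), tolerance = 1e-12)

  upright <- matrix(rep(c(1, 0, 0), each = 10), ncol = 3) # x axis vertical
  f2 <- acc_features(upright)
  expect_equal(f2[["pitch_deg"]], 90)
  expect_equal(f2[["odba"]], 0)

  expect_error(acc_features(matrix(0, 10, 3)), "zero-norm")
})

test_that("ODBA matches a direct recomputation from its definition", {
  set.seed(42)
  for (i in 1:20) {
    burst <- matrix(rnorm(30, c(0, 0, 1), 0.3), ncol = 3, byrow = FALSE)
    f <- acc_features(burst)
    # independent re-evaluation, scalar arithmetic
    odba <- 0
    for (ax in 1:3) {
      odba <- odba + mean(abs(burst[, ax] - mean(burst[, ax])))
    }
    expect_equal(f[["odba"]], odba, tolerance = 1e-12)
    d <- 0
    for (j in 2:10) d <- d + abs(burst[j, 1] - burst[j - 1, 1])
    expect_equal(f[["dx_abs"]], d / 9 * 20, tolerance = 1e-12)
  }
})

test_that("Cohen's kappa: perfect, chance-level and hand-computed cases", {
  expect_equal(cohen_kappa(diag(c(10, 5, 3))), 1)
  # rows proportional to the column margins: exactly chance agreement
  expect_equal(cohen_kappa(matrix(c(30, 20, 30, 20), 2)), 0)
  # hand computation: p_o = 0.7, p_e = 0.5
  expect_equal(cohen_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4)
})

test_that("kappa is invariant under simultaneous row+column permutation", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rpois(16, 20), 4)
    p <- sample(4)
    expect_equal(cohen_kappa(m), cohen_kappa(m[p, p]), tolerance = 1e-12)
  }
})

test_that("kappa warns on degenerate margins", {
  m <- matrix(c(5, 0, 0, 0), 2) # single occupied cell: chance agreement 1
  expect_warning(k <- cohen_kappa(m), "degenerate")
  expect_true(is.na(k))
})

test_that("a 40/60 split of the calibration set leaves 567 test samples", {
  expect_equal(unname(split_sizes(945, 0.4)), c(378, 567))
})

test_that("classifier separates synthetic burst classes", {
  feats <- default_burst_features()
  clf <- train_classifier(feats, seed = 3)
  expect_equal(clf$report$n_test, 567)
  expect_gt(clf$report$overall_accuracy, 0.95)
  expect_gt(clf$report$kappa, 0.85)
  expect_length(clf$report$per_class_precision, 4)
  expect_true(all(clf$report$per_class_precision >= 0 &
                  clf$report$per_class_precision <= 1))
  # seeded determinism
  clf2 <- train_classifier(feats, seed = 3)
  expect_identical(clf$report, clf2$report)
  expect_identical(clf$train_idx, clf2$train_idx)
})

test_that("resampling keeps the first fix per slot", {
  t0 <- as.POSIXct("2015-02-01 00:00:00", tz = "UTC")
  f15 <- data.frame(bird = "b1", t = t0 + 900 * (0:19))
  r <- resample_fixes(f15, 30)
  expect_equal(nrow(r), 10)
  expect_equal(r$t, f15$t[seq(1, 20, by = 2)]) # every second fix

  f30 <- data.frame(bird = "b1", t = t0 + 1800 * (0:9))
  r30 <- resample_fixes(f30, 30)
  expect_equal(r30$t, f30$t) # already 30-min data: identity

  # irregular data: occupancy equals brute-force slot assignment
  set.seed(4)
  tt <- t0 + sort(sample(0:(6 * 3600), 50))
  fi <- data.frame(bird = "b1", t = tt)
  ri <- resample_fixes(fi, 30)
  slots <- unique(floor(as.numeric(tt) / 1800))
  expect_equal(nrow(ri), length(slots))
  expect_equal(as.numeric(ri$slot_start) / 1800, slots)
  for (i in seq_len(nrow(ri))) {
    in_slot <- tt[floor(as.numeric(tt) / 1800) == slots[i]]
    expect_equal(ri$t[i], min(in_slot)) # first fix in the slot retained
  }
})

test_that("foraging on open water is corrected to inactive", {
  f <- data.frame(behavior = c("foraging", "foraging", "flying", "inactive"),
                  habitat = c("water", "agricultural", "water", "water"),
                  stringsAsFactors = FALSE)
  g <- water_correction(f)
  expect_equal(g$behavior, c("inactive", "foraging", "flying", "inactive"))
  expect_equal(g$habitat, f$habitat)
})

test_that("daily budgets conserve minutes and match a brute-force oracle", {
  w <- small_world()
  bud <- daily_time_budget(w$fixes, SITE_LAT, SITE_LON, nights = w$nights)
  cats <- c("forage_day_agri_min", "forage_day_nat_min",
            "forage_night_agri_min", "forage_night_nat_min",
            "forage_other_min", "active_day_min", "active_night_min",
            "inactive_min", "flying_min", "missing_min")
  expect_true(all(abs(rowSums(bud[, cats]) - 1440) < 1e-9))
  expect_true(all(bud[, cats] >= 0))

  # brute-force oracle for one bird-day, classifying slots directly
  b <- bud$bird[1]
  day <- as.Date("2015-01-20")
  sol <- solar_events(day, SITE_LAT, SITE_LON)
  fx <- w$fixes[w$fixes$bird == b &
                as.Date(w$fixes$slot_start, tz = "UTC") == day, ]
  mids <- fx$slot_start + 900
  is_day <- mids >= sol$sunrise & mids < sol$sunset
  oracle_fday <- 30 * sum(fx$behavior == "foraging" & is_day &
                          fx$habitat %in% c("agricultural", "natural"))
  oracle_fnight <- 30 * sum(fx$behavior == "foraging" & !is_day &
                            fx$habitat %in% c("agricultural", "natural"))
  row <- bud[bud$bird == b & bud$date == day, ]
  expect_equal(row$forage_day_min, oracle_fday, tolerance = 1e-9)
  expect_equal(row$forage_night_min, oracle_fnight, tolerance = 1e-9)
})

test_that("a fully foraging 8-hour day books about 480 daytime minutes", {
  day <- as.Date("2015-01-20") # ~8-h day at the site
  t0 <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  fx <- data.frame(bird = "b1", t = t0 + 1800 * (0:47),
                   behavior = "foraging", habitat = "agricultural",
                   stringsAsFactors = FALSE)
  fx <- resample_fixes(fx, 30)
  bud <- daily_time_budget(fx, SITE_LAT, SITE_LON)
  row <- bud[bud$date == day, ]
  expect_lt(abs(row$forage_day_min -
                60 * solar_events(day, SITE_LAT, SITE_LON)$day_length_h),
            31) # slot granularity
  # four night slots foraging only
  fx2 <- fx
  fx2$behavior <- "inactive"
  fx2$behavior[1:4] <- "foraging" # 00:00-02:00, well before sunrise
  bud2 <- daily_time_budget(fx2, SITE_LAT, SITE_LON)
  expect_equal(bud2[bud2$date == day, "forage_night_min"], 120)
})

test_that("nightly budgets aggregate by the night of the sunset", {
  w <- small_world()
  nb <- nightly_budget(w$fixes, SITE_LAT, SITE_LON, nights = w$nights)
  expect_true(all(nb$forage_night_min >= 0))
  expect_true(all(nb$forage_night_min <= nb$night_length_h * 60 + 30))
  # a night's foraging equals the sum over its slots in both halves of the night
  b <- nb$bird[1]
  nd <- as.Date("2015-01-15")
  dn <- assign_day_night(w$fixes$slot_start + 900, SITE_LAT, SITE_LON)
  sel <- w$fixes$bird == b & dn$daynight == "night" &
    !is.na(dn$night_date) & dn$night_date == nd
  expect_equal(nb$forage_night_min[nb$bird == b & nb$night_date == nd],
               30 * sum(w$fixes$behavior[sel] == "foraging"))
})
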