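# End-to-end orchestration and table validation.

#' Pipeline configuration
#'
#' Bundles the generator settings, energetic parameters, true intake model,
#' scenario list, inference settings and output directory for
#' [run_pipeline()].
#'
#' @param sim [sim_config()] for the synthetic inputs.
#' @param out_dir Output directory (created if missing).
#' @param pi_true True intake model used by the generator.
#' @param params [energetics_params()].
#' @param start_mass_g Starting body mass (g).
#' @param scenarios Scenario subset to simulate.
#' @param sensitivity list with `n_pi`, `n_bmr`, `n_both` (set to `NULL` to
#'   skip the sensitivity stage).
#' @param seed Pipeline seed (defaults to the generator seed).
#' @return `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = tempfile("goosefuel_run_"),
                            pi_true = pi_model(),
                            params = energetics_params(),
                            start_mass_g = 1600,
                            scenarios = c("baseline", "no_night",
                                          "max_foraging"),
                            sensitivity = list(n_pi = 3, n_bmr = 3,
                                               n_both = 6),
                            seed = sim$seed) {
  scenarios <- match.arg(scenarios, c("baseline", "no_night", "max_foraging"),
                         several.ok = TRUE)
  structure(list(sim = sim, out_dir = out_dir, pi_true = pi_true,
                 params = params, start_mass_g = start_mass_g,
                 scenarios = scenarios, sensitivity = sensitivity,
                 seed = seed), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates inputs, trains and evaluates the behavior classifier, builds
#' daily time budgets, fits the intake model, simulates body-mass
#' trajectories under the requested scenarios, estimates fueling-onset
#' breakpoints and departure metrics, compares scenarios, optionally runs a
#' sensitivity analysis, and writes every table plus a manifest (inputs,
#' parameter values, seed, md5 hashes) to `config$out_dir`.
#'
#' @param config [pipeline_config()].
#' @param verbose Print stage progress.
#' @return (invisibly) a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  sim <- config$sim
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    for (j in seq_along(df)) { # ISO-8601 UTC timestamps in all tables
      if (inherits(df[[j]], "POSIXct")) {
        df[[j]] <- format(df[[j]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      }
    }
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  say("ephemeris: solar events and moonlit nights")
  dates <- seq(sim$start_date, sim$end_date, by = 1)
  nights <- stage("ephemeris", night_table(dates, sim$site_lat, sim$site_lon))

  say("generate: tracks, bursts, weather, intake observations")
  tracks <- stage("generate_track", generate_track(sim, nights = nights))
  bursts <- stage("generate_bursts", generate_bursts(sim))
  weather <- stage("generate_weather", generate_weather(sim))
  intake_obs <- stage("generate_intake_obs",
                      generate_intake_obs(sim, config$pi_true))
  emit(tracks, "tracks.csv"); emit(weather, "weather.csv")
  emit(intake_obs, "intake_obs.csv")

  say("classify: burst features and random-forest validation")
  feats <- stage("classify", burst_features(bursts))
  clf <- stage("classify", train_classifier(feats, seed = config$seed))

  say("budgets: resampling, water correction, daily time budgets")
  fixes <- stage("budgets", resample_fixes(tracks, sim$fix_interval))
  fixes <- water_correction(fixes)
  budgets <- stage("budgets",
                   daily_time_budget(fixes, sim$site_lat, sim$site_lon,
                                     nights = nights))
  emit(budgets, "budgets.csv")

  say("intake: growing degree days and PI regression")
  gdd <- stage("intake", growing_degree_days(weather_daily_means(weather)))
  pim <- stage("intake", fit_pi_regression(intake_obs))

  say("bmt: trajectories for ", paste(config$scenarios, collapse = ", "))
  scen_fixes <- list(baseline = fixes)
  if ("no_night" %in% config$scenarios ||
      !is.null(config$sensitivity) || "max_foraging" %in% config$scenarios) {
    scen_fixes$no_night <- apply_no_night_scenario(fixes, sim$site_lat,
                                                   sim$site_lon)
    scen_fixes$max_foraging <- apply_max_foraging_scenario(fixes,
                                                           sim$site_lat,
                                                           sim$site_lon)
  }
  bmts <- lapply(config$scenarios, function(sc) {
    tr <- stage(paste0("bmt_", sc),
                simulate_bmt(scen_fixes[[sc]], weather, pim, gdd,
                             config$start_mass_g, config$params,
                             scenario = sc))
    emit(tr, paste0("bmt_", sc, ".csv"))
    tr
  })
  names(bmts) <- config$scenarios

  say("inference: breakpoints, departure metrics, scenario comparison")
  birds <- unique(fixes$bird)
  base <- bmts[["baseline"]]
  metrics <- stage("inference", do.call(rbind, lapply(birds, function(b) {
    tr <- base[base$bird == b, ]
    daily <- tr[!duplicated(as.Date(tr$t, tz = "UTC"), fromLast = TRUE), ]
    bp <- fit_breakpoint(fractional_doy(as.Date(daily$t, tz = "UTC")),
                         daily$mass_g)
    dm <- departure_metrics(tr, breakpoint_day = bp$breakpoint)
    reach_max <- if ("max_foraging" %in% names(bmts)) {
      mm <- departure_metrics(bmts[["max_foraging"]][
        bmts[["max_foraging"]]$bird == b, ],
        reference_mass_g = dm$max_mass_g)
      if (is.na(mm$t_reach_reference[1])) NA_real_ else
        fractional_doy(as.POSIXct(mm$t_reach_reference[1],
                                  origin = "1970-01-01", tz = "UTC"))
    } else NA_real_
    min_mass <- min(tr$mass_g)
    min_no_night <- if ("no_night" %in% names(bmts)) {
      min(bmts[["no_night"]]$mass_g[bmts[["no_night"]]$bird == b])
    } else NA_real_
    data.frame(bird = b, breakpoint_doy = bp$breakpoint,
               degenerate_breakpoint = bp$degenerate,
               max_mass_g = dm$max_mass_g, doy_max_mass = dm$doy_max_mass,
               deposition_period_days = dm$deposition_period_days,
               doy_max_foraging_reach = reach_max,
               min_mass_g = min_mass, min_mass_no_night_g = min_no_night,
               stringsAsFactors = FALSE)
  })))
  emit(metrics, "metrics.csv")
  comparison <- if ("max_foraging" %in% names(bmts) &&
                    sum(complete.cases(metrics$doy_max_mass,
                                       metrics$doy_max_foraging_reach)) >= 2) {
    compare_scenarios(metrics$doy_max_mass, metrics$doy_max_foraging_reach)
  } else NULL

  sens <- NULL
  if (!is.null(config$sensitivity)) {
    say("sensitivity: perturbing PI and BMR_ref")
    ns <- config$sensitivity
    sens <- stage("sensitivity",
                  sensitivity_analysis(fixes, scen_fixes$max_foraging,
                                       weather, pim, gdd,
                                       config$start_mass_g, config$params,
                                       n_pi = ns$n_pi, n_bmr = ns$n_bmr,
                                       n_both = ns$n_both,
                                       seed = config$seed))
    emit(sens$runs, "sensitivity.csv")
  }

  manifest <- list(
    seed = config$seed,
    generated = format(Sys.time(), tz = "UTC", usetz = TRUE),
    sim_config = sim[setdiff(names(sim), "burst_class_counts")],
    burst_class_counts = as.list(sim$burst_class_counts),
    energetics = config$params[c("bmr_ref_w", "w_ref_g", "lct_c",
                                 "energy_density_kj_g", "store_eff",
                                 "burn_eff", "flight_speed_kmh",
                                 "flight_bmr_multiple")],
    classifier = clf$report[c("overall_accuracy", "kappa")],
    files = lapply(written, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: ", config$out_dir)
  invisible(list(tracks = tracks, bursts = bursts, weather = weather,
                 intake_obs = intake_obs, classifier = clf, fixes = fixes,
                 budgets = budgets, gdd = gdd, pi_model = pim, bmts = bmts,
                 metrics = metrics, comparison = comparison,
                 sensitivity = sens, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Validate pipeline CSV tables
#'
#' Schema, vocabulary and ordering checks for the table dialects the
#' pipeline writes/reads. Returns one row per violation (empty data.frame
#' when everything is clean).
#'
#' @param paths Named character vector/list; recognised names are `tracks`,
#'   `weather`, `intake`, `budgets`.
#' @return data.frame `file`, `row`, `problem`.
#' @export
validate_tables <- function(paths) {
  problems <- list()
  note <- function(file, row, problem) {
    problems[[length(problems) + 1]] <<- data.frame(
      file = file, row = row, problem = problem, stringsAsFactors = FALSE)
  }
  need <- function(df, cols, file) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      note(file, NA_integer_,
           paste("missing columns:", paste(missing, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  if (!is.null(paths[["tracks"]])) {
    f <- paths[["tracks"]]; df <- read.csv(f, stringsAsFactors = FALSE)
    if (need(df, c("bird", "t", "behavior", "habitat"), f)) {
      bad <- which(!(df$behavior %in% BEHAVIOR_LEVELS))
      for (i in head(bad, 20)) note(f, i, paste("behavior vocabulary:", df$behavior[i]))
      bad <- which(!(df$habitat %in% HABITAT_LEVELS))
      for (i in head(bad, 20)) note(f, i, paste("habitat vocabulary:", df$habitat[i]))
      tt <- parse_utc(df$t)
      ord <- unlist(tapply(as.numeric(tt), df$bird,
                           function(v) c(FALSE, diff(v) <= 0)), use.names = FALSE)
      for (i in head(which(ord), 20)) note(f, i, "timestamps not strictly increasing within bird")
    }
  }
  if (!is.null(paths[["weather"]])) {
    f <- paths[["weather"]]; df <- read.csv(f, stringsAsFactors = FALSE)
    if (need(df, c("t", "t_air_c", "u10_m_s", "v10_m_s", "cloud",
                   "radiation_w_m2"), f)) {
      bad <- which(df$cloud < 0 | df$cloud > 1)
      for (i in head(bad, 20)) note(f, i, "cloud outside [0, 1]")
      bad <- which(df$radiation_w_m2 < 0)
      for (i in head(bad, 20)) note(f, i, "negative radiation")
    }
  }
  if (!is.null(paths[["intake"]])) {
    f <- paths[["intake"]]; df <- read.csv(f, stringsAsFactors = FALSE)
    if (need(df, c("habitat", "gdd", "intake_kj_h"), f)) {
      bad <- which(!(df$habitat %in% HABITAT_LEVELS))
      for (i in head(bad, 20)) note(f, i, paste("habitat vocabulary:", df$habitat[i]))
      bad <- which(df$gdd < 0)
      for (i in head(bad, 20)) note(f, i, "negative GDD")
    }
  }
  if (!is.null(paths[["budgets"]])) {
    f <- paths[["budgets"]]; df <- read.csv(f, stringsAsFactors = FALSE)
    mins <- grep("_min$", names(df), value = TRUE)
    if (need(df, c("bird", "date", "missing_min"), f) && length(mins)) {
      bad <- which(rowSums(df[, mins, drop = FALSE] < 0) > 0)
      for (i in head(bad, 20)) note(f, i, "negative minutes")
    }
  }
  if (length(problems)) do.call(rbind, problems) else
    data.frame(file = character(0), row = integer(0), problem = character(0))
}
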