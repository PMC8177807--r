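# Metabolizable energy intake: growing degree days, PI regressions,
# conversion of foraging time to metabolized energy.

#' Cumulative growing degree days
#'
#' `GDD(d) = sum over days <= d of max(0, T_mean - base)`, anchored at 0 on
#' `start_date`. A proxy for plant growth and hence food quality.
#'
#' @param daily_temp data.frame with `date` (Date) and `t_mean_c` columns;
#'   must cover `start_date` onward without gaps.
#' @param base_temp_c Base temperature (deg C), default 0.
#' @param start_date First date of accumulation (GDD = 0 there, accumulation
#'   starts the day after).
#' @return data.frame `date`, `gdd` (non-decreasing, 0 at `start_date`).
#' @export
growing_degree_days <- function(daily_temp, base_temp_c = 0,
                                start_date = min(daily_temp$date)) {
  stopifnot(all(c("date", "t_mean_c") %in% names(daily_temp)))
  daily_temp <- daily_temp[order(daily_temp$date), ]
  start_date <- as.Date(start_date)
  daily_temp <- daily_temp[daily_temp$date >= start_date, ]
  if (nrow(daily_temp) == 0 || daily_temp$date[1] != start_date) {
    stop("daily temperature series must cover start_date onward")
  }
  if (any(diff(as.numeric(daily_temp$date)) != 1)) {
    stop("gap in daily temperature series")
  }
  inc <- pmax(0, daily_temp$t_mean_c - base_temp_c)
  inc[1] <- 0 # anchor: zero at start_date
  data.frame(date = daily_temp$date, gdd = cumsum(inc))
}

#' Fit habitat-specific intake-rate regressions
#'
#' Ordinary least squares of potential metabolizable energy intake rate (PI,
#' kJ/h) on growing degree days, fitted separately per habitat. The standard
#' error of a pooled-habitat intercept is retained for the sensitivity
#' analysis.
#'
#' @param obs data.frame with columns `habitat`, `gdd`, `intake_kj_h`.
#' @return An object of class `pi_model`: per-habitat `intercept`, `slope`,
#'   `intercept_sd`, plus `intercept_sd_pooled`.
#' @export
fit_pi_regression <- function(obs) {
  stopifnot(all(c("habitat", "gdd", "intake_kj_h") %in% names(obs)))
  habs <- intersect(SUITABLE_HABITATS, unique(as.character(obs$habitat)))
  if (length(habs) == 0) stop("no observations on forageable habitats")
  coefs <- lapply(habs, function(h) {
    sub <- obs[obs$habitat == h, ]
    if (nrow(sub) < 3) stop("need >= 3 observations for habitat ", h)
    fit <- lm(intake_kj_h ~ gdd, data = sub)
    sm <- suppressWarnings(summary(fit)$coefficients) # exact fits are fine
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         intercept_sd = unname(sm[1, 2]))
  })
  names(coefs) <- habs
  pooled <- lm(intake_kj_h ~ gdd, data = obs)
  pooled_sd <- suppressWarnings(summary(pooled)$coefficients[1, 2])
  structure(list(habitats = coefs, intercept_sd_pooled = unname(pooled_sd)),
            class = "pi_model")
}

#' Construct a PI model from known coefficients
#'
#' @param agricultural,natural Numeric `c(intercept, slope)` in kJ/h and
#'   kJ/h per GDD.
#' @param intercept_sd Per-habitat intercept SD (kJ/h).
#' @return A `pi_model` object.
#' @export
pi_model <- function(agricultural = c(85, 0.06), natural = c(75, 0.06),
                     intercept_sd = 8) {
  structure(list(habitats = list(
    agricultural = list(intercept = agricultural[1], slope = agricultural[2],
                        intercept_sd = intercept_sd),
    natural = list(intercept = natural[1], slope = natural[2],
                   intercept_sd = intercept_sd)),
    intercept_sd_pooled = intercept_sd), class = "pi_model")
}

#' Shift all PI intercepts by a constant
#'
#' Used by the sensitivity analysis, which perturbs the intercept of the
#' PI-GDD relationship with habitats pooled.
#'
#' @param model A `pi_model`.
#' @param delta kJ/h added to every habitat intercept.
#' @return The shifted `pi_model`.
#' @export
shift_pi_intercept <- function(model, delta) {
  model$habitats <- lapply(model$habitats, function(h) {
    h$intercept <- h$intercept + delta
    h
  })
  model
}

#' Potential metabolizable energy intake rate
#'
#' `PI = intercept + slope * GDD`, floored at 0 (negative extrapolations are
#' unphysical).
#'
#' @param habitat Habitat label(s) present in the model.
#' @param gdd Growing degree days.
#' @param model A `pi_model`.
#' @return kJ/h.
#' @export
potential_intake <- function(habitat, gdd, model) {
  habitat <- as.character(habitat)
  out <- numeric(length(habitat))
  gdd <- rep_len(gdd, length(habitat))
  for (h in unique(habitat)) {
    cf <- model$habitats[[h]]
    if (is.null(cf)) stop("habitat not modeled: ", h)
    sel <- habitat == h
    out[sel] <- pmax(0, cf$intercept + cf$slope * gdd[sel])
  }
  out
}

#' Metabolizable energy intake over a time budget
#'
#' PI is multiplied by foraging time plus active time, but only on habitats
#' suitable for foraging (agricultural pastures or natural grasslands);
#' elsewhere intake is zero.
#'
#' @param pi_kj_h Potential intake rate (kJ/h).
#' @param forage_h,active_h Hours foraging / active (>= 0).
#' @param habitat_suitable Logical; whether the habitat supports foraging.
#' @return Metabolized energy (kJ).
#' @export
metabolizable_intake <- function(pi_kj_h, forage_h, active_h = 0,
                                 habitat_suitable = TRUE) {
  if (any(forage_h < 0) || any(active_h < 0)) stop("time must be non-negative")
  ifelse(habitat_suitable, pi_kj_h * (forage_h + active_h), 0)
}
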