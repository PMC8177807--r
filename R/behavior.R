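# Accelerometer burst features, behavior classification, time budgets.

#' Features of one accelerometer burst
#'
#' Computes the four classifier features from a 10-sample triaxial burst
#' recorded at 20 Hz: overall dynamic body acceleration (ODBA, sum over axes
#' of the mean absolute deviation from the within-burst axis mean), mean
#' pitch (angle of the anterior x axis against the horizontal, from the mean
#' gravity vector), and the mean absolute time derivatives of the x and y
#' axes.
#'
#' @param burst Numeric 10 x 3 matrix (columns x, y, z in g).
#' @param hz Sampling rate (Hz), default 20.
#' @return Named numeric vector `odba`, `pitch_deg`, `dx_abs`, `dy_abs`.
#' @examples
#' acc_features(matrix(rep(c(0, 0, 1), each = 10), ncol = 3))
#' @export
acc_features <- function(burst, hz = 20) {
  burst <- as.matrix(burst)
  stopifnot(nrow(burst) == 10, ncol(burst) == 3, all(is.finite(burst)))
  mu <- colMeans(burst)
  nrm <- sqrt(sum(mu^2))
  if (nrm == 0) stop("zero-norm mean acceleration vector: pitch undefined")
  odba <- sum(colMeans(abs(sweep(burst, 2, mu))))
  pitch <- asin(mu[1] / nrm) * 180 / pi
  d <- abs(diff(burst)) * hz
  c(odba = unname(odba), pitch_deg = unname(pitch),
    dx_abs = mean(d[, 1]), dy_abs = mean(d[, 2]))
}

#' Feature table for a set of labeled bursts
#'
#' @param bursts Burst table as produced by [generate_bursts()]: one row per
#'   burst with columns `class` and `x1..x10`, `y1..y10`, `z1..z10`.
#' @return data.frame with `class`, `odba`, `pitch_deg`, `dx_abs`, `dy_abs`.
#' @export
burst_features <- function(bursts) {
  xcols <- paste0("x", 1:10); ycols <- paste0("y", 1:10); zcols <- paste0("z", 1:10)
  stopifnot(all(c(xcols, ycols, zcols, "class") %in% names(bursts)))
  feats <- t(vapply(seq_len(nrow(bursts)), function(i) {
    acc_features(cbind(as.numeric(bursts[i, xcols]),
                       as.numeric(bursts[i, ycols]),
                       as.numeric(bursts[i, zcols])))
  }, numeric(4)))
  data.frame(class = bursts$class, feats, stringsAsFactors = FALSE)
}

#' Cohen's kappa for a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (trace over
#' total) and chance agreement `p_e` from the marginal products. Rows are
#' reference classes, columns predictions.
#'
#' @param m Square count matrix.
#' @return Kappa; `NA` with a warning when chance agreement is 1
#'   (degenerate margins).
#' @examples
#' cohen_kappa(matrix(c(40, 20, 10, 30), 2)) # 0.4
#' @export
cohen_kappa <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0), sum(m) > 0)
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate margins: chance agreement is 1, kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Train the behavior classifier on labeled burst features
#'
#' Random 40/60 train/test split, then a random forest with 50 trees on the
#' four burst features. The confusion report (matrix, per-class precision,
#' overall accuracy, Cohen's kappa) is computed on the held-out test set.
#' If a class is missing from the training split the split is redone
#' stratified by class, with a warning.
#'
#' @param features data.frame from [burst_features()].
#' @param train_frac Fraction of samples used for training (default 0.4).
#' @param n_trees Number of trees (default 50).
#' @param seed Integer seed for the split and forest.
#' @return list with `model` (randomForest), `report` (list `matrix`,
#'   `per_class_precision`, `overall_accuracy`, `kappa`, `n_test`) and
#'   `train_idx`.
#' @export
train_classifier <- function(features, train_frac = 0.4, n_trees = 50,
                             seed = 1) {
  stopifnot(all(c("class", "odba", "pitch_deg", "dx_abs", "dy_abs") %in%
                names(features)))
  features$class <- factor(features$class)
  if (nlevels(features$class) < 2) stop("need >= 2 classes to train")
  n <- nrow(features)
  n_train <- round(train_frac * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  if (!all(levels(features$class) %in% features$class[idx])) {
    warning("class missing from training split; re-splitting stratified by class")
    idx <- unlist(lapply(split(seq_len(n), features$class), function(ii) {
      sample(ii, max(1, round(train_frac * length(ii))))
    }), use.names = FALSE)
  }
  model <- randomForest::randomForest(
    class ~ odba + pitch_deg + dx_abs + dy_abs,
    data = features[idx, ], ntree = n_trees)
  test <- features[-idx, ]
  pred <- predict(model, test)
  m <- table(reference = test$class, predicted = factor(pred, levels = levels(test$class)))
  m <- unclass(m)
  precision <- diag(m) / pmax(1, colSums(m))
  list(model = model,
       report = list(matrix = m,
                     per_class_precision = precision,
                     overall_accuracy = sum(diag(m)) / sum(m),
                     kappa = cohen_kappa(m),
                     n_test = nrow(test)),
       train_idx = sort(idx))
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sizes of a train/test split
#'
#' @param n Total sample count.
#' @param train_frac Training fraction.
#' @return Named integer vector `train`, `test`.
#' @examples
#' split_sizes(945, 0.4) # 378 train, 567 test
#' @export
split_sizes <- function(n, train_frac = 0.4) {
  tr <- round(train_frac * n)
  c(train = tr, test = n - tr)
}

#' Resample fixes to a fixed interval
#'
#' Keeps one fix per interval slot (the first fix falling in each
#' `interval_min` slot, slots aligned to midnight UTC) per bird. The kept
#' fix's behavior is taken to represent the whole slot. Empty slots are
#' missing time, accounted for by [daily_time_budget()].
#'
#' @param fixes data.frame with at least `bird`, `t` (POSIXct UTC); sorted
#'   or not.
#' @param interval_min Slot length in minutes (default 30).
#' @return The retained fixes with added `slot_start` (POSIXct) and `dt_min`
#'   (= `interval_min`) columns, ordered by bird and time.
#' @export
resample_fixes <- function(fixes, interval_min = 30) {
  stopifnot(all(c("bird", "t") %in% names(fixes)))
  fixes <- fixes[order(fixes$bird, fixes$t), ]
  slot <- floor(as.numeric(as_utc(fixes$t)) / (interval_min * 60))
  keep <- !duplicated(data.frame(fixes$bird, slot))
  out <- fixes[keep, ]
  out$slot_start <- as.POSIXct(slot[keep] * interval_min * 60,
                               origin = "1970-01-01", tz = "UTC")
  out$dt_min <- interval_min
  rownames(out) <- NULL
  out
}

#' Correct foraging-on-water fixes to inactive
#'
#' Wave motion of birds sitting on open water mimics the accelerometer
#' signature of grazing; fixes classified as foraging on water habitat are
#' therefore relabeled inactive. All other fixes are untouched.
#'
#' @param fixes data.frame with `behavior` and `habitat` columns.
#' @return The corrected fixes.
#' @export
water_correction <- function(fixes) {
  stopifnot(all(c("behavior", "habitat") %in% names(fixes)))
  sel <- fixes$behavior == "foraging" & fixes$habitat == "water"
  fixes$behavior[sel] <- "inactive"
  fixes
}

#' Daily time budgets per bird
#'
#' Aggregates resampled fixes into minutes per behavior, split day/night and
#' (for foraging and active time) by habitat. Slots are attributed to the
#' UTC calendar date of their start, so classified plus missing minutes sum
#' exactly to 1440 per bird-day. Night slots additionally carry the date of
#' the sunset that opened their night (`night_date`), which
#' [nightly_budget()] uses for night-level bookkeeping.
#'
#' @param fixes Resampled fixes ([resample_fixes()]) with `behavior` and
#'   `habitat`.
#' @param lat,lon Location (degrees) for the solar/lunar calculations.
#' @param nights Optional precomputed [night_table()] covering the period
#'   (saves recomputation).
#' @return data.frame keyed by `bird`, `date` with `day_length_h`,
#'   `moonlit_h`, foraging/active minutes split by day/night and habitat,
#'   `inactive_min`, `flying_min`, `other_min` and `missing_min`.
#' @export
daily_time_budget <- function(fixes, lat, lon, nights = NULL) {
  stopifnot(all(c("bird", "slot_start", "dt_min", "behavior", "habitat") %in%
                names(fixes)))
  check_behavior(fixes$behavior); check_habitat(fixes$habitat)
  mid <- fixes$slot_start + fixes$dt_min * 30 # slot midpoint (s = min*60/2)
  dn <- assign_day_night(mid, lat, lon)
  fixes$daynight <- dn$daynight
  fixes$night_date <- dn$night_date
  fixes$date <- as.Date(fixes$slot_start, tz = "UTC")

  dates <- seq(min(fixes$date), max(fixes$date), by = 1)
  sol <- solar_events(dates, lat, lon)
  if (is.null(nights)) nights <- night_table(dates, lat, lon)

  key <- expand.grid(bird = unique(fixes$bird), date = dates,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mins <- function(sel) {
    if (!any(sel)) return(rep(0, nrow(key)))
    agg <- aggregate(dt_min ~ bird + date, data = fixes[sel, , drop = FALSE],
                     FUN = sum)
    v <- merge(key, agg, all.x = TRUE)
    v$dt_min[is.na(v$dt_min)] <- 0
    v[order(v$bird, v$date), "dt_min"]
  }
  key <- key[order(key$bird, key$date), ]
  suit <- fixes$habitat %in% SUITABLE_HABITATS
  out <- key
  out$forage_day_agri_min  <- mins(fixes$behavior == "foraging" & fixes$daynight == "day" & fixes$habitat == "agricultural")
  out$forage_day_nat_min   <- mins(fixes$behavior == "foraging" & fixes$daynight == "day" & fixes$habitat == "natural")
  out$forage_night_agri_min <- mins(fixes$behavior == "foraging" & fixes$daynight == "night" & fixes$habitat == "agricultural")
  out$forage_night_nat_min <- mins(fixes$behavior == "foraging" & fixes$daynight == "night" & fixes$habitat == "natural")
  out$forage_other_min <- mins(fixes$behavior == "foraging" & !suit)
  out$active_day_min   <- mins(fixes$behavior == "active" & fixes$daynight == "day")
  out$active_night_min <- mins(fixes$behavior == "active" & fixes$daynight == "night")
  out$inactive_min <- mins(fixes$behavior == "inactive")
  out$flying_min   <- mins(fixes$behavior == "flying")
  classified <- rowSums(out[, c("forage_day_agri_min", "forage_day_nat_min",
                                "forage_night_agri_min", "forage_night_nat_min",
                                "forage_other_min", "active_day_min",
                                "active_night_min", "inactive_min",
                                "flying_min")])
  out$missing_min <- 1440 - classified
  out$forage_day_min <- out$forage_day_agri_min + out$forage_day_nat_min
  out$forage_night_min <- out$forage_night_agri_min + out$forage_night_nat_min
  out$day_length_h <- sol$day_length_h[match(out$date, sol$date)]
  out$moonlit_h <- nights$moonlit_h[match(out$date, nights$date)]
  rownames(out) <- NULL
  out
}

#' Night-level foraging budgets
#'
#' Aggregates night minutes by the night they belong to (the night starting
#' at `night_date`'s sunset), the unit used in the moonlight analysis and in
#' the counterfactual night-substitution scenario.
#'
#' @inheritParams daily_time_budget
#' @return data.frame `bird`, `night_date`, `night_length_h`, `moonlit_h`,
#'   `forage_night_min`, `active_night_min`.
#' @export
nightly_budget <- function(fixes, lat, lon, nights = NULL) {
  mid <- fixes$slot_start + fixes$dt_min * 30
  dn <- assign_day_night(mid, lat, lon)
  nf <- fixes[dn$daynight == "night", ]
  nf$night_date <- dn$night_date[dn$daynight == "night"]
  dates <- seq(min(nf$night_date), max(nf$night_date), by = 1)
  if (is.null(nights)) nights <- night_table(dates, lat, lon)
  # boundary part-nights outside the supplied night table are dropped
  dates <- dates[dates %in% nights$date]
  nf <- nf[nf$night_date %in% dates, ]
  key <- expand.grid(bird = unique(nf$bird), night_date = dates,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- key[order(key$bird, key$night_date), ]
  one <- function(sel) {
    if (!any(sel)) return(rep(0, nrow(key)))
    agg <- aggregate(dt_min ~ bird + night_date,
                     data = nf[sel, , drop = FALSE], FUN = sum)
    v <- merge(key, agg, all.x = TRUE)
    v$dt_min[is.na(v$dt_min)] <- 0
    v[order(v$bird, v$night_date), "dt_min"]
  }
  key$forage_night_min <- one(nf$behavior == "foraging")
  key$active_night_min <- one(nf$behavior == "active")
  key$night_length_h <- nights$night_length_h[match(key$night_date, nights$date)]
  key$moonlit_h <- nights$moonlit_h[match(key$night_date, nights$date)]
  rownames(key) <- NULL
  key
}
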