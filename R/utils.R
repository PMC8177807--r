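# Shared small helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a timestamp to fractional day-of-year
#'
#' Day-of-year is 1-based: 1.0 at 00:00 UTC on January 1. Used for night
#' indexing and breakpoint covariates.
#'
#' @param t POSIXct (UTC) or Date vector.
#' @return Numeric day-of-year (fractional for POSIXct).
#' @export
fractional_doy <- function(t) {
  if (inherits(t, "Date")) {
    return(as.numeric(format(t, "%j")))
  }
  d <- as.Date(t, tz = "UTC")
  as.numeric(format(d, "%j")) +
    as.numeric(difftime(t, as.POSIXct(paste(d, "00:00:00"), tz = "UTC"),
                        units = "days"))
}

# Parse timestamp strings that may mix ISO-8601 "T...Z", space-separated
# and date-only forms (base parsing locks onto the first row's format).
parse_utc <- function(x) {
  x <- as.character(x)
  x <- gsub("T", " ", sub("Z$", "", x))
  x[!grepl(" ", x)] <- paste(x[!grepl(" ", x)], "00:00:00")
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

#' Relative load of a tracking device on a bird
#'
#' Device mass as a percentage of body mass, the standard figure reported when
#' assessing whether a tag/harness combination stays below accepted
#' load guidelines.
#'
#' @param device_g Device plus harness mass in grams.
#' @param body_mass_g Bird body mass in grams.
#' @return Percentage (0-100).
#' @examples
#' device_load_percent(35, 1495) # ~2.3 %
#' @export
device_load_percent <- function(device_g, body_mass_g) {
  stopifnot(device_g >= 0, body_mass_g > 0)
  100 * device_g / body_mass_g
}

# behavior / habitat vocabularies used throughout
BEHAVIOR_LEVELS <- c("inactive", "active", "foraging", "flying")
HABITAT_LEVELS  <- c("agricultural", "natural", "water", "other")
SUITABLE_HABITATS <- c("agricultural", "natural")

check_behavior <- function(x) {
  bad <- setdiff(unique(as.character(x)), BEHAVIOR_LEVELS)
  if (length(bad)) {
    stop("unknown behavior label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

check_habitat <- function(x) {
  bad <- setdiff(unique(as.character(x)), HABITAT_LEVELS)
  if (length(bad)) {
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
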