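# Shared helpers: clock-time parsing, rounding, formatting.

ROOMS <- c("kitchen", "bathroom", "bedroom", "lounge", "hall", "other")
SENSOR_TYPES <- c("motion", "wall_plug", "water_meter")

# "HH:MM" (or "H:MM") -> minutes since midnight
parse_hm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2})[:.]([0-9]{2})$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(paste0("invalid clock time: '", x[bad][1], "' (expected HH:MM)"))
  }
  h <- as.integer(vapply(m, `[`, character(1), 2L))
  mm <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(h > 23L | mm > 59L)) {
    abort(paste0("clock time out of range: '", x[h > 23L | mm > 59L][1], "'"))
  }
  h * 60L + mm
}

format_hm <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

# half-away-from-zero rounding to integers (base round() is half-to-even)
round_half_away <- function(x) {
  trunc(abs(x) + 0.5) * sign(x)
}

# minutes rendered at 0.1-min precision without trailing ".0"
fmt_minutes <- function(x) {
  x <- round(x, 1)
  ifelse(x == round(x), format(round(x), scientific = FALSE, trim = TRUE),
         sprintf("%.1f", x))
}

# POSIXct (UTC wall clock) from ISO-8601 "YYYY-MM-DDTHH:MM:SS" or with space
parse_timestamp <- function(x) {
  y <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(strptime(y, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  na <- is.na(out) & !is.na(y)
  if (any(na)) {
    out[na] <- as.POSIXct(strptime(y[na], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# POSIXct for calendar date + minutes-since-midnight
date_time <- function(date, minutes) {
  as.POSIXct(as.character(date), tz = "UTC") + minutes * 60
}

stopifnot_sorted <- function(ts, what = "events") {
  if (length(ts) > 1 && any(diff(as.numeric(ts)) < 0)) {
    abort(paste0(what, " must be sorted ascending by timestamp"))
  }
}
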