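#' Remove duplicate (bounced) sensor readings
#'
#' PIR motion sensors and plug meters frequently re-emit an identical
#' reading within a fraction of a second ("retrigger bounce"). An event is
#' a duplicate when it matches its predecessor from the same sensor in
#' `(sensor_id, sensor_type, room, value)` and lies within
#' `tolerance_seconds` of it. Deduplication is idempotent and never
#' removes the first event of a run.
#'
#' @param events event tibble sorted ascending by timestamp.
#' @param tolerance_seconds maximum spacing for two identical readings to
#'   count as one (default 2 s, a typical PIR retrigger bounce).
#' @return A list with `events` (deduplicated, still sorted) and
#'   `removed_count`.
#' @export
dedup_events <- function(events, tolerance_seconds = 2) {
  if (tolerance_seconds < 0) abort("tolerance_seconds must be >= 0")
  stopifnot_sorted(events$timestamp)
  if (nrow(events) < 2) {
    return(list(events = events, removed_count = 0L))
  }
  ord <- order(events$sensor_id, as.numeric(events$timestamp), method = "radix")
  sid <- events$sensor_id[ord]
  key <- paste(sid, events$sensor_type[ord], events$room[ord],
               events$value[ord], sep = "\r")
  dt <- c(Inf, diff(as.numeric(events$timestamp)[ord]))
  same_sensor <- c(FALSE, sid[-1] == sid[-length(sid)])
  identical_prev <- c(FALSE, key[-1] == key[-length(key)])
  dup_sorted <- same_sensor & identical_prev & dt <= tolerance_seconds
  dup <- logical(nrow(events))
  dup[ord] <- dup_sorted
  out <- events[!dup, ]
  attr(out, "malformed") <- attr(events, "malformed")
  list(events = out, removed_count = sum(dup))
}

#' Find whole-home silence gaps
#'
#' Reports every maximal interval longer than `max_gap_minutes` during
#' which no sensor in the home produced any event. Whole-home silence —
#' as opposed to one quiet sensor — indicates a data outage (gateway or
#' power failure) rather than resident behaviour, and downstream windows
#' it covers are marked as having insufficient data.
#'
#' @param events event tibble sorted by timestamp (any sensor types).
#' @param max_gap_minutes silence threshold in minutes (default 60).
#' @return A gap tibble with columns `sensor_id` (always `"all"`),
#'   `gap_start`, `gap_end`, `gap_minutes`, sorted by `gap_start`.
#' @export
find_gaps <- function(events, max_gap_minutes = 60) {
  empty <- tibble::tibble(sensor_id = character(),
                          gap_start = as.POSIXct(character(), tz = "UTC"),
                          gap_end = as.POSIXct(character(), tz = "UTC"),
                          gap_minutes = numeric())
  if (nrow(events) < 2) return(empty)
  stopifnot_sorted(events$timestamp)
  ts <- sort(unique(events$timestamp))
  dmin <- diff(as.numeric(ts)) / 60
  i <- which(dmin > max_gap_minutes)
  if (length(i) == 0) return(empty)
  tibble::tibble(sensor_id = "all",
                 gap_start = ts[i],
                 gap_end = ts[i + 1],
                 gap_minutes = dmin[i])
}

#' Drop feature rows on excluded dates
#'
#' Removes every window-feature row whose date appears in the exclusion
#' calendar for its apartment (e.g. scheduled home-care visit days).
#' Applied to both threshold-fitting history and detection input so that
#' third-party presence never contaminates a resident's model.
#'
#' @param features a window-feature tibble (see [extract_features()]).
#' @param exclusions an exclusion tibble (`apartment_id`, `date`, ...).
#' @return The filtered tibble; the number of removed rows is reported
#'   via a message and the `"excluded_count"` attribute.
#' @export
apply_exclusions <- function(features, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    attr(features, "excluded_count") <- 0L
    return(features)
  }
  drop <- paste(features$apartment_id, features$date) %in%
    paste(exclusions$apartment_id, exclusions$date)
  out <- features[!drop, ]
  if (sum(drop) > 0) {
    rlang::inform(paste0("apply_exclusions: removed ", sum(drop),
                         " feature row(s) on excluded dates"))
  }
  attr(out, "excluded_count") <- sum(drop)
  out
}

# fraction of the window [ws, we) (minutes on `date`) covered by
# whole-home gaps; a window covered > 50% has insufficient data
gap_window_overlap <- function(gaps, date, ws, we) {
  if (nrow(gaps) == 0) return(0)
  w0 <- as.numeric(date_time(date, ws))
  w1 <- as.numeric(date_time(date, we))
  ov <- pmax(0, pmin(as.numeric(gaps$gap_end), w1) -
                pmax(as.numeric(gaps$gap_start), w0))
  sum(ov) / (w1 - w0)
}
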