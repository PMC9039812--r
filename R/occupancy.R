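#' Segment motion events into room-occupancy intervals
#'
#' A single-resident home admits a simple occupancy state machine: the
#' resident is attributed to the room of the most recent motion event.
#' An interval for room R opens at the first motion event in R after
#' being elsewhere (or at stream start) and closes at the first
#' subsequent motion event in a different room; the final interval closes
#' at the last event's timestamp. Time with no motion anywhere is
#' attributed to the current room ("moving or not moving in the room"),
#' so intervals tile the span between the first and last event.
#' Zero-length intervals (a room change at the same instant) are dropped.
#'
#' @param motion_events event tibble containing only `sensor_type ==
#'   "motion"`, sorted by timestamp.
#' @return An occupancy tibble: `room`, `start`, `end`,
#'   `duration_minutes`; consecutive rows change room and do not overlap.
#' @examples
#' ev <- sensor_events(c("K", "K", "B"), "motion",
#'                     c("kitchen", "kitchen", "bedroom"),
#'                     c("2020-07-21T08:00:00", "2020-07-21T08:20:00",
#'                       "2020-07-21T08:45:00"), 1)
#' build_occupancy(ev)   # kitchen 08:00-08:45, 45 min
#' @export
build_occupancy <- function(motion_events) {
  if (nrow(motion_events) > 0 && any(motion_events$sensor_type != "motion")) {
    abort("build_occupancy expects motion events only")
  }
  empty <- tibble::tibble(room = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_minutes = numeric())
  if (nrow(motion_events) < 2) return(empty)
  stopifnot_sorted(motion_events$timestamp, "motion events")

  r <- rle(motion_events$room)
  n_runs <- length(r$lengths)
  first_idx <- cumsum(c(1L, r$lengths[-n_runs]))
  starts <- motion_events$timestamp[first_idx]
  ends <- c(starts[-1], motion_events$timestamp[nrow(motion_events)])
  out <- tibble::tibble(
    room = r$values,
    start = starts,
    end = ends,
    duration_minutes = as.numeric(difftime(ends, starts, units = "mins"))
  )
  out[out$duration_minutes > 0, ]
}

#' Features of one activity window
#'
#' Computes the duration / visit-frequency / appliance-usage features for
#' one (apartment, activity, date) time window. Windows are half-open
#' `[start, end)`: an interval touching only the end instant contributes
#' nothing. Duration is the total overlap (clipped to the window) of the
#' routine room's occupancy intervals, reported at 0.1-minute precision;
#' `visit_count` is the number of distinct room intervals with positive
#' overlap. An appliance counts as used when a wall-plug reading inside
#' the window exceeds `plug_threshold_watts`.
#'
#' @param intervals occupancy tibble for one apartment-day
#'   ([build_occupancy()]).
#' @param plug_events wall-plug events for the same day (may be empty).
#' @param routine a single routine row ([routine_spec()]).
#' @param date the calendar date (`Date` or string).
#' @param data_sufficient whether the window has enough sensor coverage
#'   (see [find_gaps()]); carried through to classification.
#' @param plug_threshold_watts power threshold for "appliance used"
#'   (default 10 W).
#' @return One-row tibble: `apartment_id`, `activity`, `date`,
#'   `duration_minutes`, `visit_count`, `appliances_used` (list column),
#'   `data_sufficient`.
#' @export
window_features <- function(intervals, plug_events = NULL, routine, date,
                            data_sufficient = TRUE,
                            plug_threshold_watts = 10) {
  stopifnot(nrow(routine) == 1)
  date <- as.Date(date)
  w <- routine_window(routine)
  w0 <- date_time(date, w$start)
  w1 <- date_time(date, w$end)

  dur <- 0
  visits <- 0L
  if (!is.null(intervals) && nrow(intervals) > 0) {
    in_room <- intervals[intervals$room == routine$room, , drop = FALSE]
    if (nrow(in_room) > 0) {
      ov <- pmax(0, as.numeric(pmin(in_room$end, w1)) -
                    as.numeric(pmax(in_room$start, w0))) / 60
      dur <- round(sum(ov), 1)
      # a stay below the 0.1-min reporting resolution counts as absent,
      # keeping visit_count == 0 <=> duration_minutes == 0
      visits <- if (dur > 0) sum(ov > 0) else 0L
    }
  }

  appl <- character()
  if (!is.null(plug_events) && nrow(plug_events) > 0) {
    p <- plug_events[plug_events$sensor_type == "wall_plug" &
                       plug_events$timestamp >= w0 &
                       plug_events$timestamp < w1 &
                       plug_events$value > plug_threshold_watts, , drop = FALSE]
    appl <- sort(unique(p$sensor_id))
  }

  tibble::tibble(
    apartment_id = routine$apartment_id,
    activity = routine$activity,
    date = date,
    duration_minutes = dur,
    visit_count = as.integer(visits),
    appliances_used = list(appl),
    data_sufficient = isTRUE(data_sufficient)
  )
}

#' Extract window features for every routine and day
#'
#' Runs the occupancy state machine once per day and evaluates every
#' configured routine window on every date of the stream (or an explicit
#' date range). Days whose whole-home silence gaps (see [find_gaps()])
#' cover more than half of a window are marked `data_sufficient = FALSE`
#' for that window — a sensor outage must not masquerade as an absence
#' anomaly.
#'
#' The event stream is assumed to come from one apartment (the routines
#' must share a single `apartment_id`); the stream should already be
#' deduplicated ([dedup_events()]).
#'
#' @param events cleaned event tibble (all sensor types).
#' @param routines routine tibble for the apartment.
#' @param dates optional `Date` vector; default all dates spanned by the
#'   events.
#' @param max_gap_minutes whole-home silence threshold passed to
#'   [find_gaps()].
#' @param insufficiency_fraction fraction of a window that must be
#'   gap-covered to invalidate it (default 0.5).
#' @param plug_threshold_watts see [window_features()].
#' @return A window-feature tibble, one row per (activity, date).
#' @export
extract_features <- function(events, routines, dates = NULL,
                             max_gap_minutes = 60,
                             insufficiency_fraction = 0.5,
                             plug_threshold_watts = 10) {
  validate_routines(routines)
  if (length(unique(routines$apartment_id)) > 1) {
    abort("extract_features expects routines for a single apartment")
  }
  if (is.null(dates)) {
    if (nrow(events) == 0) abort("no events and no explicit dates")
    rng <- range(as.Date(events$timestamp, tz = "UTC"))
    dates <- seq(rng[1], rng[2], by = "day")
  }
  dates <- as.Date(dates)

  gaps <- find_gaps(events, max_gap_minutes)
  motion <- events[events$sensor_type == "motion", , drop = FALSE]
  plugs <- events[events$sensor_type == "wall_plug", , drop = FALSE]
  intervals <- build_occupancy(motion)

  purrr::map(dates, function(d) {
    purrr::map(seq_len(nrow(routines)), function(i) {
      r <- routines[i, ]
      w <- routine_window(r)
      suff <- gap_window_overlap(gaps, d, w$start, w$end) <= insufficiency_fraction
      window_features(intervals, plugs, r, d,
                      data_sufficient = suff,
                      plug_threshold_watts = plug_threshold_watts)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
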