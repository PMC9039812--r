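#' Sensor event streams
#'
#' A sensor event stream is a tibble with one row per timestamped reading:
#' \describe{
#'   \item{sensor_id}{opaque device identifier (character)}
#'   \item{sensor_type}{one of `"motion"`, `"wall_plug"`, `"water_meter"`}
#'   \item{room}{one of `"kitchen"`, `"bathroom"`, `"bedroom"`, `"lounge"`,
#'     `"hall"`, `"other"`}
#'   \item{timestamp}{local wall-clock instant (`POSIXct`, stored tz-naive
#'     as UTC), second precision}
#'   \item{value}{motion: always 1; wall_plug: instantaneous power in
#'     watts (>= 0); water_meter: cumulative volume in litres,
#'     non-decreasing per sensor}
#' }
#'
#' @param sensor_id,sensor_type,room,timestamp,value vectors recycled to a
#'   common length; `timestamp` may be `POSIXct` or ISO-8601 character.
#' @return A validated event tibble sorted by timestamp.
#' @examples
#' sensor_events("M1", "motion", "kitchen", "2020-07-21T06:00:00", 1)
#' @export
sensor_events <- function(sensor_id, sensor_type, room, timestamp, value) {
  if (is.character(timestamp)) timestamp <- parse_timestamp(timestamp)
  ev <- tibble::tibble(
    sensor_id = as.character(sensor_id),
    sensor_type = as.character(sensor_type),
    room = as.character(room),
    timestamp = timestamp,
    value = as.numeric(value)
  )
  ev <- ev[order(ev$timestamp, method = "radix"), ]
  validate_events(ev)
  ev
}

#' Validate a sensor event tibble
#'
#' Checks the event-stream invariants: known sensor types and rooms,
#' parseable timestamps, non-negative values, motion values equal to 1,
#' and per-sensor non-decreasing water-meter readings.
#'
#' @param events an event tibble (see [sensor_events()]).
#' @return `events`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_events <- function(events) {
  req <- c("sensor_id", "sensor_type", "room", "timestamp", "value")
  missing <- setdiff(req, names(events))
  if (length(missing)) {
    abort(paste0("events missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(events) == 0) return(invisible(events))
  if (anyNA(events$timestamp)) abort("invalid event: unparseable timestamp")
  if (!all(events$sensor_type %in% SENSOR_TYPES)) {
    abort(paste0("invalid event: unknown sensor_type '",
                 setdiff(unique(events$sensor_type), SENSOR_TYPES)[1], "'"))
  }
  if (!all(events$room %in% ROOMS)) {
    abort(paste0("invalid event: unknown room '",
                 setdiff(unique(events$room), ROOMS)[1], "'"))
  }
  if (anyNA(events$value) || any(events$value < 0)) {
    abort("invalid event: value must be a number >= 0")
  }
  motion <- events$sensor_type == "motion"
  if (any(events$value[motion] != 1)) {
    abort("invalid event: motion events must have value == 1")
  }
  wm <- events[events$sensor_type == "water_meter", ]
  if (nrow(wm) > 1) {
    dec <- wm |>
      dplyr::arrange(.data$timestamp) |>
      dplyr::group_by(.data$sensor_id) |>
      dplyr::summarise(dec = any(diff(.data$value) < 0), .groups = "drop")
    if (any(dec$dec)) {
      abort(paste0("invalid event: water_meter values decrease for sensor '",
                   dec$sensor_id[dec$dec][1], "'"))
    }
  }
  invisible(events)
}

#' Read a sensor event log
#'
#' Reads a CSV (header `sensor_id,sensor_type,room,timestamp,value`,
#' comma-separated, UTF-8) or JSON-lines event log. Timestamps are
#' ISO-8601 local wall-clock with seconds and no timezone offset.
#' Rows that fail validation are dropped, counted and reported via a
#' message and the `"malformed"` attribute (a tibble of line numbers and
#' reasons); they are never silently discarded.
#'
#' @param source path to the log file.
#' @param format `"csv"` or `"jsonl"`; default guessed from the file
#'   extension (`.jsonl`/`.ndjson` vs anything else).
#' @return An event tibble sorted ascending by timestamp (stable on
#'   ties), with attribute `malformed`.
#' @seealso [write_events()] for the inverse; the pair round-trips all
#'   field values exactly.
#' @export
read_events <- function(source, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(source)) abort(paste0("cannot read event log: ", source))
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", source)) "jsonl" else "csv"
  }
  if (format == "csv") {
    raw <- readr::read_csv(source, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    req <- c("sensor_id", "sensor_type", "room", "timestamp", "value")
    if (!all(req %in% names(raw))) {
      abort(paste0("event CSV must have header ", paste(req, collapse = ",")))
    }
    # line number in file: +1 for header
    lines <- seq_len(nrow(raw)) + 1L
  } else {
    txt <- readLines(source, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    rows <- lapply(txt, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    ok <- !vapply(rows, is.null, logical(1))
    raw <- dplyr::bind_rows(lapply(rows[ok], function(r) {
      tibble::tibble(sensor_id = as.character(r$sensor_id %||% NA),
                     sensor_type = as.character(r$sensor_type %||% NA),
                     room = as.character(r$room %||% NA),
                     timestamp = as.character(r$timestamp %||% NA),
                     value = as.character(r$value %||% NA))
    }))
    lines <- which(ok)
    if (!all(ok)) {
      bad_json <- tibble::tibble(line = which(!ok), reason = "unparseable JSON")
    }
  }
  if (nrow(raw) == 0) {
    out <- sensor_events(character(), character(), character(),
                         as.POSIXct(character(), tz = "UTC"), numeric())
    attr(out, "malformed") <- tibble::tibble(line = integer(), reason = character())
    return(out)
  }

  ts <- parse_timestamp(raw$timestamp)
  val <- suppressWarnings(as.numeric(raw$value))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(reason) & !(raw$sensor_type %in% SENSOR_TYPES)] <- "unknown sensor_type"
  reason[is.na(reason) & !(raw$room %in% ROOMS)] <- "unknown room"
  reason[is.na(reason) & (is.na(val) | val < 0)] <- "invalid value"
  reason[is.na(reason) & raw$sensor_type == "motion" & val != 1] <- "motion value != 1"
  bad <- !is.na(reason)

  malformed <- tibble::tibble(line = lines[bad], reason = reason[bad])
  if (format == "jsonl" && exists("bad_json", inherits = FALSE)) {
    malformed <- dplyr::arrange(dplyr::bind_rows(malformed, bad_json), .data$line)
  }
  n_total <- nrow(raw) + (nrow(malformed) - sum(bad))  # + unparseable JSON lines
  if (nrow(malformed) > 0) {
    if (nrow(malformed) > 0.10 * n_total) {
      abort(paste0("more than 10% malformed rows; first offending line ",
                   malformed$line[1], " (", malformed$reason[1], ")"))
    }
    rlang::inform(paste0("read_events: dropped ", nrow(malformed),
                         " malformed row(s); see attr(x, 'malformed')"))
  }

  ev <- tibble::tibble(
    sensor_id = raw$sensor_id[!bad],
    sensor_type = raw$sensor_type[!bad],
    room = raw$room[!bad],
    timestamp = ts[!bad],
    value = val[!bad]
  )
  ev <- ev[order(ev$timestamp, method = "radix"), ]
  wm <- ev[ev$sensor_type == "water_meter", ]
  if (nrow(wm) > 1) {
    dec <- tapply(wm$value, wm$sensor_id, function(v) any(diff(v) < 0))
    if (any(unlist(dec))) {
      warn("water_meter readings decrease within a sensor stream")
    }
  }
  attr(ev, "malformed") <- malformed
  ev
}

#' Write a sensor event log
#'
#' Writes events to CSV or JSON lines in the dialect [read_events()]
#' expects; `read_events(write_events(x))` reproduces `x` field for field.
#'
#' @param events a valid event tibble.
#' @param sink output path.
#' @param format `"csv"` or `"jsonl"`; default guessed from extension.
#' @return The number of rows written, invisibly.
#' @export
write_events <- function(events, sink, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  validate_events(events)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", sink)) "jsonl" else "csv"
  }
  out <- tibble::tibble(
    sensor_id = events$sensor_id,
    sensor_type = events$sensor_type,
    room = events$room,
    timestamp = format_timestamp(events$timestamp),
    value = events$value
  )
  if (format == "csv") {
    readr::write_csv(out, sink, progress = FALSE)
  } else {
    con <- file(sink, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(out) > 0) {
      writeLines(vapply(seq_len(nrow(out)), function(i) {
        jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE, digits = NA)
      }, character(1)), con)
    }
  }
  invisible(nrow(out))
}
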