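#' Routine specifications and exclusion calendars
#'
#' A routine specification describes one monitored activity for one
#' apartment: the room it happens in, a fixed daily clock-time window
#' (`HH:MM`, start strictly before end, no midnight-spanning windows),
#' and the household's notification preference (`"N"` = negative
#' notifications only, `"NP"` = both negative and positive).
#'
#' @param apartment_id,activity character scalars or vectors.
#' @param room room name (see [sensor_events()] for the room set).
#' @param window_start,window_end clock times as `"HH:MM"`.
#' @param preference `"N"` (default) or `"NP"` (`"N/P"` is accepted and
#'   normalised).
#' @return A routine tibble with columns `apartment_id`, `activity`,
#'   `room`, `window_start`, `window_end`, `preference`.
#' @examples
#' routine_spec("1", "breakfast", "kitchen", "06:00", "09:00", "NP")
#' @export
routine_spec <- function(apartment_id, activity, room, window_start,
                         window_end, preference = "N") {
  r <- tibble::tibble(
    apartment_id = as.character(apartment_id),
    activity = as.character(activity),
    room = as.character(room),
    window_start = as.character(window_start),
    window_end = as.character(window_end),
    preference = normalize_preference(preference)
  )
  validate_routines(r)
  r
}

normalize_preference <- function(x) {
  x <- toupper(gsub("/", "", as.character(x)))
  if (!all(x %in% c("N", "NP"))) {
    abort("preference must be 'N' or 'NP' (aka 'N/P')")
  }
  x
}

validate_routines <- function(routines) {
  if (nrow(routines) == 0) return(invisible(routines))
  if (!all(routines$room %in% ROOMS)) {
    abort(paste0("unknown room in routine config: '",
                 setdiff(unique(routines$room), ROOMS)[1], "'"))
  }
  s <- parse_hm(routines$window_start)
  e <- parse_hm(routines$window_end)
  if (any(e <= s)) {
    i <- which(e <= s)[1]
    abort(paste0("routine '", routines$activity[i], "' (apartment ",
                 routines$apartment_id[i], "): window_end ", routines$window_end[i],
                 " <= window_start ", routines$window_start[i],
                 "; midnight-spanning windows are not supported"))
  }
  invisible(routines)
}

# minutes-since-midnight window bounds for one routine row
routine_window <- function(routine) {
  list(start = parse_hm(routine$window_start),
       end = parse_hm(routine$window_end))
}

#' Read a routine configuration file
#'
#' Parses a YAML or JSON configuration mapping apartments to monitored
#' activities and exclusion dates, e.g.:
#'
#' ```yaml
#' apartments:
#'   "1":
#'     preference: NP
#'     activities:
#'       breakfast: {room: kitchen, start: "06:00", end: "09:00"}
#'     exclusions: [2020-08-05, 2020-08-12]
#'     exclusion_reason: home care visit
#' ```
#'
#' Missing `preference` defaults to `"N"`. Windows with
#' `end <= start` or unknown rooms are configuration errors.
#'
#' @param config path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `routines` (routine tibble, one row per
#'   apartment-activity) and `exclusions` (tibble with `apartment_id`,
#'   `date`, `reason`).
#' @export
read_routines <- function(config) {
  if (!file.exists(config)) abort(paste0("cannot read config: ", config))
  cfg <- if (grepl("\\.json$", config)) {
    jsonlite::fromJSON(config, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(config)
  }
  if (is.null(cfg$apartments)) abort("config must have an 'apartments' map")

  routines <- purrr::imap(cfg$apartments, function(apt, apt_id) {
    pref <- normalize_preference(apt$preference %||% "N")
    acts <- apt$activities %||% list()
    purrr::imap(acts, function(a, name) {
      routine_spec(apt_id, name,
                   a$room %||% abort(paste0("activity '", name, "': missing room")),
                   a$start %||% abort(paste0("activity '", name, "': missing start")),
                   a$end %||% abort(paste0("activity '", name, "': missing end")),
                   a$preference %||% pref)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  exclusions <- purrr::imap(cfg$apartments, function(apt, apt_id) {
    dates <- unique(as.Date(unlist(apt$exclusions %||% character())))
    if (length(dates) == 0) return(NULL)
    tibble::tibble(apartment_id = apt_id, date = dates,
                   reason = apt$exclusion_reason %||% "excluded")
  }) |> dplyr::bind_rows()
  if (nrow(exclusions %||% tibble::tibble()) == 0) {
    exclusions <- tibble::tibble(apartment_id = character(),
                                 date = as.Date(character()),
                                 reason = character())
  }

  list(routines = routines, exclusions = exclusions)
}

#' Build an exclusion calendar
#'
#' Days on which a third party (typically scheduled home care) was in the
#' apartment produce sensor traces that do not reflect the resident's own
#' routine; those dates are excluded from both threshold fitting and
#' detection.
#'
#' @param apartment_id apartment identifier.
#' @param dates a vector coercible to `Date`; duplicates are dropped.
#' @param reason free-text reason recorded with each date.
#' @return An exclusion tibble (`apartment_id`, `date`, `reason`).
#' @export
exclusion_calendar <- function(apartment_id, dates, reason = "home care visit") {
  tibble::tibble(apartment_id = as.character(apartment_id),
                 date = unique(as.Date(dates)),
                 reason = reason)
}
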