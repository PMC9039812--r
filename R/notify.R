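#' Notification message templates
#'
#' Default English templates with named `{placeholder}` fields. Any
#' subset can be overridden via the `templates` argument of
#' [render_notification()].
#'
#' Placeholders: `{duration}`, `{room}`, `{start}`, `{end}`,
#' `{end_minus_1}` (window end minus one minute, used for absence
#' messages), `{visits}`, `{appliance_clause}`, `{lower}`, `{upper}`,
#' `{message_id}`, `{date}`.
#'
#' @return Named list of template strings (`normal`, `short`, `long`,
#'   `not_present`, `appliance`, `footer`).
#' @export
default_templates <- function() {
  list(
    normal = paste0(
      "{duration} minutes of activity in the {room} between {start} and ",
      "{end}, during {visits} visits.{appliance_clause} Our analysis shows ",
      "that {lower}-{upper} minutes is the normal time duration in the ",
      "{room}.{footer}"),
    short = paste0(
      "Only {duration} minutes of activity in the {room} between {start} ",
      "and {end}, during {visits} visits.{appliance_clause} This is shorter ",
      "than the normal {lower}-{upper} minutes in the {room}.{footer}"),
    long = paste0(
      "{duration} minutes of activity in the {room} between {start} and ",
      "{end}, during {visits} visits.{appliance_clause} This is longer than ",
      "the normal {lower}-{upper} minutes in the {room}.{footer}"),
    not_present = paste0(
      "No activity in the {room} between {start} and {end_minus_1}. ",
      "Our analysis shows that {lower}-{upper} minutes is the normal time ",
      "duration in the {room}.{footer}"),
    appliance = " The {appliances} has been used.",
    footer = paste0(
      " If that message is not correct and deviates from the actual event, ",
      "we are grateful for feedback with a description of the deviation. ",
      "Message ID: {message_id}, {date}")
  )
}

fill_template <- function(template, fields) {
  for (nm in names(fields)) {
    template <- gsub(paste0("{", nm, "}"), fields[[nm]], template, fixed = TRUE)
  }
  template
}

#' Render a notification for one classified window
#'
#' Produces the positive message for a normal day or the negative message
#' for a short / long / not-present day, filled with the day's duration
#' (0.1-minute precision), visit count, appliance usage, window and the
#' learned normal range. `insufficient_data` days yield no notification
#' (`NULL`, with a log message): an outage is not reported as behaviour.
#'
#' @param result one classified row ([classify_windows()]).
#' @param routine the matching routine row (supplies room, window,
#'   apartment).
#' @param message_id integer message sequence number for the apartment.
#' @param templates template list, see [default_templates()].
#' @return One-row notification tibble (`apartment_id`, `date`,
#'   `polarity`, `message`, `message_id`, `label`), or `NULL` for
#'   insufficient data.
#' @export
render_notification <- function(result, routine, message_id = 1L,
                                templates = default_templates()) {
  stopifnot(nrow(result) == 1, nrow(routine) == 1)
  label <- as.character(result$label)
  if (label == "insufficient_data") {
    rlang::inform(paste0("no notification for ", result$apartment_id, "/",
                         result$activity, " on ", result$date,
                         ": insufficient sensor data"))
    return(NULL)
  }
  tpl <- utils::modifyList(default_templates(), templates)
  w <- routine_window(routine)
  appl <- unlist(result$appliances_used)
  appliance_clause <- if (length(appl) > 0) {
    fill_template(tpl$appliance,
                  list(appliances = paste(appl, collapse = " and the ")))
  } else {
    ""
  }
  fields <- list(
    duration = fmt_minutes(result$duration_minutes),
    room = routine$room,
    start = format_hm(w$start),
    end = format_hm(w$end),
    end_minus_1 = format_hm(w$end - 1L),
    visits = result$visit_count,
    appliance_clause = appliance_clause,
    lower = fmt_minutes(result$lower),
    upper = fmt_minutes(result$upper),
    message_id = message_id,
    date = as.character(result$date)
  )
  fields$footer <- fill_template(tpl$footer, fields)
  tibble::tibble(
    apartment_id = result$apartment_id,
    date = result$date,
    polarity = if (label == "normal") "positive" else "negative",
    message = fill_template(tpl[[label]], fields),
    message_id = as.integer(message_id),
    label = label
  )
}

#' Route a notification by household preference
#'
#' Households choose `"N"` (negative notifications only — alerts when
#' behaviour deviates) or `"NP"` (both polarities — including daily
#' confirmations of normal behaviour). Routing suppresses positives for
#' `"N"` households and sends everything else.
#'
#' @param polarity `"positive"` or `"negative"` (vectorised).
#' @param preference `"N"` or `"NP"` (recycled).
#' @return `"send"` or `"suppress"` per notification.
#' @examples
#' route_notification("positive", "N")   # suppress
#' route_notification("positive", "NP")  # send
#' @export
route_notification <- function(polarity, preference) {
  preference <- normalize_preference(preference)
  if (!all(polarity %in% c("positive", "negative"))) {
    abort("polarity must be 'positive' or 'negative'")
  }
  ifelse(polarity == "positive" & preference == "N", "suppress", "send")
}

#' Render and route all notifications for classified results
#'
#' Convenience wrapper: renders one notification per classified window
#' (skipping insufficient-data days), numbers messages sequentially per
#' apartment in date order, and applies preference routing.
#'
#' @param results classified window tibble ([classify_windows()]).
#' @param routines routine tibble covering every (apartment, activity) in
#'   `results`.
#' @param templates see [render_notification()].
#' @return Notification tibble with an added `decision` column
#'   (`"send"`/`"suppress"`).
#' @export
build_notifications <- function(results, routines,
                                templates = default_templates()) {
  results <- dplyr::arrange(results, .data$apartment_id, .data$date,
                            .data$activity)
  out <- vector("list", nrow(results))
  counter <- integer(0)
  for (i in seq_len(nrow(results))) {
    row <- results[i, ]
    r <- routines[routines$apartment_id == row$apartment_id &
                    routines$activity == row$activity, , drop = FALSE]
    if (nrow(r) != 1) {
      abort(paste0("no unique routine for apartment ", row$apartment_id,
                   ", activity '", row$activity, "'"))
    }
    if (as.character(row$label) == "insufficient_data") next
    prev <- if (row$apartment_id %in% names(counter)) {
      counter[[row$apartment_id]]
    } else {
      0L
    }
    id <- prev + 1L
    counter[row$apartment_id] <- id
    n <- render_notification(row, r, message_id = id, templates = templates)
    n$decision <- route_notification(n$polarity, r$preference)
    out[[i]] <- n
  }
  dplyr::bind_rows(out)
}

#' Aggregate a trial report of normal/anomalous activity counts
#'
#' Summarises observed meal/bathroom activities per (apartment,
#' activity): how many days were normal vs anomalous, and how many
#' positive/negative notifications routing would send given each
#' household's preference. Accepts either classified window results
#' ([classify_windows()] output, with a `preference` supplied per
#' apartment via `routines`) or a pre-aggregated counts table with
#' columns `apartment_id`, `activity`, `preference`, `observed`,
#' `normal`, `anomaly`.
#'
#' All percentages are recomputed from the counts and rounded
#' half-away-from-zero to integers.
#'
#' @param x classified results or a counts tibble.
#' @param routines routine tibble (needed only for classified results,
#'   to supply preferences).
#' @return A `trial_report` object: list with tibbles `rows` (per
#'   apartment-activity), `by_apartment` and `totals`.
#' @export
aggregate_report <- function(x, routines = NULL) {
  if (all(c("observed", "normal", "anomaly") %in% names(x))) {
    rows <- tibble::as_tibble(x)
    rows$preference <- normalize_preference(rows$preference)
    if (any(rows$observed != rows$normal + rows$anomaly)) {
      abort("counts inconsistent: observed must equal normal + anomaly")
    }
  } else {
    if (is.null(routines)) abort("routines needed to supply preferences")
    pref <- dplyr::distinct(routines, .data$apartment_id, .data$preference)
    rows <- x |>
      dplyr::filter(.data$label != "insufficient_data") |>
      dplyr::group_by(.data$apartment_id, .data$activity) |>
      dplyr::summarise(observed = dplyr::n(),
                       normal = sum(.data$label == "normal"),
                       anomaly = sum(.data$label != "normal"),
                       .groups = "drop") |>
      dplyr::left_join(pref, by = "apartment_id")
  }
  rows <- rows |>
    dplyr::mutate(
      positive_sent = ifelse(.data$preference == "NP", .data$normal, 0L),
      negative_sent = .data$anomaly,
      sent = .data$positive_sent + .data$negative_sent
    )

  pct <- function(num, den) {
    ifelse(den > 0, as.integer(round_half_away(100 * num / den)), NA_integer_)
  }
  by_apartment <- rows |>
    dplyr::group_by(.data$apartment_id, .data$preference) |>
    dplyr::summarise(dplyr::across(c("observed", "normal", "anomaly",
                                    "positive_sent", "negative_sent", "sent"),
                                   sum),
                     .groups = "drop") |>
    dplyr::mutate(normal_pct = pct(.data$normal, .data$observed),
                  positive_share_pct = pct(.data$positive_sent, .data$sent))
  totals <- rows |>
    dplyr::summarise(dplyr::across(c("observed", "normal", "anomaly",
                                    "positive_sent", "negative_sent", "sent"),
                                   sum)) |>
    dplyr::mutate(normal_pct = pct(.data$normal, .data$observed),
                  anomaly_pct = pct(.data$anomaly, .data$observed),
                  positive_share_pct = pct(.data$positive_sent, .data$sent))

  structure(list(rows = rows, by_apartment = by_apartment, totals = totals),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Trial report:", x$totals$observed, "observed activities,",
      x$totals$normal, paste0("(", x$totals$normal_pct, "%) normal,"),
      x$totals$anomaly, paste0("(", x$totals$anomaly_pct, "%) anomalous\n"))
  cat("  notifications sent:", x$totals$sent,
      paste0("(", x$totals$positive_sent, " positive, ",
             x$totals$negative_sent, " negative)\n"))
  print(x$rows, ...)
  invisible(x)
}

#' Per-mealtime activity counts from a two-month notification trial
#'
#' Observed / normal / anomalous daily meal-activity counts for eight
#' single-resident apartments over a July-August trial (13
#' apartment-mealtime rows), with each household's notification
#' preference. Useful as a worked input for [aggregate_report()].
#'
#' @return Counts tibble (`apartment_id`, `preference`, `activity`,
#'   `observed`, `normal`, `anomaly`).
#' @export
trial_meal_counts <- function() {
  path <- system.file("extdata", "trial_meal_counts.csv",
                      package = "routinewatch", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccciii", progress = FALSE)
}
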