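#' Duration model for a simulated activity
#'
#' Daily activity durations in real homes are rarely Gaussian — meal
#' durations typically show right-skewed, occasionally multi-modal
#' shapes — so the generator defaults to a lognormal family and also
#' offers normal, gamma and bimodal (two-component normal mixture)
#' families. Parameters are given as the target mean and standard
#' deviation in minutes and converted internally to the family's natural
#' parameters.
#'
#' @param family `"lognormal"` (default), `"normal"`, `"gamma"` or
#'   `"bimodal"`.
#' @param mean,sd target mean and standard deviation of the generated
#'   durations, in minutes (both > 0).
#' @param separation for `"bimodal"`: distance between the two component
#'   means as a multiple of `sd` (default 1.6); component weights are
#'   equal.
#' @return A `duration_model` list.
#' @examples
#' m <- duration_model("lognormal", mean = 87, sd = 35)
#' summary(sample_durations(m, 1000))
#' @export
duration_model <- function(family = c("lognormal", "normal", "gamma", "bimodal"),
                           mean, sd, separation = 1.6) {
  family <- match.arg(family)
  if (mean <= 0 || sd <= 0) abort("duration model needs mean > 0 and sd > 0")
  structure(list(family = family, mean = mean, sd = sd,
                 separation = separation),
            class = "duration_model")
}

#' Draw daily durations from a duration model
#'
#' Draws are truncated below at 0.5 minutes (a shorter stay is not
#' resolvable at the 0.1-minute reporting precision and a duration can
#' never be negative).
#'
#' @param model a [duration_model()].
#' @param n number of draws.
#' @return Numeric vector of durations in minutes.
#' @export
sample_durations <- function(model, n) {
  stopifnot(inherits(model, "duration_model"))
  m <- model$mean
  s <- model$sd
  x <- switch(model$family,
    lognormal = {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      rlnorm(n, meanlog, sdlog)
    },
    normal = rnorm(n, m, s),
    gamma = rgamma(n, shape = (m / s)^2, rate = m / s^2),
    bimodal = {
      # equal-weight mixture of two normals centred mean -/+ delta with
      # component sd chosen so the mixture sd equals the target
      delta <- model$separation * s / 2
      comp_sd <- sqrt(max(s^2 - delta^2, (0.1 * s)^2))
      mid <- m + ifelse(runif(n) < 0.5, -delta, delta)
      rnorm(n, mid, comp_sd)
    }
  )
  pmax(x, 0.5)
}

#' Inject a scheduled anomaly into a day plan
#'
#' Mutates the planned activity stays of one simulated day: `"skip"`
#' removes the activity entirely (an absence day), `"short_factor"` /
#' `"long_factor"` multiply the planned stay length by `factor`
#' (< 1 or > 1 respectively); the result is later clipped to the
#' activity window.
#'
#' @param day_plan tibble with columns `activity`, `duration`, `visits`.
#' @param activity which activity to perturb.
#' @param type `"skip"`, `"short_factor"` or `"long_factor"`.
#' @param factor multiplier, > 0 (ignored for `"skip"`).
#' @return The modified day plan.
#' @examples
#' plan <- tibble::tibble(activity = "breakfast", duration = 50, visits = 3L)
#' inject_anomaly(plan, "breakfast", "long_factor", 3)   # 150-min stay
#' inject_anomaly(plan, "breakfast", "skip")             # no stay
#' @export
inject_anomaly <- function(day_plan, activity, type, factor = NULL) {
  if (!type %in% c("skip", "short_factor", "long_factor")) {
    abort("anomaly type must be 'skip', 'short_factor' or 'long_factor'")
  }
  i <- which(day_plan$activity == activity)
  if (length(i) == 0) return(day_plan)
  if (type == "skip") {
    day_plan$duration[i] <- 0
    day_plan$visits[i] <- 0L
  } else {
    if (is.null(factor) || factor <= 0) abort("factor must be > 0")
    day_plan$duration[i] <- day_plan$duration[i] * factor
  }
  day_plan
}

#' Scenario configuration for the apartment simulator
#'
#' Describes a single-resident apartment and the statistical regime of
#' its simulated sensor stream. The defaults emulate a monitored
#' apartment with a morning kitchen routine: breakfast 06:00-09:00
#' (lognormal durations, mean 87 min, SD 35 min) and lunch 11:00-13:00
#' (mean 52 min, SD 25 min), a handful of short bathroom visits per day,
#' night-time in the bedroom, and PIR retrigger bounce injected as
#' duplicate readings.
#'
#' @param apartment_id apartment identifier.
#' @param routines routine tibble ([routine_spec()]); windows must not
#'   overlap.
#' @param duration_models named list (by activity) of
#'   [duration_model()]s.
#' @param visits_mean mean number of room visits making up one activity
#'   (>= 1); the visit count is `1 + Poisson(visits_mean - 1)`.
#' @param bathroom_visits_per_day mean number of short background
#'   bathroom visits (2-8 min each).
#' @param retrigger_rate mean PIR retrigger rate within a stay, events
#'   per minute; sensors also have a 5-second refractory period.
#' @param duplicate_rate probability that an emitted reading is followed
#'   by an identical duplicate within ~1 s.
#' @param dropouts optional tibble (`date`, `start`, `end` as `HH:MM`) of
#'   whole-home outage windows during which all readings are lost.
#' @param anomalies optional schedule tibble (`date`, `activity`, `type`,
#'   `factor`) of injected anomalies (see [inject_anomaly()]).
#' @param home_care_dates dates on which a home-care visit adds a 20-25
#'   minute assisted bathroom stay; these dates go into the exclusion
#'   calendar.
#' @param n_days number of simulated days.
#' @param start_date first simulated date.
#' @param seed RNG seed; a fixed seed makes the simulation byte-identical.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(apartment_id = "1",
                            routines = NULL,
                            duration_models = NULL,
                            visits_mean = 3,
                            bathroom_visits_per_day = 3,
                            retrigger_rate = 1,
                            duplicate_rate = 0.05,
                            dropouts = NULL,
                            anomalies = NULL,
                            home_care_dates = as.Date(character()),
                            n_days = 60,
                            start_date = as.Date("2020-07-01"),
                            seed = 1L) {
  if (is.null(routines)) {
    routines <- dplyr::bind_rows(
      routine_spec(apartment_id, "breakfast", "kitchen", "06:00", "09:00", "NP"),
      routine_spec(apartment_id, "lunch", "kitchen", "11:00", "13:00", "NP")
    )
  }
  validate_routines(routines)
  ws <- parse_hm(routines$window_start)
  we <- parse_hm(routines$window_end)
  ord <- order(ws)
  if (any(ws[ord][-1] < we[ord][-length(ord)])) {
    abort("routine windows must not overlap")
  }
  if (is.null(duration_models)) {
    duration_models <- list(
      breakfast = duration_model("lognormal", mean = 87, sd = 35),
      lunch = duration_model("lognormal", mean = 52, sd = 25)
    )
  }
  missing <- setdiff(routines$activity, names(duration_models))
  if (length(missing)) {
    abort(paste0("no duration model for activity: ",
                 paste(missing, collapse = ", ")))
  }
  if (duplicate_rate < 0 || duplicate_rate > 1) {
    abort("duplicate_rate must lie in [0, 1]")
  }
  if (visits_mean < 1) abort("visits_mean must be >= 1")
  if (!is.null(anomalies) && nrow(anomalies) > 0) {
    if (!all(anomalies$type %in% c("skip", "short_factor", "long_factor"))) {
      abort("anomaly type must be 'skip', 'short_factor' or 'long_factor'")
    }
    if ("factor" %in% names(anomalies) &&
        any(!is.na(anomalies$factor) & anomalies$factor <= 0)) {
      abort("anomaly factor must be > 0")
    }
  }
  structure(list(
    apartment_id = as.character(apartment_id),
    routines = routines[ord, ],
    duration_models = duration_models,
    visits_mean = visits_mean,
    bathroom_visits_per_day = bathroom_visits_per_day,
    retrigger_rate = retrigger_rate,
    duplicate_rate = duplicate_rate,
    dropouts = dropouts,
    anomalies = anomalies,
    home_care_dates = as.Date(home_care_dates),
    n_days = as.integer(n_days),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

# run code under a local RNG seed, restoring global RNG state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# split a filler stay to insert a visit of `len` minutes to `room`;
# returns the modified stay table or NULL if nothing fits
insert_visit <- function(stays, room, len, after_minute = 0) {
  cand <- which(stays$filler & (stays$end - stays$start) > len + 4 &
                  stays$end > after_minute)
  if (length(cand) == 0) cand <- which(stays$filler &
                                         (stays$end - stays$start) > len + 4)
  if (length(cand) == 0) return(NULL)
  i <- cand[[sample.int(length(cand), 1)]]
  s <- stays[i, ]
  lo <- max(s$start, after_minute) + 1
  hi <- s$end - len - 1
  if (hi <= lo) { lo <- s$start + 1; hi <- s$end - len - 1 }
  at <- runif(1, lo, hi)
  dplyr::bind_rows(
    stays[seq_len(i - 1), ],
    tibble::tibble(room = s$room, start = s$start, end = at, filler = TRUE),
    tibble::tibble(room = room, start = at, end = at + len, filler = FALSE),
    tibble::tibble(room = s$room, start = at + len, end = s$end, filler = TRUE),
    stays[setdiff(seq_len(nrow(stays)), seq_len(i)), ]
  )
}

# contiguous room stays for one simulated day (minutes since midnight);
# returns the stay table plus the visit count actually realised per
# activity (excursions are dropped when a stay fills its whole window)
plan_day_stays <- function(routines, plan, cfg, home_care = FALSE) {
  stays <- list()
  visits_realized <- integer(nrow(plan))
  names(visits_realized) <- plan$activity
  cursor <- 0
  for (i in seq_len(nrow(routines))) {
    r <- routines[i, ]
    w <- routine_window(r)
    d <- plan$duration[plan$activity == r$activity]
    v <- plan$visits[plan$activity == r$activity]
    len_w <- w$end - w$start
    if (d <= 0) next
    d <- min(d, len_w)
    exc <- if (v > 1) runif(v - 1, 1, 3) else numeric(0)
    if (d + sum(exc) > len_w && length(exc) > 0) {
      exc <- exc * max(0, len_w - d) / sum(exc)
      if (sum(exc) < 0.5 * (v - 1)) { exc <- numeric(0); v <- 1L }
    }
    visits_realized[r$activity] <- v
    slack <- len_w - d - sum(exc)
    b0 <- w$start + runif(1, 0, max(0, slack))
    segw <- runif(v, 0.5, 1.5)
    seg <- d * segw / sum(segw)
    # filler up to the block
    if (b0 > cursor) {
      room <- if (w$start < 720 && cursor < 360) "bedroom" else "lounge"
      stays[[length(stays) + 1]] <-
        tibble::tibble(room = room, start = cursor, end = b0, filler = TRUE)
    }
    t <- b0
    for (j in seq_len(v)) {
      stays[[length(stays) + 1]] <-
        tibble::tibble(room = r$room, start = t, end = t + seg[j],
                       filler = FALSE)
      t <- t + seg[j]
      if (j < v) {
        stays[[length(stays) + 1]] <-
          tibble::tibble(room = "lounge", start = t, end = t + exc[j],
                         filler = FALSE)
        t <- t + exc[j]
      }
    }
    cursor <- t
  }
  night <- 1290  # 21:30 bedtime
  if (cursor < night) {
    stays[[length(stays) + 1]] <-
      tibble::tibble(room = "lounge", start = cursor, end = night,
                     filler = TRUE)
    cursor <- night
  }
  stays[[length(stays) + 1]] <-
    tibble::tibble(room = "bedroom", start = cursor, end = 1439, filler = TRUE)
  stays <- dplyr::bind_rows(stays)

  n_bath <- max(1L, rpois(1, cfg$bathroom_visits_per_day))
  for (b in seq_len(n_bath)) {
    res <- insert_visit(stays, "bathroom", runif(1, 2, 8))
    if (!is.null(res)) stays <- res
  }
  if (home_care) {
    res <- insert_visit(stays, "bathroom", runif(1, 20, 25), after_minute = 720)
    if (!is.null(res)) stays <- res
  }
  list(stays = stays[stays$end - stays$start > 0, ],
       visits = visits_realized)
}

# motion/plug/water events for one day of stays; times in seconds of day
emit_day_events <- function(stays, date, cfg, water_state) {
  meal_rooms <- unique(cfg$routines$room)
  ev <- vector("list", nrow(stays))
  water <- list()
  for (i in seq_len(nrow(stays))) {
    s <- stays[i, ]
    t0 <- round(s$start * 60)
    t1 <- round(s$end * 60)
    len <- t1 - t0
    n_re <- rpois(1, cfg$retrigger_rate * len / 60)
    times <- sort(c(0, runif(n_re, 0, max(len - 1, 1))))
    # 5-second sensor refractory period
    keep <- c(TRUE, diff(times) >= 5)
    while (any(!keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= 5)
    }
    ev[[i]] <- tibble::tibble(
      sensor_id = paste0("M_", s$room),
      sensor_type = "motion",
      room = s$room,
      second = t0 + round(times),
      value = 1
    )
    if (s$room == "bathroom") {
      water_state$total <- water_state$total + runif(1, 4, 9)
      water[[length(water) + 1]] <- tibble::tibble(
        sensor_id = "water_main", sensor_type = "water_meter",
        room = "bathroom", second = t0 + min(30, len),
        value = round(water_state$total, 1)
      )
    }
  }
  ev <- dplyr::bind_rows(ev)

  # kettle plug during the first meal-room stay of each activity window
  plugs <- list()
  for (i in seq_len(nrow(cfg$routines))) {
    w <- routine_window(cfg$routines[i, ])
    in_w <- stays$room %in% meal_rooms & !stays$filler &
      stays$start >= w$start & stays$start < w$end
    j <- which(in_w)[1]
    if (!is.na(j) && stays$end[j] - stays$start[j] >= 6) {
      t0 <- round(stays$start[j] * 60)
      plugs[[length(plugs) + 1]] <- tibble::tibble(
        sensor_id = "kettle", sensor_type = "wall_plug",
        room = cfg$routines$room[i],
        second = t0 + c(60, 180, 300),
        value = c(1800, 1500, 0)
      )
    }
  }
  ev <- dplyr::bind_rows(ev, dplyr::bind_rows(plugs), dplyr::bind_rows(water))
  ev$timestamp <- as.POSIXct(as.character(date), tz = "UTC") + ev$second
  ev$second <- NULL
  list(events = ev, water_state = water_state)
}

#' Simulate a single-resident apartment sensor stream
#'
#' Generates one apartment's event stream over `n_days` with full ground
#' truth. Each day a plan of room stays realises the sampled activity
#' durations inside their routine windows (split across several visits
#' with short excursions), interleaved with background bedroom/lounge
#' time and short bathroom visits; motion events fire at every stay
#' start with Poisson retriggers during the stay, a kettle wall plug runs
#' during meal stays and a cumulative water meter ticks on bathroom
#' visits. Scheduled anomalies perturb the plan ([inject_anomaly()]),
#' home-care dates add an assisted 20-25 min bathroom stay, and noise —
#' duplicate readings and whole-home dropouts — is applied last and
#' recorded in the truth. Identical configuration and seed give a
#' byte-identical stream.
#'
#' @param config a [scenario_config()].
#' @return A list:
#'   \describe{
#'     \item{events}{sorted event tibble (after noise)}
#'     \item{truth}{list with `activities` (per date x activity: planned
#'       `true_duration` minutes, `true_visits`, `anomaly` type or `NA`),
#'       `duplicates` (tibble of injected duplicate readings),
#'       `duplicate_count`, and `dropouts` (tibble of outage intervals)}
#'     \item{routines}{the routine tibble}
#'     \item{exclusions}{exclusion calendar covering the home-care dates}
#'   }
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_local_seed(config$seed, {
    dates <- config$start_date + seq_len(config$n_days) - 1L
    all_events <- vector("list", config$n_days)
    truth_rows <- vector("list", config$n_days)
    water_state <- list(total = 0)

    for (di in seq_along(dates)) {
      d <- dates[di]
      plan <- tibble::tibble(
        activity = config$routines$activity,
        duration = vapply(config$routines$activity, function(a) {
          sample_durations(config$duration_models[[a]], 1)
        }, numeric(1)),
        visits = 1L + rpois(nrow(config$routines), config$visits_mean - 1)
      )
      anomaly <- rep(NA_character_, nrow(plan))
      if (!is.null(config$anomalies) && nrow(config$anomalies) > 0) {
        sched <- config$anomalies[as.Date(config$anomalies$date) == d, ,
                                  drop = FALSE]
        for (k in seq_len(nrow(sched))) {
          plan <- inject_anomaly(plan, sched$activity[k], sched$type[k],
                                 if ("factor" %in% names(sched)) sched$factor[k])
          anomaly[plan$activity == sched$activity[k]] <- sched$type[k]
        }
      }
      # clip to window length (what a real day can physically contain)
      wlen <- parse_hm(config$routines$window_end) -
        parse_hm(config$routines$window_start)
      plan$duration <- pmin(plan$duration, wlen)

      planned <- plan_day_stays(config$routines, plan, config,
                                home_care = d %in% config$home_care_dates)
      day <- emit_day_events(planned$stays, d, config, water_state)
      water_state <- day$water_state
      all_events[[di]] <- day$events
      truth_rows[[di]] <- tibble::tibble(
        date = d, activity = plan$activity,
        true_duration = plan$duration,
        true_visits = unname(planned$visits[plan$activity]),
        anomaly = anomaly
      )
    }

    events <- dplyr::bind_rows(all_events)
    events <- events[order(events$timestamp, method = "radix"), ]
    events <- events[, c("sensor_id", "sensor_type", "room", "timestamp",
                         "value")]

    # dropouts: whole-home outages, all readings lost
    dropouts <- tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                               end = as.POSIXct(character(), tz = "UTC"))
    if (!is.null(config$dropouts) && nrow(config$dropouts) > 0) {
      d0 <- date_time(as.Date(config$dropouts$date),
                      parse_hm(config$dropouts$start))
      d1 <- date_time(as.Date(config$dropouts$date),
                      parse_hm(config$dropouts$end))
      lost <- rep(FALSE, nrow(events))
      for (k in seq_along(d0)) {
        lost <- lost | (events$timestamp >= d0[k] & events$timestamp < d1[k])
      }
      events <- events[!lost, ]
      dropouts <- tibble::tibble(start = d0, end = d1)
    }

    # duplicate injection: identical reading ~1 s after the original
    dup_idx <- which(runif(nrow(events)) < config$duplicate_rate)
    duplicates <- events[dup_idx, , drop = FALSE]
    if (length(dup_idx) > 0) {
      duplicates$timestamp <- duplicates$timestamp + 1
      events <- dplyr::bind_rows(events, duplicates)
      events <- events[order(events$timestamp, method = "radix"), ]
    }

    list(
      events = tibble::as_tibble(events),
      truth = list(activities = dplyr::bind_rows(truth_rows),
                   duplicates = tibble::as_tibble(duplicates),
                   duplicate_count = length(dup_idx),
                   dropouts = dropouts),
      routines = config$routines,
      exclusions = exclusion_calendar(config$apartment_id,
                                      config$home_care_dates)
    )
  })
}
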