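# shared fixture builders

# motion events in one room at given HH:MM(:SS) times on one date
mk_motion <- function(rooms, times, date = "2020-07-21") {
  ts <- paste0(date, "T", ifelse(nchar(times) == 5, paste0(times, ":00"), times))
  sensor_events(paste0("M_", rooms), "motion", rooms, ts, 1)
}

# a features row as produced by window_features()
mk_features <- function(duration, visits = as.integer(duration > 0),
                       date = as.Date("2020-07-21"), activity = "breakfast",
                       apartment_id = "1", appliances = character(),
                       sufficient = TRUE) {
  tibble::tibble(apartment_id = apartment_id, activity = activity,
                 date = as.Date(date), duration_minutes = duration,
                 visit_count = as.integer(visits),
                 appliances_used = list(appliances),
                 data_sufficient = sufficient)
}

# n days of features from raw durations
mk_history <- function(durations, start = as.Date("2019-01-01"), ...) {
  dplyr::bind_rows(lapply(seq_along(durations), function(i) {
    mk_features(durations[i], date = start + i - 1, ...)
  }))
}

# seeded draws from a duration model, restoring RNG state
sample_durations_fixed <- function(mean, sd, n, seed, family = "lognormal") {
  withr::with_seed(seed, sample_durations(duration_model(family, mean, sd), n))
}

# seconds-of-day -> "HH:MM:SS"
format_hm_sec <- function(sec) {
  sec <- round(sec)
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

breakfast_routine <- function(pref = "NP") {
  routine_spec("1", "breakfast", "kitchen", "06:00", "09:00", pref)
}

# small default scenario for end-to-end tests
small_scenario <- function(n_days = 10, seed = 1, ...) {
  scenario_config(n_days = n_days, seed = seed, ...)
}
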