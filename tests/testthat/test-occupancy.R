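# occupancy state machine and window feature extraction

test_that("occupancy intervals follow the room state machine", {
  ev <- mk_motion(c("kitchen", "kitchen", "bedroom"),
                  c("08:00", "08:20", "08:45"))
  iv <- build_occupancy(ev)
  # the zero-length final bedroom interval is dropped
  expect_equal(nrow(iv), 1)
  expect_equal(iv$room, "kitchen")
  expect_equal(iv$duration_minutes, 45)

  # a single event has nothing to close
  expect_equal(nrow(build_occupancy(mk_motion("kitchen", "08:00"))), 0)

  # intervals tile the span, never overlap, and change room
  ev <- mk_motion(c("bedroom", "kitchen", "kitchen", "lounge", "kitchen",
                    "bedroom"),
                  c("06:00", "06:30", "07:00", "07:40", "08:00", "08:30"))
  iv <- build_occupancy(ev)
  expect_equal(iv$room, c("bedroom", "kitchen", "lounge", "kitchen"))
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  expect_equal(sum(iv$duration_minutes), 150)  # 06:00 -> 08:30

  expect_error(build_occupancy(sensor_events("P", "wall_plug", "kitchen",
                                             "2020-07-21T08:00:00", 100)),
               "motion")
})

test_that("occupancy recovers the simulator's scripted stays", {
  sim <- simulate_scenario(small_scenario(n_days = 1, seed = 21,
                                          duplicate_rate = 0))
  motion <- sim$events[sim$events$sensor_type == "motion", ]
  iv <- build_occupancy(motion)
  expect_true(all(iv$end[-nrow(iv)] == iv$start[-1]))
  expect_true(all(iv$room[-1] != iv$room[-nrow(iv)]))
  # the planned breakfast duration is recovered inside its window
  tr <- sim$truth$activities
  fe <- extract_features(sim$events, sim$routines)
  m <- dplyr::inner_join(fe, tr, by = c("date", "activity"))
  expect_true(all(abs(m$duration_minutes - m$true_duration) <= 0.2))
  expect_equal(m$visit_count, m$true_visits)
})

test_that("window features clip, count visits, and flag appliances", {
  routine <- breakfast_routine()
  # one kitchen interval 06:30-07:20 inside 06:00-09:00
  iv <- build_occupancy(mk_motion(c("lounge", "kitchen", "lounge"),
                                  c("06:00", "06:30", "07:20")))
  f <- window_features(iv, NULL, routine, "2020-07-21")
  expect_equal(f$duration_minutes, 50)
  expect_equal(f$visit_count, 1L)
  expect_equal(f$appliances_used[[1]], character())

  # interval straddling the window start is clipped
  iv <- build_occupancy(mk_motion(c("kitchen", "lounge"),
                                  c("05:40", "06:10")))
  f <- window_features(iv, NULL, routine, "2020-07-21")
  expect_equal(f$duration_minutes, 10)
  expect_equal(f$visit_count, 1L)

  # eight kitchen stays totalling 50.4 min, kettle plug active
  starts <- c("07:00", "07:20", "07:40", "08:00", "08:20", "08:40",
              "09:00", "09:20")
  stay_min <- c(6.3, 6.3, 6.3, 6.3, 6.3, 6.3, 6.3, 6.3)  # 50.4 total
  rooms <- character(0); times <- character(0)
  for (i in seq_along(starts)) {
    t0 <- parse_hm(starts[i])
    rooms <- c(rooms, "kitchen", "lounge")
    times <- c(times, format_hm_sec(t0 * 60), format_hm_sec((t0 + stay_min[i]) * 60))
  }
  ev <- mk_motion(rooms, times)
  routine2 <- routine_spec("1", "breakfast", "kitchen", "07:00", "10:04", "NP")
  plug <- sensor_events("kettle", "wall_plug", "kitchen",
                        "2020-07-21T07:02:00", 1800)
  f <- window_features(build_occupancy(ev), plug, routine2, "2020-07-21")
  expect_equal(f$duration_minutes, 50.4)
  expect_equal(f$visit_count, 8L)
  expect_equal(f$appliances_used[[1]], "kettle")
})

test_that("windows are half-open and extension is monotone", {
  # an interval touching only the end instant contributes nothing
  iv <- build_occupancy(mk_motion(c("kitchen", "lounge"),
                                  c("09:00", "09:30")))
  f <- window_features(iv, NULL, breakfast_routine(), "2020-07-21")
  expect_equal(f$duration_minutes, 0)
  expect_equal(f$visit_count, 0L)

  # growing the window never decreases duration or visits
  sim <- simulate_scenario(small_scenario(n_days = 1, seed = 31))
  iv <- build_occupancy(sim$events[sim$events$sensor_type == "motion", ])
  ends <- c("07:00", "08:00", "09:00", "10:00")
  f <- lapply(ends, function(e) {
    r <- routine_spec("1", "breakfast", "kitchen", "06:00", e)
    window_features(iv, NULL, r, "2020-07-01")
  })
  dur <- vapply(f, `[[`, numeric(1), "duration_minutes")
  vis <- vapply(f, `[[`, integer(1), "visit_count")
  expect_true(all(diff(dur) >= 0))
  expect_true(all(diff(vis) >= 0))
  expect_true(all(dur <= c(60, 120, 180, 240)))
})

test_that("visit counts are invariant to duplicate events", {
  ev <- mk_motion(c("lounge", "kitchen", "kitchen", "lounge"),
                  c("06:00:00", "06:30:00", "06:30:01", "07:00:00"))
  f1 <- window_features(build_occupancy(ev), NULL, breakfast_routine(),
                        "2020-07-21")
  dd <- dedup_events(ev, 2)$events
  f2 <- window_features(build_occupancy(dd), NULL, breakfast_routine(),
                        "2020-07-21")
  expect_equal(f1$visit_count, f2$visit_count)
  expect_equal(f1$duration_minutes, f2$duration_minutes)
})
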