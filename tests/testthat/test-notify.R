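# notification rendering, preference routing, trial report aggregation

mk_result <- function(duration, label, visits = 8L, appliances = "kettle",
                      lower = 9, upper = 70) {
  tibble::tibble(apartment_id = "1", activity = "breakfast",
                 date = as.Date("2020-07-21"), duration_minutes = duration,
                 visit_count = as.integer(visits),
                 appliances_used = list(appliances),
                 data_sufficient = TRUE,
                 label = factor(label, levels = c("normal", "short", "long",
                                                  "not_present",
                                                  "insufficient_data")),
                 lower = lower, upper = upper, mu = 39.5, sigma = 15.25)
}

test_that("the positive message carries duration, visits, appliance, range", {
  routine <- routine_spec("1", "breakfast", "kitchen", "07:00", "10:04", "NP")
  n <- render_notification(mk_result(50.4, "normal"), routine, message_id = 1)
  expect_equal(n$polarity, "positive")
  expect_match(n$message, "50.4 minutes of activity in the kitchen")
  expect_match(n$message, "between 07:00 and 10:04")
  expect_match(n$message, "during 8 visits")
  expect_match(n$message, "The kettle has been used")
  expect_match(n$message, "9-70 minutes is the normal time duration")
  expect_match(n$message, "Message ID: 1, 2020-07-21")
})

test_that("absence messages quote the window end minus one minute", {
  routine <- routine_spec("6", "breakfast", "kitchen", "05:00", "08:00", "NP")
  r <- mk_result(0, "not_present", visits = 0L, appliances = character())
  r$apartment_id <- "6"
  n <- render_notification(r, routine)
  expect_equal(n$polarity, "negative")
  expect_match(n$message,
               "No activity in the kitchen between 05:00 and 07:59",
               fixed = TRUE)
})

test_that("the appliance clause is omitted when no plug fired", {
  routine <- breakfast_routine()
  n <- render_notification(mk_result(50, "normal", appliances = character()),
                           routine)
  expect_no_match(n$message, "has been used")

  # short and long days render negative messages with the range
  n_short <- render_notification(mk_result(4, "short", visits = 1L,
                                           appliances = character()), routine)
  expect_equal(n_short$polarity, "negative")
  expect_match(n_short$message, "shorter than the normal 9-70")
  n_long <- render_notification(mk_result(120, "long", visits = 2L,
                                          appliances = character()), routine)
  expect_match(n_long$message, "longer than the normal 9-70")

  # insufficient data yields no message at all
  expect_message(
    out <- render_notification(mk_result(0, "insufficient_data"), routine),
    "insufficient")
  expect_null(out)
})

test_that("routing suppresses positives for N and sends everything for NP", {
  expect_equal(route_notification("positive", "N"), "suppress")
  expect_equal(route_notification("positive", "NP"), "send")
  expect_equal(route_notification("negative", "N"), "send")
  expect_equal(route_notification("negative", "NP"), "send")
  expect_equal(route_notification("positive", "N/P"), "send")
})

test_that("trial counts aggregate to the published totals", {
  counts <- trial_meal_counts()
  expect_equal(nrow(counts), 13)
  rep <- aggregate_report(counts)
  expect_equal(rep$totals$observed, 716)
  expect_equal(rep$totals$normal, 668)
  expect_equal(rep$totals$anomaly, 48)
  expect_equal(rep$totals$normal_pct, 93)
  expect_equal(rep$totals$anomaly_pct, 7)

  apt1 <- rep$by_apartment[rep$by_apartment$apartment_id == "1", ]
  expect_equal(apt1$observed, 135)
  expect_equal(apt1$positive_sent, 119)
  expect_equal(apt1$sent, 135)
  expect_equal(apt1$positive_share_pct, 88)   # 119/135
  # arithmetic rounding of 56/69 gives 81
  expect_equal(as.integer(round_half_away(100 * 56 / 69)), 81L)
})

test_that("sent notifications conserve counts, with equality only for NP", {
  rep <- aggregate_report(trial_meal_counts())
  expect_true(all(rep$rows$positive_sent + rep$rows$negative_sent <=
                    rep$rows$observed))
  np <- rep$rows$preference == "NP"
  expect_true(all((rep$rows$positive_sent + rep$rows$negative_sent ==
                     rep$rows$observed) == np))
  # empty input -> all-zero report
  empty <- aggregate_report(trial_meal_counts()[0, ])
  expect_equal(empty$totals$observed, 0)
  expect_equal(empty$totals$sent, 0)
})

test_that("classified results aggregate with per-apartment message ids", {
  h <- mk_history(c(rep(45, 30), rep(50, 25), rep(55, 30)))
  m <- fit_thresholds(h)
  days <- mk_history(c(50, 0, 44, 56, 200))
  days$date <- as.Date("2020-07-21") + 0:4
  res <- classify_windows(days, m)
  routines <- breakfast_routine("NP")
  notes <- build_notifications(res, routines)
  expect_equal(nrow(notes), 5)
  expect_equal(notes$message_id, 1:5)
  expect_equal(notes$decision, rep("send", 5))
  expect_equal(sum(notes$polarity == "negative"), 2)  # the 0 and the 200

  rep <- aggregate_report(res, routines)
  expect_equal(rep$totals$observed, 5)
  expect_equal(rep$totals$normal, 3)
  expect_equal(rep$totals$positive_sent, 3)
  expect_equal(rep$totals$negative_sent, 2)

  # N preference suppresses the positives in the sent counts
  rep_n <- aggregate_report(res, breakfast_routine("N"))
  expect_equal(rep_n$totals$positive_sent, 0)
  expect_equal(rep_n$totals$negative_sent, 2)
})
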