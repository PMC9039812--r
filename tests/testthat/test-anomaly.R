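# Chebyshev constants, threshold fitting, classification, coverage

test_that("k follows the inverse-square-root relation exactly", {
  expect_identical(chebyshev_k(0.25), 2)
  expect_identical(chebyshev_k(1.0), 1)
  expect_identical(chebyshev_k(0.01), 10)
  expect_identical(chebyshev_bound(2), 0.25)
  expect_error(chebyshev_k(0), "p_level")
  expect_error(chebyshev_k(1.5), "p_level")
  expect_error(chebyshev_bound(-1), "k")
})

test_that("normality assessment matches an independent reference", {
  # reference W and p computed with a second statistical implementation
  # (scipy.stats.shapiro) on the same fixed samples
  set.seed(42); x <- rnorm(200, 50, 10)
  r <- shapiro_normality(x)
  expect_equal(r$W, 0.996672, tolerance = 1e-5)
  expect_equal(r$p_value, 0.946418, tolerance = 1e-4)
  expect_false(r$reject_normality)

  set.seed(43); y <- rlnorm(200, log(50), 0.6)
  r <- shapiro_normality(y)
  expect_equal(r$W, 0.861809, tolerance = 1e-5)
  expect_true(r$reject_normality)

  expect_error(shapiro_normality(c(5, 5, 5, 5)), "degenerate")
  expect_error(shapiro_normality(c(1, 2)), "n")
})

test_that("threshold fitting follows mu +/- k*sigma with clipping", {
  # symmetric 101-point grid scaled to mean 50, sd 10 exactly
  s <- seq(-1, 1, length.out = 101)
  d <- 50 + s * 10 / stats::sd(s)
  h <- mk_history(d)
  m <- fit_thresholds(h, p_level = 0.25, min_days = 50)
  expect_equal(m$mu, 50)
  expect_equal(m$sigma, 10)
  expect_equal(m$lower, 30)
  expect_equal(m$upper, 70)
  expect_equal(m$k, 2)
  expect_equal(m$n_days, 101)

  # lower bound clips at zero; upper at the window length
  s2 <- seq(-1, 1, length.out = 60)
  h2 <- mk_history(6 + s2 * 3.5 / stats::sd(s2))  # mean 6, sd 3.5
  m2 <- fit_thresholds(h2, window_minutes = 12)
  expect_equal(m2$lower, 0)    # 6 - 2*3.5 < 0, clipped
  expect_equal(m2$upper, 12)   # 6 + 2*3.5 > window length, clipped

  expect_error(fit_thresholds(mk_history(rep(50, 10))), "insufficient history")
  expect_error(fit_thresholds(mk_history(rep(50, 60))), "degenerate")
})

test_that("insufficient-data days are dropped before fitting", {
  d <- 50 + seq(-1, 1, length.out = 80) * 10
  h <- mk_history(d)
  h$data_sufficient[1:20] <- FALSE
  m <- fit_thresholds(h, min_days = 50)
  expect_equal(m$n_days, 60)
  expect_equal(m$mu, mean(d[21:80]))
})

test_that("classification is a partition with the documented precedence", {
  h <- mk_history(c(rep(45, 30), rep(50, 30), rep(55, 30)))
  m <- fit_thresholds(h, min_days = 50)

  lab <- function(dur, suff = TRUE) {
    as.character(classify_windows(mk_features(dur, sufficient = suff), m)$label)
  }
  expect_equal(lab(m$mu), "normal")
  expect_equal(lab(m$lower), "normal")           # closed bounds
  expect_equal(lab(m$upper), "normal")
  expect_equal(lab(m$lower - 0.1), "short")
  expect_equal(lab(m$upper + 0.1), "long")
  expect_equal(lab(0), "not_present")            # absence beats short
  expect_equal(lab(0, suff = FALSE), "insufficient_data")
  expect_equal(lab(999, suff = FALSE), "insufficient_data")

  # exactly one label for any duration
  durs <- seq(0, 120, by = 0.5)
  labels <- as.character(classify_windows(mk_history(durs), m)$label)
  expect_true(all(labels %in% c("normal", "short", "long", "not_present")))
  expect_equal(sum(labels == "not_present"), 1)  # only the zero
})

test_that("worked example: 50.4 min against bounds [9, 70] is normal", {
  m <- structure(list(apartment_id = "1", activity = "breakfast",
                      mu = 39.5, sigma = 15.25, k = 2, p_level = 0.25,
                      lower = 9, upper = 70, window_minutes = 184,
                      n_days = 355,
                      normality = tibble::tibble(W = NA_real_,
                                                 p_value = NA_real_,
                                                 reject_normality = NA,
                                                 n = 355L)),
                 class = "threshold_model")
  r <- classify_windows(mk_features(50.4, visits = 8), m)
  expect_equal(as.character(r$label), "normal")
})

test_that("smaller k never widens the normal range", {
  h <- mk_history(sample_durations_fixed(87, 35, 200, seed = 4))
  ms <- lapply(c(0.1, 0.25, 0.5, 1.0), function(p) fit_thresholds(h, p_level = p))
  lowers <- vapply(ms, `[[`, numeric(1), "lower")
  uppers <- vapply(ms, `[[`, numeric(1), "upper")
  expect_true(all(diff(lowers) >= 0))
  expect_true(all(diff(uppers) <= 0))
})

test_that("self-fit k=2 coverage honours the Chebyshev guarantee", {
  # identical history -> full coverage (trivially within bounds)
  h0 <- mk_history(50 + seq(-0.1, 0.1, length.out = 60))
  m0 <- fit_thresholds(h0)
  expect_equal(coverage(h0, m0), 1.0)

  # any distribution the simulator produces: >= 75% at n = 1000
  fams <- c("lognormal", "gamma", "bimodal")
  for (fam in fams) {
    for (seed in 1:3) {
      h <- mk_history(sample_durations_fixed(87, 35, 1000, seed = seed,
                                             family = fam))
      m <- fit_thresholds(h)
      expect_gte(coverage(h, m), 0.75)
    }
  }

  # normal data: coverage approaches the 2-sigma tail value, not 75%
  h <- mk_history(sample_durations_fixed(87, 10, 4000, seed = 1,
                                         family = "normal"))
  m <- fit_thresholds(h)
  expect_equal(coverage(h, m), 2 * pnorm(2) - 1, tolerance = 0.02)
})

test_that("fitting 355 simulated days recovers the generator mean", {
  hits <- 0
  for (seed in 1:20) {
    d <- sample_durations_fixed(87, 35, 355, seed = seed)
    m <- fit_thresholds(mk_history(d))
    se <- m$sigma / sqrt(m$n_days)
    hits <- hits + (abs(m$mu - 87) <= 2 * se)
  }
  expect_gte(hits, 19)
})
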