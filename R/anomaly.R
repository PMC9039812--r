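#' Number of standard deviations for a Chebyshev significance level
#'
#' Chebyshev's inequality bounds the probability of a value falling more
#' than k standard deviations from the mean by `1/k^2`, for any
#' distribution with finite variance. Choosing a significance level p for
#' that tail probability gives `k = 1/sqrt(p)`: with p = 0.25 (75%
#' confidence), k = 2, i.e. at least 75% of any duration distribution
#' lies within two standard deviations of its mean.
#'
#' @param p_level significance level in (0, 1].
#' @return k, the number of standard deviations.
#' @examples
#' chebyshev_k(0.25)  # 2
#' @export
chebyshev_k <- function(p_level) {
  if (!is.numeric(p_level) || any(p_level <= 0) || any(p_level > 1)) {
    abort("p_level must lie in (0, 1]")
  }
  1 / sqrt(p_level)
}

#' Chebyshev tail bound for k standard deviations
#'
#' The upper bound `1/k^2` on `P(|X - mu| >= k * sigma)`; the inverse of
#' [chebyshev_k()].
#'
#' @param k number of standard deviations, > 0.
#' @return The tail probability bound `1/k^2`.
#' @examples
#' chebyshev_bound(2)  # 0.25
#' @export
chebyshev_bound <- function(k) {
  if (!is.numeric(k) || any(k <= 0)) abort("k must be > 0")
  1 / k^2
}

#' Shapiro-Wilk normality assessment of duration samples
#'
#' Diagnostic only: the detection path always uses distribution-free
#' Chebyshev thresholds regardless of the outcome. The test is suited to
#' samples of roughly 50-2000 days; normality is rejected when p < 0.05.
#'
#' @param samples numeric vector of daily durations (minutes), 3 <= n <=
#'   2000, not all equal.
#' @return One-row tibble: `W`, `p_value`, `reject_normality`, `n`.
#' @export
shapiro_normality <- function(samples) {
  n <- length(samples)
  if (n < 3 || n > 2000) {
    abort(paste0("Shapiro-Wilk needs 3 <= n <= 2000 samples, got ", n))
  }
  if (diff(range(samples)) == 0) {
    abort("degenerate sample: all durations equal")
  }
  sw <- shapiro.test(samples)
  tibble::tibble(W = unname(sw$statistic),
                 p_value = sw$p.value,
                 reject_normality = sw$p.value < 0.05,
                 n = n)
}

#' Fit a per-activity Chebyshev threshold model
#'
#' Learns the normal duration range for one (apartment, activity) from a
#' history of daily window features: `mu` and `sigma` are the sample mean
#' and standard deviation (n - 1 denominator) of `duration_minutes`;
#' the normal range is `[max(0, mu - k*sigma), min(L, mu + k*sigma)]`
#' with `k = 1/sqrt(p_level)` and L the window length in minutes.
#' Because Chebyshev's inequality holds for any distribution, at least
#' `1 - p_level` of the fitting history is expected to fall inside the
#' range, whatever shape the durations take — daily activity durations
#' are typically not normally distributed, which is why a
#' distribution-free range is used. A Shapiro-Wilk result is attached as
#' diagnostic metadata when the sample size permits.
#'
#' Rows on excluded dates should already be removed
#' ([apply_exclusions()]); rows flagged `data_sufficient = FALSE` are
#' dropped here. Below `min_days` of usable history the fit is refused
#' rather than extrapolated.
#'
#' @param history window-feature tibble for one activity.
#' @param p_level Chebyshev significance level (default 0.25, k = 2).
#' @param min_days minimum usable fitting days (default 50, the lower end
#'   of the Shapiro-Wilk guidance range).
#' @param window_minutes window length used to cap the upper bound;
#'   default taken from the span of the routine window if `routine` is
#'   given, otherwise `Inf`.
#' @param routine optional single routine row; supplies
#'   `window_minutes` and identification.
#' @return An object of class `"threshold_model"`: a list with `mu`,
#'   `sigma`, `k`, `p_level`, `lower`, `upper`, `n_days`, `normality`,
#'   `apartment_id`, `activity`, `window_minutes`.
#' @seealso [classify_windows()], [coverage()], [tidy.threshold_model()]
#' @export
fit_thresholds <- function(history, p_level = 0.25, min_days = 50,
                           window_minutes = NULL, routine = NULL) {
  k <- chebyshev_k(p_level)
  if (!is.null(routine)) {
    w <- routine_window(routine)
    window_minutes <- window_minutes %||% (w$end - w$start)
  }
  window_minutes <- window_minutes %||% Inf

  usable <- history
  if ("data_sufficient" %in% names(usable)) {
    usable <- usable[usable$data_sufficient, , drop = FALSE]
  }
  d <- usable$duration_minutes
  if (length(d) < min_days) {
    abort(paste0("insufficient history: ", length(d), " usable day(s), need >= ",
                 min_days))
  }
  if (diff(range(d)) == 0) {
    abort("degenerate model: all durations equal (sigma = 0)")
  }
  mu <- mean(d)
  sigma <- sd(d)

  normality <- if (length(d) >= 3 && length(d) <= 2000) {
    shapiro_normality(d)
  } else {
    tibble::tibble(W = NA_real_, p_value = NA_real_,
                   reject_normality = NA, n = length(d))
  }

  structure(
    list(
      apartment_id = if (nrow(usable)) usable$apartment_id[1] else NA_character_,
      activity = if (nrow(usable)) usable$activity[1] else NA_character_,
      mu = mu,
      sigma = sigma,
      k = k,
      p_level = p_level,
      lower = max(0, mu - k * sigma),
      upper = min(window_minutes, mu + k * sigma),
      window_minutes = window_minutes,
      n_days = length(d),
      normality = normality
    ),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Chebyshev threshold model",
      if (!is.na(x$activity)) paste0("for '", x$activity, "'"),
      if (!is.na(x$apartment_id)) paste0("(apartment ", x$apartment_id, ")"),
      "\n")
  cat(sprintf("  fitted on %d days: mu = %.1f min, sigma = %.1f min\n",
              x$n_days, x$mu, x$sigma))
  cat(sprintf("  k = %g (p = %g): normal range [%.1f, %.1f] min\n",
              x$k, x$p_level, x$lower, x$upper))
  if (!is.na(x$normality$W)) {
    cat(sprintf("  Shapiro-Wilk: W = %.3f, p = %.3g (%s normality)\n",
                x$normality$W, x$normality$p_value,
                if (x$normality$reject_normality) "rejects" else "does not reject"))
  }
  invisible(x)
}

#' Tidy a threshold model
#'
#' @param x a `threshold_model`.
#' @param ... unused.
#' @return One-row tibble with the model parameters and bounds.
#' @exportS3Method generics::tidy
tidy.threshold_model <- function(x, ...) {
  tibble::tibble(apartment_id = x$apartment_id, activity = x$activity,
                 mu = x$mu, sigma = x$sigma, k = x$k, p_level = x$p_level,
                 lower = x$lower, upper = x$upper, n_days = x$n_days)
}

#' One-row model summary including the normality diagnostic
#'
#' @param x a `threshold_model`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.threshold_model <- function(x, ...) {
  tibble::tibble(n_days = x$n_days, mu = x$mu, sigma = x$sigma,
                 lower = x$lower, upper = x$upper,
                 shapiro_W = x$normality$W,
                 shapiro_p = x$normality$p_value,
                 reject_normality = x$normality$reject_normality)
}

#' Classify daily windows against a threshold model
#'
#' Four-way classification of each day's activity window:
#' \describe{
#'   \item{`insufficient_data`}{the window lacked sensor coverage; takes
#'     precedence over everything (an outage is not an absence)}
#'   \item{`not_present`}{duration is exactly 0 — the resident never
#'     entered the room during the window}
#'   \item{`short` / `long`}{duration falls below `lower` / above
#'     `upper`}
#'   \item{`normal`}{duration within the closed range
#'     `[lower, upper]` — a boundary value does not alarm}
#' }
#' Exactly one label applies to every row.
#'
#' @param features window-feature tibble.
#' @param model a `threshold_model`.
#' @return `features` with added columns `label` (factor), `lower`,
#'   `upper`, `mu`, `sigma`.
#' @export
classify_windows <- function(features, model) {
  stopifnot(inherits(model, "threshold_model"))
  d <- features$duration_minutes
  suff <- if ("data_sufficient" %in% names(features)) {
    features$data_sufficient
  } else {
    rep(TRUE, length(d))
  }
  label <- dplyr::case_when(
    !suff ~ "insufficient_data",
    d == 0 ~ "not_present",
    d < model$lower ~ "short",
    d > model$upper ~ "long",
    .default = "normal"
  )
  dplyr::mutate(
    features,
    label = factor(label, levels = c("normal", "short", "long",
                                     "not_present", "insufficient_data")),
    lower = model$lower,
    upper = model$upper,
    mu = model$mu,
    sigma = model$sigma
  )
}

#' Empirical coverage of a threshold model
#'
#' Fraction of a history's durations inside the closed normal range.
#' For thresholds fit on the same sample with k = 2 the Chebyshev
#' guarantee makes this at least about 0.75 for any distribution.
#'
#' @param history window-feature tibble (non-empty).
#' @param model a `threshold_model`.
#' @return A fraction in \[0, 1\].
#' @export
coverage <- function(history, model) {
  stopifnot(inherits(model, "threshold_model"))
  d <- history$duration_minutes
  if (length(d) == 0) abort("coverage needs a non-empty history")
  mean(d >= model$lower & d <= model$upper)
}
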