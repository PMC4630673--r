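#' Fit an exponential growth rate to a count-time series
#'
#' Estimates the log-phase population growth rate by least-squares
#' regression of `ln(count)` on time (the closed-form, numerically stable
#' reading of an exponential fit); `method = "nls"` refits
#' `count = N0 * exp(r * t)` by nonlinear least squares, started from the
#' log-linear estimates, for comparison.
#'
#' @param data Data frame with the time and count columns, e.g. from
#'   [gen_growth_series()].
#' @param time,count Column names (tidy-eval) holding times in hours and
#'   strictly positive counts. Defaults `time_h` and `count`.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return A `growth_fit` object with fields `rate` (per hour), `intercept`
#'   (log-count at t = 0), `se_rate`, `n_points`, `r_squared`, `method`.
#' @export
#' @examples
#' d <- tibble::tibble(time_h = 0:2, count = c(1000, 2000, 4000))
#' fit <- fit_growth_rate(d)
#' fit$rate # log(2)
#' glance(fit)
fit_growth_rate <- function(data, time = time_h, count = count,
                            method = c("loglinear", "nls")) {
  method <- match.arg(method)
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ count }})
  if (length(t) < 3) abort("at least 3 time points are required")
  if (any(!is.finite(y)) || any(y <= 0)) abort("all counts must be > 0")
  if (is.unsorted(t, strictly = TRUE)) abort("times must be strictly increasing")
  ll <- lm(log(y) ~ t)
  # summary.lm warns on noiseless data ("essentially perfect fit"); exact
  # series are a supported input here
  sm <- suppressWarnings(summary(ll))
  rate <- unname(coef(ll)[2])
  intercept <- unname(coef(ll)[1])
  se_rate <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  if (method == "nls") {
    nl <- stats::nls(y ~ n0 * exp(r * t),
                     start = list(n0 = exp(intercept), r = rate))
    cf <- summary(nl)$coefficients
    rate <- cf["r", "Estimate"]
    intercept <- log(cf["n0", "Estimate"])
    se_rate <- cf["r", "Std. Error"]
    r2 <- 1 - sum(stats::resid(nl)^2) / sum((y - mean(y))^2)
  }
  structure(
    list(rate = rate, intercept = intercept, se_rate = se_rate,
         n_points = length(t), r_squared = min(max(r2, 0), 1),
         method = method),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> rate %.4f/h (SE %.4f), doubling time %.2f h, n = %d, R^2 = %.4f\n",
              x$rate, x$se_rate, log(2) / x$rate, x$n_points, x$r_squared))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("rate", "intercept"),
    estimate = c(x$rate, x$intercept),
    std.error = c(x$se_rate, NA_real_)
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(rate = x$rate, se_rate = x$se_rate, r.squared = x$r_squared,
         n_points = x$n_points, method = x$method)
}

#' Relative fitness of one strain to another
#'
#' Ratio of two fitted growth rates with its standard error by first-order
#' (delta-method) propagation:
#' `se = ratio * sqrt((se_a/rate_a)^2 + (se_b/rate_b)^2)`.
#'
#' @param fit_a,fit_b `growth_fit` objects (numerator and denominator).
#' @return A one-row tibble with `ratio`, `se`, and the two rates.
#' @export
relative_fitness <- function(fit_a, fit_b) {
  if (fit_b$rate == 0) abort("denominator growth rate is zero")
  ratio <- fit_a$rate / fit_b$rate
  se <- abs(ratio) * sqrt((fit_a$se_rate / fit_a$rate)^2 +
                            (fit_b$se_rate / fit_b$rate)^2)
  tibble(ratio = ratio, se = se, rate_a = fit_a$rate, rate_b = fit_b$rate)
}

#' Fit a log-normal distribution to cell-size samples
#'
#' Gaussian fit on the log scale (`mu` = mean of logs, `sigma` = SD of
#' logs), reported as the quantities the size analysis uses: the mode
#' `exp(mu - sigma^2)` — the peak of the size distribution, taken as the
#' dominant cell size — and the linear-scale standard deviation
#' `sqrt((exp(sigma^2) - 1) * exp(2*mu + sigma^2))`, in the same units as
#' the mode. An optional winsorization quantile caps oversized particles
#' (clumps of unsonicated cells) before fitting; it is off by default.
#'
#' @param samples Numeric vector of positive sizes, or a data frame with a
#'   `size` column.
#' @param winsorize Upper quantile at which to cap samples (e.g. 0.995), or
#'   `NULL` (default) for no capping.
#' @return A `size_fit` object with fields `mu`, `sigma`, `mode`,
#'   `sd_linear`, `n`.
#' @export
#' @examples
#' x <- exp(rnorm(1000, log(50), 0.3))
#' fit_lognormal(x)$mode # near 50 * exp(-0.09)
fit_lognormal <- function(samples, winsorize = NULL) {
  if (is.data.frame(samples)) samples <- samples$size
  if (length(samples) < 10) abort("at least 10 samples are required")
  check_positive(samples, "size samples")
  if (!is.null(winsorize)) {
    cap <- stats::quantile(samples, winsorize, names = FALSE)
    samples <- pmin(samples, cap)
  }
  lx <- log(samples)
  mu <- mean(lx)
  sigma <- sd(lx)
  structure(
    list(
      mu = mu, sigma = sigma,
      mode = exp(mu - sigma^2),
      sd_linear = sqrt((exp(sigma^2) - 1) * exp(2 * mu + sigma^2)),
      n = length(samples)
    ),
    class = "size_fit"
  )
}

#' @export
print.size_fit <- function(x, ...) {
  cat(sprintf("<size_fit> mode %.3f, linear SD %.3f (mu %.4f, sigma %.4f), n = %d\n",
              x$mode, x$sd_linear, x$mu, x$sigma, x$n))
  invisible(x)
}

#' @export
tidy.size_fit <- function(x, ...) {
  tibble(term = c("mu", "sigma", "mode", "sd_linear"),
         estimate = c(x$mu, x$sigma, x$mode, x$sd_linear))
}

#' @export
glance.size_fit <- function(x, ...) {
  tibble(mode = x$mode, sd_linear = x$sd_linear, mu = x$mu, sigma = x$sigma,
         n = x$n)
}
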