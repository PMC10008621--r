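#' Single-arm exponential survival design
#'
#' Sample-size machinery for a single-arm trial with a historical survival
#' control under the exponential assumption: the hazard ratio is the
#' ratio of medians, the required event count follows from the one-sided
#' normal approximation to the log hazard-ratio test, and the expected
#' event fraction accounts for uniform accrual with administrative
#' censoring at the end of follow-up.
#'
#' @param median_control historical-control median survival, months.
#' @param median_experimental alternative median survival, months.
#' @param alpha_one_sided one-sided significance level.
#' @param power target power.
#' @param accrual accrual period, months.
#' @param total maximum follow-up from study start, months
#'   (`accrual <= total`).
#' @return a `design_spec` list.
#' @export
design_spec <- function(median_control = 9.5, median_experimental = 16,
                        alpha_one_sided = 0.05, power = 0.8,
                        accrual = 24, total = 48) {
  if (median_control <= 0 || median_experimental <= 0)
    stop("medians must be positive")
  if (alpha_one_sided <= 0 || alpha_one_sided >= 1 ||
      power <= 0 || power >= 1)
    stop("alpha and power must lie strictly in (0, 1)")
  if (accrual > total) stop("accrual must not exceed total follow-up")
  structure(list(median_control = median_control,
                 median_experimental = median_experimental,
                 alpha_one_sided = alpha_one_sided, power = power,
                 accrual = accrual, total = total),
            class = "design_spec")
}

#' Required number of events
#'
#' `d = ceiling((z_{1-alpha} + z_{power})^2 / log(HR)^2)` with
#' `HR = median_control / median_experimental` — the one-arm
#' (historical-control) event formula, without the factor-4 two-arm
#' multiplier.
#'
#' @param spec a [design_spec()].
#' @return integer event count.
#' @export
required_events <- function(spec) {
  if (spec$median_control == spec$median_experimental)
    stop("medians must differ (log hazard ratio is zero)")
  hr <- spec$median_control / spec$median_experimental
  z <- stats::qnorm(1 - spec$alpha_one_sided) + stats::qnorm(spec$power)
  d <- z^2 / log(hr)^2
  if (d == 0) stop("degenerate design: zero required events")
  as.integer(ceiling(d))
}

#' Probability of observing an event under uniform accrual
#'
#' For exponential survival with the given median, patients enter
#' uniformly over `[0, accrual]` and are administratively censored at
#' `total` months after study start:
#' `P = 1 - (exp(-lambda (total - accrual)) - exp(-lambda total)) /
#' (lambda accrual)` with `lambda = log(2) / median`. The `accrual = 0`
#' limit is `1 - exp(-lambda total)`.
#'
#' @param median exponential median survival, months.
#' @param accrual accrual period, months.
#' @param total maximum follow-up, months (may be `Inf`).
#' @return event probability in [0, 1].
#' @export
event_probability <- function(median, accrual, total) {
  if (median <= 0) stop("median must be positive")
  if (accrual < 0 || accrual > total) stop("need 0 <= accrual <= total")
  lambda <- log(2) / median
  if (is.infinite(total)) return(1)
  if (accrual == 0) return(1 - exp(-lambda * total))
  1 - (exp(-lambda * (total - accrual)) - exp(-lambda * total)) /
    (lambda * accrual)
}

#' Required sample size
#'
#' `n = ceiling(required_events / P(event))`, with the event probability
#' evaluated under the alternative (experimental) hazard — the convention
#' under which the motivating design's 23 events translate into 30
#' patients.
#'
#' @param spec a [design_spec()].
#' @return integer sample size.
#' @export
required_sample_size <- function(spec) {
  d <- required_events(spec)
  p <- event_probability(spec$median_experimental, spec$accrual, spec$total)
  as.integer(ceiling(d / p))
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Single-arm exponential design\n")
  cat(sprintf("  medians %.3g -> %.3g months, one-sided alpha %.3g, power %.3g\n",
              x$median_control, x$median_experimental,
              x$alpha_one_sided, x$power))
  cat(sprintf("  accrual %.3g / total %.3g months\n", x$accrual, x$total))
  d <- required_events(x)
  p <- event_probability(x$median_experimental, x$accrual, x$total)
  cat(sprintf("  required events %d, P(event) %.3f, sample size %d\n",
              d, p, required_sample_size(x)))
  invisible(x)
}

#' One-sided exponential-rate test for a single-arm survival trial
#'
#' Tests H0: hazard = log(2)/median_null against the one-sided
#' alternative of a lower hazard (longer survival), using the asymptotic
#' normality of `log(events / total time at risk)` with variance
#' `1/events`. Used to verify the design by simulation.
#'
#' @param time observed times (months).
#' @param event 0/1 event indicators.
#' @param median_null null-hypothesis median, months.
#' @param alpha one-sided significance level.
#' @return list: `lambda_hat`, `z`, `p`, `reject`.
#' @export
exponential_rate_test <- function(time, event, median_null, alpha = 0.05) {
  d <- sum(event)
  if (d == 0) return(list(lambda_hat = NA_real_, z = NA_real_, p = 1,
                          reject = FALSE))
  lambda_hat <- d / sum(time)
  z <- (log(lambda_hat) - log(log(2) / median_null)) * sqrt(d)
  p <- stats::pnorm(z)
  list(lambda_hat = lambda_hat, z = z, p = p, reject = p <= alpha)
}
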