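#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator with Greenwood variance and log(-log) pointwise
#' confidence bands (computed through the survival package).
#'
#' @param data data.frame with columns `time` (months, > 0) and `event`
#'   (1 = event, 0 = censored).
#' @param conf_level confidence level for the pointwise bands.
#' @return object of class `km_curve`: data.frame of steps (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `greenwood_se`, `lower`,
#'   `upper`) plus the underlying `survfit` in `attr(, "fit")`.
#' @export
km_estimate <- function(data, conf_level = 0.95) {
  if (nrow(data) < 1) stop("need >= 1 record")
  if (any(!is.finite(data$time) | data$time <= 0))
    stop("survival times must be positive and finite")
  if (any(!data$event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                           conf.type = "log-log", conf.int = conf_level)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv,
                      greenwood_se = fit$std.err * fit$surv,
                      lower = fit$lower, upper = fit$upper)
  structure(steps, class = c("km_curve", "data.frame"), fit = fit,
            n = nrow(data), conf_level = conf_level)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", attr(x, "n"), "subjects,",
      sum(x$n_event), "events\n")
  med <- km_median(x)
  cat("  median:", if (is.character(med)) med else
    sprintf("%.2f months", med), "\n")
  invisible(x)
}

#' Survival rate at a milestone time
#'
#' Right-continuous step-function evaluation of the Kaplan-Meier estimate
#' with its log(-log) confidence interval. Times beyond the last follow-up
#' return the last step, flagged via `beyond_followup`.
#'
#' @param curve a `km_curve`.
#' @param t milestone time (months, >= 0).
#' @return list: `estimate`, `lower`, `upper`, `beyond_followup`.
#' @export
survival_rate_at <- function(curve, t) {
  if (t < 0) stop("t must be >= 0")
  idx <- findInterval(t, curve$time)
  if (idx == 0) return(list(estimate = 1, lower = 1, upper = 1,
                            beyond_followup = FALSE))
  beyond <- t > max(curve$time)
  list(estimate = curve$surv[idx], lower = curve$lower[idx],
       upper = curve$upper[idx], beyond_followup = beyond)
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate drops to 0.5 or
#' below; the string `"not reached"` when it never does.
#'
#' @param curve a `km_curve`.
#' @return numeric months, or `"not reached"`.
#' @export
km_median <- function(curve) {
  hit <- which(curve$surv <= 0.5 & curve$n_event > 0)
  if (length(hit) == 0) return("not reached")
  curve$time[min(hit)]
}

#' Median survival with confidence interval
#'
#' Median and its interval by inversion of the log(-log) confidence band
#' (Brookmeyer-Crowley style, as computed by the survival package).
#'
#' @param data data.frame with `time` and `event` columns.
#' @param conf_level confidence level.
#' @return list: `median`, `lower`, `upper` (each numeric or
#'   `"not reached"`).
#' @export
km_median_ci <- function(data, conf_level = 0.95) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  nr <- function(x) if (is.na(x)) "not reached" else unname(x)
  list(median = nr(tab["median"]),
       lower = nr(tab[grep("LCL", names(tab))]),
       upper = nr(tab[grep("UCL", names(tab))]))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric
#' variance, 1 degree of freedom, two-sided p.
#'
#' @param group_a,group_b data.frames with `time` and `event` columns.
#' @return list: `chi2`, `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    stop("both groups must be non-empty")
  if (sum(group_a$event) + sum(group_b$event) == 0) {
    warning("no events in either group; log-rank p set to 1")
    return(list(chi2 = 0, p = 1))
  }
  df <- rbind(data.frame(time = group_a$time, event = group_a$event, g = 0L),
              data.frame(time = group_b$time, event = group_b$event, g = 1L))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards hazard ratio
#'
#' Partial-likelihood fit for one binary covariate (Efron tie handling by
#' default; Breslow available), Wald confidence interval and p-value.
#' Monotone-likelihood situations (a group with no events) are reported
#' as non-estimable rather than fitted.
#'
#' @param data data.frame with `time`, `event` and a binary `group`
#'   column; the hazard ratio is for `group`'s second level (sorted order)
#'   versus the first.
#' @param ties `"efron"` or `"breslow"`.
#' @param conf_level Wald confidence level.
#' @return list: `hr`, `lower`, `upper`, `p`, `coef`, `se`, `estimable`.
#' @export
cox_univariate_hr <- function(data, ties = c("efron", "breslow"),
                              conf_level = 0.95) {
  ties <- match.arg(ties)
  g <- data$group
  lev <- sort(unique(g))
  if (length(lev) != 2)
    stop("group must take exactly two values (got ", length(lev), ")")
  x <- as.integer(g == lev[2])
  ev <- tapply(data$event, x, sum)
  if (any(ev == 0))
    return(list(hr = NA_real_, lower = NA_real_, upper = NA_real_,
                p = NA_real_, coef = NA_real_, se = NA_real_,
                estimable = FALSE))
  fit <- survival::coxph(survival::Surv(time, event) ~ x,
                         data = data.frame(time = data$time,
                                           event = data$event, x = x),
                         ties = ties)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), lower = exp(beta - z * se), upper = exp(beta + z * se),
       p = 2 * stats::pnorm(-abs(beta / se)), coef = beta, se = se,
       estimable = TRUE)
}
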