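#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator \eqn{S(t) = \prod_{t_i \le t}
#' (1 - d_i / n_i)} (events precede censorings at tied times) with
#' Greenwood variance, via [survival::survfit()]. Optionally restricted to
#' one arm and/or weighted (used by the IPW-adjusted analysis).
#'
#' @param records Data.frame with columns `time`, `event` (and `arm` if
#'   `arm` is given).
#' @param arm Optional arm filter (0 or 1).
#' @param weights Optional positive case weights (same length as the
#'   filtered records).
#' @return An object of class `km_fit`: list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `greenwood` (cumulative
#'   \eqn{\sum d/(n(n-d))}), `var_surv`, `n`.
#' @export
km_estimate <- function(records, arm = NULL, weights = NULL) {
  if (!is.null(arm)) {
    keep <- records$arm == arm
    records <- records[keep, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[keep]
  }
  if (!is.data.frame(records) || nrow(records) < 1L) {
    stop("no records to estimate from", call. = FALSE)
  }
  if (any(records$time <= 0)) stop("times must be > 0", call. = FALSE)
  df <- data.frame(time = records$time, event = records$event)
  if (is.null(weights)) weights <- rep(1, nrow(df))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                           weights = weights, conf.type = "none")
  gw <- fit$std.err^2          # survfit std.err is sqrt(sum d/(n(n-d)))
  gw[!is.finite(gw)] <- NA_real_
  structure(
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv,
         greenwood = gw, var_surv = fit$surv^2 * gw, n = nrow(df)),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, events = %g, last time = %g days, S(last) = %.3f\n",
              x$n, sum(x$n_event), max(x$time), min(x$surv)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier fit at given days
#'
#' Right-continuous step lookup: `S(day)` is the estimate just after the
#' last event time at or before `day`; days before the first observed time
#' give 1. Days beyond the last observed time return the last value and are
#' flagged in the `extrapolated` attribute.
#'
#' @param sf A `km_fit`.
#' @param day Numeric vector of days, all >= 0.
#' @return Numeric vector of survival fractions with a logical attribute
#'   `extrapolated`.
#' @export
survival_at <- function(sf, day) {
  stopifnot(inherits(sf, "km_fit"))
  if (any(day < 0)) stop("day must be >= 0", call. = FALSE)
  idx <- findInterval(day, sf$time)
  s <- c(1, sf$surv)[idx + 1L]
  structure(s, extrapolated = day > max(sf$time))
}

#' Kaplan-Meier fit as a per-day survival series
#'
#' @param sf A `km_fit`.
#' @param horizon_day Last day of the grid.
#' @return A [daily_series()]; days beyond the last observed time are
#'   flagged `extrapolated`.
#' @export
km_daily_series <- function(sf, horizon_day) {
  day <- 0:horizon_day
  s <- survival_at(sf, day)
  daily_series(day, as.numeric(s),
               ifelse(attr(s, "extrapolated"), "extrapolated", "observed"))
}

#' Two-sample log-rank test
#'
#' Standard two-sample log-rank chi-square (1 df) comparing the arms, via
#' [survival::survdiff()].
#'
#' @param records Data.frame with `time`, `event`, `arm` (both arms
#'   present, at least one event).
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank <- function(records) {
  assert_records(records, require_two_arms = TRUE)
  if (sum(records$event) < 1) stop("at least one event required", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = records)
  list(statistic = unname(sd$chisq), df = 1L,
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Piecewise hazard-ratio constancy diagnostic
#'
#' Splits follow-up at `cut_days`, tabulates events and person-time by arm
#' and period, and tests whether a single hazard ratio fits all periods: a
#' likelihood-ratio test between Poisson person-time models with one rate
#' ratio per period (full) versus a common rate ratio (null), on
#' `K - 1` degrees of freedom. A non-constant ratio over time is the
#' proportional-hazards violation that motivates risk-curve and RMST
#' analyses.
#'
#' Periods in which either arm contributes zero person-time are flagged,
#' excluded, and the degrees of freedom reduced accordingly.
#'
#' @param records Data.frame with `time`, `event`, `arm`.
#' @param cut_days Strictly ascending interior cut points (days).
#' @return An object of class `ph_diagnostic`: list with `table` (per
#'   period and arm: events, person-time, and the period hazard ratio),
#'   `statistic`, `df`, `p`, `excluded_periods`.
#' @export
ph_constancy_test <- function(records, cut_days) {
  assert_records(records, require_two_arms = TRUE)
  if (length(cut_days) < 1L || is.unsorted(cut_days, strictly = TRUE) ||
      any(cut_days <= 0)) {
    stop("cut_days must be strictly ascending positive days", call. = FALSE)
  }
  if (max(cut_days) >= max(records$time)) {
    stop("cut_days must lie within observed follow-up", call. = FALSE)
  }
  breaks <- c(0, cut_days, Inf)
  K <- length(breaks) - 1L
  tab <- expand.grid(period = seq_len(K), arm = c(0, 1))
  tab$start <- breaks[tab$period]
  tab$end <- breaks[tab$period + 1L]
  tab$events <- 0
  tab$person_time <- 0
  for (r in seq_len(nrow(tab))) {
    sel <- records$arm == tab$arm[r]
    tt <- records$time[sel]
    ev <- records$event[sel]
    at <- pmax(0, pmin(tt, tab$end[r]) - tab$start[r])
    tab$person_time[r] <- sum(at)
    tab$events[r] <- sum(ev == 1 & tt > tab$start[r] & tt <= tab$end[r])
  }
  pt0 <- tab$person_time[tab$arm == 0]
  pt1 <- tab$person_time[tab$arm == 1]
  ok <- pt0 > 0 & pt1 > 0
  excluded <- which(!ok)
  hr <- rep(NA_real_, K)
  d0 <- tab$events[tab$arm == 0]; d1 <- tab$events[tab$arm == 1]
  hr[ok] <- (d1[ok] / pt1[ok]) / (d0[ok] / pt0[ok])
  use <- tab[tab$period %in% which(ok), , drop = FALSE]
  K_used <- sum(ok)
  if (K_used < 2L) {
    stop("fewer than two usable periods; widen cut_days", call. = FALSE)
  }
  use$period <- factor(use$period)
  full <- glm(events ~ period + period:arm, offset = log(person_time),
              family = poisson(), data = use)
  null <- glm(events ~ period + arm, offset = log(person_time),
              family = poisson(), data = use)
  stat <- max(0, null$deviance - full$deviance)
  df <- K_used - 1L
  per <- data.frame(period = seq_len(K), start = breaks[seq_len(K)],
                    end = breaks[-1],
                    events_control = d0, events_treated = d1,
                    pt_control = pt0, pt_treated = pt1, hr = hr)
  structure(list(table = per, cut_days = cut_days, statistic = stat, df = df,
                 p = pchisq(stat, df = df, lower.tail = FALSE),
                 excluded_periods = excluded),
            class = "ph_diagnostic")
}

#' @export
print.ph_diagnostic <- function(x, ...) {
  cat("Piecewise hazard-ratio constancy diagnostic\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("LR statistic = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p))
  if (length(x$excluded_periods)) {
    cat("excluded periods (zero person-time in an arm):",
        paste(x$excluded_periods, collapse = ", "), "\n")
  }
  invisible(x)
}
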