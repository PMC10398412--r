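#' Windowed progression risk from a per-day survival series
#'
#' The progression risk at day `t` is the decrease of the survival curve
#' over the following `window_days` days: `risk(t) = S(t) - S(t + w)`
#' (absolute mode, the default). Conditional mode divides by `S(t)` — the
#' risk among subjects still progression-free at `t` — and is missing where
#' `S(t) = 0`. Days whose window extends past the series horizon are
#' missing.
#'
#' @param series A [daily_series()].
#' @param window_days Window length in days (default 30).
#' @param mode `"absolute"` or `"conditional"`.
#' @return A data.frame of class `risk_curve` with columns `day`, `risk`,
#'   `missing`; attributes `window_days` and `mode`.
#' @export
progression_risk <- function(series, window_days = 30,
                             mode = c("absolute", "conditional")) {
  stopifnot(inherits(series, "daily_series"))
  mode <- match.arg(mode)
  window_days <- as.integer(window_days)
  if (window_days <= 0) stop("window_days must be > 0", call. = FALSE)
  n <- nrow(series)
  if (n - 1L < window_days) {
    stop("series horizon must be at least the window length", call. = FALSE)
  }
  day <- series$day
  if (any(diff(day) != 1L)) stop("series must be on a consecutive daily grid",
                                 call. = FALSE)
  risk <- rep(NA_real_, n)
  i <- seq_len(n - window_days)
  risk[i] <- series$S[i] - series$S[i + window_days]
  if (mode == "conditional") {
    denom <- series$S[i]
    risk[i] <- ifelse(denom > 0, risk[i] / denom, NA_real_)
  }
  out <- data.frame(day = day, risk = risk, missing = is.na(risk))
  attr(out, "window_days") <- window_days
  attr(out, "mode") <- mode
  attr(out, "smoothed") <- FALSE
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' Between-arm relative risk curve
#'
#' `RR(t)` is the ratio of the treated arm's windowed progression risk to
#' the control arm's at each day. Where either risk is 0, the relative risk
#' is incalculable and flagged missing with a reason code:
#' `zero-denominator` (control risk 0), `zero-numerator-rule` (treated risk
#' 0), or `out-of-range` (either input already missing).
#'
#' @param risk_treat,risk_ctrl `risk_curve`s on the same grid, window and
#'   mode.
#' @return A data.frame of class `relative_risk_curve` with columns `day`,
#'   `rr`, `missing`, `reason`.
#' @export
relative_risk <- function(risk_treat, risk_ctrl) {
  stopifnot(inherits(risk_treat, "risk_curve"), inherits(risk_ctrl, "risk_curve"))
  if (!identical(risk_treat$day, risk_ctrl$day)) {
    stop("risk curves are on different day grids", call. = FALSE)
  }
  if (!identical(attr(risk_treat, "mode"), attr(risk_ctrl, "mode")) ||
      !identical(attr(risk_treat, "window_days"), attr(risk_ctrl, "window_days"))) {
    stop("risk curves must share window length and mode", call. = FALSE)
  }
  rt <- risk_treat$risk
  rc <- risk_ctrl$risk
  reason <- rep(NA_character_, length(rt))
  reason[is.na(rt) | is.na(rc)] <- "out-of-range"
  reason[is.na(reason) & rc == 0] <- "zero-denominator"
  reason[is.na(reason) & rt == 0] <- "zero-numerator-rule"
  rr <- ifelse(is.na(reason), rt / rc, NA_real_)
  out <- data.frame(day = risk_treat$day, rr = rr, missing = is.na(rr),
                    reason = reason)
  attr(out, "window_days") <- attr(risk_treat, "window_days")
  attr(out, "smoothed") <- FALSE
  class(out) <- c("relative_risk_curve", "data.frame")
  out
}

moving_average <- function(day, value, halfwidth) {
  n <- length(value)
  obs <- !is.na(value)
  cs_v <- cumsum(ifelse(obs, value, 0))
  cs_n <- cumsum(obs)
  lo <- pmax(seq_len(n) - halfwidth, 1L)
  hi <- pmin(seq_len(n) + halfwidth, n)
  sum_v <- cs_v[hi] - c(0, cs_v)[lo]
  cnt <- cs_n[hi] - c(0L, cs_n)[lo]
  ifelse(cnt > 0, sum_v / cnt, NA_real_)
}

#' Moving-average smoothing of a risk or relative-risk curve
#'
#' Simple centered moving average over the `halfwidth_days` days before and
#' after each day (a 121-day window at the default 60), truncated at the
#' grid edges. Missing days are excluded from the mean rather than
#' propagated, so isolated incalculable days do not erase the curve; a day
#' whose whole window is missing stays missing.
#'
#' @param curve A `risk_curve` or `relative_risk_curve`.
#' @param halfwidth_days Half-width of the smoothing window in days
#'   (default 60; 0 returns the input values unchanged).
#' @return A curve of the same class with smoothed values and updated
#'   missing flags; attribute `smoothed = TRUE`.
#' @export
smooth_curve <- function(curve, halfwidth_days = 60) {
  if (halfwidth_days < 0) stop("halfwidth_days must be >= 0", call. = FALSE)
  halfwidth_days <- as.integer(halfwidth_days)
  if (inherits(curve, "risk_curve")) {
    val <- moving_average(curve$day, curve$risk, halfwidth_days)
    out <- curve
    out$risk <- val
    out$missing <- is.na(val)
  } else if (inherits(curve, "relative_risk_curve")) {
    val <- moving_average(curve$day, curve$rr, halfwidth_days)
    out <- curve
    out$rr <- val
    newly_filled <- is.na(curve$rr) & !is.na(val)
    out$missing <- is.na(val)
    out$reason[newly_filled] <- NA_character_
    out$reason[is.na(val) & is.na(out$reason)] <- "smoothing-window-empty"
    out$reason[!is.na(val)] <- NA_character_
  } else {
    stop("curve must be a risk_curve or relative_risk_curve", call. = FALSE)
  }
  attr(out, "smoothed") <- TRUE
  attr(out, "halfwidth_days") <- halfwidth_days
  out
}

#' Detect post-discontinuation rebound in a smoothed relative-risk curve
#'
#' Rebound is a sustained excess of treated-arm progression risk after the
#' scheduled treatment stop: the report gives the first day at or after
#' `discontinuation_day` from which the smoothed relative risk exceeds 1 on
#' at least `run_days` consecutive non-missing days, together with the
#' post-discontinuation peak and the pre-discontinuation minimum of the
#' curve. The run-length requirement suppresses single-day noise crossings.
#'
#' @param rr A (smoothed) `relative_risk_curve`.
#' @param discontinuation_day Scheduled treatment-stop day; must lie on the
#'   curve's day grid.
#' @param run_days Minimum run of consecutive days with RR > 1 (default 30).
#' @return An object of class `rebound_report`: list with `rebound`
#'   (TRUE/FALSE, or NA when the post-discontinuation segment is entirely
#'   missing), `onset_day`, `peak_rr`, `peak_day`, `pre_min_rr`,
#'   `pre_min_day`, `discontinuation_day`, `run_days`.
#' @export
detect_rebound <- function(rr, discontinuation_day, run_days = 30) {
  stopifnot(inherits(rr, "relative_risk_curve"))
  if (!(discontinuation_day %in% rr$day)) {
    stop("discontinuation_day must lie on the curve's day grid", call. = FALSE)
  }
  if (run_days < 1) stop("run_days must be >= 1", call. = FALSE)
  post <- rr[rr$day >= discontinuation_day, , drop = FALSE]
  pre <- rr[rr$day < discontinuation_day, , drop = FALSE]
  pre_min_rr <- pre_min_day <- NA_real_
  if (any(!pre$missing)) {
    i <- which.min(ifelse(pre$missing, Inf, pre$rr))
    pre_min_rr <- pre$rr[i]; pre_min_day <- pre$day[i]
  }
  if (all(post$missing)) {
    res <- list(rebound = NA, onset_day = NA_real_,
                peak_rr = NA_real_, peak_day = NA_real_)
  } else {
    j <- which.max(ifelse(post$missing, -Inf, post$rr))
    exceeds <- !post$missing & post$rr > 1
    r <- rle(exceeds)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= run_days)
    if (length(hit)) {
      res <- list(rebound = TRUE, onset_day = post$day[starts[hit[1]]],
                  peak_rr = post$rr[j], peak_day = post$day[j])
    } else {
      res <- list(rebound = FALSE, onset_day = NA_real_,
                  peak_rr = post$rr[j], peak_day = post$day[j])
    }
  }
  structure(c(res, list(pre_min_rr = pre_min_rr, pre_min_day = pre_min_day,
                        discontinuation_day = discontinuation_day,
                        run_days = run_days)),
            class = "rebound_report")
}

#' @export
print.rebound_report <- function(x, ...) {
  cat(sprintf("Rebound detection (discontinuation day %g, run length %d days)\n",
              x$discontinuation_day, x$run_days))
  if (is.na(x$rebound)) {
    cat("  indeterminate: no evaluable post-discontinuation relative risk\n")
  } else if (x$rebound) {
    cat(sprintf("  rebound detected: smoothed RR > 1 sustained from day %g\n",
                x$onset_day))
    cat(sprintf("  post-discontinuation peak RR %.3f at day %g\n",
                x$peak_rr, x$peak_day))
  } else {
    cat("  no rebound: smoothed RR never exceeded 1 for the required run\n")
  }
  if (!is.na(x$pre_min_rr)) {
    cat(sprintf("  pre-discontinuation minimum RR %.3f at day %g\n",
                x$pre_min_rr, x$pre_min_day))
  }
  invisible(x)
}

#' Plot a relative-risk curve
#'
#' Draws the smoothed relative-risk curve with the treatment-administration
#' period shaded and the RR = 1 reference line, mirroring the standard
#' presentation of time-varying risk-ratio panels.
#'
#' @param x A `relative_risk_curve`.
#' @param shade_to Right edge (day) of the shaded administration period;
#'   `NULL` for no shading.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.relative_risk_curve <- function(x, shade_to = NULL, ...) {
  ok <- !x$missing
  graphics::plot(x$day[ok], x$rr[ok], type = "n",
                 xlab = "Days since randomization", ylab = "Relative risk", ...)
  if (!is.null(shade_to)) {
    usr <- graphics::par("usr")
    graphics::rect(0, usr[3], shade_to, usr[4],
                   col = grDevices::adjustcolor("grey70", 0.4), border = NA)
  }
  graphics::abline(h = 1, lty = 2)
  graphics::lines(x$day[ok], x$rr[ok])
  invisible(x)
}

#' Plot a progression-risk curve
#'
#' @param x A `risk_curve`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.risk_curve <- function(x, ...) {
  ok <- !x$missing
  graphics::plot(x$day[ok], x$risk[ok], type = "l",
                 xlab = "Days since randomization",
                 ylab = sprintf("%d-day progression risk", attr(x, "window_days")),
                 ...)
  invisible(x)
}
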