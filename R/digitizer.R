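#' Calibrate a digitized curve's pixel axes
#'
#' Builds the affine pixel-to-value maps from the calibration points: the x
#' map uses the pixel columns of time 0 and the 12- or 24-month anchor
#' (months converted at 365/12 days), the y map the pixel rows of survival
#' 0% and 100%.
#'
#' @param curve A [digitized_curve()].
#' @return A list with functions `px_to_day(px)` and `py_to_S(py)` and the
#'   scale attributes `day_per_px` and `S_per_px`.
#' @export
calibrate <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  ax <- curve$axis
  if (ax$x0_px == ax$x1_px || ax$y0_px == ax$y100_px) {
    stop("calibration pixels coincide", call. = FALSE)
  }
  anchor_day <- ax$x1_month * days_per_month()
  day_per_px <- anchor_day / (ax$x1_px - ax$x0_px)
  S_per_px <- 1 / (ax$y100_px - ax$y0_px)
  list(
    px_to_day = function(px) (px - ax$x0_px) * day_per_px,
    py_to_S = function(py) (py - ax$y0_px) * S_per_px,
    day_per_px = day_per_px,
    S_per_px = S_per_px
  )
}

#' Convert a digitized curve to a calibrated per-day survival series
#'
#' Maps the pixel polyline through the axis calibration and evaluates
#' survival on an integer day grid. Between consecutive polyline points that
#' are close in x (within `gap_px` pixel columns) the survival step
#' convention applies (previous value carried forward, flagged `observed`);
#' across wider pixel gaps — trace interruptions — days are filled by linear
#' interpolation and flagged `interpolated`; days beyond the last point
#' carry the last value and are flagged `extrapolated`. Pixel jitter that
#' makes survival rise is repaired by a running minimum, so the output is
#' always a valid non-increasing series.
#'
#' If the first calibrated point lies within 2% of survival 1, the series is
#' anchored at S(0) = 1; otherwise a warning is issued and the curve is used
#' as traced.
#'
#' @param curve A [digitized_curve()].
#' @param horizon_day Last day of the output grid (defaults to the last
#'   polyline day, floored).
#' @param gap_px Pixel-column separation beyond which a trace interruption
#'   is assumed (default 2).
#' @return A [daily_series()] with per-day provenance flags.
#' @export
to_daily_series <- function(curve, horizon_day = NULL, gap_px = 2) {
  cal <- calibrate(curve)
  t <- cal$px_to_day(curve$polyline$px)
  s <- cal$py_to_S(curve$polyline$py)
  inside <- s > -0.1 & s < 1.1 & t > -0.5
  if (!any(inside)) {
    stop("digitized curve lies entirely outside the plot box", call. = FALSE)
  }
  t <- t[inside]; s <- pmin(pmax(s[inside], 0), 1)
  px <- curve$polyline$px[inside]
  o <- order(t)
  t <- t[o]; s <- s[o]; px <- px[o]
  if (abs(s[1] - 1) <= 0.02) {
    if (t[1] > 0) { t <- c(0, t); s <- c(1, s); px <- c(NA, px) }
    s[which(t == 0)] <- 1
  } else {
    warning("first digitized point is more than 2% below survival 1; ",
            "S(0) not forced to 1", call. = FALSE)
  }
  horizon_day <- horizon_day %||% floor(max(t))
  day <- 0:horizon_day
  # previous-point index for each grid day
  idx <- findInterval(day + 1e-9, t)
  S <- numeric(length(day))
  prov <- character(length(day))
  gap_after <- c(diff(px) > gap_px + 0.5, FALSE)
  gap_after[is.na(gap_after)] <- FALSE
  for (k in seq_along(day)) {
    i <- idx[k]
    if (i < 1L) {            # before the first point (first point above 0)
      S[k] <- s[1]; prov[k] <- "interpolated"
    } else if (i >= length(t)) {
      S[k] <- s[length(t)]
      prov[k] <- if (day[k] > max(t) + 1e-9) "extrapolated" else "observed"
    } else if (gap_after[i] && day[k] > t[i] + 1e-9) {
      # inside a trace gap: linear fill between the flanking points
      w <- (day[k] - t[i]) / (t[i + 1] - t[i])
      S[k] <- (1 - w) * s[i] + w * s[i + 1]
      prov[k] <- "interpolated"
    } else {
      S[k] <- s[i]; prov[k] <- "observed"
    }
  }
  S <- cummin(pmin(pmax(S, 0), 1))  # monotonicity repair of jitter
  daily_series(day, S, prov)
}
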