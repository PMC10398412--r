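#' Axis calibration specification for a rendered survival figure
#'
#' Pixel positions of the reference points used to calibrate a digitized
#' Kaplan-Meier figure: time 0 and a 12- or 24-month anchor on the x axis,
#' and the 0% and 100% survival gridlines on the y axis. Pixel rows grow
#' downward, as in image coordinates.
#'
#' @param x0_px Pixel column of time 0.
#' @param x1_px Pixel column of the month anchor.
#' @param x1_month Month value at `x1_px` (12 or 24 conventionally).
#' @param y0_px Pixel row of survival 0%.
#' @param y100_px Pixel row of survival 100%.
#' @return An object of class `axis_spec`.
#' @export
axis_spec <- function(x0_px = 100, x1_px = 500, x1_month = 12,
                      y0_px = 650, y100_px = 50) {
  if (x0_px == x1_px) stop("x-axis calibration pixels coincide", call. = FALSE)
  if (y0_px == y100_px) stop("y-axis calibration pixels coincide", call. = FALSE)
  if (x1_month <= 0) stop("x1_month must be > 0", call. = FALSE)
  structure(list(x0_px = x0_px, x1_px = x1_px, x1_month = x1_month,
                 y0_px = y0_px, y100_px = y100_px),
            class = "axis_spec")
}

#' Digitized survival curve
#'
#' A pixel polyline extracted from a published Kaplan-Meier figure together
#' with the axis calibration points, as produced by coordinate-extraction
#' software or by [rasterize_km()].
#'
#' @param polyline Data.frame with columns `px`, `py` (>= 2 points).
#' @param axis An [axis_spec()].
#' @param label Source label.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(polyline, axis, label = "") {
  stopifnot(inherits(axis, "axis_spec"))
  polyline <- as.data.frame(polyline)
  if (!all(c("px", "py") %in% names(polyline)) || nrow(polyline) < 2L) {
    stop("polyline must have columns px, py and at least 2 points",
         call. = FALSE)
  }
  structure(list(polyline = polyline[order(polyline$px), , drop = FALSE],
                 axis = axis, label = label),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized curve '%s': %d pixel points, x anchor %g months\n",
              x$label, nrow(x$polyline), x$axis$x1_month))
  invisible(x)
}

#' Rasterize per-day survival series into digitized-curve fixtures
#'
#' Renders daily survival series as pixel polylines under an axis
#' calibration, one point per pixel column, with optional uniform vertical
#' jitter (emulating tracing error) and deleted day spans (emulating curve
#' segments hidden by overplotting that a human tracer would have to fill
#' in). The output feeds [to_daily_series()] for round-trip validation of
#' the image-based pipeline.
#'
#' @param series_by_arm Named list of [daily_series()] objects.
#' @param axis An [axis_spec()].
#' @param jitter_px Half-width of uniform pixel jitter added to each y pixel
#'   before rounding (0 for exact rasterization).
#' @param gap_spans Optional list of `c(from_day, to_day)` spans whose
#'   samples are deleted from every curve.
#' @param seed Seed for the jitter draw (required when `jitter_px > 0`).
#' @return A named list of [digitized_curve()] objects.
#' @export
rasterize_km <- function(series_by_arm, axis = axis_spec(), jitter_px = 0,
                         gap_spans = NULL, seed = 1) {
  stopifnot(inherits(axis, "axis_spec"), is.list(series_by_arm))
  day_per_px <- axis$x1_month * days_per_month() / (axis$x1_px - axis$x0_px)
  with_seed(seed, {
    lapply(setNames(names(series_by_arm), names(series_by_arm)), function(nm) {
      ser <- series_by_arm[[nm]]
      stopifnot(inherits(ser, "daily_series"))
      px_lo <- axis$x0_px
      px_hi <- axis$x0_px + round(max(ser$day) / day_per_px)
      px <- seq(px_lo, px_hi)
      day_at <- (px - axis$x0_px) * day_per_px
      # step lookup: value at the last grid day <= day_at
      idx <- findInterval(day_at + 1e-9, ser$day)
      idx[idx < 1L] <- 1L
      s <- ser$S[idx]
      py <- axis$y0_px + s * (axis$y100_px - axis$y0_px)
      if (jitter_px > 0) py <- py + runif(length(py), -jitter_px, jitter_px)
      py <- round(py)
      keep <- rep(TRUE, length(px))
      for (g in gap_spans %||% list()) {
        keep <- keep & !(day_at >= g[1] & day_at <= g[2])
      }
      digitized_curve(data.frame(px = px[keep], py = py[keep]), axis, label = nm)
    })
  })
}
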