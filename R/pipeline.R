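#' Analysis configuration
#'
#' Bundles every tunable setting of the two workflows: `ipd` (patient-level
#' records through Kaplan-Meier) and `digitized` (calibrated pixel
#' polylines). Defaults follow the package's standard analysis: 30-day risk
#' window, absolute risk mode, 60-day smoothing half-width, discontinuation
#' (landmark) at day 365.
#'
#' @param workflow `"ipd"` or `"digitized"`.
#' @param window_days Risk window in days.
#' @param smooth_halfwidth_days Moving-average half-width in days.
#' @param risk_mode `"absolute"` or `"conditional"`.
#' @param discontinuation_day Scheduled treatment-stop day.
#' @param tau RMST horizon (NULL = shorter arm's largest observed time).
#' @param landmark Landmark day for the before/after RMST split (NULL =
#'   `discontinuation_day`).
#' @param covariates Covariate names for IPW adjustment (NULL = none).
#' @param boot Bootstrap resamples for adjusted comparisons.
#' @param seed Integer seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(workflow = c("ipd", "digitized"),
                            window_days = 30, smooth_halfwidth_days = 60,
                            risk_mode = c("absolute", "conditional"),
                            discontinuation_day = 365, tau = NULL,
                            landmark = NULL, covariates = NULL,
                            boot = 1000, seed = 1) {
  workflow <- match.arg(workflow)
  risk_mode <- match.arg(risk_mode)
  if (window_days <= 0 || smooth_halfwidth_days < 0) {
    stop("windows must be positive", call. = FALSE)
  }
  structure(list(workflow = workflow, window_days = window_days,
                 smooth_halfwidth_days = smooth_halfwidth_days,
                 risk_mode = risk_mode,
                 discontinuation_day = discontinuation_day, tau = tau,
                 landmark = landmark %||% discontinuation_day,
                 covariates = covariates, boot = boot, seed = seed),
            class = "analysis_config")
}

risk_rr_stage <- function(series_treat, series_ctrl, config) {
  risk1 <- progression_risk(series_treat, config$window_days, config$risk_mode)
  risk0 <- progression_risk(series_ctrl, config$window_days, config$risk_mode)
  rr <- relative_risk(risk1, risk0)
  rr_s <- smooth_curve(rr, config$smooth_halfwidth_days)
  rebound <- if (config$discontinuation_day %in% rr_s$day &&
                 config$discontinuation_day <= max(rr_s$day[!rr_s$missing], -Inf)) {
    detect_rebound(rr_s, config$discontinuation_day)
  } else {
    NULL
  }
  list(risk_treated = risk1, risk_control = risk0,
       risk_treated_smooth = smooth_curve(risk1, config$smooth_halfwidth_days),
       risk_control_smooth = smooth_curve(risk0, config$smooth_halfwidth_days),
       relative_risk = rr, relative_risk_smooth = rr_s, rebound = rebound)
}

#' Run the full analysis pipeline
#'
#' Executes one of the two workflows end to end. The `ipd` workflow fits
#' per-arm Kaplan-Meier curves, evaluates them on a daily grid over the
#' jointly observed horizon, computes windowed risk / relative-risk /
#' smoothed curves and rebound detection, and compares arms by RMST for the
#' overall window and before/after the landmark (IPW-adjusted when
#' covariates are configured). The `digitized` workflow starts from
#' calibrated pixel polylines and runs the curve-level stages (no
#' patient-level inference is possible from digitized curves).
#'
#' @param config An [analysis_config()].
#' @param records Patient-level records (for `workflow = "ipd"`).
#' @param curves Named list with elements `treated` and `control` of
#'   [digitized_curve()] objects (for `workflow = "digitized"`).
#' @param out_dir Optional directory; when given, CSV/JSON outputs and a
#'   run log (with the configuration and its MD5 hash) are written.
#' @return A list of class `kmrisk_analysis` with the curves, rebound
#'   report and (ipd only) RMST results.
#' @export
run_pipeline <- function(config, records = NULL, curves = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  out <- list(config = config)
  if (config$workflow == "ipd") {
    if (is.null(records)) stop("ipd workflow needs `records`", call. = FALSE)
    assert_records(records, require_two_arms = TRUE)
    for (cv in config$covariates %||% character()) {
      if (!cv %in% names(records)) {
        stop("unknown covariate '", cv, "' in records", call. = FALSE)
      }
    }
    fit0 <- km_estimate(records, arm = 0)
    fit1 <- km_estimate(records, arm = 1)
    horizon <- floor(min(max(fit0$time), max(fit1$time)))
    s1 <- km_daily_series(fit1, horizon)
    s0 <- km_daily_series(fit0, horizon)
    out <- c(out, list(km_treated = fit1, km_control = fit0,
                       series_treated = s1, series_control = s0))
    out <- c(out, risk_rr_stage(s1, s0, config))
    tau <- config$tau %||% min(max(fit0$time), max(fit1$time))
    L <- config$landmark
    out$logrank <- logrank(records)
    out$rmst_overall <- rmst_compare(records, tau = tau, boot = config$boot,
                                     seed = config$seed)
    if (L > 0 && L < tau) {
      sp <- landmark_split(records, L)
      out$rmst_pre <- rmst_compare(sp$pre, tau = L, boot = config$boot,
                                   seed = config$seed + 1L)
      post_tau <- min(tapply(sp$post$time, sp$post$arm, max))
      out$rmst_post <- rmst_compare(sp$post, tau = post_tau,
                                    boot = config$boot,
                                    seed = config$seed + 2L)
    }
    if (length(config$covariates)) {
      ipw <- fit_ipw(records, config$covariates)
      out$ipw <- ipw
      out$rmst_adjusted <- adjusted_rmst_compare(records, ipw, tau = tau,
                                                 boot = config$boot,
                                                 seed = config$seed + 3L)
    }
  } else {
    if (is.null(curves) || !all(c("treated", "control") %in% names(curves))) {
      stop("digitized workflow needs `curves$treated` and `curves$control`",
           call. = FALSE)
    }
    s1 <- to_daily_series(curves$treated)
    s0 <- to_daily_series(curves$control)
    horizon <- min(max(s1$day), max(s0$day))
    s1 <- daily_series(s1$day[s1$day <= horizon], s1$S[s1$day <= horizon],
                       s1$provenance[s1$day <= horizon])
    s0 <- daily_series(s0$day[s0$day <= horizon], s0$S[s0$day <= horizon],
                       s0$provenance[s0$day <= horizon])
    out <- c(out, list(series_treated = s1, series_control = s0))
    out <- c(out, risk_rr_stage(s1, s0, config))
  }
  class(out) <- "kmrisk_analysis"
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.kmrisk_analysis <- function(x, ...) {
  cat(sprintf("kmrisk analysis (%s workflow)\n", x$config$workflow))
  if (!is.null(x$rebound)) print(x$rebound)
  for (nm in c("rmst_overall", "rmst_pre", "rmst_post", "rmst_adjusted")) {
    if (!is.null(x[[nm]])) {
      cat("--", sub("rmst_", "RMST ", nm), "--\n")
      print(x[[nm]])
    }
  }
  invisible(x)
}

config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                   digits = NA)
}

write_analysis <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(config_json(x$config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  wr <- function(df, name) {
    df$config_md5 <- cfg_hash
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(as.data.frame(x$risk_treated), "risk_treated.csv")
  wr(as.data.frame(x$risk_control), "risk_control.csv")
  wr(as.data.frame(x$relative_risk_smooth), "relative_risk_smooth.csv")
  rows <- list()
  for (nm in c("rmst_overall", "rmst_pre", "rmst_post", "rmst_adjusted")) {
    r <- x[[nm]]
    if (is.null(r)) next
    rows[[nm]] <- data.frame(
      comparison = nm, weighting = r$weighting, lower = r$lower, tau = r$tau,
      rmst_control = r$arms$rmst[r$arms$arm == 0],
      rmst_treated = r$arms$rmst[r$arms$arm == 1],
      ratio = r$ratio, ratio_lo = r$ratio_ci[1], ratio_hi = r$ratio_ci[2],
      ratio_p = r$ratio_p, difference = r$difference,
      difference_lo = r$difference_ci[1], difference_hi = r$difference_ci[2],
      difference_p = r$difference_p
    )
  }
  if (length(rows)) wr(do.call(rbind, rows), "rmst.csv")
  if (!is.null(x$rebound)) {
    writeLines(jsonlite::toJSON(
      c(unclass(x$rebound), list(config_md5 = cfg_hash)),
      auto_unbox = TRUE, null = "null", na = "null", digits = NA
    ), file.path(out_dir, "rebound.json"))
  }
  invisible(out_dir)
}

#' Read and write patient-level records
#'
#' CSV with header `id,time,event,arm` plus one column per covariate.
#'
#' @param records Data.frame of records.
#' @param path File path.
#' @return `read_records` returns the records data.frame;
#'   `write_records` invisibly returns `path`.
#' @export
write_records <- function(records, path) {
  assert_records(records)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  assert_records(rec)
  rec
}

#' Read and write digitized curves
#'
#' The polyline is stored as a `px,py` CSV; the axis calibration goes in a
#' JSON sidecar (same path with extension `.json`).
#'
#' @param curve A [digitized_curve()].
#' @param path CSV file path.
#' @return `read_digitized_curve` returns the curve;
#'   `write_digitized_curve` invisibly returns `path`.
#' @export
write_digitized_curve <- function(curve, path) {
  stopifnot(inherits(curve, "digitized_curve"))
  write.csv(curve$polyline, path, row.names = FALSE)
  side <- sub("\\.[^.]*$", ".json", path)
  writeLines(jsonlite::toJSON(c(unclass(curve$axis), list(label = curve$label)),
                              auto_unbox = TRUE, digits = NA), side)
  invisible(path)
}

#' @rdname write_digitized_curve
#' @export
read_digitized_curve <- function(path) {
  poly <- read.csv(path)
  side <- jsonlite::fromJSON(sub("\\.[^.]*$", ".json", path))
  ax <- axis_spec(x0_px = side$x0_px, x1_px = side$x1_px,
                  x1_month = side$x1_month, y0_px = side$y0_px,
                  y100_px = side$y100_px)
  digitized_curve(poly, ax, label = side$label %||% "")
}

#' Write a per-day survival series
#'
#' CSV with columns `day,S,provenance`.
#'
#' @param series A [daily_series()].
#' @param path File path.
#' @return `read_daily_series` returns the series; `write_daily_series`
#'   invisibly returns `path`.
#' @export
write_daily_series <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_series
#' @export
read_daily_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  daily_series(df$day, df$S, df$provenance)
}
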