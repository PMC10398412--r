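#' Piecewise-hazard two-arm trial scenario
#'
#' Defines the generating model for a two-arm trial with a piecewise-constant
#' control hazard and a piecewise-constant relative hazard \eqn{r(t)} applied
#' to the treated arm, plus independent exponential censoring and an
#' administrative follow-up cutoff. Time is measured in days throughout.
#'
#' @param control_rates Two-column matrix or data.frame
#'   (`start`, `rate`): interval start day and control-arm hazard per day.
#'   Intervals must be sorted and start at day 0; the last interval extends
#'   to infinity.
#' @param relative_hazard Two-column matrix or data.frame (`start`, `ratio`):
#'   interval start day and the hazard ratio \eqn{r(t)} applied to the
#'   treated arm on that interval. Defaults to a constant ratio of 1 (null).
#' @param censor_rate Rate per day of independent exponential censoring.
#' @param admin_cutoff_day Administrative censoring horizon in days.
#' @param discontinuation_day Scheduled treatment-stop day (landmark used by
#'   rebound detection and the before/after RMST split).
#'
#' @return An object of class `hazard_scenario`.
#' @seealso [icon7a_scenario()] for the shipped default, [simulate_trial()].
#' @export
hazard_scenario <- function(control_rates,
                            relative_hazard = cbind(start = 0, ratio = 1),
                            censor_rate = 0,
                            admin_cutoff_day = Inf,
                            discontinuation_day = NA_real_) {
  cr <- as.data.frame(control_rates)
  names(cr) <- c("start", "rate")
  rh <- as.data.frame(relative_hazard)
  names(rh) <- c("start", "ratio")
  check_intervals <- function(df, what) {
    if (nrow(df) < 1L) stop(what, ": at least one interval required", call. = FALSE)
    if (df$start[1] != 0) stop(what, ": first interval must start at day 0", call. = FALSE)
    if (is.unsorted(df$start, strictly = TRUE)) {
      stop(what, ": interval starts must be strictly ascending", call. = FALSE)
    }
  }
  check_intervals(cr, "control_rates")
  check_intervals(rh, "relative_hazard")
  if (any(cr$rate < 0)) stop("control rates must be >= 0", call. = FALSE)
  if (any(rh$ratio <= 0)) stop("relative hazard ratios must be > 0", call. = FALSE)
  if (censor_rate < 0) stop("censor_rate must be >= 0", call. = FALSE)
  if (!(admin_cutoff_day > 0)) stop("admin_cutoff_day must be > 0", call. = FALSE)
  structure(
    list(control_rates = cr, relative_hazard = rh, censor_rate = censor_rate,
         admin_cutoff_day = admin_cutoff_day,
         discontinuation_day = discontinuation_day),
    class = "hazard_scenario"
  )
}

#' @export
print.hazard_scenario <- function(x, ...) {
  cat("Piecewise-hazard trial scenario\n")
  cat("  control hazard (per day):\n")
  for (i in seq_len(nrow(x$control_rates))) {
    cat(sprintf("    from day %g: %g\n",
                x$control_rates$start[i], x$control_rates$rate[i]))
  }
  cat("  treated-arm relative hazard r(t):\n")
  for (i in seq_len(nrow(x$relative_hazard))) {
    cat(sprintf("    from day %g: %g\n",
                x$relative_hazard$start[i], x$relative_hazard$ratio[i]))
  }
  cat(sprintf("  censor rate: %g/day; admin cutoff: %g days; discontinuation: %g\n",
              x$censor_rate, x$admin_cutoff_day, x$discontinuation_day))
  invisible(x)
}

# Merge control and relative-hazard breakpoints into one piecewise grid of
# effective per-day rates for the requested arm.
arm_segments <- function(scenario, arm) {
  starts <- sort(unique(c(scenario$control_rates$start,
                          if (arm == 1) scenario$relative_hazard$start)))
  rate_at <- function(s) {
    i <- findInterval(s, scenario$control_rates$start)
    r <- scenario$control_rates$rate[i]
    if (arm == 1) {
      j <- findInterval(s, scenario$relative_hazard$start)
      r <- r * scenario$relative_hazard$ratio[j]
    }
    r
  }
  data.frame(start = starts, rate = vapply(starts, rate_at, numeric(1)))
}

# Piecewise-linear cumulative hazard at times t (vectorised), for segment
# table seg (start, rate) with last segment extending to Inf.
pw_cumhaz <- function(seg, t) {
  ends <- c(seg$start[-1], Inf)
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    sum(pmax(0, pmin(ti, ends) - seg$start) * seg$rate)
  }, numeric(1))
}

# Invert the cumulative hazard: smallest t with Lambda(t) >= target.
# Returns Inf when the total cumulative hazard never reaches the target.
pw_invert_cumhaz <- function(seg, target) {
  ends <- c(seg$start[-1], Inf)
  lam0 <- 0
  for (k in seq_len(nrow(seg))) {
    width <- ends[k] - seg$start[k]
    gain <- seg$rate[k] * width  # Inf * 0 avoided: rate 0 -> gain 0 even if width Inf
    if (seg$rate[k] == 0) gain <- 0
    if (is.finite(gain) && lam0 + gain < target) {
      lam0 <- lam0 + gain
      next
    }
    if (seg$rate[k] == 0) next
    return(seg$start[k] + (target - lam0) / seg$rate[k])
  }
  Inf
}

#' Categorical covariate model for simulation
#'
#' Describes baseline categorical covariates (e.g. stage, debulking status,
#' age group, histology), their marginal category probabilities, their
#' multiplicative effects on the hazard (log scale), and their effects on the
#' log-odds of treatment assignment. Zero assignment log-odds everywhere
#' corresponds to a randomized trial; nonzero values induce confounding.
#'
#' @param ... Named covariate specifications. Each is a list with elements
#'   `levels` (character), `probs` (summing to 1), and optionally `log_hr`
#'   and `assign_log_odds` (numeric per level, default 0). The first level is
#'   conventionally the reference with effect 0.
#' @param assign_intercept Intercept of the assignment log-odds (0 gives a
#'   50:50 marginal split when all assignment effects are 0).
#'
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(..., assign_intercept = 0) {
  covs <- list(...)
  if (length(covs) == 1L && is.null(names(covs)) && is.list(covs[[1]]) &&
      !is.null(names(covs[[1]])) && is.list(covs[[1]][[1]])) {
    covs <- covs[[1]]  # allow covariate_model(list(stage = ..., ...))
  }
  if (is.null(names(covs)) || any(names(covs) == "")) {
    stop("covariates must be named", call. = FALSE)
  }
  for (nm in names(covs)) {
    cv <- covs[[nm]]
    if (is.null(cv$levels) || is.null(cv$probs)) {
      stop("covariate '", nm, "' needs `levels` and `probs`", call. = FALSE)
    }
    if (length(cv$levels) != length(cv$probs)) {
      stop("covariate '", nm, "': levels/probs length mismatch", call. = FALSE)
    }
    if (abs(sum(cv$probs) - 1) > 1e-8) {
      stop("covariate '", nm, "': category probabilities must sum to 1",
           call. = FALSE)
    }
    covs[[nm]]$log_hr <- cv$log_hr %||% rep(0, length(cv$levels))
    covs[[nm]]$assign_log_odds <- cv$assign_log_odds %||% rep(0, length(cv$levels))
  }
  structure(list(covariates = covs, assign_intercept = assign_intercept),
            class = "covariate_model")
}

#' Default trial scenario with benefit, attenuation and rebound
#'
#' A shipped configuration emulating a first-line two-arm trial with a
#' 12-month treatment protocol: control hazard giving a median
#' progression-free survival of about 17 months, a treated-arm relative
#' hazard of 0.6 before day 180, 0.85 on days 180-364 (attenuating benefit),
#' 1.0 on days 365-394, 1.4 on days 395-719 (post-discontinuation excess
#' risk), and 1.0 thereafter; independent exponential censoring at
#' 1.5e-4/day and an administrative cutoff at 3 years. These values are
#' package defaults chosen to reproduce the qualitative
#' benefit/attenuation/rebound time course, not estimates from any trial.
#'
#' @return A `hazard_scenario`.
#' @export
icon7a_scenario <- function() {
  hazard_scenario(
    control_rates = cbind(start = 0, rate = log(2) / 517),
    relative_hazard = cbind(start = c(0, 180, 365, 395, 720),
                            ratio = c(0.6, 0.85, 1.0, 1.4, 1.0)),
    censor_rate = 1.5e-4,
    admin_cutoff_day = 1095,
    discontinuation_day = 365
  )
}

#' Default covariate model mirroring the adjusted analysis
#'
#' Four categorical baseline covariates (FIGO stage, debulking status, age
#' group dichotomized at 65 years, histology) with modest hazard effects and
#' no effect on assignment (a randomized trial). Use nonzero
#' `assign_log_odds` values (see [covariate_model()]) to create confounded
#' variants.
#'
#' @return A `covariate_model`.
#' @export
icon7a_covariates <- function() {
  covariate_model(
    stage = list(levels = c("I-II", "III-IV"), probs = c(0.3, 0.7),
                 log_hr = c(0, 0.5)),
    debulking = list(levels = c("complete", "incomplete"), probs = c(0.55, 0.45),
                     log_hr = c(0, 0.3)),
    age = list(levels = c("<65", ">=65"), probs = c(0.7, 0.3),
               log_hr = c(0, 0.2)),
    histology = list(levels = c("serous", "nonserous"), probs = c(0.72, 0.28),
                     log_hr = c(0, -0.1))
  )
}
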