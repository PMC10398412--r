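#' Simulate a two-arm trial from a piecewise-hazard scenario
#'
#' Event times are drawn by inverse-CDF sampling from the piecewise-constant
#' hazard: the cumulative hazard is piecewise linear and is inverted segment
#' by segment against an Exp(1) draw. Observed time is the minimum of the
#' event time, an independent exponential censoring time, and the
#' administrative cutoff; events take precedence over censoring at ties.
#'
#' Without a covariate model, arms are allocated deterministically
#' (`n_per_arm` subjects each). With a covariate model, `2 * n_per_arm`
#' subjects are generated and each subject's arm is Bernoulli with logistic
#' probability from the model's assignment log-odds (all-zero log-odds gives
#' a 50:50 randomized trial); covariate hazard effects multiply the subject's
#' hazard by `exp(sum of per-category log-hazard effects)`.
#'
#' @param scenario A [hazard_scenario()].
#' @param covmodel Optional [covariate_model()].
#' @param n_per_arm Subjects per arm (expected per arm under a covariate
#'   model).
#' @param seed Integer seed; identical inputs give identical output.
#'
#' @return A data.frame with columns `id`, `time` (days), `event`
#'   (1 progression / 0 censored), `arm` (0 control / 1 treated), and one
#'   column per covariate.
#' @export
simulate_trial <- function(scenario, covmodel = NULL, n_per_arm, seed) {
  stopifnot(inherits(scenario, "hazard_scenario"))
  if (!is.null(covmodel)) stopifnot(inherits(covmodel, "covariate_model"))
  if (n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  seg0 <- arm_segments(scenario, 0)
  seg1 <- arm_segments(scenario, 1)
  if (all(seg0$rate <= 0) && all(seg1$rate <= 0) &&
      scenario$censor_rate == 0 && !is.finite(scenario$admin_cutoff_day)) {
    stop("no event, censoring, or cutoff possible: all hazard rates are zero ",
         "with infinite follow-up", call. = FALSE)
  }
  n <- 2L * as.integer(n_per_arm)
  with_seed(seed, {
    covs <- NULL
    lp_hazard <- rep(0, n)
    lp_assign <- rep(0, n)
    if (!is.null(covmodel)) {
      covs <- lapply(covmodel$covariates, function(cv) {
        idx <- sample.int(length(cv$levels), n, replace = TRUE, prob = cv$probs)
        list(label = cv$levels[idx],
             log_hr = cv$log_hr[idx],
             alo = cv$assign_log_odds[idx])
      })
      lp_hazard <- Reduce(`+`, lapply(covs, `[[`, "log_hr"))
      lp_assign <- covmodel$assign_intercept +
        Reduce(`+`, lapply(covs, `[[`, "alo"))
      arm <- rbinom(n, 1L, plogis(lp_assign))
    } else {
      arm <- rep(c(0L, 1L), each = n_per_arm)
    }
    u <- rexp(n)  # Exp(1) targets for the cumulative hazard
    ev <- numeric(n)
    for (i in seq_len(n)) {
      seg <- if (arm[i] == 1L) seg1 else seg0
      seg_i <- seg
      seg_i$rate <- seg$rate * exp(lp_hazard[i])
      ev[i] <- pw_invert_cumhaz(seg_i, u[i])
    }
    cens <- if (scenario$censor_rate > 0) rexp(n, scenario$censor_rate) else rep(Inf, n)
    cens <- pmin(cens, scenario$admin_cutoff_day)
    time <- pmin(ev, cens)
    event <- as.integer(ev <= cens)  # events precede censorings at ties
    out <- data.frame(id = seq_len(n), time = time, event = event, arm = arm)
    if (!is.null(covs)) {
      for (nm in names(covs)) out[[nm]] <- covs[[nm]]$label
    }
    out
  })
}

#' Per-day survival series
#'
#' The common currency between the simulator, the Kaplan-Meier stage, and
#' the digitizer: survival fraction on an integer day grid, with a per-day
#' provenance flag (`observed`, `interpolated`, or `extrapolated`).
#'
#' @param day Integer day grid (consecutive, ascending).
#' @param S Survival fraction per day, in `[0, 1]`, non-increasing.
#' @param provenance Character flag per day.
#' @return A data.frame of class `daily_series`.
#' @export
daily_series <- function(day, S, provenance = "observed") {
  stopifnot(length(day) == length(S))
  if (is.unsorted(day, strictly = TRUE)) stop("`day` must be ascending", call. = FALSE)
  if (any(S < -1e-9 | S > 1 + 1e-9)) stop("S must lie in [0, 1]", call. = FALSE)
  if (any(diff(S) > 1e-9)) stop("S must be non-increasing", call. = FALSE)
  out <- data.frame(day = day, S = pmin(pmax(S, 0), 1),
                    provenance = rep_len(provenance, length(day)))
  class(out) <- c("daily_series", "data.frame")
  out
}

#' True survival function of a scenario arm
#'
#' Evaluates \eqn{S(t) = \exp(-\Lambda(t))} with \eqn{\Lambda} the
#' piecewise-linear cumulative hazard of the requested arm (the treated arm
#' multiplies each segment rate by \eqn{r(t)}). Covariate effects are not
#' marginalized here; this is the baseline-subject survival used as the
#' recovery oracle for covariate-free simulations.
#'
#' @param scenario A [hazard_scenario()].
#' @param arm 0 (control) or 1 (treated).
#' @param day_grid Ascending day grid starting at >= 0.
#' @return A [daily_series()].
#' @export
true_survival <- function(scenario, arm, day_grid) {
  stopifnot(inherits(scenario, "hazard_scenario"), arm %in% c(0, 1))
  if (length(day_grid) < 1L || is.unsorted(day_grid) || day_grid[1] < 0) {
    stop("day_grid must be ascending and start at >= 0", call. = FALSE)
  }
  seg <- arm_segments(scenario, arm)
  daily_series(day_grid, exp(-pw_cumhaz(seg, day_grid)))
}

#' Counterfactual marginal RMST truth for a confounded scenario
#'
#' Simulates every generated subject under both arms (same covariates, no
#' censoring other than the horizon) and returns the ratio and difference of
#' the marginal restricted mean survival times. This is the ground truth
#' against which adjusted analyses of confounded data are judged.
#'
#' @param scenario A [hazard_scenario()].
#' @param covmodel A [covariate_model()].
#' @param n Number of subjects to draw from the covariate distribution.
#' @param tau RMST horizon in days.
#' @param seed Integer seed.
#' @return A list with `rmst1`, `rmst0`, `ratio`, `difference`.
#' @export
counterfactual_rmst_truth <- function(scenario, covmodel, n, tau, seed) {
  stopifnot(inherits(scenario, "hazard_scenario"),
            inherits(covmodel, "covariate_model"), tau > 0)
  seg0 <- arm_segments(scenario, 0)
  seg1 <- arm_segments(scenario, 1)
  with_seed(seed, {
    lp <- rep(0, n)
    for (cv in covmodel$covariates) {
      idx <- sample.int(length(cv$levels), n, replace = TRUE, prob = cv$probs)
      lp <- lp + cv$log_hr[idx]
    }
    u <- rexp(n)
    area <- function(seg) {
      # mean of min(T, tau) across subjects, exact per-subject inversion
      mean(vapply(seq_len(n), function(i) {
        s <- seg
        s$rate <- seg$rate * exp(lp[i])
        min(pw_invert_cumhaz(s, u[i]), tau)
      }, numeric(1)))
    }
    r0 <- area(seg0)
    r1 <- area(seg1)
    list(rmst1 = r1, rmst0 = r0, ratio = r1 / r0, difference = r1 - r0)
  })
}
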