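#' Restricted mean survival time of a Kaplan-Meier fit
#'
#' The RMST at horizon `tau` is the exact area under the Kaplan-Meier step
#' function on `[lower, tau]` (mean event-free time over the window). The
#' standard error uses the Greenwood-based integrated-variance formula
#' \eqn{\mathrm{Var} = \sum_{t_i \le \tau} A_i^2\, d_i / (n_i (n_i - d_i))}
#' with \eqn{A_i} the area under the curve from \eqn{t_i} to \eqn{\tau}.
#'
#' @param sf A `km_fit`.
#' @param tau Horizon in days; must not exceed the last observed time
#'   (lower `tau` if it does).
#' @param lower Left edge of the integration window (default 0; nonzero
#'   gives the unconditional between-landmark area).
#' @return List with `rmst` and `se`.
#' @export
rmst <- function(sf, tau, lower = 0) {
  stopifnot(inherits(sf, "km_fit"))
  if (tau <= lower) stop("tau must exceed the lower integration edge", call. = FALSE)
  if (tau > max(sf$time)) {
    stop("tau exceeds the last observed time (", max(sf$time),
         "); lower tau to within follow-up", call. = FALSE)
  }
  keep <- sf$time < tau
  tt <- c(0, sf$time[keep], tau)
  ss <- c(1, sf$surv[keep])          # S on [tt[k], tt[k+1])
  width <- pmax(0, pmin(tt[-1], tau) - pmax(tt[-length(tt)], lower))
  area <- sum(ss * width)
  # area from each event time to tau (within [lower, tau])
  cum_from_right <- rev(cumsum(rev(ss * width)))
  ev <- which(keep & sf$n_event > 0)
  var <- 0
  for (i in ev) {
    k <- match(sf$time[i], tt)        # segment starting at this event time
    A <- if (k <= length(width)) cum_from_right[k] else 0
    d <- sf$n_event[i]; nr <- sf$n_risk[i]
    if (nr > d && A > 0) var <- var + A^2 * d / (nr * (nr - d))
  }
  list(rmst = area, se = sqrt(var))
}

#' Compare restricted mean survival time between arms
#'
#' Estimates each arm's RMST at horizon `tau` and reports the between-arm
#' difference (normal-approximation CI on the natural scale) and ratio
#' (delta-method CI on the log scale), each with a two-sided p-value.
#' Optionally adds nonparametric bootstrap confidence intervals (resampling
#' subjects within arm).
#'
#' @param records Data.frame with `time`, `event`, `arm`.
#' @param tau Horizon in days; default is the shorter arm's largest
#'   observed time.
#' @param lower Left edge of the integration window (default 0).
#' @param conf_level Confidence level (default 0.95).
#' @param boot Number of bootstrap resamples for additional CIs (0 = none).
#' @param seed Seed for the bootstrap.
#' @return An object of class `rmst_result`.
#' @export
rmst_compare <- function(records, tau = NULL, lower = 0, conf_level = 0.95,
                         boot = 0, seed = 1) {
  assert_records(records, require_two_arms = TRUE)
  if (is.null(tau)) {
    tau <- min(tapply(records$time, records$arm, max))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  fit0 <- km_estimate(records, arm = 0)
  fit1 <- km_estimate(records, arm = 1)
  r0 <- rmst(fit0, tau, lower)
  r1 <- rmst(fit1, tau, lower)
  if (r0$rmst <= 0 || r1$rmst <= 0) {
    stop("an arm has zero restricted mean survival on the window", call. = FALSE)
  }
  diff <- r1$rmst - r0$rmst
  diff_se <- sqrt(r1$se^2 + r0$se^2)
  ratio <- r1$rmst / r0$rmst
  log_se <- sqrt((r1$se / r1$rmst)^2 + (r0$se / r0$rmst)^2)
  res <- list(
    tau = tau, lower = lower, weighting = "unadjusted",
    conf_level = conf_level,
    arms = data.frame(
      arm = c(0, 1),
      n = c(fit0$n, fit1$n),
      events = c(sum(fit0$n_event), sum(fit1$n_event)),
      rmst = c(r0$rmst, r1$rmst),
      se = c(r0$se, r1$se)
    ),
    difference = diff, difference_se = diff_se,
    difference_ci = diff + c(-1, 1) * z * diff_se,
    difference_p = 2 * pnorm(-abs(diff / diff_se)),
    ratio = ratio, ratio_log_se = log_se,
    ratio_ci = exp(log(ratio) + c(-1, 1) * z * log_se),
    ratio_p = 2 * pnorm(-abs(log(ratio) / log_se))
  )
  if (boot > 0) {
    bs <- with_seed(seed, {
      i0 <- which(records$arm == 0)
      i1 <- which(records$arm == 1)
      reps <- vapply(seq_len(boot), function(b) {
        idx <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
        rb <- records[idx, , drop = FALSE]
        taub <- min(tau, min(tapply(rb$time, rb$arm, max)))
        a0 <- rmst(km_estimate(rb, arm = 0), taub, lower)$rmst
        a1 <- rmst(km_estimate(rb, arm = 1), taub, lower)$rmst
        c(diff = a1 - a0, logratio = log(a1 / a0))
      }, numeric(2))
      reps
    })
    res$boot <- list(
      n_boot = boot,
      difference_se = sd(bs["diff", ]),
      difference_ci = res$difference + c(-1, 1) * z * sd(bs["diff", ]),
      ratio_ci = exp(log(ratio) + c(-1, 1) * z * sd(bs["logratio", ]))
    )
  }
  class(res) <- "rmst_result"
  res
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("RMST comparison (%s), window [%g, %g] days\n",
              x$weighting, x$lower, x$tau))
  a <- x$arms
  cat(sprintf("  control: RMST %.1f (SE %.2f), n = %d\n",
              a$rmst[a$arm == 0], a$se[a$arm == 0], a$n[a$arm == 0]))
  cat(sprintf("  treated: RMST %.1f (SE %.2f), n = %d\n",
              a$rmst[a$arm == 1], a$se[a$arm == 1], a$n[a$arm == 1]))
  cat(sprintf("  RMST ratio, %.2f; %g%% CI, %.2f-%.2f; P = %.3g\n",
              x$ratio, 100 * x$conf_level, x$ratio_ci[1], x$ratio_ci[2],
              x$ratio_p))
  cat(sprintf("  RMST difference, %.1f days; %g%% CI, %.1f-%.1f; P = %.3g\n",
              x$difference, 100 * x$conf_level, x$difference_ci[1],
              x$difference_ci[2], x$difference_p))
  if (!is.null(x$boot)) {
    cat(sprintf("  bootstrap (%d): ratio CI %.2f-%.2f; difference CI %.1f-%.1f\n",
                x$boot$n_boot, x$boot$ratio_ci[1], x$boot$ratio_ci[2],
                x$boot$difference_ci[1], x$boot$difference_ci[2]))
  }
  invisible(x)
}

#' Split records at a landmark for before/after analyses
#'
#' The `pre` set keeps all subjects with follow-up capped at the landmark
#' (events after it recoded as censored at the landmark). The `post` set
#' keeps only subjects still at risk at the landmark — no event and not
#' censored by then — with time re-zeroed at the landmark. This is the
#' construction behind before/after-discontinuation RMST comparisons.
#'
#' @param records Data.frame with `time`, `event`, `arm`.
#' @param landmark_day Landmark in days (>= 0, within follow-up).
#' @return List with elements `pre` and `post`.
#' @export
landmark_split <- function(records, landmark_day) {
  assert_records(records)
  if (landmark_day < 0 || landmark_day >= max(records$time)) {
    stop("landmark_day must lie within follow-up", call. = FALSE)
  }
  pre <- records
  after <- records$time > landmark_day
  pre$event[after] <- 0
  pre$time[after] <- landmark_day
  if (landmark_day > 0) pre <- pre[pre$time > 0, , drop = FALSE]
  post <- records[records$time > landmark_day, , drop = FALSE]
  post$time <- post$time - landmark_day
  if (landmark_day > 0) {
    per_arm <- table(factor(post$arm, levels = c(0, 1)))
    if (any(per_arm < 2)) {
      stop("fewer than 2 at-risk subjects in an arm after the landmark",
           call. = FALSE)
    }
  }
  list(pre = pre, post = post)
}

#' Fit inverse-probability-of-treatment weights
#'
#' Models treatment assignment with a logistic generalized linear model on
#' categorical covariates (IRLS to convergence tolerance 1e-8) and returns
#' stabilized weights: `P(arm = 1) / p(x)` for treated subjects and
#' `P(arm = 0) / (1 - p(x))` for controls. On randomized data the fitted
#' probabilities reduce to the arm share and all weights are ~1.
#'
#' @param records Data.frame with `arm` and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `ipw_model`: list with `covariates`, `coef`,
#'   `fitted`, `weights`, `diagnostics` (weight range and per-arm effective
#'   sample size).
#' @export
fit_ipw <- function(records, covariates) {
  assert_records(records, require_two_arms = TRUE)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) {
    stop("unknown covariate columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- records[, c("arm", covariates), drop = FALSE]
  for (cv in covariates) df[[cv]] <- factor(df[[cv]])
  form <- if (length(covariates)) {
    as.formula(paste("arm ~", paste(covariates, collapse = " + ")))
  } else {
    arm ~ 1
  }
  fit <- glm(form, family = binomial(), data = df,
             control = glm.control(epsilon = 1e-8, maxit = 100))
  p <- fit$fitted.values
  if (any(p < 1e-8 | p > 1 - 1e-8)) {
    stop("fitted assignment probabilities at 0/1: perfect separation; ",
         "coarsen or drop covariates", call. = FALSE)
  }
  share1 <- mean(records$arm == 1)
  w <- ifelse(records$arm == 1, share1 / p, (1 - share1) / (1 - p))
  ess <- function(wi) sum(wi)^2 / sum(wi^2)
  structure(
    list(covariates = covariates, formula = form, coef = stats::coef(fit),
         fitted = p, weights = w,
         diagnostics = list(
           weight_range = range(w),
           ess = c(control = ess(w[records$arm == 0]),
                   treated = ess(w[records$arm == 1]))
         )),
    class = "ipw_model"
  )
}

#' @export
print.ipw_model <- function(x, ...) {
  cat("Inverse-probability-of-treatment weights (stabilized)\n")
  cat("  covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none: null model)", "\n")
  cat(sprintf("  weight range: %.3f-%.3f; ESS control %.0f, treated %.0f\n",
              x$diagnostics$weight_range[1], x$diagnostics$weight_range[2],
              x$diagnostics$ess["control"], x$diagnostics$ess["treated"]))
  invisible(x)
}

#' Weighted covariate balance diagnostic
#'
#' Total-variation distance between each arm's weighted covariate
#' distribution and the pooled (unweighted) distribution; values near 0
#' indicate the weights balance the covariate.
#'
#' @param records Data.frame with `arm` and the covariate columns.
#' @param covariates Character vector of covariate names.
#' @param weights Per-subject weights (e.g. from [fit_ipw()]).
#' @return Named numeric: the maximum TV distance over arms, per covariate.
#' @export
ipw_balance <- function(records, covariates, weights) {
  vapply(covariates, function(cv) {
    lev <- unique(records[[cv]])
    pooled <- prop.table(table(factor(records[[cv]], levels = lev)))
    tv <- function(arm) {
      sel <- records$arm == arm
      wt <- weights[sel]
      wtab <- tapply(wt, factor(records[[cv]][sel], levels = lev), sum)
      wtab[is.na(wtab)] <- 0
      sum(abs(wtab / sum(wt) - pooled)) / 2
    }
    max(tv(0), tv(1))
  }, numeric(1))
}

#' IPW-adjusted RMST comparison
#'
#' Kaplan-Meier estimation with weighted risk and event counts (the
#' adjusted Kaplan-Meier estimator), RMST as the area under the weighted
#' step function, and uncertainty by nonparametric bootstrap: subjects are
#' resampled, the assignment model refitted, and the weighted RMSTs
#' recomputed in each resample. With all weights equal to 1 the point
#' estimates coincide exactly with the unadjusted comparison.
#'
#' @param records Data.frame with `time`, `event`, `arm` and covariates.
#' @param ipw An [ipw_model()] fitted on `records`.
#' @param tau Horizon in days (default: shorter arm's largest observed
#'   time).
#' @param lower Left edge of the integration window (default 0).
#' @param boot Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return An `rmst_result` with `weighting = "IPW"`; CIs and p-values are
#'   bootstrap-based.
#' @export
adjusted_rmst_compare <- function(records, ipw, tau = NULL, lower = 0,
                                  boot = 1000, seed = 1, conf_level = 0.95) {
  assert_records(records, require_two_arms = TRUE)
  stopifnot(inherits(ipw, "ipw_model"))
  if (length(ipw$weights) != nrow(records)) {
    stop("weights must be available for every record", call. = FALSE)
  }
  if (any(ipw$diagnostics$ess < 10)) {
    stop("effective sample size below 10 in an arm; weights too extreme",
         call. = FALSE)
  }
  if (is.null(tau)) tau <- min(tapply(records$time, records$arm, max))
  z <- qnorm(1 - (1 - conf_level) / 2)
  point <- function(rec, w) {
    f0 <- km_estimate(rec, arm = 0, weights = w)
    f1 <- km_estimate(rec, arm = 1, weights = w)
    taub <- min(tau, max(f0$time), max(f1$time))
    c(rmst0 = rmst(f0, taub, lower)$rmst, rmst1 = rmst(f1, taub, lower)$rmst)
  }
  est <- point(records, ipw$weights)
  diff <- est["rmst1"] - est["rmst0"]
  ratio <- est["rmst1"] / est["rmst0"]
  bs <- with_seed(seed, {
    n <- nrow(records)
    vapply(seq_len(boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      rb <- records[idx, , drop = FALSE]
      if (length(unique(rb$arm)) < 2L) return(c(NA_real_, NA_real_))
      wb <- tryCatch(fit_ipw(rb, ipw$covariates)$weights,
                     error = function(e) NULL)
      if (is.null(wb)) return(c(NA_real_, NA_real_))
      eb <- point(rb, wb)
      c(eb["rmst1"] - eb["rmst0"], log(eb["rmst1"] / eb["rmst0"]))
    }, numeric(2))
  })
  ok <- !is.na(bs[1, ])
  if (sum(ok) < boot * 0.5) {
    stop("bootstrap failed in more than half of the resamples", call. = FALSE)
  }
  diff_se <- sd(bs[1, ok])
  log_se <- sd(bs[2, ok])
  fit0 <- km_estimate(records, arm = 0, weights = ipw$weights)
  fit1 <- km_estimate(records, arm = 1, weights = ipw$weights)
  res <- list(
    tau = tau, lower = lower, weighting = "IPW", conf_level = conf_level,
    arms = data.frame(
      arm = c(0, 1),
      n = c(sum(records$arm == 0), sum(records$arm == 1)),
      events = c(sum(records$event[records$arm == 0]),
                 sum(records$event[records$arm == 1])),
      rmst = unname(est[c("rmst0", "rmst1")]),
      se = c(NA_real_, NA_real_)
    ),
    difference = unname(diff), difference_se = diff_se,
    difference_ci = unname(diff) + c(-1, 1) * z * diff_se,
    difference_p = 2 * pnorm(-abs(diff / diff_se)),
    ratio = unname(ratio), ratio_log_se = log_se,
    ratio_ci = exp(log(unname(ratio)) + c(-1, 1) * z * log_se),
    ratio_p = 2 * pnorm(-abs(log(ratio) / log_se)),
    boot = list(n_boot = sum(ok)),
    ipw_diagnostics = ipw$diagnostics
  )
  class(res) <- "rmst_result"
  res
}
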