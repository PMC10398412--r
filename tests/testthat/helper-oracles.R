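# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: survival is estimated by explicit risk-set
# enumeration, areas by exact quadrature through the public lookup only.

# Product-limit estimate by brute-force enumeration of risk sets.
# Events precede censorings at tied times: subjects censored at t are still
# at risk for events at t.
km_brute <- function(time, event, eval_times) {
  ev_times <- sort(unique(time[event == 1]))
  vapply(eval_times, function(t) {
    s <- 1
    for (ti in ev_times[ev_times <= t]) {
      n_i <- sum(time > ti | (time == ti))       # at risk just before ti
      d_i <- sum(time == ti & event == 1)
      s <- s * (1 - d_i / n_i)
    }
    s
  }, numeric(1))
}

# Two-sample log-rank statistic from first principles (O-E and hypergeometric
# variance accumulated over event times).
logrank_brute <- function(time, event, arm) {
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (ti in ev_times) {
    at_risk <- time >= ti
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == 1)
    d <- sum(time == ti & event == 1)
    d1 <- sum(time == ti & event == 1 & arm == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Exact quadrature of the area under a km_fit on [0, tau], using only the
# public survival_at lookup: the function is constant between knots, so the
# midpoint rule on knot intervals is exact.
rmst_quadrature <- function(fit, tau) {
  knots <- sort(unique(c(0, fit$time[fit$time < tau], tau)))
  mids <- (knots[-1] + knots[-length(knots)]) / 2
  sum(as.numeric(survival_at(fit, mids)) * diff(knots))
}

# Random censored survival data for small-instance property tests.
random_records <- function(n, rate = 0.1, cens_rate = 0.05) {
  time <- round(rexp(n, rate), 1) + 0.1
  cens <- round(rexp(n, cens_rate), 1) + 0.1
  data.frame(
    id = seq_len(n),
    time = pmin(time, cens),
    event = as.integer(time <= cens),
    arm = rep_len(c(0L, 1L), n)
  )
}

# Flat daily series helpers
exp_series <- function(lambda, horizon) {
  daily_series(0:horizon, exp(-lambda * (0:horizon)))
}

# Default scenario's true relative hazard at given days
true_r <- function(scenario, days) {
  scenario$relative_hazard$ratio[
    findInterval(days, scenario$relative_hazard$start)]
}
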