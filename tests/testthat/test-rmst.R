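test_that("RMST equals exact step areas on simple curves", {
  # S identically 1: area is the horizon
  rec <- data.frame(time = 25, event = 0, arm = 0)
  expect_equal(rmst(km_estimate(rec), 20)$rmst, 20, tolerance = 1e-12)

  # one drop to 0.5 at day 10, horizon 20: 10 * 1 + 10 * 0.5 = 15
  rec2 <- data.frame(time = c(10, 10, 20, 20), event = c(1, 1, 0, 0), arm = 0)
  expect_equal(rmst(km_estimate(rec2), 20)$rmst, 15, tolerance = 1e-12)

  # tau beyond follow-up is rejected with guidance
  expect_error(rmst(km_estimate(rec2), 50), "lower tau")
})

test_that("RMST matches exact quadrature of survival_at on random instances", {
  set.seed(11)
  for (i in 1:200) {
    rec <- random_records(sample(3:40, 1))
    fit <- km_estimate(rec)
    tau <- stats::runif(1, 0.5, 1) * max(rec$time)
    expect_equal(rmst(fit, tau)$rmst, rmst_quadrature(fit, tau),
                 tolerance = 1e-9)
  }
})

test_that("RMST is monotone in tau and its ratio is unit-invariant", {
  set.seed(5)
  rec <- random_records(80)
  fit <- km_estimate(rec)
  taus <- seq(1, max(rec$time), length.out = 10)
  areas <- vapply(taus, function(t) rmst(fit, t)$rmst, numeric(1))
  expect_true(all(diff(areas) > 0))

  res <- rmst_compare(rec, tau = 10)
  rec2 <- rec
  rec2$time <- rec2$time * 30.44
  res2 <- rmst_compare(rec2, tau = 10 * 30.44)
  expect_equal(res$ratio, res2$ratio, tolerance = 1e-10)
  expect_equal(res$ratio_p, res2$ratio_p, tolerance = 1e-8)
  expect_equal(res2$difference, res$difference * 30.44, tolerance = 1e-8)
})

test_that("identical arms give ratio 1, difference 0, p = 1", {
  one <- random_records(40)[, c("time", "event")]
  rec <- rbind(cbind(one, arm = 0), cbind(one, arm = 1))
  res <- rmst_compare(rec, tau = stats::median(one$time))
  expect_equal(res$ratio, 1, tolerance = 1e-12)
  expect_equal(res$difference, 0, tolerance = 1e-12)
  expect_equal(res$ratio_p, 1, tolerance = 1e-9)
})

test_that("RMST-ratio test is calibrated under the null", {
  sc <- hazard_scenario(cbind(0, log(2) / 517), censor_rate = 1.5e-4,
                        admin_cutoff_day = 1095)
  rej <- vapply(1:300, function(i) {
    rec <- simulate_trial(sc, n_per_arm = 200, seed = 7000 + i)
    rmst_compare(rec)$ratio_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("benefit-only scenario recovers the true RMST ratio", {
  sc <- hazard_scenario(cbind(0, log(2) / 517),
                        relative_hazard = cbind(0, 0.6),
                        admin_cutoff_day = 1095)
  rec <- simulate_trial(sc, n_per_arm = 2000, seed = 23)
  tau <- 1000
  res <- rmst_compare(rec, tau = tau)
  tr1 <- true_survival(sc, 1, 0:tau)
  tr0 <- true_survival(sc, 0, 0:tau)
  # trapezoid on the closed-form curves (1-day grid; curvature error ~1e-6)
  area <- function(s) sum((s$S[-1] + s$S[-length(s$S)]) / 2)
  expect_lt(abs(res$ratio - area(tr1) / area(tr0)), 0.03)
})

test_that("landmark split caps, censors, filters and re-zeroes correctly", {
  rec <- data.frame(id = 1:6,
                    time = c(400, 200, 365, 500, 420, 610),
                    event = c(1, 1, 0, 0, 1, 1),
                    arm = c(0, 1, 0, 1, 0, 1))
  sp <- landmark_split(rec, 365)
  expect_equal(sp$pre$time, c(365, 200, 365, 365, 365, 365))
  expect_equal(sp$pre$event, c(0, 1, 0, 0, 0, 0))
  # at-risk at 365: all but ids 2 and 3 (id 3 censored exactly at 365)
  expect_equal(sp$post$id, c(1, 4, 5, 6))
  expect_equal(sp$post$time, c(35, 135, 55, 245))
  expect_equal(sp$post$event, c(1, 0, 1, 1))

  # landmark 0 keeps everything
  sp0 <- landmark_split(rec, 0)
  expect_equal(sp0$post, rec)

  expect_error(landmark_split(rec, 550), "at-risk")
  expect_error(landmark_split(rec, 1000), "within follow-up")
})

test_that("landmark pieces reconstruct the overall RMST on uncensored data", {
  set.seed(31)
  tt <- round(rexp(400, 0.01), 1) + 0.1
  rec <- data.frame(time = tt, event = 1, arm = rep(0:1, 200))
  L <- 60; tau <- 200
  sp <- landmark_split(rec, L)
  for (a in 0:1) {
    whole <- rmst(km_estimate(rec, arm = a), tau)$rmst
    pre <- rmst(km_estimate(sp$pre, arm = a), L)$rmst
    at_risk <- as.numeric(survival_at(km_estimate(rec, arm = a), L))
    post <- rmst(km_estimate(sp$post, arm = a), tau - L)$rmst
    expect_equal(whole, pre + at_risk * post, tolerance = 1e-9)
  }
})

test_that("IPW on randomized data reduces to the null model", {
  sc <- icon7a_scenario()
  rec <- simulate_trial(sc, icon7a_covariates(), n_per_arm = 1000, seed = 41)
  ipw <- fit_ipw(rec, c("stage", "debulking", "age", "histology"))
  expect_true(all(abs(ipw$fitted - mean(rec$arm)) < 0.1))
  expect_true(all(ipw$weights > 0))
  expect_lt(max(abs(ipw$weights - 1)), 0.25)
})

test_that("IPW recovers a known assignment coefficient and balances covariates", {
  sc <- hazard_scenario(cbind(0, 0.002), admin_cutoff_day = 2000)
  cm <- covariate_model(
    grp = list(levels = c("a", "b"), probs = c(0.5, 0.5),
               log_hr = c(0, 0.7), assign_log_odds = c(0, 1)),
    assign_intercept = -0.5
  )
  rec <- simulate_trial(sc, cm, n_per_arm = 2500, seed = 47)  # n = 5000
  ipw <- fit_ipw(rec, "grp")
  # coefficient of the non-reference level; sign depends on factor order
  slope <- ipw$coef[grepl("^grp", names(ipw$coef))]
  expect_lt(abs(abs(slope) - 1), 0.15)
  expect_lt(max(ipw_balance(rec, "grp", ipw$weights)), 0.02)
  expect_true(all(ipw$weights > 0))
})

test_that("perfect separation is rejected with a diagnostic", {
  rec <- data.frame(time = rep(10, 40), event = 1,
                    arm = rep(c(0, 1), each = 20),
                    g = rep(c("x", "y"), each = 20))
  expect_error(fit_ipw(rec, "g"), "separation")
})

test_that("adjusted comparison with unit weights equals the unadjusted one", {
  sc <- icon7a_scenario()
  rec <- simulate_trial(sc, n_per_arm = 400, seed = 53)
  rec$dummy <- "same"                    # single-level: null assignment model
  ipw <- fit_ipw(rec, character(0))
  expect_equal(ipw$weights, rep(1, nrow(rec)), tolerance = 1e-12)
  un <- rmst_compare(rec, tau = 900)
  ad <- adjusted_rmst_compare(rec, ipw, tau = 900, boot = 50, seed = 3)
  expect_equal(ad$ratio, un$ratio, tolerance = 1e-12)
  expect_equal(ad$arms$rmst, un$arms$rmst, tolerance = 1e-12)
})

test_that("adjustment on randomized data barely moves the ratio", {
  sc <- icon7a_scenario()
  rec <- simulate_trial(sc, icon7a_covariates(), n_per_arm = 2000, seed = 59)
  ipw <- fit_ipw(rec, c("stage", "debulking", "age", "histology"))
  un <- rmst_compare(rec, tau = 1000)
  ad <- adjusted_rmst_compare(rec, ipw, tau = 1000, boot = 50, seed = 7)
  expect_lt(abs(ad$ratio - un$ratio), 0.02)
})
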