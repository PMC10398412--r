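test_that("windowed risk matches hand arithmetic and closed forms", {
  ser <- daily_series(0:30, c(1, rep(0.95, 29), 0.9))
  rc <- progression_risk(ser, 30)
  expect_equal(rc$risk[1], 0.1, tolerance = 1e-12)
  cc <- progression_risk(ser, 30, mode = "conditional")
  expect_equal(cc$risk[1], 0.1, tolerance = 1e-12)

  flat <- daily_series(0:100, rep(1, 101))
  expect_true(all(progression_risk(flat)$risk[1:71] == 0))

  # exponential series: absolute risk decays, conditional risk is constant
  lam <- 0.01
  ser2 <- exp_series(lam, 400)
  ab <- progression_risk(ser2, 30)
  t <- 0:370
  expect_equal(ab$risk[1:371], exp(-lam * t) * (1 - exp(-0.3)),
               tolerance = 1e-12)
  cd <- progression_risk(ser2, 30, mode = "conditional")
  expect_equal(cd$risk[1:371], rep(1 - exp(-0.3), 371), tolerance = 1e-12)

  # window reaching past the horizon is missing
  expect_true(all(ab$missing[372:401]))
  expect_error(progression_risk(ser2, 0), "> 0")
})

test_that("relative risk applies the either-zero incalculability rule", {
  treat <- daily_series(0:40, 1 - 0.05 / 30 * (0:40))
  ctrl <- daily_series(0:40, 1 - 0.10 / 30 * (0:40))
  rr <- relative_risk(progression_risk(treat, 10), progression_risk(ctrl, 10))
  expect_equal(rr$rr[1], 0.5, tolerance = 1e-9)

  flat <- daily_series(0:40, rep(1, 41))
  rr2 <- relative_risk(progression_risk(treat, 10), progression_risk(flat, 10))
  expect_true(all(rr2$missing[1:31]))
  expect_true(all(rr2$reason[1:31] == "zero-denominator"))

  rr3 <- relative_risk(progression_risk(flat, 10), progression_risk(ctrl, 10))
  expect_true(all(rr3$reason[1:31] == "zero-numerator-rule"))

  short <- daily_series(0:30, rep(1, 31))
  expect_error(relative_risk(progression_risk(treat, 10),
                             progression_risk(short, 10)),
               "grids")
})

test_that("moving-average smoothing has the exact linear-filter properties", {
  ser <- daily_series(0:300, rep(1, 301))
  rc <- progression_risk(ser, 30)       # constant 0 where defined
  sm <- smooth_curve(rc, 60)
  expect_true(all(sm$risk[!sm$missing] == 0))

  # unit impulse spreads to a plateau of 1/121 over the interior window
  rc2 <- rc
  rc2$risk[] <- 0
  rc2$risk[rc2$day == 150] <- 1
  rc2$missing[] <- FALSE
  sm2 <- smooth_curve(rc2, 60)
  inside <- sm2$day >= 90 & sm2$day <= 210
  expect_equal(sm2$risk[inside], rep(1 / 121, sum(inside)), tolerance = 1e-12)
  expect_true(all(sm2$risk[sm2$day > 210 & sm2$day < 241] == 0))

  # halfwidth 0 is the identity
  sm0 <- smooth_curve(rc2, 0)
  expect_equal(sm0$risk, rc2$risk)

  # smoothing never leaves the observed value range
  set.seed(1)
  rc3 <- rc
  rc3$risk[seq_len(271)] <- runif(271)
  rc3$missing[] <- c(rep(FALSE, 271), rep(TRUE, 30))
  sm3 <- smooth_curve(rc3, 60)
  expect_gte(min(sm3$risk, na.rm = TRUE), min(rc3$risk[1:271]))
  expect_lte(max(sm3$risk, na.rm = TRUE), max(rc3$risk[1:271]))
})

test_that("missing days are excluded from the mean, not propagated", {
  ser <- daily_series(0:200, rep(1, 201))
  rc <- progression_risk(ser, 30)
  rc$risk[] <- 2
  rc$missing[] <- FALSE
  rc$risk[rc$day %in% 100:105] <- NA
  rc$missing[rc$day %in% 100:105] <- TRUE
  sm <- smooth_curve(rc, 60)
  expect_equal(sm$risk[sm$day == 102], 2, tolerance = 1e-12)
  expect_false(sm$missing[sm$day == 102])
})

test_that("rebound detection follows the sustained-run definition", {
  mk_rr <- function(vals) {
    treat <- daily_series(0:(length(vals) + 30), rep(1, length(vals) + 31))
    rc <- progression_risk(treat, 30)
    rr <- relative_risk(rc, rc)
    rr$rr <- c(vals, rep(NA, nrow(rr) - length(vals)))
    rr$missing <- is.na(rr$rr)
    rr$reason[] <- NA_character_
    rr
  }
  # uniformly below 1: no rebound
  rr1 <- mk_rr(rep(0.8, 500))
  rep1 <- detect_rebound(rr1, 365)
  expect_false(rep1$rebound)
  expect_true(is.na(rep1$onset_day))

  # step from 0.7 to 1.3 at day 365: onset at the discontinuation day
  rr2 <- mk_rr(c(rep(0.7, 365), rep(1.3, 135)))
  rep2 <- detect_rebound(rr2, 365)
  expect_true(rep2$rebound)
  expect_equal(rep2$onset_day, 365)
  expect_equal(rep2$peak_rr, 1.3)
  expect_equal(rep2$pre_min_rr, 0.7)

  # a brief 10-day crossing does not qualify at run length 30
  rr3 <- mk_rr(c(rep(0.9, 400), rep(1.2, 10), rep(0.9, 90)))
  expect_false(detect_rebound(rr3, 365)$rebound)
  expect_true(detect_rebound(rr3, 365, run_days = 5)$rebound)

  # entirely missing after discontinuation: indeterminate
  rr4 <- mk_rr(c(rep(0.8, 365), rep(NA, 135)))
  rep4 <- detect_rebound(rr4, 365)
  expect_true(is.na(rep4$rebound))

  expect_error(detect_rebound(rr1, 1e6), "grid")
})

test_that("smoothed relative risk concentrates on its exact estimand at scale", {
  # the estimand of the smoothed KM-based curve is the smoothed ratio of
  # 30-day drops of the true survival functions; with 10000 per arm the
  # estimate tracks it closely, and rebound fires just after treatment stop
  sc <- icon7a_scenario()
  rec <- simulate_trial(sc, n_per_arm = 10000, seed = 17)
  f0 <- km_estimate(rec, arm = 0)
  f1 <- km_estimate(rec, arm = 1)
  H <- floor(min(max(f0$time), max(f1$time)))
  rr <- smooth_curve(relative_risk(
    progression_risk(km_daily_series(f1, H)),
    progression_risk(km_daily_series(f0, H))
  ))
  t1 <- true_survival(sc, 1, 0:H)
  t0 <- true_survival(sc, 0, 0:H)
  oracle <- smooth_curve(relative_risk(progression_risk(t1),
                                       progression_risk(t0)))
  elig <- !rr$missing & !oracle$missing & rr$day <= H - 120
  err <- abs(rr$rr[elig] - oracle$rr[elig])
  expect_lt(mean(err), 0.1)
  expect_lt(max(err), 0.3)
  rb <- detect_rebound(rr, 365)
  expect_true(rb$rebound)
  expect_true(rb$onset_day >= 365 && rb$onset_day <= 450)
  expect_lt(rb$pre_min_rr, 1)
})
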