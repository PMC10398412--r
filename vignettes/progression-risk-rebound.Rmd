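---
title: "Time-varying progression risk, rebound detection, and RMST comparison"
author: "kmrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying progression risk, rebound detection, and RMST comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmrisk)
```

## The problem

Anti-angiogenic maintenance therapy in ovarian cancer (bevacizumab is the
motivating case) is given for a protocol-fixed period — typically 12 to 15
months — and then stopped in patients whose disease has not progressed.
When the between-arm hazard ratio changes over this course, a single Cox
hazard ratio misrepresents the treatment effect: the proportional-hazards
assumption fails, and summaries that average over follow-up hide both the
early benefit and any late harm. Two complementary tools deal with this:

* a **day-by-day windowed progression-risk curve**, which localizes the
  treatment effect in time, and
* **restricted mean survival time (RMST)**, which summarizes survival over
  an explicit window without any proportionality assumption.

A second practical obstacle is that patient-level data for most published
trials are inaccessible: often only the printed Kaplan-Meier (KM) figure
exists. `kmrisk` therefore supports two workflows with a shared core: an
`ipd` workflow starting from patient-level records, and a `digitized`
workflow starting from pixel coordinates traced off a published figure.

## The statistics

**Windowed progression risk.** Given a per-day survival series $S(t)$
(from a KM fit or a calibrated digitization), the progression risk at day
$t$ with window $w$ (default 30 days) is the drop of the curve over the
window,

$$R(t) = S(t) - S(t + w),$$

the absolute probability of progressing in $(t, t+w]$. A conditional
variant $R(t)/S(t)$ — the risk among patients still progression-free at
$t$ — is provided because the absolute drop and the at-risk-conditional
risk differ once the curves separate; the absolute form is the default.
On an exponential curve with hazard $\lambda$ the conditional form is
constant at $1 - e^{-\lambda w}$, which the test suite checks to $10^{-12}$.

**Relative risk and incalculability.** The relative risk curve is
$RR(t) = R_1(t)/R_0(t)$ (treated over control). Where either windowed risk
is exactly zero the ratio is declared incalculable and flagged missing
with a reason code (`zero-denominator`, `zero-numerator-rule`) rather than
propagated as 0 or infinity. Flat curve segments — common in digitized
figures and in sparse tails — therefore produce gaps, not artifacts.

**Smoothing.** Both risks and the relative risk are smoothed by a simple
centered moving average over the 60 days before and after each day — a
121-day window including the day itself, truncated at the grid edges.
Missing days are excluded from the mean rather than propagated, so
isolated incalculable days do not erase the curve; a day whose entire
window is missing stays missing. The filter is linear, exact on constants,
and never leaves the range of its inputs.

**Rebound.** Rebound is a sustained excess of treated-arm risk after the
scheduled treatment stop. `detect_rebound()` reports the first day at or
after the discontinuation day from which the smoothed $RR$ exceeds 1 on at
least `run_days` (default 30) consecutive non-missing days, plus the
post-discontinuation peak and the pre-discontinuation minimum. The
run-length requirement suppresses single-day noise crossings; 30 days is a
package choice, not an estimate.

**RMST.** The RMST at horizon $\tau$ is
$\int_0^\tau S(u)\,du$, computed as the exact area under the KM step
function, with the Greenwood-based variance
$\sum_{t_i \le \tau} A_i^2\, d_i /\{n_i(n_i - d_i)\}$ where
$A_i = \int_{t_i}^\tau S(u)\,du$. Arms are compared by difference (normal
CI on the natural scale) and ratio (delta-method CI on the log scale),
with two-sided p-values and a 0.05 threshold. The default $\tau$ is the
shorter arm's largest observed time; $\tau$ beyond follow-up is rejected
rather than extrapolated.

**Before/after the landmark.** The before/after-discontinuation
comparison is built as a landmark analysis: *before* caps every subject's
follow-up at the landmark $L$ (events after $L$ recoded as censored at
$L$); *after* keeps only subjects still at risk at $L$, re-zeroed at $L$.
How published before/after splits are constructed is generally not stated;
landmark conditioning is the construction we adopt, and an unconditional
alternative — the area on $[L, \tau]$ without re-selection — is exposed via
the `lower` argument of `rmst()`/`rmst_compare()` so the two can be
compared. On complete (uncensored) data the landmark pieces reconstruct
the overall area exactly: $\mathrm{RMST}(\tau) =
\mathrm{RMST}_{pre}(L) + S(L)\,\mathrm{RMST}_{post}(\tau - L)$, which the
suite asserts to $10^{-9}$.

**Covariate adjustment.** `fit_ipw()` models treatment assignment on
categorical covariates (stage, debulking status, age group dichotomized at
65, histology in the shipped default) with a logistic GLM (IRLS,
convergence $10^{-8}$) and forms stabilized weights
$\Pr(A{=}a)/\Pr(A{=}a \mid X)$. `adjusted_rmst_compare()` then fits a
weighted KM per arm and integrates it as above. A closed-form variance for
the weighted KM area is deliberately not used: its standard derivations
ignore the estimation of the weights, so uncertainty comes from a
nonparametric bootstrap (subjects resampled, assignment model refitted in
each resample; default 1000 resamples, seeded). With all weights equal to 1
the point estimates coincide exactly with the unadjusted analysis.
Fitted probabilities within $10^{-8}$ of 0 or 1 are treated as separation
and rejected; effective sample size below 10 per arm is rejected.

## The digitizer

The digitized workflow expects what coordinate-extraction software
produces: a pixel polyline per curve plus calibration pixels — the columns
of time 0 and of a 12- or 24-month anchor, and the rows of survival 0% and
100%. Months convert to days at $365/12$; this conversion is a package
decision, applied consistently to axis anchors only (the analysis grid is
integer days throughout). Calibration is exact at the anchors and
invariant to uniform image rescaling.

`to_daily_series()` evaluates the calibrated polyline on an integer day
grid with the survival step convention. Three imperfections of traced
curves are handled explicitly, and every output day carries a provenance
flag so the repairs can be audited:

* **trace gaps** (consecutive points more than `gap_px` columns apart,
  e.g. where curves overplot): filled linearly, flagged `interpolated`;
* **pixel jitter** that makes survival rise: repaired by a running
  minimum, so the output is always a valid non-increasing series;
* **days beyond the last traced point**: carried forward, flagged
  `extrapolated`.

If the first traced point is within 2% of survival 1 the series is
anchored at $S(0)=1$; otherwise a warning is raised and the trace is used
as-is — a curve genuinely starting below 100% is surfaced, not silently
"fixed". The round-trip error of rasterize-then-digitize is bounded by one
y-pixel of survival fraction plus the one-day step quantization, which the
suite asserts; at a 1000×700-px figure with 1-px jitter the per-day
survival error stays below 0.01.

## The simulator: what it emulates and what it does not

`simulate_trial()` draws two-arm trials with a piecewise-constant control
hazard, a piecewise-constant treated-arm relative hazard $r(t)$,
independent exponential censoring, and an administrative cutoff. Event
times use exact inverse-CDF sampling: the cumulative hazard is piecewise
linear and is inverted segment by segment, so no discretization error
enters. Categorical covariates can multiply the hazard
(`log_hr`) and shift the assignment log-odds (`assign_log_odds`), giving
randomized or confounded designs from one model.

The shipped default (`icon7a_scenario()`) encodes a first-line,
12-month-protocol trial: control hazard $\log 2 / 517$ per day (median
progression-free survival about 17 months), and

$$r(t) = 0.6 \text{ on } [0, 180), \;
  0.85 \text{ on } [180, 365), \;
  1.0 \text{ on } [365, 395), \;
  1.4 \text{ on } [395, 720), \;
  1.0 \text{ after},$$

i.e. strong early benefit, attenuation toward the 12-month stop, a short
neutral transition, a rebound window of excess risk, then convergence.
Censoring is exponential at $1.5 \times 10^{-4}$/day (roughly 5% per
year) with an administrative cutoff at 1095 days, a typical data maturity
for these trials; trial reports rarely state their censoring process, so
these are declared defaults, not estimates. All numeric values are package
choices that reproduce the qualitative benefit/attenuation/rebound shape —
none is an estimate from any real cohort.

What the simulator does **not** emulate: dependent censoring, cure
fractions, delayed entry, per-site assessment schedules (real
progression times cluster at scan visits), informative dropout after
toxicity, and any molecular substructure. Tests passing on this generator
therefore validate the estimators' mathematics and their behaviour under
non-proportional hazards — they do not certify performance on real trial
idiosyncrasies, particularly interval-censored progression times.

## Numerical and design choices

* **Tie rule**: events precede censorings at equal times (the standard
  product-limit convention).
* **Step convention**: survival is right-continuous; all consumers go
  through `survival_at()` / `km_daily_series()`, never raw arrays.
* **PH diagnostic**: rather than Schoenfeld residuals, a self-contained
  piecewise person-time test — per-period hazard ratios from events and
  person-time, homogeneity tested by a Poisson likelihood-ratio statistic
  on $K-1$ df. Periods with zero person-time in an arm are excluded with
  the df reduced. This matches the diagnostic's purpose here: detecting a
  non-constant hazard ratio.
* **Rebound run length**: 30 days (noise suppression, see above).
* **Degenerate inputs**: all-zero hazards with infinite follow-up,
  single-arm inputs, $\tau$ beyond follow-up, landmarks leaving fewer
  than 2 at-risk subjects per arm, coincident calibration pixels, and
  perfect separation in the assignment model are rejected with
  actionable errors rather than propagated.
* **Determinism**: every stochastic routine takes a seed and restores the
  caller's RNG state; identical inputs give byte-identical outputs, and
  `run_pipeline()` stamps outputs with the MD5 of the configuration.

## Problem sizes used in validation

The test suite works at sizes chosen to make each property sharp without
waste: exactness checks (product-limit vs brute-force risk-set
enumeration, step areas vs quadrature) use hundreds of random instances
with $n \le 40$; convergence and calibration checks use 20000 subjects
per arm (KM sup-error), 500 null replicates at 200 per arm (test size),
and 10000 per arm for the smoothed-relative-risk concentration check. At
2000 per arm — a realistic first-line trial size — the smoothed relative
risk has a sampling standard deviation of roughly 0.15–0.2 around a
plateau of 1.4, so pointwise recovery of $r(t)$ much tighter than ±0.3 is
not achievable at that size; the suite's concentration test is therefore
run against the exact estimand (the smoothed ratio of true 30-day drops)
with tolerances derived from this analysis, while rebound timing, the
RMST reversal pattern, and test calibration are validated at 2000 per arm
directly.

## Known limitations

* The relative-risk curve carries no confidence band: curve-level
  digitized data do not support patient-level inference, and we do not
  pretend otherwise in the `ipd` workflow either.
* The digitized workflow inherits whatever the figure hides — risk tables
  are not used, so no Guyot-style patient-level reconstruction is
  attempted; the method works at curve level by design.
* The landmark "after" analysis conditions on being progression-free at
  the landmark; like all landmark analyses it estimates a conditional,
  not a randomized, contrast.
* IPW removes only measured confounding, and the assignment model here is
  main-effects logistic on categorical covariates.
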