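---
title: "Methods: radiation-driven potato yield simulation and gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiation-driven potato yield simulation and gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potatogap)
```

# The model and its assumptions

`potatogap` simulates *potential* potato production: growth limited only
by temperature and radiation, with water, nutrients and disease assumed
non-limiting. That assumption is what makes the simulated yield an upper
bound against which actual farm yields can be compared (the yield gap).
The daily loop is the classic light-interception-and-utilization (LINTUL)
structure:

1. **Thermal time.** Each day contributes
   $\max\{0, (T_{max}+T_{min})/2 - T_b\}$ °C·d from the emergence day
   onward (the emergence day's own increment counts; earlier days
   contribute nothing). The daily mean of the two temperature extremes is
   the coarsest standard estimator of mean temperature; nothing finer is
   available from monthly climate tables anyway.
2. **Canopy.** Fractional ground cover follows the beta growth function
   $W(t)=W_{max}\left(1+\frac{t_e-t}{t_e-t_m}\right)\left(\frac{t}{t_e}\right)^{t_e/(t_e-t_m)}$
   of thermal time $t$, with $0 \le t_m < t_e$. The function is exactly 0
   at $t=0$, exactly $W_{max}$ at $t_e$, and has its maximum growth rate
   at $t_m$ — the property test in the suite locates the numerical argmax
   of the derivative for every bundled parameter set and confirms it sits
   at $t_m$ within grid resolution.
3. **Interception and growth.** Intercepted PAR on a day is
   $f_{PAR} \cdot SR \cdot W$ and biomass is RUE times cumulative IPAR.
4. **Partitioning.** The harvest index follows the Gompertz curve
   $HI(t) = A\,e^{-e^{-(t-T_u)/b}}$; tuber dry mass is $HI \times$
   cumulative biomass, and fresh yield at maturity is tuber dry mass
   divided by the dry-matter fraction, times 0.01 (g·m⁻² → t·ha⁻¹).

Tuber mass is computed as harvest index times biomass (the
dynamic-harvest-index approach) rather than by integrating a partition
rate: it matches the definition of the harvest index as a mass ratio,
keeps tuber ≤ total mass structurally true, and needs no extra state.

# Parameter choices that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| base temperature $T_b$ | 2 | °C | the common potato convention; configurable per `crop_parameters()` |
| PAR fraction $f_{PAR}$ | 0.5 | – | PAR is conventionally half of total solar radiation; applied **once** |
| dry-matter fraction | 0.20 | – | typical tuber dry-matter content; fresh yield scales as its inverse, so it is the single most consequential constant and is prominently configurable |
| g·m⁻² → t·ha⁻¹ | 0.01 | – | unit identity |

The single application of the 0.5 PAR conversion deserves a note: some
formulations write the interception sum with an additional factor of
one half, which would amount to converting to PAR twice. We apply the
conversion once, because double-halving makes the RUE values that
practitioners report for potato (≈2.5–5.5 g·MJ⁻¹ of intercepted PAR)
dimensionally inconsistent with LINTUL norms. `par_fraction` is exposed
for users who want a different radiation partition.

Similarly, the Gompertz curve is parameterized with $b$ as a
thermal-time *scale* ($e^{-(t-T_u)/b}$) rather than a rate multiplier
($e^{-(t-T_u)\cdot b}$): with scale values of 150–470 °C·d — the
magnitudes of the bundled parameter sets — the rate reading would
collapse the curve to a step function, and only the scale reading makes
$T_u$ the thermal time of the maximum partition rate, which is what the
parameter is called.

**Canopy beyond $t_e$.** The beta function is undefined past $t_e$;
cover is held at $W_{max}$ until an optional senescence onset day, then
declines linearly to zero at maturity. By default no senescence is
applied (the run ends at harvest); pass `senescence_day` — ideally the
observed date of 50 % death of the above-ground canopy — when the
maintenance phase demonstrably ends before harvest.

**Thermal-time clock.** The origin is the emergence day by default
(emergence is recorded separately from sowing in field surveys, and the
bundled tuber-initiation thermal times are consistent with an
emergence-based clock); `origin_day` makes the sowing-based convention
available.

# Estimation procedures

All curve fits are Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) with parameter/function tolerance $10^{-10}$ and up
to 500 iterations, under box constraints that keep parameters in their
scientific domain ($W_{max}, A \in (0,1]$, thermal times positive).
Starting values are data-driven — amplitude from the maximum observed
response, $t_m$/$T_u$ from the largest finite-difference growth rate
computed on per-date means (replicate readings share a date), scales from
the observed span — and five deterministically jittered restarts are
always explored, keeping the lowest-RSS convergent fit. Non-convergence
is flagged on the returned object, never silently dropped; a flat
response (e.g. an all-zero harvest-index series) is flagged as
non-identifiable rather than returned as an arbitrary parameter vector.
Inputs are sorted internally, making every fitter invariant to row order.

RUE is the slope of the regression of total dry biomass on cumulative
IPAR **through the origin**: zero interception cannot produce biomass,
and freeing the intercept just donates one degree of freedom to noise
(an `intercept = TRUE` diagnostic mode exists). The days-to-1 %-cover
summary fits a quadratic to the early-season observations only (up to the
first local maximum of cover), because a parabola is a local
approximation of the establishment phase, not of the full trajectory,
and returns the smallest real root of cover = 1 % inside the observed
span — roots outside the span are extrapolation and are rejected.

Yield-gap accounting averages potential yields across genotypes within a
season (unweighted — the bundled data have one run per cultivar) and
differences against the season's actual yield after rounding the mean to
one decimal, so that reported gaps are exactly consistent with
fixed-precision potential yields; `digits = Inf` differences unrounded
means. The disease index used in the yield regression is the AUDPC
normalized by (time span × 100), i.e. the fraction of the worst-case
epidemic area, which puts intercepts and slopes on an interpretable
\[0, 1\] predictor scale; raw AUDPC can be passed instead.

# The synthetic-data generator

`generate_trial()` emulates one season's field trial with known truth,
which is what makes the estimation chain testable without any external
data:

- **Weather**: monthly climate disaggregated to days; day-to-day Gaussian
  jitter of the daily mean temperature and radiation is re-centred within
  each month, and rainfall is split with Gamma-weighted shares — so
  monthly means and totals are conserved *exactly* at any jitter level,
  and the zero-jitter configuration reduces to plain disaggregation. The
  monthly diurnal range is kept, so `tmax ≥ tmin` holds by construction.
- **Observations**: canopy cover = beta curve + additive Gaussian noise
  (sd 0.02, truncated to \[0, 1\]; the scale of image-segmentation
  error); destructive biomass samplings = true biomass × log-normal
  factor (CV 5 %); harvest-index readings = Gompertz curve + additive
  Gaussian noise (sd 0.03); tuber mass = HI reading × sampled total, so
  the tables stay internally consistent. Three replicate readings per
  sampling date emulate the three-replication randomized-block layout of
  the emulated trial; sampling cadence is 10 days.
- **Epidemic**: the uncontrolled treatment carries a logistic severity
  curve whose diseased canopy fraction stops intercepting radiation —
  the epidemic terminates the growth cycle early — while the controlled
  treatment suppresses 97 % of severity. Severity readings (7 per
  season) get Gaussian noise (sd 3 points, clipped to \[0, 100\]).

The default truth parameters (wmax 0.92, tm 449, te 1027 °C·d; A 0.97,
Tu 545, b 186 °C·d; RUE 3.13 g/MJ) are representative autumn-season
magnitudes, chosen once for good conditioning (the curves' action spans
the observation window).

What the generator does **not** emulate: spatially correlated plot
effects, temporally autocorrelated weather, canopy-image segmentation
artifacts, or measurement-protocol drift. Passing recovery tests
therefore demonstrate that the estimators are correct and
well-conditioned under the stated noise model — not that field data of
arbitrary quality will yield 5 % accuracy.

# Problem sizes and numerical checks

The test suite and the acceptance script use: 20 seeded replicate trials
for the parameter-recovery experiment (median relative error of all
seven parameters is required ≤ 5 %, and a noise-free round trip ≤ 0.1 %);
1000 random severity series for the AUDPC/trapezoid equivalence; a
0.5 °C·d derivative grid for the maximum-rate property; and 210-day
(7 × 30) disaggregated seasons for the spring simulations. These sizes
keep every check well inside interactive runtimes while leaving the
stochastic checks enough replicates for stable medians.

Floating-point guards: the beta kernel clamps to $[0, W_{max}]$ (the
power term can overshoot by an ulp near the endpoints), and the analytic
tuber-initiation inversion
$t = T_u - b\,\ln(-\ln(\theta/A))$ is cross-checked against bisection in
the tests.

# Known limitations

- **Reconstructed weather.** When only monthly climate tables are
  available, disaggregation at 30 days/month conserves monthly aggregates
  but erases within-month structure; simulated cultivar yields driven by
  reconstructed weather are order-of-magnitude results, and fine yield
  *differences between cultivars* — which trade off RUE against canopy
  and partition timing — are sensitive to it. The bundled spring runs
  reproduce the reported seasonal magnitude but not the reported
  cultivar ordering; the pinned regression values in the test suite
  document exactly what this package computes under these inputs.
- **Dry-matter fraction.** Fresh yield scales as $1/\mathrm{DM}$; a
  0.18–0.24 plausible range moves yields by ±10–20 %. Measure it when
  fresh-yield accuracy matters.
- **Potential production only.** No water, nitrogen, frost or CO₂
  response is modelled, by design; the simulator must not be used as a
  forecasting tool for actual yields.
- **Actual yields are inputs.** The gap side of the analysis is
  bookkeeping on survey data, never simulation.
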