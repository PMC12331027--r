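# potatogap

Radiation-driven potential-yield simulation and yield-gap analysis for
potato (*Solanum tuberosum* L.), with the parameter-estimation,
late-blight epidemic and synthetic-trial machinery needed to run the
whole analysis chain end to end.

## The problem

The yield gap — the difference between the *potential* yield a cultivar
could reach in a given season under non-limiting water, nutrients and
disease pressure, and the *actual* yield in farmers' fields — tells
agronomists where intensification effort pays off. Potential yield
cannot be observed directly; it is simulated. This package implements
the light-interception-and-utilization (LINTUL-type) daily loop used by
potato crop models, parameterized from ordinary field observations:
canopy-cover imaging, destructive biomass samplings and weather-station
records. It targets users studying multi-season potato systems (the
bundled reference data cover the spring, autumn and early-spring
cropping seasons of Yunnan, southwestern China), but all components take
generic inputs.

## The model

All growth is driven by cumulative thermal time
`TT(d) = Σ max(0, (Tmax + Tmin)/2 − Tb)` (base temperature `Tb = 2` °C,
clock started at crop emergence). Three curves and one efficiency
constant define a cultivar-season run:

- **Canopy cover** follows the beta growth function
  `W(t) = Wmax (1 + (te − t)/(te − tm)) (t/te)^(te/(te−tm))`, `0 ≤ tm < te`,
  rising from 0 to `Wmax` at `te` with its fastest growth at `tm`.
- **Interception**: daily intercepted PAR is `0.5 × SR × W`, PAR taken as
  half of total solar radiation `SR`; `IPAR` is its running sum.
- **Growth**: dry biomass is `RUE × IPAR` (radiation-use efficiency, g MJ⁻¹,
  estimated as the through-origin regression slope of biomass on IPAR).
- **Partitioning**: the harvest index follows the Gompertz curve
  `HI(t) = A e^{−e^{−(t − Tu)/b}}`; tuber dry mass is `HI × biomass`, and
  fresh tuber yield is `tuber dry mass / dry-matter fraction × 0.01`
  (g m⁻² → t ha⁻¹; dry-matter fraction defaults to 0.20).

Around the simulator sit the estimation procedures (nonlinear least
squares for both curves, the RUE regression, a quadratic interpolation
for days to 1 % canopy cover), seasonal yield-gap accounting, late-blight
analysis (AUDPC by the midpoint formula, disease-index/yield regression,
logistic tuberization-curve fits, controlled-vs-uncontrolled yield
increase), and a seeded synthetic-trial generator with known ground
truth.

## Worked example

```r
library(potatogap)

p <- crop_parameter_set("Yunshu 505", "spring")
w <- disaggregate_monthly(load_climate("spring"), 30)
simulate_growth(w, p, emergence_day = 44, maturity_day = 164)
#> Potential-growth simulation
#>   emergence day 44, maturity day 164 (164 simulated days)
#>   thermal time at maturity : 1709 degree C d
#>   peak canopy cover        : 0.990
#>   cumulative IPAR          : 718.8 MJ m-2
#>   final dry biomass        : 3163 g m-2
#>   final harvest index      : 0.782
#>   fresh tuber yield        : 123.7 t/ha
```

The run turns the season's reconstructed daily weather into 1709 °C·d of
thermal time; the canopy intercepts 718.8 MJ m⁻² of PAR, which at
4.4 g MJ⁻¹ becomes 3.2 kg m⁻² of dry biomass, 78 % of it in tubers by
maturity — 123.7 t ha⁻¹ of fresh tubers under potential conditions.

Seasonal yield-gap accounting over the bundled records:

```r
gap_report(reference_yield_records())
#>         season n_genotypes mean_potential actual    gap relative_gap_pct
#> 1       spring           3          125.6  19.60 106.00         84.39490
#> 2       autumn           3           45.3  15.27  30.03         66.29139
#> 3 early_spring           3           56.4  20.72  35.68         63.26241
```

Spring potential averages 125.6 t ha⁻¹ against a 19.6 t ha⁻¹ actual —
a 106 t ha⁻¹ gap (84 % of the potential), the largest of the three
seasons.

A synthetic trial exercises the estimation chain against a known truth:

```r
trial <- generate_trial(synthetic_config(seed = 42))
fit_beta_canopy(trial$canopy)
#> Beta canopy growth-curve fit (cover vs tt)
#>   coefficients:
#>      wmax        tm        te
#>    0.9222  468.0978 1018.0678
#>   RSS 0.02018, R^2 0.9952, 9 iterations, n = 42
```

(the generating truth was `wmax = 0.92, tm = 449, te = 1027`), and the
late-blight comparison on the same trial gives an AUDPC of 5240 %·days
uncontrolled vs 302 %·days controlled and an 89.3 % yield increase under
fungicide protection.

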