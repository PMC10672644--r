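# osteosim

Simulation and calibration of menopausal and age-related bone loss, for
researchers studying how bone turnover, focal bone balance and mechanical
loading jointly shape the bone mineral density (BMD) trajectory of the
femur through the menopausal transition — and when that trajectory crosses
the clinical osteoporosis threshold.

## The model

Bone is remodeled by basic multicellular units (BMUs) that resorb a packet
of tissue and refill it after a delay.  At each of a small ensemble of
femur sites (cortical to trabecular), the package steps a daily balance

```
dv_b/dt = v̇_f(t) − v̇_r(t)
v̇_r(t) = (A·v/T_R) ∫ over the trailing T_R days of Ṅ_bmu(τ) dτ
v̇_f(t) = (A·v/T_F) ∫ over [t−T_R−T_I−T_F, t−T_R−T_I) of Ṅ_bmu(τ)·f_bb(τ) dτ
```

where `Ṅ_bmu = f_or·S_v(p)` is BMU origination on free surface (Martin's
quintic in porosity), `f_or = f_bio·ζ_ref/(ζ+ζ_ref)` is activation
inhibited by the daily strain stimulus `ζ = (Σ N_i ε_i⁴)^(1/4)`, and the
focal balance `f_bb(ζ−ζ_ref)` is the mechanostat dead-zone curve.  The
reference stimulus accommodates as `dζ_ref/dt = φ(ζ−ζ_ref)`.  Tissue is a
stack of aging layers mineralizing as
`α(a) = α_max − (α_max−α_0)e^(−a/τ)`, so turnover and balance move BMD
(`ρ_m·v_m·v_b`) through two distinct channels: bone volume and mineral
content.

Menopause and ageing enter as multiplicative modifiers `κ(t)` on the
activation ceiling (increasing) and the focal-balance curve (decreasing):
unity before perimenopause onset (−4 y relative to the last menses), a
linear ramp to a permanent value at +4 y, then a linear ageing drift.
Fitted presets (`fbio_only`, `fbb_only`, `combined`) ship with the package,
and `fit_kappa()` re-estimates such parameters from any relative-BMD series
by deterministic least squares.

## Worked example

```r
library(osteosim)

## forward simulation under the combined menopause + ageing preset
sim <- simulate_remodeling(menopause_schedule("combined"))
summary(sim)
#>   t_years   bmd_rel       v_b alpha_mean  porosity
#> 1       0 0.9867881 0.6965976  0.6728208 0.3034024
#> 2       4 0.9441324 0.6655340  0.6728028 0.3344660
#> 3      15 0.6931402 0.5106736  0.6647989 0.4893264
```

Femur-average BMD falls to 98.7% of its premenopausal value by the last
menses, 94.4% by the end of perimenopause and 69.3% fifteen years after —
porosity rises from 0.30 to 0.49 while mean ash fraction barely moves,
because the combined scenario loses bone volume faster than mineral.

```r
## osteoporosis thresholds from reference population statistics
threshold_table()
#>           population ... bmd_s bmd_sd bmd_ref ... threshold
#> 1 non_hispanic_white ... 0.942  0.122   0.885 ...     0.720
#> 2 non_hispanic_black ... 1.026  0.134   0.990 ...     0.698
#> 3      mexican_white ... 0.950  0.113   0.919 ...     0.726

## when do ±30% load scenarios reach threshold 0.72?
over  <- simulate_remodeling(menopause_schedule("combined"),
                             load_schedule(1.3, tolc_years = 0), t_end = 28)
under <- simulate_remodeling(menopause_schedule("combined"),
                             load_schedule(0.7, tolc_years = 0), t_end = 28)
threshold_crossing_time(under, 0.72)   # 10.9 y after last menses
threshold_crossing_time(over, 0.72)    # 17.0 y
crossing_gap(under, over, 0.72)        # 6.14 y earlier under disuse
```

A sedentary (−30% load) trajectory reaches the osteoporosis threshold about
six years earlier than a +30% activity trajectory: disuse both removes
stimulus inhibition of BMU activation (more turnover at a resorptive
balance) and costs more than the symmetric overload gains.

```r
## close the loop: synthetic observations -> parameter recovery
obs <- generate_observations(menopause_schedule("combined"),
                             noise_sd = 0.005, seed = 1)
fit <- fit_kappa(obs, "combined")
coef(fit)
#> kappa_perm_fbio      slope_fbio  kappa_perm_fbb       slope_fbb
#>       1.271e+00       2.519e-04       9.165e-01      -3.863e-05
plot(fit)
```

The generator's truth was (1.230, 1.61e-4, 0.903, −4.452e-5); with 39
noisy half-yearly observations a single draw lands within a few percent on
the permanent multipliers, and the median over ten seeds is within 5%.

## Package layout

* `R/tissue.R` — composition, ash fraction, stiffness, densities, specific
  surface
* `R/bmu.R` — activation, origination, windowed formation/resorption,
  focal balance, layer stacks
* `R/stimulus.R`, `R/menopause.R` — daily stimulus, accommodation, κ(t)
* `R/engine.R`, `src/engine.cpp` — equilibrium initialization and the
  daily-step engine (pure-R reference + C++ fast path)
* `R/calibrate.R`, `R/synthetic.R` — `fit_kappa()` estimator and the
  seeded observation generator
* `R/osteo.R` — thresholds, crossing times, stage porosity, density-space
  export
* `vignettes/bone-remodeling-methods.Rmd` — model assumptions, parameter
  rationale, numerical choices, limitations
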