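---
title: "Modeling postmenopausal bone loss: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling postmenopausal bone loss: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(osteosim)
```

osteosim simulates how a woman's femur-averaged bone mineral density (BMD)
evolves through the menopausal transition, driven by the population dynamics
of basic multicellular units (BMUs) — the osteoclast/osteoblast teams that
continuously resorb and rebuild packets of bone — under mechanical feedback.
This vignette explains the model, the choices behind every tunable constant,
and what the package's tests do and do not demonstrate.

## Tissue state

Each material point ("site") carries a *layer stack*: an ordered sequence of
tissue layers, youngest at the surface, each with a thickness (its
contribution to the bone volume fraction $v_b$) and an age.  A layer's ash
fraction follows the secondary-mineralization law

$$\alpha(a) = \alpha_{max} - (\alpha_{max} - \alpha_0)\,e^{-a/\tau},$$

with primary level $\alpha_0 = 0.45$, asymptote $\alpha_{max} = 0.72$ and
$\tau = 1500$ days.  Fresh osteoid is therefore soft and mineral-poor;
decade-old tissue is saturated near $\alpha_{max}$.  From the
thickness-weighted composition the package derives stiffness
($E = 84370\,v_b^{2.58}\alpha^{2.74}$ MPa), volumetric BMD
($\rho_m v_m v_b$), material density and apparent density, using the
standard phase constants ($\rho_m = 3.2$, $\rho_o = 1.1$,
$\rho_w = 1.0$ g/cm³, organic fraction $v_o = 3/7$).

BMUs originate on free surface, whose density per unit volume is Martin's
quintic in porosity, $S_v(p) = 32.3p - 93.9p^2 + 134p^3 - 101p^4 + 28.8p^5$
(1/mm).  The curve is maximal in the cortical–trabecular transition zone,
which is what makes cortical bone vulnerable: as it porosifies, its free
surface *grows*, remodeling accelerates, and losses compound.  The published
quintic evaluates to 0.2/mm (about 5% of its peak) at $p = 1$ rather than
exactly zero; we keep the published coefficients rather than forcing the
endpoint, and the coefficients are configurable.

## BMU kinetics

The model iterates in 1-day steps.  Each day, at every site:

1. BMUs originate at density $\dot N = f_{or} S_v(p)$, where the activation
   frequency $f_{or} = f_{bio}\,\zeta_{ref}/(\zeta + \zeta_{ref})$ is the
   biological ceiling $f_{bio}$ (5e-3 /mm²/day) inhibited by the mechanical
   stimulus — half the ceiling under habitual loading.
2. Resorption integrates the origination history over the trailing
   $T_R = 24$ days; formation integrates the window delayed by the reversal
   phase, $[t - T_R - T_I - T_F,\ t - T_R - T_I)$ with $T_I = 18$,
   $T_F = 64$ days, each cohort weighted by the focal balance $f_{bb}$ that
   prevailed when it originated.  Both windows are scaled by
   $A_{bmu} v_{bmu} / T$; histories live in a ring buffer with O(1)
   incrementally-maintained window sums, which the tests check against
   naive re-summation.
3. The focal balance — bone formed per unit resorbed — is a piecewise-linear
   curve of the stimulus error $\zeta - \zeta_{ref}$: a dead zone of
   half-width $w = 1.5\times10^{-3}$ where remodeling is balanced, linear
   zones of width $v = 1.5\times10^{-3}$, saturation at 0.85 and 1.15.
4. The daily stimulus is the cycle-weighted strain norm
   $\zeta = (\sum_i N_i \varepsilon_i^4)^{1/4}$ over habitual load cases
   (5000 walking and 500 stair-climbing cycles/day; stair stress 1.2× the
   walking amplitude), with uniaxial strains $\varepsilon = \sigma/E$.  The
   reference stimulus accommodates slowly,
   $\dot\zeta_{ref} = \phi(\zeta - \zeta_{ref})$, $\phi = 10^{-4}$/day
   (explicit Euler; $\phi\,dt = 10^{-4}$ is deep inside the stability
   region, and the tests verify the $(1-\phi)^t \approx e^{-\phi t}$
   contraction to 0.1% at $t = 1/\phi$).

### Where resorption takes its bone from

Formation always deposits at the surface.  Resorption is split: a fraction
$\lambda = 0.7$ (`lifo_fraction`) is taken youngest-first from the surface
layers — the superficial, less-mineralized tissue that remodeling reaches
first — and the remaining 30% removes a proportional cross-section of all
layer ages, standing for BMUs that tunnel through older interstitial bone.
The tunneling share is what couples turnover to tissue age: with purely
surface-first resorption, balanced remodeling only churns the newest deposit
and the bulk never rejuvenates, so raising the activation frequency could
not lower mean mineralization — contradicting the behaviour this model
family is built to capture (turnover-driven scenarios de-mineralize the
skeleton at nearly constant bone volume).  $\lambda$ was fixed once so that
the premenopausal equilibrium mean ash is ≈ 0.67, the literature range for
adult cortical bone; it is configurable.

Layer stacks are bounded in size by merging the daily deposit into the
current surface layer while the latter is younger than `coalesce_days`
(30 days, thickness-weighted ages), i.e. layers effectively resolve tissue
age at monthly granularity against a mineralization time constant of
1500 days.

### Turnover scale

Only the product $A_{bmu} v_{bmu} \dot N$ enters the volume balance, so the
effective remodeling cross-section $A_{bmu}$ sets the absolute turnover
scale.  The default ($A_{bmu} = 1$ mm², $v_{bmu} = 0.04$ mm/day) puts
premenopausal turnover at ≈ 5%/yr at a cortical site, 15–20%/yr in the
transition zone and ≈ 14%/yr femur-averaged — the histomorphometric range.
Literature values quoted for the BMU section itself (≈ 2.8×10⁻² mm²) would,
inserted literally into the windowed rate equations above, give turnover
two orders of magnitude below physiological rates and a skeleton almost
inert on a 19-year horizon; $A_{bmu}$ here is therefore an effective
parameter lumping the section with the tunnel length each origination event
processes, and any calibration of the κ modifiers absorbs its residual
uncertainty.

## Menopause and ageing: the κ(t) modifiers

Hormonal change enters as two multiplicative modifiers of the premenopausal
constants: $\kappa_{fbio}(t) \ge 1$ scales the activation ceiling (more
turnover), $\kappa_{fbb}(t) \le 1$ scales the whole focal-balance curve
down (net resorption even in the dead zone).  Each is 1 until
perimenopause onset $t_1 = -4$ y (relative to the last menses), ramps
linearly to its permanent value $\kappa_{perm}$ at $t_2 = +4$ y, then
drifts linearly with ageing.  The drift slopes are interpreted **per day**,
matching the model's daily iteration; read per year they would be
negligible and could not produce any sustained postmenopausal decline.  The
ramp shape between $t_1$ and $t_2$ is not constrained by the data the
presets were fitted to; linear is the default, a smoothstep is selectable.
κ is floored at 0, so a collapsed balance modifier means no formation
regardless of stimulus.

Three fitted presets ship with the package (`menopause_schedule()`):
turnover-only (`fbio_only`: $\kappa_{perm} = 1.489$, slope 3.654e-4/day),
balance-only (`fbb_only`: 0.793, −7.085e-5/day) and `combined`
(1.230 / 1.610e-4 and 0.903 / −4.452e-5).  They are presets and
plausibility anchors, not quantities the package claims to re-derive: they
were originally estimated against literature BMD curves with an organ-level
finite-element model, neither of which is reproduced here.

## The site ensemble

The femur is represented by five independent material points spanning the
porosity range (bone volume fractions 0.95, 0.85, 0.60, 0.35, 0.20) with
mass weights (0.35, 0.25, 0.15, 0.15, 0.10) — a cortical-heavy mix loosely
following the compartmentation of a proximal femur.  All headline outputs
are normalized (BMD relative to its premenopausal value), which makes them
insensitive to the exact weights; the weights are configuration, not a
claim.  Each site's habitual stress amplitudes are solved at initialization
so that its daily stimulus equals the habitual target
$\zeta_{target} = 8\times10^{-3}$ — about 950 µε of walking effective
strain after cycle weighting — which places the dead zone
$w = 1.5\times10^{-3}$ at ±19% of habitual stimulus, consistent with
mechanostat adaptation bands.  Sites do not exchange load: there is no
stress redistribution between compartments, and no spatial map.

## Initialization and numerics

A simulation must start from remodeling equilibrium, otherwise initial
transients masquerade as menopausal change.  `init_site()` constructs the
stationary state analytically: history buffers pre-filled with the
equilibrium origination density, stimulus error centred in the dead zone,
and the layer stack carrying the stationary tissue-age distribution of the
mixed resorption process (an exponential of rate
$(1-\lambda)\,\mathrm{turnover}/v_b$, discretized in 30-day bins over six
mineralization time constants, the remainder lumped at its conditional mean
age).  The approximation relaxes to the model's own fixed point with a
residual $v_b$ drift that starts near $10^{-7}$/day and falls below that
within three simulated years, so `simulate_remodeling()` prepends a
discarded 5-year burn-in by default (`run_in_years`); with it, a 19-year
constant-conditions run holds femur-average relative BMD within 0.1% and
`equilibrate_site()` verifies drift below $10^{-7}$/day.

Two engines implement the identical day-step: a pure-R loop written
directly with the exported module functions (the readable reference) and a
C++ translation used by default, which carries each layer's mineralization
decay factor multiplicatively so a day costs one pass over the stack with
no transcendentals.  The test suite holds them to $10^{-9}$ relative
agreement over spans with menopause ramps and load steps; the forward model
is deterministic, and identical configurations are bit-identical.

## Calibration

`fit_kappa()` estimates $\kappa_{perm}$ and the ageing slopes from a
relative-BMD series by least squares: a coarse grid over the bounded
parameter box ($\kappa_{perm,fbio} \in [1,2]$,
$\kappa_{perm,fbb} \in [0.5,1]$, |slope| ≤ 1e-3/day, signs fixed by the
direction of each modifier), a refinement level centred on the parabolic
vertex through the grid optimum, then a bounded L-BFGS-B polish on scaled
numerical gradients.  The simplex polish that is conventional in this kind
of pipeline is selectable (`control$polish_method`), but the four-parameter
combined fit has a long curved valley in its mse surface on which a simplex
reliably stalls far from the floor, while the quasi-Newton polish tracks it;
this was the single largest accuracy factor in parameter recovery.

Relative series are pinned to 1 at their first observation.  When that
first observation is noisy, the pinning rescales the entire series by an
error factor the forward model cannot reproduce (its trajectory starts at
exactly 1), which biases the fit.  The objective therefore profiles out a
free multiplicative scale ($\min_c \overline{(c\,m_i - o_i)^2}$, default
`normalize = TRUE`), which also makes the fit exactly invariant to
rescaling the observations.  `bmd_mse()` itself is the plain mean squared
error.  The optimizer is fully deterministic; nothing in the fit draws
random numbers.

## The synthetic-observation generator

`generate_observations()` runs the forward model under a known schedule,
samples half-yearly over $[-4, 15]$ years (39 points, mimicking
biennial-to-annual densitometry follow-up), adds i.i.d. Gaussian noise of
sd 0.005 in relative units (the scatter scale of longitudinal densitometry
series), renormalizes the first point to 1, and records the truth.  It
emulates the *statistical structure* calibration assumes — plateau,
perimenopausal acceleration, sustained postmenopausal decline, additive
noise — not any particular published curve, and real series differ in ways
the tests therefore cannot vouch for: measurement error is neither i.i.d.
nor Gaussian across visits, cohorts mix women with different menopause
timing, and site-specific (forearm, spine, femoral neck) trajectories
differ from a femur average.  One shape caveat: under the per-day drift
interpretation the simulated decline keeps steepening after $t_2$ (the
balance deficit grows with the drift), so the steepest model segment lies
in late postmenopause rather than inside the perimenopausal window; tests
assert the plateau/decline structure, not where the steepest half-year
falls.

Under these conditions the end-to-end loop closes: with noise sd 0.005 and
39 observations, median recovery of the generating $\kappa_{perm}$ over ten
seeds is within 5% for all three scenarios (exact on noiseless data), which
is what the acceptance suite asserts.

## Clinical endpoints

The osteoporosis threshold is the WHO-style criterion expressed on the
normalized scale: $(\mathrm{BMD}_s - z\,\mathrm{BMD}_{SD}) /
\mathrm{BMD}_{ref}$ with $z = 2.5$ (exposed as a parameter), applied to
shipped young-adult and 40–59-y reference statistics for three
populations.  The statistics are carried at the three decimals their
published source reports, which leaves one row's conventional threshold
(0.727) a rounding ulp away from what its own inputs give (0.7263); the
package always reports what the inputs give.  Scenario comparisons use
0.72.  Crossing times are
linearly interpolated between daily samples on the femur-averaged
trajectory; `stage_porosity_change()` reports femur-average porosity change
per stage in percentage points per year, signed, which matches the
magnitudes this model family tabulates (a compounded-rate reading is also
conceivable but fits neither the experimental nor the simulated rows).

## A worked scenario comparison

```{r scenarios}
sch <- menopause_schedule("combined")
normal <- simulate_remodeling(sch, t_end = 28)
over <- simulate_remodeling(sch, load_schedule(1.3, tolc_years = 0), t_end = 28)
under <- simulate_remodeling(sch, load_schedule(0.7, tolc_years = 0), t_end = 28)
c(under = threshold_crossing_time(under, 0.72),
  normal = threshold_crossing_time(normal, 0.72),
  over = threshold_crossing_time(over, 0.72))
crossing_gap(under, over, threshold = 0.72)
```

```{r scenario-plot}
plot(normal, threshold = 0.72)
lines(over$time, over$femur$bmd_rel, col = "forestgreen")
lines(under$time, under$femur$bmd_rel, col = "firebrick")
legend("bottomleft", c("normal", "+30% load", "-30% load"),
       col = c("black", "forestgreen", "firebrick"), lty = 1, bty = "n")
```

The ordering is structural — more load means more stimulus, fewer
activations and a balance pushed toward formation — while the size of the
gap between the underload and overload crossings depends on the turnover
scale and stimulus calibration described above.

## Limitations

* The femur is an ensemble of independent points: no geometry, no load
  redistribution, no spatial maps of loss.
* Continuum layers cannot represent trabecular thinning or connectivity
  loss, and there is no microdamage accumulation.
* Only permanent (irreversible) κ changes are modelled; transient drug
  effects would need different κ shapes.
* The mineralization law and the tunneling fraction are calibration
  surrogates for processes this data cannot identify separately; their
  constants matter mostly through the normalized trends.
* Problem sizes in the tests are the study scale itself (19–28-year daily
  runs, five sites, ten-seed recovery studies); the compiled engine makes
  a full run a few tens of milliseconds, so nothing was scaled down.
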