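---
title: "From force plates to extinct bipeds: the models behind avigait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From force plates to extinct bipeds: the models behind avigait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avigait)
```

## The scientific problem

Ground-dwelling birds are the living relatives of extinct non-avian theropod
dinosaurs, and the only other extant obligate striding bipeds besides humans.
If we can describe quantitatively how avian gait — duty factor, stance
duration, stride length, and the shape of the ground reaction force (GRF)
waveform — changes with speed and body size, we can extrapolate those
relationships to bipeds we can never put on a force plate. `avigait`
implements that whole chain: conditioning raw single-footfall force-plate
records, describing their force-time profiles compactly, deriving
cross-species speed-scaling laws, and running the chain forward to predict
the gait of a hypothetical biped from nothing but its body mass, speed and
(optionally) leg length.

## Dimensionless framing

All kinematics are normalized by standing hip height $h$ and gravity $g$
(default 9.81 m s$^{-2}$, configurable because studies of extinct taxa
sometimes explore other values):

$$v^* = \frac{v}{\sqrt{gh}}, \qquad
  t^*_{stance} = t_{stance}\sqrt{\frac{g}{h}}, \qquad
  S^* = \frac{S}{h},$$

where $v^*$ is the square root of the Froude number. Forces are expressed in
body weights (BW $= mg$) and stance time as a fraction $t \in [0,1]$ from
touchdown to liftoff. Posture is summarized by the degree of crouch
$DC = 1 - h/L$, with $L$ the summed interarticular lengths of femur,
tibiotarsus and tarsometatarsus: 0 is a fully erect limb, larger values are
more crouched. Larger animals stand more erect, so $DC$ falls predictably
with size — the key to estimating $h$ for a fossil skeleton where only $L$
is measurable.

## Conditioning force-plate records

`lowpass_filter()` applies a Butterworth design forward and backward. We read
"fourth-order, zero-lag" as a second-order design per pass (the squared
magnitude response is fourth-order), which is the standard convention in gait
analysis; `order = 4` selects the stricter reading. Signals are
reflect-padded before filtering; the default padding, `min(n - 1, max(12,
3*round(fs/cutoff)))` samples, scales with the filter's impulse-response
length because a fixed handful of samples cannot absorb the transient at low
cutoff-to-rate ratios.

`detect_stance()` takes the longest contiguous run of vertical force above a
noise threshold; the threshold defaults to three standard deviations of an
unloaded baseline segment when one is supplied, since "above the background
noise" must be quantified somehow — this default is a package convention, not
an empirical result.

`impulse_correction()` enforces dynamic consistency. In steady locomotion the
mean vertical force over a stride must equal body weight, i.e. the recorded
single-foot vertical impulse $I_z$ must satisfy $2 I_z = I_w$, with $I_w$
the body-weight impulse over the stride. Measurement error breaks this, and
the remedy is proportional rescaling of the vertical channel only:

$$F_z' = \alpha F_z, \qquad
  \alpha = \frac{m\,g\,t_{stance}}{2\beta \int_0^{t_{stance}} F_z\,dt}.$$

## The sine-series waveform description

A normalized profile on $t \in [0,1]$ is written as
$f(t) = a_0 + \sum_n (a_n \sin(\pi n t) + b_n \cos(\pi n t))$. Two numerical
points matter:

* The half-range sines $\sin(\pi n t)$ are orthogonal on $[0,1]$, so the
  sine-only coefficients are trapezoid-rule projections
  $a_n = 2\int_0^1 f \sin(\pi n t)\,dt$. Sines and cosines of these
  frequencies are *not* mutually orthogonal on the half range, so the full
  fit must be a joint linear least squares; `fit_fourier()` does both, with
  `sine_only = TRUE` the default.
* Profiles are linearly resampled to 1001 uniform points before fitting.
  This harmonizes source records sampled anywhere from 50 Hz to 10 kHz and
  is accurate to well below the $10^{-4}$ BW round-trip tolerance the tests
  enforce for band-limited profiles.

The sine-only representation vanishes identically at $t = 0$ and $t = 1$,
matching the physics (no force before touchdown or after liftoff). Power
analysis across empirical bird data shows cosine terms contribute under
0.7% of signal power and about three harmonics carry 99% of the vertical
signal; the model-facing representation is therefore sine-only, truncated at
$n = 10$. The ratio of the first two vertical coefficients, $Za_2/Za_1$, is
a magnitude-normalized skew measure: negative values give late-skewed
(second hump dominant) profiles, as at very slow speeds; positive values
give the early-skew characteristic of birds at speed.

## Whole-stride centre-of-mass mechanics

With the duty factor $\beta$ known, one footfall is superimposed on itself at
a half-stride offset to synthesize the total two-foot force over a stride
(`synthesize_whole_stride()`; 2000-sample stride grid, linear
interpolation). The vertical profile is rescaled so its stride mean is
exactly 1 BW, and `integrate_com()` integrates accelerations to velocities
and position under steady-state constants: stride-mean vertical velocity
zero, stride-mean forward velocity equal to the measured speed. Integration
uses a cumulative trapezoid rule on the periodic grid, so an
impulse-balanced stride closes exactly (net velocity change at the level of
rounding error, reported as `net_dvz`). Predicted fore-aft profiles carry a
small spurious net impulse because fitted odd harmonics need not cancel;
`demean_fx = TRUE` (default) subtracts the stride mean before integration so
the single-stride problem stays well posed.

Percent congruity is the percentage of stride intervals where the KE and PE
slopes share sign — 0% for pure vaulting (pendular exchange), 100% for pure
bouncing. Intervals with slopes within $10^{-9}$ of each curve's range are
excluded as numerical noise at the extrema. Note that a biped with aerial
phases cannot reach 100% congruity no matter how spring-like its stance,
because KE and PE must trade during ballistic flight; the bouncing extreme
is realized by grounded running at $\beta \approx 0.5$, and the test suite's
directional check is built accordingly. Net vertical displacement (NVD) is
the peak-to-peak vertical COM excursion, reported in metres and as a
fraction of hip height.

## The regression protocol

Each variable's dependence on $v^*$ is fitted per species with three
candidate forms — linear $Av^*+B$, power I $A{v^*}^B$, power II
$A{v^*}^B + C$ — by least squares *on the untransformed variables* (power
fits via Levenberg–Marquardt, initialized from the log-log OLS solution).
Untransformed fitting weights the upper end of the range properly when the
goal is prediction rather than allometric inference. The power II offset $C$
is estimated once from the pooled all-species data and then held fixed per
species, so each species estimates only two free coefficients and spurious
local minima are avoided. Model choice is an AIC majority vote across
species, with ties broken towards the simpler form (parsimony; the tie rule
is a package convention). AIC uses the Gaussian form
$n\ln(SS_{res}/n) + 2k$ with the error variance counted in $k$. Fitted
coefficients are then regressed on $\log_{10} m$; when the slope is
significant at $P = 0.05$ the coefficient becomes mass-modulated, otherwise
the cross-species mean is used. Slope significance for data violating
parametric assumptions is available via a permutation test
(`permutation_slope_test()`, two-sided on slope magnitude), and major-axis
fits (optionally through the origin) serve parity comparisons.

Phylogenetic regression (PGLS, Blomberg's K) is outside this package's
scope: in the source analyses phylogeny influenced under a fifth of the
coefficients, weakly, and changed no model choices of consequence.

## The forward model

`predict_locomotion(mass_kg, v_mps, leg_length_m)` chains everything:

1. Morphometrics: $L$ from mass if not given; $DC$ from $L$ (or from mass);
   $h = L(1-DC)$. The direct $h$–$L$ power law is also reported but is known
   to over-predict at large size (it would give a 3.1 m-legged theropod a
   3.11 m hip height; the crouch route gives 2.99 m). The crouch route is
   the default because it drives all downstream numbers.
2. Kinematics: $v^*$, then $\beta$, $t^*_{stance}$, $S^*$ from the packaged
   speed-scaling laws, de-normalized through $h$.
3. Waveforms: the $Xa_2$–$Xa_5$ and $Za_1$–$Za_6$ laws evaluated at
   $(v^*, m)$, reconstructed on a 1001-point stance grid. The headline peak
   force is the reconstructed-profile maximum (peak timing by argmax with
   parabolic refinement); the direct regression prediction of each scalar
   feature is reported alongside as a cross-check, and the two routes agree
   within 20% across the calibrated speed range.
4. COM mechanics: whole-stride synthesis at the predicted $\beta$, percent
   congruity and NVD.

Inputs outside the calibration ranges (masses beyond 0.047–74.35 kg, $v^*$
outside about $[0.1, 3]$) warn but do not fail — extrapolation to extinct
taxa is the model's purpose; the warning marks where empirical support ends.

```{r tyrannosaurus}
p <- predict_locomotion(8000, 5, leg_length_m = 3.1)
p
```

### Known limitations

* The three kinematic laws are independent regressions, so the identity
  $S^* = v^* t^*_{stance}/\beta$ holds only approximately: within about 3%
  over the well-sampled mid-range of speed and mass, but degrading to roughly
  20% at the extreme corners (a 10-tonne biped at $v^* = 2$, or a 50 g bird
  at $v^* = 0.3$). The test suite asserts a 10% envelope over the full
  product grid and reports the observed maximum; that check documents this
  limitation rather than certifying the corners.
* The mediolateral force is neither modelled nor predicted (it shows no
  systematic speed dependence and is small), and KE excludes mediolateral
  velocity accordingly.
* The packaged laws describe birds, whose centre of mass sits well forward
  of the hip. Non-avian theropods with a more posterior COM likely had less
  skewed force profiles; applying the model to them inherits this caveat.

## The synthetic-data generator

`make_footfall()` builds records from known sine coefficients — zero force
at touchdown/liftoff by construction, configurable sampling rate, Gaussian
sensor noise in BW units, unloaded margins, and an optional deliberate
impulse inflation for testing the consistency correction.
`make_scaling_dataset()` draws per-trial $v^*$ uniformly (default 0.3–1.5,
the well-sampled empirical span) and generates each variable from its law
plus additive Gaussian noise; coefficient presets come from the packaged
laws themselves so fixtures are self-consistent with the model. Everything
is deterministic under a fixed seed.

What the generator does *not* emulate: heteroscedastic and correlated sensor
error, left/right force asymmetry ("mixed gaits"), head-bobbing artifacts,
and between-individual variation within species. Passing recovery tests on
these fixtures therefore demonstrates correctness of the algorithms, not
robustness to every pathology of real plate data.

## Test problem sizes

The suite fits Fourier round trips at 1001 samples, runs the regression
protocol recovery on 12 synthetic species with 20 trials each (100 noisy
replicates), and calibrates the permutation test's type-I error on 500 null
datasets of $n = 50$ at 2000 permutations each — sizes chosen to give stable
Monte-Carlo statistics while keeping a full run in well under half an hour
on one core.
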