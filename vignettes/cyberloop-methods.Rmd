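---
title: "Models and methods behind cyberloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cyberloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyberloop)
```

`cyberloop` simulates external feedback control of gene expression in yeast:
a computer measures a population's fluorescence every five minutes and
decides, through a PI controller encoded as binary sugar pulses, whether the
cells see galactose (inducing) or glucose (repressing) next. This vignette
documents the models, the numerical choices, and the design decisions the
package makes, in enough detail to judge what its simulations do and do not
show.

## 1. Plant models

### GAL1 promoter

The one-gene plant is the linear production/decay model

$$\dot y = v_{\max}\,u(t - \ell) - \delta\, y,$$

with binary input $u \in \{0,1\}$, maximal production $v_{\max}$
(fluorescence units/min), decay $\delta$ (1/min, lumping degradation and
growth dilution) and an optional transport lag $\ell$ (min). It is solved
exactly (piecewise exponentials between input switches), so GAL1 plants
carry no integration error. Defaults $v_{\max} = 1$, $\delta = 0.01$ give a
maximum level of 100 fluorescence units and a 100-min time constant —
promoter-reporter kinetics on the timescale of a yeast cell cycle. This
model exists mainly to tune and sanity-check the controller: a linear,
delay-free (or purely transport-delayed) plant where every closed-loop
property can be verified against closed forms.

### IRMA network

The five-gene synthetic network is modelled as a hybrid (input-switched)
delay differential equation system in the species
$(x_1,\dots,x_5)$ = (Cbf1, Gal4, Swi5, Ash1, Gal80), each with basal
production $\alpha_i$, a Hill-regulated term with maximal rate $v_i$, and
first-order removal $d_i x_i$:

$$
\begin{aligned}
\dot x_1 &= \alpha_1 + v_1\,
  \frac{x_3(t-\tau)^{h_1}}{k_1^{h_1} + x_3(t-\tau)^{h_1}}\cdot
  \frac{k_2^{h_2}}{k_2^{h_2} + x_4(t-\tau)^{h_2}} - d_1 x_1
  &&\text{(CBF1: HO promoter)}\\
\dot x_2 &= \alpha_2 + v_2\,\mathrm{H^+}(x_1; k_3, h_3) - d_2 x_2
  &&\text{(GAL4)}\\
\dot x_3 &= \alpha_3 + u\, v_3\,
  \mathrm{H^+}\!\bigl(\tfrac{x_2}{1 + x_5/\gamma}; k_4, h_4\bigr) - d_3 x_3
  &&\text{(SWI5: GAL10 promoter)}\\
\dot x_4 &= \alpha_4 + v_4\,\mathrm{H^+}(x_3; k_5, h_5) - d_4 x_4
  &&\text{(ASH1)}\\
\dot x_5 &= \alpha_5 + v_5\,\mathrm{H^+}(x_3; k_6, h_6) - d_5 x_5
  &&\text{(GAL80)}
\end{aligned}
$$

with $\mathrm{H^+}(x;k,h) = x^h/(k^h + x^h)$. The wiring follows the
network's biology: Swi5 activates CBF1 at the HO promoter against Ash1
repression; Cbf1 activates GAL4; Gal4 — when not sequestered by Gal80
(protein–protein inhibition constant $\gamma$) — drives SWI5 from the
GAL10 promoter; Swi5 closes the positive loop through CBF1 and the negative
loop through ASH1, and feeds GAL80. The discrete input $u$ gates the GAL10
term: galactose ($u=1$) enables Swi5 transcription, glucose ($u=0$) shuts
it off, giving two distinct vector fields switched by the sugar. The HO
promoter's slow chromatin remodelling is modelled as a pure transcriptional
delay $\tau$ on the CBF1 production term, which reads both of its
regulators at $t - \tau$.

**Calibration.** The numeric values shipped in
`inst/extdata/irma_params_default.conf` are the package's own default
calibration, chosen once against qualitative targets and not fitted to any
dataset: a several-fold Cbf1 separation between the galactose and glucose
steady states (7.4× at the defaults), switch-on settling within a few
hundred minutes (95% in ≈ 280 min), an essentially monotone switch-on step
response (Ash1 turnover is set fast enough that the delayed negative loop
does not overshoot the rise), a switch-off transient in which Cbf1 keeps
rising for ≈ τ after glucose arrives and then decays monotonically, and
$\tau = 100$ min, the order of magnitude reported for HO-promoter
activation in the network's original characterization. Degradation rates of
0.02–0.06 /min correspond to half-lives of 12–35 min including dilution.
All parameters are in model concentration units; the loop relates them to
fluorescence through an affine calibration map estimated per experiment.

### Integration

Both the single-cell and the ensemble IRMA plants use fixed-step classical
RK4 with a ring buffer of past states for the delayed term; off-grid lagged
lookups interpolate linearly inside the buffer, and the initial history is
a constant state (the pre-experiment steady state, matching the assumption
that cells enter the device in balanced growth). A fixed step was chosen
over adaptive integration deliberately: closed-loop runs are sequences of
thousands of short windows with discontinuous inputs, and a fixed grid
aligned with the PWM quantum makes every switch fall on a step boundary and
every run bit-reproducible. The input is held constant over each step
(evaluated at the left endpoint). Steps that undershoot zero are clipped to
zero with a warning — Hill terms have no meaning at negative
concentrations; at the default step (0.5 min single-cell, 1 min ensemble)
clipping never triggers in the shipped experiments. Against a 100×-finer
forward-Euler oracle over 1000 min of input switching, the integrator
agrees to a relative error below $10^{-4}$; the test suite also
cross-checks the delayed model against an independent `deSolve::dede`
solution. Steady states are found by damped fixed-point iteration on the
production/degradation balance and verified to a vector-field residual
below $10^{-8}$.

## 2. Controller

**Sampling.** Everything runs on a $T_s = 5$ min grid — the imaging
cadence of the experimental platform this emulates.

**PI.** The controller acts on the *normalized* error
$e = (r - y_\mathrm{fb})/(y_{\max} - y_{\min})$, where the range comes from
the calibration phase, and outputs a level on the PWM scale $[0,1]$. The
integral is a rectangular (backward-Euler) sum $I \leftarrow I + e\,T_s$;
anti-windup freezes the integral whenever the unsaturated output exceeds
the limits and the error would push it further. Normalizing the error makes
the gains dimensionless and portable across plants.

**PWM.** A rising sawtooth of period $T_\mathrm{pwm} = 10$ min spanning
$[0,1]$ is compared with the PI level: the input is galactose while
level ≥ sawtooth, so the high time sits contiguously at the start of each
period and the duty equals the clamped level. Ties count as high, making
duty exactly 1 at saturation. Pulses are realized on a 0.5-min quantum
grid; the realized duty therefore matches the commanded level to within one
quantum per period (0.05), which is also the quantization floor visible as
a small ripple around any set-point. The sawtooth phase runs on absolute
time, so the two 5-min sampling windows inside each 10-min period join
seamlessly.

**Tuning.** `tune_irma_pi()` reproduces the classical recipe end to end: it
simulates the delayed model's 0→1 step response, normalizes the output by
its steady-state range, fits a first-order-plus-dead-time triple $(K,T,d)$
with the deterministic two-point construction
($T = 1.5\,(t_{63.2\%} - t_{28.3\%})$, $d = t_{63.2\%} - T$ — chosen over
tangent constructions because it needs no derivative estimates), and
applies Cohen-Coon PI rules. At the shipped calibration this yields
$K = 1$, $T = 74.2$ min, $d = 107.2$ min and $K_p = 0.707$,
$K_i = 0.0073$ /min. The rules are singular at $d = 0$, so delay-free
plants (GAL1) take explicit gains; the shipped GAL1 experiments use
$K_p = 2$, $K_i = 0.02$, picked in simulation for a well-damped response —
mirroring how such gains are selected empirically in-silico before an
experiment.

**Measurement filter.** A first-order low-pass (exact discretization
$y_f \mathrel{+}= (1 - e^{-\Delta t/T_f})(y - y_f)$) is available on the
measurement path; $T_f = 0$ disables it. In predictor runs the filtering
happens inside the predictor (below) rather than on the raw measurement.

## 3. Smith-type predictor

The predictor runs the *delay-free* internal model ($\tau_m$ forced to 0)
in parallel with the plant under the actually-applied input, producing an
anticipated output $\hat y(t)$, and keeps a history of $\hat y$ from which
it forms the delayed replica $\hat y(t - \tau_m)$. The feedback signal is

$$y_\mathrm{fb}(t) = \hat y(t) + \mathrm{LPF}\bigl(y(t) - \hat y(t-\tau_m)\bigr),$$

so with a perfect model the correction term vanishes and the PI sees a
delay-free plant; plant/model mismatch and measurement noise enter only
through the low-passed correction. The mismatch filter is first-order with
$T_f = 3\,T_s = 15$ min by default — wide enough to pass slow model error,
tight enough to suppress frame-to-frame measurement noise. Model units and
fluorescence are related by the affine map sending the calibrated
fluorescence range onto the model's own steady-state output range; the loop
recomputes this map from each run's calibration phase unless an explicit
map is supplied. The delayed replica is read from a stored ring of
$\hat y$ values (linear interpolation) rather than re-simulated, for
determinism and cost. For a plant whose delay is a pure transport delay the
construction is exact, and the test suite verifies the classical Smith
property there to $10^{-6}$: the predictor loop's error sequence equals the
delay-free loop's. For IRMA the delay sits *inside* the feedback loops, so
delaying the model output is an approximation — the same approximation the
experimental scheme makes — and its value shows up empirically as the
3× NRMSE improvement on delayed tracking.

## 4. Experiment automaton

`run_fsa_loop()` drives an experiment the way the platform's finite-state
automaton does. State 0 is calibration: constant-input phases (default
300 min galactose then 300 min glucose) during which the maximal and
minimal fluorescence are estimated as the mean of the last six samples
(30 min) of the respective phase; this range then anchors the reference,
the error normalization and the predictor's unit map. Then, per 5-min
sample: (1) the PI-PWM computes the input window from the current error;
(2) the internal model prediction advances; (3) the window is applied to
the plant; (4) the delayed predicted output is formed; (5) the new
measurement is ingested and the error recomputed. Exactly one input window
is emitted per sampling interval. References are specified as fractions of
the calibrated range: constant set-points, triangular waves (baseline 0.2,
peak 0.7, period 1600 min by default — one slow triangle over a day-long
run, the regime in which tracking is feasible for a plant with a 100-min
delay), and downward ramps. Negative-control modes replay the protocol
with a randomized (Bernoulli-½ per window, after first reaching the
set-point) or constant-galactose input. Metrics are computed over the
control-active interval only: NRMSE is the RMS of $y - r$ normalized by the
calibration range; settling is defined as $|e|$ first dropping below 10% of
the range.

## 5. Virtual cell population

The ensemble plant emulates a monolayer trap. Each of up to 1200 cells
follows the same IRMA model with per-cell multipliers on its production
rates (basal and maximal), drawn i.i.d. log-normal with unit median and a
target coefficient of variation of 0.3 — extrinsic noise on expression
capacity, the dominant source of cell-to-cell variability; thresholds,
Hill coefficients and degradation rates are shared. Cells start at their
own parameter set's steady state with ages uniform over one division
interval (desynchronized), divide on a deterministic age schedule
(doubling time 180 min, giving the 100 → 1200 growth inside a 2600-min
run; a stochastic-interval mode exists behind a flag), and daughters
inherit the mother's state and delay history with multiplier jitter.
Inheritance is mean-reverting in log space
($\log m_\mathrm{daughter} = \rho\,\log m_\mathrm{mother} + \mathcal N(0,
\sigma_j)$, with $\rho$ chosen so the multiplier distribution is
stationary): naive multiplicative jitter would random-walk the population
variance upward across generations, which contradicts both the i.i.d.
log-normal population model and the empirical observation the ensemble is
meant to emulate — a CV that stays flat while the population grows an
order of magnitude. At capacity, a division evicts the oldest cell
(wash-out). The readout is the population mean of per-cell fluorescence
(affine in Cbf1), with the population (divide-by-N) SD convention for the
per-frame SD and CV, plus additive Gaussian measurement noise on the mean
(SD 1 fluorescence unit ≈ 1% of range). The whole ensemble advances as one
vectorized RK4 on an N×5 state matrix with a shared delay ring buffer, so
a 2600-min closed-loop run at 1200 cells takes seconds. All randomness
flows from the configuration seed; runs are bit-reproducible.

What this generator does *not* emulate: intrinsic (birth–death)
transcriptional noise, spatial crowding and nutrient gradients in the trap,
cell-cycle-dependent expression, and segmentation errors feeding back into
control (the imaging chain is validated separately). Closed-loop robustness
results on the ensemble therefore speak to extrinsic-noise and
population-turnover robustness, not to every noise source of a wet
experiment.

## 6. Imaging chain

The measurement pipeline mirrors a phase-contrast segmentation stack, and
ships with its own scene generator so it can be scored against ground
truth. Rendered scenes place ~100 cells of radius 5–8 px in a 256-px frame
by seeded rejection sampling (centers at least 0.95× the radius sum apart —
crowded but mostly non-fused), drawn as dark bodies with a 2-px bright rim
on a mid-grey background, plus Gaussian optics noise (SD 0.02); the
fluorescence channel carries each cell's intensity on a dark background.

Segmentation proceeds: (1) Otsu binarization of the phase image — the
threshold maximizing between-class variance over a 256-bin histogram, with
the cell class identified as the one unlike the image border; (2) connected
components (via `EBImage::bwlabel`) replaced by their convex hulls, whose
padded bounding boxes restrict the subsequent search; (3) a circular Hough
transform with gradient-direction voting: every strong-gradient pixel votes
at the two points ±r along its gradient for each integer radius in 4–12 px,
accumulators are 3×3-box-smoothed and circumference-normalized, and peaks
above a score of 0.65 are accepted greedily with non-maximum suppression
(no two centers within 2·r_min). The score threshold sits between the two
empirical score populations — true rims concentrate ≳ 0.85 of a
circumference of votes, spurious inter-cell coincidences ≲ 0.55 — giving
recall and precision above 0.99 on rendered frames with center error below
1.5 px. (4) The quantification mask is the union of detected disks eroded
by 1 px (keeping the mask inside cell bodies), and the loop's measurement
is the mean fluorescence over the mask, within 3% of the true mean cell
intensity on rendered frames. A frame with zero detections is flagged and
the previous measurement is carried forward, so a control run never crashes
on a bad frame.

## 7. Reproducibility and problem sizes

Every stochastic component draws from an explicit seed (ensemble
initialization, measurement noise, scene placement and rendering,
negative-control inputs), and identical seeds give byte-identical outputs,
including recipe CSVs. The shipped experiments use the sizes at which their
conclusions are stable and each run stays light: 0.5-min integration steps
for single-cell runs and 1-min for ensembles, 2400-min tracking runs
(1.5 triangle periods), 2000-min set-point and robustness runs, 20 rendered
frames for imaging scores. `scripts/acceptance.R` recomputes all headline
quantities from scratch at exactly these sizes.

## 8. Known limitations

* The IRMA calibration is qualitative. Absolute concentrations, rates and
  the delay are plausible-scale defaults, not fitted values; conclusions
  should be read as properties of the control architecture on a realistic
  network, not predictions for a specific strain.
* The delay is a single lumped transcriptional lag on one term; chromatin
  dynamics are not modelled mechanistically, and the predictor's delayed
  replica is exact only for transport delays.
* The binary-input abstraction is ideal: media switches are instantaneous
  and complete, with no mixing dynamics or uptake kinetics.
* The PI output quantizes to one PWM quantum per period (0.05 duty), which
  floors the achievable steady-state ripple.
* Imaging is validated on rendered scenes; real phase-contrast artifacts
  (halos, debris, focus drift) are out of scope.
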