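# cyberloop

In-silico closed-loop control of gene expression in growing yeast populations.

## The problem

External ("cybergenetic") feedback control regulates the expression of a
protein in living cells by measuring a fluorescent reporter in real time and
actuating an environmental input — here the sugar fed to *S. cerevisiae*:
galactose switches the relevant promoters on, glucose switches them off. The
control loop is unusual by engineering standards: the input is strictly
binary (cells ignore galactose whenever glucose is present), the plant is a
noisy, growing population of cells rather than a single device, measurements
arrive every 5 minutes through an image-segmentation pipeline, and in
networks where the reporter sits several transcriptional steps away from the
input the response is delayed by on the order of 100 minutes.

`cyberloop` is a desk-scale simulation platform for this problem, aimed at
control engineers and systems biologists who want to design and stress-test
such loops before (or instead of) running a microfluidics experiment. It
provides:

* **Plant models** — a one-gene GAL1 promoter model
  (dy/dt = v·u(t−lag) − d·y) and a five-species hybrid delay differential
  equation model of the IRMA synthetic network (CBF1, GAL4, SWI5, ASH1,
  GAL80), in which galactose (u = 1) gates GAL10-promoter-driven Swi5
  production and HO-promoter-driven Cbf1 production reads its regulators a
  delay τ in the past.
* **Controller** — a discrete-time PI regulator on the range-normalized
  error, u(t) = sat(Kp·e + Ki·∫e dt), encoded into binary sugar pulses by
  pulse-width modulation against a 10-min sawtooth; gains come from
  Cohen-Coon rules, Kp = (1/K)(T/d)(0.9 + d/(12T)),
  Ti = d(30 + 3d/T)/(9 + 20d/T), applied to a first-order-plus-dead-time fit
  of the model's own step response.
* **Smith-type predictor** — a delay-free internal model run in parallel
  with the plant; the loop feeds back ŷ(t) + LPF(y(t) − ŷ(t−τ)), removing
  the delay from the loop dynamics.
* **Virtual cell population** — 100 → 1200 cells with log-normal extrinsic
  variability on production rates (CV ≈ 0.3), age-based division and trap
  eviction, measured as a population-average fluorescence.
* **Imaging chain** — synthetic phase-contrast/fluorescence frame rendering,
  Otsu binarization, convex-hull region grouping, a circular Hough transform
  for cell localization, and masked fluorescence quantification.

## Worked example

Tune a PI controller from the delayed IRMA model's step response, then
compare triangular-wave tracking with and without the predictor:

```r
library(cyberloop)

p <- irma_default_params()          # shipped calibration, tau = 100 min
tn <- tune_irma_pi(p)
tn$fit
#> First-order-plus-dead-time fit (two-point 28.3%/63.2% method)
#>   K = 1, T = 74.247 min, d = 107.2 min
tn$pi
#> PI controller: Kp = 0.70668, Ki = 0.0072729 1/min, Ts = 5 min,
#>   limits [0, 1], anti-windup on

ref <- reference_spec("triangular", f = 0.2, f_peak = 0.7, period = 1600)
plain <- run_fsa_loop(irma_plant(p, u0 = 0), tn$pi, ref_spec = ref,
                      duration = 2400)
pred  <- run_fsa_loop(irma_plant(p, u0 = 0), tn$pi, ref_spec = ref,
                      predictor = predictor_config(p, tau_m = p$tau),
                      duration = 2400)
compute_metrics(plain)$nrmse
#> [1] 0.3027263
compute_metrics(pred)$nrmse
#> [1] 0.1011982
```

The plain PI-PWM loop oscillates around the reference (range-normalized
RMS tracking error ≈ 0.30) because the 100-min transcriptional delay eats
its phase margin; the predictor loop tracks the same reference three times
more tightly (≈ 0.10). With `tau = 0` both loops perform equivalently —
the predictor is only needed when the delay is long relative to the
reference dynamics.

Canned experiments (switch-off protocol, set-point regulation, tracking
with/without predictor, negative controls) live behind one call:

```r
run_recipe("s25_switchoff", out_dir = "out/")   # writes CSVs, JSON, plots
```

A thin CLI wrapping the same functions is installed at
`system.file("cli", "cyberloop", package = "cyberloop")` with verbs `run`,
`tune`, `metrics`, `recipe` and `segment`.

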