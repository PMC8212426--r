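# sparsacc

Detection of normal and pathologically slow saccades in eye-tracking
time-series by sparse-derivative denoising and velocity thresholding.

## The problem

Saccades — the rapid eye movements that redirect gaze — obey the *main
sequence*: peak velocity Vp saturates with amplitude A as

    Vp = eta * (1 - exp(-A / c))

with `eta` the subject's maximum attainable peak velocity (deg/s) and
`eta/c` the small-saccade slope. In brainstem disorders such as progressive
supranuclear palsy or internuclear ophthalmoplegia, saccades fall below the
normative main-sequence band ("slow saccades"), and recognizing them is
diagnostically decisive. Conventional detectors threshold a differentiated
position signal; differentiation amplifies tracker noise, and the gentle
velocity tail of a slow saccade disappears into it — typically the saccade's
*end* is misplaced and its amplitude badly underestimated.

`sparsacc` is written for researchers and clinician-scientists who analyze
eye-position recordings (degrees vs. seconds, 250–1000 Hz) and need event
detection that works for slow saccades without per-recording tuning.

## The method

The eye-position trace is modeled as *intermittent piecewise quadratic*:
constant during fixations (sparse first derivative), smooth
quadratic-like arcs during saccades (sparse third derivative). Denoising
minimizes the convex objective

    J(x) = 1/2 ||y - x||_2^2 + alpha ||D1 x||_1 + beta ||D3 x||_1

(`D1`, `D3` the first/third difference operators) by
majorization–minimization: each iteration reweights the penalties by
`1 / (|D x| + 1e-10)` and solves a banded linear system, computed here as a
banded least-squares problem via Givens QR in compiled code (O(n) per
iteration, numerically stable across the reweighting's 10 orders of
magnitude). The objective trace is guaranteed non-increasing. With
`beta = 0` this is classical total variation denoising.

The denoised velocity is exactly zero between saccades, so detection is a
fixed hysteresis threshold — open above 30 deg/s, close below 10 deg/s —
plus standard plausibility rules (blink proximity, 40 ms minimum
inter-saccadic interval, 12 ms minimum duration, 800 deg/s cap).
`alpha` and `beta` are set automatically from the data (estimated noise SD,
mean candidate-saccade amplitude and duration, with sampling-rate scaling):
no user tuning.

The package also ships the parametric saccade simulator used for
validation (soft-ramp waveform whose analytic peak velocity is exactly the
main-sequence value), velocity- and dispersion-threshold baseline
detectors, event-overlap evaluation metrics, main-sequence fitting, and a
small CLI (`inst/cli/sparsacc`) with `simulate` / `detect` / `evaluate` /
`benchmark` subcommands.

## Worked example

```r
library(sparsacc)

# 8 saccades at 500 Hz with heavy measurement noise (sigma = 0.4 deg)
sim  <- simulate_scanpath(n_saccades = 8, rate = 500, sigma = 0.4, seed = 7)
scan <- detect_saccades(sim$noisy)
scan
#> Saccade scan (proposed detector): 8 event(s) in 6.54 s of data
#>   alpha = 3.212, beta = 8.279 (auto: sigma = 0.402 deg, A = 8.93 deg, D = 0.109 s, 10 candidates)

score_events(sim$truth, scan$events)
#> TP 8, FP 0, FN 0 | precision 1.000, recall 1.000, F1 1.000

head(scan$events[, c("onset_s", "offset_s", "amplitude", "peak_velocity")], 3)
#>   onset_s offset_s amplitude peak_velocity
#> 1   0.622    0.688 19.605312      547.3205
#> 2   1.062    1.106  8.918408      399.0103
#> 3   1.982    2.016  3.849434      202.3985
```

The estimated noise level (0.402 deg vs. true 0.4) drives the
regularization; all 8 events are recovered with no false alarms despite the
noise floor being ~100 deg/s on the raw differentiated signal. Detected
amplitudes and peak velocities can then be fed to `fit_main_sequence()` to
place a subject on (or off) the normative main-sequence band.

`plot(scan)` draws the noisy trace, the denoised estimate and the detected
events as shaded bars; `plot(gtv_denoise(...))` shows a denoising fit with
its objective trace.

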