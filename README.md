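# phasesmooth

Robust instantaneous-phase estimation for narrow-band oscillatory signals.

When the instantaneous envelope $A_t$ of an analytic signal
$\hat{x}_t = x_t + iH(x_t)$ approaches zero, the instantaneous phase
$\theta_t = \operatorname{atan2}(u_t, x_t)$ becomes an arctangent of two
noise-dominated small numbers and jumps wildly. In EEG phase-synchronization
analysis these *spurious phase variations* are easily mistaken for genuine
stimulus-locked phase resets. `phasesmooth` removes them by modelling the
band-passed analytic signal as a complex linear-Gaussian state space rotating
at the band's centre frequency,

$$\hat{s}_{t+1} = e^{i\omega_0}\hat{s}_t + \hat\eta_t,\quad
\hat\eta_t \sim \mathcal{CN}(0,\sigma); \qquad
\hat{x}_t = \hat{s}_t + \hat{W}_t,\quad \hat{W}_t \sim \mathcal{CN}(0,\alpha),$$

and running a simplified scalar-covariance Kalman smoother (forward filter
plus Rauch–Tung–Striebel backward pass). Phase excursions at low envelope are
small complex displacements and get flattened; genuine phase resets are large
displacements and survive. The package is aimed at researchers analysing
oscillation phase (EEG/LFP rhythms, phase-locking studies) who need phase
trajectories that do not invent resets where the signal momentarily vanishes.

It provides, as tidyverse-style functions over tibbles:

- `compute_analytic()`, `decompose_phase()`, `flag_low_envelope()` — Hilbert
  analytic signal; envelope, wrapped/unwrapped phase, residual
  $r(t) = p(t) - \omega_0 t$ and instantaneous frequency; low-envelope masks;
- `ensemble_filter()` — M zero-phase IIR elliptic narrow-band filters with
  slightly perturbed centre frequencies, for robust phase estimation;
- `forward_pass()`, `backward_pass()`, `smooth_phase()` — the Kalman
  smoother, with `tidy()`/`glance()`/`autoplot()` methods;
- `estimate_alpha()`, `estimate_sigma()` — moment-based noise-variance
  estimators ($\alpha$ from the ensemble spread, $\sigma = \beta\,\epsilon$
  from the differenced analytic signal);
- `simulate_am()`, `simulate_random_shifts()`, `simulate_eeg()` — synthetic
  study signals with known ground truth;
- `detect_change_points()`, `score_change_points()`, `run_benchmark()` —
  change-point detection on the phase residual, TP/FP/FN/MCC scoring with a
  10-sample tolerance, and the batch pre-vs-post-smoothing benchmark.

A thin command-line front end with `simulate`, `smooth`, `estimate-params`,
`evaluate` and `benchmark` subcommands ships in `inst/cli/phasesmooth`.

## Worked example

An amplitude-modulated 50 Hz tone whose envelope dips to 0.05 every second,
with one genuine π phase reset at t = 2.18 s and white noise (sd 0.2),
smoothed in the known-signal setting (α from the band-passed noise):

```r
library(phasesmooth)

sig <- simulate_am(fs = 500, duration = 4, f_env = 0.5, f_carrier = 50,
                   epsilon = 0.05, shift_times = 2.18, noise_sd = 0.2,
                   seed = 105)
noise_a <- compute_analytic(Re(ensemble_filter(sig$value - sig$clean,
                 fc = 50, fs = 500, bandwidth = 20, M = 1,
                 perturbation_scale = 0, seed = 1)$mean_signal))
keep <- 76:1925  # drop filter edge transients
alpha <- (var(Re(noise_a[keep])) + var(Im(noise_a[keep]))) / 2

sm <- smooth_phase(sig, fc = 50, bandwidth = 20, M = 20, alpha = alpha,
                   beta = 0.1, seed = 105)
sm
#> <phase_smooth> 2000 samples at fs = 500 Hz, band 50 +/- 10 Hz
#>   alpha = 0.005501, sigma = 1.47e-05 (epsilon = 0.000147, beta = 0.1), p* = 0.0002771
autoplot(sm)
```

Comparing the phase residual before and after smoothing (medians over fixed
windows around the reset and the t = 1.5 s envelope dip):

```
step at 2.18 s:  pre 9.47 rad   post 3.16 rad
dip excursion:   pre 1.66 rad   post 0.54 rad  (67% reduction)
```

Read: before smoothing, the residual jumps by 9.47 rad across the reset —
the true π step *plus* a spurious full-cycle slip picked up in a low-envelope
dip — and wanders by 1.66 rad inside the dip at 1.5 s. After smoothing the
step is 3.16 rad ≈ π (the genuine reset, preserved) and the dip excursion
drops by two thirds. `tidy(sm)` exposes all per-sample series;
`glance(sm)` the fitted $\epsilon$, $\alpha$, $\sigma$ range and the
steady-state variance $p^\ast$.

The batch benchmark reproduces the headline effect of the method — averaged
over 200 signals per cell, smoothing cuts false-positive reset detections in
every noisy cell while slightly raising false negatives, improving MCC
overall:

```r
bench <- run_benchmark(seed = 1)   # ~2 min
autoplot(bench)                    # mean MCC vs SNR, pre vs post
```

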