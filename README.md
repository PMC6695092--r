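# clockwave

Spatial waves of circadian clock gene expression in *Arabidopsis* seedlings:
simulation and image-analysis tools.

Plant organs keep time with organ-specific circadian periods — cotyledons
run fast (~23.8 h), roots slow (~29 h) — and neighbouring cells exchange
weak local coupling signals. Together these two ingredients are enough to
generate travelling waves of clock gene (*GIGANTEA*) expression along the
root, visible in time-lapse luciferase movies. `clockwave` implements the
computational core of that analysis for people who model plant circadian
organization or analyse bioluminescence imaging:

* **Phase-oscillator simulator.** Each template pixel (i, j) is a Kuramoto
  oscillator

  dθ⁽ⁱʲ⁾/dt = ω⁽ⁱʲ⁾ + K Σ⟨m,n⟩ sin(θ⁽ᵐⁿ⁾ − θ⁽ⁱʲ⁾) − K_LD sin((π/12)·t − θ⁽ⁱʲ⁾)

  on a seedling-shaped lattice (cotyledon disc, 3-px-wide hypocotyl and
  root, 5×5 root tip), with organ-specific intrinsic periods
  (23.82 / 25.41 / 29.04 / 26.90 h means, sd 10%), Moore-neighbour
  coupling (K = 1), optional 24-h light forcing (K_LD = 1, zero phase at
  dawn, expression antiphase to light), and root growth of one row every
  5 h. Simulated expression is GI = cos θ + 1.
* **Synthetic movie renderer** (`render_stack()`): 16-bit multi-frame TIFF
  stacks every 90 min with baseline, damping, shot/read noise, cosmic-ray
  spikes, curved roots and neighbour contamination — so the whole pipeline
  is testable without any raw data.
* **Kymograph extraction** (`build_kymograph()`): 3×3 median filter,
  ROI-mean threshold, <50 px component removal, grey-level-weighted
  centroids, degree-7 centerline fit, Bresenham-rasterized 10-px normal
  sections.
* **Wavelet phase maps** (`phase_map()`): single-scale Morlet CWT
  (Z(u) = π^(−1/4) e^(6iu) e^(−u²/2)) turning each kymograph row into a
  wrapped instantaneous phase, with cone-of-influence flags.
* **Rhythm metrics**: FFT-seeded damped-cosine least squares with a
  relative-amplitude-error rhythmicity rule (period 18–36 h, RAE < 0.6),
  zero-phase Butterworth peak detection with 18–36 h spacing rules, and
  the Kuramoto order parameter R(t) = |N⁻¹ Σ e^(iθⱼ)|.

## Worked example

Simulate an entrained cohort, estimate organ periods, and quantify
synchrony:

```r
library(clockwave)

cfg <- preset_config("LD_to_LD", rng_seed = 1)   # K = 1, K_LD = 1, n = 24
sim <- simulate_clock(cfg)
per <- region_periods(sim)
round(tapply(per$period, per$organ, mean), 2)
#> cotyledon hypocotyl      root  root_tip
#>     24.00     23.83     23.92     23.92
```

All four organs entrain to the 24-h light-dark cycle despite intrinsic
periods from 23.8 to 29 h — the light forcing dominates the period
differences. Under free run the intrinsic differences reappear:

```r
ll <- clock_config(regime = "LD_to_LL", K = 0, sd_frac = 0, growth = FALSE,
                   t_end = 120, dt = 0.05, cotyledon_radius = 2.5,
                   hypocotyl_rows = 6, root_rows = 12)
per <- region_periods(simulate_clock(ll))
per[, c("organ", "period")]
#>       organ  period
#> 1 cotyledon 23.8125
#> 2 hypocotyl 25.4375
#> 3      root 29.0000
#> 4  root_tip 26.8750
```

(periods are read off the 0.25-h storage grid by peak detection, hence the
quarter-hour quantization)

```r
```

A single forced oscillator peaks at dusk (12 h after dawn), the model's
entrained phase reference:

```r
osc <- simulate_oscillator(24, K_LD = 1, theta0 = 2, t_end = 240)
late <- osc$times > 192
peak_to_peak_period(osc$gi[late], osc$times[late])$peak_times %% 24
#> [1] 12 12
```

And the imaging pipeline closes the loop — a rendered synthetic movie is
segmented, sectioned and wavelet-transformed back to the phases it was
built from:

```r
src <- list(mask = matrix(TRUE, 50, 16), period = 24)
stack <- render_stack(src, render_config(n_frames = 96, baseline = 300,
                                         amplitude = 2000))
pm <- phase_map(build_kymograph(stack, min_area = 30), period_hint = 24)
plot(pm)
```

`run_scenario("LD_to_LL", "out/")` executes the full
simulate → readout → phase-map → periods → synchrony chain and writes CSV
tables plus a checksummed JSON manifest.

## Documentation

The methods vignette (`vignettes/clockwave-methods.Rmd`) describes the
model, the template and growth bookkeeping, the wavelet and rhythm
analysis choices, what the synthetic movies do and do not emulate, and
known limitations.
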