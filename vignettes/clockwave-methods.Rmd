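---
title: "Models and methods behind clockwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clockwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockwave)
```

`clockwave` studies how organ-specific circadian periods and weak local
cell–cell coupling jointly produce spatial waves of clock gene expression
along *Arabidopsis* seedlings. This vignette is the package's own account
of the models and numerical choices; the README shows the user-facing
workflow.

## The phase-oscillator model

Each occupied pixel (i, j) of a seedling-shaped lattice carries a phase
$\theta^{(i,j)}(t)$ obeying

$$\frac{d\theta^{(i,j)}}{dt} = \omega^{(i,j)}
 + K \sum_{\langle m,n\rangle} \sin\!\left(\theta^{(m,n)} - \theta^{(i,j)}\right)
 - K_{LD} \sin\!\left(\tfrac{\pi}{12}\,t - \theta^{(i,j)}\right),$$

with simulated reporter expression $GI = \cos\theta + 1 \in [0, 2]$.

**Intrinsic frequencies.** $\omega = 2\pi/P$ with per-pixel periods drawn
i.i.d. from organ-specific normal distributions: means 23.82 h
(cotyledon), 25.41 h (hypocotyl), 29.04 h (root), 26.90 h (root tip),
standard deviation a fraction $\Omega$ of the mean (default 0.1). Draws
are truncated below at 0.1 h — with $\Omega = 0.1$ the truncation is a
10-sigma event and never binds in practice; it only guards pathological
configurations. The root-assignment mean (29.04 h) deliberately differs
from the 28.04 h mean used when tip rows convert to root tissue during
growth; both numbers are part of the model parameterization and each is
used exactly where the parameterization uses it, even though they sit only
1 h apart. We surface rather than reconcile this asymmetry.

**Coupling.** The sum runs over the occupied Moore neighbourhood (up to 8
neighbours; `neighborhood = "von_neumann"` switches to 4). There is no
1/N normalization of the sum — boundary pixels simply receive fewer
contributions. $K$ is identical everywhere; 1 by default. On a symmetric
coupling graph the pairwise sine terms cancel, so the pixel-mean drift
equals the mean intrinsic frequency at every step; the test suite asserts
this conservation to near machine precision.

**Light forcing.** $K_{LD} > 0$ only in the LD-to-LD regime (default 1
there). Time zero is dawn and the forcing zero-phase occurs at dawn; the
negative sign places the entrained expression peak in antiphase to light,
i.e. at dusk. A single matched oscillator ($\omega = \pi/12$) has Adler
dynamics $\dot\psi = K_{LD}\sin\psi$ for $\psi = (\pi/12)t - \theta$, with
the stable fixed point at $\psi = \pi$: expression peaks 12 h after dawn.
Entrainment holds exactly for $|\omega - \pi/12| \le K_{LD}$, and the test
suite probes both sides of that boundary numerically.

**Template.** A cotyledon disc (radius 4.5 px), a 3-px-wide hypocotyl
column (16 rows), a 3-px-wide root (40 rows at t = 0) and a 5×5 root tip,
all 4-connected. These dimensions are configurable; published figures do
not pin the aerial geometry precisely, and for the quantities computed
here (root kymographs, organ periods, synchrony) only the organ
composition and root topology matter materially.

**Initial phases.** LD-entrained regimes start with the first expression
peak 11 h after the start of measurement. We give each pixel
$\theta_0 = -11\,\omega$ so that every pixel's free-running first peak is
exactly at 11 h; a `theta0_mode = "common"` switch instead shares one
$\theta_0 = -11 \cdot 2\pi/24$ across pixels (strictly identical phases,
first peaks then spread with the period). The two conventions cannot both
hold simultaneously — identical phases imply period-dependent first-peak
times — and we default to the per-pixel convention because the 11-h first
peak is the observable anchored to data. LL-to-LL runs draw initial
phases uniformly on the circle.

**Growth.** The root grows one row every 5 h. Our bookkeeping keeps the
tip a fixed 5×5 block while occupancy rises by exactly 3 px per event:
five new tip pixels appear below the old tip bottom row, inheriting the
phases of the pixels directly above them bit-for-bit and drawing periods
around the tip mean (26.90 h); the middle three pixels of the formerly
uppermost tip row convert to root tissue with periods redrawn around
28.04 h; the two edge pixels of that row leave the occupied set (the
region label moves down across the tissue, as a root apex does). A
description in terms of a single inserted 3-px row cannot satisfy all
three constraints (tip stays 5×5, root stays 3 wide, net +3 px) at once;
the implementation here is the unique reading that does, and it uses both
growth-period means exactly where the model specifies them.

**Integration.** Explicit Euler with dt = 0.01 h by default (dt ≤ 0.1 h
enforced). The convergence test halves dt and observes the expected
first-order error decay. Phases are wrapped to $(-\pi, \pi]$ at every
step and stored on a coarser grid (`save_dt`, default 0.25 h) to bound
memory; single-oscillator analyses store every step. Per-seedling RNG
streams are derived from the root seed so cohorts are reproducible and
individually re-runnable.

## Organ-level periods from simulations

`region_periods()` takes the median expression trace of a designated
5×5-pixel region per organ and returns the mean of consecutive
peak-to-peak intervals. Cotyledon, hypocotyl and root regions are static
windows on the initial template; the root-tip region is the current tip
block, which advances with growth — mirroring how a tracked experimental
ROI follows the tip. Organs whose trace holds fewer than two peaks are
omitted with a warning. Periods are read off the storage grid, so their
resolution is `save_dt` (0.25 h by default); cohort means average this
quantization away.

## The synthetic movie generator

`render_stack()` emulates the statistical structure of luciferase
time-lapse movies: frames every 90 min; in-mask counts
$\text{baseline} + \text{amplitude}\, e^{-\delta t} (\cos\theta + 1)/2$
(so `amplitude` is the peak-to-trough count range and $\delta$ models
luciferin depletion, off by default); Gaussian or Poisson noise; isolated
single-pixel cosmic-ray spikes at a Poisson rate per frame (single-pixel
by design, so the 3×3 median filter must remove them); an optionally
curved root via a quadratic horizontal shear; and an optional dim (20%)
offset copy emulating a neighbouring seedling. Ground-truth phases travel
only in metadata — pixel data carry no hidden labels, so the analysis
pipeline cannot cheat. Stacks round-trip losslessly through 16-bit
multi-frame TIFF plus a JSON sidecar; counts above 65535 are clipped with
a warning, and a missing sidecar is an error rather than silent defaults.

What the generator does **not** emulate: optics (PSF, vignetting), camera
gain structure, plate autofluorescence gradients, seedling movement, or
organ-shape change beyond root elongation. Tests passing on these movies
therefore validate the pipeline's geometry, filtering and phase
arithmetic — not its robustness to every artefact of real imaging.

## Kymograph extraction

Per frame and region of interest: a 3×3 median filter (exact medians via
a sorting network; replicate padding), segmentation of pixels strictly
above the ROI mean — strict, so a constant frame segments to empty — and
removal of 8-connected components below 50 px, implemented as
connected-component area filtering since the removal criterion is stated
in pixels. The grey-level-weighted centroid
$C_n = \sum_m m W_{m,n} / \sum_m W_{m,n}$ of each vertical section feeds
a least-squares polynomial of degree 7 (fitted in a centred/scaled row
coordinate for conditioning; the analytic derivative gives the tangent).
The normal through $(C_n, n)$ is rasterized with Bresenham's algorithm
and trimmed to the 10 rasterized pixels nearest the intersection — a
contiguous run centred on the nearest rasterized pixel, since the curve
generally falls between pixels. Section values are the mean filtered
intensity over those pixels. Sections missing in single frames are
linearly interpolated across gaps of at most 2 frames; more than 20%
failed frames aborts. Output sections are 0-based from the organ top,
increasing towards the tip.

Because dim sections (near an expression trough, with a low baseline)
can fall below the ROI-mean threshold, exact-intensity ground-truth
comparisons in the tests use baselines above the ROI mean; phase
recovery is insensitive to this because the wavelet phase ignores
amplitude.

## Wavelet phase maps

The single-scale continuous wavelet transform
$W_s(t) = s^{-1/2}\sum_p V_p Z^*\!\big((p-t)/s\big)$ with the Morlet
mother wavelet $Z(u) = \pi^{-1/4} e^{6iu} e^{-u^2/2}$ is evaluated
directly (a complex kernel matrix; no FFT shortcut is needed at these
series lengths, and the tests hold the implementation to a brute-force
double-loop oracle at 1e-10). The phase $\varphi = \arg W_s$ is invariant
to positive rescaling of the series exactly, and to constant offsets in
the deep interior, which is the point of phase plots: dynamics
independent of amplitude fluctuations.

The scale is matched to a characteristic period: with centre frequency 6
the transform's phase advances 6/s per sample, giving pseudo-period
$2\pi s\,\Delta t/6$; `scale_for_period()` inverts this. When no hint is
given, the section-mean trace is fitted by the rhythm module (fallback
24 h). Edges are zero-padded implicitly by the truncated sum; samples
within $\sqrt{2}\,s$ of either end are flagged as cone of influence but
still reported. The per-row robustness check recomputes phases at
s ± 10% and flags rows whose interior phases move by ≥ 0.1 rad; the
interior for this check extends 2 scale widths in from the edges, because
the Gaussian envelope still carries $e^{-1}$ of its weight at the
$\sqrt{2}\,s$ cone boundary and scale sensitivity there reflects the
boundary, not the signal. Flagged rows are reported, never dropped.

## Organ-level rhythm analysis

`extract_trace()` takes the per-frame median of a circular ROI (the
median resists up to half-minus-one corrupted pixels) and subtracts the
per-frame mean of a user-designated empty background region; traces whose
minimum drops below zero after subtraction are excluded with the reason
recorded. The ROI diameter is a pixel-level parameter; its physical
analog in organ-tracking protocols is on the order of 315 µm.

`estimate_period()` detrends the 24–144 h window by a cubic polynomial,
seeds a single exponentially damped cosine from the discrete Fourier
transform, and refines by Levenberg–Marquardt. The confidence score is
the relative amplitude error: the half-width of the approximate 95%
confidence interval of the amplitude divided by the amplitude, so values
near 1 mean the amplitude is indistinguishable from zero. Rhythmic means
period in 18–36 h *and* RAE < 0.6. This is a single-component analog of
the multi-component FFT-NLLS procedure used by circadian data servers,
whose exact confidence definition is not public; equivalence cannot be
asserted, only the construction documented. On labelled synthetic sets
the rule attains ≥95% sensitivity (damped cosines, SNR ≥ 5, periods
18–36 h, recovered within 2%) and ≥95% specificity (white noise), which
the test suite reports.

`detect_peaks()` applies a third-order zero-phase (forward–backward)
Butterworth low-pass — cutoff period 10 h, chosen between the circadian
band and the high-frequency noise it must remove; zero-phase filtering
avoids biasing peak times — then keeps local maxima inside 24–144 h and
enforces 18–36 h spacing between consecutive retained peaks, discarding
the later peak of a violating pair with the reason recorded.
`common_cycles()` optionally trims organs of a seedling to their common
cycle count so that compared cycles are complete everywhere.

`order_parameter()` computes $R(t) = |N^{-1}\sum_j e^{i\theta_j}|$ over
hypocotyl and root pixels (the tip counts as root tissue); cotyledons are
excluded because their orientation and movement make experimental phase
extraction unreliable, and the simulation mirrors that scope.

## Scenario workflows

`preset_config()` encodes the study conditions: LD-to-LL, LD-to-LD
(K_LD = 1), LL-to-LL (uniform random initial phases), the uncoupled
gradient variant (K = 0; root period means rising linearly from 25.41 h
at the hypocotyl junction to 28.04 h mid-root and falling to 26.90 h at
the tip junction — under growth, new rows keep the standard growth
means), a constant-darkness preset in which the light-sensitive aerial
organs slow drastically (cotyledon 28.5 h, hypocotyl 29.5 h — chosen to
reproduce the qualitative inversion of the shoot–root period order, since
darkness removes the light input that keeps aerial clocks fast), and a
coupling sweep over K ∈ {0, 0.5, 1, 2, 5}. Under the sweep, the
within-seedling spread of realized periods tightens monotonically with K,
and in LL-to-LL runs local coupling measurably raises terminal
adjacent-row phase coherence relative to K = 0 with matched seeds — the
model's signature that coupling, not initialization, builds the spatial
patterns. `run_scenario()` executes simulate → readout → phase map →
periods → synchrony, writing CSVs and an atomically-written JSON manifest
with config echo, seed and output checksums; identical config and seed
give byte-identical outputs.

## Problem sizes and numerical choices

Defaults integrate ~260–400 pixels for 144 h at dt = 0.01 h; a 24-
seedling cohort completes in well under a minute. Property tests use
reduced templates (shorter roots, dt = 0.05 h) — the properties checked
(conservation, convergence order, coherence contrasts) are
size-independent. Degenerate inputs are handled explicitly: constant
series have zero wavelet magnitude and undefined phase; empty
segmentation masks flag the frame; traces with fewer than two peaks are
omitted from period maps with a warning; non-finite phases abort with the
offending pixel named.

## Known limitations

* The phase model abstracts the gene network entirely; amplitudes,
  damping and waveform asymmetries of real reporter traces are outside
  its scope.
* Euler integration is first-order by design (matching the original
  analysis); stiff parameter regimes (very large K) would need smaller
  steps.
* The RAE-based rhythmicity rule approximates, but is not identical to,
  the confidence score of multi-component FFT-NLLS servers.
* The renderer's artefact models are parametric and minimal; a flat (or
  linear-gradient) background stands in for structured plate backgrounds,
  which real movies may exhibit.
* Section coordinates assume the organ runs roughly top-to-bottom in the
  frame; there is no general rotation/registration stage.
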