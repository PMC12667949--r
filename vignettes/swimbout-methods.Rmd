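---
title: "Methods: bout segmentation, postural compensation and circadian analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bout segmentation, postural compensation and circadian analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimbout)
```

## The behavioral model

Larval zebrafish swim in discrete bouts separated by inactive inter-bout
intervals (IBIs). Because the center of mass sits anterior to the center of
buoyancy, a resting larva passively rotates nose-down during each IBI and
must correct its pitch by rotating nose-up during subsequent swim bouts.
`swimbout` quantifies this behavior from side-view pose time-series
(time, horizontal position $x$, vertical position $z$, pitch angle
$\theta$, sampled uniformly — 166 Hz in the standard apparatus) and asks
three questions:

1. **Postural compensation.** How much of the drift accrued during an IBI
   does the next bout's rotation undo? We regress bout rotation on
   preceding-IBI drift; the *compensation gain* is the absolute slope, with
   gain 1 meaning full correction.
2. **Navigation.** How efficiently do chains of bouts move the animal
   (displacement per second) and how variable is the heading (directional
   change per second), over sliding epochs of five consecutive bouts?
3. **Circadian modulation.** Do bout kinematics fluctuate with ~24 h
   period under constant lighting, once binned into per-repeat medians?

## Segmentation conventions

Speed is the centrally differenced planar velocity magnitude,
$f_s \sqrt{\Delta x^2 + \Delta z^2} / 2$, smoothed by a 3-frame centered
moving average (`smooth_window`, configurable; 1 disables smoothing). Bouts
are maximal runs with speed above the 5 mm/s threshold. Two defaults are
declared rather than inherited from any upstream tracker, and exposed in
`segmentation_params()`:

* `min_duration_s` (3 frame-periods): suppresses single-frame noise
  crossings;
* `merge_gap_s` (50 ms): sub-threshold dips strictly shorter than this are
  bridged, since a mid-bout deceleration below threshold does not end the
  bout. Bout count is non-increasing in this parameter (tested).

Each bout contributes a peak-aligned window from −250 ms to +200 ms around
the speed peak (earliest frame on ties, for determinism). At frame rate
$f_s$ the window holds $\lfloor 0.25 f_s \rfloor + \lfloor 0.20 f_s
\rfloor + 1$ samples — 75 at 166 Hz. Bouts whose window would cross the
epoch boundary are flagged truncated and excluded from windowed analyses.

Per-bout kinematics:

* **Duration** — full width at half maximum (FWHM) of the speed profile,
  crossings located by linear interpolation; a profile that never falls
  below half-max inside the window is kept but flagged censored.
* **Displacement** — summed per-frame step lengths while speed exceeds the
  threshold.
* **Direction** — elevation $\operatorname{atan2}(\dot z, |\dot x|)$ of
  the central-difference velocity at the peak; the $|\dot x|$ fold maps
  left- and right-swimming fish to one vertical-direction convention.
* **Rotation** — pitch at +200 ms minus pitch at −250 ms (window
  endpoints, the literal net change; no fitted slope).
* **IBI drift** — pitch at the next bout's window start minus pitch at the
  previous bout's window end. With these endpoint conventions, rotations
  and drifts tile the pitch trajectory without overlap, so the
  compensation residual (drift + rotation) telescopes cleanly.

IBI *duration*, in contrast, runs between super-threshold run boundaries
("the time between two bouts"), not window edges.

## Robust compensation fit

Extreme rotations (struggles, wall contacts) would dominate ordinary least
squares, so the gain is estimated by iteratively reweighted least squares
with Tukey bisquare weights: tuning constant 4.685, scale re-estimated each
iteration as $1.4826 \cdot \mathrm{MAD}$ of the residuals, convergence when
the largest coefficient change drops below $10^{-8}$ (cap 50 iterations).
On outlier-free Gaussian data this reproduces least squares to $10^{-3}$
(tested); with 5% gross outliers the bisquare slope moves by less than
0.02 where least squares moves by more than 0.1.

$R^2$ is reported unweighted about the robust line — it can be negative
when down-weighted outliers carry large squared error; we label the
convention rather than guessing a weighted variant. Slope significance
uses case (pairwise) bootstrap resampling — robust-fit residuals are not
exchangeable under heteroscedasticity, so residual resampling would be
wrong — with the add-one two-sided p-value $\min(1,\, 2(k+1)/(B+1))$,
deterministic given a seed. At $B = 1000$ the smallest attainable p is
0.002.

Analyses are restricted to *middle bouts of 3-bout sequences* (both
flanking IBIs defined) and stratified long/short by the median
dark-condition IBI duration; ties classify as short. Whether "the dark
condition" means pooled dark-day IBIs or all dark-phase IBIs is exposed as
configuration (`long_ibi_reference`, default dark-day pooled, with a
fallback to all IBIs for single-condition recordings).

## Phases and circadian analysis

Clock times are decimal hours in $[0, 24)$. Day is the lights-on span
(default 9–23 h, applied as zeitgeber time under constant conditions);
*transition* covers the hour on each side of both boundaries (4 h total)
and is excluded from day/night summaries. The analysis window is 48 h from
the clock anchor (10 a.m. on day 1 by default).

Binned series take the per-repeat median in 2 h bins (0.5 h for
autocorrelation); empty bins are missing, never zero, and z-scores are
computed per repeat over its occupied bins (mean 0, SD 1, asserted
exactly in tests). For rhythm detection each repeat's series is
interpolated across at most 20% missing bins, demeaned, and correlated
with itself at lags up to 36 h; the peak lag is the argmax within the
18–30 h band.

**Estimator choice.** A naive unbiased lagged covariance
($\sum y_t y_{t+k} / (n-k)$, normalized by lag 0) seems natural, but on a
finite two-period record its partial-period boundary sums push
near-period coefficients slightly *above* 1, so the argmax lands half a
bin off the true period. We therefore use the per-lag segment
correlation — Pearson correlation of the two overlapping segments at each
lag. It is exactly 1 at lag 0, bounded by 1 everywhere (Cauchy–Schwarz),
attains exactly 1 at the period of a pure periodic series, and makes the
true period the band argmax; tests pin all four properties.

## Statistical toolbox

* **Mood's median test**: counts per group above vs not-above the pooled
  median (ties "not above", disclosed), Pearson $\chi^2$ on the 2×K table
  without continuity correction, effect size $\chi^2/N$ (bounded by 1 for
  two groups). Calibration is verified: empirical type-I error within
  [0.03, 0.07] at nominal 0.05 over 2000 null simulations.
* **Scott's rule** for histogram bins: $h = 3.49\,s\,n^{-1/3}$, bin count
  $\lceil \mathrm{range}/h \rceil$, edges spanning [min, max].
* **Per-repeat-median t-tests**: each experimental repeat summarized by
  its median; equal-variance two-sample t-test on the medians (the
  conventional choice for small balanced repeat designs; Welch by flag)
  with pooled-SD Cohen's d, positive when the first group's mean is
  larger.

## The synthetic swimmer

`generate_recording()` simulates an alternating renewal process on the
frame grid and returns raw tracks plus a ground-truth event log, so every
pipeline stage can be validated without any recorded data. Defaults encode
the study conditions; where only medians and IQRs are known the
distribution family is a modeling choice (gamma IBIs, log-normal bout
durations and peak speeds), stated here and nowhere inferred:

| parameter | dark | light | anchor |
|---|---|---|---|
| IBI | gamma, mean 2.29 s, shape 1 | mean 0.62 s, shape 3 | medians 1.58 / 0.55 s |
| bout FWHM | log-normal, mean 145 ms, CV 0.30 | mean 71 ms, CV 0.25 | medians ≈ 144 / 72 ms |
| peak speed | log-normal, mean 11.4 mm/s, CV 0.40 | 13.0 mm/s, CV 0.35 | medians 11.3 / 13.2 mm/s |
| direction | N(13°, 10°) | N(0°, 16°) | 13° climbs in dark |
| drift rate | 2.7 °/s nose-down | 1.5 °/s | IBI-drift medians / IBI medians |
| gain | 0.86 | 0.36 | regression slopes |
| rotation noise | 4.65° | 2.5° | chosen so the long-previous-IBI $R^2$ ≈ 0.57 |

During IBIs pitch integrates $-\omega\,dt$ plus Brownian noise
(0.3 °/√s), the body sinks at 0.3 mm/s, and $x$ jitters slightly. Each
bout has a Gaussian speed profile (σ = FWHM / 2√(2 ln 2)); its pitch
change is $-g \cdot (\text{drift accrued since the previous bout's window
end})$ plus noise, applied as a raised-cosine ramp across the window so
that the endpoint-difference rotation downstream recovers it exactly (the
ramp's zero endpoint slope also makes the measurement robust to one-frame
peak shifts). Drawn IBIs are floored at 0.3 s and bout placement keeps
consecutive windows disjoint. An LD schedule switches the active strategy
parameter set at the lights boundaries; the circadian option multiplies
the IBI and bout-duration means by $1 + A\cos(2\pi (t - \phi)/T)$
(preset `circadian_dd`: $A = 0.15$, $T = 24$ h, peak at 4 h — the middle
of circadian night; the amplitude sits between the ~0.11 implied by the
day/night bout-duration ratio and the ~0.33 implied by the IBI ratio).

What the generator deliberately does **not** emulate: serial correlation
of bout directions (real dark bouts keep stable headings across bouts, so
the real per-bout direction spread is *wider* in dark while consecutive
changes are smaller; with i.i.d. directions one cannot have both, and the
presets reproduce the directional-change-per-second ordering), heading
persistence (the horizontal heading sign resamples every bout, which
deflates absolute displacement-per-second levels relative to real fish
while preserving the light > dark ordering), burst/turn bout subtypes,
multi-fish occupancy, and any acute light-transition kinematics beyond an
instantaneous parameter switch. Passing recovery tests therefore
demonstrates correctness of the measurement pipeline under the assumed
generative structure, not realism of that structure.

## Numerical and scale choices

* Window frame counts use `floor()` so the 166 Hz window is exactly
  41 + 33 + 1 = 75 samples.
* Peak ties break to the earliest frame; detection, segmentation and the
  simulator are bitwise deterministic given their seeds.
* Degenerate inputs error loudly: zero-variance drift (no regression),
  all-identical samples (degenerate median-test table), flat binned series
  (no rhythm), non-positive peaks (no FWHM).
* Test problem sizes: compensation recovery uses 5 h dark recordings at
  166 Hz (~3,500 long-IBI middle bouts per gain level); rhythm detection
  uses 48 h recordings generated at 40 Hz — the frame rate only
  discretizes the speed profile, and at 40 Hz the interpolated FWHM is
  still accurate to well under the modulation amplitude, while memory and
  runtime drop fourfold. The vignette's numbers and the acceptance script
  recompute everything from these synthetic conditions at run time.

## Worked example

```{r example, eval = FALSE}
p <- swimmer_preset("dark_strategy", duration_h = 1, seed = 1)
rec <- generate_recording(p)
seg <- segment_recording(rec$tracks, rec$meta, keep_windows = TRUE)
mid <- select_middle_bouts(seg)
long <- classify_ibi(mid$prev_duration, seg$ibis$duration_s) == "long"
fit_compensation(mid$prev_drift[long], mid$rotation_deg[long])
```

## Known limitations

* CSV (+ YAML sidecar) is the only on-disk format.
* Epochs carry no fish identity; all statistics are per bout or per epoch,
  matching an apparatus that records whoever enters the field of view.
* No sub-frame peak interpolation; at 166 Hz bout-duration resolution is
  ~6 ms.
* The long-IBI threshold convention (pooled vs per-repeat dark median) is
  configurable because the convention itself is ambiguous in the field.
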