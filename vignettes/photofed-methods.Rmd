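---
title: "Methods: photometry normalization, time-constant estimation, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry normalization, time-constant estimation, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photofed)
```

## The measurement problem

Bulk fiber photometry measures the summed fluorescence of a calcium
indicator (e.g. GCaMP6s) in a genetically defined neural population
through a chronically implanted fiber. The raw 465 nm-evoked signal
confounds three things: population activity, slow photobleaching, and
motion of the fiber/brain interface. A second excitation wavelength near
the indicator's isosbestic point (405 nm) yields a calcium-independent
reference that shares the motion artifact but not the activity signal.
This package implements the standard analysis chain for such recordings —
alongside home-cage operant feeding logs (FED3-style, fixed-ratio 1) — and
a generator that simulates both with known ground truth.

## Normalization chain

Two recording classes are handled with a fixed operation order:

* **Short trials** (minutes; e.g. presentation of a food pellet to a
  fasted mouse): both channels are first denoised with a truncated
  discrete Gaussian kernel (window 7 samples, sigma 1 sample, weights
  renormalized after truncation; edges renormalize over the samples
  available rather than padding). Motion correction, ΔF/F₀ and zΔF/F₀
  then follow, with the baseline window 3 min to 10 s before pellet drop.
* **Day-long recordings** (≥ 23 h): motion correction on the raw channels,
  ΔF/F₀ against the ZT6–ZT9 window (ZT3–ZT6 when fasting starts at ZT6),
  a 30-minute *trailing* mean to isolate slow dynamics, then z-scoring of
  the smoothed signal against the same window.

Motion correction regresses the 465 nm signal on the 405 nm signal by
ordinary least squares over the whole recording, subtracts the
prediction, and adds back the mean 465 nm signal:
`corrected = f_ca − (â + b̂·f_iso) + mean(f_ca)`. Because OLS residuals
have zero mean, the corrected trace preserves the raw mean exactly; and
because the residual is orthogonal to the regressor, a shared artifact is
removed exactly when the isosbestic channel is noise-free. Two practical
limitations are worth knowing:

* **Errors in variables.** White noise on the isosbestic channel
  attenuates the fitted slope by `var(a)/(var(a) + var(ε_iso))`, leaving
  a proportional artifact residue in the corrected trace.
* **Trend leakage.** The single whole-recording fit is only a valid
  artifact estimator while the isosbestic channel's variance is dominated
  by the shared artifact. If its bleach trend is comparable, the slope
  absorbs any slow signal that covaries with that trend (a fasting rise
  against a monotone decay, for instance), injecting a scaled trend into
  the corrected trace. The generator's defaults respect this validity
  condition (artifact variance more than 10× the within-session trend
  variance), and a test asserts it.

All baseline and analysis windows are half-open `(start, end]` in seconds;
Zeitgeber-time windows (hours after lights-on) resolve to the first
occurrence at or after recording start and may wrap midnight (ZT12–ZT2 is
a 14-h window). The z-score uses the sample (n−1) standard deviation; the
convention is documented rather than configurable because every consumer
in the package agrees on it. Non-finite samples are dropped at load time,
never interpolated.

## Time-constant estimation

State transitions are quantified by a threshold-crossing time constant:
within a search window, find the extremum of the baseline-subtracted
signal (maximum for rises, minimum for falls), then report the earliest
sample time at which 63.8% of that extremum has occurred. The constant
0.638 is used exactly as conventionally printed (not 1 − 1/e ≈ 0.632) and
is configurable. Standard windows:

* **falls** (food presentation): search 30 s before to 5 min after the
  pellet drop, baseline 3 min to 10 s pre-drop (the pre-stimulus ΔF/F₀
  baseline — reused here as the reference level, an explicit assumption);
  τ reported in seconds from presentation;
* **rises** (food removal): search ZT11–ZT18, baseline ZT11–ZT12, τ
  reported in hours from fast onset at ZT12.

τ is reported at sample resolution of the filtered trace; no sub-sample
interpolation. A trace whose extremum has the wrong sign is flagged
invalid rather than yielding a spurious time. The estimate is invariant
to affine rescaling of the trace.

Three systematic properties of this estimator, derived in closed form and
reproduced by the test suite:

1. On a pure saturating exponential with time constant `T` observed over
   a long window, the crossing occurs at `T·ln(1/(1−0.638)) ≈ 1.016 T`.
   `tau_to_exponential()` inverts this when an exponential time constant
   is wanted.
2. A trailing mean of window `w` applied before estimation delays the
   crossing by approximately its group delay `w/2` (exactly
   `T·ln((T/w)(e^{w/T}−1))` for an exponential). The day-long wrapper
   `estimate_rise_tau()` therefore passes `filter_delay = w/2` to subtract
   the delay of the smoothing it itself applied; the bare estimator
   applies no such correction. Without this, recovered rise constants
   near 1 h are biased high by ~25%.
3. The finite ZT18 search end truncates slow rises: for `T = 3 h` only
   `1 − e^{-2}` of the asymptote is reached, biasing τ̂ low by ~15–25%.
   This is inherent to the printed window and is left uncorrected.

Two further caveats are quantified by simulation rather than corrected:
a circadian component of amplitude comparable to 20% of the rise biases
τ̂ by 10–16% regardless of its phase (the 1-h pre-onset baseline cannot
distinguish rise from circadian trajectory), and noise deepens the
detected extremum, which lengthens fall τ̂ slightly (≈ +1 s at the
default noise for a 7.5 s fall).

## Event-locked analysis

Poke-aligned activity uses only pokes (both ports combined) during the
fast period (ZT12–ZT2) with no poke in the preceding 45 s — tested
against *all* pokes, not only kept ones. Snippets run 45 s before to
100 s after each poke on the recording's sample grid; each snippet is
independently re-normalized (ΔF/F₀ then z) against its own −45 s…−1 s
window, and events whose window is incomplete or whose baseline is
degenerate are excluded with counts reported, never padded. Pooled
means ± SEM are over all pokes from all mice (the figure convention); a
per-mouse two-stage average (`pool_and_average()`, SEM over mice) is
provided for all other summaries.

The decile progression assigns poke `i` of `N` (time order) the decile
`⌈(100·i/N)/10⌉` clipped to `[1, 10]` — the
ceiling-of-cumulative-percentage rule, with a brute-force oracle as the
normative test (e.g. `N = 23` gives sizes 2,2,2,3,2,2,3,2,2,3); deciles
1, 4, 7, 10 are the presented subset. Poke rate is the mean count per
minute in a sliding 30-min window, centered by default (configurable to
trailing), with edge windows normalized by the minutes actually covered.

## The synthetic generator

The generator produces data with the statistical structure the analysis
assumes, with fully known ground truth; it is first-class, tested code.

**Latent state.** `s(t)` sums a single-harmonic circadian cosine and a
condition term: a saturating-exponential rise at food removal
(`fast_rise_tau`), or an exponential fall at pellet presentation
(`food_fall_tau`). One harmonic is deliberate — enough daily structure to
exercise ZT windowing without complicating ground truth — and documented
as replaceable. The state couples to behavior only through the schedule
(no closed loop), keeping ground truth analytically known.

**Acquisition.** `ca = B_ca·bleach_ca(t)·(1+s) + a + ε`, `iso =
B_iso·bleach_iso(t) + g·a + ε′`, with `a` an Ornstein–Uhlenbeck artifact
(1-s correlation time) common to both channels up to the gain `g`,
mono-exponential per-channel bleaching (off when the half-life is
infinite), and independent white noise. Identical seeds give bit-identical
recordings.

**Behavior.** Pokes are an inhomogeneous Poisson process: a base ad-lib
rate with 10-min meal clusters at 8× the base rate; during the fast
window (pellet delivery paused ZT12–ZT2) the intensity is
`floor + burst·e^{−(t−t_fast)/τ_ext}` — an extinction burst that decays
as the animal learns that pokes no longer deliver food. Outside the fast
window every poke yields a pellet drop (FR1) and a retrieval after an
exponential delay (mean 10 s, a documented invention: delays are not
reported in this literature).

**Defaults and their rationale.** Defaults are the package's statement of
realistic study conditions and are fixed, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| circadian amplitude | 0.1 ΔF/F | ad-lib daily modulation ≈ 20% of the fasting rise |
| circadian peak | ZT12 (ARC^AgRP preset), ZT13 (PVH^Sim2) | ad-lib activity peaks at/just after dark onset and declines over the dark period; the PVH population peaks slightly later |
| fast-rise amplitude / τ | 0.5 ΔF/F; 1.78 h (ARC^AgRP), 0.87 h (PVH^Sim2) | τ calibrated to published population estimates |
| food-fall amplitude / τ | 0.3 ΔF/F; 7.5 s | calibrated to the published food-response estimate |
| bleach half-life | 500 h per channel | a few %/day, the stability long-term home-cage recording hardware is designed for; keeps the isosbestic channel artifact-dominated (the regression validity condition above) |
| artifact SD | 0.05 a.u. (10% of iso baseline) | home-cage mice move constantly |
| white noise SD | 0.01 a.u. (1% of ca baseline) | shot-noise scale at which pulse recovery is tested |
| poke rates | base 0.3/min, clusters 1.5/h, burst 3/min, floor 0.05/min, τ_ext 1.5 h | an extinction burst of a few pokes/min decaying over hours, over a sparse floor |

What the generator does **not** emulate: indicator kinetics (no
biophysical calcium model — `s(t)` is already "activity"), hemodynamic or
spectral crosstalk, state-dependent behavior feedback, or video. Passing
recovery tests therefore demonstrates correctness of the analysis chain
under the stated model, not robustness to every artifact of real
recordings.

## Recovery experiments and problem sizes

Day-long simulations run at 1 Hz for 23 h (ZT6 to ZT5), the package's
choice of problem size for its own verification experiments: τ is resolved
to 1 s against values of 0.5–3 h, so sampling density is not the limiting
error. The τ-recovery experiment draws `fast_rise_tau` log-uniformly in
[0.5, 3] h at default acquisition noise with the circadian term off —
isolating the property under test (noise robustness of the estimator);
with the circadian term on, the contamination described above dominates,
and that is reported as a limitation rather than folded into the recovery
statistic. The condition-contrast experiment (a 1.8-h onset delay
recovered as Δτ across 10 simulated mice) keeps the full default state,
circadian included, because the contamination cancels in the paired
difference — as it does in a within-animal vehicle/treatment design.

## Degenerate inputs and numerical choices

* Zero-variance isosbestic channel → intercept-only fallback: motion
  correction returns the calcium channel unchanged, with a warning.
* `F₀ = 0` or a zero-SD baseline → an error naming the degenerate
  window; in per-event alignment such events are excluded and counted.
* Baseline windows require ≥ 2 samples.
* Ties at the threshold: the earliest sample at or past the threshold is
  taken (`≥` for rises, `≤` for falls), so a step crosses at the step.
* Trailing-mean and smoothing edges shrink to the available samples, so
  outputs are defined from the first sample; both operators are linear.
* All randomness flows from a single integer seed per simulated object;
  identical inputs give bit-identical CSV output (no timestamps in any
  table or manifest).

## Known limitations

The isosbestic regression's two failure modes above; the circadian
contamination of rise-τ estimates; truncation bias of the ZT18 search
end for rises slower than ~2.5 h; noise-deepened extrema lengthening
fall-τ estimates; and the refractory/alignment machinery assuming event
and photometry clocks are already synchronized (hardware alignment is out
of scope). Summary statistics beyond the Holm–Šidák step-down utility —
ANOVAs, t-tests — are deliberately left to standard tools.
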