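---
title: "EEG fatigue monitoring: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG fatigue monitoring: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The monitoring model

Mental fatigue alters the spectral composition of scalp EEG, most visibly in
the theta (4–7 Hz) and alpha (8–11 Hz) rhythms: as fatigue develops, the
relative power of these rhythms drifts away from its alert-state pattern.
`eegfatigue` operationalizes this as a novelty-detection problem. During an
alert calibration period, the per-epoch spectral feature vectors of the two
rhythms, $x_\theta$ and $x_\alpha$, are summarized by their means
($\mu_\theta$, $\mu_\alpha$) and covariances ($N$, $C$). Each subsequent
epoch is scored by the Mahalanobis distances

$$D(x_\alpha) = \left[(x_\alpha - \mu_\alpha)^T C^{-1} (x_\alpha -
\mu_\alpha)\right]^{1/2},\qquad
D(x_\theta) = \left[(x_\theta - \mu_\theta)^T N^{-1} (x_\theta -
\mu_\theta)\right]^{1/2},$$

combined into a single statistic by a convex weight $\sigma \in [0, 1]$:

$$D_C = \sigma\, D(x_\alpha) + (1 - \sigma)\, D(x_\theta).$$

Fatigue is declared when $D_C$ strictly exceeds a threshold, either the
fixed operating value 6.0 or a value calibrated from labeled epochs by ROC
analysis (Youden's $J = TPR - FPR$, ties resolved toward the lower
threshold). The full pipeline is: artifact handling, rhythm extraction,
baseline scoring, threshold decision.

Note on units: the alarm threshold is conventionally quoted in microvolts in
the source tradition of this method, but a Mahalanobis distance is unitless;
the package treats all $D$ values as unitless.

The statistic uses *band-specific* means. A single shared mean across two
bands with different covariances is ill-defined — the two feature vectors
measure different frequency ranges — so the baseline stores one mean per
band.

## Pipeline stages and their parameters

### Artifact handling

Two mechanisms, both governed by the 50 µV rule (scalp EEG of cerebral
origin rarely exceeds this amplitude; the comparison is strict, so a sample
at exactly 50 µV is clean):

* `flag_artifacts()` marks samples with $|x| > 50$ µV; an epoch is
  contaminated iff any of its samples is flagged. Contaminated epochs are
  skipped by the monitor, not scored, because spectra estimated from
  artifact-bearing windows corrupt $D_C$.
* `remove_artifacts_bss()` separates the record into uncorrelated sources by
  second-order blind identification (SOBI): whitening followed by joint
  approximate diagonalization of time-lagged covariance matrices (lags 1–8
  samples by default). Single-channel records are first delay-embedded into
  16 lagged copies (a trajectory matrix, as in singular-spectrum analysis)
  and mapped back by diagonal averaging. A component is rejected when its
  back-projection violates the 50 µV rule or its raw kurtosis exceeds 5
  (Gaussian background activity has kurtosis 3; sparse transients such as
  blinks are strongly leptokurtic).

Rejected components that violate the amplitude rule are subtracted only on
the intervals where the violation occurs, dilated by 0.25 s on each side.
Globally zeroing such a component would also delete the genuine
low-frequency brain signal that shares it, which measurably degrades the
cleaned signal's fidelity away from the artifact; windowed subtraction keeps
the record untouched where there is no artifact. Components rejected on
kurtosis alone (no amplitude violation anywhere) are subtracted globally.
When nothing is rejected, the reconstruction is the identity up to rounding.

### Rhythm extraction

`decompose()` expands each epoch on a periodized orthogonal wavelet-packet
tree deep enough that every leaf spans at most 2 Hz (depth 7 at 512 Hz),
retains the leaves whose nominal bands intersect 4–7 Hz (theta) or 8–11 Hz
(alpha), inverts them, and sharpens the result to the exact band edges with
a zero-phase 4th-order Butterworth band-pass applied forward and backward.
The residual is defined as input minus the two rhythm components, so the
three components sum to the input exactly. A plain dyadic wavelet transform
cannot express the 4–7/8–11 Hz edges (its octave bands at 512 Hz are 4–8 and
8–16 Hz), which is why the packet tree plus edge sharpening is used.

The default mother wavelet is **db20**. This was a genuinely open choice
that implementation settled: short Daubechies filters (db4) leak heavily
across the narrow 2 Hz packet leaves at depth ≥ 5 — a pure 10 Hz tone
retains only ~62% of its energy in the alpha component — while the 40-tap
db20 filter bank concentrates ~87% and suppresses theta leakage of an
in-alpha tone by more than two orders of magnitude, at unchanged (exact)
reconstruction. db10, db4, db2 and haar remain selectable.

`band_feature_vector()` converts each band component into log power in
half-open 1 Hz bins ($[f, f+1)$; three bins per band under the default
edges), estimated from the epoch periodogram with total power normalized so
that the bins over the full spectrum sum to the mean square (Parseval). A
floor of $10^{-12}$ µV² keeps the logarithm finite on silent epochs.
Log power (rather than raw power) stabilizes the covariance estimate
entering the Mahalanobis form.

### Baseline and scoring

`fit_baseline()` uses sample means and covariances shrunk toward their
diagonal, $(1-\lambda) S + \lambda\,\mathrm{diag}(S)$ with $\lambda = 0.1$
by default; short calibration periods (the monitor defaults to the first 30
artifact-free epochs) otherwise give ill-conditioned covariances. A tiny
absolute ridge ($10^{-8}$ scaled by the mean variance) is always added so
that even a degenerate constant baseline yields a positive-definite model.
$\sigma$ defaults to 0.5: neither band is privileged a priori, and the
weight is exposed for per-application tuning.

Per-epoch $D_C$ values from 2 s windows are intrinsically noisy: a 1 Hz bin
of a 2 s epoch carries roughly $2BT = 4$ spectral degrees of freedom, so the
log-power bins fluctuate with a standard deviation near 0.7 even in a
perfectly stationary recording. `smooth_scores()` therefore provides an
exponentially weighted moving average (default $\lambda = 0.5$, a mean lag
of one epoch); smoothing is linear, so the convex-combination identity for
$D_C$ is preserved row by row. Session-level detection works markedly
better on the smoothed trace and this is the recommended operating mode for
the real-time monitor; per-epoch diagnostics remain available unsmoothed.

### Epoching and I/O

Epochs default to 2 s with no overlap: at 512 Hz this gives 1024-sample
windows — at least 8 cycles of the lowest theta frequency and an integer
multiple of the $2^7$ leaves of the packet tree. Time is 0-based seconds
from record start; sample matrices are channels × time. Readers/writers
cover a simple CSV dialect (header row, first column seconds, one column
per channel in µV; lossless to writer precision) and 16-bit EDF (lossy only
by the stated quantization step, available from `edf_quantization_step()`).

## The synthetic-data generator

`simulate_eeg()` emulates the features of scalp EEG this method depends on:

* **Band structure.** One narrowband component per classical rhythm (delta
  1–4, theta 4–7, alpha 8–11, beta 12–30 Hz), each synthesized as zero-phase
  band-pass-filtered white noise at a target RMS amplitude, plus broadband
  noise. Narrowband noise rather than pure sinusoids is deliberate: the
  covariance-based baseline needs nonzero within-band variance.
* **Amplitudes.** Defaults (delta 5, theta 5, alpha 6, beta 3, noise
  2 µV RMS; total ≈ 10 µV RMS) are typical of forehead dry-electrode
  recordings and keep a clean signal comfortably below the 50 µV artifact
  criterion.
* **Fatigue trajectory.** A per-epoch drift level in $[0, 1]$ scales the
  theta and alpha amplitudes by $1 - 0.5\,d$ (band power falls to 25% at
  full drift). The direction — relative theta/alpha power *decreasing* with
  fatigue — is the package's modeling assumption throughout; a sign switch
  is exposed for sensitivity analyses because part of the fatigue
  literature reports the opposite direction. Epochs at drift 0 are labeled
  `alert`, all others `fatigued`.
* **Artifacts.** Blinks are 300 ms raised-cosine pulses with peaks drawn
  uniformly in 100–150 µV (the amplitude criterion, not a waveform, defines
  an artifact; the raised cosine is a reasonable eyelid transient), spikes
  are 40 ms triangles at 80–150 µV, and line noise is a 1 s burst of a
  mains-frequency sinusoid at 30 µV. Events are placed on disjoint slots.
* **Sampling rate** defaults to 512 Hz, typical of consumer forehead
  headsets and dyadic-friendly for the packet tree.

What the generator does *not* emulate: volume conduction and multi-source
mixing, 1/f background structure, non-stationary artifact morphology
(saccades, chewing), electrode pops, or inter-subject variability. Passing
tests therefore demonstrate the correctness and internal consistency of the
algorithms under band-structured stationary noise with a controlled fatigue
mechanism — not clinical performance on human recordings.

`simulate_trials()` generates per-trial outcome series (errors, completion
time, perceived fatigue) from contiguous piecewise-linear phase models with
additive Gaussian noise, clipped below at 0 and above at a cap (300 s for
completion time, matching the simulator limit of the peg-transfer task the
series describe). With zero noise the phase lines are reproduced exactly,
which is what lets `fit_phase()` recover printed slopes and intercepts to
machine precision.

## Trial-series analysis

`fit_phase()` is closed-form OLS of value on trial index over an inclusive
range, with $R^2 = 1 - SSE/SST$, defined as 1 for a perfectly fit constant
series. `segment_phases()` fits one line per given segment, or scans all
breakpoint placements exhaustively in auto mode (at most `max_phases`
segments, minimum 3 trials per segment) minimizing total SSE; ties prefer
fewer phases, then earlier breakpoints. Three trials is the minimum segment
because two-point segments always achieve $R^2 = 1$ and make the objective
degenerate. Phase boundaries differ across outcome measures in practice, so
the function takes boundaries as input rather than asserting a canonical
set.

## Numerical choices and degenerate inputs

* Mahalanobis distances are computed through the Cholesky factor (one
  triangular solve), which fails loudly — reporting the condition number —
  on a non-positive-definite covariance rather than silently inverting.
* The periodized packet transform requires the epoch length to be divisible
  by $2^{\text{depth}}$; violations are errors, not silent truncation.
* SOBI's whitening drops eigenvalues below $10^{-10}$ of the largest;
  eigenvector signs are fixed (largest-magnitude entry positive) so the
  separation is deterministic, and the joint diagonalization is plain Jacobi
  sweeps to a $10^{-8}$ rotation tolerance.
* ROC candidate thresholds are the sorted unique scores with $\pm\infty$
  endpoints; the decision rule is strictly `score > t` everywhere, matching
  the alarm's strict inequality at 6.0.
* All generators are deterministic functions of (configuration, seed).

## Problem sizes used in validation

The shipped validation suite exercises sessions of 10–600 s at 512 Hz
(up to 300 epochs), baselines of 10–30 epochs, trial series of 8–20 trials,
and Monte-Carlo loops of 100–10 000 draws for the distance, ROC and OLS
oracles; these sizes give stable statistics for every property checked
while keeping the suite quick to run. The end-to-end detection check uses
two independently seeded 10-minute sessions (calibration and held-out) with
a fatigue step at the midpoint, the baseline fitted from the first 30
epochs, $\sigma = 0.5$, EWMA smoothing at $\lambda = 0.5$, and a Youden
threshold carried from the calibration to the held-out session.

## Known limitations

* The alert baseline is assumed stationary; slow non-fatigue drifts
  (electrode impedance, temperature) inflate $D_C$ and are not modeled.
  Online baseline adaptation is deliberately out of scope.
* Single-channel BSS can only separate what second-order temporal structure
  distinguishes; artifacts spectrally identical to background EEG and below
  50 µV pass through.
* The 6.0 operating threshold is a published convention, not a per-subject
  calibration; for new subjects the ROC/Youden route on labeled data is
  preferable.
* EDF support covers the plain 16-bit format (no EDF+ annotations).
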