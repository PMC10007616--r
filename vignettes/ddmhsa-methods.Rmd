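---
title: "Dual-channel heart-sound analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-channel heart-sound analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmhsa)
```

## The problem

A phonocardiogram (PCG) records the acoustic vibrations of the beating
heart. Each cardiac cycle produces two dominant transients: S1 at the
onset of ventricular systole (closure of the atrioventricular valves) and
S2 at the onset of diastole (closure of the semilunar valves). Detecting
and telling these two sounds apart is the first step of any automated
auscultation, but it is hard with the acoustic channel alone: S2 is
systematically weaker than S1, and in ambulatory recordings the noise
floor can swallow it entirely.

This package implements a *dual deterministic* approach: alongside the
PCG it uses a finger photoplethysmogram (PPG), whose per-beat systolic
peak arrives a vascular transit time (VTT, nominally about 200 ms) after
the heart contracts. The timing of the systolic peak then disambiguates
the acoustic candidates: a heart-sound candidate that precedes a systolic
peak by roughly the VTT is an S1; candidates near or after the peak are
S2. Both sensors are wearable-friendly, which is the setting the method
targets.

## The acoustic branch

For a PCG segment $s(t)$ sampled at $f_s$ (2000 Hz throughout), the
detection chain is:

1. **Band-pass, 20–200 Hz** (4th-order Butterworth, applied
   forward–backward so the phase response is zero and event timing is
   preserved). Heart-sound energy lives in this band; baseline wander and
   hiss do not.
2. **Analytic envelope.** The analytic signal
   $s_a(t) = s(t) + j\hat{s}(t)$ (Hilbert transform by spectral
   construction: negative frequencies zeroed, positive doubled) yields
   the instantaneous envelope $m(t) = |s_a(t)|$ and phase cosine
   $\cos\phi(t) = s(t)/m(t)$.
3. **Envelope filtering** (model III only, see below).
4. **Shannon-entropy weighting.** The working signal $w(t)$ is squared,
   min–max-normalised to $[0,1]$, and passed through the kernel
   $x \mapsto -x\ln x$ (with $0\ln 0 = 0$). The kernel is bounded by
   $1/e$ and emphasises mid-level intensities: combined with the
   quadratic compression of the energy it suppresses the noise floor
   while flattening the dynamic range between loud S1 and softer S2
   bursts.
5. **Savitzky–Golay smoothing** (degree 3) of the entropy trace, negative
   undershoot clipped at zero, followed by min–max normalisation to give
   $NSE(t) \in [0,1]$.
6. **Impulse thresholding.** Samples with
   $NSE(t) > \sigma \cdot \overline{NSE}$ (default $\sigma = 5$) form the
   impulse train; its rising edges are the heart-sound start points.
   Rising edges closer than 100 ms to the previously kept one are merged
   (S1 and S2 are at least ~200 ms apart at rest, so anything closer is
   threshold chatter).

### Why the entropy acts on the energy

The kernel $-x \ln x$ has infinite slope at $x = 0$; applied to the raw
normalised *magnitude* it amplifies the noise floor, the smoothed trace
acquires a high baseline, and a mean-based threshold with $\sigma = 5$
can never fire (the threshold lands above the normalised maximum of 1).
Applied to the normalised *energy* $w^2(t)$, small values are first
compressed quadratically, the baseline stays near zero, and the
$\sigma\,\overline{NSE}$ rule separates bursts cleanly. This is the
classical "Shannon energy" formulation used throughout the heart-sound
segmentation literature, and it is what `run_model()` feeds to
`shannon_entropy()`.

### The smoothing window

`smooth_entropy()` defaults to a 0.45 s window (901 samples at 2000 Hz),
a scale comparable to the S1–S2 interval, and is exact on cubics by
construction. For the *detection* chain, however, a window of that length
makes each burst's entropy bump about half a beat wide; at 59–87 bpm the
bumps of consecutive sounds tile the whole record, the trace mean rises
above $0.2 \times$ its maximum, and the $5 \times$-mean threshold again
exceeds every sample — independent of the noise level. `model_config()`
therefore uses a **0.091 s** window: the S1 burst-duration scale. A
window of one burst length integrates the entropy of a whole burst, so
the bump height reflects burst *energy* — which is exactly the quantity
that separates an unboosted S2 from S1 — while the trace stays sparse
enough for the mean-based threshold. The choice was calibrated once on
synthetic recordings (sweeping 0.05–0.10 s and inspecting the model I /
model III sensitivity split) and is configurable.

## Envelope filtering (model III)

S2's lower amplitude is the main failure mode of the plain chain, so
model III equalises amplitudes before the entropy step:

* the envelope $m(t)$ is low-pass filtered (zero-phase, 40 Hz default)
  to give $m_f(t)$;
* a threshold $\delta \cdot \overline{m_f}$ (default $\delta = 2$)
  separates burst regions from the baseline;
* every contiguous supra-threshold region is rescaled so its peak equals
  the global maximum of $m_f$ — the S1 amplitude level;
* the boosted envelope is multiplied by $\cos\phi(t)$, reconstructing an
  amplitude-equalised waveform $z(t)$ that re-enters the chain at step 4.

Two remarks on fidelity. First, the threshold is a *constant*
$\delta \cdot \overline{m_f}$ compared against $m_f(t)$; a threshold of
the form $m_f(t) + \delta\,\overline{m_f}$ would exceed every sample for
$\delta > 0$ and never trigger a boost. Second, the filter applied to the
envelope is a low-pass, not the 20–200 Hz band-pass used on the raw
signal: the envelope of 20–200 Hz bursts varies on a scale of tens of
milliseconds (spectral content below roughly 30 Hz), and a band-pass with
a nonzero low corner would remove the envelope's baseline level — the
very quantity the mean-based threshold needs. A `bandpass_spec()` can
still be supplied where band-passed envelopes are wanted.

## The pulse branch and fusion

`detect_systolic_peaks()` band-passes the PPG to the beat band
(0.5–8 Hz), selects strict local maxima greedily by height under a
refractory period of $60/\mathrm{HR}_{\max}$ s, rejects dicrotic humps by
a prominence floor (0.3 × median candidate prominence), and refines each
peak to the raw-signal maximum within ±25 ms.

`classify_heart_sounds()` applies the VTT interval rule: a candidate at
$T$ with nearest following systolic peak $P$ (within
$\mathrm{VTT} + 0.1$ s) is S1 iff

$$P - \mathrm{VTT} - \ell \;\le\; T \;\le\; P - \beta,$$

with $\mathrm{VTT} = 200$ ms, $\beta = 100$ ms, endpoints inclusive, and
otherwise S2. $\ell$ is an *onset-lead allowance*: the chain reports
burst start points, which systematically precede the sound the nominal
VTT refers to by about half the entropy smoothing window, and the
systolic-peak refinement can move a peak by up to 25 ms on noisy data.
`model_config()` therefore sets
$\ell = \texttt{entropy\_window\_s}/2 + 0.025$; at the fusion level the
default is $\ell = 0$, the rule exactly as stated. When two candidates
fall in one peak's S1 window the earlier keeps S1 (one S1 per cycle).
Candidates with no peak in scope — the usual case for S2 under the
nominal timing, where the systolic peak *precedes* S2 — are labelled by
alternation against the nearest preceding labelled event (within 0.6 s),
then by an amplitude heuristic, then S2. `refine_s2()` flags S2 events
farther than 50 ms (20 ms window + 30 ms slack) from every systolic peak
as low-confidence; they are retained.

Note that the nominal timing constants quoted in the field are not
mutually consistent: an S1→S2 gap of 300 ms, a VTT of 200 ms and an
"S2 20 ms before the systolic peak" cannot hold simultaneously. The
fusion rule only relies on S1 preceding its peak by about the VTT; S2
placement relative to the peak is treated as a confidence check, not a
labelling premise.

## Evaluation

`match_events()` pairs detections with reference events one-to-one within
a tolerance (default 60 ms, below half the minimum S1–S2 separation)
using the maximum-cardinality non-crossing matching computed by dynamic
programming; on a line with a tolerance an optimal matching can always be
uncrossed, so this attains the bipartite optimum (the test suite verifies
equality against a brute-force matcher on random instances). True
negatives — ill-defined in continuous time — are counted over half-beat
decision slots bounded by reference events and the midpoints between
them; a slot not anchored by a reference and free of false detections is
a true negative. Metrics are the standard SEN/PRE/SPE/ACC percentages;
cohort summaries use the arithmetic mean and sample (n−1) standard
deviation. The package ships the published per-subject counts of the
20-subject study cohort (`reference_detection_counts()`); the test suite
recomputes all 120 rows' metrics from the counts and reproduces the
printed values to their 2-decimal rounding, as well as the printed
between-model accuracy differences.

## The synthetic generator

Real recordings of the study cohort are not redistributable, so every
stage is validated against `generate_recording()`:

* beats from 0.5 s at `hr_bpm` with a jitter CV of 3 % by default
  (resting-state variability);
* S1: unit-amplitude Gaussian-windowed 60 Hz tone burst, ~70 ms wide, at
  each beat onset; S2: amplitude 0.4, 90 Hz, ~50 ms, 300 ms later — all
  inside the analysis band;
* PPG: a gamma-shaped pulse (fast rise, slow decay) peaking exactly VTT
  after the beat onset;
* white Gaussian noise on both channels, calibrated so that the
  within-burst signal power over the noise power matches `snr_db`
  (default 20 dB);
* annotations are the exact construction times, and identical seeds give
  bit-identical output.

What it does *not* emulate: murmurs and extra sounds (S3/S4), arrhythmic
beat sequences, amplitude drift across a recording, structured noise
(speech, sensor rubbing), or a dicrotic notch on the PPG. Passing the
synthetic acceptance checks therefore demonstrates the mechanics of the
pipeline — amplitude equalisation, thresholding, timing fusion — not
clinical performance on real data. In particular, model I's S2 blindness
on the synthetic cohort is sharper than on real recordings (constant
amplitudes make the energy separation clean), while its real-data
counterpart was a partial deficit.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on
60-second records, 20 subjects per cohort, at 2000 Hz — sizes chosen so
the whole validation executes in a few minutes on one core while still
containing 60–90 beats per record. Degenerate inputs are defined rather
than rejected: constant signals have zero envelope phase, min–max
normalisation maps constants to zero, a flat PPG yields an empty peak
list, and interval-rule boundary comparisons carry a nanosecond slack so
that exact construction identities survive floating-point arithmetic.

## Known limitations

* The fixed nominal VTT ignores inter-subject variability; no per-subject
  calibration is attempted (by design).
* The fallback labelling for candidates without a peak in scope is a
  heuristic; dense false-positive regimes can propagate an alternation
  error for one beat.
* Model II/III window boundaries can split a burst; events within 0.5 s
  of a boundary may differ from whole-signal detection, and duplicates
  closer than 50 ms are removed when windows overlap.
* The envelope-filter boost rescales *every* supra-threshold region,
  including noise bursts that clear the threshold; precision on very
  noisy records degrades before sensitivity does.
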