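---
title: "Quantifying spinal hyperexcitability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spinal hyperexcitability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinalreflex)
```

Spasticity after spinal cord injury (SCI) shows up in the lab as a coherent
set of measurable signatures: spontaneous ventral-root bursting in the
isolated cord, exaggerated dorsal-root-evoked reflexes, occasionally a
locomotor-like left/right alternation, a depolarized IPSP reversal potential
(weakened chloride-mediated inhibition), an enlarged persistent sodium
current (I~NaP~), and, in vivo, long EMG responses to tail pinch plus
frequent myoclonic twitches. This package implements the full quantification
chain for all of these signals, together with seeded generators that emulate
each input class with ground-truth annotations, so every stage can be
validated without animal data. This vignette explains the models, the
parameters that matter, and the choices made where the design was genuinely
open.

## Signal conditioning

Ventral-root activity is analyzed on a *rectified-integrated envelope*:
full-wave rectification followed by a causal first-order leaky integrator
with unity DC gain and time constant `tau_s = 0.1` s, emulating the analog
RC integrator of the acquisition chain. The discrete update is
$y_n = a\,y_{n-1} + (1-a)\,|x_n|$ with $a = e^{-1/(f_s \tau)}$. A constant
input settles to itself; a step reaches $1 - e^{-1}$ of its final value one
time constant after onset. A trailing rolling-mean smoother of the same
width is selectable (`method = "rolling"`) but non-default.

The EMG chain instead uses a *zero-phase* 4th-order Butterworth low-pass at
8 Hz (forward–backward filtering): EMG durations are measured off-line, so
the symmetric filter's freedom from group delay matters more than causality.
This asymmetry — causal envelope for ventral roots, zero-phase for EMG — is
deliberate and both properties are tested. Whether the original off-line
8 Hz filter was zero-phase is not documented anywhere we know of; the choice
here is explicit and configurable through `lowpass()`.

Baselines everywhere are `mean + k·sd` of the envelope over a *period of
inactivity*, with `k = 3` as the shared default. The inactivity window is
ideally user-chosen; `baseline_stats(env, "auto")` falls back to the 1 s
sliding window of minimal RMS for batch runs.

## Burst detection

`detect_bursts()` marks maximal epochs with envelope ≥ threshold, merges
epochs separated by less than `merge_gap_s = 0.2` s, and drops merged epochs
shorter than `min_dur_s = 0.05` s. The merge gap and minimum duration are
set relative to the 0.1 s envelope constant: sub-tau gaps and blips are
smoothing artifacts, not biology. Onset and end are threshold crossings *of
the envelope* (the integrated trace is what the original analysis chain
displays and measures); amplitude is the envelope peak, with the raw-trace
peak available by slicing the recording. The extracellular detection `k` is
not documented in the source methodology ("threshold-based" only); we use 3
for coherence with the EMG rule, and it is a logged, configurable parameter.
Detection is invariant under joint positive scaling of signal and baseline,
and the burst count is monotone non-increasing in `k`.

## Evoked reflexes

Each stimulus-aligned sweep is scanned by a voltage peak detector: local
maxima of the rectified trace above `mean + 3·sd` of the pre-stimulus
baseline, a 3 ms refractory period, and a 2 ms artifact blanking window.
Events accumulate over five consecutive sweeps into a PSTH with 20 ms bins
over the 15 s post-stimulus window. The short-latency reflex (SLR) is
counted over 10–40 ms post-stimulus and the long-lasting reflex (LLR) over
0.5–15 s. Because the 10–40 ms window is not aligned to the 20 ms bin grid,
SLR/LLR counts are taken directly from event latencies (exact window
membership); the binned PSTH is kept for display and aggregation.

Counts are corrected for spontaneous activity by subtracting the
pre-stimulus event rate scaled to each window:
`corrected = max(0, raw − pre_rate × window_length × n_sweeps)`. The
matched-window scaling and the floor at zero are our precisions of the
stated subtraction rule — counts cannot be negative. Per-preparation SLR and
LLR are the five-sweep *sums* (cumulative counts); a per-sweep mean is a
trivial division by `n_sweeps`.

The monosynaptic amplitude is the mean over sweeps of the peak rectified
amplitude in a 1–10 ms window. The monosynaptic latency and artifact width
are not parameterized in the source description; the defaults (3 ms latency
in the generator, 2 ms blanking) are configurable, not asserted.

`estimate_threshold()` returns the lowest stimulus intensity whose summary
satisfies the criterion (corrected SLR ≥ 1, or monosynaptic amplitude above
a stated criterion); `assess_use_dependence()` tabulates mean LLR per
interpulse interval normalized to the longest interval, flagging a monotone
use-dependent decline.

## Left/right coupling

`cross_correlogram()` computes the Pearson correlation of the two
mean-subtracted envelopes over a grid of lags; the zero-lag coefficient
$r_0$ is always the exact full-overlap Pearson correlation. Classification
follows the fixed rule: $r_0 > 0.5$ synchronous, $r_0 < -0.5$
locomotor-like, otherwise unclassified — boundary values are unclassified
(the rule says "above"/"below"; we take that strictly). Correlation is
computed on smoothed envelopes, after the rectify/integrate chain, not on
raw traces. The default lag grid is 10 ms (set `lag_step_s = 1/rate` for
sample resolution); $r_0$, the classified quantity, is independent of the
grid. The correlogram window is the whole episode by default.

## Intracellular analyses

**E_IPSP.** IPSP amplitudes at different holding potentials are fitted by
ordinary least squares; the reversal potential is the x-intercept $-b/m$,
and the chloride driving force is $E_{IPSP} - V_{rest}$. Junction potential
is a scalar offset subtracted from holdings before the fit (off-line
correction). Fewer than 22 points triggers a warning, not an error — 22 is
the conventional sampling density per cell. A numerically flat slope makes
the intercept unidentifiable and is an error.

**I_NaP.** The command is a slow ramp (12 mV/s, −70 to −10 mV over 5 s),
slow enough to avoid transient sodium channel opening. `fit_leak()` fits
$I = g_{leak}(V - E_{leak})$ over a subthreshold window, default
(−70, −60) mV; `extract_inap()` subtracts the leak and reports the peak of
the leak-subtracted inward current during the ascending phase (as a
positive magnitude) and the activation threshold, the potential at which the
slope of the leak-subtracted current first becomes negative. Numerical
choices:

* Slopes are estimated by least squares over a sliding 2 mV window — raw
  differencing at 10 kHz is noise-dominated — and the negative slope must
  persist for 1 mV, preventing single-sample triggers. The automatic slope
  tolerance is 3 standard errors of the window-slope estimate, with the
  noise SD taken from residuals of a local linear detrend at the foot of the
  ramp (detrending keeps the activation tail's systematic slope out of the
  tolerance). It degrades to zero for noiseless traces.
* The peak is read from a 0.5 mV running mean of the leak-subtracted
  current. The raw minimum over ~5×10⁵ samples would be inflated by
  $\sigma\sqrt{2\ln n}$ under additive noise (tens of pA at 5 pA noise);
  the smoothing bias on a noiseless standard trace is below 0.1%.
* Inward current is negative by convention; amplitudes are reported as
  positive magnitudes.

A known limitation, quantified by the tests: with a shallow activation
curve (Boltzmann slope k = 5 mV) the activation tail is not negligible even
at −70 to −60 mV, and a linear leak fit over that window absorbs about
0.46 nS of apparent conductance for the standard parameters (g_nap = 1 nS,
V½ = −45 mV, E_Na = +60 mV) — about 4.6% of g_leak — which biases the
leak-subtracted peak downward by roughly 20%. The test suite asserts the
analytically computed contamination rather than pretending it away. In
practice the leak should be fitted over a span verified to be linear, or
known leak parameters supplied; oracle-equivalence checks use the
generator's true leak for exactly this reason.

## EMG and behavior

`emg_response_duration()` applies the rectify → 8 Hz low-pass → mean+3SD
rule and sums all supra-threshold epochs between first onset and last
offset; long-lasting responses can be interrupted, so the total
supra-threshold time is the default and the onset-to-offset span is an
option. `mechanical_threshold()` returns the minimal pressure (grams) with
a positive-duration response. Per-animal EMG statistics across the ≥5
trials per animal should use the median (robust to a single failed trial);
this is the documented convention, not a hard-coded reduction.

`count_twitches()` implements the single-twitch rule: events across
channels within 0.1 s of each other merge *transitively* into one twitch,
counted at the earliest event's time. "Simultaneous" has no stated numeric
width; 0.1 s is our configurable default, comfortably inside human scoring
resolution. Merging is symmetric in channel order and invariant to event
ordering. `twitch_timecourse()` gives the hourly mean ± SD summary used for
post-treatment time courses.

## The synthetic generators

Every generator draws from one explicit seed, restores the caller's RNG
state, and emits ground truth sufficient to score the downstream analysis
without re-deriving it. Equal configs give bit-identical output.

* **Ventral-root bursts** are multiplicative noise-amplitude envelopes on a
  Gaussian carrier (white by default, 1/f selectable): detection operates on
  envelopes, so carrier detail is irrelevant. The burst envelope has a fast
  attack (50 ms) and slower release (250 ms) — multiunit bursts switch on
  abruptly — a plateau at the configured multiple of baseline SD, and
  Poisson-timed onsets with a 0.5 s separation guard (the annotation records
  what was actually placed). Defaults: 600 s at 10 kHz, 2 bursts/min at 8×
  baseline SD, 1–2 s duration.
* **Evoked sweeps** span 15 s on each side of the stimulus and contain a
  1 ms biphasic artifact, a monosynaptic spike (default 3 ms, 1 ms
  half-sine), deterministic SLR spikes, Poisson LLR events over 0.5–15 s,
  and Poisson spontaneous events pre-stimulus. Ground-truth latencies mark
  spike *peaks*, matching the peak detector's semantics. The default
  baseline is silent: the fixed mean+3SD rule presumes a baseline whose
  excursions rarely reach threshold, and full-bandwidth Gaussian noise
  violates that by construction (a rectified Gaussian crosses
  mean+3SD ≈ 2.4σ at a fixed ~2% per-sample rate). The fixtures therefore
  model the spike evidence; additive noise remains available, but exact-count
  checks do not hold under it — which is a faithful statement about
  threshold detectors, not a defect of the fixtures.
* **Coupled pairs** are envelope-scale signals at 1 kHz (cross-correlation
  operates on smoothed envelopes; simulating a 10 kHz carrier would add
  cost, not information). At the default duty cycle 0.5 the envelope is a
  pure sinusoid, so noiseless synchronous/alternating pairs give exactly
  ±1 at zero lag; other duty cycles use Hann-windowed bursts, which
  classify correctly but not at exactly ±1. Independent mode uses two
  separately smoothed noise processes.
* **IPSP series** are exact lines plus Gaussian noise; **ramps** are
  leak + Boltzmann persistent conductance with the analytic dense-grid
  (0.01 mV) peak and threshold stored as ground truth; **EMG/twitch**
  fixtures place isolated events on a 2 s grid (so isolated events can
  never fall inside one coincidence window) and coincident hindlimb+tail
  pairs 50 ms apart.

What the generators do *not* emulate: biophysical membrane dynamics, gating
kinetics beyond the steady-state Boltzmann, spike waveform diversity,
electrode drift, movement artifacts, or realistic baseline spiking
statistics. Passing tests therefore demonstrate that the measurement chain
is correct and self-consistent under controlled statistical structure — not
that it is robust to every pathology of real recordings.

## Problem sizes and reproducibility

The validation suite runs the standard fixtures at their native sizes —
600 s at 10 kHz for burst recovery (20 seeds), five 30 s sweeps at 10 kHz
per evoked preparation (50 seeds for the correction property), 30 s at
1 kHz per coupling episode (100 seeds per mode), 22-point IPSP series
(100 seeds), 5 s ramps at 10 kHz, and 20 s EMG segments at 13.5 kHz —
sizes chosen to match the recordings the methods describe while keeping a
full run in a few minutes on one CPU. `run_pipeline()` outputs are a pure
function of manifest, config and input files; the provenance log
(`provenance.jsonl`) records every parameter of every operation and
deliberately omits wall-clock timestamps so identical runs are
byte-identical.
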