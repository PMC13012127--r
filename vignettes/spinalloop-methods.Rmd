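---
title: "Methods: identifying and modeling autogenic spinal interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and modeling autogenic spinal interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinalloop)
```

## The scientific problem

Spinal interneurons that receive group I proprioceptive input from a hand
muscle and project excitation back to the motoneurons of that same muscle
close a segmental positive-feedback loop.  `spinalloop` implements the
analysis chain used to find such "autogenic" excitatory interneurons
(agINs) in chronic recordings from behaving primates and to characterize
what the loop does during voluntary wrist movements:

1. **Input**: peristimulus time histograms of responses to muscle-nerve
   stimulation, with the central latency referenced to the afferent volley
   (monosynaptic criterion < 1.5 ms).
2. **Output**: spike-triggered averages (STA) of rectified EMG, screened
   and tested for postspike effects (PSEs).
3. **Coupling**: decoding the neuron's spiking from the 50 ms of preceding
   EMG (sparse Bayesian lagged regression), and reconstructing the task
   EMG from the neuron's movement-aligned firing convolved with its PSE
   snippet.
4. **Function**: a closed-loop reflex simulator whose Ib (force) feedback
   gain governs EMG amplitude and duration, and trial-level labeling of
   afferent gain from stimulus-evoked responses, related to the size and
   duration of the upcoming burst.

Raw recordings are not distributed with the package; a seeded synthetic
session generator reproduces every data feature the pipeline consumes, with
full ground truth, so each stage is testable end to end.

## The synthetic session generator

`generate_session()` builds a mutually consistent set of task trials,
multichannel EMG, an interneuron spike train, and nerve stimulation events.

**Task structure.** Trials follow the instructed-delay wrist task: 0.8 s
central hold (rest), a 0.2–0.5 s cue, a 1 s instructed delay, a go cue,
movement against an elastic load, a 1.5 s active hold, passive return, and
reward.  Short-hold error trials truncate the hold uniformly at 20–60% of
its span and carry no reward; the torque trace is a critically damped
second-order step toward a direction-signed plateau.

**EMG.** Each channel is motor-unit shot noise: inhomogeneous-Poisson
events convolved with a 3 ms biphasic waveform (Gaussian derivative), plus
a Gaussian noise floor (SD 0.1 of the unit peak), sampled at 2 kHz.  Burst
*amplitude* factors act on the rectified-EMG scale; because the rectified
amplitude of shot noise grows with the square root of the event rate, the
rate carries the squared factor.  Bursts are phasic–tonic — the rate starts
at 2.2 times the tonic level and decays with a 0.25 s time constant — and
span 75% of the movement-to-release interval, so measured durations stay
inside the 1.8 s offset-search bound.  Each muscle draws independent
per-trial amplitude (log-SD 0.06), onset (SD 35 ms), and duration (log-SD
0.06) jitter: synergist envelopes share the task structure but are not
collinear, which is what makes the decoding closure identifiable.

**Interneuron.** Background spiking is drawn by thinning from
`descending(t) + gain * activity(t - delay)`, where `activity` is the
*realized* rectified, 20-ms-smoothed EMG of the target muscle (rescaled to
rate units).  Feedback from the realized signal rather than from the
abstract rate envelope matters twice over: it is what the afferent pathway
actually senses, and it couples the neuron to target-specific EMG
fluctuations that the decoder can exploit.  Defaults (tonic 5 Hz, +5 Hz
during the delay, gain 0.2, delay 10 ms) put the firing rates near the
observed regime (roughly 10 Hz at rest, 35–50 Hz during movement).

**Postspike kernel.** The injected facilitation is a raised cosine with
configurable amplitude, onset latency, and width at half maximum (the full
base width is twice the PWHM), added to the target channel after each
spike.

**Stimulation.** Each trial receives a configurable number of stimuli
spread over the rest/cue/delay epochs; each independently evokes a spike at
1.7 ms latency with the trial's gain probability (volley at +0.7 ms, so the
central latency is 1.0 ms — monosynaptic).  A trial whose stimuli evoke at
least one response is recorded as ground-truth *higher-gain*, and its
target-muscle amplitude and duration multipliers are drawn with a +20%
mean shift (SD 0.05) relative to lower-gain trials.  Labels are drawn
*before* the envelopes so the coupling is causal and exactly recorded.

**What the generator does not emulate**: motor-unit recruitment order and
unit-size heterogeneity, torque-from-muscle forward dynamics, correlated
multi-neuron populations, non-stationary electrode drift, and true
crosstalk between implanted wire pairs.  Passing closures on these sessions
therefore validate the *pipeline*, not any claim about a particular real
dataset.

## Spike-triggered averaging

`compute_sta()` averages rectified EMG from 50 ms before to 50 ms after
each spike; spikes are accepted as triggers only when the RMS of the
−30..+50 ms segment exceeds 1.25 times the channel noise floor (estimated
from the quietest tenth of 100 ms windows unless supplied), and fewer than
`min_triggers` (default 2000) accepted triggers is a reported error, never
a silent skip.  `smooth_and_detrend()` applies a flat five-point smoother
and subtracts the incremented-shifted-averages trend (shifts ±10, ±20, ±30
ms — the method's reference leaves the shifts unspecified; these bracket
the STA window at the package's sampling rate).  The baseline window is
−30..−10 ms, pre-trigger lags that are causally effect-free while avoiding
both the trigger and the acceptance-segment edge.

Significance uses the multiple-fragment analysis: accepted triggers are cut
into 20 contiguous blocks, each fragment contributes a paired
(test-window, baseline-window) mean from the raw rectified segments — the
paired design removes fragment-level trend, so no per-fragment detrending
is needed — and a two-tailed paired *t* test across fragments gives the
*p* value (threshold 0.05/12 for 12 muscles).  The test window is the
12-ms-long span 3–15 ms after the trigger — the only self-consistent
reading of the source's "12 and 3 to 15 ms".  Calibration holds when
trigger segments do not overlap heavily; at inter-spike intervals
comparable to the 100 ms averaging window, shared samples couple the two
windows and the test turns slightly anticonservative, so the null
calibration is run at ~5 Hz trigger rates.

Effect measurement: onset is the first post-trigger lag beyond 2 baseline
SDs (in the peak's direction) sustained ≥ 0.5 ms; the peak is the extremum
in the test window; PWHM is linearly interpolated at half the peak height;
magnitude is peak height as a percent of the raw baseline mean
(peak-based, noted in output metadata).  PSE vs synchrony follows onset
> 3.5 ms and PWHM < 7 ms.  The crosstalk screen combines a ±1 ms
cross-correlation threshold (0.3, calibrated so independent shot-noise
channels are flagged in well under 1% of runs) with narrow near-zero-lag
peaks in third-differenced STAs of both channels; the narrowness bound
defaults to the 3 ms motor-unit width, the sharpest feature the package's
2 kHz / 3 ms design point can resolve.  The putative-motoneuron screen
flags an unrectified 50-spike STA peak above 5 baseline SDs.

## Stimulus-evoked responses and trial gain

PSTHs use 0.2 ms bins over ±10 ms; onset is the first post-stimulus bin
exceeding baseline mean + 2 SD for two consecutive bins, and the central
latency subtracts the volley time (monosynaptic < 1.5 ms).  The evoked
peak area integrates the baseline-subtracted response density between the
onset and offset of the *pooled* response, separately per epoch — the
neuron's input–output gain.  Trial labeling is binary: a trial is
higher-gain when any pre-movement stimulus evokes a spike within (0, 5] ms
(stimulus-referenced, per the defining wording), lower-gain when none
does, and excluded (not lower) when no stimulus fell in those epochs.

## Task statistics

EMG preprocessing is zero-phase: 4th-order Butterworth band-pass 50–200
Hz, full-wave rectification, then a 2nd-order 5 Hz low-pass.  The envelope
smoother is deliberately low-order — higher orders pre-ring tens of
milliseconds around burst edges and bias onset estimates; zero-phase
filtering keeps onsets free of group delay.  Burst onset requires 2 SD
above the rest-epoch mean for ≥ 50 ms beginning no later than just after
movement onset; the hold-variant offset is the end of the last ≥ 200 ms
run above 1 SD before movement onset + 1.8 s; the sharp-drop variant takes
the local peak with the steepest drop to the next local peak.  Because
threshold crossings on a 5 Hz envelope carry an irreducible edge bias of a
few tens of ms, the duration-bias property is assessed on envelope-level
rectangles; at the burst scale of the task (≥ 0.5 s) this bias is a small,
label-independent offset that rank statistics ignore.

Both burst metrics are reported.  The trial-gain closure ranks trials by
the burst *mean* amplitude: the maximum of a 5 Hz envelope carries ~12%
intrinsic relative noise (rate-independent in the Gaussian-process limit of
overlapping units), which would bury a +20% coupling, while the
burst-mean averages it to ~4%.  Normalized ranks divide the ascending rank
by the per-session trial count (ties broken by trial order); the top-decile
test is the exact one-tailed binomial tail against 0.1.

The per-neuron direction bias compares movement+hold firing between
directions (two-sided Welch at 0.05 — the labeling rule is not fully
pinned down by the source, so it is config-exposed), and the population
test is a one-tailed exact binomial toward extension with unbiased neurons
excluded — the only reading consistent with a sub-0.001 bound at 13 of
14.  The success-vs-short-hold comparison is a two-tailed paired *t* test
on per-neuron response probabilities.

## Decoding

`build_design()` pairs each 1 ms spike-count bin inside the extension
movement epochs with the preprocessed EMG of every muscle at lags 1–50 ms
— strictly causal by construction.  For decoding, the envelope low-pass is
raised to 20 Hz: the informative signal includes fast target-specific
fluctuations that a 5 Hz envelope removes.  `fit_ard()` is
evidence-maximization (type-II ML) automatic relevance determination with
one precision per column, internally standardized columns, noise-variance
re-estimation, and pruning at precision 10^6 relative to the response
variance; convergence is declared when no column was pruned in the last
sweep and log-precisions moved less than 10^-3.  ARD at realistic SNR
retains a minority of noise columns at small finite precisions (an
inherent property of the evidence fixed points, shared by reference
implementations); sparsity claims are therefore stated as weight-mass
concentration rather than total pruning.  Cross-validation splits by trial
(never by bin) and scores Pearson correlation between 10-ms-Gaussian
smoothed predicted and observed rates.

## Reconstruction

The PSE snippet is the detrended STA over lags (0, 15]; a waveform still
above half its extreme value at the 15 ms edge is flagged truncated.  The
PETH (5 ms bins, −500..+2000 ms around movement onset) is upsampled by
zero-order hold and a bin-wide boxcar (area-preserving), convolved with
the snippet, and scaled by the sample duration.  The original trace for
comparison is the rectified, trial-averaged EMG smoothed with a boxcar
(5 ms by default; the closure analyses use 10–20 ms so both traces carry
comparable bandwidth — the source does not specify its smoother).  R is
the Pearson correlation over the burst onset→offset span; the area ratio
uses baseline-subtracted areas over the same span, and
`neurons_needed()` is `round(100 / ratio)`.

At the study scale (90 trials) the target-muscle reconstruction reaches
R ≈ 0.85; the ceiling is sampling noise — Poisson PETH noise and
trial-to-trial burst variability — not model mismatch, as the exact
spikes-convolved-kernel closure (R > 0.999 at 400 trials) shows.
Nontarget reconstructions use snippets that contain no injected effect;
their feedback-conditioned STAs tilt slightly negative at post-spike lags,
so their R is near zero or negative, and the target > nontarget ordering
is the robust, direction-preserving property.

## The closed-loop reflex simulator

`simulate_reflex()` integrates, at a fixed 0.5 ms step (explicit Euler; a
C++ kernel, because fitting re-runs it thousands of times):

- interneuron drive `a(t) = max(0, SP·pulse(t) + G_Ib · F(t − 20 ms))`,
- motoneuron drive `m(t) = sat(a(t) − G_Ia · x(t − 20 ms))` with
  `sat(u) = S·tanh(u₊/S)`, S = 10,
- EMG `e`: first-order on `m`, τ = 30 ms,
- force `F`: critically damped second order (ω = 15 rad/s) on
  `e · max(0, 1 − 0.8·x)` (force–length decline),
- plant `0.2·ẍ + 1.1·ẋ + 1.0·x = F`.

The free parameters are the Ib gain, Ia gain, and set-point amplitude
(defaults 1.4, 0.8, 0.3; 50 ms pulse).  The constants were chosen — the
source model's own constants are not printed in its main text — to place
the loop in the regime its block structure implies: early in the burst the
displacement is still small, so the effective loop gain `G_Ib·(1 − c·x)`
exceeds one and the loop amplifies regeneratively beyond the pulse
response; as the plant catches up, spindle inhibition and force–length
decline pull the gain below one and the burst self-terminates (the DC loop
gain `G_Ib − G_Ia/stiffness` is below one at the defaults).  A stiffness
an order of magnitude larger — with everything else equal — would make the
DC gain exceed one and latch the loop at a nonzero fixed point with no
burst offset; the chosen plant avoids that regime.  In this regime the Ib
gain dominates both the amplitude and the duration of the burst, the Ia
gain and set point have an order weaker effects, and 90–110% Ib sweeps are
strictly monotone in both metrics.

`emg_metrics()` takes the peak and the total time above 5% of it,
flagging no-offset runs; `fit_gains()` minimizes
`(1 − R) + normalized amplitude error` over the three gains with a 5×5×5
log-spaced grid followed by Nelder–Mead refinement from the best three
starts (deterministic, seed-free); recovery of generating gains from a
noiseless target is exact to optimizer tolerance, and within ~10% for the
Ib gain under 5% additive noise.  Halving the step changes the metrics by
under 0.5%.

## Problem sizes and frozen study conditions

Everything below is a package design choice, fixed once and exported so
tests and the acceptance script run identical conditions:

- `config_decoding_study()`: 12 extension trials, four muscles — about a
  hundred seeded neurons decode in a few minutes.
- `config_reconstruction_study()`: 90 extension trials (the scale of the
  largest recorded example), kernel amplitude 0.4, feedback gain 0.3.
- `config_trial_gain_study()`: 100 extension trials, target channel only,
  two stimuli per trial at gain 0.10 — roughly 20 true higher-gain trials
  plus a few mislabeled by background spikes in the 5 ms window, the
  realistic contamination the binomial test must overcome.
- Null calibration uses 1000 sessions at ~5 Hz trigger rates; kernel
  recovery uses ~5000 triggers.

## Known limitations

- The trial-gain label inherits a floor of false "higher" labels from
  background spiking (about 5% per stimulus at 10 Hz pre-movement rates);
  the power analysis in the tests accounts for it, but analyses of real
  sessions should, too.
- ARD retains occasional small-weight noise columns; muscle-level weight
  summaries are robust to this, individual lag coefficients are not.
- The reflex model is a lumped, deliberately minimal loop: no spiking
  motoneuron pool, no Hill-type muscle, a single delay per pathway.  Its
  constants are package defaults, all overridable, not estimates of any
  animal's parameters.
- Burst onset/offset estimates carry the envelope smoother's edge bias
  (tens of ms); comparisons across trials are unaffected, absolute
  latencies should be read with that in mind.
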