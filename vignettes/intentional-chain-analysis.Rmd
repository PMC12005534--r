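---
title: "Analysing the intentional chain in BMI-mediated actions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the intentional chain in BMI-mediated actions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentchain)
```

## The problem

A voluntary act unfolds as a chain: an *intention* to move, the *action*
itself, and an *effect* in the environment. In a person using a motor-cortex
brain-machine interface (BMI) whose decoder output drives real hand movement
through neuromuscular electrical stimulation (NMES), each link of that chain
can be switched on or off independently: NMES can move the hand without any
intention, the stimulation can be withheld while the decoder still registers
the intention, or the action's auditory consequence can be silenced. While
this happens, the participant watches a Libet-style clock (one hand, full
cycle in 2,560 ms, 60 ticks) and afterwards reports the clock position at
which they intended to move, moved, or heard the tone; a 96-channel
microelectrode array records spiking and field potentials in the hand area
of primary motor cortex (M1).

`intentchain` implements the full analysis pipeline for such sessions —
clock-report circular statistics and binding contrasts, multi-unit and
single-unit spiking analyses including a single-trial sigmoid model of
intention-locked firing, the wavelet-power movement decoder and its timing
statistics, and population-level PCA and LFP band-power analyses — together
with a synthetic-session generator that emulates the statistical structure
of the experiment so that every stage can be tested without any recorded
data.

## Session model and time conventions

All times are in milliseconds. Event times in the trial table are
trial-relative (0 = trial start); spike times in the spike table are
session-absolute, and each trial carries `t_start_ms`/`duration_ms` to move
between the two. Alignment windows put 0 at the alignment event with
negative values before it, and all bins are half-open `[t, t + bin)`.

A clock report is a tick position in `[0, 60)`. Because trials span several
clock cycles the position is ambiguous; `report_to_event_relative_time()`
resolves it by choosing the occurrence nearest the objective event, which is
safe because reports cluster well within half a cycle (±1,280 ms) of their
events. The resulting signed offsets are the unit of all behavioral
analysis; the `circular_median()` is defined as the in-sample geodesic
minimizer so that every test can check it against brute-force enumeration.

## The synthetic generator

`generator_params()` holds the study conditions; its defaults are the
design constants of the experiment, not tuning knobs:

* six conditions (IAE, AE, IE, IA, A-only, E-only) with 50 repetitions
  each, report queries rotated in mini-runs of five trials;
* the tone 300 ms after movement onset (or after the decoder threshold on
  movement-free IE trials);
* report biases of −597 ms (intention with ensuing action), −796 ms
  (intention without action), −526/−355 ms (action with/without intention)
  and −512 ms (effect); trial-level dispersions equal to the reported
  standard errors times √50 (≈263/151/122 ms);
* 96 multi-unit channels and 66 sorted units firing as inhomogeneous
  Poisson processes (thinning — chosen over time-rescaling because the
  accept-reject construction doubles as its own oracle), with gamma-drawn
  baselines of ~5 Hz, a movement transient peaking ~373 ms after movement
  (channel-average peak ~20 Hz), and in 30% of units a logistic step
  `f(t) = f_I / (1 + exp(-(t - t0)/α)) + f_b` locked to the trial's
  *latent* subjective intention time, with per-unit midpoints around
  −108 ms and steepness around α ≈ 23 ms;
* 12% of sorted units whose pre-movement spike count co-varies with the
  latent intention time at a target correlation of 0.5.

The latent-variable structure matters: the subjective intention time is
drawn per trial (event + bias + noise), the report is a noisy reading of it,
and responsive units lock to the latent time rather than the report. This
is what makes report-aligned averages sharper than stimulus-aligned ones,
the structure the evoked-onset analyses exploit.

Trial length is not dictated by the design, so the generator draws action
times uniformly in 4–8 s after trial start (snapped to the 100 ms decoder
grid) with a 3 s tail — matching the ~11 s trial periods of the original
protocol while leaving room for the ±2.5 s analysis windows.

### Decoder traces

Per-trial decoder traces are the mean condition profile plus bin noise
(SD 0.15), clipped to [−1, 1]. For intended movements the mean profile
rests at −0.85, steps up detectably at −1,100 ms (the ensemble bifurcation
time), rises linearly to 5 noise SDs above rest at −70 ms (the per-trial
"objective intention" criterion) and crosses zero exactly at the action;
NMES-evoked movements rise abruptly just before the action; movement-free
IE trials collapse shortly after crossing; no-effect IA trials hold their
plateau longer. A per-trial gain on the positive lobe produces the AUC
variability that the binding couplings act on (high AUC shifts intention
reports later and action reports earlier, the qualitative pattern of the
study). These pieces cannot all be made exact simultaneously — with bin
noise, the first 5-SD exceedance on single trials tends to precede the
−70 ms mean crossing — so the profile prioritizes the zero-crossing
contract (exact) and the ensemble bifurcation time; the per-trial objective
lead is whatever the 5-SD rule yields, and the acceptance script reports
the computed value.

### LFP

One array-average channel at 1 kHz: 1/f background plus a sustained 2 Hz
(delta) envelope from −1,000 ms before the anchor on intention trials and a
post-movement 10/20 Hz (alpha/beta) transient on action trials. The
single-channel choice reflects what the in-scope analyses consume (band
power of a field signal); no spatial structure is modelled.

## Analysis stages and numerical choices

**Smoothing.** Spikes are binned at 1 ms and convolved with a Gaussian
kernel (SD 50 ms, truncated at ±4 SD, unit area), so the integral of the
rate equals the spike count — the invariant the unit tests assert.

**Evoked onset.** Noise is the SD of the trial-averaged trace over a
baseline window (default −2,000 to −1,500 ms); the onset is the first bin
exceeding baseline mean + 5 SD, sustained for at least 10 ms. The sustain
requirement is ours: a bare 5-SD rule fires on single-bin noise.

**Perturbation robustness.** Reports are jittered uniformly in ±w for
w = 10…1,000 ms; the response counts as degraded once ≥10 one-millisecond
bins differ from the unjittered average at p < 0.01 (per-bin unpaired
Welch t — the test statistic is not dictated by the procedure's source, so
the most conservative unpaired choice is used and is swappable).

**Single-trial sigmoid fits.** `fit_sigmoid()` profiles the two linear
parameters in closed form over a (t0, α) grid and refines with bounded
Levenberg-Marquardt; when the trace was kernel-smoothed the model is the
*smoothed* logistic, so the recovered α describes the underlying rate
change rather than the kernel. `fit_sigmoid_counts()` is the recommended
single-trial path: the trace-stage fit supplies starting values and the
retention r², and a Poisson maximum-likelihood refinement on 10 ms counts
supplies the parameters — the correct noise model for sparse spiking, which
removes most of the Gaussian-loss bias at low rates. Fits whose midpoint
lands on the window boundary are flagged invalid (they are change-point
fits that never located a change). Retention keeps fits with r² > 0.5
(strict); r² of a nonlinear fit can be negative and is reported as-is.
Even so, single-trial change-point estimation at ~5→20 Hz is left-skewed:
spurious basins in the long baseline attract a few percent of fits, so
retained means carry a residual bias of a few tens of milliseconds that
shrinks with the evoked-response SNR. The default fit window is −2,000 to
+200 ms around the reported intention; shortening the baseline flips the
bias sign rather than removing it.

**Decoder pipeline.** The wavelet transform is an 11-level periodized
Daubechies pyramid (db4 by default — the order is a dialect knob, the
source method names only the family); levels 3–6 span 234.375 Hz–3.75 kHz
at 30 kHz, the multi-unit band. Mean squared detail coefficients are
averaged in 100 ms bins and z-scored per channel against a trailing 10 s
baseline. Because db4 filters roll off slowly, a tone near a band edge
(e.g., 1 kHz against the 937.5 Hz edge) legitimately spreads into the
neighbouring level; tests therefore probe mid-band tones and cross-check
against a Butterworth filter-bank oracle. The classifier is an RBF-kernel
SVM preceded by an L1-logistic feature ranking that zeroes out the least
valuable features ("sparsity optimization"); scores are decision values
scaled by the largest training magnitude and clipped to [−1, 1]. Movement
triggers at the first zero-crossing from below; the objective intention
time is the first bin exceeding rest noise by 5 SD, with rest statistics
pooled from bins well before each trial's anchor (≥5 s required).

**Population stages.** PCA is fit on time-concatenated condition-average
channel rates (channels as variables) and the bootstrap refits the PCA on
every resample, as the source procedure specifies. The LFP map is a Morlet
transform (ω₀ = 6) normalized so a unit sine yields the same power at every
frequency, making band powers directly comparable; band edges are
delta 0.5–4, theta 4–8, alpha 8–13 and beta 13–30 Hz (the upper beta edge
is our choice; the source names only "alpha and lower beta"). Baseline
(−2,200…−2,000 ms) versus induced power is classified per 100 ms step by a
10-fold cross-validated SVM with a one-sided binomial test against chance.

## Problem sizes

The test-suite fixtures use 4–8 trials per condition with 4–8 units; the
calibration and recovery studies use the sizes of their respective designs
(200 trials for sigmoid recovery, 1,000 null units × 15 trials for the
correlation calibration, 100 replicate seeds for the binding power check,
500 simulations for the divergence family-wise-error check). The
acceptance script runs the behavioral and spiking sessions at the full
design scale (50 trials per condition, 96 channels + 66 units) and the LFP
session at 30 trials per condition.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analyses assume:
Poisson spiking with additive rate components, Gaussian report noise with
linear binding couplings, piecewise-linear decoder profiles, stationary
band envelopes. Real sessions add non-Poisson bursting and refractoriness,
electrode drift and unit instability across hours, NMES artifacts far more
structured than threshold deflections, correlated noise across channels,
and report idiosyncrasies (clock-position anchoring, strategic rounding).
Passing the suite therefore demonstrates that each stage recovers what it
is designed to recover under its own assumptions — not that those
assumptions hold in any particular recording. The external-data targets
(e.g., the 257 ms pairwise interval or the 81.9% explained variance of the
deposited sessions) require the deposited data and are out of desk scope;
the acceptance script instead reports the same quantities computed on
synthetic sessions at design scale.

## Known limitations

* The sigmoid recovery bias discussed above: retained-fit means of t0 are
  accurate to a few tens of milliseconds, not better, at realistic rates.
* The decoder profile is phenomenological; it reproduces timing contracts
  and condition contrasts, not the geometry of real decoder dynamics.
* Artifact blanking detects threshold crossings on monitor channels; real
  NMES artifacts have ringing that the 3.5 ms blank may not fully cover.
* No spike sorting: the generator emits already-sorted units, and
  channel-level multi-unit activity is modelled directly.
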