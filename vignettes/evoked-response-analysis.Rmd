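---
title: "Quantifying optogenetically evoked responses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optogenetically evoked responses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoresp)
```

## The measurement problem

Brief (1-ms) optogenetic activation of channelrhodopsin-expressing axons
perturbs the ongoing firing of downstream neurons. Given sorted spike times
and stimulus markers from an awake recording, the analysis must decide, per
unit, whether the stimulus evoked excitation, inhibition, excitation
followed by inhibition, or nothing; estimate the latency of each component;
and quantify response magnitude in a way that is comparable across cells,
light powers, and pulses of a 20-Hz train. A companion problem arises in
vitro: measuring evoked EPSC amplitudes, and their short-term depression
across a five-pulse 20-Hz train, from voltage-clamp sweeps that also carry
the slow subthreshold membrane oscillation typical of inferior olive
neurons.

`optoresp` implements both halves plus a synthetic-data generator, so each
estimator is validated by parameter recovery against known ground truth
rather than against unavailable raw recordings.

## The PSTH model and detection criteria

All in vivo statistics derive from the peristimulus time histogram:
trial-aligned spike counts in half-open bins `[start, start + width)`,
summed across trials (`compute_psth()`, default width 2 ms). A spike
falling exactly at stimulus onset belongs to the first post-stimulus bin;
half-open windows are used everywhere in the package so that no spike can
be double-counted across adjacent bins or windows.

Baseline statistics (`baseline_stats()`) come from the 3 s preceding
stimulus onset: the mean firing rate, and the mean and SD of the per-bin
trial-summed counts. The detection thresholds are applied to the
trial-summed PSTH, so the matching spread measure is the SD of the
trial-summed bin counts; this choice is kept configurable (`per_trial`)
because the convention cannot be recovered from summary reports alone.

* **Excitation** (`detect_excitation()`): the first post-stimulus bin
  within the 30-ms search window whose count reaches
  `bin_mean + 3 * bin_sd`. The 30-ms bound mirrors the extra-spikes window;
  it is configurable because an unbounded search only raises the
  false-positive rate without changing true detections at these latencies.
* **Inhibition** (`detect_inhibition()`): the first run of three
  consecutive bins, within a 100-ms window (suppression outlasts the brief
  excitation), each below a low threshold. The published criterion — counts
  "less than 1 SD of the mean baseline count" — admits two readings. The
  default reads it as `bin_mean - 1 * bin_sd`, the only reading that yields
  a usable suppression test for tonically active cells; `criterion =
  "sd-value"` implements the literal alternative (`1 * bin_sd`). Under the
  default, a unit with `bin_mean <= bin_sd` cannot express the signature at
  all (counts are non-negative); such units are reported absent with flag
  `"floor-limited"` rather than silently negative.

`classify_response()` combines the detectors: Ex, In, Ex+In (excitation
precedes inhibition) or NR. Inhibition detected at or before the
excitation latency is classified In and flagged as an anomaly.

### Latency reporting

A threshold crossing is resolved only to a bin. The package reports the
crossing bin's **midpoint** by default: for an event known only to lie in a
half-open bin, the midpoint is the unbiased location estimate, whereas the
leading edge is biased early by half a bin width. `point = "leading"` gives
the literal reading of the definition. Cohort latency means with sub-bin
precision are obtained by narrowing the bins (recovery analyses in this
package use 0.5-ms bins), not by interpolation.

### Operating characteristics of the published criteria

Because trial-summed bin counts are Poisson rather than Gaussian, the
single-bin 3-SD excitation criterion has a per-bin tail probability of
roughly 0.8–0.9% at realistic baseline counts (versus 0.13% for a Gaussian
3-sigma test). Over a 15-bin (30-ms, 2-ms bins) search this compounds to a
~10–13% family-wise false-positive rate on genuinely unresponsive units.
The inhibition criterion is a 1-sigma left-tail test (per-bin mass
~12–17%); three consecutive sub-threshold bins then occur spuriously
somewhere in a 100-ms window in roughly 10–40% of active null units. These
rates are properties of the criteria themselves, not of this
implementation; the test suite measures them on simulated no-response
cohorts, and users comparing cohort compositions should treat the NR/Ex
boundary as correspondingly soft. Raising the threshold multiplier is
monotone (a response can only disappear), so more conservative analyses are
easy to run.

## Response magnitudes

* **Extra spikes** (`extra_spikes()`): spikes within 30 ms of onset,
  averaged over trials, minus the count expected from the 3-s pre-stimulus
  baseline rate (`baseline_mean_rate * window`). Reported per stimulus;
  zero in expectation for an unperturbed Poisson train, negative under
  suppression.
* **Train profiles** (`train_profile()`): the extra-spikes statistic per
  pulse position of the five-pulse 20-Hz train, normalized to pulse 1, with
  depression percentages `(1 - normalized[k]) * 100`. Per-pulse windows are
  capped at the 50-ms pulse spacing so windows never overlap the next
  pulse. A non-positive first-pulse response leaves normalization undefined
  (flagged), rather than producing unstable ratios.
* **Graded responses** (`graded_response()`): extra spikes per light power
  (at least three powers), normalized to the 1-mW response — measured
  directly when 1 mW was tested, otherwise linearly interpolated between
  the bracketing powers; one-sided designs fall back to the nearest power
  with a flag. Normalizing by a noisy denominator biases ratios upward by
  a factor `~(1 + CV^2)` of the denominator; at the trial counts used here
  this is a few percent and is quantified in the recovery tests.

## EPSC measurement

`measure_epsc()` measures each pulse against a **local** pre-pulse
baseline: the mean current over the 5 ms before the pulse, with the
amplitude taken as the largest inward deflection from that baseline within
20 ms after it (extremal sample, no curve fitting — the quantities of
interest are amplitudes and ratios, not kinetics). Local baselining is the
minimal correction that removes both the residual decay of the previous
EPSC in a 20-Hz train (with an 8-ms decay constant the tail 50 ms later is
under 1% of the peak) and the slow membrane oscillation, provided the
oscillation period is long relative to the 5-ms baseline window.

`epsc_train_profile()` averages the sweeps pointwise **before** measuring
(the conventional treatment of repeated voltage-clamp responses; a
per-sweep mode is available). Averaging first matters because peak-picking
on a noisy trace is max-biased: each amplitude inflates by roughly 1–2
noise SDs, which cancels only partially in normalized ratios. Amplitudes
are reported as positive magnitudes of inward current.

## The synthetic-data generator

`simulate_spike_train()` draws from an inhomogeneous Poisson process:
constant baseline, multiplicative suppression windows, and additive evoked
spikes per pulse. Because thinning and superposition preserve Poissonity,
the realized process follows the target rate function exactly
(`unit_rate_function()` exposes it for quadrature checks).

Generator design choices worth stating:

* **Evoked kernel anchored at the latency.** Evoked spike times are
  `pulse + evoked_latency + |N(0, jitter_sd)|` — a causal half-normal tail
  whose onset equals `evoked_latency`. The latency the analysis measures is
  a threshold-crossing (onset) time; anchoring the kernel at the onset
  makes recovery self-calibrating. A symmetric kernel centred on the
  nominal latency would make every measured onset earlier than the
  parameter by about two jitter SDs, turning a parameterization convention
  into an apparent estimator bias.
* **Area parameterizes extra spikes directly** (expected evoked spikes per
  pulse), scaled by a per-pulse depression factor (fixed multiplier vector,
  not a dynamic resource model — only first-to-k ratios are analyzed) and a
  power-gain function (default proportional to light power).
* **Inhibition as multiplicative rate suppression** over a configurable
  window — the simplest mechanism producing the consecutive-low-bin
  signature.
* **Seeding:** each unit owns a private RNG stream derived from
  `(master seed, unit index)`; simulation never disturbs the caller's RNG
  state, and cohorts regenerate byte-identically.
* **Baselines.** Spontaneous rates of these precerebellar populations are
  not pinned down by published summaries; defaults assume 10 Hz for
  excitatory/unresponsive units and 40 Hz for inhibition-bearing classes in
  `make_cohort()`. The latter is a detectability requirement, not a free
  dial: below ~13 Hz (at 2-ms bins, 40 trials) the inhibition criterion is
  floor-limited, so a cohort meant to contain detectable inhibition must be
  tonically active — consistent with these nuclei firing at tens of Hz.

`simulate_sweep()` builds sweeps as holding current plus superposed
difference-of-exponentials EPSC kernels (unit-normalized peak, so the
amplitude parameter is the peak in pA), sinusoidal oscillation with random
phase per sweep, and white noise, at 10 kHz.

What the generator does **not** emulate: bursting or refractory structure
in baseline firing, spike-sorting contamination, non-stationary baselines,
ChR2 desensitization within trains (depression is imposed, not mechanistic),
conductance-based oscillation dynamics, or series-resistance artifacts.
Passing recovery tests therefore demonstrates estimator correctness under
the stated statistical assumptions, not robustness to every pathology of
real recordings.

## Problem sizes and numerical choices in the validation suite

The recovery analyses simulate cohorts matched to the published study
designs: 28- and 15-unit excitatory cohorts (40 trials each, 0.3-ms jitter,
detection at 0.5-ms bins, recovery tolerance ±0.3 ms), a 5-unit
inhibition-only cohort (200 trials, 1-ms bins, 40-Hz baseline, ±1 ms),
a 10-unit graded cohort (±3 cohort SEM), 8 simulated cells × 10 sweeps for
EPSC depression (±3 percentage points), and 7 units for in vivo train
depression. For the latter, the per-cell normalized pulse ratio at 40
trains carries a counting SD of ~0.2 (Poisson spiking with ~1 evoked spike
per pulse), i.e. a 7-cell cohort SEM near 8 percentage points; the
package's own recovery test therefore uses 2000 trains per unit, which
brings the SEM near 1 percentage point and isolates estimator bias from
sampling noise. The always-on property suite checks exact count
conservation against loop oracles, null calibration of extra spikes over
100 seeds, threshold monotonicity, label recovery on strong-effect cohorts
(≥ 90%), I/O round trips (lossless to 1e-9 s), and the false-positive
operating characteristics discussed above.

## Known limitations

* Latencies are bin-resolved; sub-bin precision requires narrow bins and
  hence enough trials per unit.
* The inhibition criterion is insensitive for low-rate units by
  construction (floor limitation) and has a high family-wise false-positive
  rate over long search windows; flags make both visible but do not repair
  them.
* Ratio-based normalizations (train profiles, graded curves) are biased
  upward by denominator noise at low trial counts.
* EPSC measurement assumes pulse-locked responses well clear of clipping;
  only an optional amplitude-limit flag guards against saturation.
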