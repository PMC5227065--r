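---
title: "Laminar analysis of attention and working-memory modulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar analysis of attention and working-memory modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamflow)
```

## The problem

A laminar multi-contact probe inserted perpendicular to the cortical
surface of primary visual cortex records, at 24 contacts spaced 0.1 mm
apart, two signals per trial: the local field potential (LFP, the
low-frequency extracellular voltage) and the multi-unit activity envelope
(MUA, the rectified and smoothed high-frequency band, a proxy for
aggregate spiking near each contact).  In a curve-tracing task the
receptive field of the recorded column contains a contour element that
belongs either to the behaviourally relevant curve (the *target*) or to an
irrelevant one (the *distractor*), while the feedforward stimulation is
identical; in the memory variants the stimulus is flashed briefly and the
animal operates on its memory.  The scientific questions are *where in the
cortical column* the attention and working-memory signals arrive, *how
strong* they are relative to the stimulus-driven response, and whether
their laminar signatures coincide.

`lamflow` implements the full analysis chain for such recordings —
current-source density (CSD) estimation, depth alignment, response
normalization, modulation and latency metrics, penetration-level
statistics, decoding and eye-movement screening — together with a
synthetic laminar-column generator with known ground truth, so that every
stage can be validated without access to recorded data.

## Current-source density

The one-dimensional CSD is the negative scaled second spatial derivative
of the potential along the probe:

$$\mathrm{CSD}(x) = -\sigma\,\frac{\phi(x+h) - 2\phi(x) + \phi(x-h)}{h^2},$$

with tissue conductivity $\sigma = 0.4\ \mathrm{S\,m^{-1}}$ and derivative
step $h = 0.2$ mm (two contacts).  Negative values are current sinks.  Two
numerical choices matter:

* channels within $h$ of the probe ends get **no** estimate (they are
  masked, not zero-padded) — padding would fabricate sinks at the
  boundaries;
* no spatial smoothing is applied; $h$ is exposed as a parameter, and
  the analysis is insensitive to using $h = 0.1$ mm instead.

`lfp_from_csd()` inverts this exact discrete operator.  Because the
second difference at step $k$ channels couples $k$ interleaved channel
chains, the inverse needs $2k$ integration constants; they are fixed by
assigning the two `boundary_values` to the $2k$ channels nearest the deep
end (zero by default).  The roundtrip
`compute_csd(lfp_from_csd(C))` is exact at interior channels to machine
precision, which is the package's primary structural oracle: the
simulator forward-models its LFP through this inverse, so the analysis
path can be checked against the generating truth exactly.

## Depth alignment and laminar compartments

The border between layer 4C and layer 5 is estimated from the evoked CSD
as the polarity reversal — sinks in layer 4C above, sources in the deep
layers below — time-averaged in a 40 ± 10 ms window after stimulus onset.
When noise produces several sign transitions, the reversal is taken at
the *lower edge of the contiguous sink region containing the strongest
sink*; a nearest-transition fallback covers profiles where no source lies
directly below that region.  The boundary is placed at the midpoint
between the straddling channels.

Compartments follow fixed anatomical depth bands relative to the
boundary: deep layers 0.05–0.55 mm below, layer 4 0.05–0.55 mm above,
superficial layers 0.65–1.15 mm above.  Each band is closed at its lower
printed bound and open at the upper one, so on the 0.1 mm contact grid
(whose depths relative to the boundary are odd multiples of 0.05 mm) each
band holds exactly five channels and every depth maps to at most one
compartment.  Channels below the deep band (layer 6 territory) and in the
0.55–0.65 mm gap stay `unassigned`; whether layer 6 deserves separate
treatment is left open deliberately, and those channels are simply
excluded from compartment statistics.

## Normalization, modulation and latency

MUA is normalized per recording site: subtract the spontaneous rate
(mean over −150–0 ms) and divide by the peak of the trial-averaged
distractor-condition response in the 50–90 ms window.  On this scale the
*modulation* — the target-minus-distractor difference averaged over the
200–750 ms sustained window — reads directly as a fraction of the peak
response.  Sites whose reference peak is not positive are flagged and
excluded rather than silently producing unstable ratios.

Response latency is estimated by fitting the sum of a Gaussian and a
cumulative Gaussian (plus offset) with bounded Levenberg–Marquardt least
squares, and reading off the earliest time at which the fitted curve
reaches 33% of its maximum above the offset.  Initialization uses the
half-peak crossing (cumulative mean) and raw peak (Gaussian mean), with
amplitudes bounded below by zero; on a noiseless cumulative Gaussian with
mean $\mu$ and width $s$ the estimate equals the closed form
$\mu + s\,z_{0.33}$ to well under one sample at 763 Hz.

LFP band power (gamma 30–90 Hz vs alpha 5–15 Hz) uses a Hann-window
Welch periodogram with 50%-overlap segments, written directly on top of
the FFT; the estimator is density-normalized, so white-noise band power
is proportional to bandwidth.  The analysis window defaults to the
modulation window, a configurable choice since no canonical window is
fixed for the spectral comparison.

Receptive fields are mapped from slow bar sweeps in eight directions:
response onset and offset times are projected to bar positions, and each
RF border is the midpoint of the estimates from opposing sweep
directions, so any response latency that is equal in the two directions
cancels exactly.

## Statistics at the penetration level

Channels of one probe are strongly correlated, so *penetrations* are the
statistical unit everywhere: values are averaged across channels (or
within compartments) per penetration before testing.  The toolbox is:

* Wilcoxon signed-rank tests for paired comparisons, rank-sum tests
  across tasks, with optional Bonferroni factors;
* a one-way repeated-measures ANOVA over the three compartments with the
  Greenhouse–Geisser $\varepsilon$ (estimated from orthonormalized
  contrasts of the sample covariance) applied whenever $\varepsilon < 1$,
  plus Bonferroni-corrected signed-rank post-hocs;
* laminar-profile consistency: Pearson correlations over all
  $N(N-1)/2$ penetration pairs within a task (or $N$ matched pairs
  between tasks), tested by a signed-rank test of the $r$ values against
  zero; the channel-shuffle control destroys the laminar structure while
  preserving the value distribution and must give mean $r \approx 0$;
* a cluster-based sign-flip permutation test on per-penetration CSD
  difference maps: t-map, cluster-forming threshold $|t| > 2$,
  4-connected clusters of common sign scored by summed $t$, null from
  random sign flips of whole penetrations, add-one-smoothed p-values
  against the maximum null cluster mass (family-wise error control).
  The threshold and permutation count are declared defaults in standard
  cluster-permutation practice, not values inherited from any particular
  analysis, and both are exposed.

Single-trial decoding uses a linear SVM (fixed cost 1, features
standardized per training fold) on per-site MUA window means, scored by
the ROC area of its continuous decision values on a held-out stratified
10% of trials, averaged over 10 random splits.  The ROC orientation is
fixed by the classifier's vote direction — letting an ROC routine pick
the favourable direction would bias chance-level accuracy upward.  For
two Gaussian classes with equal covariance at Mahalanobis separation
$d'$, the optimal ROC area is $\Phi(d'/\sqrt 2)$, which the
cross-validated accuracy tracks within sampling error.

Microsaccades are runs of at least 5 consecutive samples of
central-difference eye speed above 5 times the speed SD at 250 Hz.  The
SD scope (whole trial vs fixation epoch) is not canonical; the default is
the whole trial, and `sd_samples` restricts it.  Trials containing any
event are excluded before analysis.

## The synthetic laminar column

The generator emulates the structure the analysis is designed to detect,
with every parameter explicit:

* **Geometry/rates**: 24 channels at 0.1 mm; LFP and MUA on a 763 Hz
  time base; eye traces at 250 Hz; 100 trials per condition by default
  (recorded sessions used blocks of about 100).
* **Task schedules**: attention (stimulus to 750 ms), memory (off at
  150 ms), mask (50 ms mask at 400 ms), capacity (cue at 700 ms, trial
  to 1200 ms).
* **MUA model**: per channel, a rate envelope — baseline 0.2, a
  transient peaking in the 50–90 ms window (latency 35 ms in layers 4C
  and 6, 5–15 ms later elsewhere), a sustained component (0.35 of peak;
  decaying with a 250 ms constant towards a 0.08 floor after stimulus
  offset, with an off-response of configurable gain, default 0.3), a
  mask transient where scheduled, and the condition modulation
  $m \cdot w(t)$ added for the target.  The drive is normalized so the
  distractor peak is exactly 1, making the configured $m$ the true
  modulation on the normalized scale.  $w(t)$ is fully established when
  the 200–750 ms window opens, is exactly zero over 450–550 ms and
  exactly one over 650–750 ms in the mask task, and covers only
  900–1150 ms in the capacity task.
* **Presets**: per-compartment modulation (superficial, layer 4, deep) =
  (0.30, 0.10, 0.30) for `attention_like` and (0.15, 0.05, 0.15) for the
  memory-type presets — stronger in superficial/deep than layer 4, and
  weaker without a visible stimulus — and all-zero for `null`.  The
  memory off-response amplitude is a free parameter, since no value
  constrains it.
* **CSD model**: an early layer-4C sink with a deep source (producing
  the polarity reversal used for alignment), a later sustained
  sink/source pattern, and a modulation pattern with sinks in the
  superficial layers and layer 5; the LFP is obtained by the exact
  inverse operator, so the analysis CSD equals the true CSD plus noise.
* **Noise**: additive Gaussian, independent across channels — LFP SD
  0.02, MUA SD 0.1 (in units of the peak response) truncated at zero,
  eye jitter SD 0.05 deg around a small (−0.02 deg) fixational bias.
  The envelope noise is deliberately small relative to the baseline rate
  (truncation touches well under 1% of samples) so that zero-truncation
  acts as a physical guard, not as a distortion of the rate model; MUA
  envelopes of well-isolated sites are smooth at this scale.

What the generator does **not** emulate: spiking point processes (the
MUA *is* an envelope, matching the recorded signal; a wideband AM-carrier
mode exists only to exercise the envelope extractor), 1/f and spatially
correlated LFP noise, realistic eye-movement dynamics (drift, tremor,
main-sequence kinematics), behavioural error structure, and
volume-conduction physics beyond the one-dimensional operator.  Passing
the validation suite therefore demonstrates the *correctness of the
analysis code* under the stated model, not robustness to every
real-data pathology.

## Validation experiments and problem sizes

The `*_experiment()` functions rerun the full simulate → analyse path:

* boundary recovery over 50 sessions with boundaries 6–18;
* parameter recovery of (0.30, 0.10, 0.30) over 24 penetrations
  (60 trials per condition, 250 Hz time base), with the compartment
  ANOVA and post-hocs;
* type-I calibration under the `null` preset: 1000 simulations of 24
  penetrations (4 trials per condition, 250 Hz) for the signed-rank test
  and the RM-ANOVA, and 1000 simulations of 12 penetrations with 199
  sign-flip permutations for the cluster test;
* the shuffle control on consistent profiles, the decoder closed form at
  $d' \in \{0, 1, 2\}$ with 1000 trials, and the mask scenario with 12
  penetrations.

The reduced trial counts and the 250 Hz time base in the Monte-Carlo
studies are the package's own problem-size choices: the quantities being
calibrated (test levels, recovery biases) are invariant to them, and they
keep thousand-replicate studies at desk scale.  Full-scale defaults
(763 Hz, 100 trials) remain the generator's defaults.

## Known limitations

* Filter *corners* are fixed by the recording protocol, but the filter
  *design* (4th-order zero-phase Butterworth, odd-reflection padding) is
  a package choice; other designs will shift stopband numbers slightly.
* The preamplifier amplitude/phase correction is an identity hook:
  the published transfer function is not available, so
  `condition_lfp(preamp_correction = )` accepts a user-supplied one.
* The cluster permutation test assumes exchangeability of penetration
  signs under the null; strongly asymmetric penetration noise would
  violate it.
* `find_reversal` requires an actual evoked sink/source pattern; on
  spontaneous activity it raises an error rather than guessing.
* Decoding uses a single fixed regularization (cost = 1); no
  hyper-parameter search is performed, matching the fixed-protocol
  analysis the package mirrors.
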