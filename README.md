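# lamflow

Laminar electrophysiology pipeline for attention and working-memory
modulation in early visual cortex.

`lamflow` is for neurophysiologists analysing trial-structured recordings
from multi-contact laminar probes (24 contacts, 100 µm spacing) in V1-like
cortex: it turns per-trial LFP and MUA-envelope arrays into
current-source density (CSD) profiles, aligns penetrations in depth at the
layer-4C/5 boundary, quantifies how much stronger the target-curve
response is than the distractor response in each laminar compartment, and
tests those effects at the penetration level.  A synthetic laminar-column
generator with known ground truth makes the entire chain testable end to
end without any recorded data.

## The core quantities

* **CSD** (Mitzdorf second spatial difference):
  `CSD(x) = -σ·[φ(x+h) − 2φ(x) + φ(x−h)]/h²`, with σ = 0.4 S/m and
  h = 0.2 mm; negative = current sink.  `lfp_from_csd()` is the exact
  discrete inverse, used as the forward model and structural oracle.
* **Depth alignment**: the 4C/5 border is the CSD polarity reversal
  (sinks above, sources below) around 40 ms after stimulus onset;
  compartments are fixed depth bands (deep 0.05–0.55 mm below, layer 4
  0.05–0.55 mm above, superficial 0.65–1.15 mm above the border).
* **Modulation**: per site, MUA is baseline-subtracted and scaled by the
  distractor-condition peak (50–90 ms); the target-minus-distractor
  difference over 200–750 ms is the modulation, in fractions of the peak
  response.
* **Statistics**: everything is aggregated to one value per penetration —
  signed-rank tests, a repeated-measures compartment ANOVA with
  Greenhouse–Geisser correction, profile-consistency correlations with
  channel-shuffle controls, and a cluster-based sign-flip permutation
  test for laminar CSD patterns.
* **Decoding**: linear SVM on per-site window means, ROC area on held-out
  trials, 10 × 90/10 splits.
* **Eye screening**: microsaccades = ≥5 consecutive samples of eye speed
  above 5 × SD at 250 Hz; contaminated trials are excluded.

## Worked example

Simulate one attention-task penetration, align it by its evoked CSD, and
read off the laminar modulation profile:

```r
library(lamflow)

cfg <- sim_config("attention", n_trials_per_condition = 40, seed = 1)
gt  <- make_ground_truth(cfg, "attention_like")   # true modulation (sup, L4, deep) = (0.30, 0.10, 0.30)
ses <- simulate_session(gt, cfg)

avg_lfp <- colMeans(ses$recording$lfp[ses$trials$condition == "target_rf", , ], dims = 1)
rev   <- find_reversal(compute_csd(avg_lfp), cfg$time_lfp)
rev$boundary_channel
#> [1] 8

align <- alignment_result(rev$boundary_channel, cfg$n_channels)
norm  <- normalize_mua(ses$recording$mua, cfg$time_mua, ses$trials)
prof  <- modulation_profile(norm$mua, cfg$time_mua, ses$trials, alignment = align)
round(prof$compartment_means, 3)
#>        deep      layer4 superficial
#>       0.299       0.100       0.297
```

The boundary is recovered at the true channel (8), and the compartment
modulation means match the configured ground truth: the target curve adds
about 30% of the peak response in the superficial and deep layers and
about 10% in input layer 4 — the laminar signature of top-down feedback,
which avoids layer 4.

The whole pipeline over several penetrations, with penetration-level
statistics:

```r
rep <- run_pipeline(pipeline_config(
  preset = "attention_like", n_penetrations = 8, seed = 1,
  sim = list(n_trials_per_condition = 20L, fs_lfp = 250, fs_mua = 250,
             conditions = c("target_rf", "distractor_rf"))))
rep
#> <lam_report> preset attention_like (attention task), 8 penetrations [config 02586eb9]
#>   modulation: target 0.599 vs distractor 0.349, signed-rank p = 0.00781
#>   compartments (deep/layer4/superficial): 0.300 / 0.099 / 0.299, RM-ANOVA p = 4.82e-18
```

The signed-rank p of 0.0078 is the minimum attainable with n = 8
penetrations — the modulation is present in every penetration — and the
compartment ANOVA confirms the superficial/deep > layer 4 profile.

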