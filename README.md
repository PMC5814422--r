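# saswave

Resting-state time–frequency analysis of subarachnoid-space (SAS) width and
blood-pressure (BP) oscillations.

The width of the subarachnoid space — the CSF layer between the arachnoid
and the pia mater — pulses with cerebral blood volume. Optical
transillumination channels (`TQ_LEFT`, `TQ_RIGHT`) record these width
changes per hemisphere while finger blood pressure is recorded
simultaneously. `saswave` is for researchers asking which physiological
oscillations (cardiac 0.6–2 Hz, respiratory 0.145–0.6, myogenic
0.052–0.145, neurogenic 0.021–0.052, and the two endothelial bands
0.0095–0.021 and 0.005–0.0095 Hz) appear in such signals, how the two
hemispheres synchronise, and whether BP and SAS width are phase-locked —
and in which bands.

## What it computes

* **Morlet continuous wavelet transform** on a logarithmic frequency grid
  (default 0.005–2 Hz, 16 voices/octave), with the mother wavelet
  φ(u) = π^(−1/4)·exp(−i2πu)·exp(−u²/2), the exact scale mapping f = 1/s,
  trapezoid-rule discretisation evaluated exactly via zero-padded FFTs, and
  a cone-of-influence mask (√2·s from each edge) excluded from all time
  averages. Time-averaged amplitude spectra are summarised per interval and
  searched for peaks by topographic prominence.
* **Wavelet phase coherence**
  C(f) = | mean over time of exp(i(θ₂ − θ₁)) | and the circular-mean phase
  difference Δθ in (−180°, 180°] (positive = signal 2 leads; signal 1 is
  the reference: BP, or TQ_RIGHT for the interhemispheric pair). Amplitude
  never enters.
* **Intersubject-surrogate significance**: channel A of subject i paired
  with channel B of subject j for all ordered i ≠ j (n(n−1) pairs; 1260 for
  36 subjects); the per-frequency 95th percentile of the surrogate
  coherences is the significance threshold, which rises at low frequencies
  exactly as the intrinsic coherence bias does.
* **Cohort statistics**: Wilcoxon rank-sum comparisons between groups
  (age < 25 vs ≥ 25, sex, interhemispheric-correlation median split),
  exact signed-rank contrasts between intervals within subjects, and an
  effect-size/power gate — a difference is only reported significant when
  the observed standardized effect reaches the minimal detectable effect
  d_min = (z₁₋α/₂ + z_power)·√(1/n₁ + 1/n₂) at power 0.8.
* **A seeded synthetic cohort generator** whose modes, amplitude orderings
  (cardiac-dominant BP, endothelial-dominant SAS), phase-wander and
  coupling structure (BP↔SAS locked in intervals I–III with a +30° SAS
  lead in the myogenic band; left↔right SAS locked through interval V)
  let the whole pipeline be validated without any recordings.

## Worked example

```r
library(saswave)
cfg <- pipeline_config(output_dir = "results", simulate = TRUE,
                       n_subjects = 12, seed = 1)
bundle <- run_pipeline(cfg)
print(bundle)
#> <sas_bundle> 12 subjects, 3 pairs, outputs in results
#>   BP~TQ_LEFT significant in: I, II, III
#>   BP~TQ_RIGHT significant in: I, II, III
#>   TQ_RIGHT~TQ_LEFT significant in: I, II, III, IV, V
```

BP–SAS coherence clears the surrogate threshold only in the cardiac,
respiratory and myogenic intervals, while the two hemispheres stay coherent
all the way down to the NO-dependent endothelial band — the coupling
structure the generator imposed, recovered end to end.

```r
subset(bundle$amplitude_comparisons, channel == "TQ_LEFT")
#>   channel comparison statistic        p effect_size gate_pass significant
#> 1 TQ_LEFT     I vs V         0 0.000488        5.63      TRUE        TRUE
#> 2 TQ_LEFT    I vs VI         0 0.000488        5.74      TRUE        TRUE
#> 3 TQ_LEFT    II vs V         0 0.000488        5.56      TRUE        TRUE
#> 4 TQ_LEFT   II vs VI         0 0.000488        5.52      TRUE        TRUE
```

Every subject's SAS spectrum carries more mean amplitude in the endothelial
intervals than in the cardiac/respiratory ones; with all 12 differences in
the same direction the exact signed-rank p is its minimum attainable value
2/2¹² ≈ 0.000488, and the standardized effects clear the power gate.

```r
head(subset(bundle$median_coherence,
            pair == "BP~TQ_LEFT" & significant &
            frequency > 0.052 & frequency <= 0.145),
     c("frequency", "median_coherence", "threshold", "delta_theta_deg"))
#>    frequency median_coherence threshold delta_theta_deg
#> 58    0.0591            0.269     0.218            29.8
#> 59    0.0617            0.297     0.210            26.4
#> 60    0.0644            0.317     0.220            25.3
```

Inside the myogenic band the median phase difference sits near +30°: the
SAS signal leads BP by the imposed offset.

All stage outputs are also written as tidy CSV tables (`spectra.csv`,
`interval_summaries.csv`, `coherence.csv`, `median_coherence.csv`,
`coherence_bands.csv`, `amplitude_comparisons.csv`,
`group_comparisons.csv`) plus a `run_log.txt` whose configuration echo
reproduces the run byte-for-byte. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`. The methods vignette
(`vignettes/sas-width-oscillations.Rmd`) documents the model, the
numerical conventions, and what the synthetic generator does and does not
emulate.

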