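---
title: "Wavelet phase coherence analysis of SAS width and blood pressure oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet phase coherence analysis of SAS width and blood pressure oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saswave)
```

## The problem

The width of the subarachnoid space (SAS) — the CSF-filled layer between the
arachnoid and the pia mater — oscillates with cerebral blood volume. Optical
transillumination measurements (the TQ_LEFT and TQ_RIGHT channels, one per
hemisphere) record these width changes non-invasively while finger blood
pressure (BP) is recorded simultaneously. The scientific questions are
spectral and relational: which physiological oscillations appear in SAS
width, how strong are they relative to BP, are the two hemispheres
synchronised, and does BP drive SAS width — and in which frequency bands?

Cardiovascular oscillations are conventionally divided into six frequency
intervals:

| Interval | Band (Hz)      | Physiology                   |
|----------|----------------|------------------------------|
| I        | 0.6–2          | cardiac                      |
| II       | 0.145–0.6      | respiratory                  |
| III      | 0.052–0.145    | myogenic (smooth muscle)     |
| IV       | 0.021–0.052    | neurogenic                   |
| V        | 0.0095–0.021   | NO-dependent endothelial     |
| VI       | 0.005–0.0095   | NO-independent endothelial   |

Resting-state recordings of 30 minutes are just long enough to resolve
interval VI; everything in this package is built around that constraint.

## The analysis chain

**Preprocessing.** Signals are detrended with a 120-s centred moving average,
z-normalized, and downsampled to 10 Hz. The moving-average window shrinks
symmetrically near the record edges (a partial-window mean), which avoids
padding artifacts and keeps the output the length of the input.
Downsampling applies a zero-phase FFT low-pass — unit gain up to 0.8× the
target Nyquist frequency, raised-cosine roll-off reaching zero at the target
Nyquist — before decimation, so cardiac harmonics cannot alias into the band
of interest while everything below 4 Hz survives to better than 1% RMS. The
declared sampling rate of the file is authoritative; 300 → 10 Hz and
100 → 10 Hz paths are both supported.

**Continuous wavelet transform.** The transform is
$W(s,t) = s^{-1/2}\int \phi\!\big((u-t)/s\big)\, g(u)\, du$ with the Morlet
mother wavelet $\phi(u) = \pi^{-1/4} e^{-i2\pi u} e^{-u^2/2}$. Because the
complex exponential has unit frequency, the scale–frequency mapping is
exactly $f = 1/s$, with no empirical centre-frequency factor. The analytic
admissibility correction term (magnitude $\approx e^{-2\pi^2} \sim 10^{-9}$)
is omitted. The integral is discretised by the trapezoid rule at the
sampling interval; the implementation evaluates this exact discretisation
with zero-padded FFTs (kernel truncated at eight envelope standard
deviations, below $10^{-13}$ relative amplitude), and the test suite checks
the FFT path against literal brute-force integration to $10^{-6}$ relative
error. Frequencies live on a logarithmic grid, by default 16 voices per
octave from 0.005 to 2 Hz — enough to put ~15 grid points in interval VI,
the narrowest band (0.93 octave).

**Cone of influence.** Within $\sqrt{2}\,s$ of either record edge (the
e-folding time of the Gaussian envelope) coefficients are attenuated by the
finite record. These cells are flagged and excluded from every time
average; otherwise the low-frequency end of the spectrum — precisely the
intervals of interest — would be biased downward. On a 30-minute record the
cone removes about 9.4 minutes at 0.005 Hz and essentially nothing above
0.1 Hz. All interval comparisons use mean amplitude $|W|$, not power
$|W|^2$ (the squared variant exists as an option).

**Phase coherence and phase difference.** For two simultaneous channels the
wavelet phase coherence at frequency $f$ is
$C_\theta(f) = \big|\,n^{-1}\sum_t e^{i(\theta_{2}-\theta_{1})}\big|$, the
modulus of the circular mean of the instantaneous phase difference, taken
over the $n$ time samples outside both cones of influence. It is 1 when the
phase relation is constant, and for unrelated phases decays to the
random-walk floor $\sqrt{\pi}/(2\sqrt{n})$. Only phase enters: amplitude
rescaling of either channel changes nothing. The phase difference is the
circular mean angle, reported in degrees in (−180°, 180°], with the
convention that signal 1 is the reference (BP, or TQ_RIGHT for the
interhemispheric pair) and a positive value means signal 2 leads. When the
mean phasor is degenerate (coherence < 1e−12) the angle is reported as
missing rather than as arctangent noise.

**Significance: intersubject surrogates.** Low frequencies contribute fewer
cycles to a fixed-length record, which inflates phase coherence even for
unrelated signals. The null distribution is therefore built from
intersubject surrogates: channel A of subject $i$ paired with channel B of
subject $j$ for every ordered pair $i \ne j$ — $n(n-1)$ pairs, 1260 for a
36-subject cohort. Mismatched subjects share the physiological spectral
structure but cannot be phase-locked, and the surrogate coherence rises
towards low frequencies exactly the way the bias does, so the per-frequency
95th percentile of the surrogates is a self-correcting threshold. The
cohort median coherence is compared against it (strictly greater =
significant, matching how group-level curves are constructed); percentiles
use the linear-interpolation (type-7) convention, fixed because percentile
definitions change thresholds at the third decimal. Whether in-cone phases
should enter the coherence sum is not externally specified; this package
excludes them, for the same reason they are excluded from spectra. For the
interhemispheric comparison, surrogates pair left$_i$ with right$_j$ for
all $i \ne j$.

**Cohort statistics.** Group comparisons use the Wilcoxon rank-sum test:
exact enumeration for combined $n \le 12$ without ties, the
continuity-corrected normal approximation otherwise. (The approximation is
within about 0.04 of exact enumeration in the worst case at these sizes —
the discreteness of the null at $n \le 12$ means no smooth approximation
can do much better, which is why the exact path exists.) Interval-versus-
interval amplitude contrasts (I vs V, I vs VI, II vs V, II vs VI) pair the
same subjects, so they use the signed-rank analogue on per-subject
differences, with its own exact enumeration over sign assignments for up to
15 informative pairs — unlike the usual exact routines this stays exact
when differences tie, and tied differences are the typical case for a
systematic offset. Every reported difference carries an effect size
(standardized mean difference with pooled deviation) and a power gate: the
minimal detectable effect at the requested power, from the two-sample
normal-approximation formula
$d_{\min} = (z_{1-\alpha/2} + z_{\text{power}})\sqrt{1/n_1 + 1/n_2}$
(0.934 at $n_1 = n_2 = 18$, $\alpha = 0.05$, power 0.8). A contrast whose
observed effect falls below $d_{\min}$ is never labelled significant,
whatever its p-value. No multiple-testing correction is applied, matching
the analysis this package operationalises.

Cohort splits: age (< 25 vs ≥ 25 years), sex, and interhemispheric SAS
correlation (product-moment correlation of the preprocessed TQ channels)
split at the cohort median, with the median subject assigned to the high
group — a fixed, documented tie rule.

## The synthetic cohort generator

No recordings are distributed, so the generator is a first-class module: it
encodes the oscillatory structure the analysis assumes, and every pipeline
stage is validated against it.

Each subject's channel is a sum over six modes (one per interval) of
$A \sin(2\pi f_c t + \delta + B(t))$ plus white measurement noise. Per
subject, each mode's centre frequency is drawn log-uniformly within its
interval — mimicking inter-subject peak scatter — and its phase performs a
random walk $B(t)$, producing the band-limited, frequency-wandering
oscillations wavelet analysis is designed for, without committing to any
particular physiological model. Channels in a mode's *coupling group* share
one phase process (centre frequency and walk) plus fixed offsets, and are
therefore phase-locked; channels outside the group draw their own frequency
and their own walk. That last choice matters: uncoupled channels are then
mismatched in exactly the way intersubject surrogate pairs are, so with all
couplings removed the fraction of frequencies where the cohort median
exceeds the 95th-percentile threshold stays below 10% in every interval. If
uncoupled channels shared a frequency and differed only in their walks,
they would retain a residual coherence (~0.1) that frequency-mismatched
surrogates cannot calibrate away.

The default wander intensity is $0.3\sqrt{f_c}$ rad/√s — constant phase
diffusion per cycle, hence the same fractional linewidth (~1.5%) for every
mode, comfortably inside one grid step at 16 voices per octave, so peak
recovery is sharp from interval I down to interval IV. (Intervals V–VI
contribute too few cycles per record for guaranteed single-step recovery;
that limitation is intrinsic to 30-minute records, not to the generator.)

`default_resting_spec()` encodes the qualitative resting-state findings
as study conditions:

* BP is cardiac-dominant: interval-I amplitude 3.0 against ≤ 0.5 elsewhere
  (amplitudes fall with frequency: 0.5, 0.3, 0.2, 0.15, 0.1 for II–VI), so
  that after the $\sqrt{s}$ scaling of the wavelet kernel the cardiac peak
  still tops the BP spectrum.
* SAS channels are endothelial-dominant: amplitudes 0.3, 0.3, 0.5, 0.6,
  1.2, 1.0 for I–VI — intervals V–VI at least 3× intervals I–II, which the
  $1/\sqrt{f}$ amplitude scaling then amplifies into the order-of-magnitude
  spectral dominance seen in interval summaries.
* Couplings: BP and both SAS channels share phase in intervals I–III, with
  a +30° SAS lead in the myogenic interval (positive phase difference =
  SAS leads, per the sign convention above); the two SAS channels are
  additionally locked at 0° through intervals IV and V; interval VI is
  uncoupled everywhere.
* 30-minute records at 10 Hz, noise SD 0.1 (≤ 0.2× the smallest mode
  amplitude, the regime in which imposed phase offsets are recovered within
  ±5°), ages drawn to straddle 25 years, sexes alternating.

Everything derives deterministically from one master seed (per-subject
streams use distinct sub-seeds, and generation does not disturb the
caller's RNG state).

What the generator does *not* emulate by default: 1/f background (a
`noise_model = "one_over_f"` option exists, but the default is white noise
— the simplest null consistent with the analysis assumptions), harmonics of
the cardiac cycle, artifacts, nonstationary amplitude modulation, and any
biophysical CSF/BP mechanics. Passing tests
therefore demonstrate that the chain recovers imposed spectral and coupling
structure under realistic record lengths and noise — not that real
recordings will show these effects.

## Numerical choices and degenerate inputs

* Frequency grid: starts exactly at `fmin`, geometric ratio
  $2^{1/\text{voices}}$, ends at the first point at or above `fmax`
  (140 points for 0.005–2 Hz at 16 voices).
* Grid maxima above the Nyquist frequency, records shorter than one full
  cone at the lowest frequency, zero-variance signals, non-integer
  decimation factors, empty intervals, empty split groups, and non-numeric
  cells in input tables are all hard errors naming the offending quantity —
  nothing is silently dropped.
* Peak detection uses topographic prominence on the log-frequency grid with
  a threshold relative to the global maximum (default 5%); strictly
  monotone spectra yield no peaks.
* Ties: a cohort median coherence exactly equal to the threshold is not
  significant; the median-correlation subject joins the high group; tied
  signed-rank magnitudes take midranks inside the exact enumeration.
* Records of unequal length entering the surrogate pool are truncated to
  the shortest, with edge masks recomputed for the truncated length.

## Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen so
each property is measured where it is genuinely informative: brute-force
transform comparisons on 1000-sample signals; tone-recovery sweeps on full
30-minute, 10 Hz records; coherence calibration on 20 pairs of iid-phase
coefficient fields (where the $\sqrt{\pi}/(2\sqrt{n})$ floor is the exact
expectation) and 20 pairs of 15-minute white-noise signals (where the
low-frequency bias genuinely arises); and a full 12-subject synthetic
cohort through the entire pipeline, whose endothelial-dominance contrasts,
cardiac BP peak, BP–SAS coherence in intervals I–III (and its absence in
V–VI), and interhemispheric coherence down to interval V are all asserted
end to end.

## Known limitations

* Fig-level reproduction of the original cohort is impossible without the
  recordings; validation is property-based on synthetic cohorts.
* The intersubject-surrogate interface accepts any externally supplied
  coherence matrix, but amplitude-adjusted Fourier-transform surrogates and
  within-subject (time-shift / phase-randomisation) surrogates are not
  implemented.
* Amplitude-weighted wavelet coherence — more appropriate outside the
  resting state — is out of scope.
* The normal-approximation rank-sum path is a large-sample tool; at
  combined $n \le 12$ use the exact path (the default).

## A minimal session

```{r example, eval = FALSE}
cfg <- pipeline_config(output_dir = "results", simulate = TRUE,
                       n_subjects = 12, seed = 1)
bundle <- run_pipeline(cfg)
print(bundle)
bundle$amplitude_comparisons
subset(bundle$median_coherence, pair == "BP~TQ_LEFT" & significant)
```
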