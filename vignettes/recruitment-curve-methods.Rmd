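---
title: "Recruitment-curve analysis at reduced EMG sampling rates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recruitment-curve analysis at reduced EMG sampling rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recruitcurve)
```

## The scientific problem

Closed-loop neurofeedback protocols that condition spinal or cortical evoked
responses need a *target stimulation intensity* chosen so that the
electrically evoked H-reflex is near-maximal (~75% of its maximum) while
the direct M-wave stays small (~10% of its maximum). That intensity is read
off the H-reflex and M-wave *recruitment curves*: the mean rectified EMG
response in fixed post-stimulus windows, plotted against stimulation
current, as the current is ramped from below the reflex threshold to the
M-wave plateau.

High-fidelity laboratory amplifiers sample surface EMG at 3200 Hz. Portable
acquisition systems built around EEG headsets sample 5-10x slower
(~300-640 Hz), which blurs the fast biphasic responses. The question this
package operationalises: **do the curve parameters that define the target
intensity survive that loss of temporal resolution?** It answers it with a
pseudo-online design: recruitment-curve runs are simulated at 3200 Hz with
known ground truth, degraded by anti-aliased decimation to each lower rate,
analysed identically at every rate, and the resulting curve parameters
compared with a repeated-measures agreement battery.

## Models

**M-wave recruitment** is a logistic (sigmoid) function of stimulation
intensity $s$:

$$M(s) = \frac{M_{max}}{1 + e^{-b_m (s - c_m)}}$$

**H-reflex recruitment** is the bell-shaped *hill curve*, the product of a
rising and a falling sigmoid with $c_{rise} < c_{fall}$:

$$H(s) = H_{scale}\; \sigma\!\big(b_{rise}(s - c_{rise})\big)\;
          \sigma\!\big(-b_{fall}(s - c_{fall})\big)$$

Six parameters are extracted from each fitted pair of curves: the
normalised residual mean squared errors of the two fits, the curve maxima
$H_{max}$ and $M_{max}$, and the stimulation intensities at $H_{max}$ and
at the M-wave threshold. The target intensity is the smallest intensity at
which the fitted M-wave reaches 10% of $M_{max}$; an advisory flag is
raised when the fitted H-reflex there is below 75% of $H_{max}$.

Two operational definitions are deliberate choices of this package, exposed
as configuration and reported in the outputs:

* **M-threshold = 5% of $M_{max}$** on the fitted curve. The threshold has
  no universal numeric definition; 5% is low enough to sit at the foot of
  the sigmoid but high enough to stay above the measurement floor.
* **MSE normalisation**: residuals are divided by the fitted maximum of the
  corresponding response before squaring, making MSEs dimensionless and
  comparable across subjects and gain settings; raw uV^2 values are also
  emitted.

## The synthetic generator as study conditions

Real recruitment-curve recordings of this kind are not publicly
distributable, so every downstream stage is validated against a simulator
with known ground truth (`generate_run()`, `simulate_cohort()`). Each trial
contains, at soleus-like latencies:

* a 1 ms **biphasic stimulus artifact** (charge-balanced, as delivered by a
  constant-current stimulator) followed by an exponential decay tail
  (default 100 uV, tau 1.5 ms);
* an **M-wave template**: a Gaussian-windowed one-cycle sinusoid, onset
  6.5 ms, duration 15 ms;
* an **H-reflex template**: a one-cycle sinusoid whose main positive and
  negative peaks are 5 ms apart (a ~100 Hz fundamental) followed by a
  slower terminal recovery half-wave (relative amplitude 0.6, 6 ms),
  approximating the triphasic morphology of surface-recorded soleus
  H-reflexes, onset 27.5 ms. A pure one-cycle sinusoid concentrates
  essentially all of its energy at 100 Hz, which the 320 Hz anti-alias
  filter (cutoff 100 Hz) would attenuate more than real H-reflexes are
  attenuated; the recovery phase restores the low-frequency content real
  waveforms have;
* **background noise** with the spectral shape of quiet-standing soleus
  EMG: 85% of the power band-limited to 15-150 Hz (motor-unit activity)
  plus 15% broadband to 500 Hz, RMS 4 uV (the 5-18 uV gating band is the
  ceiling for acceptable background);
* **trial-to-trial variability**: multiplicative lognormal amplitude
  factors (CV 0.15 for the H-reflex, 0.05 for the much more stable
  M-wave), M-wave recruitment noise with a binomial-like variance profile
  ($\propto \sqrt{p(1-p)}$ of the recruited fraction — zero below
  threshold and at the plateau, maximal mid-recruitment), and a slow AR(1)
  drift of the *effective* stimulation intensity (sd 0.1 mA, 60 s
  correlation time) standing in for posture and electrode-coupling
  changes;
* a **trigger sample jitter** of up to 40 samples, because the stimulus is
  asynchronous with the acquisition clock. This detail matters: without
  it, every trial would decimate with the same phase and the
  trigger-quantisation jitter that degrades low-rate measurements could
  not exist in the simulation.

Templates are normalised so that their mean rectified value inside the
canonical windows (M 6-23 ms, H 28-45 ms post-trigger) equals the
ground-truth recruitment amplitude — so with all stochastic components
switched off the measurement pipeline must reproduce the generating curves
essentially exactly, which the test suite asserts.

The ramp protocol steps 1 mA every 4 trials from 8 mA, at ~1 Hz with 10%
ISI jitter, capped at 50 mA, stopping once the true M-wave has exceeded
99% of $M_{max}$ for two consecutive steps. Step size, trials per step and
the starting intensity are this package's defaults (the ramp is described
in the field only as "predefined steps after a set number of trials").
Cohort heterogeneity draws each subject's truth parameters uniformly from
soleus-plausible ranges (e.g. $M_{max}$ MRV 350-700 uV, H/M amplitude
ratio well below 1, $c_{rise} < c_{fall}$ by construction).

**What the generator does not emulate:** real waveform-shape variability
across subjects (latencies and durations are fixed), movement artifacts,
amplifier nonlinearities and saturation, stimulation-electrode physics, or
EEG. Passing tests therefore demonstrate that the *pipeline* preserves
target intensities under rate reduction for signals with realistic timing,
spectra and variability — not that any specific human dataset would yield
identical numbers.

## The degradation pathway

`downsample_run()` applies a zero-phase (forward-backward) 2nd-order
Butterworth low-pass at $0.3125 \times$ the target rate — 200 Hz for
640 Hz, 100 Hz for 320 Hz, generalising to 500/250/125 Hz for the interim
rates — then keeps every k-th sample. Zero phase is used for the
retrospective anti-alias filter because group delay would bias the fixed
response windows; the 10 Hz high-pass that emulates the real-time
acquisition path defaults to causal. Whether the original retrospective
analysis used zero-phase filters is not documented; the choice is exposed
for sensitivity analysis.

The trigger index maps by **floor division**, deliberately modelling the
worst-case trigger-onset quantisation of a genuinely low-rate system; the
sub-sample residual is recorded per trial. Only integer decimation factors
of 3200 Hz are supported; a native 600 Hz portable recording is emulated
by generating at 600 Hz, not by resampling.

## Measurement and delineation

Epochs span -200 to +400 ms around the (possibly quantised) trigger,
half-open on the right. Measurement blanks the first 3 ms (1 ms pulse plus
margin for ringing and filter smear), fits one pooled exponential
$a e^{-t/\tau} + c$ over 3-15 ms to the *sub-threshold* trials and
subtracts it everywhere. Sub-threshold trials are those where both the
H-window MRV and the late-M-window MRV are at most 5% of their run maxima
— the H criterion alone would also select supra-maximal intensities, where
the bell-shaped H-reflex has fallen off but the M-wave is maximal. When
fewer than four such trials exist the four lowest intensities are pooled;
when the pooled fit fails, no subtraction is applied (per-epoch fallback
fits were rejected: on supra-threshold trials the fit window is
contaminated by the M-wave itself and diverges). Finally, the rectified
noise floor estimated from the pre-trigger segment (-150..-50 ms) is
subtracted from both MRV columns, because the floor depends on the
sampling rate (the anti-alias filter removes part of the noise band) and
would otherwise leak a spurious rate effect into threshold-type
parameters.

**Manual windows** come from configuration (defaults M 6-23 ms,
H 28-45 ms) and never from data. **Automated delineation**
(`delineate_auto()`) uses the whole run: 1 ms bins over 3-60 ms (one
sample per bin when a bin would hold less), a per-bin rectified-mean
amplitude per trial, and a logistic-vs-hill-vs-constant model comparison
across intensity. A bin is labeled only when the better model reduces MSE
by at least 20% relative to a constant fit and its peak amplitude reaches
5% of the largest bin; a winning hill counts as H only when its fitted
curve genuinely falls off (below 75% of its peak) within the sampled
range, since a hill with a barely-interior maximum can mimic a logistic.
The M window is the longest contiguous M run and the H window the longest
contiguous H run after it. These bin-level criteria are this package's
reconstruction of whole-run delineation — the published description of
the original algorithm is deliberately not detailed enough to copy — and
all thresholds are exposed as arguments.

## Curve fitting

Both curves are fitted to per-trial points by bounded Levenberg-Marquardt
least squares with five deterministic starting points derived from
per-intensity means (slopes in (0.01, 10] /mA, centers within the data
range +/- 50%, amplitudes bounded by multiples of the data maximum),
keeping the lowest-residual converged solution; the hill fit additionally
requires $c_{rise} < c_{fall}$ and a maximum strictly inside the sampled
range, with a structurally-constrained reparameterisation
($c_{fall} = c_{rise} + \mathrm{gap}$, gap > 0) as a fallback. All
"smallest intensity where" quantities use a 0.01 mA grid over the data
range extended by one ramp step, taking the first grid point that meets
the criterion; the hill maximum is located by grid search rather than
calculus so the answer is robust to reparameterisation.

## Agreement statistics

`friedman_rm()` ranks within subject (mid-ranks for ties) and reports both
the tie-corrected statistic (which drives the p value) and the uncorrected
one, from which Kendall's $w = \chi^2 / (N(k-1))$ is computed so that $w$
stays in [0, 1] by construction. Post-hoc pairs compare mean ranks with
the studentized range ($SE = \sqrt{k(k+1)/(12N)}$, infinite error df).
Manual-vs-automated agreement uses the absolute-agreement single-measure
two-way ICC, which penalises systematic offsets (the common "ICC(3,1)"
label usually denotes the consistency form; the absolute-agreement form is
implemented because that is what method comparison requires). Equivalence
uses the TOST 90% confidence-interval inclusion rule at prespecified
bounds of +/- 1 mA, and Bland-Altman limits are reported alongside.
Subjects missing any condition are dropped listwise with the count
reported.

## Numerical choices and degenerate inputs

* Decay-fit $\tau$ is bounded to (0.1, 50] ms; non-convergent fits fall
  back to no subtraction, flagged.
* All-zero response columns, fewer than 8 distinct intensities, ramp
  configurations that cannot start, cutoffs at or above Nyquist, epochs
  shorter than the span, and missing H-reflexes all fail with specific
  messages rather than producing numbers.
* Experiments continue past per-subject failures; gaps are logged and
  reported.
* Seeds: a master seed derives per-subject seeds through a counter-based
  map, so enlarging a cohort never changes existing subjects; the subject
  label is hashed into the stream so identical seeds with different labels
  give different noise.

## Problem sizes used by the validation suite

The packaged checks run a 21-subject cohort across 3200/640/320 Hz for the
cross-rate pattern, 100 ten-subject cohorts for the equivalence property,
and 50 seeded subjects for noisy parameter recovery; these sizes mirror
the study design (21 participants, three rates) while keeping the full
suite comfortably reproducible on a laptop.

## Known limitations

* Template shapes are stylised; real H-reflex and M-wave morphology varies
  across subjects and electrode placements.
* The automated delineation is a reconstruction, not a reimplementation of
  any published algorithm's exact criteria.
* The normalised MSE convention cannot be compared unit-for-unit with
  residual errors reported under other conventions.
* TOST bounds of +/- 1 mA are protocol-specific; other applications should
  prespecify their own.

## A minimal session

```{r example, eval = FALSE}
truth <- recruitment_truth()
run <- generate_run(truth, sweep_protocol(), waveform_spec(), seed = 1)
windows <- delineate_auto(run)
data <- measure_run(downsample_run(run, 640), windows)
curves <- fit_recruitment(data)
extract_params(curves, data)

# the full pseudo-online experiment
rc <- run_experiment(experiment_config(n_subjects = 21,
                                       rates = c(3200, 640, 320),
                                       methods = "manual",
                                       master_seed = 42))
report(rc)$tests
```
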