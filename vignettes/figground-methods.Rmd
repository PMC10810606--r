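---
title: "Models and methods behind figground"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind figground}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figground)
```

figground implements the analysis chain of a head-fixed mouse
figure-detection experiment: mice report the side of a figure stimulus
(defined against the background by contrast, orientation, or grating phase)
by licking, while the superficial superior colliculus is either
optogenetically silenced at graded delays (behavioral arm) or recorded with
a laminar probe (electrophysiology arm). This vignette documents the models,
the tunable parameters, the synthetic-data design, and the numerical choices;
it states no empirical result that the package's tests and acceptance script
do not themselves compute.

## Behavioral psychometrics

Accuracy is defined as hits/(hits + errors) per laser-onset condition;
misses enter the denominator only on request, and correction trials are
always dropped. The accuracy-versus-silencing-onset curve is modeled as a
four-parameter logistic,

$$p(t) = \textrm{floor} + \frac{\textrm{ceiling} - \textrm{floor}}
{1 + e^{-\textrm{slope}\,(t - \textrm{inflection})}},$$

fitted by bounded least squares with the floor bounded below at chance
(0.5) and the ceiling at 1. The *inflection* is the logistic location
parameter — the latency at which accuracy reaches the midpoint of the
fitted span — and its uncertainty is estimated by refitting on 1000
bootstrap resamples. Resampling is stratified within mouse and laser-onset
condition so that every latency remains represented in every resample, the
per-mouse accuracies are averaged across mice, and the refit inflections
are summarised by their mean and SD. The no-laser condition is excluded
from the fit by default (the bounded ceiling plays the role of the
asymptote); no lapse parameter is used.

Session inclusion follows a two-branch rule: sessions of at least 40
scored trials are included when a one-sided exact binomial test rejects
chance (p < 0.05 against 0.5); shorter sessions when overall accuracy is at
least 65% *and* per-side accuracy at least 50%. Forty trials is exactly the
length at which 65% accuracy first reaches one-sided significance, which
the acceptance script re-derives by enumeration.

The laser-onset effect on accuracy, lick responsiveness and reaction time
is tested with a one-way repeated-measures ANOVA (mouse as the repeated
unit) and Bonferroni-corrected paired comparisons against the no-laser
condition. Trial tables store only the first lick (the operative response),
so the responsiveness summary reports the per-condition response rate
rather than a continuous lick rate.

## Signal preprocessing and trial exclusion

**Envelope MUA artifact rejection.** The raw voltage (sampled above 10 kHz)
is band-pass filtered 500–5000 Hz with a zero-phase Butterworth filter,
half-wave rectified, and low-pass filtered at 200 Hz, giving a per-channel
envelope of high-frequency activity. Each channel's envelope is z-scored
over all trials and time points and the absolute value taken; the geometric
mean across channels,
$Z_{ij} = \left(\prod_c \mathrm{zmua}_{ijc}\right)^{1/n}$,
is large only when the majority of channels excurse together, which makes
it selective for broadband artifacts over neuronal events confined to a few
contacts. Samples with $Z > 3$ are removed from all channels together with
three samples of padding on each side, and $Z$ is recomputed on the masked
data. The per-trial statistic $\chi_j = (\mathrm{mean}_i\, Z_{ij})^2$ is then
fitted with a Gaussian by nonlinear least squares on a Freedman–Diaconis
histogram — fitting the bulk rather than using moments keeps the estimate
robust to the artifact trials themselves — and trials farther than
3σ from μ are removed (trials whose samples were entirely masked are
removed outright). The geometric mean is computed as
$\exp(\mathrm{mean}(\log(\mathrm{zmua} + 10^{-12})))$ so that an exact zero
cannot annihilate the product.

**Eye movements.** Per trial, eye speed is the mean finite-difference speed
in 0–450 ms after stimulus onset, after a 20 ms moving-average denoising of
the position traces (the derivative estimator is not dictated by the
experiment; without smoothing, camera noise dominates). Trials above the
across-trial mean + 2.5 SD are excluded; a maximum-speed variant is
available via the `stat` argument. Trials whose window is not covered by
the trace are flagged `other`.

**Rates.** Spike trains are convolved with a Gaussian kernel (SD 10 ms) on
a 1 ms grid; the kernel is normalised to unit integral so the trace
integral reproduces the spike count. Trial-averaged rates pool binned
counts before a single convolution, which is exactly the mean of the
per-trial traces by linearity.

**Depth assignment.** The LFP (low-passed, 50 Hz line noise removed with a
2nd-order Butterworth band-stop at 49–51 Hz; the environment's filter
toolbox has no dedicated notch design, and a narrow band-stop serves the
same purpose) is trial-averaged and differentiated twice across channels
(simple second difference at the 25 µm contact spacing — the minimal CSD
estimator) to find the visual-response current sink. The sink channel is
anchored 119 µm below the collicular surface and other channels follow at
the probe spacing; a sink on the probe edge is flagged as unreliable.

## Receptive fields

Sparse-noise checker responses (40–300 ms window after checker onset,
baseline-subtracted) are averaged per position, separately for ON and OFF
checkers, and fitted with an axis-aligned 2D Gaussian by bounded least
squares; the more reliable polarity (higher r²) is retained. When spike
times rather than per-event counts are supplied, the per-neuron response
window is chosen deterministically as the 100 ms sub-window of 40–300 ms
(stepped by 20 ms) maximising the absolute evoked rate — an automated,
reproducible stand-in for window selection by eye.

Fit reliability uses the bootstrapped variability index:
resample the mapping events with replacement, refit, and take
BVI = SD(bootstrap centers) / SD(fitted Gaussian). Two scalar reductions
are needed and are deliberate package choices: the center SD is the rms of
the per-axis SDs, and the Gaussian SD is the geometric mean of σx and σy
(scale-symmetric in the two axes). A fit is `reliable` when r² > 0.25 and
BVI < 0.5 — thresholds exposed in the API; they are artifact defaults, not
values inherited from any specific dataset.

RF classification relative to the task figure treats the RF as the 1σ disk
around the fitted center (the contour conventionally drawn on RF maps):
`inside` when the disk lies entirely within the figure circle (40°
diameter by default), `edge` when it intersects the boundary, `outside`
otherwise. Stimulus placement puts the figure on the RF center and the
ground figure 55° lateral (stretched up to 60° if needed) into the
opposite hemifield; placements that cannot cross the vertical meridian are
clipped with a warning.

## Figure-ground modulation statistics

A neuron is *visual* when its baseline-subtracted evoked rate (50–200 ms
minus the 150 ms baseline, over all trials with a grating in the RF) is at
least 3 spikes/s; the criterion is baseline-subtracted by default, with the
raw-rate variant available. Responses are normalised per neuron as
$R_{\mathrm{norm}} = (R - R_{\mathrm{baseline}})/(R_{\max} -
R_{\mathrm{baseline}})$, with both constants taken from the across-trial
mean trace over grating-in-RF trials and then applied to every trial of
that neuron, figure and ground alike. Neurons with
$R_{\max} = R_{\mathrm{baseline}}$ are flagged degenerate and excluded from
population traces.

**Cluster permutation test.** Population traces are per-neuron mean
normalised responses in 10 ms bins (matching the smoothing SD; the bin
width is an analysis choice). Per bin, the condition effect is tested with
a mixed model (fixed effect: figure vs. ground; random intercept per
neuron). Because the design is balanced — one figure and one ground mean
per neuron — the REML mixed-model F has a closed form: the paired
t-squared when the between-neuron variance estimate is interior, and the
iid-error F when that estimate is truncated at zero. The default engine
uses this closed form, vectorised over permutations; an `engine = "lmer"`
path fits lme4 per bin and produces the same statistics (asserted in the
test suite), at a cost that makes permutation calibration studies
impractical. Contiguous bins with p < 0.05 form clusters scored by summed
F; the null distribution of the maximum cluster score is built by randomly
swapping the figure/ground labels within neuron (whole-condition swaps,
equivalently random sign flips of the per-neuron difference traces), and
cluster p-values use +1 smoothing, so the smallest attainable p is
1/(n_perm + 1).

**Modulation latency.** The figure-minus-ground population trace in
0–300 ms is fitted with the sum of an exponentially modified Gaussian and a
cumulative Gaussian sharing μ and σ — the first component captures the
transient of the modulation, the second its sustained tail. Amplitudes are
bounded at zero, σ at 2–150 ms, τ at 5–500 ms; two start points are tried
before declaring non-convergence, and traces without positive modulation
are flagged rather than fitted. The latency is the time on the rising
flank at which the fitted curve reaches 33% of its maximum, solved by
bisection between zero and the fitted argmax; as a fractional criterion it
is invariant to trace scaling.

**Optogenetic suppression.** Per unit, the visual response is the mean
rate 0–200 ms after stimulus onset; units with a laser-off evoked rate of
at least 2 spikes/s enter, and the per-unit reduction is
100·(1 − on/off), averaged across units.

## Decoding and discriminability

Neurons with at least five figure and five ground trials form the
pseudo-population. Each bootstrap repeat holds out one random trial per
neuron of the test class — the test class alternates figure/ground across
repeats so test sets are balanced by construction — assembles one test
pseudo-trial from the held-out trials, draws ten trials per class per
neuron with replacement from the remaining data as training pseudo-trials,
trains a linear SVM (cost 1, features standardised on the training set),
and classifies the held-out pseudo-trial. Performance is the fraction of
correct repeats over 2000 bootstraps, computed in 50 ms windows stepped by
10 ms. Significance per window is a two-sided exact binomial test of the
bootstrap outcome counts against 0.5 with Holm step-down correction across
windows; counting bootstraps as trials overstates independence (bootstraps
share trials), which is retained as the method's convention and should be
read as anti-conservative. SVM weights are re-oriented so that a positive
weight means higher figure response pushes the decision toward "figure",
averaged over bootstraps, and normalised so the population's absolute
weights sum to one.

Discriminability uses
$d' = (\mu_F - \mu_G)\big/\sqrt{(\sigma_F^2 + \sigma_G^2)/2}$. Its null is
built by shuffling each neuron's trial identities 1000 times and averaging
across neurons; the observed population mean is compared against the 95%
interval of that null.

**Hit/error comparison.** Per-trial responses are mean rates between
stimulus onset and the first lick, and d′ is computed separately on hit and
error trials (tasks pooled; misses carry no outcome label and are
excluded). Because every neuron recorded in a session shares that session's
trials, the per-trial response windows induce a session-level component in
the hit-minus-error contrast that a per-neuron random intercept cannot
absorb; the comparison is therefore designed for multi-session pooled
populations, and the mixed model adds a session-by-outcome random
intercept whenever the d′ table spans several sessions. Model complexity
(intercept-only vs. outcome effect) is selected by AIC on
maximum-likelihood fits; the reported p-value for the outcome effect comes
from the REML fit with the Satterthwaite approximation, which is far
better calibrated at these sample sizes than the maximum-likelihood
likelihood-ratio test.

## Synthetic sessions and what they do (not) show

Every generator is a pure function of its specification and seed, and
writes its ground truth alongside the data, so downstream tests are
parameter-recovery or type-I-error studies, never regressions against
stored outputs.

* **Behavior** (`gen_behavior`): per-trial hits are Bernoulli draws from
  the logistic above (defaults: floor 0.55, ceiling 0.85, inflection
  99 ms, slope 50 s⁻¹, laser onsets 0–200 ms in 25 ms steps, 40 trials per
  latency, 5% misses) — accuracies and latency spacing in the range a
  trained mouse produces in this task.
* **Spikes** (`gen_spikes`): inhomogeneous Poisson with rate
  baseline + gain·v(t) + amplitude·m(t)·1{figure}; v(t) is a difference of
  exponentials peaking near 55 ms (a stereotyped collicular visual
  transient), m(t) ramps up over 30 ms from the modulation onset (default
  75 ms), holds for 100 ms and decays over 50 ms. Per-trial gamma gain
  noise (CV 0.3 by default) produces realistic over-dispersion. An
  optional separate amplitude on error trials gives the outcome analyses a
  generator-level ground truth.
* **Voltage** (`gen_emua_channels`): white Gaussian noise per channel;
  sample artifacts are brief large excursions on a configurable majority
  of channels, trial artifacts a sustained noise-amplitude increase
  (broadband, as a DC offset would be removed by the 500 Hz high-pass).
* **Eye** (`gen_eye`): smoothed random-walk drift plus step-like saccades
  on labeled trials within 0–450 ms.
* **RF maps** (`gen_rf_map`): per-event responses around a known 2D
  Gaussian surface; at zero noise the map equals the surface exactly, so
  the fit oracle is exact.

The generators emulate the statistical structure the analyses assume —
they do not emulate drifting electrodes, correlated population noise,
multi-unit contamination, or non-Poisson spiking history. Passing
recovery tests therefore demonstrates correctness of the estimators under
their own assumptions, not performance on any particular recorded dataset,
and none of the defaults were tuned to reproduce published numbers.

## Problem sizes used by tests and the acceptance script

Calibration studies use 500 null simulations (20 neurons, 30 trials per
class, 200 permutations) for the cluster-test family-wise error rate, 50
seeds for latency recovery, 500 bootstraps for decoder calibration/power
(the analysis default is 2000), 1000 bootstrap refits for the psychometric
inflection, 1000 shuffles for the d′ null, a 500-trial session with 5%
injected artifact trials for the eMUA recovery study, and 200 simulated
eight-session populations for the hit/error type-I study. These sizes give
stable estimates of the tested rates while keeping the full suite fast to
run routinely.

## Known limitations

* The cluster test's closed-form engine covers the balanced two-condition
  design; unbalanced designs must use the lme4 engine.
* The binomial significance of decoding performance inherits the
  bootstrap-counting convention described above.
* The latency functional form is smooth, so very abrupt modulation onsets
  are estimated with a small early bias (quantified by the acceptance
  script, not corrected).
* Session storage is plain CSV/YAML; very long multichannel recordings are
  better kept out of the session directory and epoched on the fly.
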