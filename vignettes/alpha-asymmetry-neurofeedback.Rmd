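---
title: "Methods: alpha-asymmetry neurofeedback pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-asymmetry neurofeedback pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaipipe)
```

## The experimental paradigm this package models

`aaipipe` implements the computational core of a sham-controlled,
double-blind EEG neurofeedback experiment on pain. Participants learn to
up- or down-regulate the lateralization of somatosensory alpha
oscillations (8–12 Hz) by shifting spatial attention to their right or
left hand; a noxious laser stimulus to the left hand follows every 15 s
regulation period, and the question is whether regulating alpha
asymmetry moves pain ratings and pain-evoked brain responses.

The feedback feature is the **alpha asymmetry index**

$$\mathrm{AAI}(t) \;=\;
\frac{\alpha_{rS1}(t)-\alpha_{lS1}(t)}{\alpha_{rS1}(t)+\alpha_{lS1}(t)}
\in [-1, 1],$$

where $\alpha_{rS1}$ and $\alpha_{lS1}$ are 8–12 Hz band powers averaged
over the right ({C4, CP4, CP6}) and left ({C3, CP3, CP5}) somatosensory
channel groups. Every 100 ms the engine analyzes the trailing 1,000 ms
segment: demean, Hanning taper, FFT at 1 Hz resolution, average over the
integer bins 8–12 Hz (the 1 s window fixes the resolution, so "8 to
< 13 Hz" is exactly those five bins). The index is dimensionless; any
common rescaling of the channels cancels.

Four conditions cross attention side (ART = attend right, ALT = attend
left) with feedback validity (verum vs yoked sham, where the displayed
trace is replayed from a donor run and hence independent of the
recipient's brain activity).

## Real-time engine

**Smoothing.** The displayed signal is a causal weighted average of the
raw AAI over the trailing $\Delta\tau$ seconds with the triangular
weight $W(\tau) = 2(\Delta\tau-\tau)/\Delta\tau^2$, applied to the
piecewise-linear interpolant of the 100 ms series. `smooth_aai()`
integrates the product of the two linear functions segment by segment
with Simpson's rule, which is exact for the quadratic integrand; the
tests verify it against a 1 ms trapezoid quadrature of the printed
integral. $\Delta\tau$ defaults to 3.0 s and is configurable. At trial
onset less than $\Delta\tau$ of history exists; the weights are then
renormalized over the available span (the very first sample is returned
unchanged). This renormalization is our choice for the start-up window —
the defining integral is silent about it — and it keeps the smoother an
unbiased average throughout.

**Visibility.** The smoothed index drives the visibility $c \in [0, 1]$
of a neutral face image through a piecewise-linear map: floor 0.2 at
AAI = 0, slope $+4/3$ per unit $|$AAI$|$ on the rewarded side saturating
at 1 beyond 0.6, slope $-1/3$ on the punished side reaching 0 beyond the
opposite 0.6. ALT mirrors ART.

**Scrambling.** Intermediate visibilities are rendered by rotating the
phases of the image's 2D Fourier transform:
$I_{\mathrm{scramb}}(c) = \mathcal{F}^{-1}\{\mathcal{F}(I-\langle I\rangle)
\odot e^{i\Delta\phi(1-c)}\} + \langle I\rangle$ with
$\Delta\phi_{kl}\sim U[-\pi,\pi]$ under the Hermitian antisymmetry
$\Delta\phi_{kl} = -\Delta\phi_{n_x-k,\,n_y-l}$ (indices mod image
size), so the output stays real and the amplitude spectrum and mean
luminance are untouched at every $c$. Self-conjugate bins are forced to
zero. The lowest spatial frequencies are excluded from perturbation to
avoid stripe artefacts; we exclude DC plus the first ring (wrapped index
magnitude $\le 1$ on both axes), the smallest set that removes the
artefact. The exact exclusion set of the original display code is not
published; ours is documented and configurable.

**Reward.** The trial reward is driven by the trial-average AAI; since
a protocol can average either the raw or the smoothed series, we fixed
the raw series as the simpler reading. The schedule is linear
from 0 € to 0.25 € as the mean moves from 0 to 0.6 on the rewarded
side, plus a 0.25 € bonus beyond 0.6 — the stated linear range 0–0.25 €
does not pin down the AAI interval, and mapping it onto $[0, 0.6]$ makes
the bonus threshold coincide with base-reward saturation (cap 0.50
€/trial).

## Offline single-trial features

Per trial the last 12 s before the stimulus (anchored as $[-12, 0)$ s)
are segmented into 1,000 ms epochs at 100 ms stride (111 epochs); epochs
overlapping artefact samples are dropped, each survivor is scored with
the same spectral pipeline as the real-time engine, and the trial AAI is
the mean across survivors. More than 50% rejected epochs excludes the
trial. Because window, step and taper are identical, the offline value
equals the mean of the real-time engine's raw steps over the same
interval to numerical precision — a cross-path invariant the tests
enforce at $10^{-6}$.

Laser-evoked potentials are quantified in two stages on 1–30 Hz
band-passed, baseline-corrected data (baseline: 2,000–2,500 ms after
fixation onset): the group-average waveform fixes the peak latency
within the component window (N1: 120–200 ms at C4 re-referenced to Fz;
N2: 180–300 ms and P2: 250–500 ms at Cz), then single trials are
averaged over a 30 ms window centred on that latency. Filters run
forward–backward (zero phase) so latencies are unbiased; where a window
contains no interior local extremum the window-edge extremum is used
with a warning (the published procedure does not cover this degenerate
case). Induced responses use Hanning sliding windows (alpha/beta:
500 ms windows, 20 ms steps, 500–900 ms, channels Cz, CPz, C2, C4, CP2,
CP4; gamma: 250 ms windows, 70–90 Hz, 150–350 ms at Cz) after a 1 Hz
high-pass and 41–51 Hz band-stop. Band power is reported in µV² with a
one-sided amplitude normalization shared by both spectral paths.

Artefact detection itself is out of scope (the study delegates it to an
automatic preprocessing pipeline); `detect_artefacts()` is an
amplitude-threshold stub (default 100 µV) that exists to drive the
rejection logic, and is not claimed to replicate the original criteria.

## Bayesian testing and the sequential design

All pairwise contrasts use the one-sided JZS Bayes factor: a Cauchy
prior with scale $r = \sqrt{2}/2$ on the standardized effect
$\delta$, truncated to the tested direction, against the point null.
`bf_paired_onesided()` integrates the noncentral-t likelihood against
the truncated prior by adaptive quadrature, evaluated in log space
relative to the null density for stability; the tests pin it to an
independent fixed-grid trapezoid oracle within 1% over a grid of
$(n, t)$ pairs. Evidence categories use BF10 ≥ 3 ("for") and ≤ 1/3
("against"), boundaries inclusive, and are deliberately not
configurable — they are part of the published decision tree.

When normality fails, a rank-based analogue is available:
`bf_signed_rank_onesided()` augments the signs and absolute ranks of
the differences with latent Gaussians and Gibbs-samples the effect
size; BF10 comes from a Rao-Blackwellized Savage–Dickey ratio at
$\delta = 0$ converted to the one-sided test by posterior mass. The
choice between the two tests is exposed as an explicit flag with a
Shapiro–Wilk screen at $\alpha = 0.05$ as the default gate: the original
analysts inspected Q–Q plots visually, which is not reproducible, so a
deterministic stand-in was required.

`simulate_sbf_maxn()` evaluates the sampling plan: starting at
$n_{\min} = 20$ and growing by 5 up to $N_{\max} = 95$, each simulated
study stops when BF10 crosses 1/10 or 10, and studies reaching
$N_{\max}$ are classified by the 3 / 1/3 thresholds. Samples grow
incrementally within a study (the standard sequential-design
convention; whether the original simulator did the same is not stated,
and the Monte-Carlo tolerances absorb the difference). Because the
one-sided BF10 is strictly increasing in the t statistic over the
reachable range, every BF boundary is inverted once per checkpoint into
a t threshold by root finding; the simulation then compares t
statistics only, making boundary decisions exact and the 10,000-study
run a matter of seconds. The far left tail of the one-sided BF
flattens to a positive constant below $t \approx -8$; that region is
unreachable under these designs and the inversion is clamped
accordingly.

## The adaptive hypothesis pipeline

`run_aai_pipeline()` encodes the preregistered decision sequence: time
contrasts (second vs first half, ART up / ALT down, verum cells) decide
whether later contrasts use second-half or all-trial averages; a time
effect in *either* condition selects second-half data for both (the
published rule is unconditional once any time effect is found);
neurofeedback contrasts (verum vs sham per side) decide whether the
attention contrast runs on sham cells only or on verum/sham-averaged
cells; the category triple maps to result patterns 1–4, absence, or
inconclusive through `classify_pattern()`, a pure function tested over
all 27 combinations. `run_outcome_pipeline()` repeats the machinery for
pain ratings and each brain response with all directions reversed
(alpha oscillations and pain are inversely related) and no time tests;
it inherits the data-selection flags and the time category from the AAI
run. For the brain-response attention contrast the preregistration
writes verum-minus-sham differences between sides while the reported
analyses used sham-only contrasts; both variants are implemented behind
the `attention_data` flag, defaulting to the sham-only behaviour.

## Multilevel mediation

`fit_multilevel_mediation()` fits the 1-1-1 model with condition
($X = -1$ for ART, $+1$ for ALT), within-person-centered trial AAI as
mediator $M$, and the pain rating as outcome $Y$ in raw NRS units
(whether the original analysis standardized $Y$ is not stated; raw
units keep the coefficients interpretable, so path $b$ is NRS per AAI
unit). Subject coefficient vectors $(d_{Mj}, a_j, d_{Yj}, c'_j, b_j)$
are jointly normal with full covariance; the indirect effect is
$ab = a\,b + \sigma_{ab}$ and the total effect $c = c' + ab$, identities
that hold draw by draw and are asserted on every fit. Sampling is a
blocked conjugate Gibbs sampler compiled with RcppArmadillo: diffuse
normal priors on the group means, an inverse-Wishart prior
(df = p + 2 = 7, diagonal scale set from per-subject OLS coefficient
spread) on the covariance, and vague inverse-gamma priors on the
residual variances. We chose the inverse-Wishart over a separated
LKJ-type prior because it admits a conjugate update and therefore an
exact, fast Gibbs step; with 5 dimensions and a data-scaled diagonal
the known IW shrinkage pathologies are mild, and the parameter-recovery
tests confirm calibrated interval coverage. Convergence is gated on a
split-chain $\widehat{R} \le 1.05$ over 4 chains (configurable); a
violation warns and flags the fit rather than failing silently.
"Significance" of a path means 0 outside its central 95% posterior
interval. The verum/sham moderation comparison
(`compare_mediation()`) tests subject-level coefficients path by path
($ab$ one-sided verum > sham, other paths two-sided) and is skipped
with an explicit status when neither fit shows a mediation effect,
mirroring the published contingency.

## The synthetic-data generator

The generator is layered. `simulate_features()` draws the per-trial
statistical model directly: the asymmetry target is
$u_j + s\,\mathrm{att}_j/2 + s v\,\mathrm{gain}/2 + s\,\mathrm{slope}\,(k-1)
+ \varepsilon$ (side sign $s$, verum indicator $v$, trial $k$), with
subject baseline and subject attention effect drawn from normals, and
the rating is
$\bar r + r_j + \beta_X X + \beta_M \mathrm{AAI} + \varepsilon$ clipped
to $[0, 100]$ (clipping, not resampling, mirrors rating-scale floor and
ceiling behaviour). `simulate_trials()` renders EEG for exactly those
draws: pink-noise background, a common 10 Hz source whose amplitudes
$\propto \sqrt{1 \pm a}$ over the two channel groups make the band-power
asymmetry equal the target $a$, Gaussian-windowed N1/N2/P2 templates, a
post-stimulus 80 Hz burst at Cz and post-stimulus alpha/beta
suppression. Defaults follow the study conditions: 40 trials per
condition, 500 Hz, 15 s regulation, stimulus at $t = 0$, trials spanning
$[-18, 2)$ s, fixation onset at $-18$ s, ratings with grand mean 50, and
a null pain model ($\beta_X = \beta_M = 0$) matching the observed
regime. The magnitude of the attention effect in raw index units is not
reported; the default (0.10, with 0.05 between-subject SD) reproduces
the qualitative separation of the published group time courses and is
deliberately left fixed. One global seed expands into per-subject
substreams, so enlarging the cohort never reshuffles earlier subjects.

What the generator does *not* emulate: volume conduction or any head
model, eye/muscle artefact morphology (only amplitude outliers for the
stub), rating drift or habituation, and the attenuation-free mapping
from cortical sources to sensors. Consequently, passing tests show the
*pipelines* are correct under the assumed statistical structure — e.g.
that pink noise dilutes the measured asymmetry towards zero exactly as
the index predicts — not that real EEG meets those assumptions.

## Problem sizes and numerical choices

The test suite runs the design simulator at 2,000 studies (the full
report uses 10,000), pattern-recovery cohorts at 40 subjects × 20 seeds
per pattern, and mediation recovery at 40 subjects × 80 trials × 20
seeds with 4 chains × 1,200 iterations per fit; these sizes give
Monte-Carlo error comfortably below the tolerances being asserted while
keeping a full run at desk scale. EEG-level checks use 1–6 trials at
the native 500 Hz (250 Hz for a 160-trial white-noise null). Other
numerical commitments: boundary BF values classify inclusively (≥ 3,
≤ 1/3); zero band power yields an explicit `NA`, never a silent 0;
zero-variance differences are handled as limits and flagged; ties in
the signed-rank sampler keep a free sign rather than erroring; and all
randomness flows from explicit seeds.

## Known limitations

The artefact stub is not the automatic pipeline it stands in for; the
generator's effect-size defaults are calibrated qualitatively, not fit
to data; the signed-rank Bayes factor relies on a kernel-free but still
Monte-Carlo Savage–Dickey estimate (about 2–3 significant digits at
1,000 iterations); and the mediation model is linear-Gaussian — ratings
are clipped at the scale limits by the generator but modelled as
unbounded.
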