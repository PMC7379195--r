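---
title: "Methods: sequence rules, synthetic ERPs, and Bayesian evidence for MMN control conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence rules, synthetic ERPs, and Bayesian evidence for MMN control conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmncontrol)
```

This vignette is the package's own account of its models and the
choices behind them: what is simulated and why, which parameters
matter, where the design was genuinely open, and what the validation
suite does and does not establish.

## 1. Design: three ordering rules

All blocks use a five-tone ladder (500, 550, 605, 666, 732 Hz; roughly
equal log-frequency steps of 0.13–0.14 octaves), 500-ms onset-to-onset
intervals, and 100-ms tones.

* **Oddball**: the 500-Hz deviant on 1/8 of trials, the 550-Hz standard
  otherwise. Gaps between deviants (number of intervening standards)
  are drawn from a normal distribution with mean 7 and SD 2,
  discretized onto the integers 3–11: each integer receives mass
  proportional to the normal density there, renormalized over the
  support. Renormalization (rather than clipping mass onto the bounds)
  was chosen because it keeps the distribution symmetric and the
  bounds' probabilities consistent with the interior. Deviants are laid
  left to right; if the final deviant overruns the block, the whole gap
  vector is redrawn (bounded retries). Seven warm-up standards precede
  the block and are counted toward the first inter-deviant gap — the
  natural reading, since they are standards in every physiological
  respect.
* **Cascade**: exact repetitions of the up-and-down cycle
  500-550-605-666-732-666-605-550 Hz, preceded by one warm-up cycle
  without the 500-Hz control tone. The 500-Hz tone is equiprobable with
  the 732-Hz tone (1/8 each); the interior tones appear twice per cycle
  (2/8 each).
* **No-repetition**: each 8-tone set is an independent, uniform
  permutation of the cascade cycle's multiset, rejection-sampled until
  no two consecutive tones share a frequency — within sets, across set
  boundaries, and at the warm-up junction. Rejection sampling from
  uniform permutations is unbiased among the valid orderings, which
  matters for any statistic computed over orderings.

Because cascade and no-repetition blocks share the same multiset, their
frequency proportions are identical by construction — the central
design control that isolates sequence *regularity* from tone-set
composition.

## 2. The synthetic EEG model

Epochs span −100 to +400 ms around tone onset (default 1024 Hz;
channels Fz, FCz, Cz plus two mastoid proxies). Each trial's waveform
is a sum of components, each a temporal profile times a per-trial
amplitude, plus noise:

* **N1** — negative Gaussian pulse, peak 93 ms, temporal SD 16 ms.
* **MMN** — negative Gaussian pulse, peak 140 ms, SD 15 ms, applied to
  oddball deviants only.
* **Repetition positivity** — a slow positive plateau (raised-cosine
  onset at 30 ms over 50 ms, flat thereafter) whose amplitude grows
  with the tone's exact-repetition history.

Real components are not Gaussians, but only peak latencies and
windowed means are analyzed downstream, for which the pulse shape is
immaterial; the plateau shape for the slow component keeps the
pre-stimulus baseline clean so that baseline correction does not eat
it. Mastoid-proxy channels receive each component scaled by a signed
gain (−0.5 for N1/MMN, −0.3 for the plateau) rather than through a head
model; that is sufficient to express the polarity reversal expected
under a nose reference, which is all the pipeline tests need.

### Neural adaptation

The N1 to a tone shrinks when preceding tones are recent and
tonotopically close. Each trial gets a score

$$S = \frac{\sum_{l=1}^{L} e^{-l/\tau}\, e^{-\Delta_l^2 / 2\sigma^2}}
           {\sum_{l=1}^{L} e^{-l/\tau}}, \qquad S \in [0, 1],$$

over the previous $L = 10$ tones, where $\Delta_l$ is the
log2-frequency distance in octaves and the N1 amplitude is
$A\,(1 - k\,S)$. The functional form (exponential recency × Gaussian
tonotopy, normalized so an all-identical history gives $S = 1$) is a
package choice; the qualitative mechanism it implements is standard.
With the calibrated kernel the score ordering over 500-Hz tones is
standard > deviant > cascade control > no-repetition control: the
deviant sits a single ladder step from the ubiquitous standard; the
cascade control is always immediately preceded by its 550-Hz neighbor;
the no-repetition control's immediate predecessor is a random other
tone, often tonotopically distant.

### Repetition positivity

A single adaptation-scaled N1 cannot make the heavily repeated
standard's windowed means *positive* while the rare control tones stay
negative — an affine function of one adaptation score misfits the
reference amplitudes by more than a microvolt. The standard differs
from all the rare tones in a second way: it is exactly repeated
hundreds of times, and exact repetition builds a slow memory-trace
positivity. The model therefore gives the plateau component the
amplitude $P_0 + P_1 R$, where $R$ is the same history aggregate with a
near-zero tonotopic width (0.02 octaves, i.e. only exact frequency
matches count) and a slow recency constant (8 trials). $R \approx 0.87$
for standards and $\approx 0.08$ for all three rare 500-Hz roles.

### Calibration

The free amplitudes — $A$ (N1), $k$ (adaptation strength), $P_0, P_1$
(plateau), $M$ (MMN) — enter every windowed mean linearly, so they are
solved by least squares against the eight reference frontocentral
window means (N1 window: 0.66, −0.55, −0.58, −0.72 µV; MMN window:
1.91, −0.76, 0.74, 0.76 µV for standard/deviant/cascade/no-repetition),
with the kernel shape $(\tau, \sigma)$ grid-searched. The solve ships
in `scripts/calibrate.R`; the frozen defaults are $A = -2.12$ µV,
$k = 0.30$, $\sigma = 0.25$ oct, $\tau = 0.8$ trials, $P_0 = 0.76$,
$P_1 = 1.42$, $M = -2.24$ µV, with residuals ≤ 0.02 µV. A noise-free
simulated subject reproduces all eight reference means within 0.03 µV
(the test suite asserts ±0.15 µV to leave room for sequence-draw
variability).

### Noise and between-subject structure

Trial noise is AR(1) across samples (lag-one correlation 0.95),
independent across trials and channels, with stationary initialization;
white noise is available for unit tests. The reference study reports no
variance decomposition, so the split between trial noise and subject
variability is a package choice: subjects draw a multiplicative
amplitude scale from Normal(1, 0.15), and the marginal noise SD is
calibrated so the across-subject SE of the critical cascade-vs-norep
contrast matches the order of the published CIs (SE ≈ 0.34 µV) — 13 µV
per sample at the full design, 6.7 µV in the scaled recovery
configuration. Each subject also draws a behavioral plus-count maximum
error from Normal(5.05, 1.04), feeding the exclusion rule.

What the generator does **not** emulate: ocular and movement artifacts
(rejection is exercised with injected high-range trials instead),
electrode-specific topography beyond the mastoid sign flip, latency
jitter of components across trials and subjects, drift and line noise,
and any effect of the visual letter-ring task (carried as a metadata
flag only). Passing tests therefore show that the *pipeline* is
correct and well calibrated, not that the generative model captures
real EEG in full.

## 3. The ERP pipeline

Baseline correction subtracts the per-trial, per-channel mean of the
pre-stimulus interval. Artifact rejection is automated and blind to
condition: a trial's amplitude range is the per-channel max-minus-min,
maximized over the frontocentral channels, and the default cutoff is
the subject's own 99th percentile of ranges capped at 200 µV —
whichever is lower. This replaces per-subject visual inspection, which
cannot be scripted reproducibly; the percentile policy mimics its
intent (retain as much as possible, clip clear outliers).

The N1 and MMN windows are data-driven but derived from oddball trials
only — the standard-tone ERP's peak negativity near 100 ms (±15 ms
window) and the deviant-minus-standard difference wave's peak
negativity between 100 and 250 ms (±25 ms window) — so they are
independent of the cascade/no-repetition data they are applied to.
Peaks are picked on the channel-averaged waveform after zero-phase
30-Hz low-pass filtering (4th-order Butterworth, forward–backward);
window means are taken from *unfiltered* averages, the conservative
reading of the convention that smoothing serves peak identification
and display. Window bounds are inclusive on the sample grid; peak ties
break to the earliest sample; an extremum on a search-window edge is
flagged as unbracketed rather than silently accepted.

Subject exclusion mirrors preregistration-style rules: behavioral
outliers (maximum plus-count error strictly above the across-subject
mean + 2 SD — a subject exactly at the bound is retained, and with
zero SD nobody is excluded), retention below 70% for any
primary-analysis ERP, and an automated stand-in for the visual
"no identifiable N1" vote: the standard-ERP N1 trough (N1-window mean
minus a same-width flank window 50 ms later) must be more negative
than −2 times the subject's pre-stimulus noise SD. The z-form makes
the criterion scale-free; the threshold is configurable.

## 4. Bayesian inference

The likelihood of the data over the true effect $\theta$ is a t density
(df = n − 1) located at the observed mean with scale SE — the standard
summary-statistic formulation for raw-unit mean differences. Informed
priors are uniform by default: one-tailed from 0 to an empirically
motivated bound (the observed deviant-minus-norep N1 difference for the
N1 test; the observed absolute oddball MMN for the MMN test), with
narrower, wider, and two-tailed variants as robustness analyses.
Integration is adaptive quadrature with absolute tolerance below 1e−8
over the prior's support (location ± 10 scales for normal families);
a point prior at the null returns BF = 1 exactly. Evidence labels
follow the conventional anecdotal/moderate/strong scheme. In synthetic
runs the prior bounds are always computed from the same run's observed
quantities; if a run's observed N1 bound is not positive the test is
reported as not applicable rather than forced.

Tolerances: recomputed Bayes factors are compared to published ones at
±5% relative, because the published inputs (means, CI bounds) are
rounded to two decimals and that rounding alone moves the BF by a few
percent.

## 5. Validation by parameter recovery

Raw recordings are not consumed anywhere, so the pipeline is validated
on its own generator. The recovery configuration scales the problem
down — 96-trial blocks, 160 Hz, three frontocentral channels, 26
subjects — keeping replicated end-to-end runs cheap while preserving
every pipeline stage; these sizes are stated here as the package's
chosen simulation design. Two suites:

* **Null recovery**: 100 replicates with a programmed
  cascade-vs-norep MMN difference of zero. The replicate-mean estimate
  must sit within 2 standard errors of the ground truth (the same
  configuration run noise-free), and BF01 > 1 — correctly favouring
  the null — in well over 70% of replicates.
* **Effect recovery**: programming the effect at the prior's upper
  bound (2.67 µV, injected as an MMN-shaped pulse on cascade controls,
  normalized by its window factor) flips the evidence, with the large
  majority of replicates giving BF10 > 1.

The ground truth is defined as the noise-free pipeline output rather
than the nominal programmed value because the adaptation model itself
induces a small intrinsic cascade-vs-norep difference (the cascade
control is slightly more adapted; ≈ +0.04 µV in the MMN window), which
is part of the generator's truth.

## 6. Known limitations

* The calibration matches eight group-level window means; it does not
  constrain full waveform shape, scalp topography, or single-subject
  heterogeneity beyond one scale factor.
* The published complete-sample (n = 40) Bayes factors are not
  reproduced: their prior bounds derive from complete-sample
  amplitudes that are not part of the printed record this package
  embeds.
* The visual-inspection steps of the original workflow (artifact
  cutoffs, N1-absence votes) are replaced by automated policies; these
  reproduce the intent, not the exact per-subject decisions.
* Event times are nominal (trial × SOA) with no jitter, and the
  letter-ring manipulation exists only as metadata.
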