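---
title: "Adaptive LDA decoding for binary EEG brain-computer interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive LDA decoding for binary EEG brain-computer interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptlda)
```

## The problem

A non-invasive, binary speech-imagery brain-computer interface (BCI) asks a
user to silently imagine pronouncing one of two syllables while scalp EEG is
recorded. A linear discriminant analysis (LDA) classifier, calibrated once on
an initial open-loop *offline training* block, then drives real-time visual
feedback during a closed-loop *online control* block. EEG statistics are not
stationary over a session: gel dries, electrodes shift, vigilance fluctuates,
and the user's own strategy changes with feedback. A decoder frozen at
calibration time therefore degrades, and it can become *biased* — increasingly
favouring one class over the other.

`adaptlda` implements the standard remedy studied in this setting: an LDA
whose class means and common inverse covariance are updated incrementally as
labelled online trials arrive, at a speed governed by two *update
coefficients* (UCs), together with the simulation machinery needed to choose
those coefficients and to quantify what adaptation buys.

## The decoder

Each sliding window of preprocessed EEG yields a feature vector $x$ of log
band power (channels x frequency bins). The binary LDA assumes both classes
are Gaussian with a common covariance $\Sigma$ and decides by the sign of the
signed distance from the separating hyperplane,

$$D(x) = w^\top x + b, \qquad
  w = \Sigma^{-1}(\mu_2 - \mu_1), \qquad
  b = -\tfrac{1}{2}\, w^\top (\mu_1 + \mu_2),$$

with $D < 0$ read as class 1 and $D > 0$ as class 2. A logistic map of $D$
provides the probability output used for feedback; because any strictly
monotone sigmoid with $D = 0 \mapsto 0.5$ yields the same labels under the
0.5 threshold, this choice does not affect accuracy metrics.

### Adaptive updates

When one new trial of each class has completed, every window-level feature
vector $x(t)$ of the pair updates the model. The mean of the trial's class
follows an exponentially weighted average

$$\mu_i(t) = (1 - UC_\mu)\,\mu_i(t-1) + UC_\mu\, x(t),$$

and the common covariance follows the rank-one recursion

$$\Sigma(t) = (1 - UC_\Sigma)\,\Sigma(t-1)
  + \frac{UC_\Sigma}{N-1}\,\big(x(t)-\mu_i(t-1)\big)\big(x(t)-\mu_i(t-1)\big)^\top,$$

where $N$ counts all feature samples incorporated so far (offline plus
online), so the rank-one correction shrinks as evidence accumulates. The
classifier needs $\Sigma^{-1}$, never $\Sigma$ itself; since the recursion is
a rank-one correction of a scaled matrix, the Woodbury identity gives
$\Sigma(t)^{-1}$ directly from $\Sigma(t-1)^{-1}$ in $O(d^2)$, with no matrix
inversion in the loop:

$$(A + uv^\top)^{-1} = A^{-1} - \frac{A^{-1} u\, v^\top A^{-1}}{1 + v^\top A^{-1} u},
  \qquad A = (1-UC_\Sigma)\,\Sigma(t-1).$$

One published description of this expansion prints the coefficient of
$\Sigma(t-1)$ inside the inverse as $(1-UC_\mu)$, which is inconsistent with
the covariance recursion it expands; `adaptlda` follows the recursion's
coefficient $(1-UC_\Sigma)$ and exposes the printed form as
`update_covariance_woodbury(printed_variant = TRUE)` for side-by-side
comparison rather than resolving the discrepancy silently.

Both $\Sigma$ and $\Sigma^{-1}$ are tracked (each update is $O(d^2)$), so the
consistency invariant $\Sigma \Sigma^{-1} \approx I$ remains checkable at any
point; symmetry is re-imposed by averaging with the transpose every 50
updates as cheap numerical hygiene, although the implementation's symmetric
rank-one form preserves symmetry by construction.

### Update granularity and causality

The recursions are written for a single sample $x(t)$, but one trial yields
many windows. The default `"per-window"` mode iterates the single-sample
update over each window of the new class-1 trial in time order, then the
class-2 trial, and refreshes $w, b$ once per trial pair — respecting the
rank-one form while matching the trial-pair cadence of a real closed-loop
session. A `"trial-mean"` mode (one update per trial using the trial's mean
feature vector) is available for sensitivity analysis; which granularity the
original closed-loop systems used is generally unstated, so it is a switch,
not a guess. Because the refresh happens after a trial pair completes, each
trial is always classified by the model in force when it began: no outcome
depends on the trial's own data or on later trials, which the test suite
verifies by perturbing future trials.

## Feature extraction

The preprocessing chain mirrors common EEG practice: channel exclusion
(reference and mastoids in a full montage), a zero-phase Butterworth
band-stop notch at the 50 Hz line frequency (order 2, half-width 2 Hz,
applied forward and backward), then a common average reference over the
retained channels. Features are one-sided Hann-tapered periodograms per
500 ms sliding window, aggregated into contiguous 2 Hz bins over 1-70 Hz by
default and log-transformed. Design notes:

* **Estimator.** No specific spectral estimator is canonical here; a single
  Hann-tapered periodogram per window is used because the windows are already
  short (one segment per window). Windows of 500 ms give exactly 2 Hz
  resolution, one spectral line per default bin.
* **Log transform.** Log power is the standard variance-stabilising choice
  ahead of a Gaussian classifier; `log_power = FALSE` disables it.
* **Window step.** Published parameter listings for this paradigm are
  inconsistent about the sliding-window "overlap" (20 ms during calibration,
  50 ms during simulation and feedback); these figures are read as the *step*
  between onsets, with 50 ms the package default everywhere and the
  calibration-specific 20 ms available via configuration.
* **No per-feature standardisation** — the pooled covariance handles scale.

Window onsets live on the continuous time grid $k \cdot \text{step}$ and are
rounded to samples individually, so the count per trial is exactly
$\lfloor(\text{duration} - \text{length})/\text{step}\rfloor + 1$ at any
sampling rate (91 windows for a 5 s trial at 500 ms / 50 ms).

## Static training, cross-validation, replay metrics

The static LDA pools within-class covariance with denominator $N - 2$ (two
estimated means; the unbiasedness convention) and optionally shrinks it
toward its diagonal by a coefficient `regularization` (default $10^{-3}$) —
spectral feature spaces with thousands of dimensions are routinely
ill-conditioned, and a singular covariance without shrinkage raises an error
naming the remedy. Cross-validation folds are stratified by class and split
at the *trial* level so overlapping windows of one trial never straddle the
train/test boundary; window-level splits would leak and inflate accuracy.

Replay of an offline-train / online-control session produces:

* **Predicted accuracy (PA)** — a trial is correct when the window-averaged
  probability of the cued class strictly exceeds 0.5 (a mean of exactly 0.5
  counts as incorrect); PA is the percentage of correct trials.
* **Classifier bias** — $|PA_{\text{class 1}} - PA_{\text{class 2}}|$.
* **BCI control performance** — the percentage of feedback ticks whose
  decoded label (sign of $D$; a tie never matches) equals the cue, averaged
  over trials.
* **Battery feedback** — the fill level moves by an amount proportional to
  $p - 0.5$ per tick, scaled so that $p \equiv 1$ fills the battery in
  exactly the timeout duration, floored at zero; the published descriptions
  do not state the decrement rate, so it is taken equal to the increment
  rate.

## Choosing the update coefficients

Candidate values for both coefficients span $0.4 \times 2^{-14}$ to $0.4$ in
powers of two (15 values; the cap guards against destabilising update
speeds), giving a 225-cell lattice. For each dataset, `grid_search()` replays
the online block adaptively at every pair and once statically, yielding per
pair the **Modulated PA** (adaptive minus static PA) and **Modulated bias**
(adaptive minus static bias); `aggregate_sim()` averages these across
datasets and counts, per pair, the datasets with strictly positive Modulated
PA (**Consistency score**).

The published selection procedure is qualitative — maximise Modulated PA and
Consistency while minimising Modulated bias, with no stated precedence.
`select_uc_pair()` therefore uses an explicit, deterministic policy: keep
cells within 0.5 percentage points of the maximal mean Modulated PA, among
those maximise Consistency, then minimise mean Modulated bias, and break any
remaining tie toward the smallest $UC_\mu$, then smallest $UC_\Sigma$
(slower adaptation is the safer default). The band width is configurable and
the full ranking is returned for audit. `select_individual_uc()` implements
the per-dataset alternative — the argmax of Modulated PA with the same
tie-break — which by construction dominates any fixed pair on its own
selection data; held-out replays of the same generative process show the
advantage shrinking, the expected overfitting signature.

## The synthetic generator

Real recordings from the motivating experiments are not publicly deposited,
so the package ships a generator whose ground truth is known exactly. Each
trial is 1/f-background noise per channel plus a band-limited oscillation on
a subset of channels; the oscillation's log-amplitude is drawn per trial from
a class-specific Gaussian, and the two class means are separated by
`class_power_gap` trial-to-trial standard deviations (`log_amp_sd`). Because
the decoder's features are log band powers, this ground truth maps directly
to feature space, and the per-trial generating parameters are attached to the
dataset so tests can build Bayes oracles. Note the gap imposes a ceiling on
any decoder's trial-level accuracy, $\Phi(\text{gap}/2)$ — about 93% at a gap
of 3 — since a trial's drawn amplitude can fall on the wrong side of the
midpoint regardless of how well the decoder reads it.

Non-stationarity is linear in the online trial index: `mean_drift_rate`
moves the class-1 log-amplitude mean up and the class-2 mean down (per-trial,
in SD units), so the centroids converge and eventually swap;
`bias_drift_asymmetry` concentrates that drift on class 1 to induce a growing
classifier bias; `cov_drift_rate` inflates the log-amplitude SD. The
`centroid_swap_rate()` helper returns the rate at which the swap completes
exactly at the last online trial.

Defaults (8 channels at 256 Hz, 5 s trials, 80 offline and 40 online trials,
alpha-band 8-16 Hz signal on half the channels, gap 2, `log_amp_sd` 0.4)
describe a desk-scale session: channel count and sampling rate are reduced
relative to a 61-channel laboratory montage so that full replays and grid
searches run in seconds, while trial structure and spectral layout follow the
paradigm. The drift experiments in the test suite and acceptance script run
at 8 channels, 2 s trials, 40 offline + 60 online trials, gap 3, with the
swap completing at the last online trial — sizes chosen once, after pilot
sweeps with the full pipeline, to give the adaptive-vs-static contrast a
realistic dynamic range at desk scale.

What the generator does **not** emulate: ocular/muscular artifacts, electrode
geometry and volume conduction (channels are independent up to the common
reference), source-space structure, or learning dynamics on the user side.
Passing tests on this synthetic family therefore demonstrate the decoder's
statistical and numerical behaviour under controlled non-stationarity — not
performance on real EEG.

## Numerical choices and degenerate inputs

* Covariance inversion uses a Cholesky factorisation; failure with zero
  shrinkage raises an actionable error rather than a cryptic one.
* The Woodbury scalar $1 + v^\top A^{-1} u$ is checked against zero; a
  degenerate update aborts rather than silently producing garbage.
* $UC_\Sigma = 1$ is rejected: it would annihilate the previous covariance
  and leave a singular rank-one matrix.
* Identical class means produce $w = 0$, $b = 0$, $D \equiv 0$ — every trial
  then counts as incorrect under the strict threshold, consistent with the
  tie rule.
* With a zero update pair the adaptive replay is bit-identical to the static
  replay; this exact equivalence is asserted across datasets in the tests.

## A worked example

```{r example, eval = FALSE}
library(adaptlda)

cfg <- synth_config(
  n_channels = 8, sampling_rate = 256,
  n_trials_offline = 40, n_trials_online = 60, trial_duration = 2,
  class_power_gap = 3, seed = 1
)
cfg$mean_drift_rate <- centroid_swap_rate(cfg)

eeg <- generate_drift_scenario(cfg)
feats <- extract_psd_features(preprocess(eeg), band = c(1, 33), bin_width = 2)
ph <- split_by_phase(feats)

static <- replay_static(ph$offline, ph$online, timeout = 2)
adaptive <- replay_adaptive(ph$offline, ph$online,
                            uc_pair(0.4 * 2^-6, 0.4 * 2^-3), timeout = 2)
glance(static); glance(adaptive)
autoplot(adaptive)
```

## Known limitations

* Binary classification only; no multi-class extension, no QDA, and no
  time-varying update coefficients (Kalman-gain schemes).
* Adaptation is supervised by the cue; unsupervised or semi-supervised
  adaptation is out of scope.
* The grid search is embarrassingly parallel but executed serially; results
  are pure functions of inputs and seed, independent of execution order.
* Serialization uses a plain-text JSON + CSV container; there is no binary
  EEG-format import or export.
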