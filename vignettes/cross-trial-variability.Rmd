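---
title: "Cross-trial beta variability in working memory: models, statistics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trial beta variability in working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialvar)
```

## The scientific problem

Trial-averaged EEG power discards a dimension of the signal that turns out
to be informative: how much the single-trial response *varies* from trial to
trial. In visual working memory, beta-band (15--25 Hz) activity over frontal
cortex is thought to carry control signals that gate memory maintenance and,
after the response, the clearing ("deletion") of no-longer-relevant content.
`trialvar` implements a complete, testable pipeline for studying the
cross-trial variability of single-trial beta power in a delayed
match-to-sample task with memory loads of 1, 2 and 4 items, contrasting a
younger and an older age group: spectral decomposition, the
relative-variance statistic, and the inference battery around it (load-slope
tests, mixed models, permutation tests, and lagged single-trial models
linking one trial's post-response beta power to the *next* trial's
accuracy).

Because raw multi-participant EEG for such studies is rarely available,
the package pairs the analysis code with a synthetic-EEG generator in which
every effect the analysis is meant to detect is a planted, parameterized
quantity. Every stage can therefore be verified against ground truth,
analytic oracles, or brute-force reimplementations.

## The core statistic

For single-trial power $P_i(c, f, t)$ (trial $i$, channel $c$, frequency
$f$, time $t$), the cross-trial **relative variance** is

$$
\mathrm{relvar}(c, f, t) \;=\;
\log_{10} \frac{\operatorname{Var}_i\, P_i(c,f,t)}
{\overline{\operatorname{Var}_i\, P_i(c,f,t_b)}^{\,t_b \in \text{baseline}}},
$$

the across-trial variance at each time--frequency point expressed relative
to the mean across-trial variance over a pre-event baseline window
($-0.4$ to $-0.1$ s). Conventions adopted here:

* **Logarithm base 10**, consistent with the decibel convention used for
  power normalization in the same pipeline.
* **Sample variance (ddof 1)** throughout.
* The statistic is computed on **dB-normalized single-trial power** by
  default (normalization precedes the variability analysis in the pipeline
  order); a raw-power mode is available for sensitivity analysis.
* The ratio is exactly invariant to global rescaling of power, which is
  enforced by a property test.

Aggregation averages over the band's frequency bins and the window's time
bins per channel first, and over the channel cluster last. The two
preplanned clusters are frontal (Fz, AFz, F1, F2, FCz) and centroparietal
(CPz, Cz, CP1, CP2, Pz). The analysis windows are maintenance 0--3 s after
delay onset and post-response 0.1--0.5 s after the button press (the first
100 ms are discarded against motor artifacts); encoding uses a 0--1.2 s
window per presented item.

## Spectral decomposition choices

Single-trial decomposition uses complex Morlet wavelets on a 1--40 Hz grid
(1 Hz steps) whose number of cycles grows linearly from 2 at the lowest to
10 at the highest frequency; "width" is read as the dimensionless cycle
count, the standard Morlet parameterization. The 50 ms "time window" is
read as the decimation step of the output time grid: wavelet duration is
already fixed by the cycle count, so an additional time constant can only
refer to the output sampling.

Convolution is computed in the frequency domain with zero padding. Output
samples within half the wavelet support (3 Gaussian SDs per side) of either
epoch edge are marked invalid (NA) and excluded from every window average.
A consequence worth making explicit: with a $-0.5$ s epoch start, the
$-0.4$ s baseline edge is *not* edge-clean at beta frequencies (half
support at 15 Hz is about 0.16 s). Synthetic epochs are therefore rendered
with a 0.5 s pad on each side of the analysis span ($-1.0$ to $4.0$ s
maintenance-locked, $-1.0$ to $1.5$ s response-locked), which makes the
baseline clean for all frequencies above about 2 Hz; `dbNormalize()`
errors on (or, on request, drops) frequencies whose baseline is still
edge-contaminated. Decibel normalization is per trial: each trial, channel
and frequency is scaled by its own baseline mean. SNR is the window-averaged
power divided by the standard error of the trial mean over 0--4 s.

## The generative model

`synthParams()` parameterizes every planted effect. Per trial, channel and
sample the waveform is

$$ x(t) = \text{1/f noise} + \text{evoked transient} + A \cdot
   w_{\text{Hann}}(t)\,\sin(2\pi f_\beta t + \phi), $$

with $A = s\,e^{a}$, $a \sim \mathcal N(\mu, \sigma)$ per condition and
$\phi$ uniform per trial. Key decisions:

* **Lognormal amplitudes** (positive support, multiplicative cross-trial
  variability). The cross-trial variance structure — the quantity the
  statistic must recover — is therefore controlled by $\sigma$ alone on the
  log scale.
* **Uniform random phase** makes the burst non-phase-locked, so it survives
  subtraction of the per-condition trial average while the evoked transient
  is removed — mirroring the phase-locked-removal logic of the analysis.
* The response occurs at probe onset plus the simulated reaction time;
  response-locked epochs are cut around that event.
* The montage is restricted to the 10 analysis channels; a full 64-channel
  montage adds nothing at desk scale.

Behaviorally, accuracy follows a logistic model whose linear predictor is
the per-condition base logit, a per-participant intercept
(SD `participant_logit_sd`), and — for all but the first trial of a block —
`n_plus_1_beta` times the previous trial's centered post-response
log-amplitude. The post-response amplitude SD may additionally be keyed on
the trial's own correctness. Because the lag effect needs the *previous*
post-response amplitude while the correctness-keyed SD needs the *current*
accuracy, the generator runs a sequential chain in trial order: draw
accuracy$_n$ from the logistic (using the already-drawn amplitude of trial
$n-1$), then draw the post-response amplitude of trial $n$ with the SD
keyed on that accuracy. With `n_plus_1_beta = 0` this reduces to drawing
correctness first and amplitudes afterwards. Reaction times are lognormal
with per-condition mean and SD.

### Default planted effect sizes

The defaults are fixed study conditions, chosen once by design analysis so
that every planted effect is recoverable with about 20 participants per
group (they are the package's choices, not estimates from any dataset):

* Maintenance log-amplitude SD: younger 0.36, 0.27, 0.16 over loads 1, 2, 4
  (a load-dependent variability *decrease*); older flat at 0.26. On
  dB-normalized power the expected aggregate is
  $\log_{10}\!\big((4\sigma^2 + \tau^2(1+1/n_b)) / (\tau^2(1-1/n_b))\big)$
  with bin-level jitter $\tau = 0.2$ and $n_b = 7$ baseline bins, giving
  aggregates of roughly 1.22, 0.99 and 0.64 and a per-participant slope
  near $-0.19$ per load unit; with $\approx 240$ trials per condition the
  per-participant sampling SD of each aggregate is about 0.1, so the
  population slope test has essentially full power at $n = 20$.
* N+1 coupling `n_plus_1_beta`: 1.0 (older), 0 (younger), on the
  log-amplitude scale. Measured dB power is about $8.7\times$ the
  log-amplitude, so the fitted coefficient on dB power is near 0.115; with
  roughly 14,000 lagged trials per group the Wald $z$ is far beyond any
  conventional threshold.
* Post-response log-amplitude SD 0.40 on correct vs 0.25 on incorrect
  trials (both groups), a correct-minus-incorrect log-variance contrast of
  about 0.4.
* Accuracy base rates fall with load and are slightly lower in the older
  group; per-participant heterogeneity enters through the accuracy
  intercept (SD 0.3), a shared multiplier on all amplitude SDs
  (log-SD 0.05), and a shared amplitude-mean offset (SD 0.1) — these are
  what the random intercepts in the mixed models absorb.

`synthParamsNull()` removes every planted effect (equal SDs everywhere, no
lag coupling, identical accuracy logits across groups) and is the
configuration for type-I-error calibration.

## Two simulation modes

Replicate-scale studies (hundreds of simulated experiments) do not render
waveforms. In **power mode**, single-trial band power on the 50 ms grid is
drawn directly from the generative model,

$$ \log P_i(t) = 2 a_{b,i} + 2 a_i h(t) + \varepsilon_i(t), $$

with a trial-level baseline offset $a_b \sim \mathcal N(0, 0.25)$, the
phase indicator $h(t)$, and bin-level jitter $\varepsilon \sim \mathcal
N(0, \tau)$ — and then fed through the *same* `dbNormalize()`,
`relativeVariance()`, `aggregateVariability()` and inference code as real
data. The closed-form `expectedRelVar()` oracle above refers to exactly
this model, and tests verify both that the oracle matches brute-force Monte
Carlo within 2% and that the measured aggregates match the oracle within
0.05 log10 units at 240 trials per condition.

The **waveform mode** is the full path — rendering, artifact rejection,
phase-locked subtraction, Morlet decomposition, normalization — and is
validated separately: the FFT convolution equals a direct time-domain
convolution oracle to below $10^{-8}$ relative error; per-trial dB band
power from waveforms rank-correlates above 0.7 with the planted amplitudes;
and two runs with identical configuration and seeds produce byte-identical
persisted tables. Waveform rendering for 40 participants across 50--200
replicates would be computationally absurd, which is why the replicate
studies use power mode; what power mode does *not* exercise (and its
passing tests therefore do not show) is robustness of the spectral
estimator itself to overlapping spectral content, edge effects or artifact
contamination — those properties are covered by the waveform-path tests at
small n.

## Inference procedures

* **Load-slope test** (`loadSlopeTest`): per participant, OLS of the
  aggregate on *numeric* set size (1, 2, 4) — the design fits lines across
  loads, so load is not treated as categorical — then a two-tailed
  one-sample t of slopes against zero. If every slope is identical the t
  statistic is undefined (0/0); the contract is a warning with p = 1.
* **Group model** (`fitGroupVariability`): `value ~ group * set_size +
  (1 | participant)` as a linear mixed model, interaction tested with a
  Satterthwaite F.
* **Accuracy model** (`fitAccuracyOnVariability`): `accuracy ~ group *
  variability + (1 | set_size)`, gamma family with inverse link by default
  (per-condition mean accuracy is negatively skewed), normal/identity as a
  check.
* **Permutation t test** (`permutationTTest`): Welch t with label
  shuffling, $p = (k+1)/(n_{\text{perm}}+1)$; when the number of label
  assignments is at most $10^4$ the test switches automatically to
  exhaustive enumeration and the p value is exact.
* **Cluster permutation** (`channelClusterPermutation`): per-channel paired
  t, supra-threshold channels joined into connected components of an
  explicit adjacency (an edge-list file, never geometric inference), cluster
  mass = summed t, null by participant sign-flipping, positive and negative
  clusters formed separately.
* **Subsampled contrast** (`subsampledContrast`): correct trials are
  subsampled to the incorrect-trial count (200 iterations) so both sides of
  the contrast see the same trial count and the small-sample bias of the
  statistic — for log-variance, a bias that depends only on n — cancels in
  the difference. Performed at the highest load, where incorrect trials are
  plentiful enough.
* **Lagged (N+1) models** (`buildLaggedDesign`, `fitNPlus1`): each trial is
  paired with the previous trial's post-response power and load. Pairs that
  span a block boundary are dropped, and a trial removed in preprocessing
  breaks the chain — both its own row and its successor's lag disappear
  (only globally consecutive within-block trials are paired). Continuous
  single-trial predictors are participant-mean-centered before fitting,
  which stabilizes the logit fits and matches the centered generative
  coupling. The full five-way-interaction specification with four random
  slopes is available (`formula = "paper"`) but is not estimable at 20
  participants per group — fits are frequently singular — so the default is
  the additive model with a group-by-lag interaction and random intercepts.
* **Same-trial (N-N) models** (`fitNN`): accuracy ~ power (logit binomial),
  RT ~ power (gamma, inverse link, correct trials only), and the two
  reverse regressions, as a confidence-control battery.

Mixed-model optimization is delegated to `lme4`/`lmerTest`; this package
owns design construction, coding, centering, lag alignment and reporting.
Boundary (singular) fits are reported as converged — a zero variance
component is a valid boundary estimate — while genuine optimizer failures
set a flag that downstream consumers must refuse.

## Calibration and recovery studies

The verification battery simulates complete studies at two scales, chosen
to keep a full run of the suite within ordinary desktop patience:

* **Calibration**: 200 replicates, 20 participants per group, reduced
  120-trial sessions (5 blocks of 24), all planted effects zero. The slope
  test, the group-by-load interaction, the pooled N+1 lag effect and the
  correct/incorrect contrast must each reject at a rate inside the binomial
  95% interval around 0.05.
* **Recovery**: 50 replicates of the default planted configuration with
  full 720-trial sessions. The qualitative pattern — significant negative
  younger maintenance slope with no significant negative older slope, a
  significant positive older-only lag coefficient, and a positive
  correct-minus-incorrect contrast in both groups — must appear in at least
  90% of replicates. "Flat" and "only" are operationalized as the *absence
  of a significant effect in the planted direction* in the other group,
  fixed before any replicate was run.

## Degenerate inputs and numerical conventions

Zero baseline variance, fewer than two trials, empty band/window/cluster
selections, singleton conditions in phase-locked subtraction, constant
values in the median split, non-positive reaction times in the gamma RT
model, and lag predictors without variance all raise errors rather than
propagate nonsense. The improbability index of artifact rejection is a
per-channel kernel-density negative log-likelihood z-scored across trials —
a deliberate approximation of joint-probability rejection; numerical parity
with other toolboxes is a non-goal. The RT outlier rule computes each
participant's mean and SD once, on pre-filter data, over correct and
incorrect trials jointly. Independent component analysis is not part of the
cleaning contract: the synthetic data contain no ocular components, and the
threshold/improbability/kurtosis trio plus RT filtering defines cleaning
here.

Persistence uses plain-text formats: a YAML + hex-float TSV internal layout
(bit-exact round-trip) and BrainVision (.vhdr/.vmrk/.eeg, IEEE float32) for
interoperability. All seeds derive from a single master seed through a
fixed 32-bit linear scheme, and every stochastic stage is reproducible
seed-for-seed.

## Known limitations

* The generator does not model volume conduction, channel covariance,
  ocular or muscle artifacts (beyond an optional spike injector), or
  session-level nonstationarity; conclusions about robustness to those
  belong to real-data applications.
* Power mode plants band power directly and so cannot detect spectral
  leakage or edge-handling mistakes — that is what the waveform-path
  oracle tests are for.
* Maintenance-locked and response-locked epochs of a trial are rendered
  with independent noise; temporal continuity across the two locks of one
  trial is not modeled.
* Bayes factors and source localization are out of scope, as is the
  omnibus behavioral ANOVA (the pipeline emits the aggregated accuracy
  table such an ANOVA would consume).
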