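---
title: "Methods: measuring vocal individuality in red deer contact calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring vocal individuality in red deer contact calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalid)
```

# The question and the statistical machinery

Mother–offspring vocal recognition presupposes that calls carry stable,
individually distinctive acoustic structure. `vocalid` measures that
structure the way the bioacoustics literature does for red deer hinds and
calves: describe each contact call by 14 variables, classify calls to
individuals with linear discriminant functions, and judge the observed
percent-correct against a randomization (label-permutation) chance level.
Because no public recordings exist for this system, the package pairs the
analysis chain with a synthetic call generator whose ground truth is known
exactly; every claim the test suite makes is a claim about that generator
plus the estimator, not about field recordings.

## The discriminant analysis and its chance level

For calls with feature vectors $x$ and individuals $g = 1..k$, the classifier
uses Fisher linear classification functions from the pooled within-group
covariance $W$ and group means $\mu_g$:

$$ s_g(x) = \mu_g^\top W^{-1} x - \tfrac12 \mu_g^\top W^{-1} \mu_g + \log \pi_g, $$

assigning each call to $\arg\max_g s_g(x)$. Priors $\pi_g$ are equal by
default: the study design is near-balanced (5–10 calls per individual), and
with unbalanced priors the reported accuracy would partly reflect sample
sizes rather than acoustic structure; `prior = "proportional"` is available.

The headline statistic is **resubstitution** accuracy — the training calls
classified by the functions fitted on them. With ~9 calls per individual and
11 variables this is substantially inflated above $100/k$ by overfitting.
That is not a defect to be corrected but the convention to be matched: the
chance level is defined operationally, by refitting the same procedure on
1000 random permutations of the call-to-individual labels (group sizes
preserved) and averaging the resulting accuracies. For 22 groups of 5–10
calls (209 total) and 11 variables this permutation mean is close to 24%,
five times the naive $1/22 = 4.5\%$ — reproducing that level is only
possible with the resubstitution reading, which is why the package adopts it
(a leave-one-out mode exists for cross-validated accuracy, and is what the
between-year transfer uses implicitly, since year-B calls are out-of-sample
for year-A functions). Significance is the one-sided percentile rule:
observed accuracy exceeding 95 / 99 / 99.9% of the permuted values is
reported as p < 0.05 / 0.01 / 0.001.

Chance-level simulations use iid standard-normal feature tables
(`gaussian_null_table()`). This is valid for arbitrary populations because
the classifier is invariant under invertible affine transformations of the
feature space (tested numerically to 1e-8): under label permutation any
multivariate-normal table is equivalent to the white one.

Per-variable contributions are partial Wilks' lambdas
$\Lambda_j = \Lambda_{\text{full}} / \Lambda_{\text{without } j}$ with
$F_j = \frac{n-k-p+1}{k-1}\,\frac{1-\Lambda_j}{\Lambda_j}$; for a single
variable this reduces exactly to the one-way ANOVA F, which the tests use as
an oracle.

## Univariate statistics

Oral/nasal comparisons operate on per-individual mean values (one oral and
one nasal mean per animal), so animals with unequal call counts carry equal
weight. The two-level repeated-measures ANOVA is fitted with an
individual-level error stratum; with two levels its F equals the squared
paired t (asserted to 1e-10). Classification rates are compared with
Yates-continuity-corrected 2×2 χ² tests on correct/incorrect counts; when
only percentages and sample sizes are reported, counts are reconstructed by
nearest-integer rounding — the worked examples in the acceptance suite
confirm this reconstruction reproduces reference statistics to two decimals.
Body mass enters as its cube root ("log₃" in the field's shorthand), since
mass scales with the cube of linear size; a literal log-base-3 transform is
available behind `transform = "log3"`. The calf sex × mass ANCOVA uses Type
III sums of squares with sum-to-zero contrasts, giving the one-df-per-term
layout with denominator df $n-4$.

# The synthetic call generator

## Latent structure

A `population_spec` holds, per call type, the population mean and SD of each
of the 14 variables (defaults: reference values for Iberian red deer hind
and calf oral/nasal contact calls). Individuality is injected by a
variance-components construction: individual $i$'s latent mean of variable
$v$ is $\mu_v + \sqrt{\text{icc}}\,\sigma_v z_i$ and calls scatter around it
with SD $\sqrt{1-\text{icc}}\,\sigma_v$, so marginal moments match the spec
while the between-individual variance fraction equals `icc`. The default
`icc = 0.7` was chosen once so that default runs show strong but imperfect
individuality — observed accuracy well above the null yet below 100% in the
pooled sample — since the reference tables conflate between- and
within-individual variance and publish no per-individual means. A
property-based test recovers `icc` from simulated tables by ANOVA variance
components.

Constraints are enforced at both the latent and per-call level. The f0
landmark trio is drawn sequentially — `f0max` from its marginal, `f0beg`
truncated below `f0max`, `f0min` truncated below `f0beg` (inverse-CDF
truncated normals) — because the reference marginals overlap enough that
joint rejection sampling would bias `f0max` and `delta_f0` upward by
half a reference SD or more; sequential truncation leaves `f0max` and
`delta_f0` unbiased at the cost of a modest downward shift in `f0beg`
(about half a reference SD for calves), which the calibration does not
target. Two reference values are mutually inconsistent and cannot be
honored literally: calf oral `dur_to_max` exceeds calf oral `durat`, and
calf oral `f0min` exceeds `f0end`. The generator therefore (a) clamps
`dur_to_max` to `durat - max(50 ms, 0.2 durat)`, keeping a falling segment
long enough for the tracker and for the 50 ms spectrum fragment, and (b)
ends the contour at `f0min` rather than at a separate `f0end`, so that the
extracted `delta_f0 = f0max - f0min` matches the reference arithmetic
exactly; extracted `f0end` consequently tracks `f0min`.

## Waveform

The call is an additive stack of harmonics of a cosine-segment contour
(zero slope at onset, maximum and offset — the smoothest shape through the
three published landmarks). The spectral envelope rises linearly in dB from
the f0 band (at `-power_f0` dB) to the emphasized harmonic `peak_harm`,
then rolls off at `rolloff_db` (default 3 dB/harmonic); harmonics above 98%
of Nyquist are dropped. Harmonic phases are randomized per call. A 10 ms
raised-cosine ramp at each end prevents clicks, and broadband Gaussian
noise is added at `noise_snr_db` (default 30 dB — clean field recordings;
the −25 dB energy-threshold bound detector needs roughly ≥ 25 dB to work).
Synthesis is at 11025 Hz, the analysis rate, so round-trip tests involve no
resampling. The generator does **not** attempt perceptual realism: no
formants (unmeasurable in these tonal calls), no nonlinear phenomena
(subharmonics, deterministic chaos), no amplitude modulation, no
reverberation or wind. Passing calibration therefore shows the estimator
chain is unbiased for idealized harmonic calls, not that it is robust to
every field artifact.

# The measurement chain

## Preprocessing

Input audio is resampled to 11025 Hz by periodic-sinc (FFT-domain)
interpolation with mirror padding (exact passband amplitude, brick-wall
anti-aliasing), then high-passed at 50 Hz with a linear-phase FIR filter
(order 1536, Hamming design), applied with odd-reflection padding and
group-delay compensation so temporal landmarks do not shift and signal
edges do not ring. Content at 30 Hz is attenuated by more than 40 dB while
the call band passes within 5%. Upsampling is refused: the workflow expects
field recordings at 11025 Hz or above.

## Fundamental-frequency contour

The primary tracker computes, per frame, the normalized cross-correlation
of the signal with itself over candidate period lags within
`[rate/ceiling, rate/floor]` (hinds: 50–400 Hz at 10 ms steps; calves:
100–1200 Hz at 5 ms). Numerical details that matter:

* The correlation function is sinc-oversampled 4× (spectral zero-padding)
  before peak picking. Broadband voiced signals have correlation peaks only
  about two samples wide; on an integer lag grid a true period falling
  between lags loses several percent of correlation while a near-integer
  multiple-period lag samples its peak exactly, biasing selection toward
  sub-octaves. After oversampling, the shortest lag among near-maximal
  (within 0.02) interior local peaks is taken — multiples of the true
  period tie for periodic signals, so the shortest wins. Lag-range boundary
  bins are never candidates.
* Two passes: the first uses a one-floor-period window and the full lag
  range; the second re-estimates every frame with a short window
  (~1.5 periods, lag search ±25–35%) sized from the smoothed first-pass
  contour. Short windows keep frames near call edges and in
  frequency-modulated segments tracking the instantaneous f0 (chirp oracle:
  within 3% at 500–2000 Hz/s sweep rates). Frames whose window would need
  to shift more than about a quarter window from the frame time yield no
  estimate rather than a mislabeled one.
* Voicing: peak normalized correlation ≥ 0.45 (the field workflow screened
  quality manually; this is its deterministic surrogate). White noise comes
  out almost entirely unvoiced.
* Octave-jump repair replaces the manual spectrogram-based corrections of
  the field workflow: frames deviating from a local (±3 voiced frames)
  median are halved/doubled toward it, with the deviation measured
  multiplicatively (|log₂ ratio| > log₂ 1.6). The threshold is the
  published "60%" figure read symmetrically — a halved frame is only −50%
  on a linear scale and would otherwise escape its own repair rule. The
  pass runs forward then backward with repaired values replacing originals
  immediately. A final whole-contour gate discards voiced frames outside
  [median/2.2, 1.6 × median]: these contact calls are moderately modulated
  (contour extremes stay well inside that band), while harmonic
  mistracking lands near 2× or 0.5×, and a run of consistent errors can
  defeat a local median but not the global one — the same logic as the
  octave-cost prior in standard pitch tools.

A second, independent estimator (`estimate_f0_spectral()`) picks the lowest
harmonically-consistent peak of the Hamming-windowed spectrum per frame
(voicing gated on the strongest in-range peak standing ≥ 12 dB above the
in-range median; candidate fundamentals must be the strongest peak, or
divide it near-integrally with a supported second harmonic, and estimates
hugging the search bounds are rejected as out-of-range-harmonic pile-up).
It exists purely as a consistency oracle: the acceptance suite requires the
two estimators' per-call `f0max` values to correlate at ≥ 0.99 on clean
synthetic calls, mirroring the dual-software cross-check of the original
workflow.

## Temporal and spectral variables

Call bounds are either the generator's exact onsets/offsets (synthetic
calls carry them) or detected at −25 dB re the loudest 10 ms block. `durat`
is offset − onset; `dur_to_max` the time of the contour maximum after
onset. The 50 ms fragment centered on the f0 maximum is analyzed with
512-sample Hamming frames zero-padded to a 1024-point FFT at a 16-sample
hop, averaged into one power spectrum; at call edges the fragment is
clipped, never zero-padded, and if the clipped fragment is shorter than one
512-sample frame the analysis falls back to 256-sample frames (an error is
raised only below that). From this spectrum: `fpeak` (arg-max frequency),
energy quartiles `q25/q50/q75` (first frequencies at which cumulative
energy crosses 25/50/75% — verified against a brute-force cumulative-sum
oracle), `peak_harm = round(fpeak / f0)` (with f0 taken at the contour
maximum), and `power_f0`, the dB difference between the `peak_harm` band
and the f0 band, where a band is the set of FFT bins within ±f0/2 of the
harmonic center (the band width is not standardized anywhere; half the
harmonic spacing is the natural partition). `power_f0` is exactly 0 when
the f0 band is the peak band. Only relative dB is meaningful — absolute
calibration of field recordings is unknown — which is consistent with how
`power_f0` is used.

# Stability analysis

Between-year drift is modeled phenomenologically: each individual's latent
mean of each variable shifts by `N(0, (year_drift_sd × σ_v)²)` between
years. The drift scale is expressed in population SDs because the 14
variables have heterogeneous units; no age, mass or social mechanism is
implied. `cross_year_classify()` fits the discriminant functions on year A,
classifies year B's calls with them (raw variables, no re-standardization),
and reports the transferred accuracy against both within-year accuracies
(Yates χ² on reconstructed counts) and year B's own permutation null. Two
regimes anchor the behavior: with zero drift and identical tables the
transferred accuracy equals the within-year accuracy exactly
(stationarity limit), and as drift grows the seed-averaged transferred
accuracy falls monotonically and settles inside the chance band. It settles
*in* the band, not below it: with few groups and many variables the year-A
decision regions are large convex cones, so even statistically unrelated
year-B calls are assigned "correctly" well above $1/k$ — the same
overfitting geometry that raises the resubstitution null.

# Problem sizes and reproducibility

Simulation sizes were chosen to estimate each quantity comfortably within
its tolerance: calibration uses 25 individuals × 4 calls (100 calls) per
caller class and call type; chance levels use the published designs with
1000 permutations; drift sweeps average 3 population seeds over five drift
levels; the type-I-error check uses 400 null replicates. Every stochastic
function takes an explicit `seed`, the pipeline derives all stage seeds
from one master seed, and a rerun with the same configuration is
byte-identical in its CSV/JSON outputs (the JSON config snapshot omits the
output path for exactly this reason).

# Known limitations

* Calibration targets the means of `durat`, `f0max` and `delta_f0`; other
  variables track their references more loosely (`f0beg` is deflated ~0.5
  SD by the ordering constraint, `f0end` reproduces `f0min` by
  construction, and the quartiles emerge from the envelope shape rather
  than being matched).
* The direct feature sampler draws variables independently; real call
  variables are correlated (e.g. `f0max` with `f0mean`), so multivariate
  effect sizes in direct-sampled tables are optimistic relative to audio
  extraction of the same population.
* The pitch tracker is not designed for noisy, overlapping or nonlinear
  calls; its hardening targets the artifact modes of clean harmonic stacks.
* The energy-threshold bound detector assumes one call per file and SNR of
  roughly 25 dB or better.
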