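---
title: "Movement-related gamma and reaching kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-related gamma and reaching kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gammareach` implements, as one tested chain, the analyses that link
movement-related gamma-band EEG dynamics to reaching kinematics: a
synthetic-data generator with known ground truth, kinematic measure
extraction and a mixed-effects model of movement extent, Morlet
time-frequency analysis with whole-epoch baseline normalization,
cluster-based permutation statistics with sensor adjacency, the debiased
squared weighted phase lag index (wPLI), Network Based Statistics (NBS)
over connectivity matrices, and regression screens of per-subject gamma
summaries against peak velocity and movement time. This vignette
documents the models, the defaults and why they were chosen, and what
the validation studies do and do not establish.

## The task and the synthetic cohort

The emulated task is a centre-out-and-back planar reach to targets at
three distances (4, 7, 10 cm) in eight directions. The generator
(`synth_config()`, `gen_reach_trials()`, `gen_eeg_epochs()`) is a
first-class component: every downstream stage is validated against its
ground truth.

**Trajectories.** The out-going segment follows the minimum-jerk
position profile $x(\tau) = D\,(10\tau^3 - 15\tau^4 + 6\tau^5)$ with
$\tau = t/T$, whose tangential speed peaks at $1.875\,D/T$ at
mid-movement; the return is minimum-jerk with duration $1.1\,T$.
Movement time is $T = a + b D$ (defaults $a = 250$ ms,
$b = 15$ ms/cm), so peak velocity rather than duration carries most of
the extent scaling, which is the regime the analyses are about.
Reaction time is truncated normal (mean 370/350/330 ms for
short/medium/long targets, SD 60 ms, floor 150 ms) — shorter for
farther targets. Tablet samples at 200 Hz with 0.01 cm Gaussian
coordinate noise (digitizing-tablet precision; a larger value would let
the movement-onset detector trigger on the noise floor). The tablet
rate and the noise level are configurable because no measurement
standard fixes them.

**EEG.** Epochs span −1 to 2.5 s around movement onset at 250 Hz. Each
channel carries 1/f background noise (spectral shaping of white noise,
exponent 1.0, SD 1.0), plus two injected bursts: a planning burst
(54 Hz carrier, Gaussian envelope with FWHM equal to the −152 to −52 ms
window, centro-parietal channels) and an execution burst (66 Hz
carrier, envelope equal to the trial's out-and-back speed profile,
parieto-occipital channels) — gamma amplitude that tracks the velocity
profile is exactly the feature the band-power analyses quantify. Burst
amplitude is `amp * gains[distance] * subject multiplier`, gains
(1.0, 1.3, 1.6) over the three distances, with per-subject lognormal
multipliers (σ = 0.2) that correlate on the log scale (r = 0.6) with
the subject's peak-velocity level: this is the brain–behaviour coupling
the regression screen is asked to recover. Optional channel-pair
couplings add a shared narrow-band component with a fixed phase lag in
(0, π) during the execution window, and `mixing_gain` adds a zero-lag
mixture of each channel's neighbours, emulating volume conduction.

What the generator does **not** emulate: dipole forward models and
realistic scalp topographies, artifacts (blinks, EMG), continuous
recordings, non-stationary background. Passing tests therefore show
that the estimators are correct and calibrated under their assumptions,
not that real-EEG preprocessing decisions are handled.

## Kinematic measures and the extent model

Trajectories are low-pass filtered with a zero-phase 4th-order
Butterworth filter at 10 Hz (neither order nor cutoff is standardized;
these are the common choices for tablet reaching data), with
endpoint-reflected padding to suppress the filter's edge transients.
Speed, acceleration and jerk come from central differences. Movement
onset is the first sustained (≥ 20 ms) crossing of 5% of the trial's
peak speed, then walked back down the rising flank to where the speed
stops decreasing or falls below 0.5% of peak — without the back-walk, a
pure threshold rule is systematically late by ≈ τ: the minimum-jerk
profile reaches 5% of peak only at τ ≈ 0.06. Extent is the maximum
radial excursion; the out-going segment ends at that reversal. Trials
whose speed never crosses the threshold are flagged invalid, never
silently dropped. The 2-SD rejection operates per subject (the pooled
alternative is configurable), tests each of RT, MT, total MT and peak
velocity against the subject's original mean and SD, and rejects
nothing when the SD is zero.

The extent model is `extent ~ pv + mt` with subjects random, fit by
REML through `lme4`/`lmerTest` after z-transforming all three
variables; `compare_lmm()` contrasts the random-intercept and
random-intercept-plus-slopes structures by BIC (maximum-likelihood
refits) and a likelihood-ratio test (χ², df = parameter difference; the
boundary problem of testing variance components at zero makes this p
conservative, which is flagged rather than corrected). The adjusted R²
is conditional — computed from fitted values that include the random
effects — matching how "variance explained" is quoted for such models.
In tests the reference oracle is a two-stage estimator: per-subject OLS
followed by averaging the coefficients.

One modelling point deserves emphasis. With a standardized outcome and
*orthogonal* standardized predictors, fitted slopes must satisfy
$\beta_1^2 + \beta_2^2 \le 1$; standardized slope pairs like (1.0, 0.7)
are only attainable when the predictors are negatively correlated.
Reaching data has exactly this structure — for a given extent, faster
movements are shorter — so `gen_lmm_cohort()` draws PV and MT with
correlation −0.5. With the default random-effect budget the outcome SD
is ≈ 1.02, so recovered z-scale slopes sit ≈ 2% below the generating
(1.0, 0.7); the recovery study averages 20 replicate cohorts of
40 subjects × 60 trials and lands well within ±0.05.

## Time-frequency analysis

`morlet_tfr()` convolves each trial and channel with complex Morlet
wavelets, $\sigma_t = c/(2\pi f)$, cycle count $c$ linear from 3 to 10
over the frequency grid (1–80 Hz in 0.5 Hz steps canonically).
Amplitude is normalized so a unit sinusoid yields unit peak power — any
consistent normalization cancels in the baseline ratio; this one makes
raw power interpretable in tests. Convolution runs in the frequency
domain on reflection-padded signals, with the padded length chosen
2-3-5-smooth for FFT speed; samples within half a wavelet (3σ) of
either epoch edge are masked invalid per frequency, not zero-filled,
and every window statistic honours the mask.

Baseline normalization is whole-epoch subtract-and-divide: per channel
and frequency, $(P - m)/m$ with $m$ the mean power over all trials and
valid times, so the normalized series averages to zero by construction.
Band/window statistics use the band means over 24 ms bins. Peak
frequency is the argmax of window- and channel-averaged normalized
power within the 25.5–80 Hz search band, ties broken toward the lower
frequency and flagged; sub-bin interpolation is deliberately out of
scope. The search band is configurable because post-movement spectra
peak near the beta/gamma border, below the gamma floor, when no
post-movement rhythm is injected (or, in the real data the design
mirrors, when the rebound sits at ~28 Hz).

A measurement subtlety the validation surfaced: dividing by a 1/f-shaped
baseline tilts the normalized spectrum upward in frequency by roughly
$\sigma_f^2/f$ (wavelet bandwidth squared over frequency), about half a
bin for a 54 Hz burst analyzed at 6–7 cycles. The burst-recovery studies
therefore analyze the gamma sub-grid with the cycle counts the canonical
1–80 Hz grid assigns to those frequencies (≈ 7.7 cycles at 54 Hz),
which keeps recovered peaks within one 0.5 Hz bin of the injected
carriers.

## Cluster-based permutation statistics

`cluster_test()` thresholds pointwise paired-t (two conditions, sign
flips) or repeated-measures F maps (condition labels permuted within
subject) at the parametric critical value for α = 0.001 (two-sided for
t). Zero-variance points get statistic 0 with a flag rather than ±∞.
The "minimum number of significant neighbouring electrodes" rule is a
gate applied before component formation: a supra-threshold point is
cluster-eligible only when at least `min_neighbors` (default 4) of its
spatial neighbours are supra-threshold at the same bin — the standard
minnbchan semantics. Eligible points form connected components over
spatial-neighbour links within a bin and same-channel links between
adjacent bins; positive and negative t-clusters form separately.
Cluster mass is the summed statistic; the null is the permutation
distribution of the maximum mass; p uses the +1/+1 convention so it is
never zero, with a Monte-Carlo CI reported. For n ≤ 4 subjects (or
whenever `n_perm = "all"`) the paired-t sign-flip null is enumerated
exhaustively and the sampled path must match it, which the tests check.

The family-wise-error calibration study runs the neighbour gate at 0:
the gate discretizes the max-mass null toward zero, making the test
conservative, and a calibration check (is the rejection rate inside the
binomial CI around α?) cannot distinguish conservatism from a broken
test. With the gate off, cluster mass is continuous and the permutation
p is exact up to Monte-Carlo error; 200 null simulations × 500
permutations at n = 15, 20 channels × 30 bins land inside the CI. The
analysis default remains `min_neighbors = 4`.

Peak-frequency differences across windows use a tie-corrected Friedman
test implemented from the rank formula (cross-checked against
`stats::friedman.test` to 1e-10) and Dunn's pairwise z with Bonferroni
correction capped at 1.

## Connectivity: debiased squared wPLI

Cross-spectra use Morlet coefficients at a fixed width of 7 cycles;
within a trial the window's time bins are collapsed into one complex
cross-spectrum per pair and frequency, and only trials act as
independent observations. The debiased squared wPLI is the U-statistic
over distinct trial pairs,

$$\widehat{\mathrm{wPLI}^2} =
\frac{\left(\sum_j I_j\right)^2 - \sum_j I_j^2}
     {\left(\sum_j |I_j|\right)^2 - \sum_j I_j^2},$$

with $I_j$ the imaginary cross-spectral component of trial $j$. (The
formula as typeset in the source literature's text is garbled; the
implementation follows the cited estimator, and a brute-force double
loop over trial pairs is the test oracle.) Because only the imaginary
part enters, zero-lag (volume-conducted) coupling contributes nothing
in expectation; because the estimator is unbiased, small negative
values are legitimate and are retained (clipping is an explicit
option). Band values average the per-frequency estimates after
debiasing (the alternative order is configurable). Validated contracts:
a constant π/2 lag gives ≥ 0.95 at 200 trials; zero-lag mixtures stay
within ±0.05; independent noise averages within ±0.02 of zero; and
expected wPLI is monotone in the fraction of trials carrying the lag.

## Network Based Statistics

`nbs_test()` thresholds per-edge statistics (same code path as the
cluster test), forms connected components of the supra-threshold graph
with `igraph` (a union-find brute force is the test oracle), and
compares each component's size against the permutation null of the
maximal component size; p again uses +1/+1. Component size defaults to
edge count ("extent"), matching how subnetworks are reported by edge
counts; "intensity" (summed statistic) is the alternative. The default
primary threshold is the t-score 4.8 used for paired contrasts at full
cohort size (~60 subjects); desk-scale studies pass the one-sided t
quantile at pointwise α = 0.001 instead, since a fixed 4.8 at n = 15 is
the 3·10⁻⁴ quantile and leaves essentially no supra-threshold edges.
The omnibus analysis across the three windows is a repeated-measures F
with within-subject label permutation (the natural scheme where none is
prescribed), followed by directional paired-t contrasts.

Calibration uses intensity mode: with sparse supra-threshold graphs the
extent statistic is an integer heavily tied at 0 and 1, which makes the
extent test conservative (a correctness property, but one a
within-the-CI check would flag). The planted-subnetwork recovery study
(8-node clique, per-edge effect d = 1.5, n = 15) runs in extent mode
and requires a significant component covering ≥ 80% of planted edges in
≥ 90% of simulations.

## Linking gamma to behaviour

The regression screen z-transforms both sides and fits one simple OLS
per (gamma summary, outcome) cell — per-subject means of band power per
window/region, subnetwork mean wPLI, against mean peak velocity and
movement time — reporting F against the constant model, slope, SE, t,
p, and adjusted R², with an additional Bonferroni column; the main
columns are deliberately uncorrected, matching how such grids are
presented. Subjects whose mean peak velocity falls more than 2 SD below
the cohort mean can be excluded before fitting (the low-performance
rule); trial-level regression is out of scope. A variant predictor
samples the band-power time course at each trial's peak-velocity time
(nearest 24 ms bin) before averaging (`gamma_at_peak_velocity()`).
Full standardization of both sides is applied everywhere, including
movement time — mixed scales in reported movement-time coefficients
elsewhere suggest inconsistent standardization, which this package does
not reproduce.

## Pipeline, determinism, and problem sizes

`run_pipeline()` executes the whole chain from one configuration and
seed and returns a machine-readable report; identical configuration and
seed give a byte-identical report, every stage derives its seed from
the run seed, and any stage failure aborts with the stage's name.
Stages are always recomputed rather than cached by content hash:
at package scale every stage is cheap relative to the permutation
stages' reduced permutation counts, and cache state can silently
desync from the configuration.

The validation studies run at sizes chosen to estimate each property
with useful precision on a single CPU: cluster FWE at 200 simulations ×
500 permutations (n = 15, 20 × 30 points); NBS null at 200 × 500 and
recovery at 50 simulations (30 nodes); wPLI contracts at 200 trials;
mixed-model recovery over 20 replicate cohorts of 40 × 60; screen signs
over 20 cohorts of 60 subjects. The demo workflow under `analysis/`
uses 6 subjects × 24 trials × 24 channels with 1000 permutations.
Binomial Monte-Carlo error at these sizes is reported alongside each
rate.

## Known limitations

- Sensor positions are abstract disc coordinates; region labels are
  rank-based anterior–posterior bands, not a fitted electrode montage.
- The Friedman/Dunn route is exercised at small cohort sizes in the
  demo, where its χ² approximation is coarse; the calibration test uses
  n = 25.
- The TLRT for random-effect structure ignores the boundary problem
  (flagged, conservative).
- Extent-mode NBS is conservative at sparse thresholds (integer ties);
  use intensity mode when calibration matters.
- The peak-frequency estimator inherits an upward bias of order
  $\sigma_f^2/f$ from the 1/f baseline ratio; at the canonical cycle
  counts this stays below one 0.5 Hz bin, but coarser wavelets or
  steeper backgrounds would push it further.
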