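---
title: "The probabilistic time-frequency mismatch response: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The probabilistic time-frequency mismatch response: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In an auditory oddball paradigm a frequent "standard" sound is occasionally
replaced by a rare "deviant". The brain's differential response — the
mismatch response (MMR) — indexes whether the two sounds are discriminated,
and can be recorded passively, which makes it attractive for infants tested
during sleep. Classical averaged-ERP analyses of the MMR suffer from large
latency variability; this package instead estimates, for every
time-frequency point, the *probability* that the deviant-minus-standard
difference exceeds a label-blind error estimate. The result (the MMR-TF) is
a scales-by-time probability surface per recording block, which a modified
joint DISTATIS then combines across subjects and stimulus-contrast
conditions into condition and group consensus maps, from which oscillatory
features (gamma, beta, theta-1, theta-2) are extracted as masks, marginal
distributions and centroids.

## The estimator

Per block (one subject, one contrast), after preprocessing and the wavelet
transform, two surfaces are estimated by bootstrap (draws with
replacement, complex mean first, squared modulus after):

* `M`: the squared modulus of the mean over `n_boot` draws of
  (random deviant trial − random standard trial);
* `E`: the same with both trials drawn from the whole block regardless of
  label.

Because the complex mean is taken before the modulus, only
*phase-consistent* differences survive: `M` is sensitive to responses that
are phase-locked to the stimulus, and trial-to-trial phase jitter
suppresses it. `M` and `E` are then jointly normalized per scale so the
squared values of both sum to one at each scale — this equates the natural
energy advantage of low frequencies — and every normalized `M` value is
mapped through the kernel-density CDF of the pooled normalized `M` and `E`
values. The MMR-TF surface is therefore a *rank-based* quantity: its
values say where, relative to every other point and to the error floor,
a phase-consistent difference is most probable.

Two consequences of this construction are worth keeping in mind:

* `E` converges to zero as `n_boot` grows (it is the modulus of a mean of
  exchangeable differences), while `M` retains the finite-sample offset of
  the class-mean difference, of order `sigma^2 (1/n_dev + 1/n_std)`. The
  null surface therefore sits *above* 0.5 — uniformly so. Absolute MMR-TF
  values are not significance levels; only their spatial structure is
  informative, and the group stage (rescaling, minimum bound, qLE) works
  entirely on that structure.
* The per-scale normalization equates scales regardless of how much
  absolute signal they carry. Under spectrally colored noise a quiet
  scale's response to the *skirt* of a strong neighboring burst can rank
  comparably to the burst's own scale. This is the price of detecting weak
  high-frequency responses next to strong low-frequency ones.

## Group analysis

Each surface is turned into spectral (`p p'`) and temporal (`p' p`)
cross-product matrices, double-centered with uniform masses and normalized
by the first eigenvalue. For a positive semidefinite cross-product matrix
the centering operator makes `-1/2 Xi CP Xi'` negative semidefinite; the
first eigenvalue (largest in magnitude) is negative, and dividing by it
restores positive semidefiniteness, zero row/column means, and a unit top
eigenvalue — the invariants every downstream step relies on.

Condition compromises are unweighted means of each condition's matrices
and the grand compromise is the mean of the condition compromises, so
conditions are equi-weighted no matter how many members they have (the
package accepts unequal condition sizes without imputation).
Eigenvectors of the two grand compromises are ranked by
`pvaf = sqrt(lambda) / sum(sqrt(lambda))` and retained at `pvaf >= 0.01`;
retained vectors are renormalized to unit L2 norm (the square-root
normalization is the only reading that makes the retained set an
orthonormal projector) with the reproducibility convention that each
vector's largest-magnitude element is positive. The relative contribution
of the spectral vs temporal dimension is the ratio of their first
eigenvalues.

Each surface is then projected onto the retained bases. The retained
eigenvectors all have zero mean (they derive from centered matrices), so
the projector is applied to the correspondingly centered surface and the
removed mean profile is added back. This choice matters: applying the
projector to the raw surface silently discards each profile's mean level
and can invert the map's topography; with the mean restored, a complete
basis reproduces the surface exactly, the projection is idempotent per
dimension, and surfaces built from discarded eigenvectors project to zero.
Condition means and the grand mean of the projections are finally rescaled
to [0, 1] jointly — one min-max transform shared by the grand mean and all
condition means — so relative probability (RP) values remain comparable
across conditions. The [0, 1] range is thus an explicit output convention,
not an automatic property.

## Feature extraction

The minimum bound `B` is the pointwise maximum over condition means; the
quasi-likelihood estimate maps the grand mean through the squared
kernel-CDF of `B`'s pooled values. Thresholding the qLE (default 0.8)
gives a binary mask whose 8-connected components are the features;
components spanning the 12 Hz boundary are split so theta and beta-gamma
content is never mixed in one feature. Per feature and condition, the
masked surface's means across scales (temporal distribution) and across
time (spectral distribution) are computed, and the centroid is the joint
argmax of the two marginals with the RP value at that point. A recursive
local-maxima search splits composite features at marginal valleys — this
is what separates the merged gamma-beta region into gamma and beta
centroids, and a swept theta region into onset and offset centroids. Two
local maxima count as separate when the valley between them drops below
75% of the smaller peak (`dip = 0.75`); equal peaks are all reported,
ordered by descending frequency, and a perfectly flat marginal falls back
to the earliest, lowest-frequency point with a warning.

The surprise statistic is `S = -log(dF / (C * dT))` with the natural
logarithm and proportionality constant fixed at 1, where `dF` and `dT` are
the probabilities of the theta-1/theta-2 frequency and latency
differences and `C` encodes the latency of the cross-frequency coupling
between the beta-gamma packet and theta-1. How `dF` and `dT` are to be
estimated from data is genuinely open; `mmr_surprise()` implements one
admissible estimator — the overlap coefficient of the sum-normalized
spectral (for `dF`) and temporal (for `dT`) feature distributions of
theta-1 vs theta-2 — and is documented as experimental. Identical
distributions give overlap 1 (no difference), disjoint ones approach the
floor (default 1e-6).

## Preprocessing choices

* **Filter.** 2–50 Hz windowed-sinc FIR (Hamming), with the order chosen
  from the low band edge so the measured rolloff there is about
  24 dB/octave; applied by FFT convolution with the symmetric kernel's
  group delay compensated exactly, hence zero-phase. Signals shorter than
  three filter lengths are refused.
* **Referencing.** Common average over the scalp channels, or linked
  mastoids ((M1+M2)/2); the analysis montage is Cz against linked
  mastoids, which concentrates the auditory dipole's polarity inversion.
  The spatial-PCA channel QC (`bootstrap_channel_differences()` +
  `spatial_pca_loadings()`) reproduces that choice as a diagnostic;
  loading magnitudes come from the mean squared retained eigenvectors and
  the sign from the first retained eigenvector, which restores the
  polarity information that squaring destroys.
* **Epochs.** −500…1500 ms inclusive, baseline the pre-stimulus mean;
  baseline intervals are closed on the left and open on the right.
  Joint-probability artifact rejection scores each trial by the summed
  negative log empirical probability of its sample amplitudes (histogram
  with automatic bin count by default, KDE optional) and flags trials
  2.5 SD above the mean score; the mask is returned without mutating data.
* **Whitening and CWT.** Trials are ZCA-whitened along the trial dimension
  (eigenvalue fraction threshold 0.01% of total variance — read as
  variance, not singular-value, fraction), then transformed with a 6-cycle
  complex Morlet bank (carrier parameter omega0 = 6), 128 log-spaced
  scales, center frequencies 1.94–48.40 Hz, computed on the full epoch and
  only then truncated to −100…700 ms with the complex pre-stimulus mean
  (−100…0 ms) subtracted. Trials whose total squared magnitude exceeds
  2.5 SD are dropped. The truncation margins keep most of the wavelet
  cone-of-influence outside the analysis window; at the lowest scales
  (below roughly 3.4 Hz) the nominal sqrt(2)*s radius still reaches into
  the window — an unavoidable property of sub-4 Hz wavelets in a 2 s
  epoch, shared by the published configuration and noted here rather than
  hidden.

## Numerical choices

* Kernel CDFs use a Gaussian kernel with Sheather-Jones plug-in bandwidth
  (computed on a capped subsample for large inputs, normal-reference rule
  as fallback), evaluated on a fine binned grid and interpolated; the
  empirical CDF is available everywhere as `cdf_method = "ecdf"` and
  serves as the test oracle (agreement within 0.02 at 10^4 points).
* Largest eigenvalues of centered matrices are found by power iteration
  started from a deterministic non-constant vector (the constant vector is
  annihilated by centering).
* Degenerate inputs: all-zero scales keep zero normalized values and are
  flagged; a degenerate pooled distribution yields 0.5 everywhere (0.25
  after the qLE squaring) with a warning; an empty feature set is returned
  with a warning when nothing clears the threshold.
* Every stochastic stage takes a seed; group runs derive one seed per
  block from the master seed and a stable string hash, so runs are
  reproducible end to end while blocks remain independent.

## The synthetic-data generator

`synthesize_block()` emulates the recording situation the pipeline
targets: 10–20 montage (default 11 channels, F5…M2), 1000 Hz sampling
(tests and examples often use 250 Hz, which keeps the full wavelet bank
below Nyquist), ~600-trial blocks at 85/15 standard/deviant with no two
deviants in succession and 1200 ms onset-to-onset interval. The background
is 1/f^alpha Gaussian noise (alpha = 1.5, per-channel SD 20 µV) with
smooth log-frequency Gaussian emphasis of the delta (2–4 Hz, ×2) and theta
(4–8 Hz, ×1.5) bands — sleep EEG in the first months of life is dominated
by these bands, and smooth bumps avoid artificial spectral cliffs that
would distort the rank-based estimator. All trials receive a small common
onset response (2 µV damped 4 Hz wave); deviant trials additionally
receive the response cascade: Hann-tapered sinusoids (or linear chirps)
projected through a dipolar topography (positive central, negative
mastoids).

The default cascade places a gamma burst (34 Hz, peak 25 ms, 100 ms),
a beta burst (17 Hz, 60 ms, 200 ms), theta-1 (5 Hz, 70 ms, 400 ms),
theta-2 (6 Hz, 220 ms, 450 ms) and a late low-frequency component
(3 Hz, 500 ms, 500 ms). Durations were fixed once against a noise-free
wavelet oracle so that each carrier's ridge peaks at its nominal frequency
— bursts much shorter than the analyzing wavelet bias the ridge toward
higher scales — and amplitudes (4 µV theta, ~2.5 µV gamma/beta before the
topography gain) were fixed once so that recovery succeeds at the
~600-trial block size at the default noise level, since no empirical
amplitude or SNR figures exist for these responses in sleeping infants.
Within a block every burst is phase-locked (fixed carrier phase at
envelope onset); across blocks each burst's phase is offset by one uniform
random draw (`random_block_phase = TRUE`). This mirrors real recordings —
phase-locking within a subject is what the complex bootstrap mean
detects, while the *relative* phases of distinct oscillators differ
between subjects — and it prevents an artifact of fully deterministic
simulation in which the same carrier interference pattern survives group
averaging and displaces ridge maxima. A `phase_jitter_sd` parameter
degrades within-block phase-locking for sensitivity analyses.

What the generator does not emulate: sleep-stage transitions and their
spectral nonstationarity, ocular or movement artifacts beyond what the
joint-probability rejection sees in Gaussian tails, inter-subject latency
and amplitude variability (subjects differ only by noise realization and
burst phases), and any habituation across trials. Passing recovery tests
on this generator therefore demonstrates the pipeline's correctness and
sensitivity under idealized-but-plausible conditions, not clinical
performance on real infant EEG.

## Problem sizes used by the test-suite

The package's validation suite runs a cohort of 12 synthetic subjects ×
3 conditions × 600 trials at 250 Hz with 1001 bootstrap draws for the
headline recovery check (embedded gamma/beta/theta-1/theta-2 centroids
recovered from the group feature table within ±1.5 Hz, ±0.5 Hz for theta,
and ±30 ms), a 6-subject cohort for the latency-shift check (a condition
delayed by 100 ms yields later centroids), and twenty 3-subject null
cohorts (zero-amplitude cascade) for the specificity check that no
feature survives qLE ≥ 0.8. The acceptance script uses 6 subjects × 3
conditions × 200 trials. These sizes are the package's choice of a
desk-scale representation of the target study design (24 subjects,
~600-trial blocks); the estimator itself is size-agnostic.

## Known limitations

* Absolute MMR-TF values are rank probabilities, not p-values; comparing
  them across preprocessing variants requires identical pooling.
* The qLE threshold (default 0.8) is procedure-specific; narrower
  consensus masks are expected when conditions differ strongly in
  latency, because the minimum bound rises above the grand mean wherever
  conditions disagree.
* Centroid frequencies of short bursts carry an intrinsic bias at wavelet
  resolution: two oscillators 1 Hz apart below 8 Hz are inside each
  other's Morlet bandwidth, and their centroids are only separable via
  the temporal marginal splits.
* The surprise estimator is one reading of an under-determined
  definition; its absolute values should not be compared across studies,
  only its ordering within one analysis.
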