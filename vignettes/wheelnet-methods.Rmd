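---
title: "Methods: from paw trajectories to persistent direct connectivity"
author: "wheelnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from paw trajectories to persistent direct connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelnet)
```

# The experiment this package models

A head-fixed mouse runs on a motorised wheel whose speed the experimenter
controls.  A session is a sequence of 2-min constant-speed blocks
(`speed_profile()`): the ascending session steps 0, 15, 30, 45, 60 mm/s and
ends with rest; the descending session jumps from rest to 60 mm/s and steps
down.  A behaviour camera tracks the two forepaws at 71.5 Hz, and a
two-photon microscope records GCaMP fluorescence from layer 2/3 and layer
5a of the forelimb motor cortex at about 6.4 frames/s per layer (4630
frames per 12-min session).  The analyses ask how stride kinematics,
single-neuron event rates, responses to speed transitions, and the
functional-connectivity graph evolve as the animal learns to adapt its gait.

Every stage of the package consumes plain tables (delimited text), so
precomputed outputs of other toolchains — pose-tracker coordinate tables,
deconvolved event rasters — drop in directly.  The synthetic generators
exist so that each stage can be exercised against planted ground truth;
they are first-class, tested code, not fixtures.

# Kinematics

Raw paw coordinates are centred as $d_{new} = \alpha\,(d_{median} -
d_{raw})$, with $\alpha$ the mm-per-pixel calibration; the median over the
session is the zero point and forward positions are positive
(`center_paw()`).  Traces are smoothed with an order-2 Butterworth filter
applied forward and backward (`smooth_trace()`).  Zero-phase filtering is a
deliberate choice: a causal filter would delay both paw traces, and any
differential lag would bias the coordination index.

A stride is the rising phase of a spike in the horizontal trace — from a
local trough to the next local peak — that contains a complete spike (a
prominent local maximum) of the vertical trace (`detect_strides()`).
Stride length is the horizontal excursion of that rising phase.  The
detector needs a prominence floor and a refractory separation, neither of
which is dictated by the experimental protocol; the defaults are
scale-free: prominence at half the interquartile range of the trace, and
separation of 0.1 s.  Both choices make the stride count invariant to
offsets and to the value of $\alpha$ (lengths scale linearly with
$\alpha$, as they must).

The coordination index is the negative Pearson correlation of the two
horizontal paw traces over the 2-min 60 mm/s block: $+1$ is perfect
alternation.  Percent changes between blocks use the
$(\text{later}-\text{earlier})/\text{earlier}\times 100$ convention.

# Calcium events

The pipeline treats event detection as replaceable: deconvolution-based
rasters can be supplied directly via `event_raster()`.  The built-in
detector (`detect_events()`) is deliberately transparent: per neuron, a
running-median baseline is subtracted and an event onset is an upward
crossing of $k\,\mathrm{MAD}$ (default $k = 2.5$) sustained for at least 2
frames.  One refinement matters in practice: at plausible rates a
non-negligible fraction of transients begins while the previous transient
is still decaying, and a pure threshold-crossing detector merges them.
Within an above-threshold excursion the detector therefore also marks
onsets where the one-frame increment exceeds $k$ times the MAD of the
differenced trace.  With this rule the detector reaches $\ge 95\%$
precision and recall on planted events at observation noise up to
0.1 dF/F (tested over seeds).

Event rates are onset counts per second per block.  "Rest" pools the
speed-0 blocks and "running" the nonzero blocks.  The width of the
event-rate distribution is the full width at half maximum of the lightly
smoothed rate histogram (3-bin moving average, linear interpolation at the
half-height crossings; Freedman–Diaconis bins by default).  If the
smoothed histogram is multimodal the width describes the highest peak and
the value is flagged.  The peri-transition analysis compares the event
rate in the 10 s after each transition with the 5 s before; ties count as
not transition-associated (conservative).

# Transition-active neurons

The transition vector $s$ has $s_t = 1$ on frames within 15 s after any
speed transition (`build_transition_vector()`), windows merged when they
overlap.  The 15-s window is read as *following* the transition,
consistent with the post-transition rate analyses; a symmetric window is
available as an option.  A neuron's trace $c$ (dF/F clipped at zero) is
compared with $s$ through the normalised inner product

$$\mathrm{sim}(c, s) = \frac{2\, s \cdot c}{\lVert s\rVert^2 + \lVert c \rVert^2},$$

which lies in $[0, 1]$, equals 1 only when $c = s$ elementwise and 0 only
when the supports are disjoint.

The null repositions the transition windows at uniformly random onsets
with circular wrap, preserving the number and lengths of the windows
(`permutation_null()`).  Repositioned windows are kept disjoint so
$\lVert s \rVert^2$ is exactly invariant across shuffles.  This choice —
rather than permuting the entries of $s$ freely — preserves the temporal
structure of the regressor; free permutation fragments the windows into
single frames and makes the null far too easy against autocorrelated
calcium traces (it is still available as `mode = "elementwise"` for
comparison).  A neuron is transition-active when its observed similarity
exceeds the 99.95th percentile of its own 5000-shuffle null.  Each neuron
gets an independent null seeded as `seed + k`, so results are independent
of evaluation order and reproducible neuron by neuron.  No further
multiple-testing correction is applied beyond the percentile rule.

# Functional connectivity: Pearson and direct correlation

Pearson correlation over a block mixes direct coupling with shared input.
The direct correlation coefficient (DCC) is the maximum-entropy
counterpart for continuous data: the pairwise maximum-entropy distribution
with given first and second moments is Gaussian, and under it the coupling
between two neurons conditional on all others is the partial correlation

$$\mathrm{DCC}_{ij} = -\,\frac{P_{ij}}{\sqrt{P_{ii}P_{jj}}},\qquad
P = \hat\Sigma_\lambda^{-1},$$

with $\hat\Sigma_\lambda = (1-\lambda)\hat\Sigma + \lambda\,
\mathrm{diag}(\hat\Sigma)$ a shrunk sample covariance (`dcc_matrix()`).
The shrinkage weight $\lambda$ (default 0.05) exists purely for
conditioning when frames are not abundant relative to neurons; at
$\lambda = 1$ the precision is diagonal and every DCC is zero.  Two
numerical notes: the estimate is exactly invariant to per-neuron affine
rescaling of the traces, and shrinkage introduces a small systematic
partial correlation between conditionally independent pairs (it perturbs
the Markov factorisation of the covariance), so analyses on very small,
well-conditioned problems — such as the three-neuron chain validation —
use $\lambda = 0$.

Strong pairs are those whose connectivity strictly exceeds the mean plus
twice the SD of the off-diagonal values in scope (`strong_pairs()`); for
DCC the rule is applied to magnitudes, since the experimental convention
summarises direct connectivity unsigned while the signed values are kept
in the pair records.  Scopes are within-layer or cross-layer
(`scope_mask()`).  Proximity bias is summarised as
$\mathrm{DCC}_{100}/\mathrm{DCC}_{200}$: mean $|$DCC$|$ of pairs closer
than 100 um over mean $|$DCC$|$ of pairs between 100 and 200 um
(`proximity_ratio()`), with distances from centroid separation times the
pixel size.

# Cross-day registration and persistence

Each session's neuron map is rendered as a sum of Gaussian peaks (height
1.0, SD 5 px — about a neuron radius) on a 512 x 512 grid
(`render_roi_image()`).  The day-1 image is padded by the search
half-width WS = 40 px on each side and the Pearson correlation with the
later day's image is evaluated at every integer offset in $[-40, 40]^2$,
an 81 x 81 score matrix (`find_shift()`); the argmax is the field shift,
with ties broken toward the smallest shift magnitude.  A well-aligned pair
produces a sparse score matrix with one sharp peak; the peak score is
returned for quality control.  The search is implemented by FFT
cross-correlation, so a full 81 x 81 sweep costs three FFTs rather than
6,561 explicit correlations.

Identities are then matched by shift-correcting the later day's centroids
and greedily pairing each reference neuron with the nearest candidate
within 5 px (inclusive), each candidate used at most once, closest first
(`match_neurons()`).  Day 1 is the reference for all later days
(`track_across_days()`).  Sub-pixel shifts and rotations are out of scope;
shifts are integer pixels.

For persistence, each day's DCC matrix over the tracked neurons is
thresholded by the same mean + 2 SD rule on $|$DCC$|$
(`detected_pairs_per_day()`); for every pair ever detected, the number of
detection days is histogrammed over 1..n\_days and normalised
(`persistence_histogram()`).  The shape of that distribution is summarised
by its Fisher (excess) kurtosis, treating the histogram as a weighted
sample (`histogram_kurtosis()`); the kurtosis convention is recorded
because the experimental literature does not state one.  A uniform
histogram over 12 day-counts gives the discrete-uniform value
$-\tfrac{6}{5}\,\frac{n^2+1}{n^2-1} \approx -1.217$.  Under independent
per-day detection with probability $p$ the histogram is
Binomial($n_{days}, p$) conditioned on at least one detection — a
calibration property the tests verify.  Group-level comparisons of
kurtosis across animals are left to external statistics; the package
supplies the per-animal values.

# The synthetic generators

The generators emulate the statistical structure the analyses rely on, not
microscope movies or biophysics.

**Paw trajectories** (`gen_paw_trajectories()`): within each running block
the horizontal trace is a sine (one cycle per stride; phase chosen so each
block begins at a trough, making every planted stride detectable) and the
vertical trace is the positive lobe of the matching cosine, so the
vertical spike peaks mid-rise.  The right paw is phase-shifted by
$\arccos(-c)$, which makes the expected coordination index equal the
requested $c$ exactly over whole cycles ($c = 1$ is exact anti-phase).
Gaussian noise is added in mm before conversion to raw pixels.

**Coupled networks** (`gen_network_traces()`): latent activity is a
stationary zero-mean Gaussian whose covariance encodes the coupling graph.
For acyclic graphs the couplings are the adjacent marginal correlations
and the covariance is the Markov-tree correlation matrix (path products),
which makes non-adjacent partial correlations exactly zero and gives the
three-neuron chain its closed form: adjacent Pearson 0.8, end-to-end
Pearson $0.8^2 = 0.64$, end-to-end partial correlation 0.  A precision
matrix $I - C$ with couplings 0.8 on a chain is not positive definite, so
the precision construction is reserved for cyclic graphs, where $I - C$ is
eigenvalue-shifted and renormalised — the zero pattern, and hence planted
edge recovery, is preserved at a reduced coupling magnitude.  The latent
draw is convolved with a variance-normalised exponential kernel (default
$\tau = 0.6$ s, a typical GCaMP6m decay scale) and observation noise is
added; the kernel acts identically on all neurons, so cross-neuron
correlation structure is untouched, though temporal autocorrelation
reduces the effective sample size of downstream correlation estimates by
roughly $(1+a^2)/(1-a^2)$ with $a = e^{-1/(\tau f)}$.

**Transition responders** (`gen_transition_responders()`): Bernoulli
events per frame at a baseline rate (default 0.1 events/s, the order of
magnitude of the quiet-state cortical rates in this preparation), scaled
by the gain inside the 15-s post-transition windows for responders, then
kernel-convolved with unit amplitude.  The experimental literature gives
no distributional description of dF/F noise, so the noise level is an
explicit parameter (`noise_sd`, default 0.05) rather than an assertion
about the real data.

**ROI sessions** (`gen_roi_sessions()`): day-1 centroids uniform with
2-px minimum spacing away from the borders; later days add a planted
integer shift, per-neuron jitter uniform in $[-j, j]$ per axis (bounded,
so jitter within the matching tolerance guarantees a candidate within
tolerance), and independent dropout.  Dropout spares day 1 because day 1
is the registration reference.  Per-day ids are shuffled so identity is
only recoverable through matching.

What passing tests on these generators shows — and what it does not: the
pipeline recovers planted structure under Gaussian noise, rigid integer
shifts, and stationary rates.  Real recordings add slow drift, non-rigid
deformation, neuropil contamination and nonstationary behaviour-locked
activity, none of which the generators emulate; conclusions about those
failure modes require real data.

# Problem sizes and reproducibility

The validation suite runs at desk scale, chosen to keep Monte-Carlo error
well inside each tolerance: networks of 50 neurons and 4000 frames for
edge recovery (ten seeds), 2000 null neurons at 1000 shuffles for the
permutation calibration (the package default remains 5000 shuffles),
twenty planted shifts for registration, and 20 seeds for stochastic
kinematics properties.  `run_pipeline()` fans a single master seed out to
the stages as `seed + 1000 * stage_index`, so any stage can be rerun in
isolation and an identical configuration reproduces every table
byte-for-byte; the run manifest records parameters, seed and package
version.

# Known limitations

Only rigid integer field shifts are corrected; rotation, scaling and
non-rigid deformation are out of scope.  The event detector is a
threshold rule, not deconvolution, and reports onsets rather than spike
counts.  The DCC is an undirected, zero-lag quantity: it excludes
indirect paths among recorded neurons but cannot distinguish direct
coupling from shared input that arrives from outside the recorded
population.  The permutation null assumes the trace is stationary at the
scale of the window placement; strongly drifting baselines should be
detrended first.
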