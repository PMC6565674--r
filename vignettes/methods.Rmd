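---
title: "Connectivity-fingerprint polytherapy screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-fingerprint polytherapy screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcscreen)
```

# The analysis model

`fcscreen` treats a drug screen as a network-correction problem. A brain in
a genetic epilepsy model (here an *scn1lab*-deficient zebrafish larva) shows
abnormal temporal correlation between the activity of its anatomical areas.
A compound's effect is summarized as a *connectivity fingerprint*: for every
pair of atlas areas and every stimulus-defined activity state, the mean
absolute Pearson correlation between the ΔF/F traces of the active
supervoxels of the two areas. With the 11-region atlas and the three-state
imaging protocol this is a 165-dimensional vector (55 pairs × 3 states).
Fingerprints of treated mutants are z-normalized metric-wise across all
conditions, clustered hierarchically, and complementary hits are chosen by
iterative cluster elimination. Candidate combinations are then scored
independently for seizure-suppression efficacy (LFP recordings) and
behavioral side effects (locomotor tracking).

The pipeline assumes recordings are already registered to the atlas
(registration is out of scope), that raw intensities are non-negative, and
that the pre-stimulus period is long enough to characterize resting
activity (defaults below).

## Voxel processing

* **Time-averaged signal.** Each voxel's activity statistic is
  `sqrt(sum((f - f0)^2)/(T - 1))` — the sample standard deviation of its
  intensity trace, computed over the pre-stimulus window. A voxel is
  dropped as non-time-varying when its statistic is at least one SD below
  the mean of its z-slice. The rule only trims the dim lower tail of a
  slice; it deliberately keeps everything in a degenerate all-constant
  slice (the cutoff is then exactly the common value, and discarding an
  entire slice on a boundary case would be indefensible).
* **Supervoxels.** Within each slice, 8-connected neighborhoods of retained
  voxels are clustered by k-means on standardized traces (time-subsampled
  to at most 400 frames) plus weakly weighted spatial coordinates
  (`spatial_weight = 0.2`). The number of clusters is chosen per
  neighborhood by time-wise cross-validation (3 folds): held-out frames of
  each voxel are reconstructed from the jackknifed cluster mean (the voxel
  itself excluded), and singleton clusters are scored against a zero
  prediction, so merging wins only when voxels genuinely co-vary (pairwise
  correlation above ~0.5). Ties in the CV error go to the smallest k; the
  final fit uses 10 restarts under a fixed seed. Clusters are split into
  spatially connected components so every supervoxel is contiguous.
* **ΔF/F.** `(f(t) - F(t))/F(t)` with `F(t)` a centered 20-s sliding mean
  of exactly `20 * rate` frames, shrinking at the edges. Alignment of the
  window was an open choice; centering keeps transients symmetric around
  their onset.
* **Active supervoxels.** A supervoxel is active when its maximal resting
  ΔF/F exceeds `median + c * 1.4826 * MAD` of its resting ΔF/F. The
  default is `c = 5`: over resting windows of several thousand frames the
  maximum of pure Gaussian noise routinely reaches 3–4.5 robust SDs, so a
  3-SD rule would flag noise wholesale, while genuine sparse calcium
  transients exceed the threshold many-fold. The multiplier is exposed for
  shorter windows.

## Connectivity and fingerprints

States are half-open intervals in seconds: resting `[0, first stimulus)`,
early `[t_k + 10, t_k + 60)` (the first 10 s after each stimulus are
discarded for stationarity) and late `[t_k + 60, t_k + 120)`. Early/late
windows across the stimuli of one recording are concatenated before
correlation — the fingerprint has exactly one slot per state. Correlations
use ΔF/F of active supervoxels only; ΔF/F was chosen over raw intensity for
scale invariance. A state contributing fewer than 100 frames, or an area
with no active supervoxel, yields a missing metric; missing metrics are
excluded from group averages and mean-imputed (with a message) before
normalization and clustering.

Significance of wild-type resting connectivity is assessed per pair by an
unpaired two-tailed t-test of per-larva observed mean |r| against a
chance-level sample from the same larvae in which the second area's traces
are circularly time-shifted (one region-wide offset per larva, preserving
autocorrelation and within-area structure while destroying inter-area
synchrony). The original description names the t-test but not the
comparison sample; the circular-shift surrogate is this package's choice.
Jarque–Bera normality is checked on both samples with a warning on
rejection. Divergence maps report `mean(treated) − mean(wild-type)` per
pair with the same test, labelling pairs "no change" at `p >= 0.05`.

## Clustering and selection

Normalized fingerprints are clustered on Euclidean distances with Ward
linkage (`ward.D2`). The flat cut maximizes the *relative* merge-height gap
`h[k-1]/h[k]` subject to a minimum cluster count — the ratio form is
scale-free and finds the boundary between between-group and within-group
merges instead of always preferring the single widest split at the top of
the tree. The reference cluster is the one holding the untreated wild-type
rows (majority vote with a warning if they split).

Selection repeats per round: re-cluster the remaining compound rows with
the fixed reference (and context) rows; among clusters holding at least one
selectable compound, take the one whose centroid is nearest the reference
centroid; inside it select the compound row with minimal distance to the
reference centroid; eliminate the cluster's compounds; repeat.
"Nearest cluster" is centroid-to-centroid Euclidean distance (the source
procedure names no definition); ties break lexicographically by row label,
so results are deterministic and invariant to row order. Untreated rows
(wild-type or mutant) are context only and never selectable.

## Stationarity QA

For a trace pair, the sliding-window correlation (SWC; 30-s windows stepped
by 1 s — the step was unstated and is configurable) is summarized by its
sample variance `kappa`. The null distribution of `kappa` under *static*
connectivity is built at the trace level: an AR(2) model is fitted to each
trace by Yule–Walker, surrogate pairs are simulated with innovations
correlated to match the observed overall Pearson r (Gaussian innovations
with matched variance by default; residual resampling available), windowed
identically, and `kappa` recomputed. The one-sided p-value is the fraction
of surrogate kappas at or above the observed one; `p < alpha` is declared
dynamic, matching the principle that an excessive `kappa` relative to the
null indicates non-stationary coupling.

Fitting the AR(2) to the SWC series itself — a literal alternative reading —
is degenerate: Yule–Walker reproduces the observed series variance exactly,
so the observed `kappa` always sits at the centre of its own surrogate
distribution, and the test has neither size nor power. The trace-level
static null is the standard construction in the dynamic-connectivity
literature and is what ships here. An optional block-bootstrap mode
(5-minute blocks reassembled from 30-s windows) can be applied to the SWC
series before `kappa`; it is off by default.

Subgroup stability splits each area's active supervoxels into random
halves (50 repetitions), recomputes the inter-area mean |r| per
half-pairing, and reports the signed differences plus a one-sample t-test
against zero mean. Because random equal splits are exchangeable, the
signed differences are mean-zero by construction for any area composition;
heterogeneous areas reveal themselves through the *dispersion* of the
differences, which is what the package's property tests examine. The
t-test is retained as the shipped summary; its p-values stay uniform for
well-sampled areas, which is the practical QA criterion (small p-values
would indicate a bookkeeping problem, not biology).

## LFP analysis

EMD uses standard sifting: cubic-spline envelopes through local maxima and
minima with up to two boundary extrema mirrored at each end, stopping a
sift when the mean-envelope energy falls below 0.05 of the component
energy (at most 15 sifts), and stopping the decomposition when the residual
has fewer than two maxima or minima. The residual is the exact remainder,
so reconstruction is exact by construction.

Detection cuts the robustly variance-normalized trace (divided by its MAD,
making calls amplitude-invariant) into 2-s segments with 50% overlap;
each segment contributes variance, skewness and excess kurtosis of its
first 4 IMFs (absent IMFs contribute zeros). A linear discriminant is
trained on labeled segments; variance features are log-transformed first
because bursts scale IMF variance multiplicatively over orders of
magnitude, which a pooled-covariance discriminant cannot separate on a
linear scale. Consecutive positive segments merge into events, and events
spanning fewer than two segments are discarded — a genuine burst of the
default 3-s duration always covers at least two overlapping segments,
while isolated single-segment positives are almost always noise. Event
frequency is reported per 45-minute interval. The efficacy score is
`1 − post/baseline` frequency — the unique linear map through the two
anchors (0 for unchanged, 1 for seizure-free); negative values (worsening)
are reported as-is with a flag, and larvae without baseline seizures are
excluded by an explicit error.

## Behavioral analysis

The tracker thins each binary silhouette (Zhang–Suen, restricted to the
silhouette bounding box), takes the longest end-to-end path across the
skeleton graph (pruning side spurs), smooths it lightly, re-anchors both
tips at the mid-line terminus one local body radius short of the silhouette
boundary (thinning erodes tips by about the local radius), and places five
points at arc-length quantiles {0, ¼, ½, ¾, 1}. Because body length is
constant, per-frame length estimates are smoothed over time before
quantile placement, suppressing along-axis jitter; each point is finally
re-centered in the body cross-section perpendicular to the local path. The
head is the end with larger local silhouette mass, with continuity to the
previous frame breaking near-ties. Blank frames or degenerate skeletons are
flagged missing.

The six features: forward velocity (signed mean of the anterior-midpoint
displacement projected on the body centerline defined by the two anterior
points), mean |perpendicular velocity| and SD of the signed perpendicular
series, percent time above `FV_mean + FV_STD` (computed on a 7-frame
smoothed forward-speed series so the exceedance fraction is robust to
single-frame jitter; defined as 0 when the SD is 0), and the summed
absolute tail-vertex angles relative to the body centerline (mean, and mean
absolute frame-to-frame change). The side-effect score takes each
feature's absolute fractional deviation of the treated group mean from the
untreated baseline mean (absolute difference when a baseline mean is zero)
and returns the RMS of the six divergences; its SD comes from per-larva
scores computed the same way.

# The synthetic-data generator

The generator emulates what the analysis assumes, with recoverable ground
truth:

* **Atlas**: an ellipsoidal brain mask tiled by anisotropy-aware Voronoi
  regions grown from farthest-point seeds — connected, non-empty,
  deterministic. Default 8 z-slices of 64×64 voxels at (40, 10, 10) µm,
  11 regions with the canonical names.
* **Calcium recordings**: each neuron (a small voxel block placed wholly
  inside its region) fires a Poisson spike train that mixes *shared
  per-area-pair event streams* (rate `rho * spike_rate`) with private
  events (rate `(1 − sum(rho)) * spike_rate`), so the cross-area
  spike-count correlation equals the planted `rho` exactly and every
  neuron keeps total rate `spike_rate`. Mixing rates switch at the state
  boundaries; a planted structure is rejected with an explicit bound when
  an area's pair loadings sum above 1. Spikes are convolved with a
  single-exponential kernel (1-frame rise, `tau_decay = 1.5` s — indicator
  kinetics are a configurable assumption) and rendered at 20 Hz with
  additive Gaussian noise (`noise_sd = 2` on a baseline of 100,
  `signal_amp = 20`, i.e. ~0.2 ΔF/F per event). The default
  `spike_rate = 0.15` events/s gives sparse, realistic transients whose
  max/MAD ratio cleanly exceeds the activity threshold while tissue noise
  does not. Mutants get a stimulus-locked multiplicative rate surge
  (5-fold, 5-s decay) on all neurons.
* **LFP**: 1/f-like background (AR(1), phi = 0.98, unit SD) plus bursts at
  Poisson or fixed times — an 8-Hz oscillation with superimposed sharp
  spikes under a rapid-onset sustained envelope, amplitude `snr = 6` times
  the background — matching the morphology of photosensitive seizure
  bursts (high-amplitude peaks persisting for seconds).
* **Behavior**: a five-segment larva rendered as tapered discs follows a
  motion program (forward speed with optional sinusoidal modulation,
  heading drift, per-segment tail bend at a tail-beat frequency, and the
  lateral body slip that accompanies beating). The exact vertex points are
  returned for tracker validation; a trajectory that cannot fit the frame
  is an explicit error, and with no start point the trajectory is centred
  deterministically.

What it does **not** emulate: optics (light-sheet point-spread, scattering,
bleaching), motion or registration error, inter-neuron kinetic diversity,
non-Poisson burst statistics within a state, electrode drift, or
multi-larva occlusion. Passing tests therefore demonstrate correctness of
the analysis chain on data satisfying its statistical assumptions, not
robustness to those nuisances.

# Numerical choices and problem sizes

All windows are half-open `[start, end)` in seconds. A single integer seed
fans out to per-stage substreams (`substream_seed`), making every pipeline
product bit-reproducible. k-means ties break by CV error then smallest k;
cluster and compound ties break lexicographically.

The test and acceptance studies run at desk scale, chosen once: planted
connectivity recovery uses a 4-region 4×14×14 atlas, two stimuli and 360-s
recordings over 20 seeds (fingerprint-vs-planted Pearson correlation
averaged over seeds); selection correctness uses 6-compound planted
3-cluster screens over 20 seeds against an exhaustive label-aware oracle;
stationarity size uses 500 AR(2) trace pairs at 10 Hz, 300 s, 99
surrogates; detector performance uses 20 independent 600-s LFP traces; and
tracker accuracy uses ten 12-s circling swim programs with per-feature
errors averaged over the replicates (single replicates carry ±1-frame
discreteness in the high-velocity time fraction). The full end-to-end
screen (`run_screen`) runs in well under a minute at its smoke-test
configuration.

# Known limitations

* The weak per-slice voxel filter cannot remove a majority background; the
  activity threshold carries that burden, which is why its default is
  calibrated for multi-thousand-frame resting windows.
* At very sparse event rates the sliding-window correlation of a genuinely
  static pair is event-driven and the stationarity test reports dynamics —
  a property of the data, not a bug; denser activity tests stationary.
* The supervoxel CV criterion favours merging only above ~0.5 pairwise
  correlation; dimmer duplicated somata may remain split (conservative for
  correlation estimates, which average over supervoxel pairs).
* The seizure classifier is trained on the synthetic burst morphology;
  applying it to real LFP requires retraining on labeled recordings via
  `train_seizure_classifier`.
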