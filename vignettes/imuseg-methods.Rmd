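---
title: "Methods: unsupervised decomposition of head-borne inertial recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised decomposition of head-borne inertial recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuseg)
```

## The problem

A head-mounted inertial measurement unit (IMU) on a freely moving rodent
streams two 3-axis signals: acceleration **a** (in g) and angular velocity
**omega** (in deg/s), in a head-fixed frame (x fore-aft, y interaural,
z head-vertical). Behavior expresses itself in these signals as a
succession of short, statistically homogeneous motifs — locomotion bouts,
sniffing, orienting head movements, grooming strokes, rest. `imuseg` turns
the raw streams into (1) a segmentation into such motifs, (2) a catalog of
candidate behavioral clusters, (3) a sequence model over the motif stream,
and (4) per-segment kinematic metrics and an anomaly score against a
reference repertoire — all without any supervision or video.

## Preprocessing: gravity and attitude

Measured acceleration mixes gravity with the animal's own movement. A
quaternion error-state extended Kalman filter integrates the gyroscope
(exact per-sample axis-angle steps) and corrects the tilt drift with the
accelerometer's direction, gated to samples whose norm lies in
[0.5, 1.5] g so that impacts and shakes do not corrupt the estimate. Its two
knobs are exposed with their validated defaults: `var_acc = 0.002` (g^2,
measurement noise) and `var_gyr = 0.75` ((deg/s)^2 per unit bandwidth,
process noise). The filter yields per sample:

* `aG` — gravity in the head frame (head tilt; the conjugate attitude
  rotation applied to the Earth vertical),
* `anG = a - aG` — movement-generated acceleration (exact by construction),
* `heading` and `azimuth` — the head x-axis in the Earth frame and its
  unwrapped horizontal angle (initialized at 0; gravity observations cannot
  anchor yaw, so azimuth is only meaningful relatively).

On noise-free piecewise-constant rotations the tilt error stays below 2
degrees after a one-second burn-in; this is the accuracy contract the test
suite enforces, and any attitude filter meeting it would be interchangeable
here.

Sensor offsets, when static calibration data exist, are estimated by
nonlinear least squares on `||a - b|| - 1` over immobile samples
(accelerometer) and by the per-axis median (gyroscope); with no calibration
the offsets default to zero.

## Segmentation: Gaussian-kernel PELT

The series handed to change-point detection is the six-channel, per-session
z-scored `[aG, omega]` (non-gravitational acceleration is deliberately left
out: its within-motif variability is high relative to the between-motif
structure). The cost of a segment is its within-segment scatter in the
feature space of a Gaussian RBF kernel,
`c(s, t) = l - (1/l) * sum k(x_i, x_j)`; because the kernel is
characteristic, a change in any aspect of the sample distribution — mean,
variance, oscillation structure — raises the cost of spanning it. The
segmentation minimizes total cost plus `lambda` per change point, solved
exactly by a PELT-pruned dynamic program (implemented in C++; ties go to
the earliest boundary, so the result is fully deterministic). An exhaustive
O(n^2) dynamic program written independently in the test helpers is the
correctness oracle; the two agree, boundary for boundary and in objective,
on every random instance tried.

Parameters, with defaults and rationale:

* `penalty` (lambda): 14 — the rat-data operating point; 9 for the
  mouse-style 200 Hz configuration. The mapping from lambda to median
  segment duration depends on the data's texture, so
  `calibrate_penalty()` performs a monotone bisection toward a target
  median duration (the canonical target is 0.35 s, the time scale of the
  finest motifs a human labeler recognizes). On the synthetic corpus, which
  is smoother than animal data, the calibrated lambda lands near 2.7.
* `bandwidth` (gamma): median heuristic, `1/(2 m^2)` with `m` the median
  pairwise distance over an evenly spaced subsample of 2000 points. The
  subsample is deterministic rather than random so that the segmentation
  module contains no RNG at all.
* `min_size`: 30 ms worth of samples — below any motif of interest, only
  there to forbid degenerate slivers.

`parallel_cpd()` runs the same optimizer on non-overlapping windows
(five minutes by default) with one shared bandwidth; window edges become
forced boundaries. On the synthetic corpus the windowed and full-recording
segmentations agree with an adjusted Rand index above 0.99, which is what
makes the linear-time windowed path a safe default for long sessions.
`fixed_windows()` provides the 700 ms fixed-length baseline, and
`ablate_immobility()` implements both the threshold rule (12 deg/s on the
angular-speed SD) for fixed windows and the duration-matched greedy removal
for variable-length segments, so the two segmentation strategies can be
compared on equal footing.

## Per-segment features

`extract_features()` computes exactly 240 named features per segment in
four families: 12 statistics x 11 channels (the nine axes plus `||anG||`
and `||omega||`); 36 pairwise axis correlations; 12 tilt/heading
descriptors (von Mises-Fisher mean tilt and its roll/pitch, dispersion,
net rotation angle and speed, net azimuthal speed, heading change rate,
azimuth range, duration); and 60 wavelet summaries. The wavelet family
comes from a complex Morlet transform (center frequency `omega0 = 6`,
1-20 Hz in 0.5 Hz steps) computed over the *whole recording* and sliced
per segment — computing it per segment would smear the violent 16-20 Hz
signature of wet-dog shakes into neighbors through edge effects and would
leave short segments unanalyzable at low frequencies. Band powers
(< 6 Hz, 8.5-11 Hz, > 14 Hz, full range) enter the catalog as log10 of the
maximal time-median power; the logarithm matters because raw band powers
span six orders of magnitude across behaviors, which would otherwise let a
handful of heavy-tailed features dominate both the outlier rule and the
z-scored PCA space. Two statistics choices follow the same logic: a
zero-crossing rate replaces excess kurtosis, and quartiles use linear
interpolation (type 7) throughout.

Outlier handling follows the canonical rules: a segment is an
outlier if any robustly rescaled feature (median/IQR) exceeds 35 in
absolute value; a wet-dog shake (WDS) is a segment whose peak `||anG||`
exceeds 2 g *and* peak `||omega||` exceeds 1000 deg/s, and both temporal
neighbors of a WDS are excluded alongside it. On the synthetic corpus at
the calibrated penalty these rules exclude about 8% of segments —
immobility-edge slivers, steering transients and the planted shakes — and
the suite asserts the fraction stays below 10%.

## Clustering: cross-validated PCA + BIC-selected Gaussian mixture

Non-excluded feature rows are z-scored (training statistics only, so a
reference group's scaler can be applied to other groups), projected onto
principal components, and modeled as a Gaussian mixture. The number of
components (5-100 in the full grid) and the covariance structure (full,
diagonal, tied, spherical) are selected by maximizing
`BIC = 2 lnL - p ln m`; the free-parameter counts per structure are spelled
out in `gmm_param_count()` and tested. EM itself is delegated to mclust
(structures VVV/VVI/EEE/VII respectively, identical parameter counts and
BIC convention); mclust's model-based hierarchical initialization is
deterministic, which is why repeated runs of the whole pipeline are
byte-identical. Posterior responsibilities, hard assignment, the top-q
most representative segments per cluster, sparse-cluster detection (the
`top_n = 3` components with the largest covariance trace) and all
likelihood scoring are computed from the stored mixture parameters by this
package's own code.

The PCA dimensionality is chosen by Wold-style element-wise
cross-validation: matrix entries are partitioned into folds, held-out
entries are imputed by iterated rank-q SVD reconstruction, and the squared
error on the held-out entries is minimized over the candidate grid. On a
planted rank-3 matrix the procedure selects 3 with the expected U-shaped
error curve; on pure noise it collapses to the grid minimum. Rows are
subsampled (seeded) beyond 2000 to bound the SVD cost.

`susm()` implements the cross-likelihood anomaly score: the mean mixture
log-density of a group's segments under a reference model fitted on
healthy animals. For the reference animals themselves a leave-one-out
refit (same component count, covariance structure and dimensionality)
removes in-sample optimism; the suite checks that the in-sample score sits
inside the Monte-Carlo band of the model's expected log-density, that a
+10 SD translation strictly lowers the score, and that LOO is not
optimistic on average.

## Sequence model: post-hoc categorical HMM

The cluster sequence (one symbol per segment, excluded segments collapsed
into one OUTLIER symbol) is modeled by a categorical hidden Markov model
fitted by Baum-Welch with per-step scaling: emissions start from perturbed
empirical symbol frequencies, transitions from a sticky-diagonal (0.6)
near-uniform matrix, ten seeded restarts by default, convergence at a
relative log-likelihood change of 1e-4 (500 iterations cap). The state
count is selected by maximizing `2 lnL - p ln T` with
`p = (S-1) + S(S-1) + S(M-1)`. Forward-backward smoothing, Viterbi
decoding, cluster-by-state splitting (which resolves clusters used in two
sequence contexts) and empirical transition summaries are all exposed; the
smoothed posteriors are verified against brute-force path enumeration for
short sequences, and the log-likelihood path is asserted non-decreasing.

## Metrics

* `vmf_tilt()`: average head tilt as the renormalized mean of the
  per-sample gravity directions (the von Mises-Fisher mean-direction MLE;
  the concentration parameter is never needed), with
  `roll = -atan2(mu_y, mu_z)` and
  `pitch = -atan2(-mu_x, sqrt(mu_y^2 + mu_z^2))`, in degrees.
* `net_angular_speed()`: geodesic angle of the start-to-finish relative
  attitude quaternion, divided by duration.
* `sniffing_score()`: the band-power ratio Phi described in its help page,
  with numerator bands at 8.5-11 Hz on fore-aft acceleration and pitch
  velocity, off-band and cross-channel terms plus the constant 100 in the
  denominator (the constant is unit-bound: g^2 and (deg/s)^2), and the
  penalty `alpha = 1/(1+eta) * 1/(1+|roll in radians|)`. Band powers are
  maxima over band frequencies of the per-segment time-median wavelet
  power, so Phi is exactly reproducible from a feature-table row.
* `turns_per_minute()`: net unwrapped azimuth change per minute divided by
  360, signed by a per-animal convention flag. This interprets the cited
  rotation quantification as net heading turning; a cycle-counting variant
  would differ only on pathological back-and-forth traces.
* `purity()`: modal-category fraction of a labeled segment set.

## The synthetic generator

`generate_imu()` emits recordings from scripted regime sequences. Regimes
are additive signal models — not biomechanics — designed to exercise every
pipeline branch: immobility (tiny sway, `anG = 0` so noise-free rest has
`||a|| = 1` g exactly); locomotion (5-7 Hz head-vertical sawtooth, pitch
bob, slow yaw meander, slight nose-down carriage); sniffing-locomotion
(~10 Hz tone on fore-aft acceleration and pitch velocity, head pitched
down, heading comparatively held); orienting (single 30-50 degree
reorientation in 100-300 ms with a raised-cosine rate profile); grooming
(~4 Hz rhythm under a large roll offset); and wet-dog shakes (16-20 Hz,
exceeding 2 g and 1000 deg/s by construction). Body rates are integrated
exactly into the planted attitude, so gravity is always consistent with
the planted orientation; regime-specific mean tilts are reached through an
80 ms steering rotation centered on the regime boundary, emulating the
head adjustment that accompanies a behavioral switch and keeping every
planted boundary within the +/-50 ms matching tolerance of a detectable
contrast. All active regimes carry broadband tremor, fast jitter and slow
postural drift on every axis (a living head never sits at the sensor noise
floor); sensor noise defaults to 0.01 g and 1 deg/s per axis. Everything is
driven by one seed.

What the generator does *not* emulate: biomechanical coupling between
axes, gait-phase-locked accelerations, arena geometry, posture-dependent
sensor placement errors, or the long-tailed duration statistics of real
behavior. Passing tests therefore demonstrate the *machinery* — boundary
recovery, model selection, score separation — under honest noise, not
field performance on animal data.

`default_corpus()` is the standard test bed: 30 minutes at 300 Hz,
~750 scripted entries with no immediate regime repetitions (so every
boundary is a real contrast), WDS kept rare (4% of entries). Corpus-level
checks in the suite run at two operating points: boundary recovery at the
calibrated penalty (350 ms target median), and the end-to-end
clustering/HMM run at the default `lambda = 14`, where segments align with
whole motifs. Scaled-down grids are used for the corpus-scale fits (PCA
grid {5, 10, 20}; K in 5-15 over full+diagonal; HMM states 2-6 with 5
restarts; penalty calibration on the first five minutes); these sizes were
chosen once as adequate for a corpus of ~2000-4000 segments and 5-6
planted motif classes.

## Visualization

`lambert_project()` maps unit vectors to the plane about the North or
South pole with `rho = 2 sin(theta/2)` — the equal-area property (checked
analytically at three colatitudes) means density on the map is density on
the sphere. `trajectory_overlay()` pairs, per segment, the tilt trajectory
(gravity in the head frame) with the heading trajectory rotated about the
Earth vertical so every segment starts at azimuth 0. `rgb_overlay()` bins
up to three groups of 2-D points on a shared 500x500 grid, normalizes each
histogram by its 99.8th percentile (clipped at 1) and writes the groups
into the red/green/blue channels. Two-dimensional embedding itself is a
pluggable hook (`embed_hook()`): it is visualization only, the built-in
backend is a PCA projection, and an external UMAP backend can be
registered with the reference parameters (`n_neighbors = 8`,
`target_weight = 1e-9`, `min_dist = 1e-3`) recorded in the call.

## Numerical choices and degenerate inputs

* Kernel-cost ties in the dynamic program break toward the earliest
  boundary; series shorter than twice `min_size` return one segment.
* Constant features rescale to 0 (with a warning) in the outlier rule;
  zero-variance columns pass through the z-scorer unscaled.
* Singular mixture covariances are floored at 1e-6 on the diagonal when a
  log-density is evaluated.
* Azimuth unwrapping removes only full +/-360 wraps; genuine fast turns are
  preserved.
* Antipodal tilt averages (zero resultant) and empty segments raise typed
  errors rather than returning NaN.
* The accelerometer update of the attitude filter is skipped whenever
  `||a||` leaves [0.5, 1.5] g, so free-fall-like and impact samples cannot
  drag the tilt.

## Known limitations

* The feature catalog is this package's own 240-entry design; it
  implements the three canonical families (statistics, tilt/heading,
  wavelet), but a different catalog of the same size could only be matched
  up to the family definitions exposed in `feature_spec()`.
* The EM backend's deterministic initialization removes restart-to-restart
  variance but can, like any EM, settle in local optima on pathological
  geometries; the planted-mixture recovery tests bound this risk only for
  separated clusters.
* SUSM compares repertoires through a fixed reference projection; a
  genuinely novel behavior that projects onto the reference PCs like a
  known one will not register as anomalous.
* Azimuth (and therefore turning metrics) drifts with gyroscope bias over
  long sessions when no static calibration is available.
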