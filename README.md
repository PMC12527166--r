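# imuseg

Unsupervised decomposition of head-borne inertial recordings of freely
moving rodents into behavioral motifs.

A head-mounted IMU streams 3-axis acceleration **a** (g) and angular
velocity **ω** (deg/s) in a head-fixed frame. `imuseg` turns those two
streams into an interpretable behavioral readout with no video and no
labels:

1. **Gravity decomposition** — a quaternion error-state extended Kalman
   filter (gyro-driven process, accelerometer gravity update; knobs
   `var_acc = 0.002`, `var_gyr = 0.75`) splits acceleration into the
   gravitational component `aG` (head tilt) and the movement component
   `anG = a − aG`, and tracks heading/azimuth.
2. **Segmentation** — penalized change-point detection over the z-scored
   `[aG, ω]` series with a Gaussian-kernel cost
   `c(s,t) = ℓ − (1/ℓ) Σ exp(−γ‖x_i − x_j‖²)`, solved exactly by a
   PELT-pruned dynamic program (C++). Because the kernel is
   characteristic, any change in the signal distribution — not just mean
   shifts — ends a segment. The penalty λ (default 14) can be calibrated
   to a target median segment duration (canonically 0.35 s).
3. **Features** — 240 named per-segment features: signal statistics, axis
   correlations, von Mises–Fisher average tilt (`roll = −atan2(μ_y, μ_z)`,
   `pitch = −atan2(−μ_x, √(μ_y²+μ_z²))`), net rotation/azimuthal speeds,
   and complex-Morlet wavelet band powers (1–20 Hz) sliced from a
   whole-recording transform. Robust outlier flagging (|rescaled| > 35)
   and the wet-dog-shake rule (‖anG‖ > 2 g and ‖ω‖ > 1000 deg/s, plus both
   temporal neighbors) exclude corrupted segments from modeling.
4. **Clustering** — z-scoring, cross-validated PCA, and a Gaussian-mixture
   grid over component count (5–100) and covariance structure
   (full/diagonal/tied/spherical), selected by `BIC = 2 lnL − p ln m`.
   Hard assignments are the candidate motifs; components with the largest
   covariance trace are flagged as sparse clusters.
5. **Sequence model** — a categorical hidden Markov model over the
   motif-symbol sequence (Baum–Welch, BIC-selected state count), with
   smoothed posteriors, Viterbi decoding, and cluster-by-state splitting.
6. **Metrics and anomaly scoring** — sniffing score Φ (an 8.5–11 Hz
   band-power ratio penalized by reorientation rate and roll), turns per
   minute, purity, and the cross-likelihood score of recordings under a
   reference ("healthy") mixture with leave-one-out handling (`susm()`).

A scripted synthetic generator (`generate_imu()`, `default_corpus()`)
emits ground-truth-annotated recordings emulating the canonical regimes —
immobility, 5–7 Hz locomotion, ~10 Hz sniffing, 100–300 ms orienting
turns of 30–50°, ~4 Hz grooming, 16–20 Hz wet-dog shakes — so every stage
is testable end to end.

## Worked example

```r
library(imuseg)

script <- default_corpus(seed = 42, duration_s = 180)   # 3-minute corpus
g   <- generate_imu(script)
g$recording
#> <imu_recording> 54939 samples @ 300 Hz (183.13 s)
#>   meta: source=synthetic, seed=42

kin <- estimate_attitude(g$recording)
seg <- kernel_cpd(cpd_input(kin), cpd_params(penalty = 14), rate_hz = 300)
seg
#> <segmentation> 165 segments over 54939 samples (median duration 837 ms)

tab <- flag_outliers(extract_features(kin, seg))
tab
#> <segment_table> 165 segments x 240 features; 41 excluded (35 outlier, 3 WDS, 6 WDS-neighbor)

model <- fit_cluster_model(tab, n_pc = "cv", pc_grid = c(5, 10, 20),
                           K_range = 2:10, cov_types = c("full", "diagonal"),
                           seed = 1)
model
#> <cluster_model> K = 5 (diagonal covariance), d = 5; BIC = -2341.1
#>   scaler + PCA front end: 240 features -> 5 PCs

asg <- assign_segments(model, tab)
tl  <- truth_labels_for(g$truth, seg)
use <- !tab$flags$excluded & tl$label_purity >= 0.99
adjusted_rand(asg$labels[use], tl$label[use])
#> [1] 1

round(tapply(sniffing_score(tab)$phi, tl$label, median), 3)
#>            groom         immobile       locomotion           orient
#>            0.000            0.014            0.014            0.002
#> sniff_locomotion              wds
#>            0.258            0.000
```

Reading the output: change-point detection cut the 3-minute recording into
165 variable-length segments; the outlier rules excluded 41 (three planted
wet-dog shakes, their neighbors, and extreme-valued transients); BIC chose
5 mixture components, which match the five non-excluded planted regimes
exactly (adjusted Rand index 1), and the sniffing score separates planted
sniffing segments (median Φ ≈ 0.26) from every other behavior by more than
an order of magnitude.

Recordings are read and written as plain CSV (`read_recording()`,
`write_recording()`; header `ax,ay,az,gx,gy,gz` plus `# rate_hz=` and
`# meta:` comment lines). A thin command-line wrapper with `synth`,
`convert` and `run` subcommands is installed at `inst/cli/imuseg`.

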