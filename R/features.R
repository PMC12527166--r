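# features: per-segment feature catalog, robust rescaling, outlier and
# wet-dog-shake flagging, immobility fraction.

#' Feature catalog specification
#'
#' The default catalog has exactly 240 uniquely named features in four
#' families:
#' * signal statistics (12 statistics x 11 channels: the 9 kinematic axes
#'   plus the norms of `anG` and `omega`) = 132,
#' * pairwise correlations among the 9 kinematic axes = 36,
#' * tilt/heading descriptors (von Mises-Fisher average tilt and its
#'   roll/pitch, dispersion, net rotation and speeds, heading change rate,
#'   azimuth range, duration) = 12,
#' * wavelet summaries (6 channels x 4 bands x \{log10 peak band power,
#'   median log-power\} + per-channel peak frequency and peak power) = 60.
#'
#' @param freqs CWT frequency grid in Hz (default 1-20 in 0.5 steps).
#' @param omega0 Morlet center-frequency parameter (default 6).
#' @param version catalog version tag.
#' @return an object of class `feature_spec` with the resolved feature
#'   `names` (length 240 by default).
#' @export
feature_spec <- function(freqs = seq(1, 20, by = 0.5), omega0 = 6,
                         version = "1") {
  stats_ <- c("mean", "median", "sd", "min", "max", "q25", "q75", "iqr",
              "rms", "skew", "zcr", "madiff")
  axes <- c(t(outer(c("aG", "anG", "omega"), c("x", "y", "z"), paste, sep = "_")))
  chans <- c(axes, "anG_norm", "omega_norm")
  pairs <- t(utils::combn(axes, 2))
  bands <- names(cwt_bands())
  wchans <- c("anG_x", "anG_y", "anG_z", "omega_x", "omega_y", "omega_z")
  nm <- c(
    paste0("stat_", rep(stats_, each = length(chans)), "_", chans),
    paste0("corr_", pairs[, 1], "_", pairs[, 2]),
    c("tilt_mu_x", "tilt_mu_y", "tilt_mu_z", "tilt_roll", "tilt_pitch",
      "tilt_dispersion", "head_net_rotation", "head_net_speed",
      "head_net_azimuth_speed", "head_eta", "head_azimuth_range",
      "seg_duration"),
    paste0("cwtpkl_", rep(wchans, each = length(bands)), "_", bands),
    paste0("cwtlog_", rep(wchans, each = length(bands)), "_", bands),
    paste0("cwtpeakf_", wchans),
    paste0("cwtpeakp_", wchans)
  )
  if (anyDuplicated(nm)) stop_value("feature names are not unique")
  structure(list(freqs = freqs, omega0 = omega0, version = version,
                 stats = stats_, channels = chans, axes = axes,
                 wavelet_channels = wchans, names = nm, size = length(nm)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec v%s> %d features; CWT %g-%g Hz (%d freqs), omega0 = %g\n",
              x$version, x$size, min(x$freqs), max(x$freqs), length(x$freqs),
              x$omega0))
  invisible(x)
}

seg_stats <- function(v) {
  m <- mean(v); s <- if (length(v) > 1) sd(v) else 0
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  cm <- v - m
  sk <- if (s > 0) mean(cm^3) / s^3 else 0
  zc <- if (length(v) > 1) mean(diff(sign(cm + (cm == 0))) != 0) else 0
  md <- if (length(v) > 1) mean(abs(diff(v))) else 0
  c(mean = m, median = q[2], sd = s, min = min(v), max = max(v),
    q25 = q[1], q75 = q[3], iqr = q[3] - q[1],
    rms = sqrt(mean(v^2)), skew = sk, zcr = zc, madiff = md)
}

#' Extract the per-segment feature table
#'
#' Computes the full feature catalog (see [feature_spec()]) for every
#' segment, along with the per-segment immobility fraction.  Wavelet
#' features are sliced from a whole-recording CWT so that segment edges do
#' not introduce artifacts.  Deterministic and permutation-equivariant over
#' segments.
#'
#' @param kin a [estimate_attitude()] result covering the segmentation.
#' @param seg a [segmentation()].
#' @param spec a [feature_spec()].
#' @param cwt_med optional precomputed [cwt_segment_medians()] array.
#' @return an object of class `segment_table`: list with `features`
#'   (m x 240 matrix), `bounds` (per-segment start/end/length, 0-based),
#'   `flags` (data.frame with `outlier`, `wet_dog_shake`, `wds_neighbor`,
#'   `excluded` - all `FALSE` until [flag_outliers()] - and
#'   `immobile_fraction`), `rate_hz` and `spec`.
#' @export
extract_features <- function(kin, seg, spec = feature_spec(), cwt_med = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  n <- nrow(kin$aG)
  if (seg$n != n)
    stop_schema("segmentation span (%d) does not match the series (%d)", seg$n, n)
  m <- n_segments(seg)
  bounds <- segment_bounds(seg)
  rate <- kin$rate_hz

  sig <- cbind(kin$aG, kin$anG, kin$omega)
  colnames(sig) <- spec$axes
  sig <- cbind(sig,
               anG_norm = sqrt(rowSums(kin$anG^2)),
               omega_norm = sqrt(rowSums(kin$omega^2)))

  if (is.null(cwt_med))
    cwt_med <- cwt_segment_medians(kin, seg, spec$freqs, spec$omega0,
                                   spec$wavelet_channels)
  bands <- cwt_bands()
  band_masks <- lapply(bands, function(f) f(spec$freqs))

  feats <- matrix(NA_real_, m, spec$size, dimnames = list(NULL, spec$names))
  pair_idx <- t(utils::combn(9L, 2L))  # same order as the corr_* names

  for (k in seq_len(m)) {
    rows <- (bounds$start[k] + 1L):bounds$end[k]
    x <- sig[rows, , drop = FALSE]
    st <- apply(x, 2, seg_stats)                     # nstat x nchan
    # correlations among the 9 kinematic axes (0 where undefined)
    cc <- suppressWarnings(cor(x[, 1:9, drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    # tilt / heading block
    tl <- vmf_tilt(kin$aG[rows, , drop = FALSE])
    nr <- net_angular_speed(kin, bounds$start[k], bounds$end[k])
    az <- kin$azimuth[rows]
    dur <- bounds$length[k] / rate
    eta <- heading_change_rate(kin, bounds$start[k], bounds$end[k])
    tilt_block <- c(tl$mu, tl$roll, tl$pitch, tl$dispersion,
                    nr$angle, nr$speed,
                    (az[length(az)] - az[1]) / dur, eta,
                    diff(range(az)), dur)
    # wavelet block
    med <- cwt_med[k, , ]                            # freq x channel
    pk <- sapply(seq_along(spec$wavelet_channels), function(ci)
      vapply(band_masks, function(msk) log10(max(med[msk, ci]) + 1e-12),
             numeric(1)))
    lg <- sapply(seq_along(spec$wavelet_channels), function(ci)
      vapply(band_masks, function(msk) median(log10(med[msk, ci] + 1e-12)),
             numeric(1)))
    pf <- spec$freqs[apply(med, 2, which.max)]
    pp <- apply(med, 2, max)
    feats[k, ] <- c(t(st), cc[pair_idx],
                    tilt_block, c(pk), c(lg), pf, pp)
  }

  imf <- immobile_fraction(kin, seg)
  flags <- data.frame(outlier = rep(FALSE, m), wet_dog_shake = FALSE,
                      wds_neighbor = FALSE, excluded = FALSE,
                      immobile_fraction = imf)
  structure(list(features = feats, names = spec$names, bounds = bounds,
                 flags = flags, rate_hz = rate, spec = spec),
            class = "segment_table")
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("<segment_table> %d segments x %d features; %d excluded (%d outlier, %d WDS, %d WDS-neighbor)\n",
              nrow(x$features), ncol(x$features), sum(x$flags$excluded),
              sum(x$flags$outlier), sum(x$flags$wet_dog_shake),
              sum(x$flags$wds_neighbor)))
  invisible(x)
}

#' Robust feature rescaling
#'
#' Per-feature median subtraction and division by the interquartile range
#' (quartiles by linear interpolation, type 7), computed over non-excluded
#' segments.  Constant features (IQR = 0) are set to 0 with a warning: they
#' carry no outlier signal.
#'
#' @param table a [extract_features()] result, or a plain feature matrix.
#' @return the rescaled matrix (same shape as the features).
#' @export
robust_rescale <- function(table) {
  x <- if (inherits(table, "segment_table")) table$features else as.matrix(table)
  use <- if (inherits(table, "segment_table")) !table$flags$excluded
  else rep(TRUE, nrow(x))
  if (sum(use) < 4L) stop_value("need at least 4 segments for IQR rescaling")
  med <- apply(x[use, , drop = FALSE], 2, median)
  iqr <- apply(x[use, , drop = FALSE], 2, function(v)
    diff(quantile(v, c(0.25, 0.75), names = FALSE, type = 7)))
  zero <- iqr <= 0
  if (any(zero))
    warning(sprintf("%d constant feature(s) rescaled to 0", sum(zero)))
  iqr[zero] <- Inf
  sweep(sweep(x, 2, med), 2, iqr, "/")
}

#' Flag outlier and wet-dog-shake segments
#'
#' A segment is an outlier when any robustly rescaled feature exceeds
#' `rescale_threshold` in absolute value.  A wet-dog shake (WDS) is a
#' segment whose maximal `||anG||` exceeds `wds_acc` *and* maximal
#' `||omega||` exceeds `wds_gyr`; its two temporal neighbors are flagged as
#' `wds_neighbor` because the 16-20 Hz WDS signature contaminates them
#' through wavelet edge effects.  `excluded` (dropped from clustering) is
#' the union of the three flags.
#'
#' @param table a [extract_features()] result.
#' @param rescale_threshold threshold on absolute rescaled features
#'   (default 35).
#' @param wds_acc non-gravitational acceleration norm threshold in g
#'   (default 2).
#' @param wds_gyr angular-velocity norm threshold in deg/s (default 1000).
#' @return the table with updated `flags`.
#' @export
flag_outliers <- function(table, rescale_threshold = 35, wds_acc = 2,
                          wds_gyr = 1000) {
  stopifnot(inherits(table, "segment_table"))
  r <- robust_rescale(table$features)
  out <- apply(abs(r) > rescale_threshold, 1, any)
  wds <- table$features[, "stat_max_anG_norm"] > wds_acc &
    table$features[, "stat_max_omega_norm"] > wds_gyr
  m <- length(wds)
  nb <- rep(FALSE, m)
  if (any(wds)) {
    i <- which(wds)
    nb[pmax(1L, i - 1L)] <- TRUE
    nb[pmin(m, i + 1L)] <- TRUE
    nb[i] <- FALSE
  }
  table$flags$outlier <- out
  table$flags$wet_dog_shake <- wds
  table$flags$wds_neighbor <- nb & !wds
  table$flags$excluded <- out | wds | table$flags$wds_neighbor
  table
}

#' Per-segment immobility fraction
#'
#' The angular speed `||omega||` is Gaussian-smoothed (sigma = 100 ms by
#' default); a sample is immobile when the smoothed value is below
#' `thresh` (20 deg/s).  Returns the fraction of immobile samples per
#' segment.
#'
#' @param kin a [estimate_attitude()] result.
#' @param seg a [segmentation()].
#' @param sigma_s Gaussian smoothing sigma in seconds (default 0.1).
#' @param thresh immobility threshold in deg/s (default 20).
#' @return numeric vector in \[0, 1\], one value per segment.
#' @export
immobile_fraction <- function(kin, seg, sigma_s = 0.1, thresh = 20) {
  speed <- sqrt(rowSums(kin$omega^2))
  sm <- gaussian_smooth(speed, kin$rate_hz, sigma_s)
  imm <- sm < thresh
  vapply(split(imm, segment_of_sample(seg)), mean, numeric(1), USE.NAMES = FALSE)
}
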