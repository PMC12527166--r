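# synthetic: scripted ground-truth IMU generator.
#
# Regimes are additive signal models, not biomechanical simulations: each
# regime prescribes body angular rates (which are integrated exactly into a
# planted attitude path, so gravity stays consistent) plus a non-
# gravitational acceleration pattern.  The emitted accelerometer signal is
# a = aG + anG + noise with aG derived from the planted attitude.

.regimes <- c("immobile", "locomotion", "sniff_locomotion", "orient",
              "groom", "wds")

# gravity direction in the head frame for given average roll/pitch (deg),
# inverting roll = -atan2(g_y, g_z), pitch = -atan2(-g_x, sqrt(g_y^2+g_z^2))
tilt_gravity <- function(roll_deg, pitch_deg) {
  r <- roll_deg * pi / 180; p <- pitch_deg * pi / 180
  c(sin(p), -cos(p) * sin(r), cos(p) * cos(r))
}

# draw regime parameters from their canonical ranges (uses the active RNG).
# Mean head tilts and angular-velocity amplitudes are chosen so that
# adjacent regimes differ by several channel SDs in the CPD input space,
# the premise under which boundary recovery is meaningful.
sample_regime_params <- function(regime) {
  switch(regime,
    # resting posture: head raised, no movement
    immobile = list(roll = 0, pitch = runif(1, 13, 17)),
    # 5-7 Hz head-vertical sawtooth, head-bob pitch velocity, slight
    # nose-down carriage, slow yaw meander
    locomotion = list(freq = runif(1, 5, 7), amp_z = runif(1, 0.25, 0.35),
                      gyro_amp = runif(1, 30, 40), yaw_amp = runif(1, 20, 30),
                      roll = 0, pitch = runif(1, -12, -8)),
    # ~10 Hz fore-aft acceleration + pitch-velocity tone, head pitched
    # well down toward the substrate
    sniff_locomotion = list(freq = runif(1, 9.5, 10.5),
                            amp_x = runif(1, 0.12, 0.18),
                            gyro_amp = runif(1, 45, 55), roll = 0,
                            pitch = runif(1, -38, -32)),
    # single 30-50 degree reorientation completed in 100-300 ms
    orient = list(angle = runif(1, 30, 50) * sample(c(-1, 1), 1),
                  axis = c(0, 0, 1)),
    # ~4 Hz grooming rhythm with a large planted roll offset
    groom = list(freq = runif(1, 3.8, 4.2), gyro_amp = runif(1, 80, 100),
                 acc_amp = runif(1, 0.25, 0.35),
                 roll = runif(1, 45, 55), pitch = runif(1, -22, -18)),
    # 16-20 Hz whole-body shake exceeding 2 g and 1000 deg/s
    wds = list(freq = runif(1, 16, 20), acc_amp = runif(1, 2.2, 3),
               gyro_amp = runif(1, 1100, 1500)),
    stop_config("unknown regime '%s'", regime))
}

#' Build a behavioral regime script
#'
#' @param entries list of entries, each a list with `regime` (one of
#'   `immobile`, `locomotion`, `sniff_locomotion`, `orient`, `groom`,
#'   `wds`), `duration` (seconds, > 0) and optional `params` (filled from
#'   the regime's canonical ranges otherwise).
#' @param rate_hz sampling rate (default 300, the rat configuration).
#' @param noise per-channel noise SDs, `c(accel = 0.01, gyro = 1)` by
#'   default (g and deg/s; typical MEMS class).
#' @param seed RNG seed making generation fully deterministic.
#' @return an object of class `regime_script`.
#' @export
regime_script <- function(entries, rate_hz = 300,
                          noise = c(accel = 0.01, gyro = 1), seed = 0L) {
  for (e in entries) {
    if (!e$regime %in% .regimes)
      stop_config("unknown regime '%s'", e$regime)
    if (is.null(e$duration) || e$duration <= 0)
      stop_config("entry durations must be > 0")
    amps <- unlist(e$params[grepl("amp|freq", names(e$params))])
    if (length(amps) && any(amps < 0))
      stop_config("regime amplitudes/frequencies must be nonnegative")
  }
  if (any(noise < 0)) stop_config("noise SDs must be nonnegative")
  structure(list(entries = entries, rate_hz = rate_hz, noise = noise,
                 seed = as.integer(seed)),
            class = "regime_script")
}

# band-limited background motion: zero-mean Gaussian noise low-passed with
# a 30 ms Gaussian kernel, rescaled to the requested SD
smooth_noise <- function(n, rate_hz, sd_target, sigma_s = 0.03) {
  spacing <- sigma_s * rate_hz
  if (spacing > 30) {
    # slow component: cubic-spline interpolation through white knots
    k <- floor(n / spacing) + 3
    if (k < 4) return(rep(0, n))
    xk <- (seq_len(k) - 2) * spacing
    x <- stats::spline(xk, rnorm(k), xout = seq_len(n))$y
  } else {
    x <- gaussian_smooth(rnorm(n), rate_hz, sigma_s)
  }
  x <- x - mean(x)
  s <- sd(x)
  if (!is.finite(s) || s < 0.05) return(rep(0, n))  # window shorter than kernel
  x * sd_target / s
}

# per-regime body rates (deg/s) and anG (g) over n samples.
# Every active regime carries broadband low-amplitude motion on all axes
# (a head on a living animal never sits at the sensor noise floor);
# immobility keeps anG = 0 (so that noise-free immobility has |a| = 1 g
# exactly) with only a tiny postural sway.
regime_signals <- function(regime, p, n, rate_hz) {
  t <- (seq_len(n) - 1L) / rate_hz
  om <- matrix(0, n, 3)
  an <- matrix(0, n, 3)
  if (regime == "immobile") {
    # tiny postural sway plus slow drift, well under the immobility threshold
    for (j in 1:3)
      om[, j] <- smooth_noise(n, rate_hz, 2) + smooth_noise(n, rate_hz, 3, 0.5)
    return(list(omega = om, anG = an))
  }
  for (j in 1:3) {
    # broadband tremor + fast jitter + slow postural drift on every axis
    om[, j] <- smooth_noise(n, rate_hz, 4, 0.008) +
      smooth_noise(n, rate_hz, 8) + smooth_noise(n, rate_hz, 12, 0.5)
    an[, j] <- smooth_noise(n, rate_hz, 0.008, 0.008) +
      smooth_noise(n, rate_hz, 0.03) + smooth_noise(n, rate_hz, 0.02, 0.3)
  }
  # heading wander: active animals keep turning slowly; sniffing is a
  # directed behavior during which the heading is comparatively held
  om[, 3] <- om[, 3] +
    smooth_noise(n, rate_hz, if (regime == "sniff_locomotion") 6 else 20, 1.0)
  if (regime == "locomotion") {
    ph <- p$freq * t
    an[, 3] <- an[, 3] + p$amp_z * 2 * (ph - floor(0.5 + ph))   # sawtooth
    om[, 2] <- om[, 2] + p$gyro_amp * sin(2 * pi * p$freq * t)
    om[, 3] <- om[, 3] + p$yaw_amp * sin(2 * pi * 0.5 * t + pi / 3)  # meander
  } else if (regime == "sniff_locomotion") {
    om[, 2] <- om[, 2] + p$gyro_amp * sin(2 * pi * p$freq * t)
    an[, 1] <- an[, 1] + p$amp_x * sin(2 * pi * p$freq * t)
  } else if (regime == "orient") {
    # raised-cosine rate profile integrating to the planted angle
    prof <- (1 - cos(2 * pi * seq_len(n) / n)) / 2
    prof <- prof / sum(prof) * p$angle * rate_hz
    ax <- p$axis / sqrt(sum(p$axis^2))
    om <- om + outer(prof, ax)
  } else if (regime == "groom") {
    om[, 1] <- om[, 1] + p$gyro_amp * sin(2 * pi * p$freq * t)
    an[, 2] <- an[, 2] + p$acc_amp * sin(2 * pi * p$freq * t)
  } else if (regime == "wds") {
    om[, 1] <- om[, 1] + p$gyro_amp * sin(2 * pi * p$freq * t)
    om[, 3] <- om[, 3] + 0.3 * p$gyro_amp * cos(2 * pi * p$freq * t)
    an[, 1] <- an[, 1] + p$acc_amp * sin(2 * pi * p$freq * t)
    an[, 2] <- an[, 2] + p$acc_amp * cos(2 * pi * p$freq * t)
  }
  list(omega = om, anG = an)
}

#' Generate a synthetic IMU recording from a regime script
#'
#' Emits accelerometer/gyroscope streams regime by regime.  Body angular
#' rates are integrated exactly into the planted attitude, so the
#' gravitational component always matches the planted orientation; regimes
#' with a target mean tilt reach it through a brief smooth rotation (80 ms)
#' centered on the regime boundary, emulating the head adjustment that
#' accompanies a behavioral switch.
#'
#' @param script a [regime_script()].
#' @return list with `recording` (an [imu_recording()]) and `truth` (class
#'   `ground_truth`): planted `boundaries` (0-based), `labels`, `params`
#'   per segment, planted attitude `quat`, true `aG`, `anG` and `omega`.
#' @export
generate_imu <- function(script) {
  stopifnot(inherits(script, "regime_script"))
  set.seed(script$seed)
  rate <- script$rate_hz
  entries <- lapply(script$entries, function(e) {
    if (is.null(e$params)) e$params <- sample_regime_params(e$regime)
    e$n <- max(2L, as.integer(round(e$duration * rate)))
    e
  })
  lens_e <- vapply(entries, function(e) e$n, integer(1))
  bnd <- c(0L, cumsum(lens_e))
  n <- bnd[length(bnd)]

  # regime oscillation rates and anG, block by block
  omega <- matrix(0, n, 3)
  anG <- matrix(0, n, 3)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    rows <- (bnd[i] + 1L):bnd[i + 1L]
    sig <- regime_signals(e$regime, e$params, e$n, rate)
    omega[rows, ] <- sig$omega
    anG[rows, ] <- sig$anG
  }

  # initial attitude: the first entry's target tilt (level if none)
  g0 <- if (!is.null(entries[[1]]$params$roll))
    tilt_gravity(entries[[1]]$params$roll, entries[[1]]$params$pitch %||% 0)
  else c(0, 0, 1)
  cr <- c(g0[2], -g0[1], 0)  # cross(g0, ez)
  sn0 <- sqrt(sum(cr^2))
  q_cur <- if (sn0 < 1e-12) c(1, 0, 0, 0)
  else quat_from_rotvec(cr / sn0 * atan2(sn0, g0[3]))

  # integrate sequentially, inserting a brief tilt-steering rotation
  # centered on each boundary whose incoming regime has a target tilt
  quat <- matrix(NA_real_, n, 4)
  pos <- 0L
  advance <- function(to) {
    if (to > pos) {
      qb <- .integrate_gyro_cpp(omega[(pos + 1L):to, , drop = FALSE], rate, q_cur)
      quat[(pos + 1L):to, ] <<- qb
      q_cur <<- qb[nrow(qb), ]
      pos <<- to
    }
  }
  for (i in seq_along(entries)[-1]) {
    e <- entries[[i]]
    if (is.null(e$params$roll)) next
    b <- bnd[i]
    h <- min(as.integer(round(0.04 * rate)), lens_e[i - 1] %/% 2L,
             lens_e[i] %/% 2L)
    if (h < 2L) next
    advance(b - h)
    g_cur <- quat_rotate(quat_conjugate(q_cur), c(0, 0, 1))
    g_tgt <- tilt_gravity(e$params$roll, e$params$pitch %||% 0)
    ax <- c(g_cur[2] * g_tgt[3] - g_cur[3] * g_tgt[2],
            g_cur[3] * g_tgt[1] - g_cur[1] * g_tgt[3],
            g_cur[1] * g_tgt[2] - g_cur[2] * g_tgt[1])
    sn <- sqrt(sum(ax^2))
    ang <- atan2(sn, sum(g_cur * g_tgt)) * 180 / pi
    if (sn > 1e-9 && ang > 0.5) {
      n_tr <- 2L * h
      prof <- (1 - cos(2 * pi * seq_len(n_tr) / n_tr)) / 2
      prof <- prof / sum(prof) * ang * rate
      rows <- (b - h + 1L):(b + h)
      omega[rows, ] <- omega[rows, ] - outer(prof, ax / sn)
    }
  }
  advance(n)
  aG <- quat_rotate(quat_conjugate(quat), matrix(c(0, 0, 1), nrow(quat), 3,
                                                byrow = TRUE))
  accel <- aG + anG
  gyro <- omega
  if (script$noise["accel"] > 0)
    accel <- accel + matrix(rnorm(3 * n, sd = script$noise["accel"]), n, 3)
  if (script$noise["gyro"] > 0)
    gyro <- gyro + matrix(rnorm(3 * n, sd = script$noise["gyro"]), n, 3)
  lens <- vapply(entries, function(e) e$n, integer(1))
  truth <- structure(list(
    boundaries = c(0L, cumsum(lens)),
    labels = vapply(entries, function(e) e$regime, character(1)),
    params = lapply(entries, function(e) e$params),
    quat = quat, aG = aG, anG = anG, omega = omega, rate_hz = rate
  ), class = "ground_truth")
  list(recording = imu_recording(accel, gyro, rate,
                                 meta = list(source = "synthetic",
                                             seed = script$seed)),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted segments (%d regimes) over %d samples\n",
              length(x$labels), length(unique(x$labels)), x$boundaries[length(x$boundaries)]))
  invisible(x)
}

#' Standard synthetic benchmark corpus
#'
#' A scripted recording interleaving all six regimes with no immediate
#' regime repetitions, giving well over 100 planted boundaries at the
#' default 30 minutes.  This corpus is the package's standard test bed for
#' boundary recovery, clustering and sequence modeling.
#'
#' @param seed RNG seed (drives regime order, durations, parameters and
#'   noise).
#' @param duration_s total duration in seconds (default 1800).
#' @param rate_hz sampling rate (default 300).
#' @return a [regime_script()].
#' @export
default_corpus <- function(seed = 0L, duration_s = 1800, rate_hz = 300) {
  set.seed(seed)
  probs <- c(immobile = 0.19, locomotion = 0.21, sniff_locomotion = 0.18,
             orient = 0.26, groom = 0.12, wds = 0.04)
  dur_range <- list(immobile = c(2, 6), locomotion = c(2, 5),
                    sniff_locomotion = c(1.5, 4), orient = c(0.1, 0.3),
                    groom = c(2, 5), wds = c(0.4, 0.7))
  entries <- list(); total <- 0; last <- ""
  while (total < duration_s) {
    r <- sample(names(probs), 1, prob = probs)
    if (r == last) next
    d <- runif(1, dur_range[[r]][1], dur_range[[r]][2])
    entries[[length(entries) + 1L]] <-
      list(regime = r, duration = d, params = sample_regime_params(r))
    total <- total + d
    last <- r
  }
  regime_script(entries, rate_hz = rate_hz, seed = seed)
}

#' Per-segment majority ground-truth label for an arbitrary segmentation
#'
#' Maps planted regime labels onto the segments of any segmentation of the
#' same recording; segments straddling a planted boundary can be identified
#' via the returned purity.
#'
#' @param truth a `ground_truth` object.
#' @param seg a [segmentation()] over the same samples.
#' @return data.frame with `label` (majority regime) and `label_purity`
#'   (fraction of the segment's samples in that regime).
#' @export
truth_labels_for <- function(truth, seg) {
  stopifnot(inherits(seg, "segmentation"))
  planted <- rep(truth$labels, diff(truth$boundaries))
  if (length(planted) != seg$n)
    stop_schema("segmentation does not span the ground-truth recording")
  sid <- segment_of_sample(seg)
  lab <- vapply(split(planted, sid), function(v) {
    tb <- table(v); names(tb)[which.max(tb)]
  }, character(1))
  pur <- vapply(split(planted, sid), function(v) max(table(v)) / length(v),
                numeric(1))
  data.frame(label = unname(lab), label_purity = unname(pur))
}
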