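# metrics: von Mises-Fisher tilt averaging, net angular/azimuthal speed,
# sniffing score, turns per minute, purity.

#' Average head tilt of a segment (von Mises-Fisher mean direction)
#'
#' Within the head frame, gravity is a point on the unit sphere; the average
#' tilt over a segment is the mean direction of a von Mises-Fisher
#' distribution fitted to those points, i.e. the renormalized sample mean of
#' the per-sample unit vectors.  Roll and pitch are the opposite polar
#' coordinates of the mean direction mu:
#' `roll = -atan2(mu_y, mu_z)`, `pitch = -atan2(-mu_x, sqrt(mu_y^2 + mu_z^2))`,
#' reported in degrees.
#'
#' @param aG_segment k x 3 matrix of gravitational-acceleration samples
#'   (unit-ish vectors; renormalized per sample).
#' @return list with `mu` (unit 3-vector), `roll` (deg, (-180, 180\]),
#'   `pitch` (deg, \[-90, 90\]) and `dispersion` (1 - mean resultant
#'   length, in \[0, 1\]).
#' @export
vmf_tilt <- function(aG_segment) {
  x <- rbind(aG_segment)
  if (nrow(x) < 1L) stop_value("empty segment")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop_value("zero-norm gravity sample")
  u <- x / nrm
  mvec <- colMeans(u)
  r <- sqrt(sum(mvec^2))
  if (r < 1e-12)
    stop_value("antipodal cancellation: mean direction undefined")
  mu <- mvec / r
  list(mu = unname(mu),
       roll = -atan2(mu[2], mu[3]) * 180 / pi,
       pitch = -atan2(-mu[1], sqrt(mu[2]^2 + mu[3]^2)) * 180 / pi,
       dispersion = 1 - r)
}

#' Net rotation angle and net angular speed of a segment
#'
#' The net head angular displacement is the geodesic angle of the relative
#' rotation between the attitude quaternions at segment start and finish;
#' the net angular speed divides it by the segment duration.
#'
#' @param kin a [estimate_attitude()] result.
#' @param start,end 0-based half-open segment bounds.
#' @return list with `angle` (deg) and `speed` (deg/s).
#' @export
net_angular_speed <- function(kin, start, end) {
  n <- nrow(kin$quat)
  if (!(start >= 0 && start < end && end <= n))
    stop_value("invalid segment [%d, %d) for n = %d", start, end, n)
  ang <- quat_angle(kin$quat[start + 1L, ], kin$quat[end, ])
  list(angle = ang, speed = ang / ((end - start) / kin$rate_hz))
}

#' Sniffing score
#'
#' An ad-hoc band-power ratio isolating the ~10 Hz sniffing signature
#' carried by fore-aft non-gravitational acceleration (`anG_x`) and pitch
#' angular velocity (`omega_y`):
#'
#' `phi = alpha * (W[anG_x, 8.5-11] + W[omega_y, 8.5-11]) /`
#' `      (W[omega_x, full] + W[anG_x, <6] + W[anG_x, >14] +`
#' `       W[anG_y, full] + W[anG_z, full] + 100)`
#'
#' where each `W` is the maximum over the band's frequencies of the
#' per-segment time-median wavelet power (signals in g and deg/s - the
#' regularizing constant 100 is unit-dependent), and
#' `alpha = 1/(1 + eta) * 1/(1 + |mu_roll|)` penalizes segments with rapid
#' head reorientation (`eta`, deg/s) or large average roll (`mu_roll`, in
#' radians), whose brief-turn or grooming-harmonic signatures would
#' otherwise masquerade as sniffing.
#'
#' @param table a [extract_features()] result (all inputs of phi are
#'   catalog features, so the score is exactly reproducible from a table
#'   row).
#' @param const regularizing denominator constant (default 100).
#' @return data.frame with one row per segment: `phi`, `alpha`, `eta`,
#'   `numerator`, `denominator`.
#' @export
sniffing_score <- function(table, const = 100) {
  stopifnot(inherits(table, "segment_table"))
  f <- table$features
  W <- function(nm) 10^f[, nm]  # peak band powers are stored as log10
  sniffing_phi(
    w_num_ang = W("cwtpkl_anG_x_mid"),
    w_num_gy = W("cwtpkl_omega_y_mid"),
    w_gx_full = W("cwtpkl_omega_x_full"),
    w_ang_low = W("cwtpkl_anG_x_low"),
    w_ang_high = W("cwtpkl_anG_x_high"),
    w_any_full = W("cwtpkl_anG_y_full"),
    w_anz_full = W("cwtpkl_anG_z_full"),
    eta = f[, "head_eta"],
    mu_roll_rad = f[, "tilt_roll"] * pi / 180,
    const = const
  )
}

#' @rdname sniffing_score
#' @param w_num_ang,w_num_gy band powers of the numerator (`anG_x` and
#'   `omega_y` in 8.5-11 Hz).
#' @param w_gx_full,w_ang_low,w_ang_high,w_any_full,w_anz_full denominator
#'   band powers.
#' @param eta heading change rate in deg/s.
#' @param mu_roll_rad average-tilt roll in radians.
#' @export
sniffing_phi <- function(w_num_ang, w_num_gy, w_gx_full, w_ang_low,
                         w_ang_high, w_any_full, w_anz_full, eta,
                         mu_roll_rad, const = 100) {
  alpha <- 1 / (1 + eta) * 1 / (1 + abs(mu_roll_rad))
  num <- w_num_ang + w_num_gy
  den <- w_gx_full + w_ang_low + w_ang_high + w_any_full + w_anz_full + const
  data.frame(phi = alpha * num / den, alpha = alpha, eta = eta,
             numerator = num, denominator = den)
}

#' Net turning rate in turns per minute
#'
#' Net unwrapped azimuth change divided by 360 per minute; `direction_sign`
#' maps the geometric sign (positive = counter-clockwise seen from above)
#' onto the ipsiversive/contraversive convention of a per-animal lesion
#' side.
#'
#' @param azimuth unwrapped azimuth series in degrees.
#' @param rate_hz sampling rate in Hz.
#' @param direction_sign +1 or -1.
#' @return signed turns/min.
#' @export
turns_per_minute <- function(azimuth, rate_hz, direction_sign = 1) {
  stopifnot(length(azimuth) >= 2L, direction_sign %in% c(-1, 1))
  minutes <- (length(azimuth) - 1L) / rate_hz / 60
  direction_sign * (azimuth[length(azimuth)] - azimuth[1]) / 360 / minutes
}

#' Purity score of a labeled set
#'
#' The proportion of items carrying the most frequent category label; used
#' to quantify how consistently a cluster maps onto one human-assigned
#' behavioral category.
#'
#' @param labels vector of category labels (any atomic type).
#' @return purity in (0, 1\].
#' @export
purity <- function(labels) {
  if (!length(labels)) stop_value("empty label set")
  max(table(labels)) / length(labels)
}
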