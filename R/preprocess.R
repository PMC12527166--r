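# preprocess: sensor offsets, attitude filtering, gravity decomposition.

#' Construct a sensor-offsets object
#'
#' @param accel_offset length-3 accelerometer bias in g.
#' @param gyro_offset length-3 gyroscope bias in deg/s.
#' @param max_accel,max_gyro sanity bounds on the offset magnitudes
#'   (defaults 0.5 g and 50 deg/s).
#' @return an object of class `sensor_offsets`.
#' @export
sensor_offsets <- function(accel_offset = c(0, 0, 0), gyro_offset = c(0, 0, 0),
                           max_accel = 0.5, max_gyro = 50) {
  accel_offset <- as.numeric(accel_offset); gyro_offset <- as.numeric(gyro_offset)
  stopifnot(length(accel_offset) == 3L, length(gyro_offset) == 3L)
  if (!all(is.finite(c(accel_offset, gyro_offset))))
    stop_value("offsets must be finite")
  if (sqrt(sum(accel_offset^2)) >= max_accel)
    stop_value("accelerometer offset magnitude exceeds %.2f g", max_accel)
  if (sqrt(sum(gyro_offset^2)) >= max_gyro)
    stop_value("gyroscope offset magnitude exceeds %.1f deg/s", max_gyro)
  structure(list(accel_offset = accel_offset, gyro_offset = gyro_offset),
            class = "sensor_offsets")
}

#' @export
print.sensor_offsets <- function(x, ...) {
  cat(sprintf("<sensor_offsets> accel (g): %s | gyro (deg/s): %s\n",
              paste(sprintf("%.4f", x$accel_offset), collapse = " "),
              paste(sprintf("%.3f", x$gyro_offset), collapse = " ")))
  invisible(x)
}

#' Estimate sensor offsets from static calibration data
#'
#' The accelerometer bias is the vector `b` minimizing the mean squared
#' difference between `||a_t - b||` and 1 g over the immobile samples
#' (nonlinear least squares); this requires static epochs spanning diverse
#' orientations.  The gyroscope bias is the per-axis median of the gyroscope
#' readings over the same samples.
#'
#' @param static_rec an [imu_recording()] containing static periods.
#' @param immobility_mask logical vector (length = samples) marking the
#'   static samples.
#' @param min_epochs warn if fewer distinct static epochs than this are
#'   present (default 10): the accelerometer fit is poorly conditioned when
#'   orientations are not diverse.
#' @return a [sensor_offsets()] object.
#' @export
estimate_offsets <- function(static_rec, immobility_mask, min_epochs = 10L) {
  stopifnot(inherits(static_rec, "imu_recording"))
  mask <- as.logical(immobility_mask)
  if (length(mask) != n_samples(static_rec))
    stop_schema("mask length (%d) does not match recording (%d)",
                length(mask), n_samples(static_rec))
  if (!any(mask)) stop_value("immobility mask selects no samples")
  runs <- rle(mask)
  n_epochs <- sum(runs$values)
  if (n_epochs < min_epochs)
    warning(sprintf("only %d static epoch(s); accelerometer offset may be poorly constrained",
                    n_epochs))
  a <- static_rec$accel[mask, , drop = FALSE]
  g <- static_rec$gyro[mask, , drop = FALSE]
  gyro_offset <- apply(g, 2, median)

  resid_fn <- function(b) {
    sqrt((a[, 1] - b[1])^2 + (a[, 2] - b[2])^2 + (a[, 3] - b[3])^2) - 1
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5))
    stop_value("accelerometer offset optimization did not converge (rms residual %.3g)",
               sqrt(mean(fit$fvec^2)))
  sensor_offsets(accel_offset = fit$par, gyro_offset = gyro_offset)
}

#' Apply sensor offsets to a recording
#'
#' @param rec an [imu_recording()].
#' @param offsets a [sensor_offsets()] object.
#' @return the offset-corrected [imu_recording()].
#' @export
apply_offsets <- function(rec, offsets) {
  stopifnot(inherits(rec, "imu_recording"), inherits(offsets, "sensor_offsets"))
  imu_recording(sweep(rec$accel, 2, offsets$accel_offset),
                sweep(rec$gyro, 2, offsets$gyro_offset),
                rec$rate_hz, rec$meta)
}

#' Estimate head attitude and decompose acceleration
#'
#' Runs a quaternion error-state extended Kalman filter over the recording:
#' the gyroscope drives the process model and the accelerometer's direction
#' supplies the gravity observation.  Returns the full kinematic series:
#' per-sample unit quaternion (head frame to a gravity-polarized Earth
#' frame), gravitational acceleration `aG` expressed in the head frame
#' (`aG = R(q)' e_z`, i.e. the conjugate rotation applied to the Earth
#' vertical), non-gravitational acceleration `anG = a - aG`, offset-corrected
#' angular velocity, the heading vector (head x-axis in the Earth frame) and
#' the unwrapped azimuth (deg, positive = counter-clockwise seen from above,
#' starting at 0).
#'
#' @param rec an [imu_recording()].
#' @param offsets optional [sensor_offsets()]; default zero offsets.
#' @param var_acc accelerometer measurement variance (g^2); default 0.002.
#' @param var_gyr gyroscope process noise scale ((deg/s)^2 per unit
#'   bandwidth); default 0.75.
#' @return an object of class `kinematic_series` with elements `quat`
#'   (n x 4), `aG`, `anG`, `omega`, `heading` (n x 3 each), `azimuth`
#'   (length n, deg, unwrapped) and `rate_hz`.
#' @export
estimate_attitude <- function(rec, offsets = NULL, var_acc = 0.002,
                              var_gyr = 0.75) {
  stopifnot(inherits(rec, "imu_recording"))
  if (is.null(rec$rate_hz) || !is.finite(rec$rate_hz))
    stop_config("sampling rate is required for attitude estimation")
  if (!is.null(offsets)) rec <- apply_offsets(rec, offsets)
  out <- .ekf_attitude_cpp(rec$accel, rec$gyro, rec$rate_hz, var_acc, var_gyr)
  qn <- sqrt(rowSums(out$quat^2))
  if (any(abs(qn - 1) > 1e-6))
    stop_value("quaternion norm diverged (max deviation %.3g)", max(abs(qn - 1)))
  az_raw <- atan2(out$heading[, 2], out$heading[, 1]) * 180 / pi
  kin <- structure(list(
    quat = out$quat,
    aG = out$aG,
    anG = rec$accel - out$aG,
    omega = rec$gyro,
    heading = out$heading,
    azimuth = unwrap_deg(az_raw),
    rate_hz = rec$rate_hz
  ), class = "kinematic_series")
  kin
}

#' @export
print.kinematic_series <- function(x, ...) {
  n <- nrow(x$quat)
  cat(sprintf("<kinematic_series> %d samples @ %g Hz; mean |aG| = %.3f g\n",
              n, x$rate_hz, mean(sqrt(rowSums(x$aG^2)))))
  invisible(x)
}

#' Heading change rate of a segment
#'
#' The angle between the heading vectors at the beginning and the end of the
#' half-open segment `[start, end)` (0-based sample indices), divided by the
#' segment duration.  Used as the reorientation penalty eta of the sniffing
#' score.
#'
#' @param kin a [estimate_attitude()] result.
#' @param start,end 0-based sample indices, `0 <= start < end <= n`.
#' @return nonnegative rate in deg/s.
#' @export
heading_change_rate <- function(kin, start, end) {
  n <- nrow(kin$heading)
  if (!(start >= 0 && start < end && end <= n))
    stop_value("invalid segment [%d, %d) for n = %d", start, end, n)
  h0 <- kin$heading[start + 1L, ]
  h1 <- kin$heading[end, ]
  vector_angle_deg(h0, h1) / ((end - start) / kin$rate_hz)
}
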