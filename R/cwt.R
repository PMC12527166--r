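# Continuous wavelet transform (complex Morlet) via FFT convolution.
#
# The transform is computed over the whole recording and then sliced per
# segment: computing it per segment would let the strong 16-20 Hz signature
# of wet-dog shakes leak into neighboring segments through edge effects,
# and short segments would be unanalyzable at low frequencies.

#' Frequency bands used by the feature catalog and the sniffing score
#'
#' `low` (< 6 Hz), `mid` (8.5-11 Hz, the sniffing band), `high` (> 14 Hz)
#' and `full` (the whole 1-20 Hz grid).
#'
#' @return named list of predicate functions over frequency (Hz).
#' @export
cwt_bands <- function() {
  list(low = function(f) f < 6,
       mid = function(f) f >= 8.5 & f <= 11,
       high = function(f) f > 14,
       full = function(f) rep(TRUE, length(f)))
}

# Morlet scale for a target Fourier frequency (Torrence & Compo mapping)
morlet_scale <- function(freq, omega0) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freq)
}

#' Continuous-wavelet power of a single channel
#'
#' Complex Morlet (analytic) wavelet, center-frequency parameter `omega0`
#' (default 6), evaluated on a grid of Fourier frequencies.  Returns the
#' squared coefficient magnitude per (sample, frequency).
#'
#' @param x numeric vector (one signal channel).
#' @param rate_hz sampling rate in Hz.
#' @param freqs frequency grid in Hz (default 1-20 Hz in 0.5 Hz steps).
#' @param omega0 Morlet center-frequency parameter.
#' @return `length(x)` x `length(freqs)` matrix of power, columns named by
#'   frequency.
#' @export
cwt_power <- function(x, rate_hz, freqs = seq(1, 20, by = 0.5), omega0 = 6) {
  n <- length(x)
  if (n < 1L) stop_value("empty signal")
  if (n < 2 * rate_hz / min(freqs))
    warning("signal shorter than 2 cycles of the lowest frequency; low bands are edge-dominated")
  fx <- cwt_fft(x)
  out <- vapply(freqs, function(f) cwt_power_one(fx, n, rate_hz, f, omega0),
                numeric(n))
  colnames(out) <- as.character(freqs)
  out
}

# precompute the padded FFT of a channel
cwt_fft <- function(x) {
  n <- length(x)
  np <- stats::nextn(2L * n, 2L)
  list(fx = stats::fft(c(x, rep(0, np - n))), n = n, np = np)
}

# power at one frequency from a precomputed channel FFT
cwt_power_one <- function(fxo, n, rate_hz, freq, omega0) {
  np <- fxo$np
  dt <- 1 / rate_hz
  s <- morlet_scale(freq, omega0)
  k <- seq_len(np) - 1L
  wk <- 2 * pi * ifelse(k <= np / 2, k, k - np) / (np * dt)
  daughter <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
    exp(-0.5 * (s * wk - omega0)^2) * (wk > 0)
  w <- stats::fft(fxo$fx * daughter, inverse = TRUE) / np
  Mod(w[seq_len(n)])^2
}

#' Per-segment time-median wavelet power
#'
#' For each of the requested kinematic channels, computes the CWT power over
#' the whole recording, then the median over time within each segment, per
#' frequency.  This is the shared basis of the wavelet feature family and of
#' the sniffing score (whose band powers are maxima over band frequencies of
#' these time-medians).
#'
#' @param kin a [estimate_attitude()] result.
#' @param seg a [segmentation()].
#' @param freqs frequency grid in Hz.
#' @param omega0 Morlet center-frequency parameter.
#' @param channels character vector among `anG_x, anG_y, anG_z, omega_x,
#'   omega_y, omega_z`.
#' @return 3-d array `[segment, frequency, channel]` of median power.
#' @export
cwt_segment_medians <- function(kin, seg,
                                freqs = seq(1, 20, by = 0.5), omega0 = 6,
                                channels = c("anG_x", "anG_y", "anG_z",
                                             "omega_x", "omega_y", "omega_z")) {
  stopifnot(inherits(seg, "segmentation"))
  if (seg$n != nrow(kin$aG))
    stop_schema("segmentation span (%d) does not match the series (%d)",
                seg$n, nrow(kin$aG))
  sid <- segment_of_sample(seg)
  m <- n_segments(seg)
  out <- array(NA_real_, dim = c(m, length(freqs), length(channels)),
               dimnames = list(NULL, as.character(freqs), channels))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    base <- sub("_[xyz]$", "", ch)
    axis <- match(sub("^.*_", "", ch), c("x", "y", "z"))
    x <- kin[[base]][, axis]
    fxo <- cwt_fft(x)
    for (fi in seq_along(freqs)) {
      p <- cwt_power_one(fxo, length(x), kin$rate_hz, freqs[fi], omega0)
      dtb <- data.table::data.table(p = p, g = sid)
      med <- dtb[, list(v = median(p)), keyby = "g"]
      out[med$g, fi, ci] <- med$v
    }
  }
  out
}
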