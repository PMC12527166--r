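# small shared helpers

#' Unwrap a sequence of angles in degrees
#'
#' Removes +/-360 jumps so that adjacent samples never differ by more than
#' 180 degrees, yielding a continuous angle series.
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector of unwrapped angles (same first element).
#' @export
unwrap_deg <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - 360 * round(d / 360)
  c(theta[1L], theta[1L] + cumsum(d))
}

#' Gaussian smoothing of a regularly sampled series
#'
#' Convolves with a Gaussian kernel of standard deviation `sigma_s` seconds,
#' truncated at 4 sigma, with edge renormalization (the kernel mass falling
#' outside the series is redistributed, so constants are preserved).
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param sigma_s kernel standard deviation in seconds.
#' @return smoothed numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, rate_hz, sigma_s) {
  stopifnot(rate_hz > 0, sigma_s >= 0)
  sigma <- sigma_s * rate_hz
  if (sigma < 1e-9) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  # zero-pad convolution, then renormalize by the local kernel mass
  xp <- c(rep(0, half), x, rep(0, half))
  num <- stats::filter(xp, k, sides = 2)[(half + 1L):(half + n)]
  mp <- c(rep(0, half), rep(1, n), rep(0, half))
  mass <- stats::filter(mp, k, sides = 2)[(half + 1L):(half + n)]
  as.numeric(num / mass)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()], provided so pipeline
#' reports and tests share one entry point.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# condition helpers ---------------------------------------------------------

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("imuseg_schema_error", "imuseg_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("imuseg_config_error", "imuseg_error")))
}

stop_value <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("imuseg_value_error", "imuseg_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
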