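# segmentation: Gaussian-kernel penalized change-point detection (PELT),
# penalty calibration, windowed-parallel execution, fixed-length baseline,
# and immobility ablation.
#
# Boundaries are 0-based sample indices t_0 = 0 < t_1 < ... < t_m = n;
# segment k is the half-open interval [t_k, t_{k+1}) and maps to R rows
# (t_k + 1):t_{k+1}.

#' Change-point detection parameters
#'
#' @param penalty penalty lambda >= 0 per change point. The defaults used on
#'   animal data are 14 (rat, 300 Hz) and 9 (mouse, 200 Hz), calibrated for
#'   a median segment duration of 300-400 ms.
#' @param bandwidth Gaussian-kernel scale gamma, or `"median"` for the
#'   median heuristic (`gamma = 1 / (2 median^2)` of pairwise distances on a
#'   deterministic subsample of up to 2000 points).
#' @param min_size minimum segment length in samples; if `NULL`, derived
#'   from `min_size_s` and the sampling rate at call time.
#' @param min_size_s minimum segment length in seconds (default 0.03 s,
#'   below the shortest behavioral motifs of interest).
#' @param channels which kinematic series enter CPD; default gravitational
#'   acceleration and angular velocity (`c("aG", "omega")`), 6 channels.
#' @return an object of class `cpd_params`.
#' @export
cpd_params <- function(penalty = 14, bandwidth = "median", min_size = NULL,
                       min_size_s = 0.03, channels = c("aG", "omega")) {
  if (penalty < 0) stop_config("penalty must be >= 0")
  if (!is.null(min_size) && min_size < 1) stop_config("min_size must be >= 1")
  structure(list(penalty = penalty, bandwidth = bandwidth, min_size = min_size,
                 min_size_s = min_size_s, channels = channels),
            class = "cpd_params")
}

#' Construct a segmentation
#'
#' @param boundaries strictly increasing integer vector of 0-based sample
#'   indices starting at 0 and ending at `n`.
#' @param rate_hz optional sampling rate, used to express durations in
#'   seconds.
#' @return an object of class `segmentation`.
#' @export
segmentation <- function(boundaries, rate_hz = NULL) {
  b <- as.integer(round(boundaries))
  if (length(b) < 2L || b[1] != 0L || any(diff(b) <= 0L))
    stop_value("boundaries must be strictly increasing from 0 to n")
  structure(list(boundaries = b, n = b[length(b)], rate_hz = rate_hz),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  len <- diff(x$boundaries)
  cat(sprintf("<segmentation> %d segments over %d samples", length(len), x$n))
  if (!is.null(x$rate_hz))
    cat(sprintf(" (median duration %.0f ms)", 1000 * median(len) / x$rate_hz))
  cat("\n")
  invisible(x)
}

#' Segment count, starts, ends and lengths
#' @param seg a [segmentation()].
#' @return `n_segments`: integer count; `segment_bounds`: a data.frame with
#'   0-based `start`, `end` and `length` per segment; `segment_of_sample`:
#'   integer vector giving the segment id (1-based) of every sample.
#' @export
n_segments <- function(seg) length(seg$boundaries) - 1L

#' @rdname n_segments
#' @export
segment_bounds <- function(seg) {
  b <- seg$boundaries
  data.frame(start = b[-length(b)], end = b[-1],
             length = diff(b))
}

#' @rdname n_segments
#' @export
segment_of_sample <- function(seg) {
  rep.int(seq_len(n_segments(seg)), diff(seg$boundaries))
}

#' Median-heuristic Gaussian-kernel bandwidth
#'
#' `gamma = 1 / (2 m^2)` where `m` is the median pairwise Euclidean distance
#' over an evenly spaced subsample of at most `max_points` rows
#' (deterministic, so segmentation involves no randomness).
#'
#' @param series numeric matrix (rows = samples).
#' @param max_points subsample cap (default 2000).
#' @return positive scalar gamma.
#' @export
median_heuristic_bandwidth <- function(series, max_points = 2000L) {
  series <- as.matrix(series)
  n <- nrow(series)
  idx <- if (n > max_points) unique(round(seq(1L, n, length.out = max_points))) else seq_len(n)
  d <- stats::dist(series[idx, , drop = FALSE])
  m <- median(d[d > 0])
  if (!is.finite(m) || m <= 0) return(1)  # degenerate (constant) series
  1 / (2 * m^2)
}

#' Gaussian-kernel segment cost
#'
#' Within-segment kernel scatter of the half-open segment `[start, end)`:
#' `c = l - (1/l) * sum_{s,t} k(x_s, x_t)` with the Gaussian RBF
#' `k(x, y) = exp(-gamma ||x - y||^2)`; `0 <= c <= l`.
#'
#' @param series numeric matrix (rows = samples), already standardized.
#' @param start,end 0-based half-open segment bounds, `end - start >= 1`.
#' @param gamma Gaussian-kernel scale.
#' @return nonnegative cost.
#' @export
kernel_cost <- function(series, start, end, gamma) {
  series <- as.matrix(series)
  if (!(start >= 0 && end > start && end <= nrow(series)))
    stop_value("invalid segment [%d, %d)", start, end)
  x <- series[(start + 1L):end, , drop = FALSE]
  l <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  l - sum(exp(-gamma * d2)) / l
}

#' Optimal Gaussian-kernel change-point detection (PELT)
#'
#' Finds the segmentation minimizing total kernel cost plus
#' `penalty * (number of change points)`, exactly, via PELT-pruned dynamic
#' programming.  Deterministic; ties broken toward the earliest boundary.
#'
#' @param series numeric matrix of standardized (z-scored per channel)
#'   signals, rows = samples.
#' @param params a [cpd_params()].
#' @param rate_hz sampling rate, needed when `params$min_size` is `NULL`
#'   (to convert `min_size_s` to samples) and to report durations.
#' @return a [segmentation()] with attribute `objective` (the achieved
#'   penalized cost) and `gamma` (the bandwidth used).
#' @export
kernel_cpd <- function(series, params = cpd_params(), rate_hz = NULL) {
  series <- as.matrix(series)
  storage.mode(series) <- "double"
  if (!all(is.finite(series))) stop_value("series contains non-finite values")
  min_size <- params$min_size
  if (is.null(min_size)) {
    if (is.null(rate_hz)) min_size <- 1L
    else min_size <- max(1L, as.integer(ceiling(params$min_size_s * rate_hz)))
  }
  gamma <- if (identical(params$bandwidth, "median"))
    median_heuristic_bandwidth(series) else as.numeric(params$bandwidth)
  res <- .kernel_pelt_cpp(series, gamma, params$penalty, as.integer(min_size))
  seg <- segmentation(res$boundaries, rate_hz)
  attr(seg, "objective") <- res$objective
  attr(seg, "gamma") <- gamma
  seg
}

#' Calibrate the CPD penalty to a target median segment duration
#'
#' The median segment duration is non-decreasing in the penalty; a monotone
#' bisection (geometric midpoints, plateau-tolerant) finds a penalty whose
#' median duration is within `tol` (default 10%) of `target_s` seconds.
#'
#' @param series standardized series matrix.
#' @param target_s target median segment duration in seconds (e.g. 0.35).
#' @param rate_hz sampling rate in Hz.
#' @param bracket length-2 positive penalty bracket that must straddle the
#'   target.
#' @param params a [cpd_params()]; its `penalty` is ignored.
#' @param tol relative tolerance on the median duration (default 0.1).
#' @param max_iter bisection cap (default 30).
#' @return the calibrated penalty (scalar), with attribute
#'   `median_duration_s`.
#' @export
calibrate_penalty <- function(series, target_s, rate_hz,
                              bracket = c(0.5, 200), params = cpd_params(),
                              tol = 0.1, max_iter = 30L) {
  stopifnot(length(bracket) == 2L, all(bracket > 0), bracket[1] < bracket[2])
  med_at <- function(lam) {
    p <- params; p$penalty <- lam
    seg <- kernel_cpd(series, p, rate_hz)
    median(diff(seg$boundaries)) / rate_hz
  }
  lo <- bracket[1]; hi <- bracket[2]
  m_lo <- med_at(lo); m_hi <- med_at(hi)
  ok <- function(m) abs(m - target_s) <= tol * target_s
  if (ok(m_lo)) lam <- lo
  else if (ok(m_hi)) lam <- hi
  else if (m_lo > target_s || m_hi < target_s)
    stop_value("target %.3f s outside achievable range [%.3f, %.3f] s for bracket [%g, %g]",
               target_s, m_lo, m_hi, lo, hi)
  else {
    lam <- NA_real_
    for (i in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)
      m <- med_at(mid)
      if (ok(m)) { lam <- mid; break }
      if (m < target_s) lo <- mid else hi <- mid
      if (hi / lo < 1.001) { lam <- mid; break }  # plateau: accept nearest
    }
    if (is.na(lam)) lam <- sqrt(lo * hi)
  }
  structure(lam, median_duration_s = med_at(lam))
}

#' Windowed-parallel change-point detection
#'
#' Runs [kernel_cpd()] independently on non-overlapping fixed-length
#' windows and concatenates the per-window segmentations; window edges are
#' forced boundaries.  With windows of several minutes the result is nearly
#' identical to full-recording CPD while allowing parallel / bounded-memory
#' execution.
#'
#' @param series standardized series matrix.
#' @param window_s window length in seconds (>= 300 recommended).
#' @param params a [cpd_params()].
#' @param rate_hz sampling rate in Hz.
#' @return a [segmentation()].
#' @export
parallel_cpd <- function(series, window_s, params = cpd_params(), rate_hz) {
  series <- as.matrix(series)
  n <- nrow(series)
  w <- max(1L, as.integer(round(window_s * rate_hz)))
  if (identical(params$bandwidth, "median")) {
    # one shared bandwidth so windows are mutually consistent
    params$bandwidth <- median_heuristic_bandwidth(series)
  }
  edges <- unique(c(seq(0L, n, by = w), n))
  bounds <- 0L
  for (k in seq_len(length(edges) - 1L)) {
    s <- edges[k]; e <- edges[k + 1L]
    sub <- kernel_cpd(series[(s + 1L):e, , drop = FALSE], params, rate_hz)
    bounds <- c(bounds, s + sub$boundaries[-1])
  }
  segmentation(unique(bounds), rate_hz)
}

#' Fixed-length window segmentation
#'
#' Non-overlapping windows of `window` samples (the canonical baseline is
#' 210 samples = 700 ms at 300 Hz, matching the average CPD segment
#' duration); a final partial window is kept.
#'
#' @param n number of samples.
#' @param window window length in samples (>= 1).
#' @param rate_hz optional sampling rate.
#' @return a [segmentation()].
#' @export
fixed_windows <- function(n, window, rate_hz = NULL) {
  stopifnot(window >= 1, n >= 1)
  b <- seq(0L, n, by = as.integer(window))
  if (b[length(b)] != n) b <- c(b, n)
  segmentation(b, rate_hz)
}

#' Ablate immobility segments prior to modeling
#'
#' `fixed` mode drops every segment whose angular-speed standard deviation
#' (SD of `||omega||` within the segment) is below `std_thresh` (deg/s).
#' `cpd_matched` mode ranks segments by ascending angular-speed SD and drops
#' the lowest-activity ones until the removed duration reaches
#' `match_duration_s` - the removed duration of the fixed-window procedure -
#' making the two ablations duration-matched.
#'
#' @param seg a [segmentation()].
#' @param omega n x 3 angular-velocity matrix aligned with `seg`.
#' @param mode `"fixed"` or `"cpd_matched"`.
#' @param std_thresh angular-speed SD threshold in deg/s (default 12).
#' @param rate_hz sampling rate in Hz.
#' @param match_duration_s required for `cpd_matched`: the removed duration
#'   (seconds) to match.
#' @return list with `keep` (logical per segment), `removed_idx`,
#'   `removed_duration_s` and `seg_std` (per-segment angular-speed SD).
#' @export
ablate_immobility <- function(seg, omega, mode = c("fixed", "cpd_matched"),
                              std_thresh = 12, rate_hz,
                              match_duration_s = NULL) {
  mode <- match.arg(mode)
  omega <- as.matrix(omega)
  if (nrow(omega) != seg$n)
    stop_schema("omega (%d rows) is not aligned with the segmentation (n = %d)",
                nrow(omega), seg$n)
  speed <- sqrt(rowSums(omega^2))
  sid <- segment_of_sample(seg)
  seg_std <- unname(vapply(split(speed, sid),
                           function(v) if (length(v) > 1) sd(v) else 0,
                           numeric(1)))
  lens <- diff(seg$boundaries) / rate_hz
  m <- n_segments(seg)
  keep <- rep(TRUE, m)
  if (mode == "fixed") {
    keep <- seg_std >= std_thresh
  } else {
    if (is.null(match_duration_s))
      stop_config("cpd_matched ablation requires match_duration_s")
    ord <- order(seg_std)
    removed <- 0
    for (i in ord) {
      if (removed >= match_duration_s) break
      keep[i] <- FALSE
      removed <- removed + lens[i]
    }
    if (removed < match_duration_s)
      warning("matched-duration target unreachable: all segments removed")
  }
  list(keep = keep, removed_idx = which(!keep),
       removed_duration_s = sum(lens[!keep]), seg_std = seg_std)
}

#' Standardize kinematic channels for change-point detection
#'
#' Builds the CPD input matrix by column-binding the requested channels of a
#' kinematic series and z-scoring each channel over the recording session.
#'
#' @param kin a [estimate_attitude()] result.
#' @param channels subset of `c("aG", "anG", "omega")`.
#' @return z-scored numeric matrix (columns named).
#' @export
cpd_input <- function(kin, channels = c("aG", "omega")) {
  bad <- setdiff(channels, c("aG", "anG", "omega"))
  if (length(bad)) stop_config("unknown CPD channel(s): %s", paste(bad, collapse = ", "))
  blocks <- lapply(channels, function(ch) {
    m <- kin[[ch]]
    colnames(m) <- paste0(ch, "_", c("x", "y", "z"))
    m
  })
  x <- do.call(cbind, blocks)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  scale(x, center = TRUE, scale = scale_)
}
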