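# Independent oracles used across the suite.

# Exhaustive O(n^2) penalized dynamic program over the Gaussian-kernel cost,
# written without pruning and without the package's segment-cost code
# (block sums come from a 2-D prefix sum of the Gram matrix).
naive_kernel_dp <- function(x, gamma, penalty, min_size = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  G <- exp(-gamma * as.matrix(dist(x))^2)
  P <- matrix(0, n + 1L, n + 1L)
  P[-1, -1] <- apply(apply(G, 2, cumsum), 1, cumsum)
  block <- function(s, t) P[t + 1, t + 1] - P[s + 1, t + 1] - P[t + 1, s + 1] + P[s + 1, s + 1]
  F <- rep(Inf, n + 1L)
  F[1] <- -penalty
  prev <- rep(-1L, n + 1L)
  for (t in seq_len(n)) {
    if (t < min_size) next
    cand <- 0:(t - min_size)
    cand <- cand[cand == 0L | cand >= min_size]
    vals <- vapply(cand, function(s) {
      l <- t - s
      F[s + 1] + (l - block(s, t) / l) + penalty
    }, numeric(1))
    ok <- is.finite(vals)
    if (!any(ok)) next
    i <- which.min(vals)          # earliest wins on ties
    F[t + 1] <- vals[i]
    prev[t + 1] <- cand[i]
  }
  b <- n
  out <- n
  while (b > 0) {
    b <- prev[b + 1]
    out <- c(b, out)
  }
  list(boundaries = out, objective = F[n + 1])
}

# closed-form per-sample quaternion integration of body rates (deg/s),
# kept in plain R as the attitude oracle
integrate_gyro_R <- function(omega_deg, rate_hz, q0 = c(1, 0, 0, 0)) {
  n <- nrow(omega_deg)
  out <- matrix(0, n, 4)
  q <- q0
  for (t in seq_len(n)) {
    q <- quat_multiply(q, quat_from_rotvec(omega_deg[t, ] * pi / 180 / rate_hz))
    q <- q / sqrt(sum(q^2))
    out[t, ] <- q
  }
  out
}

aG_from_quat <- function(quat) {
  quat_rotate(quat_conjugate(quat), matrix(c(0, 0, 1), nrow(quat), 3, byrow = TRUE))
}

# brute-force HMM likelihood and smoothed posteriors by path enumeration
hmm_brute <- function(model, symbols) {
  S <- model$S
  T_ <- length(symbols)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  lp <- apply(paths, 1, function(st) {
    p <- log(model$initial[st[1]]) + log(model$emission[st[1], symbols[1]])
    if (T_ > 1) {
      for (t in 2:T_) {
        p <- p + log(model$transition[st[t - 1], st[t]]) +
          log(model$emission[st[t], symbols[t]])
      }
    }
    p
  })
  mx <- max(lp)
  w <- exp(lp - mx)
  gamma <- sapply(seq_len(T_), function(t)
    vapply(seq_len(S), function(s) sum(w[paths[, t] == s]) / sum(w), numeric(1)))
  list(loglik = mx + log(sum(w)), gamma = t(gamma))
}

# static calibration recording: k orientations held for hold_s seconds each,
# with a known accelerometer bias and optional noise
static_orientation_rec <- function(k = 50, hold_s = 0.2, rate_hz = 300,
                                   accel_bias = c(0, 0, 0), gyro_bias = c(0, 0, 0),
                                   noise_sd = 0, seed = 0) {
  set.seed(seed)
  per <- as.integer(hold_s * rate_hz)
  dirs <- matrix(rnorm(3 * k), k, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  accel <- dirs[rep(seq_len(k), each = per), ]
  if (noise_sd > 0) accel <- accel + matrix(rnorm(length(accel), sd = noise_sd), ncol = 3)
  accel <- sweep(accel, 2, accel_bias, "+")
  gyro <- matrix(rep(gyro_bias, each = k * per), ncol = 3)
  if (noise_sd > 0) gyro <- gyro + matrix(rnorm(length(gyro), sd = noise_sd * 50), ncol = 3)
  # mask leaves a gap between epochs so they count as distinct
  mask <- rep(c(rep(TRUE, per - 1L), FALSE), k)
  list(rec = imu_recording(accel, gyro, rate_hz), mask = mask)
}

# short mixed-regime script for fast integration-style tests
mini_script <- function(seed = 1, duration_s = 60, rate_hz = 300) {
  default_corpus(seed = seed, duration_s = duration_s, rate_hz = rate_hz)
}

# wrap a plain feature matrix as a minimal segment table
as_segment_table <- function(X) {
  X <- as.matrix(X)
  m <- nrow(X)
  flags <- data.frame(outlier = rep(FALSE, m), wet_dog_shake = FALSE,
                      wds_neighbor = FALSE, excluded = FALSE,
                      immobile_fraction = 0)
  structure(list(features = X, names = colnames(X),
                 bounds = data.frame(start = 0:(m - 1), end = seq_len(m),
                                     length = 1L),
                 flags = flags, rate_hz = 1, spec = NULL),
            class = "segment_table")
}
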