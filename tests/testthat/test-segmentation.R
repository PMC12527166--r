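# kernel cost, PELT, penalty calibration, windows, immobility ablation

test_that("kernel cost obeys its closed-form identities and bounds", {
  x <- matrix(rnorm(40), 20, 2)
  g <- 0.7
  # identical points -> zero cost
  xc <- matrix(1, 10, 2)
  expect_equal(kernel_cost(xc, 0, 10, g), 0, tolerance = 1e-12)
  # two points: 1 - k(x, y)
  x2 <- rbind(c(0, 0), c(1, 2))
  expect_equal(kernel_cost(x2, 0, 2, g), 1 - exp(-g * 5), tolerance = 1e-12)
  # bounds 0 <= c <= l for random segments and scales
  set.seed(5)
  for (i in 1:20) {
    s <- sample(0:15, 1); e <- sample((s + 1):20, 1)
    gg <- runif(1, 0.01, 5)
    cval <- kernel_cost(x, s, e, gg)
    expect_gte(cval, 0)
    expect_lte(cval, e - s)
  }
  expect_error(kernel_cost(x, 5, 5, g), class = "imuseg_value_error")
})

test_that("PELT equals the exhaustive dynamic program on random instances", {
  set.seed(42)
  for (i in 1:12) {
    n <- sample(30:120, 1)
    d <- sample(1:6, 1)
    k <- sample(1:3, 1)
    mu <- matrix(rnorm(k * d, sd = 3), k, d)
    x <- do.call(rbind, lapply(seq_len(k), function(j)
      sweep(matrix(rnorm(ceiling(n / k) * d), ncol = d), 2, mu[j, ], "+")))
    gamma <- median_heuristic_bandwidth(x)
    lam <- runif(1, 0.5, 10)
    ms <- sample(1:5, 1)
    fast <- kernel_cpd(x, cpd_params(penalty = lam, bandwidth = gamma,
                                     min_size = ms))
    slow <- naive_kernel_dp(x, gamma, lam, ms)
    expect_identical(as.integer(fast$boundaries), as.integer(slow$boundaries))
    expect_equal(attr(fast, "objective"), slow$objective,
                 tolerance = 1e-8)
  }
})

test_that("a constant series yields no change points and a clean step is found", {
  xc <- matrix(0, 100, 2)
  seg <- kernel_cpd(xc, cpd_params(penalty = 0.5, bandwidth = 1, min_size = 2))
  expect_equal(seg$boundaries, c(0L, 100L))
  set.seed(1)
  xs <- rbind(matrix(rnorm(60, 0, 0.01), ncol = 1),
              matrix(rnorm(60, 5, 0.01), ncol = 1))
  seg <- kernel_cpd(xs, cpd_params(penalty = 1, min_size = 2))
  expect_equal(seg$boundaries, c(0L, 60L, 120L))
})

test_that("penalty limits and monotonicity behave as the theory demands", {
  set.seed(7)
  x <- cbind(rnorm(240), rnorm(240))
  hi <- kernel_cpd(x, cpd_params(penalty = 1e6, min_size = 5))
  expect_equal(n_segments(hi), 1L)
  lo <- kernel_cpd(x, cpd_params(penalty = 0, min_size = 5))
  expect_gt(n_segments(lo), 20)
  # number of change points non-increasing, median duration non-decreasing
  lams <- c(0.1, 0.3, 1, 3, 10, 30)
  res <- lapply(lams, function(l)
    kernel_cpd(x, cpd_params(penalty = l, min_size = 5)))
  ncp <- vapply(res, n_segments, integer(1))
  med <- vapply(res, function(s) median(diff(s$boundaries)), numeric(1))
  expect_true(all(diff(ncp) <= 0))
  expect_true(all(diff(med) >= 0))
})

test_that("penalty calibration hits the target median duration", {
  g <- generate_imu(mini_script(seed = 1, duration_s = 90))
  kin <- estimate_attitude(g$recording)
  x <- cpd_input(kin)
  lam <- calibrate_penalty(x, 0.35, 300, bracket = c(0.1, 100))
  med <- attr(lam, "median_duration_s")
  # plateau handling may stop at the nearest achievable median
  expect_lt(abs(med - 0.35), 0.35 * 0.35)
  # re-running CPD at the returned penalty reproduces that median
  seg <- kernel_cpd(x, cpd_params(penalty = as.numeric(lam)), 300)
  expect_equal(median(diff(seg$boundaries)) / 300, med, tolerance = 1e-9)
  expect_error(calibrate_penalty(x, 500, 300, bracket = c(0.1, 1)),
               class = "imuseg_value_error")
})

test_that("windowed-parallel CPD covers the series and matches a single window", {
  set.seed(9)
  x <- cbind(rnorm(600), rnorm(600))
  p <- cpd_params(penalty = 2, min_size = 5)
  full <- kernel_cpd(x, p, rate_hz = 100)
  one <- parallel_cpd(x, window_s = 10, p, rate_hz = 100)  # window >= length
  expect_equal(one$boundaries, full$boundaries)
  two <- parallel_cpd(x, window_s = 2.5, p, rate_hz = 100)
  b <- two$boundaries
  expect_equal(b[1], 0L)
  expect_equal(b[length(b)], 600L)
  expect_true(all(diff(b) > 0))
  expect_true(all(c(250L, 500L) %in% b))  # forced window edges
})

test_that("fixed windows partition the samples, keeping the last partial window", {
  expect_equal(n_segments(fixed_windows(630, 210)), 3L)
  s <- fixed_windows(631, 210)
  expect_equal(n_segments(s), 4L)
  expect_equal(diff(s$boundaries)[4], 1L)
  expect_equal(n_segments(fixed_windows(100, 210)), 1L)
})

test_that("immobility ablation removes quiet windows and matches durations", {
  rate <- 100
  omega <- rbind(matrix(rnorm(300 * 3, sd = 30), ncol = 3),  # moving
                 matrix(rnorm(100 * 3, sd = 1), ncol = 3),   # quiet
                 matrix(rnorm(200 * 3, sd = 30), ncol = 3))
  seg <- fixed_windows(600, 100, rate)
  ab <- ablate_immobility(seg, omega, "fixed", std_thresh = 12, rate_hz = rate)
  expect_equal(ab$removed_idx, 4L)
  expect_equal(ab$removed_duration_s, 1.0)
  # all-moving series: nothing removed
  ab2 <- ablate_immobility(seg, matrix(rnorm(600 * 3, sd = 30), ncol = 3),
                           "fixed", rate_hz = rate)
  expect_length(ab2$removed_idx, 0L)
  # cpd_matched removes lowest-activity segments first, total >= target
  cp <- segmentation(c(0, 150, 300, 400, 600), rate)
  ab3 <- ablate_immobility(cp, omega, "cpd_matched", rate_hz = rate,
                           match_duration_s = ab$removed_duration_s)
  expect_gte(ab3$removed_duration_s, ab$removed_duration_s)
  # greedy order: removed segments are exactly the lowest-std prefix
  ord <- order(ab3$seg_std)
  k <- length(ab3$removed_idx)
  expect_setequal(ab3$removed_idx, ord[seq_len(k)])
  # minimality: dropping the last removed segment would undershoot
  expect_lt(ab3$removed_duration_s -
              diff(cp$boundaries)[ord[k]] / rate, ab$removed_duration_s)
  expect_warning(ablate_immobility(cp, omega, "cpd_matched", rate_hz = rate,
                                   match_duration_s = 100), "unreachable")
})

test_that("segmentation containers enforce their invariants", {
  expect_error(segmentation(c(1, 5, 10)), class = "imuseg_value_error")
  expect_error(segmentation(c(0, 5, 5)), class = "imuseg_value_error")
  s <- segmentation(c(0, 3, 10))
  expect_equal(segment_of_sample(s), rep(c(1L, 2L), c(3, 7)))
  expect_error(kernel_cpd(matrix(c(1, NA), 2, 1), cpd_params()),
               class = "imuseg_value_error")
  # n < min_size: single segment
  expect_equal(kernel_cpd(matrix(rnorm(6), 6, 1),
                          cpd_params(min_size = 10))$boundaries, c(0L, 6L))
})
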