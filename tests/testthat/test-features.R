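# CWT, feature catalog, robust rescaling, outlier flags, immobility fraction

test_that("the Morlet CWT localizes a known tone and scales quadratically", {
  rate <- 300
  x <- sin(2 * pi * 10 * (0:2999) / rate)
  p <- cwt_power(x, rate)
  med <- apply(p, 2, median)
  f_at_max <- as.numeric(colnames(p)[which.max(med)])
  expect_lt(abs(f_at_max - 10), 0.5)
  # quadratic energy
  p2 <- cwt_power(2 * x, rate)
  expect_equal(median(p2 / pmax(p, 1e-300)), 4, tolerance = 1e-6)
  # zero signal -> zero power
  expect_equal(max(cwt_power(rep(0, 700), rate)), 0)
  expect_error(cwt_power(numeric(0), rate), class = "imuseg_value_error")
  expect_warning(cwt_power(rnorm(100), rate), "2 cycles")
})

test_that("the default catalog has 240 unique names and honest values", {
  spec <- feature_spec()
  expect_equal(spec$size, 240L)
  expect_equal(anyDuplicated(spec$names), 0L)

  # constant-attitude recording: statistics collapse to the constant
  rate <- 300
  n <- 900
  rec <- imu_recording(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                       matrix(0, n, 3), rate)
  kin <- estimate_attitude(rec)
  seg <- fixed_windows(n, 300, rate)
  tab <- suppressWarnings(extract_features(kin, seg))
  expect_equal(dim(tab$features), c(3L, 240L))
  expect_true(all(is.finite(tab$features)))
  expect_equal(unname(tab$features[, "stat_mean_aG_z"]), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(tab$features[, "stat_sd_omega_x"]), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(tab$features[, "corr_aG_x_omega_z"]), rep(0, 3))
  expect_equal(unname(tab$features[, "tilt_pitch"]), rep(0, 3), tolerance = 1e-6)
})

test_that("a planted 10 Hz tone dominates its own band feature", {
  rate <- 300
  n <- 1800
  om <- cbind(rep(0, n), 40 * sin(2 * pi * 10 * (0:(n - 1)) / rate), 0)
  q <- integrate_gyro_R(om, rate)
  aG <- aG_from_quat(q)
  accel <- aG
  accel[, 1] <- accel[, 1] + 0.2 * sin(2 * pi * 10 * (0:(n - 1)) / rate)
  kin <- estimate_attitude(imu_recording(accel, om, rate))
  tab <- extract_features(kin, fixed_windows(n, 600, rate))
  expect_true(all(tab$features[, "cwtpkl_anG_x_mid"] >
                    tab$features[, "cwtpkl_anG_x_low"]))
})

test_that("feature extraction is permutation-equivariant and reproducible", {
  g <- generate_imu(mini_script(seed = 2, duration_s = 20))
  kin <- estimate_attitude(g$recording)
  seg <- kernel_cpd(cpd_input(kin), cpd_params(penalty = 5), 300)
  t1 <- extract_features(kin, seg)
  t2 <- extract_features(kin, seg)
  expect_identical(t1$features, t2$features)
})

test_that("robust rescaling follows the quartile convention", {
  m <- cbind(a = c(0, 1, 2, 3), b = c(5, 5, 5, 5))
  expect_warning(r <- robust_rescale(m), "constant")
  # column {0,1,2,3}: quartiles 0.75/2.25 (type 7), IQR 1.5... value 3 ->
  # (3 - 1.5)/1.5
  expect_equal(unname(r[4, "a"]), (3 - 1.5) / 1.5)
  expect_equal(unname(r[, "b"]), rep(0, 4))
  # v = median -> 0
  expect_equal(unname(r[2, "a"]), (1 - 1.5) / 1.5)
  expect_error(robust_rescale(m[1:3, ]), class = "imuseg_value_error")
})

test_that("outlier and wet-dog-shake rules flag exactly the planted segments", {
  sc <- regime_script(list(
    list(regime = "locomotion", duration = 4),
    list(regime = "wds", duration = 0.5),
    list(regime = "locomotion", duration = 4),
    list(regime = "sniff_locomotion", duration = 4)
  ), seed = 3)
  g <- generate_imu(sc)
  kin <- estimate_attitude(g$recording)
  seg <- segmentation(g$truth$boundaries, 300)
  tab <- flag_outliers(extract_features(kin, seg))
  expect_true(tab$flags$wet_dog_shake[2])
  expect_false(any(tab$flags$wet_dog_shake[-2]))
  expect_equal(which(tab$flags$wds_neighbor), c(1L, 3L))
  expect_true(all(tab$flags$excluded[1:3]))
  expect_false(tab$flags$excluded[4])
})

test_that("a single extreme rescaled value flags only its segment", {
  set.seed(8)
  g <- generate_imu(mini_script(seed = 8, duration_s = 30))
  kin <- estimate_attitude(g$recording)
  seg <- kernel_cpd(cpd_input(kin), cpd_params(penalty = 5), 300)
  tab <- extract_features(kin, seg)
  r <- suppressWarnings(robust_rescale(tab))
  base <- rowSums(abs(r) > 35) > 0
  # plant one absurd feature value in a clean segment
  k <- which(!base)[1]
  med <- median(tab$features[, "stat_mean_aG_z"])
  iqr <- diff(quantile(tab$features[, "stat_mean_aG_z"], c(0.25, 0.75)))
  tab$features[k, "stat_mean_aG_z"] <- med + 40 * iqr
  tab2 <- flag_outliers(tab)
  expect_true(tab2$flags$outlier[k])
})

test_that("immobility fraction matches a direct-convolution oracle", {
  rate <- 300
  # constant angular speeds
  kin_const <- function(speed, n) {
    rec <- imu_recording(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                         cbind(rep(speed, n), 0, 0), rate)
    estimate_attitude(rec)
  }
  seg <- fixed_windows(600, 600, rate)
  expect_equal(immobile_fraction(kin_const(10, 600), seg), 1)
  expect_equal(immobile_fraction(kin_const(30, 600), seg), 0)
  # step 0 -> 100 deg/s at the midpoint
  n <- 1200
  om <- cbind(c(rep(0, n / 2), rep(100, n / 2)), 0, 0)
  kin <- estimate_attitude(imu_recording(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                                         om, rate))
  fr <- immobile_fraction(kin, fixed_windows(n, n, rate))
  expect_equal(fr, 0.5, tolerance = 3 * 0.1 * rate / n + 0.01)
})
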