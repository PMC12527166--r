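# sensor offsets, attitude filtering, gravity decomposition

test_that("gyroscope bias is recovered exactly by the median over immobility", {
  so <- static_orientation_rec(k = 12, gyro_bias = c(1.0, -0.5, 0.2))
  off <- estimate_offsets(so$rec, so$mask)
  expect_equal(off$gyro_offset, c(1.0, -0.5, 0.2), tolerance = 1e-9)
})

test_that("accelerometer bias is recovered by norm-residual least squares", {
  so <- static_orientation_rec(k = 50, accel_bias = c(0.03, -0.02, 0.05),
                               noise_sd = 0.005, seed = 0)
  off <- estimate_offsets(so$rec, so$mask)
  expect_lt(max(abs(off$accel_offset - c(0.03, -0.02, 0.05))), 0.005)
  # zero-bias noise-free input: optimum at the truth
  so0 <- static_orientation_rec(k = 20)
  off0 <- estimate_offsets(so0$rec, so0$mask)
  expect_lt(max(abs(off0$accel_offset)), 1e-6)
  expect_equal(off0$gyro_offset, c(0, 0, 0))
})

test_that("offset estimation guards its preconditions", {
  so <- static_orientation_rec(k = 3)
  expect_warning(estimate_offsets(so$rec, so$mask), "static epoch")
  expect_error(estimate_offsets(so$rec, rep(FALSE, n_samples(so$rec))),
               class = "imuseg_value_error")
  expect_error(sensor_offsets(accel_offset = c(0.9, 0, 0)),
               class = "imuseg_value_error")
})

test_that("static input is an equilibrium of the attitude filter", {
  n <- 600
  rec <- imu_recording(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                       matrix(0, n, 3), 300)
  kin <- estimate_attitude(rec)
  expect_equal(kin$aG[n, ], c(0, 0, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(max(abs(kin$anG)), 0, tolerance = 1e-9)
  expect_lt(diff(range(kin$azimuth)), 1e-6)
  expect_equal(sqrt(rowSums(kin$quat^2)), rep(1, n), tolerance = 1e-6)
})

test_that("noise-free Earth-vertical rotation advances the azimuth correctly", {
  rate <- 300; n <- 10 * rate
  rec <- imu_recording(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                       matrix(rep(c(0, 0, 36), each = n), n, 3), rate)
  kin <- estimate_attitude(rec)
  expect_equal(kin$azimuth[n], 360, tolerance = 2 / 360 * 100)
  expect_lt(max(abs(sqrt(rowSums(kin$aG^2)) - 1)), 1e-6)
  expect_equal(kin$azimuth[1], 0, tolerance = 0.2)
})

test_that("tilt tracks noise-free piecewise-constant rotations within 2 degrees", {
  rate <- 300
  # 1 s still, then a 90-degree pitch over 2 s, then hold
  om <- rbind(matrix(0, rate, 3),
              matrix(rep(c(0, 45, 0), each = 2 * rate), ncol = 3),
              matrix(0, 2 * rate, 3))
  q_true <- integrate_gyro_R(om, rate)
  aG_true <- aG_from_quat(q_true)
  rec <- imu_recording(aG_true, om, rate)
  kin <- estimate_attitude(rec)
  burn <- (rate + 1):nrow(om)
  errs <- vapply(burn, function(i)
    imuseg:::vector_angle_deg(kin$aG[i, ], aG_true[i, ]), numeric(1))
  expect_lt(max(errs), 2)
  # terminal gravity direction on the great circle target
  expect_lt(imuseg:::vector_angle_deg(kin$aG[nrow(om), ], aG_true[nrow(om), ]), 2)
})

test_that("filter output ignores the arbitrary initial azimuth up to an offset", {
  rate <- 300
  set.seed(3)
  om <- matrix(rep(runif(3, -40, 40), each = 2 * rate), ncol = 3)
  q_true <- integrate_gyro_R(om, rate)
  rec <- imu_recording(aG_from_quat(q_true), om, rate)
  kin <- estimate_attitude(rec)
  # rotating the whole Earth frame cannot change aG (a head-frame quantity)
  expect_equal(kin$azimuth[1], 0, tolerance = 0.2)
  expect_lt(imuseg:::vector_angle_deg(kin$aG[nrow(om), ], aG_from_quat(q_true)[nrow(om), ]), 2)
})

test_that("heading change rate follows the angle/duration contract", {
  rate <- 300; n <- 150  # 0.5 s
  om <- matrix(rep(c(0, 0, 180), each = n), ncol = 3)  # 90 deg yaw in 0.5 s
  q <- integrate_gyro_R(om, rate)
  rec <- imu_recording(aG_from_quat(q), om, rate)
  kin <- estimate_attitude(rec)
  expect_equal(heading_change_rate(kin, 0, n), 180, tolerance = 3)
  # no rotation -> 0
  rec0 <- imu_recording(matrix(c(0, 0, 1), 100, 3, byrow = TRUE),
                        matrix(0, 100, 3), rate)
  kin0 <- estimate_attitude(rec0)
  expect_equal(heading_change_rate(kin0, 0, 100), 0, tolerance = 1e-6)
  # +45 then -45 inside one segment -> net 0
  om2 <- rbind(matrix(rep(c(0, 0, 90), each = 150), ncol = 3),
               matrix(rep(c(0, 0, -90), each = 150), ncol = 3))
  q2 <- integrate_gyro_R(om2, rate)
  kin2 <- estimate_attitude(imu_recording(aG_from_quat(q2), om2, rate))
  expect_equal(heading_change_rate(kin2, 0, 300), 0, tolerance = 1.5)
  expect_error(heading_change_rate(kin2, 10, 10), class = "imuseg_value_error")
})

test_that("the gravity split is exact by construction", {
  g <- generate_imu(regime_script(list(
    list(regime = "locomotion", duration = 2),
    list(regime = "orient", duration = 0.2),
    list(regime = "immobile", duration = 2)
  ), seed = 4))
  kin <- estimate_attitude(g$recording)
  expect_equal(kin$aG + kin$anG, g$recording$accel, tolerance = 1e-12,
               ignore_attr = TRUE)
})
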