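# ad-hoc metrics: vMF tilt, net speeds, sniffing score, turns, purity

test_that("vMF tilt formulas evaluate exactly at the canonical directions", {
  t1 <- vmf_tilt(matrix(c(0, 0, 1), 5, 3, byrow = TRUE))
  expect_equal(c(t1$roll, t1$pitch), c(0, 0))
  t2 <- vmf_tilt(rbind(c(0, 1, 0)))
  expect_equal(t2$roll, -90)
  expect_equal(t2$pitch, 0)
  t3 <- vmf_tilt(rbind(c(1, 0, 0)))
  expect_equal(t3$pitch, 90)
  expect_equal(sqrt(sum(t3$mu^2)), 1, tolerance = 1e-9)
  expect_error(vmf_tilt(rbind(c(0, 0, 1), c(0, 0, -1))),
               class = "imuseg_value_error")
})

test_that("vMF tilt is duplication-invariant and z-rotation-equivariant on roll-free input", {
  set.seed(6)
  v <- rbind(c(0.2, 0, 0.98), c(0.25, 0, 0.97), c(0.15, 0, 0.99))
  a <- vmf_tilt(v)
  b <- vmf_tilt(v[rep(1:3, 4), ])
  expect_equal(a$mu, b$mu, tolerance = 1e-12)
  # rotating the samples about the head z-axis rotates mu identically
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- vmf_tilt(v %*% t(R))
  expect_equal(rot$mu, as.numeric(R %*% a$mu), tolerance = 1e-9)
})

test_that("net angular speed uses the start-to-finish relative rotation", {
  rate <- 300
  n <- 150
  om <- matrix(rep(c(0, 180, 0), each = n), ncol = 3)  # 90 deg in 0.5 s
  q <- integrate_gyro_R(om, rate)
  kin <- estimate_attitude(imu_recording(aG_from_quat(q), om, rate))
  r <- net_angular_speed(kin, 0, n)
  expect_equal(r$angle, 90, tolerance = 2)
  expect_equal(r$speed, 180, tolerance = 4)
  # +45 then -45 about one axis -> net 0
  om2 <- rbind(matrix(rep(c(0, 90, 0), each = 150), ncol = 3),
               matrix(rep(c(0, -90, 0), each = 150), ncol = 3))
  q2 <- integrate_gyro_R(om2, rate)
  kin2 <- estimate_attitude(imu_recording(aG_from_quat(q2), om2, rate))
  expect_equal(net_angular_speed(kin2, 0, 300)$angle, 0, tolerance = 2)
  # no rotation -> 0
  kin0 <- estimate_attitude(imu_recording(matrix(c(0, 0, 1), 60, 3, byrow = TRUE),
                                          matrix(0, 60, 3), rate))
  expect_equal(net_angular_speed(kin0, 0, 60)$speed, 0, tolerance = 1e-6)
})

test_that("the sniffing score assembles exactly from its parts", {
  # zero signals -> numerator 0 -> phi 0
  z <- sniffing_phi(0, 0, 0, 0, 0, 0, 0, eta = 0, mu_roll_rad = 0)
  expect_equal(z$phi, 0)
  # alpha halves when eta goes 0 -> 1 at zero roll
  a0 <- sniffing_phi(5, 5, 1, 1, 1, 1, 1, eta = 0, mu_roll_rad = 0)
  a1 <- sniffing_phi(5, 5, 1, 1, 1, 1, 1, eta = 1, mu_roll_rad = 0)
  expect_equal(a0$alpha, 1)
  expect_equal(a1$alpha, 0.5)
  expect_equal(a1$phi, a0$phi / 2)
  # identity phi = alpha * num / den holds exactly
  expect_equal(a1$phi, a1$alpha * a1$numerator / a1$denominator)
})

test_that("phi is monotone decreasing in eta and |roll|", {
  etas <- seq(0, 200, by = 20)
  phis <- sniffing_phi(10, 10, 1, 1, 1, 1, 1, eta = etas, mu_roll_rad = 0)$phi
  expect_true(all(diff(phis) < 0))
  rolls <- seq(0, pi, length.out = 10)
  phir <- sniffing_phi(10, 10, 1, 1, 1, 1, 1, eta = 0, mu_roll_rad = rolls)$phi
  expect_true(all(diff(phir) < 0))
  phirn <- sniffing_phi(10, 10, 1, 1, 1, 1, 1, eta = 0, mu_roll_rad = -rolls)$phi
  expect_equal(phir, phirn)  # penalty depends on |roll|
})

test_that("a 10 Hz tone scores higher than a matched 5 Hz tone", {
  rate <- 300
  n <- 1800
  mk <- function(freq) {
    om <- cbind(0, 40 * sin(2 * pi * freq * (0:(n - 1)) / rate), 0)
    q <- integrate_gyro_R(om, rate)
    accel <- aG_from_quat(q)
    accel[, 1] <- accel[, 1] + 0.15 * sin(2 * pi * freq * (0:(n - 1)) / rate)
    kin <- estimate_attitude(imu_recording(accel, om, rate))
    tab <- extract_features(kin, fixed_windows(n, n, rate))
    sniffing_score(tab)$phi
  }
  expect_gt(mk(10), mk(5))
})

test_that("turns per minute integrates net unwrapped azimuth", {
  rate <- 100
  az <- 36 * (0:(60 * rate)) / rate  # constant 36 deg/s for 60 s
  expect_equal(turns_per_minute(az, rate), 6)
  expect_equal(turns_per_minute(az, rate, direction_sign = -1), -6)
  expect_equal(turns_per_minute(rep(0, 600), rate), 0)
  # +180 then -180: zero net
  az2 <- c(seq(0, 180, length.out = 300), seq(180, 0, length.out = 300))
  expect_equal(turns_per_minute(az2, rate), 0, tolerance = 1e-9)
})

test_that("purity is the modal-category fraction", {
  expect_equal(purity(c("a", "a", "b", "c")), 0.5)
  expect_equal(purity(rep("x", 7)), 1.0)
  expect_equal(purity(rep(c("a", "b", "c", "d"), 25)), 0.25)
  expect_error(purity(character(0)), class = "imuseg_value_error")
})

test_that("azimuth unwrapping removes 360-degree jumps", {
  th <- c(170, 179, -179, -170)  # crosses the 180 boundary
  u <- unwrap_deg(th)
  expect_equal(diff(u), c(9, 2, 9))
  expect_equal(u[1], 170)
})
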