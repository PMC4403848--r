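rotq <- function(angle_deg, axis = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

test_that("quaternion algebra satisfies the closed forms", {
  idq <- c(1, 0, 0, 0)
  a <- rotq(47, c(0.3, -0.5, 0.8))
  expect_equal(quatMultiply(a, idq), a, tolerance = 1e-12)
  expect_equal(quatMultiply(a, quatInverse(a)), idq, tolerance = 1e-12)
  ## 90 deg about x twice = 180 deg about x
  x90 <- rotq(90)
  expect_equal(quatMultiply(x90, x90), rotq(180), tolerance = 1e-12)
  expect_error(quatInverse(c(0, 0, 0, 0)), "zero-norm")

  set.seed(2)
  for (i in 1:25) {
    p <- rotq(runif(1, -180, 180), rnorm(3))
    q <- rotq(runif(1, -180, 180), rnorm(3))
    expect_equal(sqrt(sum(quatMultiply(p, q)^2)), 1, tolerance = 1e-9)
  }
})

test_that("relative and delta quaternions compose rotations about an axis", {
  z30 <- rotq(30, c(0, 0, 1)); z90 <- rotq(90, c(0, 0, 1))
  expect_equal(relativeQuaternion(z30, z90), rotq(60, c(0, 0, 1)),
               tolerance = 1e-12)
  expect_equal(relativeQuaternion(z90, z90), c(1, 0, 0, 0),
               tolerance = 1e-12)
  expect_equal(relativeQuaternion(c(1, 0, 0, 0), z90), z90,
               tolerance = 1e-12)
  expect_equal(deltaQuaternion(z30, z90), rotq(60, c(0, 0, 1)),
               tolerance = 1e-12)
})

test_that("the ROM angle resolves the double cover and clamps", {
  expect_equal(romAngle(c(1, 0, 0, 0)), 0)
  for (theta in c(30, 90, 179)) {
    q <- rotq(theta, c(0.2, 0.7, -0.4))
    expect_equal(romAngle(q), theta, tolerance = 1e-9)
    expect_equal(romAngle(-q), theta, tolerance = 1e-9)
  }
  ## left-invariance of the relative construction
  set.seed(3)
  r <- rotq(runif(1, -180, 180), rnorm(3))
  qref <- rotq(40, c(0, 1, 0)); qrel <- rotq(110, c(0, 1, 0))
  expect_equal(romAngle(deltaQuaternion(quatMultiply(r, qref),
                                        quatMultiply(r, qrel))),
               romAngle(deltaQuaternion(qref, qrel)), tolerance = 1e-9)
})

test_that("ROM traces recover a synthesized knee extension ramp", {
  n <- 300
  ramp <- seq(0, 90, length.out = n)   # shin rotating 0 -> 90 about x
  q_shin <- t(vapply(ramp, function(a) rotq(a), numeric(4)))
  q_thigh <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  rec <- TugRecording(
    rbind(t(q_thigh), t(q_shin)),
    data.frame(site = rep(c("left_thigh", "left_shin"), each = 4),
               quantity = "orientation",
               axis = rep(c("w", "x", "y", "z"), 2)),
    rate_hz = 60)
  rom <- romTrace(rec, "left_knee")
  expect_equal(rom$angles_deg, ramp, tolerance = 0.1)

  ## both segments static in the reference pose: all-zero ROM
  rec0 <- TugRecording(
    rbind(t(q_thigh), t(q_thigh)),
    data.frame(site = rep(c("left_thigh", "left_shin"), each = 4),
               quantity = "orientation",
               axis = rep(c("w", "x", "y", "z"), 2)),
    rate_hz = 60)
  expect_equal(romTrace(rec0, "left_knee")$angles_deg, rep(0, n),
               tolerance = 1e-9)

  expect_error(romTrace(rec0, "right_knee"), "missing")
})

test_that("simulated knee ROM reflects the stand-up and sit-down excursions", {
  sim <- tug_trial(seed = 35)
  tr <- truthTransitions(sim$truth)
  rom <- romTrace(sim$recording, "left_knee")
  t <- (seq_along(rom$angles_deg) - 1) / 60
  ## seated at the reference pose, extended while upright
  expect_lt(mean(rom$angles_deg[t < tr["sit_to_stand"]]), 5)
  upright <- t > tr["stand_to_walk_out"] & t < tr["walk_out_to_turn"]
  expect_gt(mean(rom$angles_deg[upright]), 70)
  expect_lt(mean(rom$angles_deg[t > tr["stand_to_sit"] + 0.2]), 10)
  ## continuity: no inter-sample jump above 90 degrees at 60 Hz
  expect_lt(max(abs(diff(rom$angles_deg))), 90)
  expect_true(all(rom$angles_deg >= 0 & rom$angles_deg < 180))
})
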