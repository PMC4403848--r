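cond_trace <- function(x, rate = 60) {
  attr(x, "rate_hz") <- rate
  x
}

test_that("major extrema are thresholded, thinned and time-ordered", {
  rate <- 60
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  expect_equal(nrow(findMajorExtrema(cond_trace(rep(0, length(t))), "both")),
               0)
  two <- exp(-(t - 10)^2 / 0.5) + exp(-(t - 20)^2 / 0.5)
  pk <- findMajorExtrema(cond_trace(two), "max", min_separation_s = 1)
  expect_equal(pk$time_s, c(10, 20), tolerance = 0.02)

  ## a 0.2-amplitude pulse is below the 30% threshold
  mix <- exp(-(t - 10)^2 / 0.5) + 0.2 * exp(-(t - 20)^2 / 0.5)
  pk <- findMajorExtrema(cond_trace(mix), "max", min_separation_s = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time_s, 10, tolerance = 0.02)

  ## thinning keeps the larger of two close extrema
  close <- exp(-(t - 10)^2 / 0.05) + 0.8 * exp(-(t - 10.5)^2 / 0.05)
  pk <- findMajorExtrema(cond_trace(close), "max", min_separation_s = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time_s, 10, tolerance = 0.02)
})

test_that("stand/sit events follow the hip acceleration derivative sign", {
  sim <- simulateTug(tugParams(seed = 21, noise_sd = 0, drift_slope = 0))
  cfg <- defaultConfig()
  az <- conditionChannel(sim$recording, "trunk", "acceleration", "z", 1.57)
  ay <- conditionChannel(sim$recording, "hip", "acceleration", "y", 1.57)
  ev <- detectStandSit(az, ay, cfg@minSeparationS)
  expect_identical(ev$label, c("Standing", "Sitting"))
  expect_true(all(ev$direction == "none"))
  ## antisymmetry: negating the derivative channel swaps the labels
  ev2 <- detectStandSit(az, cond_trace(-as.numeric(ay)), cfg@minSeparationS)
  expect_identical(ev2$label, c("Sitting", "Standing"))

  ## default-noise trials localize the events near the truth peaks
  sim <- tug_trial(seed = 22)
  tr <- truthTransitions(sim$truth)
  az <- conditionChannel(sim$recording, "trunk", "acceleration", "z", 1.57)
  ay <- conditionChannel(sim$recording, "hip", "acceleration", "y", 1.57)
  ev <- detectStandSit(az, ay, cfg@minSeparationS)
  stand_mid <- mean(tr[c("sit_to_stand", "stand_to_walk_out")])
  sit_mid <- mean(tr[c("turn_to_stand", "stand_to_sit")])
  expect_lt(abs(ev$peak_time_s[ev$label == "Standing"] - stand_mid), 0.25)
  expect_lt(abs(ev$peak_time_s[ev$label == "Sitting"] - sit_mid), 0.25)
})

test_that("turning requires same-sign head verification", {
  sim <- simulateTug(tugParams(seed = 23, noise_sd = 0, drift_slope = 0))
  cfg <- defaultConfig()
  wy <- conditionChannel(sim$recording, "trunk", "angular_velocity", "y", 1.0)
  hy <- conditionChannel(sim$recording, "head", "angular_velocity", "y", 1.0)
  ev <- detectTurning(wy, hy, min_separation_s = cfg@minSeparationS)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$label == "Turning"))
  expect_true(all(ev$direction == "left"))

  ## flat head channel: unverified events are dropped
  flat <- cond_trace(rep(0, length(wy)))
  expect_equal(nrow(detectTurning(wy, flat,
                                  min_separation_s = cfg@minSeparationS)), 0)
  ## opposite-sign head channel: dropped too
  neg <- cond_trace(-as.numeric(hy))
  expect_equal(nrow(detectTurning(wy, neg,
                                  min_separation_s = cfg@minSeparationS)), 0)
})

test_that("walking mask covers oscillation support and nothing else", {
  rate <- 60
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  expect_error(detectWalking(cond_trace(rep(0, 10)), window_s = 1),
               "longer than the trial")
  expect_true(all(!detectWalking(cond_trace(rep(0, length(t))))))

  x <- ifelse(t >= 5 & t <= 15, sin(2 * pi * 1.8 * t), 0)
  mask <- detectWalking(cond_trace(x))
  on <- range(t[mask])
  expect_lt(abs(on[1] - 5), 0.55)
  expect_lt(abs(on[2] - 15), 0.55)
  expect_true(all(!mask[t < 4.4]))
  expect_true(all(!mask[t > 15.6]))

  ## simulated trial: mask against true walking intervals, Jaccard >= 0.8
  sim <- tug_trial(seed = 24)
  cls <- classifyTrial(sim$recording)
  truth_walk <- truthLabels(sim$truth) == "Walking"
  jac <- sum(cls$walking_mask & truth_walk) /
    sum(cls$walking_mask | truth_walk)
  expect_gte(jac, 0.8)
})

test_that("square signals mark the 30% contiguous region around a peak", {
  rate <- 60
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  tri <- pmax(0, 1 - abs(t - 5))            # unit triangle at t = 5
  ev <- data.frame(peak_time_s = 5, peak_value = 1)
  sq <- squareSignal(cond_trace(tri), ev, 0.30)
  expect_identical(sq, tri > 0.3)
  ## fraction near 1 shrinks the region to the peak sample
  sq1 <- squareSignal(cond_trace(tri), ev, 0.999)
  expect_lte(sum(sq1), 3)
  expect_true(sq1[round(5 * rate) + 1])
  expect_error(squareSignal(cond_trace(tri), ev, 1.2), "fraction")

  ## simulated turn pulse: square duration is a stable fraction of the turn
  sim <- tug_trial(seed = 25)
  cls <- classifyTrial(sim$recording)
  turn_sq <- cls$square_signals[[grep("Turning", names(cls$square_signals))[1]]]
  segs <- truthSegments(sim$truth)
  turn_len <- segs$end_s[3] - segs$start_s[3]
  expect_gt(sum(turn_sq) / 60, 0.4 * turn_len)
  expect_lt(sum(turn_sq) / 60, 0.9 * turn_len)
})

test_that("turn priority and scale invariance hold for classification", {
  sim <- tug_trial(seed = 26)
  cls <- classifyTrial(sim$recording)
  peaks <- cls$events[cls$events$label != "Walking", ]
  expect_identical(peaks$label, c("Standing", "Turning", "Turning", "Sitting"))
  ## no sample is labeled Walking inside any turning square region
  for (nm in grep("Turning", names(cls$square_signals), value = TRUE)) {
    expect_true(all(cls$labels[cls$square_signals[[nm]]] != "Walking"))
  }
  ## walking is detected during the first turn but relabeled Turning
  segs <- truthSegments(sim$truth)
  turn1 <- seq(round(segs$start_s[3] * 60) + 1, round(segs$end_s[3] * 60))
  expect_gt(sum(cls$walking_mask[turn1]), 0)
  expect_true(all(cls$labels[turn1][cls$walking_mask[turn1]] != "Walking"))

  ## multiplying any raw channel by a positive constant changes nothing
  rec2 <- sim$recording
  m <- assay(rec2, "samples")
  i <- which(rownames(m) == "trunk.angular_velocity.y")
  m[i, ] <- 7.3 * m[i, ]
  SummarizedExperiment::assay(rec2, "samples") <- m
  cls2 <- classifyTrial(rec2)
  expect_equal(cls2$events$peak_time_s, cls$events$peak_time_s)
  expect_identical(cls2$events$label, cls$events$label)
})
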