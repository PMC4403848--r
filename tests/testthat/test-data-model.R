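test_that("TugRecording validates channels and renormalizes quaternions", {
  n <- 100
  q <- matrix(rep(c(1, 0, 0, 0) * 1.0005, n), nrow = 4)
  rec <- TugRecording(
    rbind(matrix(rnorm(n), 1), q),
    data.frame(site = c("trunk", rep("left_thigh", 4)),
               quantity = c("acceleration", rep("orientation", 4)),
               axis = c("z", "w", "x", "y", "z")),
    rate_hz = 60)
  expect_s4_class(rec, "TugRecording")
  expect_equal(unname(rowSums(orientationTrace(rec, "left_thigh")^2)),
               rep(1, n), tolerance = 1e-12)
  expect_equal(durationS(rec), n / 60)

  expect_error(TugRecording(matrix(0, 0, 0), data.frame()), "no channels")
  expect_error(TugRecording(
    rbind(matrix(rnorm(n), 1), q * 3),
    data.frame(site = c("trunk", rep("left_thigh", 4)),
               quantity = c("acceleration", rep("orientation", 4)),
               axis = c("z", "w", "x", "y", "z"))),
    "far from unit norm")
})

test_that("missing channels raise errors naming the absent site/quantity", {
  rec <- vector_recording(rnorm(100))
  expect_error(getChannel(rec, "trunk", "angular_velocity", "y"),
               "missing trunk angular_velocity")
  expect_error(classifyTrial(rec), "missing")
  expect_true(hasChannel(rec, "trunk", "acceleration"))
  expect_false(hasChannel(rec, "hip", "acceleration"))
})

test_that("trial files round-trip losslessly through the columnar format", {
  dir <- withr::local_tempdir()
  for (seed in 1:3) {
    sim <- simulateTug(tugParams(distance_m = 5, seed = seed,
                                 walk_speed_mps = 2.5))
    path <- file.path(dir, paste0("t", seed, ".csv"))
    writeTrial(sim$recording, path)
    back <- readTrial(path)
    expect_equal(assay(back, "samples"), assay(sim$recording, "samples"),
                 tolerance = 1e-9)
    expect_identical(channelInfo(back), channelInfo(sim$recording))
    expect_equal(rateHz(back), rateHz(sim$recording))
    expect_equal(distanceM(back), 5)
  }
})

test_that("a full 17-site trial writes 17 x (3 + 3 + 4) channels of rows", {
  dir <- withr::local_tempdir()
  sim <- simulateTug(tugParams(distance_m = 5, seed = 1,
                               walk_speed_mps = 2.5), sites = "full")
  n <- ncol(sim$recording)
  expect_equal(nrow(sim$recording), 17 * 10)
  path <- file.path(dir, "full.csv")
  writeTrial(sim$recording, path)
  ## header comment + column header + one row per (channel, sample)
  expect_equal(length(readLines(path)), 2L + 17L * 10L * n)
})

test_that("ground truth JSON sidecars round-trip", {
  dir <- withr::local_tempdir()
  sim <- tug_trial(seed = 6)
  path <- file.path(dir, "truth.json")
  writeGroundTruth(sim$truth, path)
  back <- readGroundTruth(path)
  expect_equal(truthTransitions(back), truthTransitions(sim$truth))
  expect_equal(truthSegments(back), truthSegments(sim$truth))
  expect_identical(truthLabels(back), truthLabels(sim$truth))
})

test_that("default config encodes the calibrated cutoff table", {
  cfg <- loadConfig("defaults")
  tab <- defaultCutoffTable()
  expect_equal(nrow(tab), 14)
  get_w2 <- function(transition, site, quantity, axis) {
    tab$w2_hz[tab$transition == transition & tab$site == site &
                tab$quantity == quantity & tab$axis == axis]
  }
  expect_equal(get_w2("sit_to_stand", "trunk", "acceleration", "z"), 1.57)
  expect_equal(get_w2("sit_to_stand", "hip", "angular_velocity", "x"), 0.69)
  expect_equal(get_w2("stand_to_walk_out", "trunk", "acceleration", "z"), 2.44)
  expect_equal(get_w2("stand_to_walk_out", "left_knee", "rom", "theta"), 8.30)
  expect_equal(get_w2("walk_out_to_turn", "trunk", "angular_velocity", "y"), 1.32)
  expect_equal(get_w2("walk_out_to_turn", "head", "angular_velocity", "x"), 0.79)
  expect_equal(get_w2("walk_out_to_turn", "hip", "angular_velocity", "y"), 0.98)
  expect_equal(get_w2("turn_to_walk_in", "hip", "angular_velocity", "y"), 0.53)
  expect_equal(get_w2("turn_to_walk_in", "head", "angular_velocity", "x"), 0.41)
  expect_equal(get_w2("walk_in_to_turn", "trunk", "angular_velocity", "y"), 1.00)
  expect_equal(get_w2("walk_in_to_turn", "hip", "angular_velocity", "y"), 0.59)
  expect_equal(get_w2("turn_to_stand", "trunk", "angular_velocity", "y"), 1.00)
  expect_equal(get_w2("turn_to_stand", "hip", "angular_velocity", "y"), 0.81)
  expect_equal(get_w2("stand_to_sit", "hip", "acceleration", "z"), 1.07)

  expect_equal(cfg@w1Hz, 0.0025)
  expect_equal(cfg@walkingW2Hz, 30)
  expect_equal(cfg@thresholdFraction, 0.30)
  expect_equal(cfg@walkingWindowS, 0.5)
  ## the transition combinations carry the same frequencies
  expect_equal(cfg@transitions$stand_to_walk_out$channels$w2_hz[1], 2.44)
  ## turn-to-walk-in uses the hip lateral angular velocity alone
  expect_equal(nrow(cfg@transitions$turn_to_walk_in$channels), 1)
  expect_equal(cfg@transitions$turn_to_walk_in$channels$site, "hip")
})

test_that("config files merge onto defaults and invalid values are rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  writeLines(c("threshold_fraction: 0.25",
               "transitions:",
               "  turn_to_walk_in:",
               "    channels:",
               "      - {site: trunk, quantity: angular_velocity, axis: y, w2_hz: 0.8}"),
             path)
  cfg <- loadConfig(path)
  expect_equal(cfg@thresholdFraction, 0.25)
  expect_equal(cfg@transitions$turn_to_walk_in$channels$w2_hz, 0.8)
  expect_equal(cfg@transitions$sit_to_stand$channels$w2_hz, c(1.57, 0.69))

  writeLines("threshold_fraction: 1.5", path)
  expect_error(loadConfig(path), "thresholdFraction")
  writeLines(c("w1_hz: 5"), path)   # above several configured w2 values
  expect_error(loadConfig(path), "w1")
})
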