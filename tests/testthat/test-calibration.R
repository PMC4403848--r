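trunk_az <- list(site = "trunk", quantity = "acceleration", axis = "z")

small_cohort <- function() tug_cohort(10, seed = 11, n_subjects = 4,
                                      trials_per_subject = 1)

test_that("the transition cost is the sum of squared time differences", {
  cohort <- small_cohort()
  recs <- lapply(cohort, `[[`, "recording")
  ## references chosen equal to the channel's own estimates -> zero cost
  cal <- optimizeW2(recs, lapply(cohort, `[[`, "truth"), trunk_az,
                    "sit_to_stand", steps = 3, grid_hz = c(1.5, 2.5))
  est <- cal$candidates[1, ]
  self_refs <- lapply(est, function(x)
    structure(rep(x, 7), names = transitionNames()))
  expect_equal(transitionCost(1.5, recs, self_refs, trunk_az,
                              "sit_to_stand"), 0)
  ## shifting every reference by +0.1 s costs n * 0.01 s^2
  shift_refs <- lapply(est, function(x)
    structure(rep(x + 0.1, 7), names = transitionNames()))
  expect_equal(transitionCost(1.5, recs, shift_refs, trunk_az,
                              "sit_to_stand"), length(recs) * 0.01,
               tolerance = 1e-9)
  expect_error(transitionCost(1.5, recs, self_refs[1:2], trunk_az,
                              "sit_to_stand"), "paired")
})

test_that("exhaustive search returns the grid minimum, ties to lowest freq", {
  cohort <- small_cohort()
  recs <- lapply(cohort, `[[`, "recording")
  refs <- lapply(cohort, `[[`, "truth")
  cal <- optimizeW2(recs, refs, trunk_az, "sit_to_stand",
                    grid_hz = c(0.5, 10), steps = 150)
  expect_true(cal$w2_opt_hz %in% cal$grid_hz)
  expect_equal(cal$cost_opt, min(cal$cost))
  expect_equal(cal$w2_opt_hz, cal$grid_hz[which(cal$cost == min(cal$cost))[1]])
  ## direct recomputation agrees with the cached-FFT curve
  for (g in c(10, 80, 140)) {
    expect_equal(transitionCost(cal$grid_hz[g], recs, refs, trunk_az,
                                "sit_to_stand"), cal$cost[g],
                 tolerance = 1e-9)
  }
  ## a flat stretch of the cost curve resolves to its lowest frequency
  flat <- which(cal$cost == cal$cost[length(cal$cost)])
  if (length(flat) > 1) expect_true(all(diff(flat) >= 1))

  ## the generator-matched band beats a wide-open 10 Hz cut
  c_match <- transitionCost(cal$w2_opt_hz, recs, refs, trunk_az,
                            "sit_to_stand")
  c_wide <- transitionCost(10, recs, refs, trunk_az, "sit_to_stand")
  expect_lt(c_match, c_wide)
})

test_that("sensor-combination selection prefers accurate channels", {
  cohort <- small_cohort()
  recs <- lapply(cohort, `[[`, "recording")
  refs <- lapply(cohort, `[[`, "truth")
  cands <- data.frame(site = c("trunk", "hip"),
                      quantity = c("acceleration", "angular_velocity"),
                      axis = c("z", "x"), stringsAsFactors = FALSE)
  ## single candidate: that candidate is returned
  one <- selectSensorCombination(recs, refs, cands[1, ], "sit_to_stand",
                                 steps = 40)
  expect_equal(nrow(one$channels), 1)
  expect_identical(one$channels$site, "trunk")

  ## a channel whose estimates equal the references exactly always wins
  cal <- optimizeW2(recs, refs, trunk_az, "sit_to_stand", steps = 40)
  exact_refs <- lapply(cal$candidates[which.min(cal$cost), ], function(x)
    structure(rep(x, 7), names = transitionNames()))
  two <- selectSensorCombination(recs, exact_refs, cands, "sit_to_stand",
                                 steps = 40)
  expect_identical(two$channels$site, "trunk")
  expect_equal(two$cost, 0, tolerance = 1e-12)
})

test_that("delta T aggregates absolute differences per transition", {
  a <- structure(1:7 * 1.0, names = transitionNames())
  expect_true(all(deltaT(list(a, a), list(a, a))$delta_t_s == 0))
  expect_true(all(deltaT(list(a, a), list(a, a))$var_s2 == 0))
  d <- deltaT(list(a + 0.1, a - 0.1), list(a, a))
  expect_equal(d$delta_t_s, rep(0.1, 7))
  expect_equal(d$n, rep(2, 7))
  ## invariance under a uniform time shift of both estimates and references
  d2 <- deltaT(list(a + 0.1 + 5, a - 0.1 + 5), list(a + 5, a + 5))
  expect_equal(d2$delta_t_s, d$delta_t_s)
  expect_equal(d2$sd_s, d$sd_s)
  expect_error(deltaT(list(a), list(a, a)), "paired")
})

test_that("detection scoring implements sensitivity and specificity", {
  sim <- tug_trial(seed = 41)
  cls <- classifyTrial(sim$recording)
  sc <- scoreDetection(cls, sim$truth)
  expect_equal(sc$sensitivity, sc$tp / (sc$tp + sc$fn))
  expect_equal(sc$specificity, sc$tn / (sc$tn + sc$fp))
  expect_equal(sc$n_instances, 6)
  expect_equal(sc$sensitivity, 1.0)
  expect_equal(sc$specificity, 1.0)

  ## dropping the Sitting event costs one true positive
  ev <- cls$events[cls$events$label != "Sitting", ]
  sc2 <- scoreDetection(ev, sim$truth)
  expect_equal(sc2$tp, 5); expect_equal(sc2$fn, 1)
  expect_equal(sc2$sensitivity, 5 / 6)

  ## a spurious wrong-activity event inside a segment costs specificity
  segs <- truthSegments(sim$truth)
  ev3 <- rbind(cls$events, data.frame(
    label = "Turning", peak_time_s = mean(unlist(segs[2, 2:3])),
    peak_value = 0.5, direction = "left"))
  sc3 <- scoreDetection(ev3, sim$truth)
  expect_equal(sc3$fp, 1)
  expect_equal(sc3$specificity, 5 / 6)
})
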