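## Synthetic TUG trial generator.  Emits the kinematic signatures the
## detection algorithm keys on -- a stand-up pulse in trunk vertical
## acceleration (with rising hip acceleration), two large yaw
## angular-velocity pulses for the 180-degree turns, rhythmic hip angular
## velocity during walking, a sit-down pulse, and knee-flexion quaternion
## excursions -- plus linear sensor drift and broadband noise, together
## with ground-truth segments and the seven transition timestamps.
##
## Activity pulses are single-cycle cosines shaped so that a dominant
## central peak is flanked by stationary minima lying exactly at the
## segment boundaries (the counter-movement dips real stand/turn signals
## show); the pulse carrier frequencies sit below every calibrated
## high-cut band, so conditioning preserves the boundary extrema that the
## first-extremum segmentation rule recovers.

#' Simulation parameters for a TUG trial
#'
#' @param distance_m Walkway length in meters (5 or 10).
#' @param walk_speed_mps Gait speed, m/s.
#' @param stride_freq_hz Stride oscillation frequency of the hip angular
#'   velocity during walking (Hz).
#' @param stand_duration_s,turn_duration_s,sit_duration_s Durations of the
#'   stand-up, each 180-degree turn, and sit-down phases (s).
#' @param lead_in_s,lead_out_s Quiet sitting before/after the task (s).
#' @param rate_hz Sampling rate (60 Hz).
#' @param turn_direction +1 (left) or -1 (right) yaw sign of both turns.
#' @param amplitudes Named list of per-channel pulse amplitudes (unitless;
#'   signals are normalized downstream).
#' @param drift_slope Maximum magnitude of the per-channel linear drift
#'   (units/s); each channel draws its slope uniformly within that bound.
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   acceleration/angular-velocity channels.
#' @param orientation_noise Component-level jitter of the orientation
#'   quaternions (renormalized afterwards).
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#' @return A list of class \code{"tug_params"}.
#' @export
tugParams <- function(distance_m = 10, walk_speed_mps = 1.05,
                      stride_freq_hz = 1.8,
                      stand_duration_s = 1.8, turn_duration_s = 3.0,
                      sit_duration_s = 1.8,
                      lead_in_s = 0.8, lead_out_s = 0.8,
                      rate_hz = 60, turn_direction = 1,
                      amplitudes = list(), drift_slope = 0.02,
                      noise_sd = 0.02, orientation_noise = 0.002,
                      seed = NULL) {
  amp <- list(trunk_az = 1, hip_az = 0.8, hip_ay = 0.9,
              trunk_wy = 1, head_wy = 0.9, head_wx = 0.7,
              hip_wy_turn = 0.8, hip_wx_walk = 1, hip_wy_walk = 0.15,
              hip_wx_stand = 0.8,
              knee_deg = 90, knee_overshoot_deg = 8, knee_swing_deg = 6)
  amp[names(amplitudes)] <- amplitudes
  p <- list(distance_m = distance_m, walk_speed_mps = walk_speed_mps,
            stride_freq_hz = stride_freq_hz,
            stand_duration_s = stand_duration_s,
            turn_duration_s = turn_duration_s,
            sit_duration_s = sit_duration_s,
            lead_in_s = lead_in_s, lead_out_s = lead_out_s,
            rate_hz = rate_hz, turn_direction = turn_direction,
            amplitudes = amp, drift_slope = drift_slope,
            noise_sd = noise_sd, orientation_noise = orientation_noise,
            seed = seed)
  stopifnot(distance_m > 0, walk_speed_mps > 0, stride_freq_hz > 0,
            stand_duration_s > 0, turn_duration_s > 0, sit_duration_s > 0,
            noise_sd >= 0, rate_hz > 0)
  class(p) <- "tug_params"
  p
}

## smooth step on [0, 1]
.sstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

## raised-cosine bump on [a, b], zero outside
.bump <- function(tt, a, b) {
  u <- (tt - a) / (b - a)
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

## Activity pulse on [a, b]: a raised-cosine bump on a shallow negative
## pedestal.  The value is exactly -depth at a and b with zero slope
## (stationary counter-movement minima at the segment boundaries, kept
## well below the 30% detection threshold), rises strictly monotonically
## to +1 at the center (no interior extrema), and tapers smoothly to zero
## outside.
.cyclePulse <- function(tt, a, b, taper = 1.0, depth = 0.1) {
  u <- (tt - a) / (b - a)
  core <- ifelse(u >= 0 & u <= 1,
                 (1 + depth) * 0.5 * (1 - cos(2 * pi * u)) - depth,
                 0)
  lft <- tt >= a - taper & tt < a
  rgt <- tt > b & tt <= b + taper
  core[lft] <- -depth * 0.5 * (1 + cos(pi * (a - tt[lft]) / taper))
  core[rgt] <- -depth * 0.5 * (1 + cos(pi * (tt[rgt] - b) / taper))
  core
}

## rotation about the x axis by ang (degrees) as rows [w x y z]
.rotxQuat <- function(ang_deg) {
  h <- ang_deg * pi / 360
  cbind(cos(h), sin(h), 0 * h, 0 * h)
}

#' Simulate one TUG trial
#'
#' Generates a \linkS4class{TugRecording} with the channels the default
#' configuration uses (trunk a_z; hip a_y, a_z, omega_x, omega_y; trunk and
#' head omega_y; head omega_x; orientation quaternions for the hip, left
#' thigh and left shin) plus matching \linkS4class{TugGroundTruth}.
#'
#' @param params A \code{\link{tugParams}} list.
#' @param sites \code{"minimal"} (default) emits only the channels the
#'   default pipeline needs; \code{"full"} pads the remaining suit sites
#'   with drift + noise channels so all 17 sites are present.
#' @return List with elements \code{recording} and \code{truth}.
#' @examples
#' sim <- simulateTug(tugParams(distance_m = 10, seed = 1))
#' durationS(sim$recording)
#' truthTransitions(sim$truth)
#' @export
simulateTug <- function(params = tugParams(), sites = c("minimal", "full")) {
  sites <- match.arg(sites)
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  walk_s <- p$distance_m / p$walk_speed_mps
  if (walk_s < 1 / p$stride_freq_hz)
    stop("degenerate walk: walking segment shorter than one stride period")
  t1 <- p$lead_in_s
  t2 <- t1 + p$stand_duration_s
  t3 <- t2 + walk_s
  t4 <- t3 + p$turn_duration_s
  t5 <- t4 + walk_s
  t6 <- t5 + p$turn_duration_s
  t7 <- t6 + p$sit_duration_s
  duration <- t7 + p$lead_out_s
  rate <- p$rate_hz
  n <- round(duration * rate)
  tt <- (0:(n - 1)) / rate
  amp <- p$amplitudes

  stand_cycle <- .cyclePulse(tt, t1, t2)
  sit_cycle <- .cyclePulse(tt, t6, t7)
  turn_core <- (.cyclePulse(tt, t3, t4) + .cyclePulse(tt, t5, t6)) *
    p$turn_direction
  updown <- .sstep((tt - t1) / p$stand_duration_s) -
    .sstep((tt - t6) / p$sit_duration_s)
  env <- .sstep((tt - t2) / 0.6) * (1 - .sstep((tt - (t5 - 0.6)) / 0.6))
  ## stepping amplitude is reduced over the whole first turn; the ramps
  ## sit just outside [t3, t4] so full-amplitude walking never overlaps
  ## the turn segment
  inturn1 <- .sstep((tt - (t3 - 0.3)) / 0.3) * (1 - .sstep((tt - t4) / 0.3))
  env <- env * (1 - 0.6 * inturn1)
  osc <- sin(2 * pi * p$stride_freq_hz * (tt - t2))

  sig <- list(
    trunk.acceleration.z = amp$trunk_az * (stand_cycle - sit_cycle),
    hip.acceleration.y = amp$hip_ay * updown,
    hip.acceleration.z = amp$hip_az * (stand_cycle - sit_cycle),
    trunk.angular_velocity.y = amp$trunk_wy * turn_core,
    head.angular_velocity.y = amp$head_wy * turn_core,
    head.angular_velocity.x = amp$head_wx * turn_core,
    hip.angular_velocity.x = amp$hip_wx_walk * env * osc +
      amp$hip_wx_stand * stand_cycle,
    hip.angular_velocity.y = amp$hip_wy_turn * turn_core +
      amp$hip_wy_walk * env * osc)

  ## thigh pitch: 90 deg (seated) -> 0 (upright), slight extension
  ## overshoot at the end of stand-up, stride swing while walking
  thigh_deg <- amp$knee_deg * (1 - .sstep((tt - t1) / p$stand_duration_s) +
                               .sstep((tt - t6) / p$sit_duration_s)) -
    amp$knee_overshoot_deg * .bump(tt, t2 - 0.3, t2 + 0.3) +
    amp$knee_swing_deg * env * osc

  chan <- do.call(rbind, strsplit(names(sig), ".", fixed = TRUE))
  values <- do.call(rbind, sig)
  ## linear drift + broadband noise on every inertial channel
  for (i in seq_len(nrow(values))) {
    slope <- p$drift_slope * runif(1, -1, 1)
    values[i, ] <- values[i, ] + slope * tt + rnorm(n, 0, p$noise_sd)
  }
  channels <- data.frame(site = chan[, 1], quantity = chan[, 2],
                         axis = chan[, 3], stringsAsFactors = FALSE)

  quat <- list(hip = .rotxQuat(rep(0, n)),
               left_thigh = .rotxQuat(thigh_deg),
               left_shin = .rotxQuat(rep(0, n)))
  for (s in names(quat)) {
    q <- quat[[s]] + matrix(rnorm(4 * n, 0, p$orientation_noise), n, 4)
    values <- rbind(values, t(q))
    channels <- rbind(channels, data.frame(
      site = s, quantity = "orientation", axis = c("w", "x", "y", "z"),
      stringsAsFactors = FALSE))
  }

  if (sites == "full") {
    ## pad every suit site to the complete 3 + 3 + 4 channel set with
    ## drift + noise (and identity orientations) where the template has
    ## no modeled movement
    for (s in sensorSites()) {
      for (qty in c("acceleration", "angular_velocity")) {
        have <- channels$axis[channels$site == s & channels$quantity == qty]
        for (ax in setdiff(c("x", "y", "z"), have)) {
          values <- rbind(values,
                          p$drift_slope * runif(1, -1, 1) * tt +
                            rnorm(n, 0, p$noise_sd))
          channels <- rbind(channels, data.frame(
            site = s, quantity = qty, axis = ax, stringsAsFactors = FALSE))
        }
      }
      if (!any(channels$site == s & channels$quantity == "orientation")) {
        q <- .rotxQuat(rep(0, n)) +
          matrix(rnorm(4 * n, 0, p$orientation_noise), n, 4)
        values <- rbind(values, t(q))
        channels <- rbind(channels, data.frame(
          site = s, quantity = "orientation", axis = c("w", "x", "y", "z"),
          stringsAsFactors = FALSE))
      }
    }
  }

  rec <- TugRecording(values, channels, rate_hz = rate,
                      subject_id = "S01", trial_id = "T1",
                      distance_m = p$distance_m)

  transitions <- c(t1, t2, t3, t4, t5, t6, t7)
  names(transitions) <- transitionNames()
  segments <- data.frame(name = segmentNames(),
                         start_s = unname(transitions[-7]),
                         end_s = unname(transitions[-1]),
                         stringsAsFactors = FALSE)
  seg_labels <- c("Standing", "Walking", "Turning", "Walking", "Turning",
                  "Sitting")
  labels <- rep("Idle", n)
  for (k in 1:6) {
    labels[tt >= segments$start_s[k] & tt < segments$end_s[k]] <- seg_labels[k]
  }
  truth <- new("TugGroundTruth", segments = segments,
               transitions = transitions, labels = labels, rateHz = rate)
  list(recording = rec, truth = truth)
}

#' Simulate a cohort of TUG trials
#'
#' Draws per-subject parameters by jittering the base parameters by a
#' fractional spread (durations, gait speed, stride frequency and channel
#' amplitudes each scaled by an independent uniform factor in
#' \code{[1 - variability, 1 + variability]}), then simulates
#' \code{trials_per_subject} trials per subject with independent noise.
#' Fully deterministic under a fixed \code{seed}.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param trials_per_subject Trials per subject.
#' @param distance_m TUG distance for every trial.
#' @param base_params Baseline \code{\link{tugParams}}; defaults to
#'   \code{tugParams(distance_m = distance_m)}.
#' @param variability Fractional spread (>= 0), default 0.1.
#' @param seed Integer seed for the cohort.
#' @return List of \code{n_subjects * trials_per_subject} elements, each
#'   \code{list(recording, truth)} with subject/trial identifiers set.
#' @export
simulateCohort <- function(n_subjects, trials_per_subject = 2,
                           distance_m = 10, base_params = NULL,
                           variability = 0.1, seed = 1) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (variability < 0) stop("variability must be non-negative")
  if (is.null(base_params)) base_params <- tugParams(distance_m = distance_m)
  set.seed(seed)
  jit <- function(x) x * runif(1, 1 - variability, 1 + variability)
  out <- vector("list", n_subjects * trials_per_subject)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    p <- base_params
    p$distance_m <- distance_m
    p$walk_speed_mps <- jit(p$walk_speed_mps)
    p$stride_freq_hz <- jit(p$stride_freq_hz)
    p$stand_duration_s <- jit(p$stand_duration_s)
    p$turn_duration_s <- jit(p$turn_duration_s)
    p$sit_duration_s <- jit(p$sit_duration_s)
    for (a in c("trunk_az", "hip_az", "hip_ay", "trunk_wy", "head_wy",
                "head_wx", "hip_wy_turn", "hip_wx_walk", "hip_wx_stand"))
      p$amplitudes[[a]] <- jit(p$amplitudes[[a]])
    trial_seeds <- sample.int(.Machine$integer.max, trials_per_subject)
    for (j in seq_len(trials_per_subject)) {
      p$seed <- trial_seeds[j]
      sim <- simulateTug(p)
      metadata(sim$recording)$subject_id <- sprintf("S%02d", i)
      metadata(sim$recording)$trial_id <- sprintf("T%d", j)
      k <- k + 1L
      out[[k]] <- sim
    }
  }
  out
}
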