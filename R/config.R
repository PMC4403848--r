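## Default configuration: the calibrated per-channel high-cut frequencies
## and sensor combinations for the 10 m TUG, plus detector parameters.

#' Calibrated high-cut frequency table
#'
#' The optimized high cutoff frequency (Hz) of every sensor channel used at
#' each of the seven transitions, as calibrated on the 10 m task.  The
#' lateral angular-velocity entries are stored as axis \code{y} of the
#' gyroscope (omega_y).
#'
#' @return data.frame with columns \code{transition}, \code{site},
#'   \code{quantity}, \code{axis}, \code{w2_hz} (14 rows).
#' @export
defaultCutoffTable <- function() {
  data.frame(
    transition = c("sit_to_stand", "sit_to_stand",
                   "stand_to_walk_out", "stand_to_walk_out",
                   "walk_out_to_turn", "walk_out_to_turn", "walk_out_to_turn",
                   "turn_to_walk_in", "turn_to_walk_in",
                   "walk_in_to_turn", "walk_in_to_turn",
                   "turn_to_stand", "turn_to_stand",
                   "stand_to_sit"),
    site = c("trunk", "hip",
             "trunk", "left_knee",
             "trunk", "head", "hip",
             "hip", "head",
             "trunk", "hip",
             "trunk", "hip",
             "hip"),
    quantity = c("acceleration", "angular_velocity",
                 "acceleration", "rom",
                 "angular_velocity", "angular_velocity", "angular_velocity",
                 "angular_velocity", "angular_velocity",
                 "angular_velocity", "angular_velocity",
                 "angular_velocity", "angular_velocity",
                 "acceleration"),
    axis = c("z", "x",
             "z", "theta",
             "y", "x", "y",
             "y", "x",
             "y", "y",
             "y", "y",
             "z"),
    w2_hz = c(1.57, 0.69,
              2.44, 8.30,
              1.32, 0.79, 0.98,
              0.53, 0.41,
              1.00, 0.59,
              1.00, 0.81,
              1.07),
    stringsAsFactors = FALSE)
}

.transitionChannels <- function(tab, transition, drop_sites = NULL) {
  ch <- tab[tab$transition == transition, c("site", "quantity", "axis", "w2_hz")]
  if (!is.null(drop_sites)) ch <- ch[!ch$site %in% drop_sites, ]
  rownames(ch) <- NULL
  ch
}

#' Default segmentation configuration
#'
#' Encodes the calibrated sensor/frequency assignments for all seven
#' transitions, the low cutoff \code{w1 = 0.0025} Hz shared by every
#' conditioned channel, the Nyquist (30 Hz) high cut for the walking
#' channel, and the detector parameters (30\% peak threshold, 0.5 s walking
#' window).  The \code{turn_to_walk_in} combination uses the hip
#' lateral angular velocity alone, the combination that best matched the
#' reference segmentation.
#'
#' @return A validated \linkS4class{SegmentationConfig}.
#' @examples
#' cfg <- defaultConfig()
#' cfg@transitions$stand_to_walk_out$channels
#' @export
defaultConfig <- function() {
  tab <- defaultCutoffTable()
  transitions <- list(
    sit_to_stand = list(anchor = "standing", side = "left",
                        channels = .transitionChannels(tab, "sit_to_stand")),
    stand_to_walk_out = list(anchor = "standing", side = "right",
                             channels = .transitionChannels(tab, "stand_to_walk_out")),
    walk_out_to_turn = list(anchor = "turning1", side = "left",
                            channels = .transitionChannels(tab, "walk_out_to_turn")),
    turn_to_walk_in = list(anchor = "turning1", side = "right",
                           channels = .transitionChannels(tab, "turn_to_walk_in",
                                                          drop_sites = "head")),
    walk_in_to_turn = list(anchor = "turning2", side = "left",
                           channels = .transitionChannels(tab, "walk_in_to_turn")),
    turn_to_stand = list(anchor = "turning2", side = "right",
                         channels = .transitionChannels(tab, "turn_to_stand")),
    stand_to_sit = list(anchor = "sitting", side = "right",
                        channels = .transitionChannels(tab, "stand_to_sit")))
  detection <- list(
    stand_sit = list(site = "trunk", quantity = "acceleration", axis = "z",
                     w2_hz = 1.57),
    derivative = list(site = "hip", quantity = "acceleration", axis = "y",
                      w2_hz = 1.57),
    turning = list(site = "trunk", quantity = "angular_velocity", axis = "y",
                   w2_hz = 1.00),
    turn_verify = list(site = "head", quantity = "angular_velocity",
                       axis = "y", w2_hz = 1.00),
    walking = list(site = "hip", quantity = "angular_velocity", axis = "x"))
  new("SegmentationConfig",
      w1Hz = 0.0025,
      walkingW2Hz = 30,
      thresholdFraction = 0.30,
      walkingWindowS = 0.5,
      minSeparationS = 2.0,
      rmsGateFraction = 0.1,
      turnVerifyWindowS = 0.5,
      peakSearchHalfWindowS = 1.5,
      detection = detection,
      transitions = transitions,
      cutoffTable = tab)
}

#' Load a segmentation configuration
#'
#' Reads a YAML file of overrides and merges it onto the defaults, or
#' returns the defaults for \code{path = "defaults"}.  Recognized top-level
#' keys are the scalar parameters (\code{w1_hz}, \code{walking_w2_hz},
#' \code{threshold_fraction}, \code{walking_window_s},
#' \code{min_separation_s}, \code{rms_gate_fraction},
#' \code{turn_verify_window_s}, \code{peak_search_half_window_s}) and a
#' \code{transitions} mapping whose entries may override \code{anchor},
#' \code{side} and the channel list (each channel a mapping with
#' \code{site}, \code{quantity}, \code{axis}, \code{w2_hz}).
#'
#' @param path Path to a YAML file, or \code{"defaults"}.
#' @return A validated \linkS4class{SegmentationConfig}.
#' @export
loadConfig <- function(path = "defaults") {
  cfg <- defaultConfig()
  if (identical(path, "defaults")) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- read_yaml(path)
  scalars <- c(w1_hz = "w1Hz", walking_w2_hz = "walkingW2Hz",
               threshold_fraction = "thresholdFraction",
               walking_window_s = "walkingWindowS",
               min_separation_s = "minSeparationS",
               rms_gate_fraction = "rmsGateFraction",
               turn_verify_window_s = "turnVerifyWindowS",
               peak_search_half_window_s = "peakSearchHalfWindowS")
  for (key in names(scalars)) {
    if (!is.null(y[[key]]))
      slot(cfg, scalars[[key]]) <- as.numeric(y[[key]])
  }
  if (!is.null(y$transitions)) {
    for (nm in names(y$transitions)) {
      if (!nm %in% transitionNames())
        stop("unknown transition in config: ", nm)
      ov <- y$transitions[[nm]]
      tr <- cfg@transitions[[nm]]
      if (!is.null(ov$anchor)) tr$anchor <- ov$anchor
      if (!is.null(ov$side)) tr$side <- ov$side
      if (!is.null(ov$channels)) {
        ch <- do.call(rbind, lapply(ov$channels, function(c1)
          data.frame(site = c1$site, quantity = c1$quantity,
                     axis = c1$axis, w2_hz = as.numeric(c1$w2_hz),
                     stringsAsFactors = FALSE)))
        tr$channels <- ch
      }
      cfg@transitions[[nm]] <- tr
    }
  }
  if (!is.null(y$detection)) {
    for (nm in names(y$detection))
      cfg@detection[[nm]] <- modifyList(cfg@detection[[nm]], y$detection[[nm]])
  }
  validObject(cfg)
  cfg
}
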