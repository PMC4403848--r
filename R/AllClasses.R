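## Central S4 containers: TugRecording (extends SummarizedExperiment),
## SegmentationConfig and TugGroundTruth.

#' Sensor sites of the 17-module body suit
#'
#' @return Character vector of the 17 recognized sensor site names.
#' @export
sensorSites <- function() {
  c("head", "trunk", "hip",
    "left_shoulder", "right_shoulder",
    "left_upper_arm", "right_upper_arm",
    "left_forearm", "right_forearm",
    "left_hand", "right_hand",
    "left_thigh", "right_thigh",
    "left_shin", "right_shin",
    "left_foot", "right_foot")
}

.QUANTITIES <- c("acceleration", "angular_velocity", "orientation", "rom")

#' Names of the seven TUG transitions, in temporal order
#'
#' @return Character vector of length 7.
#' @export
transitionNames <- function() {
  c("sit_to_stand", "stand_to_walk_out", "walk_out_to_turn",
    "turn_to_walk_in", "walk_in_to_turn", "turn_to_stand", "stand_to_sit")
}

#' Names of the six TUG segments, in temporal order
#'
#' @return Character vector of length 6.
#' @export
segmentNames <- function() {
  c("Stand up", "Walk-out", "Turn 180 (first)", "Walk-in",
    "Turn 180 (second)", "Sit down")
}

#' TugRecording: a multi-sensor TUG trial
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"samples"}
#' holds one channel per row (uniformly sampled at \code{rateHz(x)}) and one
#' time point per column.  \code{rowData} carries the channel identity
#' (\code{site}, \code{quantity}, \code{axis}); trial metadata (sampling
#' rate, TUG distance, subject and trial identifiers) lives in
#' \code{metadata}.
#'
#' Orientation channels are stored as four rows (axes \code{w}, \code{x},
#' \code{y}, \code{z}) and are renormalized to unit quaternions on
#' construction.
#'
#' @export
setClass("TugRecording", contains = "SummarizedExperiment")

setValidity("TugRecording", function(object) {
  msg <- character()
  md <- metadata(object)
  if (is.null(md$rate_hz) || !is.numeric(md$rate_hz) || md$rate_hz <= 0)
    msg <- c(msg, "metadata 'rate_hz' must be a positive number")
  if (nrow(object) < 1L || ncol(object) < 1L)
    msg <- c(msg, "recording must contain at least one channel and one sample")
  rd <- rowData(object)
  need <- c("site", "quantity", "axis")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain columns site, quantity, axis")
  } else {
    if (!all(rd$quantity %in% .QUANTITIES))
      msg <- c(msg, "unknown quantity in rowData")
    vec <- rd$quantity %in% c("acceleration", "angular_velocity")
    if (any(!rd$axis[vec] %in% c("x", "y", "z")))
      msg <- c(msg, "vector quantities must use axes x, y, z")
    ori <- rd$quantity == "orientation"
    if (any(!rd$axis[ori] %in% c("w", "x", "y", "z")))
      msg <- c(msg, "orientation channels must use axes w, x, y, z")
    if (any(ori)) {
      per <- table(rd$site[ori])
      if (any(per != 4L))
        msg <- c(msg, "each orientation site needs exactly 4 component rows")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TugRecording
#'
#' @param values Numeric matrix, channels in rows, time points in columns.
#' @param channels data.frame with one row per channel and columns
#'   \code{site}, \code{quantity}, \code{axis} identifying each row of
#'   \code{values}.
#' @param rate_hz Sampling rate in Hz (default 60).
#' @param subject_id,trial_id Identifiers stored in trial metadata.
#' @param distance_m TUG walking distance in meters (typically 5 or 10).
#' @return A validated \linkS4class{TugRecording}.  Orientation quaternions
#'   are renormalized; a quaternion whose norm deviates from 1 by more than
#'   0.5 is rejected as corrupt.
#' @examples
#' n <- 120
#' rec <- TugRecording(
#'   values = matrix(sin(seq_len(n) / 10), nrow = 1),
#'   channels = data.frame(site = "trunk", quantity = "acceleration",
#'                         axis = "z"),
#'   rate_hz = 60, subject_id = "S1", trial_id = "T1", distance_m = 10)
#' durationS(rec)
#' @export
TugRecording <- function(values, channels, rate_hz = 60,
                         subject_id = "S1", trial_id = "T1",
                         distance_m = NA_real_) {
  values <- as.matrix(values)
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (nrow(values) != nrow(channels))
    stop("'values' and 'channels' must describe the same number of channels")
  if (nrow(values) == 0L)
    stop("no channels")
  rownames(values) <- paste(channels$site, channels$quantity, channels$axis,
                            sep = ".")
  ## renormalize orientation quaternions site by site
  ori_sites <- unique(channels$site[channels$quantity == "orientation"])
  for (s in ori_sites) {
    idx <- which(channels$site == s & channels$quantity == "orientation")
    if (length(idx) != 4L)
      stop("orientation for site '", s, "' must have 4 components")
    ord <- idx[match(c("w", "x", "y", "z"), channels$axis[idx])]
    if (anyNA(ord))
      stop("orientation for site '", s, "' must use axes w, x, y, z")
    q <- values[ord, , drop = FALSE]
    nrm <- sqrt(colSums(q^2))
    if (any(abs(nrm - 1) > 0.5))
      stop("orientation quaternions for site '", s,
           "' are far from unit norm")
    values[ord, ] <- sweep(q, 2, nrm, "/")
  }
  se <- SummarizedExperiment(
    assays = list(samples = values),
    rowData = DataFrame(site = channels$site,
                        quantity = channels$quantity,
                        axis = channels$axis))
  metadata(se) <- list(rate_hz = rate_hz, subject_id = subject_id,
                       trial_id = trial_id, distance_m = distance_m)
  new("TugRecording", se)
}

#' SegmentationConfig: channel bands and detection parameters
#'
#' Holds the per-transition sensor combinations and high-cut frequencies
#' (the Table-1 calibration of the 10 m TUG), the common low-cut frequency
#' \code{w1Hz}, the detection channel assignments, and the detector
#' parameters (square-signal threshold fraction, walking window, extremum
#' separation).
#'
#' @slot w1Hz Low cutoff (Hz) shared by all conditioned channels.
#' @slot walkingW2Hz High cutoff for the walking channel (the Nyquist,
#'   30 Hz at 60 Hz sampling, so stride oscillation is preserved).
#' @slot thresholdFraction Square-signal / major-extremum threshold as a
#'   fraction of peak amplitude (default 0.30).
#' @slot walkingWindowS Sliding-window length for the walking oscillation
#'   test, seconds (default 0.5).
#' @slot minSeparationS Minimum separation between major extrema, seconds.
#' @slot rmsGateFraction Walking windows must exceed this fraction of the
#'   whole-trace RMS.
#' @slot turnVerifyWindowS Maximum head/trunk peak lag for turn
#'   verification, seconds.
#' @slot peakSearchHalfWindowS Half-width of the one-sided window used to
#'   re-locate the governing peak on each transition channel, seconds.
#' @slot detection Named list of detection channel assignments.
#' @slot transitions Named list (one entry per transition) of
#'   \code{list(anchor, side, channels)} where \code{channels} is a
#'   data.frame with columns site, quantity, axis, w2_hz.
#' @slot cutoffTable data.frame of every optimized (transition, sensor,
#'   frequency) cell.
#' @export
setClass("SegmentationConfig",
  representation(w1Hz = "numeric",
                 walkingW2Hz = "numeric",
                 thresholdFraction = "numeric",
                 walkingWindowS = "numeric",
                 minSeparationS = "numeric",
                 rmsGateFraction = "numeric",
                 turnVerifyWindowS = "numeric",
                 peakSearchHalfWindowS = "numeric",
                 detection = "list",
                 transitions = "list",
                 cutoffTable = "data.frame"))

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (object@thresholdFraction <= 0 || object@thresholdFraction >= 1)
    msg <- c(msg, "thresholdFraction must lie in (0, 1)")
  if (object@w1Hz < 0)
    msg <- c(msg, "w1Hz must be non-negative")
  if (object@walkingW2Hz <= object@w1Hz)
    msg <- c(msg, "walkingW2Hz must exceed w1Hz")
  if (object@walkingWindowS <= 0)
    msg <- c(msg, "walkingWindowS must be positive")
  bad <- setdiff(names(object@transitions), transitionNames())
  if (length(bad))
    msg <- c(msg, paste("unknown transitions:", paste(bad, collapse = ", ")))
  for (nm in names(object@transitions)) {
    tr <- object@transitions[[nm]]
    if (!all(c("anchor", "side", "channels") %in% names(tr))) {
      msg <- c(msg, paste0("transition '", nm, "' needs anchor, side, channels"))
      next
    }
    if (!tr$side %in% c("left", "right"))
      msg <- c(msg, paste0("transition '", nm, "' side must be left or right"))
    ch <- tr$channels
    if (!is.data.frame(ch) || nrow(ch) < 1L ||
        !all(c("site", "quantity", "axis", "w2_hz") %in% names(ch))) {
      msg <- c(msg, paste0("transition '", nm, "' channels malformed"))
      next
    }
    if (any(ch$w2_hz <= object@w1Hz))
      msg <- c(msg, paste0("transition '", nm, "': w1 must be below every w2"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegmentationConfig", function(object) {
  cat("SegmentationConfig\n")
  cat("  w1:", object@w1Hz, "Hz; walking w2:", object@walkingW2Hz, "Hz\n")
  cat("  threshold fraction:", object@thresholdFraction,
      "; walking window:", object@walkingWindowS, "s\n")
  for (nm in names(object@transitions)) {
    tr <- object@transitions[[nm]]
    cat(sprintf("  %-18s %-9s %-5s %s\n", nm, tr$anchor, tr$side,
                paste(sprintf("%s.%s.%s@%.2fHz", tr$channels$site,
                              tr$channels$quantity, tr$channels$axis,
                              tr$channels$w2_hz), collapse = ", ")))
  }
  invisible(NULL)
})

#' TugGroundTruth: simulator-emitted labels and transition times
#'
#' @slot segments data.frame with columns \code{name}, \code{start_s},
#'   \code{end_s}: the six ordered, non-overlapping TUG segments.
#' @slot transitions Named numeric of the seven transition timestamps
#'   (seconds), strictly increasing.
#' @slot labels Character vector with one activity label per sample
#'   (\code{Idle}, \code{Standing}, \code{Walking}, \code{Turning},
#'   \code{Sitting}).
#' @slot rateHz Sampling rate the label sequence refers to.
#' @export
setClass("TugGroundTruth",
  representation(segments = "data.frame", transitions = "numeric",
                 labels = "character", rateHz = "numeric"))

setValidity("TugGroundTruth", function(object) {
  msg <- character()
  tr <- object@transitions
  if (length(tr) != 7L || !identical(names(tr), transitionNames()))
    msg <- c(msg, "transitions must be the seven named TUG transitions")
  else if (any(diff(tr) <= 0))
    msg <- c(msg, "transitions must be strictly increasing")
  if (nrow(object@segments) != 6L)
    msg <- c(msg, "exactly six segments required")
  else {
    if (!identical(object@segments$name, segmentNames()))
      msg <- c(msg, "segment names/order must match segmentNames()")
    if (any(object@segments$start_s >= object@segments$end_s))
      msg <- c(msg, "each segment needs start_s < end_s")
    if (any(diff(as.vector(rbind(object@segments$start_s,
                                 object@segments$end_s))) < 0))
      msg <- c(msg, "segments must be ordered and non-overlapping")
  }
  if (object@rateHz <= 0) msg <- c(msg, "rateHz must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TugGroundTruth", function(object) {
  cat("TugGroundTruth:", length(object@labels), "samples at",
      object@rateHz, "Hz\n")
  print(round(object@transitions, 3))
  invisible(NULL)
})
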