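## Peak-based activity detection: Standing / Sitting from the trunk
## vertical acceleration (disambiguated by the hip acceleration
## derivative), Turning from trunk yaw angular velocity verified against
## the head, Walking from an oscillation test on hip angular velocity.

## All strict local extrema of a trace; plateaus are assigned to their
## earliest sample.  Returns 1-based sample indices.
.localExtrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(imax = integer(), imin = integer()))
  keep <- c(TRUE, x[-1] != x[-n])         # run starts
  starts <- which(keep)
  v <- x[starts]
  m <- length(v)
  if (m < 3L) return(list(imax = integer(), imin = integer()))
  j <- 2:(m - 1)
  imax <- starts[j][v[j] > v[j - 1] & v[j] > v[j + 1]]
  imin <- starts[j][v[j] < v[j - 1] & v[j] < v[j + 1]]
  list(imax = imax, imin = imin)
}

#' Major extrema of a conditioned trace
#'
#' Local extrema whose absolute value reaches \code{threshold_fraction}
#' of the trace's absolute maximum, thinned so that no two returned
#' extrema lie closer than \code{min_separation_s} (the larger magnitude
#' wins).  These are the dominant kinematic peaks that mark activities.
#'
#' @param conditioned Conditioned numeric vector (see
#'   \code{\link{conditionSignal}}).
#' @param polarity \code{"max"}, \code{"min"}, or \code{"both"}.
#' @param min_separation_s Minimum spacing between returned extrema (s).
#' @param rate_hz Sampling rate; defaults to the trace attribute.
#' @param threshold_fraction Amplitude threshold as a fraction of
#'   \code{max(abs(conditioned))} (default 0.30).
#' @return data.frame with columns \code{time_s}, \code{value}, sorted by
#'   time (possibly zero rows).
#' @export
findMajorExtrema <- function(conditioned, polarity = c("both", "max", "min"),
                             min_separation_s = 1.0,
                             rate_hz = attr(conditioned, "rate_hz"),
                             threshold_fraction = 0.30) {
  polarity <- match.arg(polarity)
  if (is.null(rate_hz)) stop("rate_hz required")
  x <- as.numeric(conditioned)
  ex <- .localExtrema(x)
  idx <- switch(polarity,
                max = ex$imax, min = ex$imin, both = c(ex$imax, ex$imin))
  if (length(idx) == 0L)
    return(data.frame(time_s = numeric(), value = numeric()))
  val <- x[idx]
  big <- abs(val) >= threshold_fraction * max(abs(x))
  idx <- idx[big]; val <- val[big]
  if (length(idx) == 0L)
    return(data.frame(time_s = numeric(), value = numeric()))
  ## greedy thinning, largest magnitude first
  ord <- order(-abs(val))
  kept <- integer()
  min_sep <- min_separation_s * rate_hz
  for (i in ord) {
    if (all(abs(idx[i] - idx[kept]) >= min_sep)) kept <- c(kept, i)
  }
  kept <- kept[order(idx[kept])]
  data.frame(time_s = (idx[kept] - 1) / rate_hz, value = val[kept])
}

## Empty events table with the canonical columns.
.emptyEvents <- function() {
  data.frame(label = character(), peak_time_s = numeric(),
             peak_value = numeric(), direction = character(),
             stringsAsFactors = FALSE)
}

#' Detect stand-up and sit-down events
#'
#' Each major extremum of the conditioned trunk vertical acceleration is
#' classified by the sign of the time derivative of the conditioned hip
#' acceleration at the extremum: positive derivative (the body accelerating
#' into upright) marks \emph{Standing}, negative marks \emph{Sitting}.  A
#' derivative of exactly zero at the sample falls back to the mean over a
#' +/-2-sample neighborhood; if that is still zero the event is ambiguous
#' and an error is raised.
#'
#' @param trunk_az Conditioned trunk a_z trace.
#' @param hip_ay Conditioned hip a_y trace (same rate and length).
#' @param min_separation_s,threshold_fraction Peak picking parameters, see
#'   \code{\link{findMajorExtrema}}.
#' @return Events data.frame (\code{label}, \code{peak_time_s},
#'   \code{peak_value}, \code{direction}).
#' @export
detectStandSit <- function(trunk_az, hip_ay, min_separation_s = 1.0,
                           threshold_fraction = 0.30) {
  rate <- attr(trunk_az, "rate_hz")
  pk <- findMajorExtrema(trunk_az, "both", min_separation_s,
                         threshold_fraction = threshold_fraction)
  if (nrow(pk) == 0L) return(.emptyEvents())
  d <- diff(as.numeric(hip_ay)) * rate
  d <- c(d, d[length(d)])                  # forward difference, padded
  n <- length(d)
  lab <- character(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    j <- round(pk$time_s[i] * rate) + 1L
    s <- d[j]
    if (s == 0) {
      nb <- max(1L, j - 2L):min(n, j + 2L)
      s <- mean(d[nb])
    }
    if (s == 0) stop("ambiguous stand/sit event at t = ", pk$time_s[i],
                     " s: zero hip acceleration derivative")
    lab[i] <- if (s > 0) "Standing" else "Sitting"
  }
  data.frame(label = lab, peak_time_s = pk$time_s, peak_value = pk$value,
             direction = "none", stringsAsFactors = FALSE)
}

#' Detect 180-degree turns
#'
#' Major extrema of the conditioned trunk yaw angular velocity become
#' Turning events; each must be verified by a same-sign head yaw extremum
#' within \code{verify_window_s}, otherwise it is dropped.  The turn
#' direction is the sign of the verifying head peak (positive yaw =
#' \code{"left"}).
#'
#' @param trunk_wy Conditioned trunk omega_y trace.
#' @param head_wy Conditioned head omega_y trace.
#' @param verify_window_s Maximum trunk/head peak lag (s, default 0.5).
#' @param min_separation_s,threshold_fraction Peak picking parameters.
#' @return Events data.frame; \code{direction} is \code{"left"} or
#'   \code{"right"}.
#' @export
detectTurning <- function(trunk_wy, head_wy, verify_window_s = 0.5,
                          min_separation_s = 1.0,
                          threshold_fraction = 0.30) {
  pk <- findMajorExtrema(trunk_wy, "both", min_separation_s,
                         threshold_fraction = threshold_fraction)
  if (nrow(pk) == 0L) return(.emptyEvents())
  hd <- findMajorExtrema(head_wy, "both", min_separation_s,
                         threshold_fraction = threshold_fraction)
  keep <- logical(nrow(pk))
  dir <- character(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (nrow(hd) == 0L) break
    near <- abs(hd$time_s - pk$time_s[i]) <= verify_window_s &
      sign(hd$value) == sign(pk$value[i])
    if (any(near)) {
      keep[i] <- TRUE
      dir[i] <- if (hd$value[which(near)[1]] > 0) "left" else "right"
    }
  }
  if (!any(keep)) return(.emptyEvents())
  data.frame(label = "Turning", peak_time_s = pk$time_s[keep],
             peak_value = pk$value[keep], direction = dir[keep],
             stringsAsFactors = FALSE)
}

#' Detect walking by windowed oscillation
#'
#' Slides a window of \code{window_s} seconds over the conditioned hip
#' angular velocity (conditioned with the high cut at the Nyquist so the
#' stride oscillation is preserved).  A window is walking-positive when
#' (i) its root-mean-square exceeds \code{rms_gate_fraction} of the
#' whole-trace RMS, and (ii) the signal alternates at least twice between
#' excursions above +h and below -h, where h is half the window RMS
#' (hysteresis zero-crossing counting: each alternation implies a genuine
#' oscillation swing through zero, so noise wiggles and one-sided ramps
#' do not count).  The mask is the union of all positive windows.
#'
#' @param hip_w Conditioned hip angular-velocity trace.
#' @param window_s Window length in seconds (default 0.5).
#' @param rms_gate_fraction RMS gate relative to the whole trace (default
#'   0.1).
#' @return Logical vector, one element per sample.
#' @export
detectWalking <- function(hip_w, window_s = 0.5, rms_gate_fraction = 0.1) {
  rate <- attr(hip_w, "rate_hz")
  if (is.null(rate)) stop("rate_hz required")
  x <- as.numeric(hip_w)
  n <- length(x)
  w <- round(window_s * rate)
  if (w > n) stop("walking window longer than the trial")
  if (w < 2L) stop("walking window too short")
  gate <- rms_gate_fraction * sqrt(mean(x^2))
  cs2 <- cumsum(c(0, x^2))                  # O(1) window RMS
  mask <- logical(n)
  for (start in 1:(n - w + 1L)) {
    end <- start + w - 1L
    rms <- sqrt((cs2[end + 1L] - cs2[start]) / w)
    if (rms <= gate) next
    seg <- x[start:end]
    h <- rms / 2
    st <- sign(seg) * (abs(seg) > h)        # -1 / 0 / +1 Schmitt states
    st <- st[st != 0]
    if (length(st) >= 2L && sum(diff(st) != 0) >= 2L)
      mask[start:end] <- TRUE
  }
  mask
}

#' Square indicator signal of a detected event
#'
#' Binary signal that is 1 over the contiguous region around the event's
#' peak where the conditioned trace (oriented so the peak is positive)
#' exceeds \code{fraction} of the peak amplitude, and 0 elsewhere --
#' the 30\%-of-peak indicator used to visualize detections.
#'
#' @param conditioned Conditioned trace carrying the event's peak.
#' @param event One-row events data.frame (or list) with
#'   \code{peak_time_s} and \code{peak_value}.
#' @param fraction Threshold fraction in (0, 1), default 0.30.
#' @return Logical vector aligned with the trace.
#' @export
squareSignal <- function(conditioned, event, fraction = 0.30) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  rate <- attr(conditioned, "rate_hz")
  if (is.null(rate)) stop("rate_hz required")
  x <- as.numeric(conditioned)
  j <- round(event$peak_time_s * rate) + 1L
  if (j < 1L || j > length(x)) stop("event peak lies outside the trace")
  s <- sign(event$peak_value)
  y <- x * s
  thr <- fraction * abs(event$peak_value)
  above <- y > thr
  if (!above[j]) {                         # peak sample itself must qualify
    above[j] <- TRUE
  }
  ## contiguous run containing the peak
  lo <- j; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- j; while (hi < length(x) && above[hi + 1L]) hi <- hi + 1L
  out <- logical(length(x))
  out[lo:hi] <- TRUE
  out
}

#' Classify a full TUG trial
#'
#' Runs the stand/sit, turning and walking detectors on their configured
#' channels and combines them into a per-sample label sequence.  Samples
#' flagged as both Walking and Turning are labeled Turning (turn
#' priority); stand/sit square regions likewise take precedence over
#' Walking.  Walking detections are reported as events whose peak time is
#' the largest-magnitude sample of each connected walking region.
#'
#' @param rec A \linkS4class{TugRecording}.
#' @param config A \linkS4class{SegmentationConfig}
#'   (default \code{defaultConfig()}).
#' @return List with elements \code{events} (data.frame of Standing /
#'   Turning / Sitting / Walking events sorted by time), \code{labels}
#'   (per-sample character vector), \code{walking_mask} (logical), and
#'   \code{square_signals} (list of logical vectors per peak event).
#' @export
classifyTrial <- function(rec, config = defaultConfig()) {
  det <- config@detection
  w1 <- config@w1Hz
  rate <- rateHz(rec)
  cond <- function(d, w2) conditionChannel(rec, d$site, d$quantity, d$axis,
                                           w2_hz = w2, w1_hz = w1)
  trunk_az <- cond(det$stand_sit, det$stand_sit$w2_hz)
  hip_ay <- cond(det$derivative, det$derivative$w2_hz)
  trunk_wy <- cond(det$turning, det$turning$w2_hz)
  head_wy <- cond(det$turn_verify, det$turn_verify$w2_hz)
  hip_w <- cond(det$walking, config@walkingW2Hz)

  ss <- detectStandSit(trunk_az, hip_ay, config@minSeparationS,
                       config@thresholdFraction)
  tn <- detectTurning(trunk_wy, head_wy, config@turnVerifyWindowS,
                      config@minSeparationS, config@thresholdFraction)
  mask <- detectWalking(hip_w, config@walkingWindowS, config@rmsGateFraction)

  n <- ncol(rec)
  labels <- rep("Idle", n)
  labels[mask] <- "Walking"

  squares <- list()
  peak_events <- rbind(ss, tn)
  if (nrow(peak_events)) {
    peak_events <- peak_events[order(peak_events$peak_time_s), , drop = FALSE]
    for (i in seq_len(nrow(peak_events))) {
      ev <- peak_events[i, ]
      tr <- if (ev$label == "Turning") trunk_wy else trunk_az
      sq <- squareSignal(tr, ev, config@thresholdFraction)
      squares[[paste0(ev$label, "_", i)]] <- sq
      ## the activity's own extent -- from the first extremum left of the
      ## peak to the first extremum right (the same rule segmentation
      ## uses) -- takes precedence over walking
      kind <- if (ev$peak_value >= 0) "min" else "max"
      lo <- round(as.numeric(firstExtremumLeft(tr, ev$peak_time_s, kind)) *
                    rate) + 1L
      hi <- round(as.numeric(firstExtremumRight(tr, ev$peak_time_s, kind)) *
                    rate) + 1L
      labels[lo:hi] <- ev$label
    }
  }

  ## walking events: connected mask regions outside turn/stand/sit labels
  walk_samples <- mask & labels == "Walking"
  walk_events <- .emptyEvents()
  if (any(walk_samples)) {
    r <- rle(walk_samples)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    xs <- abs(as.numeric(hip_w))
    for (k in which(r$values)) {
      span <- starts[k]:ends[k]
      j <- span[which.max(xs[span])]
      walk_events <- rbind(walk_events, data.frame(
        label = "Walking", peak_time_s = (j - 1) / rate,
        peak_value = as.numeric(hip_w)[j], direction = "none",
        stringsAsFactors = FALSE))
    }
  }
  events <- rbind(peak_events, walk_events)
  events <- events[order(events$peak_time_s), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, labels = labels, walking_mask = mask,
       square_signals = squares)
}
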