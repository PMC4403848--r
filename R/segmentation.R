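## Transition segmentation: seven transition timestamps located as the
## first local extremum to the left/right of the governing activity peak,
## averaged over the configured sensor combination.

#' First local extremum left/right of a peak
#'
#' Scanning outward sample by sample from \code{peak_time_s}, returns the
#' time of the first local extremum of the requested kind (a sample
#' strictly below/above both neighbors; plateaus take the earliest
#' sample).  If the trace boundary is reached without finding one, the
#' boundary time is returned with attribute \code{boundary = TRUE}.
#'
#' @param conditioned Conditioned trace.
#' @param peak_time_s Time (s) of the governing peak; must map to a sample.
#' @param kind \code{"min"} or \code{"max"}.
#' @param rate_hz Sampling rate; defaults to the trace attribute.
#' @return Time in seconds (attribute \code{boundary} flags the fallback).
#' @export
firstExtremumLeft <- function(conditioned, peak_time_s, kind = c("min", "max"),
                              rate_hz = attr(conditioned, "rate_hz")) {
  .firstExtremum(conditioned, peak_time_s, match.arg(kind), -1L, rate_hz)
}

#' @rdname firstExtremumLeft
#' @export
firstExtremumRight <- function(conditioned, peak_time_s, kind = c("min", "max"),
                               rate_hz = attr(conditioned, "rate_hz")) {
  .firstExtremum(conditioned, peak_time_s, match.arg(kind), 1L, rate_hz)
}

.firstExtremum <- function(conditioned, peak_time_s, kind, step, rate_hz) {
  if (is.null(rate_hz)) stop("rate_hz required")
  x <- as.numeric(conditioned)
  n <- length(x)
  j <- round(peak_time_s * rate_hz) + 1L
  if (j < 1L || j > n) stop("peak_time_s outside the trace")
  cmp <- if (kind == "min") function(a, b) a < b else function(a, b) a > b
  i <- j + step
  while (i > 1L && i < n) {
    ## plateau handling: an extremum run is credited to its earliest sample
    if (cmp(x[i], x[i + 1L]) || x[i] == x[i + 1L]) {
      ## find run of equal values containing i
      lo <- i; while (lo > 1L && x[lo - 1L] == x[i]) lo <- lo - 1L
      hi <- i; while (hi < n && x[hi + 1L] == x[i]) hi <- hi + 1L
      if (lo > 1L && hi < n && cmp(x[i], x[lo - 1L]) && cmp(x[i], x[hi + 1L])) {
        out <- (lo - 1L) / rate_hz
        attr(out, "boundary") <- FALSE
        return(out)
      }
    }
    i <- i + step
  }
  out <- if (step < 0L) 0 else (n - 1L) / rate_hz
  attr(out, "boundary") <- TRUE
  out
}

## Resolve the anchor event time for a transition from the classification.
.anchorTime <- function(events, anchor) {
  pick <- function(lab, k, top = 1L) {
    sel <- events[events$label == lab, , drop = FALSE]
    if (nrow(sel) < max(k, top))
      stop("missing ", lab, " event", if (max(k, top) > 1) paste0(" #", k),
           " required for segmentation")
    ## keep the `top` dominant peaks by magnitude, then order by time
    sel <- sel[order(-abs(sel$peak_value)), , drop = FALSE][seq_len(top), ]
    sort(sel$peak_time_s)[k]
  }
  switch(anchor,
         standing = pick("Standing", 1L),
         turning1 = pick("Turning", 1L, top = 2L),
         turning2 = pick("Turning", 2L, top = 2L),
         sitting = pick("Sitting", 1L),
         stop("unknown anchor '", anchor, "'"))
}

## One channel's candidate transition time: re-locate the governing peak
## on this channel's band within a one-sided window at the anchor, then
## take the first extremum on the requested side (minima for a positive
## peak, maxima for a negative one).
.channelCandidate <- function(cond, anchor_time, side, half_window_s,
                              rate_hz = attr(cond, "rate_hz")) {
  x <- as.numeric(cond)
  n <- length(x)
  j <- round(anchor_time * rate_hz) + 1L
  w <- round(half_window_s * rate_hz)
  win <- if (side == "left") max(1L, j - w):min(n, j) else
    max(1L, j):min(n, j + w)
  jpk <- win[which.max(abs(x[win]))]
  peak_t <- (jpk - 1L) / rate_hz
  kind <- if (x[jpk] >= 0) "min" else "max"
  cand <- if (side == "left")
    firstExtremumLeft(cond, peak_t, kind, rate_hz)
  else
    firstExtremumRight(cond, peak_t, kind, rate_hz)
  cand
}

#' Estimate one transition time
#'
#' For each channel configured for the transition, conditions the channel
#' with its calibrated high cut, re-locates the governing activity peak
#' near the anchoring detection event, takes the first extremum on the
#' transition's side of the peak (first minima for a positive peak, first
#' maxima for a negative one), and averages the per-channel candidate
#' times.  Boundary-fallback candidates are discarded from the mean when
#' at least one channel yields an interior extremum.
#'
#' @param rec A \linkS4class{TugRecording}.
#' @param name Transition name (one of \code{\link{transitionNames}}).
#' @param config A \linkS4class{SegmentationConfig}.
#' @param classification Optional result of \code{\link{classifyTrial}}
#'   (recomputed if missing).
#' @return List with \code{name}, \code{time_s} (combined estimate),
#'   \code{candidates} (per-channel data.frame with columns channel,
#'   time_s, boundary, used).
#' @export
estimateTransition <- function(rec, name, config = defaultConfig(),
                               classification = NULL) {
  if (!name %in% names(config@transitions))
    stop("no configuration for transition '", name, "'")
  tr <- config@transitions[[name]]
  if (is.null(classification)) classification <- classifyTrial(rec, config)
  anchor_time <- .anchorTime(classification$events, tr$anchor)
  ch <- tr$channels
  cand <- data.frame(channel = paste(ch$site, ch$quantity, ch$axis, sep = "."),
                     time_s = NA_real_, boundary = NA, used = NA)
  for (i in seq_len(nrow(ch))) {
    cond <- conditionChannel(rec, ch$site[i], ch$quantity[i], ch$axis[i],
                             w2_hz = ch$w2_hz[i], w1_hz = config@w1Hz)
    est <- .channelCandidate(cond, anchor_time, tr$side,
                             config@peakSearchHalfWindowS)
    cand$time_s[i] <- as.numeric(est)
    cand$boundary[i] <- isTRUE(attr(est, "boundary"))
  }
  cand$used <- if (all(cand$boundary)) rep(TRUE, nrow(cand)) else !cand$boundary
  list(name = name, time_s = mean(cand$time_s[cand$used]), candidates = cand)
}

#' Segment a TUG trial
#'
#' Estimates all seven transition timestamps (requiring the full event
#' sequence: one Standing, two Turning, one Sitting detection) and builds
#' the six segments between consecutive transitions.  Non-monotone
#' transition estimates raise an \code{"inconsistent segmentation"} error
#' naming the offending pair.
#'
#' @param rec A \linkS4class{TugRecording}.
#' @param config A \linkS4class{SegmentationConfig}.
#' @return List with \code{transitions} (named numeric, seconds),
#'   \code{segments} (data.frame name/start_s/end_s), and
#'   \code{candidates} (per-channel audit data.frame).
#' @export
segmentTrial <- function(rec, config = defaultConfig()) {
  cls <- classifyTrial(rec, config)
  ev <- cls$events
  missing <- character()
  if (sum(ev$label == "Standing") < 1L) missing <- c(missing, "Standing")
  if (sum(ev$label == "Turning") < 2L) missing <- c(missing, "Turning (x2)")
  if (sum(ev$label == "Sitting") < 1L) missing <- c(missing, "Sitting")
  if (length(missing))
    stop("cannot segment trial: missing activity events: ",
         paste(missing, collapse = ", "))
  nms <- transitionNames()
  times <- numeric(length(nms)); names(times) <- nms
  audit <- list()
  for (nm in nms) {
    est <- estimateTransition(rec, nm, config, classification = cls)
    times[nm] <- est$time_s
    est$candidates$transition <- nm
    audit[[nm]] <- est$candidates
  }
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1]
    stop("inconsistent segmentation: ", nms[i], " (", round(times[i], 3),
         " s) is not before ", nms[i + 1], " (", round(times[i + 1], 3), " s)")
  }
  segments <- data.frame(name = segmentNames(),
                         start_s = unname(times[-7]),
                         end_s = unname(times[-1]),
                         stringsAsFactors = FALSE)
  list(transitions = times, segments = segments,
       candidates = do.call(rbind, audit))
}

#' Compare estimated and reference transition sets
#'
#' @param estimated,reference Named numerics over the seven transitions
#'   (any common subset is compared).
#' @return data.frame with columns \code{transition}, \code{estimated_s},
#'   \code{reference_s}, \code{diff_s} (estimated - reference), and
#'   \code{abs_diff_s}.
#' @export
compareTransitions <- function(estimated, reference) {
  common <- intersect(names(estimated), names(reference))
  if (length(common) == 0L) stop("no common transitions to compare")
  common <- common[order(match(common, transitionNames()))]
  d <- unname(estimated[common] - reference[common])
  data.frame(transition = common,
             estimated_s = unname(estimated[common]),
             reference_s = unname(reference[common]),
             diff_s = d, abs_diff_s = abs(d),
             stringsAsFactors = FALSE)
}
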