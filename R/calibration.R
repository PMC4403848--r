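## Exhaustive-search calibration of per-channel high-cut frequencies
## against reference transition times, and sensor-combination selection.

## Normalize heterogeneous reference input (TugGroundTruth, segmentTrial
## result, or named numeric) to a named numeric of transition times.
.refTimes <- function(ref) {
  if (is(ref, "TugGroundTruth")) return(truthTransitions(ref))
  if (is.list(ref) && !is.null(ref$transitions)) return(ref$transitions)
  if (is.numeric(ref) && !is.null(names(ref))) return(ref)
  stop("reference must be a TugGroundTruth, a segmentTrial result, ",
       "or a named numeric of transition times")
}

.recOf <- function(x) if (is(x, "TugRecording")) x else x$recording

## Per-trial preparation for repeated filtering at many w2 values: the
## detrended, normalized channel, its FFT, and the anchoring event time.
.prepCalibTrial <- function(rec, channel, transition, config) {
  tr <- config@transitions[[transition]]
  if (is.null(tr)) stop("no configuration for transition '", transition, "'")
  cls <- classifyTrial(rec, config)
  anchor <- .anchorTime(cls$events, tr$anchor)
  samples <- if (identical(channel$quantity, "rom")) {
    romTrace(rec, joint = channel$site)$angles_deg
  } else {
    getChannel(rec, channel$site, channel$quantity, channel$axis)
  }
  y <- normalizeSignal(detrendSignal(samples))
  n <- length(y)
  rate <- rateHz(rec)
  k <- 0:(n - 1)
  list(fft = fft(y), freq = pmin(k, n - k) * rate / n, n = n,
       rate = rate, anchor = anchor, side = tr$side)
}

.calibCandidate <- function(prep, w2_hz, w1_hz, half_window_s) {
  keep <- prep$freq >= w1_hz & prep$freq <= w2_hz
  X <- prep$fft
  X[!keep] <- 0
  x <- Re(fft(X, inverse = TRUE)) / prep$n
  attr(x, "rate_hz") <- prep$rate
  est <- .channelCandidate(x, prep$anchor, prep$side, half_window_s)
  as.numeric(est)
}

#' Sum-of-squares transition cost at one high-cut frequency
#'
#' For every (trial, reference) pair, re-estimates the transition time
#' from the given channel conditioned with high cut \code{w2_hz}, and
#' accumulates the squared difference to the reference time.  A trial on
#' which estimation fails is excluded with a warning.
#'
#' @param w2_hz Candidate high cutoff (Hz).
#' @param trials List of \linkS4class{TugRecording} (or simulator
#'   \code{list(recording, truth)} elements).
#' @param references List of reference transition sets (one per trial):
#'   \linkS4class{TugGroundTruth}, \code{segmentTrial} results, or named
#'   numerics.
#' @param channel List with \code{site}, \code{quantity}, \code{axis}.
#' @param transition Transition name.
#' @param config A \linkS4class{SegmentationConfig}.
#' @return Cost in seconds squared.
#' @export
transitionCost <- function(w2_hz, trials, references, channel, transition,
                           config = defaultConfig()) {
  if (length(trials) != length(references))
    stop("trials and references must be paired")
  if (length(trials) < 1L) stop("at least one (trial, reference) pair needed")
  cost <- 0
  for (k in seq_along(trials)) {
    ref <- .refTimes(references[[k]])[[transition]]
    est <- tryCatch({
      prep <- .prepCalibTrial(.recOf(trials[[k]]), channel, transition, config)
      .calibCandidate(prep, w2_hz, config@w1Hz, config@peakSearchHalfWindowS)
    }, error = function(e) {
      warning("trial ", k, " excluded from cost: ", conditionMessage(e))
      NA_real_
    })
    if (!is.na(est)) cost <- cost + (ref - est)^2
  }
  cost
}

#' Exhaustive-search optimization of a channel's high-cut frequency
#'
#' Evaluates the sum-of-squares transition cost at every point of an
#' evenly spaced frequency grid (default 0.5 to 10 Hz in 2000 steps,
#' endpoints included) and returns the minimizing frequency; ties go to
#' the lowest frequency.  The full cost curve is retained for convergence
#' inspection.
#'
#' @inheritParams transitionCost
#' @param grid_hz Length-2 numeric: grid limits (Hz).
#' @param steps Number of grid points.
#' @return List of class \code{"tugCalibration"}: \code{grid_hz},
#'   \code{cost} (per grid point), \code{w2_opt_hz}, \code{cost_opt},
#'   \code{candidates} (steps x trials matrix of estimated times),
#'   \code{references} (numeric), \code{channel}, \code{transition}.
#' @export
optimizeW2 <- function(trials, references, channel, transition,
                       config = defaultConfig(), grid_hz = c(0.5, 10),
                       steps = 2000) {
  if (length(trials) != length(references))
    stop("trials and references must be paired")
  grid <- seq(grid_hz[1], grid_hz[2], length.out = steps)
  preps <- vector("list", length(trials))
  refs <- numeric(length(trials))
  ok <- logical(length(trials))
  for (k in seq_along(trials)) {
    refs[k] <- .refTimes(references[[k]])[[transition]]
    preps[[k]] <- tryCatch(
      .prepCalibTrial(.recOf(trials[[k]]), channel, transition, config),
      error = function(e) {
        warning("trial ", k, " excluded from calibration: ",
                conditionMessage(e))
        NULL
      })
    ok[k] <- !is.null(preps[[k]])
  }
  if (!any(ok)) stop("calibration failed on every trial")
  cand <- matrix(NA_real_, nrow = steps, ncol = length(trials))
  for (k in which(ok)) {
    for (g in seq_len(steps)) {
      cand[g, k] <- .calibCandidate(preps[[k]], grid[g], config@w1Hz,
                                    config@peakSearchHalfWindowS)
    }
  }
  err2 <- sweep(cand[, ok, drop = FALSE], 2, refs[ok])^2
  cost <- rowSums(err2)
  best <- which.min(cost)            # first index wins ties -> lowest freq
  structure(list(grid_hz = grid, cost = cost, w2_opt_hz = grid[best],
                 cost_opt = cost[best], candidates = cand,
                 references = refs, trials_used = which(ok),
                 channel = channel, transition = transition),
            class = "tugCalibration")
}

#' @export
print.tugCalibration <- function(x, ...) {
  cat("Exhaustive w2 calibration:", x$transition, "on",
      paste(unlist(x$channel[c("site", "quantity", "axis")]), collapse = "."),
      "\n  grid:", length(x$grid_hz), "points in [",
      min(x$grid_hz), ",", max(x$grid_hz), "] Hz\n",
      " optimum:", round(x$w2_opt_hz, 4), "Hz, cost",
      signif(x$cost_opt, 4), "s^2 over", length(x$trials_used), "trials\n")
  invisible(x)
}

#' Select the best sensor combination for a transition
#'
#' Optimizes each candidate channel's high cut individually, then scores
#' every non-empty subset of candidates by the sum-of-squares cost of the
#' subset's mean estimate (each channel conditioned at its own optimized
#' high cut).  Returns the lowest-cost combination.
#'
#' @inheritParams transitionCost
#' @param candidates data.frame of candidate channels (columns
#'   \code{site}, \code{quantity}, \code{axis}).
#' @param grid_hz,steps Grid for the per-channel optimization.
#' @return List: \code{channels} (chosen subset of \code{candidates} with
#'   an added \code{w2_hz} column), \code{cost}, and \code{per_channel}
#'   (each channel's individual calibration).
#' @export
selectSensorCombination <- function(trials, references, candidates,
                                    transition, config = defaultConfig(),
                                    grid_hz = c(0.5, 10), steps = 200) {
  if (nrow(candidates) < 1L) stop("at least one candidate channel required")
  per <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    per[[i]] <- optimizeW2(trials, references,
                           as.list(candidates[i, c("site", "quantity", "axis")]),
                           transition, config, grid_hz, steps)
  }
  refs <- per[[1]]$references
  est <- sapply(per, function(cal)
    cal$candidates[which.min(cal$cost), ])    # best-w2 estimates per channel
  if (is.null(dim(est))) est <- matrix(est, nrow = 1)
  best_cost <- Inf; best_set <- NULL
  nc <- nrow(candidates)
  for (m in seq_len(2^nc - 1)) {
    sel <- which(bitwAnd(m, 2^(seq_len(nc) - 1)) > 0)
    comb <- rowMeans(est[, sel, drop = FALSE])
    cost <- sum((refs - comb)^2, na.rm = TRUE)
    if (cost < best_cost) {
      best_cost <- cost
      best_set <- sel
    }
  }
  chosen <- candidates[best_set, , drop = FALSE]
  chosen$w2_hz <- vapply(per[best_set], function(cal) cal$w2_opt_hz, 0)
  list(channels = chosen, cost = best_cost, per_channel = per)
}
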