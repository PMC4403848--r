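## Evaluation metrics: detection sensitivity/specificity over segment
## instances, and cohort mean absolute transition differences (Delta T).

.asTrialList <- function(x) {
  if (is(x, "TugGroundTruth") || (is.list(x) && !is.null(x$events)) ||
      (is.numeric(x) && !is.null(names(x))) ||
      (is.list(x) && !is.null(x$transitions)) || is.data.frame(x))
    list(x) else x
}

.eventsOf <- function(pred) {
  if (is.data.frame(pred)) pred else pred$events
}

#' Score activity detection against ground truth
#'
#' Counting unit is the ground-truth segment instance (six per trial).  A
#' segment is a true positive when at least one predicted event of its
#' activity has its peak time inside the segment, otherwise a false
#' negative.  The same instance is the negative-class opportunity for
#' spurious detections: it counts as a false positive when a predicted
#' event of a \emph{different} activity peaks inside it, and as a true
#' negative otherwise.  Sensitivity = TP / (TP + FN); specificity =
#' TN / (TN + FP).
#'
#' @param predictions \code{\link{classifyTrial}} result(s) or events
#'   data.frame(s); a list for a cohort.
#' @param truths Matching \linkS4class{TugGroundTruth}(s).
#' @return List with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{sensitivity}, \code{specificity}, \code{n_instances}, and the
#'   per-instance data.frame \code{instances}.
#' @export
scoreDetection <- function(predictions, truths) {
  predictions <- .asTrialList(predictions)
  truths <- .asTrialList(truths)
  if (length(predictions) != length(truths))
    stop("predictions and truths must be paired")
  seg_activity <- c("Stand up" = "Standing", "Walk-out" = "Walking",
                    "Turn 180 (first)" = "Turning", "Walk-in" = "Walking",
                    "Turn 180 (second)" = "Turning", "Sit down" = "Sitting")
  rows <- list()
  for (k in seq_along(truths)) {
    ev <- .eventsOf(predictions[[k]])
    segs <- truthSegments(truths[[k]])
    for (i in seq_len(nrow(segs))) {
      act <- seg_activity[[segs$name[i]]]
      inside <- ev$peak_time_s >= segs$start_s[i] &
        ev$peak_time_s < segs$end_s[i]
      detected <- any(inside & ev$label == act)
      spurious <- any(inside & ev$label != act)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = k, segment = segs$name[i], activity = act,
        detected = detected, spurious = spurious,
        stringsAsFactors = FALSE)
    }
  }
  inst <- do.call(rbind, rows)
  tp <- sum(inst$detected); fn <- sum(!inst$detected)
  fp <- sum(inst$spurious); tn <- sum(!inst$spurious)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       n_instances = nrow(inst), instances = inst)
}

#' Cohort mean absolute transition differences
#'
#' Per transition, the mean absolute difference between estimated and
#' reference transition times across trials, together with the standard
#' deviation and variance of the signed differences.
#'
#' @param estimates List (one per trial) of estimated transition sets:
#'   \code{segmentTrial} results or named numerics.
#' @param references Matching list of references (ground truth or named
#'   numerics).
#' @return data.frame with columns \code{transition}, \code{n},
#'   \code{delta_t_s} (mean absolute difference), \code{sd_s},
#'   \code{var_s2}.
#' @export
deltaT <- function(estimates, references) {
  estimates <- .asTrialList(estimates)
  references <- .asTrialList(references)
  if (length(estimates) != length(references))
    stop("estimates and references must be paired trial for trial")
  diffs <- lapply(seq_along(estimates), function(k) {
    est <- .refTimes(estimates[[k]])
    ref <- .refTimes(references[[k]])
    common <- intersect(names(est), names(ref))
    stats::setNames(est[common] - ref[common], common)
  })
  nms <- transitionNames()
  out <- lapply(nms, function(nm) {
    d <- unlist(lapply(diffs, function(x) x[[nm]]))
    if (is.null(d)) return(NULL)
    data.frame(transition = nm, n = length(d),
               delta_t_s = mean(abs(d)),
               sd_s = if (length(d) > 1) sd(d) else 0,
               var_s2 = if (length(d) > 1) var(d) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
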