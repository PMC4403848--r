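## Accessors for TugRecording and TugGroundTruth.

#' @rdname TugRecording-accessors
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))

#' @rdname TugRecording-accessors
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' @rdname TugRecording-accessors
#' @export
setGeneric("distanceM", function(x) standardGeneric("distanceM"))

#' @rdname TugRecording-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname TugRecording-accessors
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))

#' Accessors for TugRecording metadata
#'
#' @param x A \linkS4class{TugRecording}.
#' @return \code{rateHz}: sampling rate in Hz; \code{durationS}: trial
#'   length in seconds (sample count / rate); \code{distanceM}: TUG
#'   distance; \code{subjectId}/\code{trialId}: identifiers.
#' @name TugRecording-accessors
#' @aliases rateHz durationS distanceM subjectId trialId
NULL

#' @rdname TugRecording-accessors
setMethod("rateHz", "TugRecording", function(x) metadata(x)$rate_hz)

#' @rdname TugRecording-accessors
setMethod("durationS", "TugRecording", function(x) ncol(x) / rateHz(x))

#' @rdname TugRecording-accessors
setMethod("distanceM", "TugRecording", function(x) metadata(x)$distance_m)

#' @rdname TugRecording-accessors
setMethod("subjectId", "TugRecording", function(x) metadata(x)$subject_id)

#' @rdname TugRecording-accessors
setMethod("trialId", "TugRecording", function(x) metadata(x)$trial_id)

#' Channel inventory of a recording
#'
#' @param x A \linkS4class{TugRecording}.
#' @return data.frame with columns \code{site}, \code{quantity},
#'   \code{axis}, one row per stored channel.
#' @export
channelInfo <- function(x) {
  as.data.frame(rowData(x))
}

#' Test whether a channel is present
#'
#' @param x A \linkS4class{TugRecording}.
#' @param site,quantity,axis Channel identity; \code{axis = NULL} tests for
#'   any axis of that (site, quantity).
#' @return Logical scalar.
#' @export
hasChannel <- function(x, site, quantity, axis = NULL) {
  rd <- rowData(x)
  hit <- rd$site == site & rd$quantity == quantity
  if (!is.null(axis)) hit <- hit & rd$axis == axis
  any(hit)
}

#' Extract a channel's samples
#'
#' @param x A \linkS4class{TugRecording}.
#' @param site,quantity Channel identity.
#' @param axis Single axis for a vector; \code{NULL} returns all axes of
#'   the (site, quantity) pair as a matrix (axes in rows).
#' @return Numeric vector (single axis) or matrix (all axes).  A missing
#'   channel raises an error naming the absent (site, quantity).
#' @export
getChannel <- function(x, site, quantity, axis = NULL) {
  rd <- rowData(x)
  hit <- rd$site == site & rd$quantity == quantity
  if (!is.null(axis)) hit <- hit & rd$axis == axis
  if (!any(hit))
    stop("missing ", site, " ", quantity,
         if (!is.null(axis)) paste0(" (axis ", axis, ")"), " channel")
  m <- assay(x, "samples")[hit, , drop = FALSE]
  if (!is.null(axis) && nrow(m) == 1L) drop(m) else m
}

#' Quaternion trace of an orientation site
#'
#' @param x A \linkS4class{TugRecording}.
#' @param site Sensor site with stored orientation.
#' @return n x 4 matrix with columns \code{w}, \code{x}, \code{y},
#'   \code{z}, one unit quaternion per time point.
#' @export
orientationTrace <- function(x, site) {
  rd <- rowData(x)
  hit <- which(rd$site == site & rd$quantity == "orientation")
  if (length(hit) != 4L)
    stop("missing ", site, " orientation channel")
  ord <- hit[match(c("w", "x", "y", "z"), rd$axis[hit])]
  t(assay(x, "samples")[ord, , drop = FALSE])
}

#' @rdname TugGroundTruth-accessors
#' @export
setGeneric("truthTransitions", function(x) standardGeneric("truthTransitions"))

#' @rdname TugGroundTruth-accessors
#' @export
setGeneric("truthSegments", function(x) standardGeneric("truthSegments"))

#' @rdname TugGroundTruth-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' Accessors for TugGroundTruth
#'
#' @param x A \linkS4class{TugGroundTruth}.
#' @return \code{truthTransitions}: named numeric of the seven transition
#'   times (s); \code{truthSegments}: the six-segment data.frame;
#'   \code{truthLabels}: per-sample activity labels.
#' @name TugGroundTruth-accessors
#' @aliases truthTransitions truthSegments truthLabels
NULL

#' @rdname TugGroundTruth-accessors
setMethod("truthTransitions", "TugGroundTruth", function(x) x@transitions)

#' @rdname TugGroundTruth-accessors
setMethod("truthSegments", "TugGroundTruth", function(x) x@segments)

#' @rdname TugGroundTruth-accessors
setMethod("truthLabels", "TugGroundTruth", function(x) x@labels)
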