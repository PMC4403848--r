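## Quaternion algebra and joint range-of-motion (ROM) traces.  Quaternions
## are scalar-first [w x y z] with the Hamilton (right-handed) product.

.asQuat <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L) stop("a quaternion has 4 components [w x y z]")
  q
}

.quatNorm <- function(q) sqrt(sum(q^2))

#' Quaternion product and inverse
#'
#' Hamilton product of two unit quaternions and the inverse (the
#' conjugate, for unit quaternions).  Results are renormalized to guard
#' against floating-point drift.
#'
#' @param a,b Numeric length-4 quaternions, scalar first \code{[w x y z]}.
#' @return A unit quaternion.
#' @examples
#' qx90 <- c(cos(pi / 4), sin(pi / 4), 0, 0)   # 90 deg about x
#' quatMultiply(qx90, qx90)                    # 180 deg about x
#' @export
quatMultiply <- function(a, b) {
  a <- .asQuat(a); b <- .asQuat(b)
  if (.quatNorm(a) == 0 || .quatNorm(b) == 0) stop("zero-norm quaternion")
  out <- c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
           a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
           a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
           a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  out / .quatNorm(out)
}

#' @rdname quatMultiply
#' @export
quatInverse <- function(a) {
  a <- .asQuat(a)
  n <- .quatNorm(a)
  if (n == 0) stop("zero-norm quaternion")
  c(a[1], -a[2], -a[3], -a[4]) / n
}

#' Relative quaternion between two limb segments
#'
#' \code{q1^{-1} * q2}: the rotation carrying segment 1's orientation onto
#' segment 2's, e.g. thigh onto shin for the knee.
#'
#' @param q1,q2 Unit quaternions \code{[w x y z]}.
#' @return Unit quaternion.
#' @export
relativeQuaternion <- function(q1, q2) quatMultiply(quatInverse(q1), q2)

#' Change of a relative quaternion against the trial reference
#'
#' \code{q_ref^{-1} * q_rel}, where the reference relative quaternion was
#' captured at the start of the trial in the standard pose.
#'
#' @param q_ref Reference relative quaternion.
#' @param q_rel Current relative quaternion.
#' @return Unit quaternion.
#' @export
deltaQuaternion <- function(q_ref, q_rel) quatMultiply(quatInverse(q_ref), q_rel)

#' Rotation angle of a delta quaternion, degrees
#'
#' \code{2 * acos(|w|)} converted to degrees.  Taking the absolute value of
#' the scalar part resolves the double cover (q and -q encode the same
#' rotation) and enforces the small-angle (< 180 degree) representation;
#' the argument is clamped to [0, 1] before \code{acos}.
#'
#' @param q_delta Unit quaternion \code{[w x y z]}.
#' @return Angle in degrees, in [0, 180].
#' @examples
#' romAngle(c(cos(pi / 4), sin(pi / 4), 0, 0))   # 90
#' @export
romAngle <- function(q_delta) {
  q <- .asQuat(q_delta)
  2 * acos(min(1, max(0, abs(q[1]) / .quatNorm(q)))) * 180 / pi
}

.JOINTS <- list(
  left_knee = c("left_thigh", "left_shin"),
  right_knee = c("right_thigh", "right_shin"),
  left_hip = c("hip", "left_thigh"),
  right_hip = c("hip", "right_thigh"))

#' Joint range-of-motion trace
#'
#' Computes the scalar joint angle over time from the orientation
#' quaternions of the two limb segments spanning a joint: per sample the
#' relative quaternion \code{q1^{-1} q2}, its change against the t = 0
#' reference (the standard pose at trial start), and the rotation angle.
#' Successive delta quaternions are hemisphere-aligned (sign-flipped when
#' the dot product with the previous sample is negative) before angle
#' extraction, ensuring continuity of the trace.
#'
#' @param rec A \linkS4class{TugRecording} with orientation channels for
#'   both segments.
#' @param joint \code{"left_knee"}, \code{"right_knee"}, \code{"left_hip"},
#'   \code{"right_hip"}, or a character vector of two site names
#'   \code{c(proximal, distal)}.
#' @param reference_time_s Time at which the reference pose is captured
#'   (default 0, the start of the trial).
#' @return List with \code{joint}, \code{angles_deg} (numeric vector, one
#'   angle per sample, in [0, 180)), and \code{reference_time_s}.
#' @export
romTrace <- function(rec, joint = "left_knee", reference_time_s = 0) {
  sites <- if (is.character(joint) && length(joint) == 2L) joint
  else .JOINTS[[joint]]
  if (is.null(sites)) stop("unknown joint '", joint, "'")
  q1 <- orientationTrace(rec, sites[1])
  q2 <- orientationTrace(rec, sites[2])
  n <- nrow(q1)
  rate <- rateHz(rec)
  jref <- round(reference_time_s * rate) + 1L
  if (jref < 1L || jref > n) stop("reference time outside the trial")
  ## vectorized relative quaternion q1^-1 * q2 per sample
  rel <- .quatRelRows(q1, q2)
  qref <- rel[jref, ]
  dq <- .quatRelRows(matrix(qref, n, 4, byrow = TRUE), rel)
  ## hemisphere alignment for continuity
  s <- rep(1, n)
  for (i in 2:n) {
    if (sum(dq[i, ] * dq[i - 1L, ] * s[i - 1L]) < 0) s[i] <- -s[i - 1L]
    else s[i] <- s[i - 1L]
  }
  dq <- dq * s
  w <- pmin(1, pmax(-1, dq[, 1]))
  angles <- 2 * acos(abs(w)) * 180 / pi
  list(joint = if (length(joint) == 1L) joint else paste(joint, collapse = "-"),
       angles_deg = angles, reference_time_s = reference_time_s)
}

## rowwise a^-1 * b for n x 4 matrices of unit quaternions
.quatRelRows <- function(a, b) {
  aw <- a[, 1]; ax <- -a[, 2]; ay <- -a[, 3]; az <- -a[, 4]  # conjugate
  bw <- b[, 1]; bx <- b[, 2]; by <- b[, 3]; bz <- b[, 4]
  out <- cbind(aw * bw - ax * bx - ay * by - az * bz,
               aw * bx + ax * bw + ay * bz - az * by,
               aw * by - ax * bz + ay * bw + az * bx,
               aw * bz + ax * by - ay * bx + az * bw)
  out / sqrt(rowSums(out^2))
}
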