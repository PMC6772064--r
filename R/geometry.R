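#' @include constructors.R
NULL

#' Perturb sensor orientations independently
#'
#' Rotates each sensor's sensitive axis by exactly `|angle|` degrees about one
#' of the three frame axes (roll, pitch or yaw) chosen uniformly at random per
#' sensor; the sign of `angle` sets the sense of rotation. Positions, gains,
#' labels and ordering are unchanged. This is the elementary orientation-error
#' injection used to build perturbation curves.
#'
#' @param array a [SensorArray-class].
#' @param angle perturbation angle, degrees.
#' @param seed RNG seed (the same seed reproduces the array bit-exactly).
#' @return the perturbed [SensorArray-class].
#' @export
perturbOrientations <- function(array, angle, seed = NULL) {
  if (!is.finite(angle)) stop("angle must be finite")
  if (angle == 0) return(array)
  n <- nChannels(array)
  ori <- sensorOrientations(array)
  axes <- withSeed(seed, sample.int(3, n, replace = TRUE))
  th <- deg2rad(angle)
  out <- ori
  for (i in seq_len(n)) {
    e <- c(0, 0, 0); e[axes[i]] <- 1
    out[i, ] <- rotationMatrix(e, th) %*% ori[i, ]
  }
  sensorArray(sensorPositions(array), out, sensorGains(array),
              channelLabels(array), array@frame)
}

#' Displace a rigid array along an arc
#'
#' Rotates the whole array rigidly about an axis through `centre` by the angle
#' subtended by an arc of length `arcMm` at the mean sensor distance from
#' `centre`. Relative inter-sensor geometry is preserved exactly; orientations
#' co-rotate. Models sliding a rigid on-scalp array around the head.
#'
#' @param array a [SensorArray-class].
#' @param arcMm arc length, millimetres (sign sets direction).
#' @param centre rotation centre, metres (typically the fitted head-sphere
#'   centre).
#' @param axis rotation axis (default the head frame's left-right x axis).
#' @export
displaceArc <- function(array, arcMm, centre, axis = c(1, 0, 0)) {
  if (vnorm(axis) == 0) stop("rotation axis must be non-zero")
  stopIfNotFinite(centre, "centre")
  if (arcMm == 0) return(array)
  pos <- sensorPositions(array)
  rbar <- mean(sqrt(rowSums(sweep(pos, 2, centre)^2)))
  theta <- (arcMm / 1000) / rbar
  R <- rotationMatrix(axis, theta)
  newPos <- sweep(sweep(pos, 2, centre) %*% t(R), 2, centre, "+")
  newOri <- sensorOrientations(array) %*% t(R)
  sensorArray(newPos, newOri, sensorGains(array), channelLabels(array),
              array@frame)
}

#' 3x3 rotation matrix of a rigid transform
#' @param pose a [RigidTransform-class].
#' @export
poseRotation <- function(pose) {
  ang <- vnorm(pose@rotation)
  if (ang == 0) diag(3) else rotationMatrix(pose@rotation, ang)
}

#' Apply a rigid transform to an array
#'
#' Positions map as p -> R (p - pivot) + pivot + t; orientations map by R.
#' Gains and labels are untouched.
#'
#' @param array a [SensorArray-class].
#' @param pose a [RigidTransform-class].
#' @param pivot rotation pivot, metres (default the array centroid).
#' @export
applyPose <- function(array, pose, pivot = NULL) {
  pos <- sensorPositions(array)
  if (is.null(pivot)) pivot <- colMeans(pos)
  R <- poseRotation(pose)
  newPos <- sweep(sweep(pos, 2, pivot) %*% t(R), 2, pivot + pose@translation, "+")
  newOri <- sensorOrientations(array) %*% t(R)
  sensorArray(newPos, newOri, sensorGains(array), channelLabels(array),
              array@frame)
}

#' Compose two rigid transforms (first `a`, then `b`, same pivot)
#' @param a,b [RigidTransform-class] objects.
#' @export
composePoses <- function(a, b) {
  Ra <- poseRotation(a); Rb <- poseRotation(b)
  R <- Rb %*% Ra
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) {
    rot <- c(0, 0, 0)
  } else {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (vnorm(ax) < 1e-12) { # angle ~ pi: extract axis from R + I
      M <- (R + diag(3)) / 2
      ax <- sqrt(pmax(diag(M), 0))
      k <- which.max(ax)
      ax <- M[, k] / ax[k]
    }
    rot <- ang * ax / vnorm(ax)
  }
  rigidTransform(rot, Rb %*% a@translation + b@translation)
}

#' Invert a rigid transform (about the same pivot)
#' @param pose a [RigidTransform-class].
#' @export
invertPose <- function(pose) {
  R <- poseRotation(pose)
  rigidTransform(-pose@rotation, -t(R) %*% pose@translation)
}

#' Apply multiplicative random gain errors
#'
#' Multiplies each sensor gain by an independent draw from
#' Normal(1, fraction^2), modelling calibration/cross-talk imperfections.
#'
#' @param array a [SensorArray-class].
#' @param fraction standard deviation of the multiplicative error (0 <= f < 1;
#'   sign flips are not modelled).
#' @param seed RNG seed; draws are fixed per seed.
#' @export
applyGainError <- function(array, fraction, seed = NULL) {
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must satisfy 0 <= fraction < 1")
  if (fraction == 0) return(array)
  mult <- withSeed(seed, stats::rnorm(nChannels(array), 1, fraction))
  sensorArray(sensorPositions(array), sensorOrientations(array),
              sensorGains(array) * mult, channelLabels(array), array@frame)
}
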