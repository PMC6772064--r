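#' @include AllClasses.R
NULL

#' Construct a sensor array
#'
#' @param positions Nc x 3 matrix of sensor positions, metres.
#' @param orientations Nc x 3 matrix of sensitive-axis directions; rows are
#'   renormalised to unit length.
#' @param gains per-channel gains (default 1).
#' @param labels channel labels (default "CH001", ...).
#' @param frame coordinate-frame identifier.
#' @return a [SensorArray-class].
#' @examples
#' arr <- sensorArray(matrix(c(0, 0, 0.1), 1, 3), matrix(c(0, 0, 1), 1, 3))
#' nChannels(arr)
#' @export
sensorArray <- function(positions, orientations, gains = NULL, labels = NULL,
                        frame = "head") {
  positions <- rbind(positions)
  orientations <- normalizeRows(rbind(orientations))
  n <- nrow(positions)
  if (is.null(gains)) gains <- rep(1, n)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(n))
  new("SensorArray", positions = unname(positions),
      orientations = unname(orientations), gains = as.numeric(gains),
      labels = as.character(labels), frame = frame)
}

#' Construct a rigid transform
#'
#' @param rotation axis-angle vector (radians); the vector norm is the angle.
#' @param translation translation vector, metres.
#' @export
rigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation))
}

#' Construct a source space
#'
#' @param positions Nd x 3 dipole locations, metres.
#' @param orientations Nd x 3 dipole orientation constraints (cortical
#'   normals); renormalised to unit length.
#' @param areas optional per-vertex weights.
#' @export
sourceSpace <- function(positions, orientations, areas = numeric()) {
  new("SourceSpace", positions = unname(rbind(positions)),
      orientations = normalizeRows(unname(rbind(orientations))),
      areas = as.numeric(areas))
}

#' Construct a sphere volume conductor
#'
#' @param centre sphere centre, metres.
#' @param radius sphere radius, metres.
#' @param kind "sphere_global" or "sphere_local".
#' @export
sphereModel <- function(centre, radius, kind = "sphere_global") {
  new("SphereModel", kind = kind, centre = as.numeric(centre),
      radius = as.numeric(radius))
}

#' Construct a corrected-sphere (single shell) volume conductor
#'
#' @param vertices,faces closed outward-oriented triangulated inner-skull
#'   surface (metres; 1-based faces).
#' @param shOrder maximum degree of the spherical-harmonic correction basis.
#' @export
singleShellModel <- function(vertices, faces, shOrder = 8) {
  fit <- fitSphere(list(vertices = vertices, faces = faces))
  new("SingleShellModel", vertices = unname(rbind(vertices)),
      faces = matrix(as.integer(faces), ncol = 3), shOrder = shOrder,
      centre = fit@centre, radius = fit@radius, cache = new.env(parent = emptyenv()))
}

#' Construct a data matrix
#'
#' @param values Nc x Nt channel-by-sample matrix, tesla.
#' @param sampleRate sampling rate, Hz.
#' @param labels channel labels.
#' @param window start/stop seconds of the represented interval.
#' @export
dataMatrix <- function(values, sampleRate, labels = NULL, window = NULL) {
  values <- rbind(values)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(nrow(values)))
  if (is.null(window)) window <- c(0, ncol(values) / sampleRate)
  if (ncol(values) < nrow(values))
    warning("fewer samples than channels; covariance estimates will be rank deficient")
  new("DataMatrix", values = unname(values), sampleRate = sampleRate,
      window = as.numeric(window), labels = as.character(labels))
}

#' Simulation protocol parameters
#'
#' Defaults reproduce the reference synthetic protocol: 13 channels, a single
#' 10 Hz dipole of 10 nAm in somatosensory cortex, 100 fT RMS white sensor
#' noise, single 1 s trials at 200 Hz.
#'
#' @param nChannels number of sensors.
#' @param sourceLocation dipole location, metres. The default scales the
#'   MNI-like target (46, -25, 60) mm onto the synthetic source shell.
#' @param sourceFreq sinusoid frequency, Hz.
#' @param dipoleMoment ampere-metres.
#' @param noiseRms tesla.
#' @param duration seconds.
#' @param sampleRate Hz.
#' @param nTrials trials averaged.
#' @param seed RNG seed.
#' @export
simulationSpec <- function(nChannels = 13,
                           sourceLocation = defaultSourceLocation(),
                           sourceFreq = 10, dipoleMoment = 10e-9,
                           noiseRms = 100e-15, duration = 1,
                           sampleRate = 200, nTrials = 1, seed = 0) {
  new("SimulationSpec", nChannels = nChannels,
      sourceLocation = as.numeric(sourceLocation), sourceFreq = sourceFreq,
      dipoleMoment = dipoleMoment, noiseRms = noiseRms, duration = duration,
      sampleRate = sampleRate, nTrials = nTrials, seed = seed)
}

#' Default somatosensory target in the synthetic head
#'
#' The MNI-like coordinate (46, -25, 60) mm scaled to the default source-shell
#' radius (70 mm), in metres.
#' @export
defaultSourceLocation <- function(sourceRadius = 0.07) {
  mni <- c(46, -25, 60) / 1000
  mni * sourceRadius / vnorm(mni)
}

#' Build a two-component covariance model directly
#'
#' Assembles C = lambda1 I + lambda2 L diag(gamma) L^T without hyperparameter
#' optimisation (useful for fixed-hyperparameter reconstructions and tests).
#'
#' @param leadfield a [LeadField-class].
#' @param gamma per-source prior weights (unit mean recommended).
#' @param lambda1 sensor-noise variance, tesla^2.
#' @param lambda2 source-prior scale.
#' @export
covarianceModel <- function(leadfield, gamma, lambda1, lambda2) {
  L <- leadfieldMatrix(leadfield)
  C <- lambda2 * (L %*% (gamma * t(L)))
  diag(C) <- diag(C) + lambda1
  C <- (C + t(C)) / 2
  new("CovarianceModel", lambda = c(lambda1 = lambda1, lambda2 = lambda2),
      gamma = gamma, Cmodel = C, logLambda = c(0, 0),
      SigmaLambda = diag(1e6, 2), priorMean = c(0, 0),
      priorPrecision = diag(1e-6, 2), scale = 1)
}
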