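#' @import methods
NULL

#' SensorArray: a rigid array of point magnetometers
#'
#' Positions (metres) and sensitive-axis orientations (unit vectors) of a set
#' of point magnetometers, with per-channel gains and unique labels. Each
#' sensor measures the field component along its orientation, scaled by its
#' gain.
#'
#' @slot positions numeric matrix, Nc x 3, metres (head frame).
#' @slot orientations numeric matrix, Nc x 3, unit rows (sensitive axes).
#' @slot gains numeric vector of positive dimensionless gains (nominal 1).
#' @slot labels character vector of unique channel labels.
#' @slot frame single string identifying the coordinate frame.
#' @exportClass SensorArray
setClass("SensorArray",
  representation(positions = "matrix", orientations = "matrix",
                 gains = "numeric", labels = "character", frame = "character"),
  validity = function(object) {
    n <- nrow(object@positions)
    msg <- character()
    if (n < 1) msg <- c(msg, "array must contain at least one sensor")
    if (!all(dim(object@positions) == c(n, 3))) msg <- c(msg, "positions must be Nc x 3")
    if (!all(dim(object@orientations) == c(n, 3))) msg <- c(msg, "orientations must be Nc x 3")
    if (length(object@gains) != n) msg <- c(msg, "one gain per sensor required")
    if (length(object@labels) != n) msg <- c(msg, "one label per sensor required")
    if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
    if (any(object@gains <= 0)) msg <- c(msg, "gains must be positive")
    if (!all(is.finite(object@positions))) msg <- c(msg, "positions must be finite")
    if (nrow(object@orientations) == n && n >= 1 &&
        any(abs(rowNorms(object@orientations) - 1) > 1e-6))
      msg <- c(msg, "orientations must be unit vectors")
    if (length(msg)) msg else TRUE
  })

#' RigidTransform: a rigid-body pose
#'
#' Axis-angle rotation (radians; vector norm = angle) plus translation
#' (metres). The parameter vector searched by the Metropolis pose sampler.
#'
#' @slot rotation numeric length-3 axis-angle vector, radians.
#' @slot translation numeric length-3 vector, metres.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric"),
  validity = function(object) {
    if (length(object@rotation) != 3 || length(object@translation) != 3)
      return("rotation and translation must have length 3")
    if (!all(is.finite(c(object@rotation, object@translation))))
      return("pose parameters must be finite")
    TRUE
  })

#' SourceSpace: candidate dipole locations with orientation constraint
#'
#' @slot positions numeric matrix Nd x 3, metres.
#' @slot orientations numeric matrix Nd x 3, unit rows (cortical normals).
#' @slot areas numeric per-vertex weights (possibly empty).
#' @exportClass SourceSpace
setClass("SourceSpace",
  representation(positions = "matrix", orientations = "matrix", areas = "numeric"),
  validity = function(object) {
    n <- nrow(object@positions)
    if (n < 1) return("source space must contain at least one dipole")
    if (!all(dim(object@orientations) == c(n, 3)))
      return("orientations must be Nd x 3")
    if (any(abs(rowNorms(object@orientations) - 1) > 1e-6))
      return("orientations must be unit vectors")
    if (length(object@areas) && length(object@areas) != n)
      return("areas must be empty or length Nd")
    TRUE
  })

#' Virtual volume-conductor class
#' @exportClass HeadModel
setClass("HeadModel", representation("VIRTUAL"))

#' SphereModel: homogeneous conducting sphere volume conductor
#'
#' @slot kind "sphere_global" or "sphere_local".
#' @slot centre numeric length-3 centre, metres.
#' @slot radius positive radius, metres.
#' @exportClass SphereModel
setClass("SphereModel", contains = "HeadModel",
  representation(kind = "character", centre = "numeric", radius = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("sphere_global", "sphere_local"))
      return("kind must be sphere_global or sphere_local")
    if (length(object@centre) != 3) return("centre must have length 3")
    if (object@radius <= 0) return("radius must be positive")
    TRUE
  })

#' SingleShellModel: corrected-sphere volume conductor
#'
#' A closed triangulated inner-skull shell. The lead field is the fitted-sphere
#' solution plus an exterior spherical-harmonic correction whose coefficients
#' cancel the mismatch in the field component normal to the shell surface.
#'
#' @slot vertices numeric matrix Nv x 3, metres.
#' @slot faces integer matrix Nf x 3 (1-based, outward-oriented).
#' @slot shOrder maximum spherical-harmonic degree of the correction basis.
#' @slot centre,radius sphere fitted to the shell (used for the sphere term).
#' @slot cache environment caching the correction solve per source space.
#' @exportClass SingleShellModel
setClass("SingleShellModel", contains = "HeadModel",
  representation(vertices = "matrix", faces = "matrix", shOrder = "numeric",
                 centre = "numeric", radius = "numeric", cache = "environment"),
  validity = function(object) {
    if (ncol(object@vertices) != 3) return("vertices must be Nv x 3")
    if (ncol(object@faces) != 3) return("faces must be Nf x 3")
    if (object@shOrder < 1) return("shOrder must be >= 1")
    v <- nrow(object@vertices); f <- nrow(object@faces)
    ed <- unique(rbind(
      t(apply(object@faces[, c(1, 2), drop = FALSE], 1, sort)),
      t(apply(object@faces[, c(2, 3), drop = FALSE], 1, sort)),
      t(apply(object@faces[, c(1, 3), drop = FALSE], 1, sort))))
    if (v - nrow(ed) + f != 2)
      return("shell mesh must be closed (Euler characteristic 2)")
    TRUE
  })

#' LeadField: sensor-by-source gain matrix
#'
#' Entry (c, d) is the field (tesla) measured by sensor c in response to a
#' unit dipole (1 A·m) at source d along its orientation constraint.
#'
#' @slot matrix numeric Nc x Nd, tesla per ampere-metre.
#' @slot arrayRef,sourceRef,headRef provenance fingerprints of the inputs.
#' @exportClass LeadField
setClass("LeadField",
  representation(matrix = "matrix", arrayRef = "character",
                 sourceRef = "character", headRef = "character"),
  validity = function(object) {
    if (!all(is.finite(object@matrix))) return("lead field must be finite")
    TRUE
  })

#' DataMatrix: multichannel field recording
#'
#' @slot values numeric Nc x Nt matrix, tesla.
#' @slot sampleRate sampling rate, Hz.
#' @slot window start/stop of the represented interval, seconds.
#' @slot labels channel labels matching a SensorArray.
#' @exportClass DataMatrix
setClass("DataMatrix",
  representation(values = "matrix", sampleRate = "numeric",
                 window = "numeric", labels = "character"),
  validity = function(object) {
    if (nrow(object@values) != length(object@labels))
      return("one label per channel required")
    if (object@sampleRate <= 0) return("sampleRate must be positive")
    if (length(object@window) != 2) return("window must be length 2")
    TRUE
  })

#' CovarianceModel: two-component sensor covariance model
#'
#' Implied model covariance C = lambda1 I + lambda2 L diag(Gamma) L^T with a
#' white sensor-noise component and an empirical beamformer source prior.
#'
#' @slot lambda named numeric(2): lambda1 (tesla^2) and lambda2.
#' @slot gamma per-source prior variance weights, unit mean.
#' @slot Cmodel implied Nc x Nc model covariance.
#' @slot logLambda posterior mean of the scaled log-hyperparameters.
#' @slot SigmaLambda 2x2 posterior covariance of the log-hyperparameters.
#' @slot priorMean,priorPrecision Gaussian prior on the log-hyperparameters.
#' @slot scale data scale factor mapping scaled to natural hyperparameters.
#' @exportClass CovarianceModel
setClass("CovarianceModel",
  representation(lambda = "numeric", gamma = "numeric", Cmodel = "matrix",
                 logLambda = "numeric", SigmaLambda = "matrix",
                 priorMean = "numeric", priorPrecision = "matrix",
                 scale = "numeric"),
  validity = function(object) {
    if (any(object@gamma < 0)) return("gamma entries must be >= 0")
    if (!isSymmetric(unname(object@Cmodel), tol = 1e-8))
      return("Cmodel must be symmetric")
    TRUE
  })

#' EvidenceResult: free energy and its decomposition
#'
#' @slot F negative variational free energy, nats.
#' @slot accuracy Gaussian log-likelihood (data-fit) term, nats.
#' @slot complexity hyperparameter Occam penalty, nats (>= 0).
#' @slot lambdaHat natural-scale hyperparameter estimates.
#' @slot SigmaLambda posterior covariance of the log-hyperparameters.
#' @slot converged logical optimizer convergence flag.
#' @slot iterations number of optimizer iterations used.
#' @exportClass EvidenceResult
setClass("EvidenceResult",
  representation(F = "numeric", accuracy = "numeric", complexity = "numeric",
                 lambdaHat = "numeric", SigmaLambda = "matrix",
                 converged = "logical", iterations = "numeric"),
  validity = function(object) {
    if (abs(object@F - (object@accuracy - object@complexity)) > 1e-9 *
        max(1, abs(object@F)))
      return("F must equal accuracy - complexity")
    TRUE
  })

#' SourceEstimate: posterior current estimate
#'
#' @slot J numeric Nd x Nt, ampere-metres.
#' @slot power per-source mean squared current.
#' @slot peakIndex index of the maximum-power source.
#' @exportClass SourceEstimate
setClass("SourceEstimate",
  representation(J = "matrix", power = "numeric", peakIndex = "integer"),
  validity = function(object) {
    if (!all(is.finite(object@J))) return("J must be finite")
    if (length(object@power) != nrow(object@J)) return("one power per source")
    if (length(object@power) &&
        abs(object@power[object@peakIndex] - max(object@power)) > 1e-12 * max(1, max(object@power)))
      return("peakIndex must attain the maximum of power")
    TRUE
  })

#' PerturbationCurve: evidence vs injected geometric error
#'
#' @slot offsets strictly increasing perturbation magnitudes (degrees or mm).
#' @slot Fvalues nRepeats x nOffsets matrix of absolute free energies.
#' @slot kind "orientation", "arc" or "volume".
#' @slot unit "degrees" or "mm".
#' @slot seed RNG seed used to draw the random perturbations.
#' @exportClass PerturbationCurve
setClass("PerturbationCurve",
  representation(offsets = "numeric", Fvalues = "matrix", kind = "character",
                 unit = "character", seed = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@offsets, strictly = TRUE))
      return("offsets must be strictly increasing")
    if (ncol(object@Fvalues) != length(object@offsets))
      return("one column of F values per offset")
    if (!all(is.finite(object@Fvalues))) return("F values must be finite")
    TRUE
  })

#' PosteriorSummary: pose posterior from Metropolis + BMA
#'
#' @slot meanPose evidence-weighted posterior mean pose.
#' @slot ellipsoidCentre weighted mean position of the tracked point, metres.
#' @slot ellipsoidCov 3x3 weighted covariance of the tracked point.
#' @slot level confidence level of the reported ellipsoid.
#' @slot volumeCm3 ellipsoid volume, cubic centimetres.
#' @slot degenerate flag set when the sample cloud is rank deficient.
#' @slot samples data.frame of chain samples (chain, iteration, pose, F, accepted).
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
  representation(meanPose = "RigidTransform", ellipsoidCentre = "numeric",
                 ellipsoidCov = "matrix", level = "numeric",
                 volumeCm3 = "numeric", degenerate = "logical",
                 samples = "data.frame"),
  validity = function(object) {
    ev <- eigen(object@ellipsoidCov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-12 * max(1, abs(ev[1])))) return("ellipsoid covariance must be PSD")
    if (object@volumeCm3 < 0) return("volume must be >= 0")
    TRUE
  })

#' SimulationSpec: parameters of the synthetic recording protocol
#'
#' Defaults emulate the simulation protocol used throughout: 13 on-scalp point
#' magnetometers over sensorimotor cortex, one 10 Hz sinusoidal dipole of
#' 10 nAm, additive white sensor noise of 100 fT RMS, 1 s single trials.
#'
#' @slot nChannels number of sensors.
#' @slot sourceLocation dipole location, metres (head frame).
#' @slot sourceFreq sinusoid frequency, Hz.
#' @slot dipoleMoment dipole moment, ampere-metres.
#' @slot noiseRms per-channel white-noise RMS, tesla.
#' @slot duration trial duration, seconds.
#' @slot sampleRate sampling rate, Hz.
#' @slot nTrials trials averaged (noise RMS scales as 1/sqrt(nTrials)).
#' @slot seed RNG seed.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(nChannels = "numeric", sourceLocation = "numeric",
                 sourceFreq = "numeric", dipoleMoment = "numeric",
                 noiseRms = "numeric", duration = "numeric",
                 sampleRate = "numeric", nTrials = "numeric", seed = "numeric"),
  validity = function(object) {
    pos <- c(object@nChannels, object@sourceFreq, object@dipoleMoment,
             object@duration, object@sampleRate, object@nTrials)
    if (any(pos <= 0)) return("all scalar parameters must be positive")
    if (object@noiseRms < 0) return("noiseRms must be >= 0")
    if (object@nChannels < 1) return("need at least one channel")
    TRUE
  })
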