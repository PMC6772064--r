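#' @include AllGenerics.R
NULL

setMethod("nChannels", "SensorArray", function(x) nrow(x@positions))
setMethod("nChannels", "DataMatrix", function(x) nrow(x@values))
setMethod("nChannels", "LeadField", function(x) nrow(x@matrix))
setMethod("nSources", "SourceSpace", function(x) nrow(x@positions))
setMethod("nSources", "LeadField", function(x) ncol(x@matrix))
setMethod("nSamples", "DataMatrix", function(x) ncol(x@values))

setMethod("sensorPositions", "SensorArray", function(x) x@positions)
setMethod("sensorOrientations", "SensorArray", function(x) x@orientations)
setMethod("sensorGains", "SensorArray", function(x) x@gains)
setMethod("channelLabels", "SensorArray", function(x) x@labels)
setMethod("channelLabels", "DataMatrix", function(x) x@labels)
setMethod("leadfieldMatrix", "LeadField", function(x) x@matrix)
setMethod("freeEnergyValue", "EvidenceResult", function(x) x@F)
setMethod("sourcePower", "SourceEstimate", function(x) x@power)
setMethod("peakIndex", "SourceEstimate", function(x) x@peakIndex)

setMethod("relativeF", "PerturbationCurve", function(x) {
  m <- colMeans(x@Fvalues)
  m - max(m)
})

#' Values of a data matrix
#' @param x a DataMatrix.
#' @export
dataValues <- function(x) x@values

#' Source positions / orientations (metres, unit vectors)
#' @param x a SourceSpace.
#' @export
sourcePositions <- function(x) x@positions

#' @rdname sourcePositions
#' @export
sourceOrientations <- function(x) x@orientations

#' Perturbation-curve offsets and per-offset free energies
#' @param x a PerturbationCurve.
#' @export
curveOffsets <- function(x) x@offsets

#' @rdname curveOffsets
#' @export
curveFvalues <- function(x) x@Fvalues

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray: %d point magnetometers [frame: %s]\n",
              nChannels(object), object@frame))
  r <- rowNorms(object@positions)
  cat(sprintf("  position radii %.1f-%.1f mm; gains %.3g-%.3g\n",
              1000 * min(r), 1000 * max(r), min(object@gains), max(object@gains)))
})

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf("SourceSpace: %d constrained dipoles\n", nSources(object)))
})

setMethod("show", "SphereModel", function(object) {
  cat(sprintf("SphereModel (%s): centre (%.1f, %.1f, %.1f) mm, radius %.1f mm\n",
              object@kind, object@centre[1] * 1000, object@centre[2] * 1000,
              object@centre[3] * 1000, object@radius * 1000))
})

setMethod("show", "SingleShellModel", function(object) {
  cat(sprintf("SingleShellModel: %d vertices / %d faces, sh order %d (fitted radius %.1f mm)\n",
              nrow(object@vertices), nrow(object@faces), object@shOrder,
              object@radius * 1000))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels x %d sources [T/(A.m)], |L| range %.3g-%.3g\n",
              nrow(object@matrix), ncol(object@matrix),
              min(abs(object@matrix)), max(abs(object@matrix))))
})

setMethod("show", "DataMatrix", function(object) {
  cat(sprintf("DataMatrix: %d channels x %d samples @ %g Hz (%.3f-%.3f s)\n",
              nChannels(object), nSamples(object), object@sampleRate,
              object@window[1], object@window[2]))
})

setMethod("show", "EvidenceResult", function(object) {
  cat(sprintf("EvidenceResult: F = %.3f (accuracy %.3f - complexity %.3f)%s\n",
              object@F, object@accuracy, object@complexity,
              if (object@converged) "" else " [not converged]"))
  cat(sprintf("  lambda1 = %.4g T^2, lambda2 = %.4g\n",
              object@lambdaHat[1], object@lambdaHat[2]))
})

setMethod("show", "SourceEstimate", function(object) {
  cat(sprintf("SourceEstimate: %d sources x %d samples, peak at source %d\n",
              nrow(object@J), ncol(object@J), object@peakIndex))
})

setMethod("show", "PerturbationCurve", function(object) {
  cat(sprintf("PerturbationCurve (%s): %d offsets (%g to %g %s), %d repeats\n",
              object@kind, length(object@offsets), min(object@offsets),
              max(object@offsets), object@unit, nrow(object@Fvalues)))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary: %d chain samples, %.0f%% ellipsoid volume %.4g cm^3%s\n",
              nrow(object@samples), 100 * object@level, object@volumeCm3,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: angle %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
              rad2deg(vnorm(object@rotation)), object@translation[1] * 1000,
              object@translation[2] * 1000, object@translation[3] * 1000))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d channels, %g Hz dipole of %.3g nAm, noise %.3g fT RMS, %g s @ %g Hz x %d trial(s)\n",
              object@nChannels, object@sourceFreq, object@dipoleMoment * 1e9,
              object@noiseRms * 1e15, object@duration, object@sampleRate,
              object@nTrials))
})
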