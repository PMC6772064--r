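#' @include AllClasses.R
NULL

#' Number of channels
#' @param x a SensorArray, DataMatrix or LeadField.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of candidate sources
#' @param x a SourceSpace or LeadField.
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' Number of time samples
#' @param x a DataMatrix.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sensor positions (metres)
#' @param x a SensorArray.
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))

#' Sensor sensitive-axis orientations (unit vectors)
#' @param x a SensorArray.
#' @export
setGeneric("sensorOrientations", function(x) standardGeneric("sensorOrientations"))

#' Sensor gains
#' @param x a SensorArray.
#' @export
setGeneric("sensorGains", function(x) standardGeneric("sensorGains"))

#' Channel labels
#' @param x a SensorArray or DataMatrix.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Lead-field gain matrix (tesla per ampere-metre)
#' @param x a LeadField.
#' @export
setGeneric("leadfieldMatrix", function(x) standardGeneric("leadfieldMatrix"))

#' Compute the lead field of an array/source-space/volume-conductor triple
#'
#' Dispatches on the volume conductor: the Sarvas closed form for
#' [SphereModel-class] and the corrected-sphere construction for
#' [SingleShellModel-class].
#'
#' @param array a [SensorArray-class].
#' @param sources a [SourceSpace-class].
#' @param head a [HeadModel-class].
#' @return a [LeadField-class].
#' @export
setGeneric("computeLeadfield",
           function(array, sources, head) standardGeneric("computeLeadfield"))

#' Free energy value
#' @param x an EvidenceResult.
#' @export
setGeneric("freeEnergyValue", function(x) standardGeneric("freeEnergyValue"))

#' Source-power vector and peak
#' @param x a SourceEstimate.
#' @export
setGeneric("sourcePower", function(x) standardGeneric("sourcePower"))

#' @rdname sourcePower
#' @export
setGeneric("peakIndex", function(x) standardGeneric("peakIndex"))

#' Mean relative free energy of a perturbation curve
#'
#' Per-offset mean F, shifted so the curve maximum is 0 (the normalisation
#' used when comparing systems whose absolute evidence is not comparable).
#' @param x a PerturbationCurve.
#' @export
setGeneric("relativeF", function(x) standardGeneric("relativeF"))
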