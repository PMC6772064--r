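#' @include inversion.R
NULL

#' Free energy of a covariance model
#'
#' Negative variational free energy F = accuracy - complexity. The accuracy is
#' the Gaussian log-likelihood of the data under the model covariance C,
#' `-Nt/2 [trace(CY C^-1) + log|C| + Nc log 2pi]` with CY = Y Y^T / Nt; the
#' complexity is the variational-Laplace Occam penalty on the
#' log-hyperparameters, `1/2 (h - nu)^T Pi (h - nu) - 1/2 log|Sigma Pi|`,
#' which is non-negative whenever the posterior is at least as precise as the
#' prior. Differences of F between models of the same data approximate log
#' Bayes factors; a difference of 3 corresponds to ~20-fold evidence.
#'
#' @param CY sensor sample covariance (tesla^2), or a [DataMatrix-class] from
#'   which it is computed.
#' @param cov a [CovarianceModel-class].
#' @param Nt number of time samples.
#' @return an [EvidenceResult-class].
#' @export
freeEnergy <- function(CY, cov, Nt) {
  if (is(CY, "DataMatrix")) {
    Nt <- nSamples(CY)
    CY <- sampleCovariance(CY)
  }
  Nc <- nrow(CY)
  ch <- tryCatch(chol(cov@Cmodel), error = function(e)
    stop("model covariance is not positive definite"))
  logdet <- 2 * sum(log(diag(ch)))
  Cinv <- chol2inv(ch)
  accuracy <- -Nt / 2 * (sum(Cinv * CY) + logdet + Nc * log(2 * pi))
  dh <- cov@logLambda - cov@priorMean
  occam <- determinant(cov@SigmaLambda %*% cov@priorPrecision, logarithm = TRUE)
  complexity <- as.numeric(0.5 * t(dh) %*% cov@priorPrecision %*% dh -
                           0.5 * occam$modulus)
  new("EvidenceResult", F = accuracy - complexity, accuracy = accuracy,
      complexity = complexity, lambdaHat = cov@lambda,
      SigmaLambda = cov@SigmaLambda, converged = TRUE, iterations = 0)
}

#' Score a sensor geometry against recorded data
#'
#' Full evidence pipeline for one (data, array, source space, volume
#' conductor) combination: lead field, Empirical Bayes Beamformer prior,
#' hyperparameter optimisation, free energy. Deterministic given its inputs.
#' The resulting F values are comparable across candidate geometries for the
#' same data.
#'
#' @param data a [DataMatrix-class].
#' @param array a [SensorArray-class].
#' @param sources a [SourceSpace-class].
#' @param head a [HeadModel-class].
#' @param config list of inversion settings: `regularization` (EBB diagonal
#'   loading fraction, default 0), `covarianceNormalizer` ("Nt"/"Nc"),
#'   `maxIter`, `tol`.
#' @return an [EvidenceResult-class].
#' @export
scoreGeometry <- function(data, array, sources, head, config = list()) {
  cfg <- modifyList(list(regularization = 0, covarianceNormalizer = "Nt",
                         maxIter = 128, tol = 1e-4), config)
  if (!identical(channelLabels(data), channelLabels(array))) {
    ord <- match(channelLabels(data), channelLabels(array))
    if (any(is.na(ord))) stop("channel labels of data and array do not match")
    array <- sensorArray(sensorPositions(array)[ord, , drop = FALSE],
                         sensorOrientations(array)[ord, , drop = FALSE],
                         sensorGains(array)[ord], channelLabels(array)[ord],
                         array@frame)
  }
  lf <- computeLeadfield(array, sources, head)
  CY <- sampleCovariance(data, cfg$covarianceNormalizer)
  g <- ebbPrior(lf, CY, cfg$regularization)
  fit <- optimizeHyperparameters(CY, lf, g, nSamples(data),
                                 maxIter = cfg$maxIter, tol = cfg$tol)
  fit$evidence
}

#' Free-energy perturbation curve
#'
#' Scores systematically perturbed copies of a sensor array against fixed
#' data: per-sensor orientation errors (`kind = "orientation"`) or rigid arc
#' displacements of the whole array (`kind = "arc"`), optionally with
#' additional per-channel random gain error per model. The width of the
#' resulting relative-evidence peak quantifies how much geometric error the
#' system can hide, and is the basis for comparing sensor systems.
#'
#' @param data a [DataMatrix-class].
#' @param array the candidate true [SensorArray-class].
#' @param sources a [SourceSpace-class].
#' @param head a [HeadModel-class].
#' @param kind "orientation" or "arc".
#' @param offsets perturbation magnitudes (degrees for orientation, mm for
#'   arc); must include 0.
#' @param nRepeats random perturbed models per offset (orientation/gain kinds
#'   are stochastic; pure arc displacement is deterministic).
#' @param seed RNG seed for the random perturbations.
#' @param gainError optional gain-error fraction applied independently per
#'   model (see [applyGainError()]).
#' @param arcCentre,arcAxis rotation centre/axis for `kind = "arc"` (defaults:
#'   fitted-sphere centre of `head`, left-right x axis).
#' @param config inversion settings passed to [scoreGeometry()].
#' @return a [PerturbationCurve-class].
#' @export
perturbationCurve <- function(data, array, sources, head,
                              kind = c("orientation", "arc"),
                              offsets = seq(-20, 20, by = 2.5),
                              nRepeats = 1, seed = 0, gainError = 0,
                              arcCentre = NULL, arcAxis = c(1, 0, 0),
                              config = list()) {
  kind <- match.arg(kind)
  if (!any(offsets == 0)) stop("offsets must include 0")
  if (is.null(arcCentre))
    arcCentre <- if (is(head, "SphereModel") || is(head, "SingleShellModel"))
      head@centre else c(0, 0, 0)
  Fv <- matrix(NA_real_, nRepeats, length(offsets))
  # paired design: repeat r re-uses the same random axis/gain draws at every
  # offset, so offset columns differ by the perturbation magnitude only
  for (j in seq_along(offsets)) {
    for (r in seq_len(nRepeats)) {
      pert <- switch(kind,
        orientation = perturbOrientations(array, offsets[j],
                                          seed = subSeed(seed, r)),
        arc = displaceArc(array, offsets[j], arcCentre, arcAxis))
      if (gainError > 0)
        pert <- applyGainError(pert, gainError, seed = subSeed(seed, 500000 + r))
      Fv[r, j] <- freeEnergyValue(scoreGeometry(data, pert, sources, head, config))
    }
  }
  new("PerturbationCurve", offsets = as.numeric(offsets), Fvalues = Fv,
      kind = kind, unit = if (kind == "orientation") "degrees" else "mm",
      seed = as.numeric(seed))
}

#' Width of a perturbation curve at an evidence threshold
#'
#' Linear interpolation of the mean relative free energy to the offsets at
#' which it crosses `deltaF` on each side of the argmax. At the default
#' threshold of -3 nats the rejected models are exp(3) (about 20) times less
#' likely than the best model. Sides that never cross within the sampled
#' range are flagged open-ended.
#'
#' @param curve a [PerturbationCurve-class] (needs >= 3 offsets spanning the
#'   maximum).
#' @param deltaF threshold on the relative free energy, nats (< 0).
#' @return list with `lower` and `upper` crossing offsets (same units as the
#'   curve), `halfWidth` (mean absolute crossing distance from the argmax),
#'   `argmax`, and logical `openLower`/`openUpper` flags.
#' @export
widthAtThreshold <- function(curve, deltaF = -3) {
  if (length(curve@offsets) < 3) stop("need at least 3 offsets")
  relF <- relativeF(curve)
  x <- curve@offsets
  imax <- which.max(relF)
  if (all(relF < deltaF)) stop("curve entirely below the threshold; degenerate model")
  if (deltaF == 0)
    return(list(lower = x[imax], upper = x[imax], halfWidth = 0,
                argmax = x[imax], openLower = FALSE, openUpper = FALSE))
  crossSide <- function(idx) {
    # walk away from the argmax until relF drops through deltaF
    for (k in seq_along(idx)[-1]) {
      i0 <- idx[k - 1]; i1 <- idx[k]
      if (relF[i1] <= deltaF) {
        t <- (deltaF - relF[i0]) / (relF[i1] - relF[i0])
        return(list(x = x[i0] + t * (x[i1] - x[i0]), open = FALSE))
      }
    }
    list(x = x[idx[length(idx)]], open = TRUE)
  }
  lo <- crossSide(seq(imax, 1))
  up <- crossSide(seq(imax, length(x)))
  list(lower = lo$x, upper = up$x,
       halfWidth = (abs(lo$x - x[imax]) + abs(up$x - x[imax])) / 2,
       argmax = x[imax], openLower = lo$open, openUpper = up$open)
}
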