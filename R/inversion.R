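#' @include constructors.R
NULL

#' Sensor-level sample covariance
#'
#' Computes Y Y^T / Nt (default) or Y Y^T / Nc; the normaliser is a global
#' scale and cancels in all model comparisons, which use free-energy
#' differences.
#'
#' @param data a [DataMatrix-class] or a numeric channels-by-samples matrix.
#' @param normalizer "Nt" (conventional) or "Nc".
#' @return symmetric positive-semidefinite Nc x Nc matrix, tesla^2.
#' @export
sampleCovariance <- function(data, normalizer = c("Nt", "Nc")) {
  normalizer <- match.arg(normalizer)
  Y <- if (is(data, "DataMatrix")) dataValues(data) else rbind(data)
  if (ncol(Y) < 1 || nrow(Y) < 1) stop("empty data matrix")
  C <- tcrossprod(Y) / switch(normalizer, Nt = ncol(Y), Nc = nrow(Y))
  (C + t(C)) / 2
}

#' Empirical Bayes Beamformer source prior
#'
#' Per-source prior variance weights from the beamformer power estimate
#' Gamma_d = 1 / (l_d^T C^-1 l_d), where C is the (optionally regularised)
#' sensor sample covariance and l_d the lead-field column of source d. Valid
#' under the assumption of no zero-lag correlated sources. Weights are
#' normalised to unit mean.
#'
#' @param leadfield a [LeadField-class].
#' @param CY sensor sample covariance, tesla^2.
#' @param regularization fraction of the mean sensor variance added to the
#'   diagonal before inversion (default 0).
#' @return numeric vector of Nd non-negative weights with mean 1.
#' @export
ebbPrior <- function(leadfield, CY, regularization = 0) {
  L <- leadfieldMatrix(leadfield)
  C <- CY
  if (regularization > 0)
    diag(C) <- diag(C) + regularization * sum(diag(CY)) / nrow(CY)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular (regularised) covariance; raise `regularization`"))
  q <- colSums(L * (Cinv %*% L))   # l_d^T Cinv l_d per column
  g <- 1 / q
  g[!is.finite(g)] <- 0            # externally silent sources get zero weight
  g / mean(g)
}

# Penalised free energy of C = sum_i exp(h_i) Q_i given CY and Nt, with
# Gaussian prior N(nu, Pi^-1) on h. Returns F and the pieces at h.
.twoCompObjective <- function(h, Q1, Q2, CY, Nt, nu, Pi) {
  C <- exp(h[1]) * Q1 + exp(h[2]) * Q2
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  Cinv <- chol2inv(ch)
  Nc <- nrow(CY)
  acc <- -Nt / 2 * (sum(Cinv * CY) + logdet + Nc * log(2 * pi))
  pen <- -0.5 * t(h - nu) %*% Pi %*% (h - nu)
  list(value = acc + as.numeric(pen), accuracy = acc, Cinv = Cinv, C = C)
}

#' Optimise the noise/source hyperparameters by restricted maximum likelihood
#'
#' Fits the two-component covariance model C = lambda1 I + lambda2 L Gamma L^T
#' to the sensor sample covariance by Fisher-scoring ascent on the penalised
#' Gaussian log-evidence, with hyperparameters parameterised on the log scale
#' (prior mean 0, precision 1e-6 I: effectively non-informative). The
#' posterior covariance of the log-hyperparameters is taken from the curvature
#' (Fisher information + prior precision) at the optimum, and feeds the
#' free-energy complexity term.
#'
#' @param CY sensor sample covariance, tesla^2.
#' @param leadfield a [LeadField-class].
#' @param gamma per-source prior weights (from [ebbPrior()]).
#' @param Nt number of time samples behind `CY`.
#' @param maxIter maximum Fisher-scoring iterations.
#' @param tol convergence tolerance on the free-energy change, nats.
#' @param priorPrecision prior precision on the scaled log-hyperparameters.
#' @return list with `cov` (a [CovarianceModel-class]) and `evidence`
#'   (an [EvidenceResult-class]).
#' @export
optimizeHyperparameters <- function(CY, leadfield, gamma, Nt,
                                    maxIter = 128, tol = 1e-4,
                                    priorPrecision = 1e-6) {
  L <- leadfieldMatrix(leadfield)
  Nc <- nrow(CY)
  s <- sum(diag(CY)) / Nc              # data scale (tesla^2)
  if (s <= 0) stop("degenerate data covariance")
  G <- L %*% (gamma * t(L))
  G <- (G + t(G)) / 2
  Q1 <- diag(Nc) * s
  Q2 <- G * (s * Nc / sum(diag(G)))    # equal-trace components, O(1) h's
  nu <- c(0, 0)
  Pi <- diag(priorPrecision, 2)
  h <- c(log(0.5), log(0.5))           # data-scaled start: half noise, half source
  ob <- .twoCompObjective(h, Q1, Q2, CY, Nt, nu, Pi)
  if (is.null(ob)) stop("initial covariance model not positive definite")
  converged <- FALSE
  iter <- 0
  damp <- 1
  for (iter in seq_len(maxIter)) {
    Cinv <- ob$Cinv
    P1 <- Cinv %*% Q1; P2 <- Cinv %*% Q2
    M <- Cinv %*% CY
    # gradient of the penalised evidence wrt h
    g1 <- Nt / 2 * (sum(diag(P1 %*% M)) - sum(diag(P1))) * exp(h[1])
    g2 <- Nt / 2 * (sum(diag(P2 %*% M)) - sum(diag(P2))) * exp(h[2])
    gr <- c(g1, g2) - Pi %*% (h - nu)
    # expected information (Fisher) in h
    I11 <- Nt / 2 * sum(P1 * t(P1)) * exp(2 * h[1])
    I22 <- Nt / 2 * sum(P2 * t(P2)) * exp(2 * h[2])
    I12 <- Nt / 2 * sum(P1 * t(P2)) * exp(h[1] + h[2])
    Fisher <- matrix(c(I11, I12, I12, I22), 2, 2)
    H <- Fisher + Pi
    step <- tryCatch(solve(H + damp * diag(diag(H)), gr),
                     error = function(e) gr / max(diag(H), 1))
    step <- pmin(pmax(step, -4), 4)    # trust region on log scale
    newh <- h + as.numeric(step)
    newob <- .twoCompObjective(newh, Q1, Q2, CY, Nt, nu, Pi)
    if (!is.null(newob) && newob$value >= ob$value - 1e-12) {
      dF <- newob$value - ob$value
      h <- newh; ob <- newob
      damp <- max(damp / 2, 1e-6)
      if (abs(dF) < tol) { converged <- TRUE; break }
    } else {
      damp <- damp * 10
      if (damp > 1e8) break
    }
  }
  if (!converged && iter >= maxIter)
    warning("hyperparameter optimisation did not converge; returning best iterate")
  # posterior curvature at the optimum
  Cinv <- ob$Cinv
  P1 <- Cinv %*% Q1; P2 <- Cinv %*% Q2
  I11 <- Nt / 2 * sum(P1 * t(P1)) * exp(2 * h[1])
  I22 <- Nt / 2 * sum(P2 * t(P2)) * exp(2 * h[2])
  I12 <- Nt / 2 * sum(P1 * t(P2)) * exp(h[1] + h[2])
  Fisher <- matrix(c(I11, I12, I12, I22), 2, 2)
  Sigma <- solve(Fisher + Pi)
  lambda1 <- exp(h[1]) * s
  lambda2 <- exp(h[2]) * s * Nc / sum(diag(G))
  cov <- new("CovarianceModel",
             lambda = c(lambda1 = lambda1, lambda2 = lambda2), gamma = gamma,
             Cmodel = (ob$C + t(ob$C)) / 2, logLambda = h, SigmaLambda = Sigma,
             priorMean = nu, priorPrecision = Pi, scale = s)
  ev <- freeEnergy(CY, cov, Nt)
  ev@converged <- converged
  ev@iterations <- iter
  list(cov = cov, evidence = ev)
}

#' Posterior source estimate
#'
#' The empirical-Bayes maximum a posteriori current estimate
#' J = Q L^T (Qeps + L Q L^T)^-1 Y with Q = lambda2 diag(Gamma), computed via
#' a linear solve. Per-source power is the temporal mean of J^2.
#'
#' @param data a [DataMatrix-class] (or channels x samples matrix).
#' @param cov a [CovarianceModel-class].
#' @param leadfield the [LeadField-class] the model was built from.
#' @return a [SourceEstimate-class].
#' @export
estimateSources <- function(data, cov, leadfield) {
  Y <- if (is(data, "DataMatrix")) dataValues(data) else rbind(data)
  L <- leadfieldMatrix(leadfield)
  if (nrow(Y) != nrow(L)) stop("channel dimension mismatch between data and lead field")
  if (ncol(L) != length(cov@gamma)) stop("lead field and prior dimensions differ")
  W <- solve(cov@Cmodel, Y)
  J <- (cov@lambda[["lambda2"]] * cov@gamma) * (t(L) %*% W)
  power <- rowMeans(J^2)
  new("SourceEstimate", J = unname(J), power = power,
      peakIndex = as.integer(which.max(power)))
}

#' Zero-phase Butterworth band-pass helper
#'
#' @param data a [DataMatrix-class].
#' @param band length-2 pass band, Hz.
#' @param order filter order (default 4).
#' @export
bandpassFilter <- function(data, band, order = 4) {
  ny <- data@sampleRate / 2
  bf <- signal::butter(order, band / ny, type = "pass")
  v <- t(apply(dataValues(data), 1, function(ch) signal::filtfilt(bf, ch)))
  dataMatrix(v, data@sampleRate, channelLabels(data), data@window)
}

#' Extract a time window
#'
#' @param data a [DataMatrix-class].
#' @param from,to window bounds in seconds relative to the data window start.
#' @export
timeWindow <- function(data, from, to) {
  t0 <- data@window[1]
  idx <- which(seq(0, by = 1 / data@sampleRate, length.out = nSamples(data)) + t0 >= from &
               seq(0, by = 1 / data@sampleRate, length.out = nSamples(data)) + t0 <= to)
  if (!length(idx)) stop("empty time window")
  dataMatrix(dataValues(data)[, idx, drop = FALSE], data@sampleRate,
             channelLabels(data), c(from, to))
}
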