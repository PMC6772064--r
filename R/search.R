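#' @include evidence.R
NULL

#' Metropolis acceptance decision
#'
#' Accept a proposal whose free energy differs from the current state by
#' `deltaF` with probability min(1, exp(deltaF)). Exposed so the acceptance
#' behaviour can be examined on surrogate evidence surfaces.
#'
#' @param deltaF proposed minus current free energy, nats.
#' @return logical.
#' @export
mhAccept <- function(deltaF) {
  if (is.nan(deltaF)) return(FALSE)          # -Inf vs -Inf: stay put
  if (!is.finite(deltaF)) return(deltaF > 0)
  deltaF >= 0 || stats::runif(1) < exp(deltaF)
}

# Uniform draw inside the prior support.
.priorDraw <- function(prior) {
  switch(prior$kind,
    box = stats::runif(3, -prior$halfWidth, prior$halfWidth),
    arc = stats::runif(1, prior$range[1], prior$range[2]),
    stop("unknown prior kind"))
}

.priorContains <- function(prior, par) {
  switch(prior$kind,
    box = all(abs(par) <= prior$halfWidth),
    arc = par >= prior$range[1] && par <= prior$range[2])
}

# Map a parameter vector to a perturbed array. box: translation in metres;
# arc: displacement in mm along the configured arc.
.parToArray <- function(par, prior, array, head) {
  if (prior$kind == "box")
    applyPose(array, rigidTransform(translation = par))
  else
    displaceArc(array, par, prior$centre, prior$axis)
}

#' Metropolis search over rigid-array pose
#'
#' Random-walk Metropolis sampling of the array pose under a flat prior, with
#' the free energy of the induced source reconstruction as log-target. Steps
#' that increase F are always taken; decreases are accepted with probability
#' exp(deltaF), which lets the chains escape shallow local maxima. Proposal
#' scales adapt multiplicatively towards a 25-40% acceptance rate during the
#' first 40% of iterations (burn-in) and are frozen afterwards. A small
#' fraction (`jumpProb`) of proposals are drawn fresh from the flat prior:
#' this independence component is symmetric within the prior support (the
#' accept rule is unchanged) and lets chains cross the deep inter-basin
#' barriers that the discrete source space induces, which a pure local random
#' walk cannot.
#'
#' @param data a [DataMatrix-class].
#' @param array the rigid [SensorArray-class] of known relative geometry.
#' @param sources a [SourceSpace-class].
#' @param head a [HeadModel-class].
#' @param prior flat prior support: `list(kind = "box", halfWidth = metres)`
#'   for a translation search (default 0.02 m, i.e. a 40 mm cube), or
#'   `list(kind = "arc", range = c(lo, hi) mm, centre =, axis =)` for a 1D arc
#'   search.
#' @param nChains number of independent chains.
#' @param nIter iterations per chain.
#' @param seed RNG seed.
#' @param jumpProb probability of a fresh prior draw instead of a local
#'   Gaussian step.
#' @param config inversion settings passed to [scoreGeometry()].
#' @return data.frame of all evaluated states: chain, iteration, the pose
#'   parameters (`par1..par3`, metres, or `arc_mm`), F, accepted.
#' @export
metropolisPoseSearch <- function(data, array, sources, head,
                                 prior = list(kind = "box", halfWidth = 0.02),
                                 nChains = 4, nIter = 600, seed = 0,
                                 jumpProb = 0.1, config = list()) {
  stopifnot(nIter >= 1, nChains >= 1)
  if (prior$kind == "arc") {
    if (is.null(prior$centre))
      prior$centre <- if (is(head, "SphereModel") || is(head, "SingleShellModel"))
        head@centre else c(0, 0, 0)
    if (is.null(prior$axis)) prior$axis <- c(1, 0, 0)
  }
  npar <- if (prior$kind == "box") 3 else 1
  burn <- ceiling(0.4 * nIter)
  width <- if (prior$kind == "box") 2 * prior$halfWidth else diff(prior$range)
  scoreF <- function(par) {
    tryCatch(
      freeEnergyValue(scoreGeometry(data, .parToArray(par, prior, array, head),
                                    sources, head, config)),
      error = function(e) {
        warning(sprintf("forward/inverse failure at a proposal (%s); rejecting",
                        conditionMessage(e)))
        -Inf
      })
  }
  rows <- vector("list", nChains)
  for (ch in seq_len(nChains)) {
    rows[[ch]] <- withSeed(subSeed(seed, ch), {
      step <- width / 10
      par <- .priorDraw(prior)
      Fcur <- scoreF(par)
      rec <- matrix(NA_real_, nIter, npar + 3)
      nAccRecent <- 0
      nLocRecent <- 0
      for (it in seq_len(nIter)) {
        jump <- stats::runif(1) < jumpProb
        prop <- if (jump) .priorDraw(prior) else par + stats::rnorm(npar, 0, step)
        if (!.priorContains(prior, prop)) {
          acc <- FALSE
          Fprop <- NA_real_
        } else {
          Fprop <- scoreF(prop)
          acc <- mhAccept(Fprop - Fcur)
        }
        if (acc) { par <- prop; Fcur <- Fprop }
        if (!jump) {                        # adapt on the local kernel only
          nLocRecent <- nLocRecent + 1
          if (acc) nAccRecent <- nAccRecent + 1
        }
        rec[it, ] <- c(it, par, Fcur, acc)
        if (it <= burn && it %% 20 == 0 && nLocRecent > 0) {
          rate <- nAccRecent / nLocRecent   # target ~25-40% acceptance
          if (rate < 0.25) step <- step * 0.7
          if (rate > 0.40) step <- step * 1.4
          nAccRecent <- 0; nLocRecent <- 0
        }
      }
      rec
    })
  }
  out <- do.call(rbind, Map(function(m, ch) cbind(ch, m), rows, seq_len(nChains)))
  cn <- if (prior$kind == "box") c("par1", "par2", "par3") else "arc_mm"
  colnames(out) <- c("chain", "iteration", cn, "F", "accepted")
  df <- as.data.frame(out)
  df$accepted <- df$accepted > 0
  attr(df, "prior") <- prior
  df
}

#' Evidence weights over pose samples
#'
#' Softmax of the free energies: w_s proportional to exp(F_s - max F),
#' normalised to sum to 1. A difference of 3 nats maps to a ~1/20 relative
#' weight.
#' @param F numeric vector of free energies, nats.
#' @export
bmaWeights <- function(F) {
  w <- exp(F - max(F))
  w / sum(w)
}

#' Bayesian model averaging of source estimates over pose samples
#'
#' Draws `nModels` pose states from the post-burn-in chain samples with
#' probability proportional to exp(F), runs the full inversion for each drawn
#' pose, and averages the current estimates. The posterior pose cloud
#' (weighted by evidence) yields a confidence ellipsoid on the position of a
#' tracked point of the array (default: the sensor closest to the array
#' centroid).
#'
#' @param samples chain data.frame from [metropolisPoseSearch()].
#' @param data,array,sources,head as in [metropolisPoseSearch()].
#' @param burnIn fraction of each chain discarded (default 0.4).
#' @param nModels number of models averaged (default 30).
#' @param level confidence level for the ellipsoid.
#' @param seed RNG seed for the model draw.
#' @param trackedSensor index of the sensor whose position is summarised.
#' @param config inversion settings.
#' @return list with `estimate` (a [SourceEstimate-class]) and `posterior`
#'   (a [PosteriorSummary-class]).
#' @export
bmaSources <- function(samples, data, array, sources, head, burnIn = 0.4,
                       nModels = 30, level = 0.95, seed = 0,
                       trackedSensor = NULL, config = list()) {
  prior <- attr(samples, "prior")
  if (is.null(prior)) stop("samples must come from metropolisPoseSearch")
  keep <- samples[samples$iteration > burnIn * max(samples$iteration) &
                  is.finite(samples$F), , drop = FALSE]
  if (nrow(keep) < 1) stop("no post-burn-in samples")
  parCols <- intersect(c("par1", "par2", "par3", "arc_mm"), names(keep))
  w <- bmaWeights(keep$F)
  nDraw <- min(nModels, nrow(keep))
  if (nrow(keep) < nModels)
    warning("fewer post-burn-in samples than requested models")
  collapsed <- sum(w > 1e-12) == 1
  idx <- if (collapsed) rep(which.max(w), nDraw)
         else withSeed(subSeed(seed, 99),
                       sample.int(nrow(keep), nDraw, replace = TRUE, prob = w))
  uidx <- unique(idx)
  Jsum <- NULL
  ests <- list()
  for (u in uidx) {
    par <- as.numeric(keep[u, parCols])
    arr <- .parToArray(par, prior, array, head)
    lf <- computeLeadfield(arr, sources, head)
    CY <- sampleCovariance(data)
    g <- ebbPrior(lf, CY, if (is.null(config$regularization)) 0 else config$regularization)
    fit <- optimizeHyperparameters(CY, lf, g, nSamples(data))
    ests[[as.character(u)]] <- estimateSources(data, fit$cov, lf)
  }
  mult <- table(factor(idx, levels = uidx))
  J <- Reduce(`+`, Map(function(u, m) m * ests[[as.character(u)]]@J,
                       uidx, as.numeric(mult))) / nDraw
  power <- rowMeans(J^2)
  est <- new("SourceEstimate", J = J, power = power,
             peakIndex = as.integer(which.max(power)))
  # posterior summary over the full weighted post-burn-in cloud
  if (is.null(trackedSensor)) {
    pos <- sensorPositions(array)
    trackedSensor <- which.min(rowSums(sweep(pos, 2, colMeans(pos))^2))
  }
  pts <- t(vapply(seq_len(nrow(keep)), function(i) {
    arr <- .parToArray(as.numeric(keep[i, parCols]), prior, array, head)
    sensorPositions(arr)[trackedSensor, ]
  }, numeric(3)))
  ell <- confidenceEllipsoid(pts, w, level = level)
  meanPar <- colSums(w * as.matrix(keep[, parCols, drop = FALSE]))
  meanPose <- if (prior$kind == "box") rigidTransform(translation = meanPar)
              else rigidTransform()
  post <- new("PosteriorSummary", meanPose = meanPose,
              ellipsoidCentre = ell$centre, ellipsoidCov = ell$covariance,
              level = level, volumeCm3 = ell$volumeCm3,
              degenerate = ell$degenerate, samples = keep)
  list(estimate = est, posterior = post)
}

#' Confidence ellipsoid of a weighted point cloud
#'
#' Weighted mean and covariance of 3D positions; the `level` ellipsoid has
#' semi-axes sqrt(chi^2_3(level) * eigenvalues) and volume
#' (4/3) pi prod(semi-axes).
#'
#' @param points n x 3 matrix, metres.
#' @param weights non-negative weights (normalised internally; default equal).
#' @param level confidence level in (0, 1); 0 gives a zero-volume ellipsoid.
#' @return list: centre (metres), covariance (m^2), semiAxes (metres),
#'   volumeCm3, degenerate flag.
#' @export
confidenceEllipsoid <- function(points, weights = NULL, level = 0.95) {
  p <- rbind(points)
  if (is.null(weights)) weights <- rep(1, nrow(p))
  w <- weights / sum(weights)
  mu <- colSums(w * p)
  d <- sweep(p, 2, mu)
  S <- t(d) %*% (w * d)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  degenerate <- any(ev$values <= 1e-18 * max(1e-30, max(ev$values)))
  q <- if (level <= 0) 0 else stats::qchisq(level, df = 3)
  semi <- sqrt(q * vals)
  vol <- 4 / 3 * pi * prod(semi)
  list(centre = mu, covariance = S, semiAxes = semi,
       volumeCm3 = if (degenerate) 0 else vol * 1e6, degenerate = degenerate)
}
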