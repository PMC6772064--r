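test_that("accuracy equals the Gaussian log-likelihood of the data", {
  # univariate closed form
  set.seed(2)
  y <- matrix(rnorm(40, 0, 2), 1, 40)
  cvar <- 3.7
  cm <- new("CovarianceModel", lambda = c(lambda1 = cvar, lambda2 = 0),
            gamma = numeric(), Cmodel = matrix(cvar, 1, 1),
            logLambda = c(0, 0), SigmaLambda = diag(2),
            priorMean = c(0, 0), priorPrecision = diag(1e-6, 2), scale = 1)
  ev <- freeEnergy(tcrossprod(y) / 40, cm, 40)
  expect_equal(ev@accuracy, sum(dnorm(y, 0, sqrt(cvar), log = TRUE)),
               tolerance = 1e-12)

  # multivariate brute force on a 3 x 50 dataset
  Y <- matrix(rnorm(150), 3, 50)
  A <- matrix(rnorm(9), 3, 3)
  Ca <- crossprod(A) + diag(3)
  cm3 <- new("CovarianceModel", lambda = c(lambda1 = 1, lambda2 = 1),
             gamma = numeric(), Cmodel = Ca, logLambda = c(0, 0),
             SigmaLambda = diag(2), priorMean = c(0, 0),
             priorPrecision = diag(1e-6, 2), scale = 1)
  ev3 <- freeEnergy(tcrossprod(Y) / 50, cm3, 50)
  brute <- sum(vapply(seq_len(50), function(t) logDensMvn(Y[, t], Ca), 0))
  expect_equal(ev3@accuracy, brute, tolerance = 1e-9)

  # F decomposes exactly and the Occam penalty is non-negative
  expect_equal(ev3@F, ev3@accuracy - ev3@complexity)
  rec <- fxRecording()
  lf <- computeLeadfield(fxArray(), fxHead()$sources, fxSphere())
  CY <- sampleCovariance(rec$data)
  fit <- optimizeHyperparameters(CY, lf, ebbPrior(lf, CY), nSamples(rec$data))
  expect_gte(fit$evidence@complexity, 0)
})

test_that("the trace + log-det likelihood term is maximised at C = CY", {
  set.seed(6)
  A <- matrix(rnorm(16), 4, 4)
  CY <- crossprod(A) + diag(4)
  term <- function(C) -(sum(solve(C) * CY) + determinant(C)$modulus)
  best <- term(CY)
  for (k in 1:50) {
    P <- matrix(rnorm(16, 0, 0.3), 4, 4)
    C <- CY + crossprod(P)        # random PD perturbation
    expect_lt(term(C), best)
  }
})

test_that("geometry scoring is deterministic and relabelling-invariant", {
  rec <- fxRecording()
  arr <- fxArray(); src <- fxHead()$sources; sph <- fxSphere()
  e1 <- scoreGeometry(rec$data, arr, src, sph)
  e2 <- scoreGeometry(rec$data, arr, src, sph)
  expect_identical(freeEnergyValue(e1), freeEnergyValue(e2))

  # permute channels consistently in data and array
  set.seed(3)
  p <- sample(nChannels(arr))
  arrP <- sensorArray(sensorPositions(arr)[p, ], sensorOrientations(arr)[p, ],
                      sensorGains(arr)[p], channelLabels(arr)[p])
  dataP <- dataMatrix(dataValues(rec$data)[p, ], 200, channelLabels(rec$data)[p])
  eP <- scoreGeometry(dataP, arrP, src, sph)
  expect_equal(freeEnergyValue(eP), freeEnergyValue(e1), tolerance = 1e-6)
})

test_that("evidence is maximal at the generating geometry across noise seeds", {
  arr <- fxArray(); src <- fxHead()$sources; sph <- fxSphere()
  wins <- vapply(1:30, function(s) {
    rec <- fxRecording(seed = 200 + s)
    f0 <- freeEnergyValue(scoreGeometry(rec$data, arr, src, sph))
    fp <- freeEnergyValue(scoreGeometry(rec$data,
            perturbOrientations(arr, 20, seed = s), src, sph))
    f0 > fp
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("perturbation curves normalise, reproduce and peak at the truth", {
  rec <- fxRecording()
  arr <- fxArray(); src <- fxHead()$sources; sph <- fxSphere()
  offs <- seq(-10, 10, 2.5)
  c1 <- perturbationCurve(rec$data, arr, src, sph, "arc", offs, nRepeats = 1, seed = 3)
  expect_equal(max(relativeF(c1)), 0)
  expect_equal(curveOffsets(c1)[which.max(relativeF(c1))], 0)
  c2 <- perturbationCurve(rec$data, arr, src, sph, "arc", offs, nRepeats = 1, seed = 3)
  expect_identical(curveFvalues(c1), curveFvalues(c2))
  expect_error(perturbationCurve(rec$data, arr, src, sph, "arc", c(1, 2, 3)),
               "include 0")
  # relative curves ignore constant F shifts by construction
  shifted <- new("PerturbationCurve", offsets = curveOffsets(c1),
                 Fvalues = curveFvalues(c1) + 123.4, kind = "arc", unit = "mm",
                 seed = 3)
  expect_equal(relativeF(shifted), relativeF(c1))
})

test_that("threshold widths interpolate linearly and map to evidence ratios", {
  x <- seq(-10, 10, 1)
  tri <- new("PerturbationCurve", offsets = x, Fvalues = rbind(-abs(x)),
             kind = "orientation", unit = "degrees", seed = 0)
  w <- widthAtThreshold(tri, -3)
  expect_equal(w$lower, -3); expect_equal(w$upper, 3)
  expect_equal(w$halfWidth, 3)
  expect_false(w$openLower || w$openUpper)
  w0 <- widthAtThreshold(tri, 0)
  expect_equal(c(w0$lower, w0$upper), c(0, 0))
  # a -3 nat drop is an evidence ratio of exp(3) ~ 20
  expect_equal(exp(-(-3)), 20.0855, tolerance = 1e-4)
  # open-ended sides flagged when the curve never reaches the threshold
  shallow <- new("PerturbationCurve", offsets = x, Fvalues = rbind(-abs(x) / 10),
                 kind = "orientation", unit = "degrees", seed = 0)
  ws <- widthAtThreshold(shallow, -3)
  expect_true(ws$openLower); expect_true(ws$openUpper)
  expect_equal(c(ws$lower, ws$upper), range(x))
})
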