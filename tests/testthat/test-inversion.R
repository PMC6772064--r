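test_that("sample covariance matches the brute-force time average", {
  set.seed(4)
  Y <- matrix(rnorm(400), 4, 100)
  C <- sampleCovariance(Y)
  Cloop <- matrix(0, 4, 4)
  for (t in seq_len(100)) Cloop <- Cloop + Y[, t] %*% t(Y[, t])
  expect_equal(C, Cloop / 100, tolerance = 1e-15)
  expect_true(isSymmetric(C))
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-18)

  # unit spike per channel
  Cspike <- sampleCovariance(diag(5))
  expect_equal(Cspike, diag(5) / 5)
  # alternative normaliser is a pure rescaling
  expect_equal(sampleCovariance(Y, "Nc"), C * 100 / 4)
  expect_error(sampleCovariance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("beamformer prior matches the per-source oracle and its symmetries", {
  set.seed(10)
  # 3 channels, 5 sources
  L <- matrix(rnorm(15), 3, 5)
  CY <- crossprod(matrix(rnorm(60), 20, 3)) / 20
  lf <- new("LeadField", matrix = L, arrayRef = "", sourceRef = "", headRef = "")
  g <- ebbPrior(lf, CY)
  oracle <- vapply(1:5, function(d) 1 / (t(L[, d]) %*% solve(CY) %*% L[, d]), 0)
  expect_equal(g, as.numeric(oracle / mean(oracle)), tolerance = 1e-12)
  # scaling the covariance leaves the normalised prior unchanged
  expect_equal(ebbPrior(lf, 7.3 * CY), g, tolerance = 1e-12)
  # orthogonal equal-norm columns under white noise: constant weights
  Lo <- diag(3)
  lfo <- new("LeadField", matrix = Lo, arrayRef = "", sourceRef = "", headRef = "")
  expect_equal(ebbPrior(lfo, 2 * diag(3)), rep(1, 3))
})

test_that("hyperparameter optimisation recovers generating variances", {
  hd <- fxHead(); arr <- fxArray()
  lf <- computeLeadfield(arr, hd$sources, fxSphere())
  L <- leadfieldMatrix(lf)
  set.seed(9)
  gamma <- rexp(ncol(L)); gamma <- gamma / mean(gamma)
  a <- (80e-15)^2
  b <- a / mean(diag(L %*% (gamma * t(L))))
  Ctrue <- a * diag(nrow(L)) + b * L %*% (gamma * t(L))
  Nt <- 1e4
  Y <- t(chol(Ctrue)) %*% matrix(rnorm(nrow(L) * Nt), nrow(L), Nt)
  fit <- optimizeHyperparameters(tcrossprod(Y) / Nt, lf, gamma, Nt)
  expect_lt(abs(fit$cov@lambda[["lambda1"]] / a - 1), 0.1)
  expect_lt(abs(fit$cov@lambda[["lambda2"]] / b - 1), 0.1)
  expect_true(fit$evidence@converged)
  # scale equivariance: scaling the data covariance by 4 scales both by ~4
  fit4 <- optimizeHyperparameters(4 * tcrossprod(Y) / Nt, lf, gamma, Nt)
  expect_equal(as.numeric(fit4$cov@lambda / fit$cov@lambda), c(4, 4), tolerance = 1e-3)
})

test_that("source variance shrinks on pure noise and the extra component is unjustified", {
  hd <- fxHead(); arr <- fxArray()
  lf <- computeLeadfield(arr, hd$sources, fxSphere())
  L <- leadfieldMatrix(lf)
  Nc <- nrow(L); Nt <- 2000
  set.seed(21)
  sig <- 1e-13
  Y <- matrix(rnorm(Nc * Nt, 0, sig), Nc, Nt)
  CY <- tcrossprod(Y) / Nt
  gamma <- rep(1, ncol(L))
  fit <- optimizeHyperparameters(CY, lf, gamma, Nt)
  G <- L %*% (gamma * t(L))
  # source component contributes a negligible share of the fitted variance
  share <- fit$cov@lambda[["lambda2"]] * mean(diag(G)) / fit$cov@lambda[["lambda1"]]
  expect_lt(share, 0.05)

  # noise-only reference model (single log-hyperparameter, same priors),
  # derived independently from the Gaussian evidence
  lam1 <- sum(diag(CY)) / Nc
  acc <- -Nt / 2 * (sum(diag(CY)) / lam1 + Nc * log(lam1) + Nc * log(2 * pi))
  fisher <- Nt * Nc / 2                      # d2/dh2 at the optimum, h = log lam1
  comp <- 0.5 * 1e-6 * log(lam1 / sum(diag(CY)) * Nc)^2 - 0.5 * log(1e-6 / (fisher + 1e-6))
  expect_lt(freeEnergyValue(fit$evidence) - (acc - comp), 3)
})

test_that("posterior current estimate honours the closed form and its limits", {
  hd <- fxHead(); arr <- fxArray()
  lf <- computeLeadfield(arr, hd$sources, fxSphere())
  rec <- fxRecording()
  CY <- sampleCovariance(rec$data)
  g <- ebbPrior(lf, CY)
  fit <- optimizeHyperparameters(CY, lf, g, nSamples(rec$data))
  est <- estimateSources(rec$data, fit$cov, lf)

  # zero data give a zero estimate
  z <- dataMatrix(matrix(0, nChannels(arr), 10), 200, channelLabels(arr))
  expect_equal(max(abs(estimateSources(z, fit$cov, lf)@J)), 0)

  # linear-solve route equals the explicit-inverse route
  L <- leadfieldMatrix(lf)
  Q <- fit$cov@lambda[["lambda2"]] * fit$cov@gamma
  Jinv <- (Q * t(L)) %*% (solve(fit$cov@Cmodel) %*% dataValues(rec$data))
  expect_equal(est@J, unname(Jinv), tolerance = 1e-10)

  # linearity in Y
  est2 <- estimateSources(dataMatrix(2 * dataValues(rec$data), 200,
                                     channelLabels(rec$data)), fit$cov, lf)
  expect_equal(est2@J, 2 * est@J, tolerance = 1e-12)

  # lambda1 -> infinity shrinks the estimate to zero
  cvBig <- covarianceModel(lf, g, lambda1 = 1, lambda2 = fit$cov@lambda[["lambda2"]])
  expect_lt(max(abs(estimateSources(rec$data, cvBig, lf)@J)), 1e-6 * max(abs(est@J)))
})

test_that("noiseless single-source data are reconstructed at the generating vertex", {
  rec <- fxRecording(noiseRms = 0)
  lf <- rec$truth$leadfield
  CY <- sampleCovariance(rec$data)
  g <- ebbPrior(lf, CY, regularization = 1e-10)
  cm <- covarianceModel(lf, g, lambda1 = 1e-40, lambda2 = 1)
  est <- estimateSources(rec$data, cm, lf)
  expect_identical(peakIndex(est), rec$truth$sourceIndex)
  resid <- dataValues(rec$data) - leadfieldMatrix(lf) %*% est@J
  expect_lt(norm(resid, "F") / norm(dataValues(rec$data), "F"), 1e-3)
})

test_that("band-pass and windowing helpers preserve in-band structure", {
  rec <- fxRecording()
  filt <- bandpassFilter(rec$data, c(2, 80))
  # the 10 Hz signal is inside the band: filtered data stay close
  expect_lt(norm(dataValues(filt) - dataValues(rec$data), "F") /
            norm(dataValues(rec$data), "F"), 0.35)
  win <- timeWindow(rec$data, 0, 0.3)
  expect_equal(nSamples(win), 61)
  expect_equal(dataValues(win), dataValues(rec$data)[, 1:61])
})
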