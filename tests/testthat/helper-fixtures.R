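# Shared fixtures, built lazily and cached per test file. Unit tests use a
# coarse (162-vertex) head for speed; the acceptance protocol uses defaults.

.fx <- new.env(parent = emptyenv())

fxHead <- function() {
  if (is.null(.fx$head)) .fx$head <- makeHead(nVertices = 162)
  .fx$head
}

fxArray <- function() {
  if (is.null(.fx$array)) .fx$array <- makeArray(fxHead())
  .fx$array
}

fxSphere <- function() {
  if (is.null(.fx$sphere)) .fx$sphere <- fitSphere(fxHead()$mesh)
  .fx$sphere
}

fxRecording <- function(seed = 42, noiseRms = 100e-15) {
  key <- sprintf("rec_%d_%g", seed, noiseRms)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulateRecording(simulationSpec(seed = seed, noiseRms = noiseRms),
                                    fxArray(), fxHead()$sources, fxSphere())
  .fx[[key]]
}

# Independent literal transcription of the closed-form field of a current
# dipole in a homogeneous conducting sphere (scalar loop style, no shared
# code with the package implementation).
sarvasReference <- function(sensorPos, dipolePos, dipoleMom, centre) {
  mu0 <- 4e-7 * pi
  r_vec <- sensorPos - centre
  r0_vec <- dipolePos - centre
  a_vec <- r_vec - r0_vec
  a <- sqrt(sum(a_vec^2))
  r <- sqrt(sum(r_vec^2))
  F_ <- a * (r * a + r^2 - sum(r0_vec * r_vec))
  nablaF <- (a^2 / r + sum(a_vec * r_vec) / a + 2 * a + 2 * r) * r_vec -
            (a + 2 * r + sum(a_vec * r_vec) / a) * r0_vec
  Qxr0 <- c(dipoleMom[2] * r0_vec[3] - dipoleMom[3] * r0_vec[2],
            dipoleMom[3] * r0_vec[1] - dipoleMom[1] * r0_vec[3],
            dipoleMom[1] * r0_vec[2] - dipoleMom[2] * r0_vec[1])
  (mu0 / (4 * pi * F_^2)) * (F_ * Qxr0 - sum(Qxr0 * r_vec) * nablaF)
}

# Log-density of a zero-mean multivariate normal, written directly from the
# definition (independent of the package's evidence code path).
logDensMvn <- function(y, C) {
  k <- length(y)
  ch <- chol(C)
  z <- backsolve(ch, y, transpose = TRUE)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

expectSameArray <- function(a, b, tol = 1e-12) {
  expect_equal(sensorPositions(a), sensorPositions(b), tolerance = tol)
  expect_equal(sensorOrientations(a), sensorOrientations(b), tolerance = tol)
  expect_equal(sensorGains(a), sensorGains(b), tolerance = tol)
  expect_identical(channelLabels(a), channelLabels(b))
}
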