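test_that("orientation perturbation rotates by the exact angle about a frame axis", {
  arr <- fxArray()
  expect_identical(perturbOrientations(arr, 0, seed = 1), arr)

  p <- perturbOrientations(arr, 20, seed = 3)
  ang <- acos(pmin(1, rowSums(sensorOrientations(p) * sensorOrientations(arr))))
  expect_true(all(ang <= 20 * pi / 180 + 1e-6))
  expect_true(any(ang > 0))
  # positions, gains, labels and ordering untouched
  expect_identical(sensorPositions(p), sensorPositions(arr))
  expect_identical(sensorGains(p), sensorGains(arr))
  expect_identical(channelLabels(p), channelLabels(arr))
  # unit norms preserved
  expect_equal(sqrt(rowSums(sensorOrientations(p)^2)),
               rep(1, nChannels(arr)), tolerance = 1e-9)
})

test_that("orientation perturbation is reproducible per seed and finite-angle only", {
  arr <- fxArray()
  expect_identical(perturbOrientations(arr, 2.5, seed = 11),
                   perturbOrientations(arr, 2.5, seed = 11))
  expect_false(identical(sensorOrientations(perturbOrientations(arr, 2.5, seed = 11)),
                         sensorOrientations(perturbOrientations(arr, 2.5, seed = 12))))
  expect_error(perturbOrientations(arr, NaN), "finite")
  expect_error(perturbOrientations(arr, Inf), "finite")
})

test_that("arc displacement is rigid, invertible and direction-signed", {
  arr <- fxArray()
  ctr <- fxSphere()@centre
  expect_identical(displaceArc(arr, 0, ctr), arr)
  expect_error(displaceArc(arr, 5, ctr, axis = c(0, 0, 0)), "non-zero")

  d <- displaceArc(arr, 12.5, ctr)
  # rigidity: pairwise distances preserved
  expect_lt(max(abs(dist(sensorPositions(d)) - dist(sensorPositions(arr)))), 1e-12)
  # inter-orientation angles preserved (orientations co-rotate)
  G0 <- sensorOrientations(arr) %*% t(sensorOrientations(arr))
  G1 <- sensorOrientations(d) %*% t(sensorOrientations(d))
  expect_lt(max(abs(G0 - G1)), 1e-12)
  expect_identical(sensorGains(d), sensorGains(arr))
  # arc length realised at the mean radius
  rbar <- mean(sqrt(rowSums(sweep(sensorPositions(arr), 2, ctr)^2)))
  mdisp <- mean(sqrt(rowSums((sensorPositions(d) - sensorPositions(arr))^2)))
  expect_equal(mdisp, 2 * rbar * sin(0.0125 / rbar / 2), tolerance = 0.05)
  # round trip
  back <- displaceArc(d, -12.5, ctr)
  expect_lt(max(abs(sensorPositions(back) - sensorPositions(arr))), 1e-9)
})

test_that("rigid transforms apply, compose and invert consistently", {
  arr <- fxArray()
  expect_equal(sensorPositions(applyPose(arr, rigidTransform())),
               sensorPositions(arr))
  # pure translation shifts positions, leaves orientations alone
  t0 <- c(0.004, -0.002, 0.001)
  tr <- applyPose(arr, rigidTransform(translation = t0))
  expect_equal(sensorPositions(tr), sweep(sensorPositions(arr), 2, t0, "+"))
  expect_equal(sensorOrientations(tr), sensorOrientations(arr))

  pose <- rigidTransform(rotation = c(0.1, -0.2, 0.15), translation = t0)
  piv <- c(0, 0, 0.02)
  fwd <- applyPose(arr, pose, piv)
  back <- applyPose(fwd, invertPose(pose), piv)
  expect_lt(max(abs(sensorPositions(back) - sensorPositions(arr))), 1e-9)
  # composition about a common pivot equals sequential application
  p2 <- rigidTransform(rotation = c(-0.05, 0.3, 0), translation = c(0.001, 0, -0.003))
  seqArr <- applyPose(applyPose(arr, pose, piv), p2, piv)
  oneArr <- applyPose(arr, composePoses(pose, p2), piv)
  expect_lt(max(abs(sensorPositions(seqArr) - sensorPositions(oneArr))), 1e-9)
  expect_lt(max(abs(sensorOrientations(seqArr) - sensorOrientations(oneArr))), 1e-9)
})

test_that("gain errors are Normal(1, f^2) multipliers, fixed per seed", {
  arr <- fxArray()
  expect_identical(applyGainError(arr, 0, seed = 1), arr)
  expect_identical(sensorGains(applyGainError(arr, 0.2, seed = 5)),
                   sensorGains(applyGainError(arr, 0.2, seed = 5)))
  expect_error(applyGainError(arr, 1), "fraction")
  expect_error(applyGainError(arr, -0.1), "fraction")
  # positions and orientations untouched
  g <- applyGainError(arr, 0.1, seed = 2)
  expect_identical(sensorPositions(g), sensorPositions(arr))

  # law of large numbers on a large synthetic array
  n <- 1e4
  set.seed(1)
  big <- sensorArray(matrix(rnorm(3 * n), n, 3),
                     matrix(rnorm(3 * n), n, 3))
  mult <- sensorGains(applyGainError(big, 0.2, seed = 77))
  expect_lt(abs(sd(mult) - 0.2) / 0.2, 0.05)
  expect_lt(abs(mean(mult) - 1), 0.01)
})
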