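test_that("sphere fitting recovers exact and partial spheres and flags degeneracy", {
  mesh <- fxHead()$mesh
  fit <- fitSphere(mesh)
  expect_lt(max(abs(fit@centre)), 1e-6)
  expect_equal(fit@radius, 0.08, tolerance = 1e-6)

  hemi <- which(mesh$vertices[, 3] > 0)
  fitH <- fitSphere(mesh, region = hemi)
  expect_lt(max(abs(fitH@centre - fit@centre)), 1e-6)
  expect_equal(fitH@radius, 0.08, tolerance = 1e-6)
  expect_identical(fitH@kind, "sphere_local")

  ell <- makeHead("ellipsoid", nVertices = 162)$mesh  # axes 70/80/90 mm
  fitG <- fitSphere(ell)
  loc <- localRegion(ell, c(0, 0, 0.09), radius = 0.04)
  fitL <- fitSphere(ell, region = loc)
  expect_gt(abs(fitG@radius - fitL@radius) + sqrt(sum((fitG@centre - fitL@centre)^2)), 1e-4)
  expect_gt(fitG@radius, 0.07); expect_lt(fitG@radius, 0.09)
  # local fit near the long-axis pole tracks the osculating sphere, whose
  # radius a^2/c (~54 mm) lies below the smallest semi-axis
  expect_gt(fitL@radius, 0.07^2 / 0.09 * 0.9)
  expect_lt(fitL@radius, 0.08)

  flat <- cbind(rnorm(20), rnorm(20), 0)
  expect_error(fitSphere(flat), "degenerate|failed")
})

test_that("sphere lead field: radial silence, gain linearity, dual-code agreement", {
  arr <- fxArray()
  sph <- sphereModel(c(0, 0, 0), 0.08)
  # radially oriented dipole is externally silent
  srcR <- sourceSpace(matrix(c(0.02, -0.01, 0.05), 1, 3),
                      matrix(c(0.02, -0.01, 0.05), 1, 3))
  expect_lt(max(abs(leadfieldMatrix(computeLeadfield(arr, srcR, sph)))), 1e-25)
  # dipole at the centre gives a zero column
  srcC <- sourceSpace(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3))
  expect_equal(max(abs(leadfieldMatrix(computeLeadfield(arr, srcC, sph)))), 0)

  src <- fxHead()$sources
  L <- leadfieldMatrix(computeLeadfield(arr, src, sph))
  # doubling one sensor's gain doubles its row exactly
  g <- sensorGains(arr); g[4] <- 2 * g[4]
  arr2 <- sensorArray(sensorPositions(arr), sensorOrientations(arr), g,
                      channelLabels(arr))
  L2 <- leadfieldMatrix(computeLeadfield(arr2, src, sph))
  expect_identical(L2[4, ], 2 * L[4, ])
  expect_identical(L2[-4, ], L[-4, ])

  # independent literal transcription of the closed-form field
  set.seed(8)
  for (k in sample(nSources(src), 12)) {
    for (c in sample(nChannels(arr), 4)) {
      Bref <- sarvasReference(sensorPositions(arr)[c, ],
                              sourcePositions(src)[k, ],
                              sourceOrientations(src)[k, ], sph@centre)
      val <- sensorGains(arr)[c] * sum(Bref * sensorOrientations(arr)[c, ])
      expect_equal(L[c, k], val, tolerance = 1e-12)
    }
  }

  expect_warning(
    computeLeadfield(arr, sourceSpace(matrix(c(0, 0, 0.09), 1, 3),
                                      matrix(c(1, 0, 0), 1, 3)), sph),
    "outside")
})

test_that("lead fields are linear in the dipole moment (superposition)", {
  arr <- fxArray()
  sph <- sphereModel(c(0, 0, 0), 0.08)
  p <- matrix(c(0.01, 0.03, 0.05), 1, 3)
  u <- c(1, 0, 0); v <- c(0, 1, -0.5) / sqrt(1.25)
  lu <- leadfieldMatrix(computeLeadfield(arr, sourceSpace(p, rbind(u)), sph))
  lv <- leadfieldMatrix(computeLeadfield(arr, sourceSpace(p, rbind(v)), sph))
  w <- u + v
  lw <- leadfieldMatrix(computeLeadfield(arr, sourceSpace(p, rbind(w / sqrt(sum(w^2)))), sph))
  expect_equal(as.numeric(lw * sqrt(sum(w^2))), as.numeric(lu + lv), tolerance = 1e-12)
})

test_that("field magnitude decays as a tangential source moves inward", {
  arr <- fxArray()
  sph <- sphereModel(c(0, 0, 0), 0.08)
  dirs <- sensorPositions(arr)[1, ] / sqrt(sum(sensorPositions(arr)[1, ]^2))
  depths <- seq(0.07, 0.02, by = -0.01)
  mags <- vapply(depths, function(r) {
    p <- rbind(r * dirs)
    tang <- c(-dirs[2], dirs[1], 0); tang <- tang / sqrt(sum(tang^2))
    abs(leadfieldMatrix(computeLeadfield(arr, sourceSpace(p, rbind(tang)), sph))[1, 1])
  }, 0)
  expect_true(all(diff(mags) < 0))
})

test_that("lead field is invariant under a global rigid transform of the scene", {
  arr <- fxArray()
  src <- fxHead()$sources
  sph <- sphereModel(c(0, 0, 0), 0.08)
  L0 <- leadfieldMatrix(computeLeadfield(arr, src, sph))
  pose <- rigidTransform(rotation = c(0.3, -0.1, 0.2), translation = c(0.01, 0.02, -0.005))
  R <- poseRotation(pose)
  piv <- c(0, 0, 0)
  arrT <- applyPose(arr, pose, piv)
  srcT <- sourceSpace(sweep(sourcePositions(src) %*% t(R), 2, pose@translation, "+"),
                      sourceOrientations(src) %*% t(R))
  sphT <- sphereModel(as.numeric(R %*% sph@centre + pose@translation), sph@radius)
  L1 <- leadfieldMatrix(computeLeadfield(arrT, srcT, sphT))
  expect_equal(L1, L0, tolerance = 1e-9)
})

test_that("corrected-sphere model degenerates to the sphere on a spherical shell", {
  hd <- fxHead()
  arr <- fxArray()
  ss <- singleShellModel(hd$mesh$vertices, hd$mesh$faces, shOrder = 8)
  Ls <- leadfieldMatrix(computeLeadfield(arr, hd$sources, ss))
  Lg <- leadfieldMatrix(computeLeadfield(arr, hd$sources,
                                         sphereModel(ss@centre, ss@radius)))
  expect_lt(norm(Ls - Lg, "F") / norm(Lg, "F"), 0.005)

  # radial dipole stays (almost) silent through the correction
  pos <- matrix(c(0, 0, 0.05), 1, 3)
  LsR <- leadfieldMatrix(computeLeadfield(arr, sourceSpace(pos, pos), ss))
  LsT <- leadfieldMatrix(computeLeadfield(arr, sourceSpace(pos, matrix(c(1, 0, 0), 1, 3)), ss))
  expect_lt(max(abs(LsR)) / max(abs(LsT)), 0.01)
})

test_that("corrected-sphere correction self-converges with harmonic order", {
  he <- makeHead("ellipsoid", nVertices = 162)
  arr <- fxArray()
  Lord <- lapply(c(4, 6, 8, 10, 14), function(o) {
    m <- singleShellModel(he$mesh$vertices, he$mesh$faces, shOrder = o)
    leadfieldMatrix(computeLeadfield(arr, he$sources, m))
  })
  ref <- Lord[[5]]
  errs <- vapply(Lord[1:4], function(L) norm(L - ref, "F") / norm(ref, "F"), 0)
  expect_true(all(diff(errs) < 0))   # monotone approach to the high-order field
  expect_lt(errs[4], 0.1)
  expect_error(singleShellModel(he$mesh$vertices[1:50, ], he$mesh$faces[1:40, ]),
               "closed|subscript")
})
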