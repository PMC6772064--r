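#' @include forward-sphere.R
NULL

# Real orthonormal spherical harmonics evaluated on unit directions.
# Returns length(x-rows) x Nb matrix, Nb = sum_{l=1..L} (2l+1); degree-major
# column order: (l,0), (l,1,cos), (l,1,sin), ..., (l,l,cos), (l,l,sin).
realSphericalHarmonics <- function(dirs, L) {
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  out <- matrix(0, n, L * (L + 2))
  col <- 1
  for (l in seq_len(L)) {
    P <- pracma::legendre(l, ct)  # (l+1) x n, rows m = 0..l, Condon-Shortley
    N0 <- sqrt((2 * l + 1) / (4 * pi))
    out[, col] <- N0 * P[1, ]
    col <- col + 1
    for (m in seq_len(l)) {
      Nm <- sqrt((2 * l + 1) / (2 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      out[, col] <- Nm * P[m + 1, ] * cos(m * phi)
      out[, col + 1] <- Nm * P[m + 1, ] * sin(m * phi)
      col <- col + 2
    }
  }
  out
}

# Exterior harmonic basis psi_k(x) = (r0/|x-c|)^(l+1) Y_lm(direction), which
# decays at infinity and is harmonic outside the centre.
shExteriorBasis <- function(points, centre, r0, L) {
  d <- sweep(rbind(points), 2, centre)
  r <- sqrt(rowSums(d^2))
  Y <- realSphericalHarmonics(d / r, L)
  ls <- rep(seq_len(L), times = 2 * seq_len(L) + 1)
  S <- outer(r0 / r, rep(1, ncol(Y)))^matrix(ls + 1, length(r), ncol(Y), byrow = TRUE)
  Y * S
}

# Directional derivative of each basis function along per-point directions.
# Central finite differences; h small relative to the reference radius.
shBasisDirDeriv <- function(points, dirs, centre, r0, L) {
  h <- 1e-6 * r0
  p1 <- rbind(points) + h * rbind(dirs)
  p0 <- rbind(points) - h * rbind(dirs)
  (shExteriorBasis(p1, centre, r0, L) - shExteriorBasis(p0, centre, r0, L)) / (2 * h)
}

faceCentresNormals <- function(vertices, faces, smooth = FALSE) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  fc <- (v1 + v2 + v3) / 3
  nrm <- crossRows(v2 - v1, v3 - v1)
  nrm <- nrm / rowNorms(nrm)
  # force outward orientation relative to the surface centroid
  ctr <- colMeans(vertices)
  flip <- rowSums(nrm * sweep(fc, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  if (smooth) {
    # vertex-averaged normals interpolated at face centres: a far better
    # estimate of the true surface normal than the flat facet normal
    vn <- matrix(0, nrow(vertices), 3)
    for (k in seq_len(nrow(faces)))
      for (j in 1:3) vn[faces[k, j], ] <- vn[faces[k, j], ] + nrm[k, ]
    vn <- vn / rowNorms(vn)
    nrm <- normalizeRows((vn[faces[, 1], , drop = FALSE] +
                          vn[faces[, 2], , drop = FALSE] +
                          vn[faces[, 3], , drop = FALSE]) / 3)
  }
  list(centres = fc, normals = nrm)
}

# Correction coefficients (Nb x Nd): least-squares fit of the exterior
# harmonic correction so that n . (B_sphere + B_corr) = n . B_primary on the
# shell (exact for a spherical conductor, where the correction vanishes).
shellCorrectionCoefficients <- function(head, sources) {
  key <- paste(fingerprint(sourcePositions(sources)),
               fingerprint(sourceOrientations(sources)), head@shOrder, sep = "|")
  hit <- head@cache[[key]]
  if (!is.null(hit)) return(hit)
  fcn <- faceCentresNormals(head@vertices, head@faces, smooth = TRUE)
  fc <- fcn$centres; nrm <- fcn$normals
  L <- head@shOrder
  # design matrix: n . (-grad psi_k) at each face centre
  A <- -shBasisDirDeriv(fc, nrm, head@centre, head@radius, L)
  sp <- sourcePositions(sources); so <- sourceOrientations(sources)
  resid <- matrix(0, nrow(fc), nSources(sources))
  for (i in seq_len(nrow(fc))) {
    Bp <- primaryFieldAt(fc[i, ], sp, so)
    Bs <- sarvasFieldAt(fc[i, ], sp, so, head@centre)
    resid[i, ] <- (Bp - Bs) %*% nrm[i, ]
  }
  sv <- svd(A)
  tol <- max(sv$d) * 1e-8
  keep <- sv$d > tol
  if (!all(keep))
    warning("ill-conditioned correction basis; fitting in a reduced subspace")
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% resid) / sv$d[keep])
  head@cache[[key]] <- coef
  coef
}

#' @describeIn computeLeadfield Corrected-sphere ("single shell") solution:
#'   the fitted-sphere Sarvas term plus an exterior spherical-harmonic
#'   correction field fitted by least-squares collocation at the shell face
#'   centres so that the field component normal to the shell matches the bare
#'   dipole (Biot-Savart) normal field. Reduces to the sphere solution when
#'   the shell is an exact sphere.
#' @export
setMethod("computeLeadfield", signature(head = "SingleShellModel"),
  function(array, sources, head) {
    sphere <- sphereModel(head@centre, head@radius)
    L0 <- computeLeadfield(array, sources, sphere)
    coef <- shellCorrectionCoefficients(head, sources)
    pos <- sensorPositions(array); ori <- sensorOrientations(array)
    G <- -shBasisDirDeriv(pos, ori, head@centre, head@radius, head@shOrder)
    corr <- sensorGains(array) * (G %*% coef)
    new("LeadField", matrix = leadfieldMatrix(L0) + corr,
        arrayRef = fingerprint(pos), sourceRef = fingerprint(sourcePositions(sources)),
        headRef = fingerprint(head@vertices))
  })
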