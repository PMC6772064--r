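#' @include geometry.R
NULL

# Subdivided icosahedron on the unit sphere. nSubdiv 0,1,2,3 -> 12, 42, 162,
# 642 vertices; always a closed genus-0 triangulation with outward faces.
icosphere <- function(nSubdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / rowNorms(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(nSubdiv)) {
    mid <- new.env(parent = emptyenv())
    nv <- nrow(v)
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      i <- mid[[key]]
      if (!is.null(i)) return(i)
      m <- (v[a, ] + v[b, ]); m <- m / vnorm(m)
      v <<- rbind(v, m)
      i <- nrow(v)
      mid[[key]] <- i
      i
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  list(vertices = unname(v), faces = matrix(as.integer(f), ncol = 3))
}

#' Generate a synthetic head surface and source space
#'
#' Parametric stand-in for subject anatomy: a closed triangulated
#' "inner-skull" surface (sphere or ellipsoid built from a subdivided
#' icosahedron), and a source space placed 10 mm interior to it, with outward
#' surface normals as the dipole orientation constraint.
#'
#' @param kind "sphere" or "ellipsoid".
#' @param radius inner-skull radius, metres (for the ellipsoid, the axes are
#'   `radius * axesScale`).
#' @param nVertices approximate vertex count; rounded up to the next
#'   icosphere subdivision (42, 162, 642, ...).
#' @param sourceDepth depth of the source shell below the surface, metres.
#' @param axesScale length-3 axis scaling for `kind = "ellipsoid"`.
#' @param tiltSd spread of the pseudo-cortical dipole orientations around the
#'   outward surface normal: each source orientation is the normal plus a
#'   seeded random tangential component of this standard deviation,
#'   renormalised. The default (1) gives a median tilt near 45 degrees,
#'   emulating the variability of cortical normals; radial-only orientations
#'   (`tiltSd = 0`) are externally silent in a spherical conductor and make
#'   the inverse problem degenerate.
#' @param tiltSmooth rounds of neighbour averaging applied to the tilt field
#'   before renormalisation. Cortical orientation fields are spatially smooth
#'   at the centimetre scale (neighbouring vertices of a gyral wall point
#'   almost the same way), which is what lets small rigid-array displacements
#'   be partially absorbed by nearby sources; 0 gives an (unrealistically)
#'   incoherent field.
#' @param seed seed for the orientation draw (the mesh is deterministic).
#' @return list with `mesh` (vertices/faces, metres) and `sources`
#'   (a [SourceSpace-class]).
#' @export
makeHead <- function(kind = c("sphere", "ellipsoid"), radius = 0.08,
                     nVertices = 642, sourceDepth = 0.01,
                     axesScale = c(0.875, 1, 1.125), tiltSd = 1,
                     tiltSmooth = 1, seed = 1) {
  kind <- match.arg(kind)
  if (nVertices < 42) stop("need at least 42 vertices")
  sub <- 1
  while (10 * 4^sub + 2 < nVertices) sub <- sub + 1
  ico <- icosphere(sub)
  scale <- if (kind == "sphere") rep(radius, 3) else radius * axesScale
  mesh <- list(vertices = ico$vertices %*% diag(scale), faces = ico$faces)
  # source shell: surface moved sourceDepth inward along the unit normal;
  # for the sphere the normal is radial, so sources sit at radius - depth
  nrml <- if (kind == "sphere") ico$vertices else
    sweep(mesh$vertices, 2, scale^2, "/")  # grad of (x/a)^2+(y/b)^2+(z/c)^2
  nrml <- normalizeRows(nrml)
  srcPos <- mesh$vertices - sourceDepth * nrml
  n <- nrow(nrml)
  ori <- nrml
  if (tiltSd > 0) {
    field <- withSeed(seed, matrix(stats::rnorm(3 * n), n, 3))
    if (tiltSmooth > 0) {
      nb <- lapply(seq_len(n), function(i) {
        adj <- mesh$faces[rowSums(mesh$faces == i) > 0, , drop = FALSE]
        setdiff(unique(as.vector(adj)), i)
      })
      for (s in seq_len(tiltSmooth))
        field <- t(vapply(seq_len(n), function(i)
          colMeans(field[c(i, nb[[i]]), , drop = FALSE]), numeric(3)))
    }
    field <- field / stats::sd(as.vector(field))        # restore unit spread
    tang <- field - rowSums(field * nrml) * nrml        # tangential part
    ori <- normalizeRows(nrml + tiltSd * tang)
  }
  list(mesh = mesh, sources = sourceSpace(srcPos, ori))
}

#' Place a scanner-cast-like sensor patch over a target
#'
#' Deterministically arranges `nSensors` point magnetometers on a spherical
#' cap of the sensor shell (scalp = inner-skull surface + `scalpOffset`;
#' sensitive volume a further `standoff` out), centred on the radial
#' projection of `target`, in concentric rings with at least `minSpacing`
#' between sensors. Orientations follow the local surface normal (radial).
#'
#' @param head output of [makeHead()] (its fitted sphere sets the geometry).
#' @param target 3-vector, metres; the patch centre direction.
#' @param nSensors number of sensors (default 13).
#' @param standoff sensitive-volume standoff from the scalp, metres
#'   (default 0.0065).
#' @param scalpOffset scalp thickness added to the inner skull, metres.
#' @param minSpacing minimum inter-sensor distance, metres (default 0.025).
#' @return a [SensorArray-class].
#' @export
makeArray <- function(head, target = defaultSourceLocation(), nSensors = 13,
                      standoff = 0.0065, scalpOffset = 0.01,
                      minSpacing = 0.025) {
  fit <- fitSphere(head$mesh)
  R <- fit@radius + scalpOffset + standoff
  ctr <- fit@centre
  u <- (target - ctr); u <- u / vnorm(u)
  # orthonormal tangent frame at the patch centre
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- crossProd3(u, ref); e1 <- e1 / vnorm(e1)
  e2 <- crossProd3(u, e1)
  dirAt <- function(theta, phi)
    cos(theta) * u + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
  dirs <- list(u)
  ringAngle <- minSpacing / R * 1.05
  ring <- 1
  while (length(dirs) < nSensors) {
    theta <- ring * ringAngle
    circ <- 2 * pi * R * sin(theta)
    nOnRing <- max(1, floor(circ / (minSpacing * 1.05)))
    nTake <- min(nOnRing, nSensors - length(dirs))
    phis <- 2 * pi * (seq_len(nTake) - 1) / nTake + ring  # stagger rings
    for (p in phis) dirs[[length(dirs) + 1]] <- dirAt(theta, p)
    ring <- ring + 1
    if (ring > 50) {
      warning("patch too small for the requested spacing; placed fewer sensors")
      break
    }
  }
  D <- do.call(rbind, dirs)
  pos <- sweep(R * D, 2, ctr, "+")
  sensorArray(pos, D, labels = sprintf("OPM%02d", seq_len(nrow(D))))
}

#' Simulate an on-scalp magnetometer recording
#'
#' Places a sinusoidal dipole of the given moment at the source-space vertex
#' nearest the requested location, forward-projects it through the volume
#' conductor, and adds i.i.d. Gaussian white sensor noise. Averaging
#' `nTrials` trials divides the effective noise RMS by sqrt(nTrials); the
#' signal part is deterministic given the geometry.
#'
#' @param spec a [SimulationSpec-class].
#' @param array a [SensorArray-class].
#' @param sources a [SourceSpace-class].
#' @param head a [HeadModel-class].
#' @return list: `data` (a [DataMatrix-class]), `truth` (list with
#'   `sourceIndex`, `J` the true Nd x Nt current matrix, `leadfield`).
#' @export
simulateRecording <- function(spec, array, sources, head) {
  d2 <- rowSums(sweep(sourcePositions(sources), 2, spec@sourceLocation)^2)
  idx <- which.min(d2)
  if (sqrt(d2[idx]) > 0.02)
    stop("source location is farther than 20 mm from any source-space vertex")
  Nt <- round(spec@duration * spec@sampleRate)
  tt <- seq(0, by = 1 / spec@sampleRate, length.out = Nt)
  s <- spec@dipoleMoment * sin(2 * pi * spec@sourceFreq * tt)
  lf <- computeLeadfield(array, sources, head)
  Ysig <- leadfieldMatrix(lf)[, idx, drop = FALSE] %*% rbind(s)
  sigmaEff <- spec@noiseRms / sqrt(spec@nTrials)
  noise <- withSeed(spec@seed,
    matrix(stats::rnorm(length(Ysig), 0, sigmaEff), nrow(Ysig), ncol(Ysig)))
  Y <- Ysig + noise
  J <- matrix(0, nSources(sources), Nt)
  J[idx, ] <- s
  list(data = dataMatrix(Y, spec@sampleRate, channelLabels(array),
                         c(0, spec@duration)),
       truth = list(sourceIndex = idx, J = J, leadfield = lf))
}
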