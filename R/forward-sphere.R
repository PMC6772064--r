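#' @include constructors.R
NULL

#' Fit a sphere to a surface
#'
#' Least-squares sphere through mesh vertices, minimising
#' sum((||v - c|| - r)^2). An algebraic (Coope) fit provides the start; a
#' Gauss-Newton refinement minimises the stated geometric loss. With `region`
#' the fit uses only that vertex subset (a "local sphere" matched to the
#' curvature under a sensor patch).
#'
#' @param surface a mesh (list with `vertices`, or an Nv x 3 matrix).
#' @param region optional integer vertex subset.
#' @param kind label of the returned model ("sphere_global"/"sphere_local";
#'   default picked from whether `region` is given).
#' @return a [SphereModel-class].
#' @export
fitSphere <- function(surface, region = NULL, kind = NULL) {
  v <- if (is.list(surface) && !is.null(surface$vertices)) surface$vertices
       else if (is(surface, "SingleShellModel")) surface@vertices
       else rbind(surface)
  if (!is.null(region)) v <- v[region, , drop = FALSE]
  if (nrow(v) < 4) stop("need at least 4 vertices to fit a sphere")
  # algebraic fit: ||v||^2 = 2 v.c + (r^2 - ||c||^2)
  A <- cbind(2 * v, 1)
  b <- rowSums(v^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) stop("sphere fit failed: degenerate (coplanar?) vertex set"))
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) stop("sphere fit failed: degenerate vertex set")
  start <- c(ctr, sqrt(r2))
  loss <- function(p) sum((sqrt(rowSums(sweep(v, 2, p[1:3])^2)) - p[4])^2)
  opt <- stats::optim(start, loss, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  if (is.null(kind)) kind <- if (is.null(region)) "sphere_global" else "sphere_local"
  sphereModel(opt$par[1:3], opt$par[4], kind = kind)
}

#' Select a local-sphere fitting region
#'
#' Vertices within `radius` (Euclidean) of the surface point nearest `target`.
#' @param surface mesh list with `vertices`.
#' @param target 3-vector, metres.
#' @param radius region radius, metres (default 0.04).
#' @export
localRegion <- function(surface, target, radius = 0.04) {
  v <- surface$vertices
  seedIdx <- which.min(rowSums(sweep(v, 2, target)^2))
  d <- sqrt(rowSums(sweep(v, 2, v[seedIdx, ])^2))
  which(d <= radius)
}

# Sarvas closed-form field of a current dipole in a homogeneous sphere.
# sensor: one position (metres); sources/moments: Nd x 3 relative to nothing
# (absolute, metres / A.m); centre: sphere centre. Returns Nd x 3 fields (T).
# Vectorised over sources. Radial dipole moments contribute exactly zero.
sarvasFieldAt <- function(sensor, sourcePos, moments, centre) {
  rv <- sensor - centre                       # sensor relative to centre
  r0 <- sweep(rbind(sourcePos), 2, centre)    # Nd x 3
  m <- rbind(moments)
  # only the tangential moment is externally visible (q x r0 kills the radial
  # part); project it out explicitly so radial dipoles are silent to machine
  # zero rather than cancellation noise
  r0n2 <- rowSums(r0^2)
  radial <- rowSums(m * r0) / pmax(r0n2, 1e-300)
  mt <- m - radial * r0
  mag <- rowNorms(m)
  silent <- rowNorms(mt) < 1e-12 * pmax(mag, 1e-300)
  mt[silent, ] <- 0
  av <- sweep(-r0, 2, rv, "+")                # rv - r0
  a <- sqrt(rowSums(av^2))
  r <- vnorm(rv)
  if (any(a < 1e-12)) stop("source coincides with a sensor position")
  ar <- av %*% rv                             # a . r
  r0r <- r0 %*% rv
  Fs <- a * (r * a + r^2 - r0r)               # Sarvas F
  alpha <- a^2 / r + ar / a + 2 * a + 2 * r
  beta <- a + 2 * r + ar / a
  gradF <- outer(as.numeric(alpha), rv) - as.numeric(beta) * r0
  qxr0 <- crossRows(mt, r0)
  k <- qxr0 %*% rv                            # (q x r0) . r
  B <- (as.numeric(Fs) * qxr0 - as.numeric(k) * gradF) * (MU0 / (4 * pi)) / as.numeric(Fs)^2
  # guard 0/0 when F underflows (source at the centre)
  bad <- !is.finite(Fs) | Fs == 0
  if (any(bad)) B[bad, ] <- 0
  B[silent, ] <- 0
  B
}

# Biot-Savart field of a bare current dipole (infinite homogeneous medium):
# B_p(x) = mu0/4pi q x (x - x0) / |x - x0|^3. Used as the normal-field
# boundary datum of the corrected-sphere model.
primaryFieldAt <- function(x, sourcePos, moments) {
  d <- sweep(-rbind(sourcePos), 2, x, "+")    # x - x0, Nd x 3
  dn3 <- (sqrt(rowSums(d^2)))^3
  crossRows(rbind(moments), d) * (MU0 / (4 * pi)) / dn3
}

#' @describeIn computeLeadfield Sarvas closed-form solution in a homogeneous
#'   conducting sphere. Radially oriented dipoles are externally silent;
#'   sources outside the sphere trigger a warning (model invalid there).
#' @export
setMethod("computeLeadfield", signature(head = "SphereModel"),
  function(array, sources, head) {
    pos <- sensorPositions(array); ori <- sensorOrientations(array)
    g <- sensorGains(array)
    sp <- sourcePositions(sources); so <- sourceOrientations(sources)
    rs <- sqrt(rowSums(sweep(sp, 2, head@centre)^2))
    if (any(rs > head@radius))
      warning(sprintf("%d source(s) outside the sphere; model invalid there",
                      sum(rs > head@radius)))
    L <- matrix(0, nChannels(array), nSources(sources))
    for (c in seq_len(nChannels(array))) {
      B <- sarvasFieldAt(pos[c, ], sp, so, head@centre)
      L[c, ] <- g[c] * (B %*% ori[c, ])
    }
    new("LeadField", matrix = L, arrayRef = fingerprint(pos),
        sourceRef = fingerprint(sp), headRef = fingerprint(c(head@centre, head@radius)))
  })
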