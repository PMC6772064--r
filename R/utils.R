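# Internal numerics shared across modules. All internal quantities are SI
# (metres, teslas, radians); millimetres/degrees appear only at user surfaces.

MU0 <- 4 * pi * 1e-7

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

rowNorms <- function(m) sqrt(rowSums(m * m))

normalizeRows <- function(m) {
  n <- rowNorms(m)
  if (any(n == 0)) stop("cannot normalize a zero vector")
  m / n
}

#' Rotation matrix from axis and angle (Rodrigues formula)
#'
#' @param axis length-3 axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @keywords internal
rotationMatrix <- function(axis, angle) {
  n <- vnorm(axis)
  if (n == 0) stop("rotation axis must be non-zero")
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Evaluate expr with a locally seeded RNG, restoring global RNG state after.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed (double
# arithmetic: products of 31-bit seeds overflow integer range).
subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 97) %% 2147483647)
}

# Cheap structural fingerprint used for provenance fields and caching only.
fingerprint <- function(x) {
  v <- as.numeric(x)
  sprintf("%d:%.10e:%.10e", length(v), sum(v), sum(v * seq_along(v)))
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
}
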