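## Internal numeric helpers shared across modules.

.DEG <- pi / 180

## Smallest signed angular difference a - b, in (-180, 180].
.angdiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## Wrap an angle into (-180, 180].
.wrap180 <- function(x) {
  d <- x %% 360
  ifelse(d > 180, d - 360, d)
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.norm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .norm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

## Signed torsion angle a-b-c-d in degrees, IUPAC sign convention
## (positive = clockwise rotation of d relative to a when viewed b -> c).
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  if (.norm(b2) < 1e-9) stop("undefined torsion: central bond has zero length")
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.norm(n1) < 1e-9 || .norm(n2) < 1e-9)
    stop("undefined torsion: three consecutive points are collinear")
  b2u <- b2 / .norm(b2)
  m1 <- .cross(n1, b2u)
  atan2(sum(m1 * n2), sum(n1 * n2)) / .DEG
}

## Place atom d given positions a, b, c, a bond length |c-d|, the bond
## angle b-c-d (degrees) and the torsion a-b-c-d (degrees).  Standard
## natural-extension-of-reference-frame construction.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * .DEG
  tor <- torsion * .DEG
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  M <- cbind(bc, m, n)
  as.vector(c + M %*% d_local)
}

## Evaluate an expression with a locally-set RNG seed, restoring the
## caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Pairwise Euclidean distances between the rows of two coordinate matrices.
.cdist <- function(x, y) {
  xx <- rowSums(x^2)
  yy <- rowSums(y^2)
  d2 <- outer(xx, yy, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
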