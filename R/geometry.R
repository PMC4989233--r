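# Low-level 3D geometry: internal-coordinate atom placement (NeRF),
# bond/dihedral measurement, and least-squares rigid superposition.

DEG2RAD <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three reference positions `a` (torsion reference), `b` (angle
#' reference) and `c` (bond parent), returns the position `d` such that
#' |d - c| = `bond`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `torsion`.
#'
#' @param a,b,c numeric 3-vectors, coordinates in Angstrom.
#' @param bond bond length c-d in Angstrom.
#' @param angle angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric 3-vector, the placed position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * DEG2RAD
  ph <- torsion * DEG2RAD
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Measure a dihedral angle
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -atan2(y, x) / DEG2RAD   # IUPAC sign convention
}

#' Measure a bond angle
#' @return angle p1-p2-p3 in degrees.
#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  u <- unit(p1 - p2)
  v <- unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) / DEG2RAD
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the rotation `R` and translation `t` minimizing
#' sum || R x_i + t - y_i ||^2 over paired coordinate sets.
#'
#' @param x,y n x 3 coordinate matrices (x is moved onto y).
#' @return list with `R` (3x3 rotation, det +1), `t` (length-3 translation)
#'   and `rmsd` (the residual RMSD of the fit).
#' @export
kabsch <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == 3, ncol(y) == 3,
            nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  h <- crossprod(x0, y0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(x %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fit - y)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param R 3x3 rotation. @param t length-3 translation.
#' @return transformed n x 3 matrix.
#' @keywords internal
apply_transform <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, "+")
}

#' Invert a rigid transform
#' @keywords internal
invert_transform <- function(R, t) {
  list(R = t(R), t = as.vector(-t(R) %*% t))
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * DEG2RAD
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Plain coordinate RMSD (no superposition)
#' @keywords internal
coord_rmsd <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

# Angular difference on the circle, degrees, in [-180, 180)
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d >= 180] <- d[d >= 180] - 360
  d
}

# Run an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards. All stochastic operations in the package draw
# through this so that per-call seeds do not disturb the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Classed error helper: all package errors carry a condition class so tests
# and the CLI can discriminate failure modes.
abort_rc <- function(class, msg, ...) {
  stop(structure(class = c(class, "refinecomplex_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
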