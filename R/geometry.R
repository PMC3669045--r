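# Small 3-vector geometry used throughout: displacement vectors under
# orthorhombic minimum-image convention, bond/angle/dihedral coordinates.
# All lengths in nm, angles in radians.

vec_norm <- function(v) sqrt(sum(v * v))

#' Minimum-image displacement
#'
#' Displacement `a - b` wrapped into the nearest periodic image of an
#' orthorhombic box.  With `box = NULL` no wrapping is applied.
#'
#' @param a,b numeric 3-vectors (nm).
#' @param box numeric 3-vector of box lengths (nm) or `NULL` for no PBC.
#' @return numeric 3-vector, the minimum-image displacement (nm).
#' @export
min_image <- function(a, b, box = NULL) {
  d <- a - b
  if (!is.null(box)) d <- d - box * round(d / box)
  d
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("pf_degenerate_geometry", "pf_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("pf_config_error", "pf_error")))
}

# angle at j in the triplet (i, j, k); returns list(theta, rij, rkj)
angle_coord <- function(ri, rj, rk, box = NULL) {
  rij <- min_image(ri, rj, box)
  rkj <- min_image(rk, rj, box)
  nij <- vec_norm(rij)
  nkj <- vec_norm(rkj)
  if (nij == 0 || nkj == 0) stop_degenerate("zero bond length in angle term")
  cost <- sum(rij * rkj) / (nij * nkj)
  cost <- max(-1, min(1, cost))
  list(theta = acos(cost), rij = rij, rkj = rkj, nij = nij, nkj = nkj,
       cost = cost)
}

# Dihedral angle for atoms (i, j, k, l) with the IUPAC sign convention:
# phi is the angle between the (i,j,k) and (j,k,l) planes, its sign taken
# from the scalar triple product r_ij . (r_kj x r_kl).
dihedral_coord <- function(ri, rj, rk, rl, box = NULL) {
  rij <- min_image(ri, rj, box)
  rkj <- min_image(rk, rj, box)
  rkl <- min_image(rk, rl, box)
  m <- cross3(rij, rkj)
  n <- cross3(rkj, rkl)
  nm <- vec_norm(m)
  nn <- vec_norm(n)
  if (nm == 0 || nn == 0) stop_degenerate("collinear atoms in dihedral term")
  cosphi <- sum(m * n) / (nm * nn)
  cosphi <- max(-1, min(1, cosphi))
  phi <- acos(cosphi)
  if (sum(rij * n) < 0) phi <- -phi
  list(phi = phi, rij = rij, rkj = rkj, rkl = rkl, m = m, n = n)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap an angle difference into (-pi, pi]
wrap_pi <- function(x) {
  x - 2 * pi * round(x / (2 * pi))
}
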