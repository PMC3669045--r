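# Analytic energies and per-atom forces for the supported potentials.
# Units: nm, kJ mol^-1, kJ mol^-1 nm^-1, radians.  All bonded displacement
# vectors are taken under the minimum-image convention of the frame's box.

#' Evaluate a bonded term
#'
#' Computes the potential energy of one bonded interaction and the analytic
#' force (minus gradient) on each of its atoms.  The per-term forces sum to
#' the zero vector (translation invariance of the potential).
#'
#' @param term a [bonded_term()].
#' @param fr a [frame()].
#' @return list with `energy` (kJ mol^-1), `forces` (k x 3 matrix,
#'   kJ mol^-1 nm^-1, rows ordered as `term$atoms`) and `atoms`
#'   (the term's 0-based atom ids).
#' @export
eval_bonded_term <- function(term, fr) {
  if (!inherits(term, "pf_term")) stop_config("term must be a pf_term")
  x <- fr$coords
  box <- fr$box
  p <- term$params
  a <- term$atoms + 1L  # 1-based rows
  switch(term$kind,
    BOND = {
      d <- min_image(x[a[1], ], x[a[2], ], box)
      r <- vec_norm(d)
      if (r == 0) stop_degenerate("zero distance in bond term")
      dr <- r - p$b0
      fi <- -p$k * dr * d / r
      list(energy = 0.5 * p$k * dr^2,
           forces = rbind(fi, -fi), atoms = term$atoms)
    },
    ANGLE = {
      g <- angle_coord(x[a[1], ], x[a[2], ], x[a[3], ], box)
      sint <- sqrt(max(0, 1 - g$cost^2))
      if (sint < 1e-12)
        stop_degenerate("degenerate angle (theta = 0 or pi)")
      dv <- p$k * (g$theta - p$theta0)      # dV/dtheta
      uij <- g$rij / g$nij
      ukj <- g$rkj / g$nkj
      # dtheta/dr_i = -(ukj - cost*uij) / (nij*sint)
      fi <- dv * (ukj - g$cost * uij) / (g$nij * sint)
      fk <- dv * (uij - g$cost * ukj) / (g$nkj * sint)
      list(energy = 0.5 * p$k * (g$theta - p$theta0)^2,
           forces = rbind(fi, -fi - fk, fk), atoms = term$atoms)
    },
    DIHEDRAL_PERIODIC = {
      g <- dihedral_coord(x[a[1], ], x[a[2], ], x[a[3], ], x[a[4], ], box)
      energy <- p$k * (1 + cos(p$n * g$phi - p$phis))
      ddphi <- -p$k * p$n * sin(p$n * g$phi - p$phis)
      list(energy = energy,
           forces = dihedral_forces(g, ddphi), atoms = term$atoms)
    },
    IMPROPER_HARMONIC = {
      g <- dihedral_coord(x[a[1], ], x[a[2], ], x[a[3], ], x[a[4], ], box)
      dxi <- wrap_pi(g$phi - p$xi0)
      list(energy = 0.5 * p$k * dxi^2,
           forces = dihedral_forces(g, p$k * dxi), atoms = term$atoms)
    },
    CROSS_BOND_BOND = {
      rij <- min_image(x[a[1], ], x[a[2], ], box)
      rkj <- min_image(x[a[3], ], x[a[2], ], box)
      nij <- vec_norm(rij); nkj <- vec_norm(rkj)
      if (nij == 0 || nkj == 0)
        stop_degenerate("zero distance in cross bond-bond term")
      fi <- -p$krr * (nkj - p$r2) * rij / nij
      fk <- -p$krr * (nij - p$r1) * rkj / nkj
      list(energy = p$krr * (nij - p$r1) * (nkj - p$r2),
           forces = rbind(fi, -fi - fk, fk), atoms = term$atoms)
    },
    CROSS_BOND_ANGLE = {
      rij <- min_image(x[a[1], ], x[a[2], ], box)
      rkj <- min_image(x[a[3], ], x[a[2], ], box)
      rik <- min_image(x[a[1], ], x[a[3], ], box)
      nij <- vec_norm(rij); nkj <- vec_norm(rkj); nik <- vec_norm(rik)
      if (nij == 0 || nkj == 0 || nik == 0)
        stop_degenerate("zero distance in cross bond-angle term")
      s <- (nij - p$r1) + (nkj - p$r2)
      fi <- -p$krt * (s * rik / nik + (nik - p$r3) * rij / nij)
      fk <- -p$krt * (-s * rik / nik + (nik - p$r3) * rkj / nkj)
      list(energy = p$krt * (nik - p$r3) * s,
           forces = rbind(fi, -fi - fk, fk), atoms = term$atoms)
    },
    stop(errorCondition(paste0("unsupported bonded term kind: ", term$kind),
                        class = c("pf_unsupported_term", "pf_error")))
  )
}

# Shared force expression for proper and improper dihedrals given the
# geometry `g` from dihedral_coord() and ddphi = dV/dphi.
dihedral_forces <- function(g, ddphi) {
  iprm <- sum(g$m * g$m)
  iprn <- sum(g$n * g$n)
  nrkj2 <- sum(g$rkj * g$rkj)
  nrkj <- sqrt(nrkj2)
  fi <- -ddphi * nrkj / iprm * g$m
  fl <- ddphi * nrkj / iprn * g$n
  pp <- sum(g$rij * g$rkj) / nrkj2
  qq <- sum(g$rkl * g$rkj) / nrkj2
  sv <- pp * fi - qq * fl
  fj <- -fi + sv
  fk <- -fl - sv
  rbind(fi, fj, fk, fl)
}

#' Evaluate a nonbonded pair interaction
#'
#' Cutoff Lennard-Jones or Coulomb interaction between two atoms under the
#' minimum-image convention.  Lennard-Jones parameters use Lorentz-Berthelot
#' combination (arithmetic sigma, geometric epsilon); Coulomb uses
#' ke = 138.935458 kJ mol^-1 nm e^-2.  The force is central; the force on
#' `j` is the exact negation of the returned force on `i`.
#'
#' @param i,j 0-based atom ids, distinct.
#' @param fr a [frame()].
#' @param top a [topology()].
#' @param kind `"LJ"` or `"COULOMB"`.
#' @param scale dimensionless scale factor (1 for plain pairs, the fudge
#'   factor for 1-4 pairs).
#' @return list with `energy` (kJ mol^-1) and `force_i`
#'   (3-vector, kJ mol^-1 nm^-1, the force exerted on `i` by `j`).
#' @export
eval_nonbonded_pair <- function(i, j, fr, top, kind = c("LJ", "COULOMB"),
                                scale = 1) {
  kind <- match.arg(kind)
  if (i == j) stop_config("nonbonded pair needs two distinct atoms")
  d <- min_image(fr$coords[i + 1L, ], fr$coords[j + 1L, ], fr$box)
  r2 <- sum(d * d)
  if (r2 == 0) stop_degenerate("zero distance in nonbonded pair")
  if (kind == "COULOMB") {
    qq <- top$atoms$charge[i + 1L] * top$atoms$charge[j + 1L]
    r <- sqrt(r2)
    energy <- scale * KE_COULOMB * qq / r
    # F_i = ke q_i q_j / r^2 * rhat_ij (repulsive for like charges)
    force_i <- scale * KE_COULOMB * qq / (r2 * r) * d
  } else {
    sig <- 0.5 * (top$atoms$sigma[i + 1L] + top$atoms$sigma[j + 1L])
    eps <- sqrt(top$atoms$epsilon[i + 1L] * top$atoms$epsilon[j + 1L])
    sr6 <- (sig^2 / r2)^3
    energy <- scale * 4 * eps * (sr6^2 - sr6)
    force_i <- scale * 24 * eps * (2 * sr6^2 - sr6) / r2 * d
  }
  list(energy = energy, force_i = force_i)
}

#' Finite-difference forces (test oracle)
#'
#' Central-difference approximation of minus the gradient of an arbitrary
#' configurational energy function; the ground truth against which analytic
#' forces are validated.
#'
#' @param energy_fn function taking a [frame()] and returning a scalar
#'   energy (kJ mol^-1).
#' @param fr a [frame()].
#' @param h finite-difference step (nm), default 1e-6.
#' @return n x 3 matrix of forces (kJ mol^-1 nm^-1).
#' @export
finite_difference_forces <- function(energy_fn, fr, h = 1e-6) {
  stopifnot(h > 0)
  n <- nrow(fr$coords)
  f <- matrix(0, n, 3)
  for (at in seq_len(n)) {
    for (dim in 1:3) {
      fp <- fr; fp$coords[at, dim] <- fp$coords[at, dim] + h
      fm <- fr; fm$coords[at, dim] <- fm$coords[at, dim] - h
      f[at, dim] <- -(energy_fn(fp) - energy_fn(fm)) / (2 * h)
    }
  }
  f
}

#' Total analytic forces on every atom
#'
#' Sums bonded-term forces and all non-excluded nonbonded pair forces
#' (with 1-4 scaling) within `cutoff`.  Used by the Langevin integrator and
#' as the reconstruction reference for the pairwise decomposition.
#'
#' @param top a [topology()].
#' @param fr a [frame()].
#' @param cutoff nonbonded cutoff (nm); `Inf` disables truncation.
#' @param itypes subset of `c("BOND","ANGLE","DIHEDRAL","LJ","COULOMB")`
#'   selecting which interaction classes contribute.
#' @return n x 3 matrix of forces (kJ mol^-1 nm^-1).
#' @export
system_forces <- function(top, fr, cutoff = Inf, itypes = ITYPES) {
  check_frame_atoms(fr, top)
  n <- n_atoms(top)
  f <- matrix(0, n, 3)
  for (term in top$terms) {
    if (!(term_itype(term$kind) %in% itypes)) next
    ev <- eval_bonded_term(term, fr)
    f[term$atoms + 1L, ] <- f[term$atoms + 1L, ] + ev$forces
  }
  if (any(c("LJ", "COULOMB") %in% itypes) && n > 1) {
    pl <- nonbonded_pairs(top, fr, cutoff)
    for (r in seq_len(nrow(pl))) {
      kind <- pl$kind[r]
      if (!(kind %in% itypes)) next
      ev <- eval_nonbonded_pair(pl$i[r], pl$j[r], fr, top, kind, pl$scale[r])
      f[pl$i[r] + 1L, ] <- f[pl$i[r] + 1L, ] + ev$force_i
      f[pl$j[r] + 1L, ] <- f[pl$j[r] + 1L, ] - ev$force_i
    }
  }
  f
}

# itype an interaction is reported under: cross terms count as ANGLE,
# improper dihedrals as DIHEDRAL (keeps the 5-value output enum closed).
term_itype <- function(kind) {
  switch(kind,
    BOND = "BOND",
    ANGLE = "ANGLE", CROSS_BOND_BOND = "ANGLE", CROSS_BOND_ANGLE = "ANGLE",
    DIHEDRAL_PERIODIC = "DIHEDRAL", IMPROPER_HARMONIC = "DIHEDRAL")
}

#' Total potential energy of a system
#'
#' @inheritParams system_forces
#' @return scalar energy (kJ mol^-1).
#' @export
system_energy <- function(top, fr, cutoff = Inf, itypes = ITYPES) {
  e <- 0
  for (term in top$terms) {
    if (!(term_itype(term$kind) %in% itypes)) next
    e <- e + eval_bonded_term(term, fr)$energy
  }
  if (any(c("LJ", "COULOMB") %in% itypes) && n_atoms(top) > 1) {
    pl <- nonbonded_pairs(top, fr, cutoff)
    for (r in seq_len(nrow(pl))) {
      if (!(pl$kind[r] %in% itypes)) next
      e <- e + eval_nonbonded_pair(pl$i[r], pl$j[r], fr, top,
                                   pl$kind[r], pl$scale[r])$energy
    }
  }
  e
}

# All non-excluded nonbonded (i, j, kind, scale) rows within cutoff,
# ignoring group selections (full system).  Pairs with a zero interaction
# prefactor (zero charge product / zero epsilon) are dropped.
nonbonded_pairs <- function(top, fr, cutoff = Inf) {
  build_pair_list(fr, top,
                  group_spec(0:(n_atoms(top) - 1L), 0:(n_atoms(top) - 1L)),
                  cutoff = cutoff, check_halfbox = FALSE)
}
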