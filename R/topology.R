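# Domain containers: topology (atoms, residues, bonded terms, exclusions,
# scaled 1-4 pairs) and trajectory frames.  Atom and residue ids are 0-based
# everywhere inside the package and in all output files; only NDX input is
# 1-based.

TERM_KINDS <- c("BOND", "ANGLE", "DIHEDRAL_PERIODIC", "IMPROPER_HARMONIC",
                "CROSS_BOND_BOND", "CROSS_BOND_ANGLE")
ITYPES <- c("BOND", "ANGLE", "DIHEDRAL", "LJ", "COULOMB")

# Coulomb constant, kJ mol^-1 nm e^-2 (GROMACS electric conversion factor)
KE_COULOMB <- 138.935458

term_arity <- function(kind) {
  switch(kind,
    BOND = 2L,
    ANGLE = 3L, CROSS_BOND_BOND = 3L, CROSS_BOND_ANGLE = 3L,
    DIHEDRAL_PERIODIC = 4L, IMPROPER_HARMONIC = 4L,
    stop(errorCondition(paste0("unsupported bonded term kind: ", kind),
                        class = c("pf_unsupported_term", "pf_error"))))
}

#' Construct a bonded term
#'
#' @param kind one of `"BOND"`, `"ANGLE"`, `"DIHEDRAL_PERIODIC"`,
#'   `"IMPROPER_HARMONIC"`, `"CROSS_BOND_BOND"`, `"CROSS_BOND_ANGLE"`.
#' @param atoms integer vector of 0-based atom ids; length must match the
#'   arity of `kind` (2, 3 or 4) and ids must be distinct.
#' @param params named list of parameters, see Details.
#' @details Parameter names per kind (GROMACS functional forms and units):
#' * `BOND`: `k` (kJ mol^-1 nm^-2), `b0` (nm); V = k/2 (r - b0)^2.
#' * `ANGLE`: `k` (kJ mol^-1 rad^-2), `theta0` (rad); V = k/2 (theta - theta0)^2.
#' * `DIHEDRAL_PERIODIC`: `k` (kJ mol^-1), `n` (multiplicity), `phis` (rad);
#'   V = k (1 + cos(n phi - phis)).
#' * `IMPROPER_HARMONIC`: `k` (kJ mol^-1 rad^-2), `xi0` (rad);
#'   V = k/2 (xi - xi0)^2 with the difference wrapped into (-pi, pi].
#' * `CROSS_BOND_BOND`: `krr` (kJ mol^-1 nm^-2), `r1`, `r2` (nm), atoms
#'   (i, j, k) with j central; V = krr (r_ij - r1)(r_kj - r2).
#' * `CROSS_BOND_ANGLE`: `krt` (kJ mol^-1 nm^-2), `r1`, `r2`, `r3` (nm);
#'   V = krt (r_ik - r3)(r_ij - r1 + r_kj - r2).
#' @return an object of class `pf_term`.
#' @export
bonded_term <- function(kind, atoms, params) {
  kind <- match.arg(kind, TERM_KINDS)
  atoms <- as.integer(atoms)
  if (length(atoms) != term_arity(kind))
    stop_config(sprintf("%s term needs %d atoms, got %d",
                        kind, term_arity(kind), length(atoms)))
  if (anyDuplicated(atoms))
    stop_config(sprintf("%s term atoms must be distinct: %s",
                        kind, paste(atoms, collapse = " ")))
  structure(list(kind = kind, atoms = atoms, params = params),
            class = "pf_term")
}

#' Construct a validated topology
#'
#' @param atoms data.frame with one row per atom (row r is atom id r-1) and
#'   columns `name`, `resid` (0-based residue index), `mass` (amu),
#'   `charge` (e), `sigma` (nm), `epsilon` (kJ mol^-1).
#' @param resnames character vector of residue names (entry r is residue
#'   id r-1); defaults to `RES<id>`.
#' @param terms list of [bonded_term()] objects.
#' @param exclusions two-column integer matrix of unordered 0-based atom-id
#'   pairs removed from nonbonded interactions.
#' @param pairs14 two-column integer matrix of unordered 0-based atom-id
#'   pairs interacting with scaled nonbonded parameters.
#' @param fudge_lj,fudge_qq dimensionless 1-4 scale factors for
#'   Lennard-Jones and Coulomb interactions.
#' @return an object of class `pf_topology`.
#' @export
topology <- function(atoms, resnames = NULL, terms = list(),
                     exclusions = NULL, pairs14 = NULL,
                     fudge_lj = 1, fudge_qq = 1) {
  atoms <- as.data.frame(atoms)
  req <- c("name", "resid", "mass", "charge", "sigma", "epsilon")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop_config(paste0("atoms table missing columns: ",
                       paste(miss, collapse = ", ")))
  n <- nrow(atoms)
  if (n == 0) stop_config("topology needs at least one atom")
  if (any(atoms$mass <= 0)) stop_config("atom masses must be positive")
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0))
    stop_config("Lennard-Jones sigma and epsilon must be non-negative")
  atoms$resid <- as.integer(atoms$resid)
  if (any(atoms$resid < 0)) stop_config("residue indices must be >= 0")
  nres <- max(atoms$resid) + 1L
  if (!setequal(unique(atoms$resid), 0:(nres - 1L)))
    stop_config("residue indices must cover 0..max without gaps")
  if (is.null(resnames)) resnames <- paste0("RES", 0:(nres - 1L))
  if (length(resnames) != nres)
    stop_config("resnames length does not match number of residues")

  check_ids <- function(ids, what) {
    bad <- ids[ids < 0 | ids >= n]
    if (length(bad))
      stop_config(sprintf("%s references unknown atom id %d (have %d atoms)",
                          what, bad[1], n))
  }
  for (t in terms) {
    if (!inherits(t, "pf_term")) stop_config("terms must be pf_term objects")
    check_ids(t$atoms, t$kind)
  }
  canon_pairs <- function(m, what) {
    if (is.null(m) || NROW(m) == 0)
      return(matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("i", "j"))))
    m <- matrix(as.integer(as.matrix(m)[, 1:2]), ncol = 2)
    check_ids(as.vector(m), what)
    if (any(m[, 1] == m[, 2]))
      stop_config(paste0(what, " pair with identical atoms"))
    m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    if (anyDuplicated(m))
      stop_config(paste0("duplicate ", what, " pair"))
    colnames(m) <- c("i", "j")
    m
  }
  exclusions <- canon_pairs(exclusions, "exclusion")
  pairs14 <- canon_pairs(pairs14, "1-4")
  if (nrow(exclusions) && nrow(pairs14)) {
    key <- function(m) paste(m[, 1], m[, 2])
    if (length(intersect(key(exclusions), key(pairs14))))
      stop_config("exclusions and 1-4 pairs must be disjoint")
  }
  structure(list(atoms = atoms, resnames = as.character(resnames),
                 terms = terms, exclusions = exclusions, pairs14 = pairs14,
                 fudge_lj = fudge_lj, fudge_qq = fudge_qq),
            class = "pf_topology")
}

n_atoms <- function(top) nrow(top$atoms)
n_residues <- function(top) length(top$resnames)

#' Construct a trajectory frame
#'
#' @param coords n x 3 numeric matrix of coordinates (nm).
#' @param time frame time (ps).
#' @param box orthorhombic box lengths, numeric 3-vector (nm), or `NULL`
#'   for a non-periodic system.
#' @return an object of class `pf_frame`.
#' @export
frame <- function(coords, time = 0, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop_config("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0))
      stop_config("box must be three positive lengths (orthorhombic)")
  }
  structure(list(time = as.numeric(time), coords = coords, box = box),
            class = "pf_frame")
}

check_frame_atoms <- function(fr, top) {
  if (nrow(fr$coords) != n_atoms(top))
    stop(errorCondition(
      sprintf("frame has %d atoms, topology has %d",
              nrow(fr$coords), n_atoms(top)),
      class = c("pf_format_error", "pf_error")))
  invisible(fr)
}

#' @export
print.pf_topology <- function(x, ...) {
  kinds <- table(vapply(x$terms, `[[`, "", "kind"))
  cat(sprintf("<pf_topology> %d atoms, %d residues, %d bonded terms\n",
              n_atoms(x), n_residues(x), length(x$terms)))
  if (length(kinds))
    cat("  ", paste(sprintf("%s:%d", names(kinds), kinds), collapse = "  "),
        "\n", sep = "")
  cat(sprintf("  exclusions: %d, 1-4 pairs: %d (fudge_lj=%g, fudge_qq=%g)\n",
              nrow(x$exclusions), nrow(x$pairs14), x$fudge_lj, x$fudge_qq))
  invisible(x)
}

#' @export
print.pf_frame <- function(x, ...) {
  cat(sprintf("<pf_frame> %d atoms, t = %g ps, box = %s\n",
              nrow(x$coords), x$time,
              if (is.null(x$box)) "none" else paste(signif(x$box, 6),
                                                    collapse = " x ")))
  invisible(x)
}

# residue membership: list of 0-based atom-id vectors, one per residue
residue_members <- function(top) {
  split(0:(n_atoms(top) - 1L), top$atoms$resid)
}

# residue centers of mass, nres x 3 (nm)
residue_com <- function(top, fr) {
  m <- top$atoms$mass
  nres <- n_residues(top)
  com <- matrix(0, nres, 3)
  for (r in seq_len(nres)) {
    idx <- which(top$atoms$resid == r - 1L)
    w <- m[idx] / sum(m[idx])
    com[r, ] <- colSums(fr$coords[idx, , drop = FALSE] * w)
  }
  com
}
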