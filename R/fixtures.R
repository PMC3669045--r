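# Deterministic toy molecular systems.  These stand in for real
# protein systems so that every pipeline stage is testable without
# external data: parameters are coarse-grained but physically sensible
# (positive force constants, nm-scale geometry, partial charges well under
# 1 e).

TOY_KINDS <- c("DIATOMIC", "TRIATOMIC_ANGLE", "CHAIN4_DIHEDRAL",
               "CHARGED_DIMER", "BEAD_CHAIN_N")

#' Generate a toy molecular system
#'
#' Deterministic generators for small test systems.  `CHAIN4_DIHEDRAL` is
#' a butane-like 4-atom chain whose middle atom pair is shared by bond,
#' angle and dihedral terms (exercising summed-versus-detailed
#' bookkeeping); `BEAD_CHAIN_N` is a zig-zag polymer of `n_beads`
#' alternating-charge beads with one residue per bead pair (exercising
#' residue aggregation and the force-clamp demo); `CHARGED_DIMER` is a +1/-1
#' ion pair at 1 nm.
#'
#' @param kind one of `"DIATOMIC"`, `"TRIATOMIC_ANGLE"`,
#'   `"CHAIN4_DIHEDRAL"`, `"CHARGED_DIMER"`, `"BEAD_CHAIN_N"`.
#' @param n_beads bead count for `BEAD_CHAIN_N` (>= 3).
#' @param seed recorded for provenance; the construction itself is fully
#'   deterministic.
#' @return list with `topology` (a [topology()]) and `frame` (a [frame()]
#'   at the equilibrium-like starting geometry).
#' @export
make_toy_system <- function(kind = TOY_KINDS, n_beads = 8, seed = 1) {
  kind <- match.arg(kind)
  sys <- switch(kind,
    DIATOMIC = {
      atoms <- data.frame(name = c("A1", "A2"), resid = 0:1,
                          mass = 12, charge = 0, sigma = 0, epsilon = 0)
      top <- topology(atoms,
                      terms = list(bonded_term("BOND", c(0, 1),
                                               list(k = 1000, b0 = 0.15))),
                      exclusions = rbind(c(0, 1)))
      list(topology = top,
           frame = frame(rbind(c(0, 0, 0), c(0.15, 0, 0))))
    },
    TRIATOMIC_ANGLE = {
      theta0 <- 110 * pi / 180
      b0 <- 0.15
      atoms <- data.frame(name = c("A1", "A2", "A3"), resid = c(0, 0, 1),
                          mass = 12, charge = 0, sigma = 0, epsilon = 0)
      top <- topology(atoms, terms = list(
        bonded_term("BOND", c(0, 1), list(k = 1000, b0 = b0)),
        bonded_term("BOND", c(1, 2), list(k = 1000, b0 = b0)),
        bonded_term("ANGLE", c(0, 1, 2), list(k = 400, theta0 = theta0))),
        exclusions = rbind(c(0, 1), c(1, 2), c(0, 2)))
      coords <- rbind(c(b0, 0, 0), c(0, 0, 0),
                      b0 * c(cos(theta0), sin(theta0), 0))
      list(topology = top, frame = frame(coords))
    },
    CHAIN4_DIHEDRAL = {
      b0 <- 0.153
      theta0 <- 111 * pi / 180
      atoms <- data.frame(name = paste0("C", 1:4), resid = c(0, 0, 1, 1),
                          mass = 12.011, charge = c(0.1, -0.1, -0.1, 0.1),
                          sigma = 0.33, epsilon = 0.4)
      top <- topology(atoms, terms = list(
        bonded_term("BOND", c(0, 1), list(k = 1000, b0 = b0)),
        bonded_term("BOND", c(1, 2), list(k = 1000, b0 = b0)),
        bonded_term("BOND", c(2, 3), list(k = 1000, b0 = b0)),
        bonded_term("ANGLE", c(0, 1, 2), list(k = 400, theta0 = theta0)),
        bonded_term("ANGLE", c(1, 2, 3), list(k = 400, theta0 = theta0)),
        bonded_term("DIHEDRAL_PERIODIC", c(0, 1, 2, 3),
                    list(k = 5, n = 3, phis = 0))),
        exclusions = rbind(c(0, 1), c(1, 2), c(2, 3), c(0, 2), c(1, 3)),
        pairs14 = rbind(c(0, 3)),
        fudge_lj = 0.5, fudge_qq = 0.8333)
      coords <- zigzag_coords(4, b0, theta0)
      # twist the last atom out of plane so the dihedral is off-stationary
      coords[4, 3] <- coords[4, 3] + 0.05
      list(topology = top, frame = frame(coords))
    },
    CHARGED_DIMER = {
      atoms <- data.frame(name = c("NA", "CL"), resid = 0:1,
                          mass = c(22.99, 35.45), charge = c(1, -1),
                          sigma = 0, epsilon = 0)
      top <- topology(atoms)
      list(topology = top,
           frame = frame(rbind(c(0, 0, 0), c(1, 0, 0))))
    },
    BEAD_CHAIN_N = {
      n <- as.integer(n_beads)
      if (n < 3) stop_config("BEAD_CHAIN_N needs n_beads >= 3")
      b0 <- 0.4
      theta0 <- 130 * pi / 180
      atoms <- data.frame(name = paste0("B", seq_len(n)),
                          resid = (seq_len(n) - 1L) %/% 2L,
                          mass = 50,
                          charge = 0.3 * (-1)^(seq_len(n) - 1L),
                          sigma = 0.35, epsilon = 0.3)
      terms <- list()
      for (b in seq_len(n - 1L))
        terms[[length(terms) + 1L]] <-
          bonded_term("BOND", c(b - 1L, b), list(k = 1000, b0 = b0))
      for (b in seq_len(n - 2L))
        terms[[length(terms) + 1L]] <-
          bonded_term("ANGLE", c(b - 1L, b, b + 1L),
                      list(k = 40, theta0 = theta0))
      excl <- rbind(
        cbind(0:(n - 2L), 1:(n - 1L)),             # 1-2
        if (n > 2) cbind(0:(n - 3L), 2:(n - 1L)))  # 1-3
      p14 <- if (n > 3) cbind(0:(n - 4L), 3:(n - 1L))
      top <- topology(atoms, terms = terms, exclusions = excl,
                      pairs14 = p14, fudge_lj = 0.5, fudge_qq = 0.8333)
      list(topology = top, frame = frame(zigzag_coords(n, b0, theta0)))
    })
  sys$kind <- kind
  sys$seed <- as.integer(seed)
  sys
}

# planar zig-zag with bond length b0 and bond angle theta0 at every
# interior bead
zigzag_coords <- function(n, b0, theta0) {
  delta <- (pi - theta0) / 2
  coords <- matrix(0, n, 3)
  for (b in 2:n) {
    ang <- if (b %% 2 == 0) delta else -delta
    coords[b, ] <- coords[b - 1, ] + b0 * c(cos(ang), sin(ang), 0)
  }
  coords
}

#' Randomly perturbed copies of a frame
#'
#' Adds i.i.d. uniform displacements in `[-amplitude, amplitude]` to every
#' coordinate, producing the random configurations used by the
#' finite-difference and decomposition-exactness test suites.
#'
#' @param fr a [frame()].
#' @param n number of perturbed frames.
#' @param amplitude maximum displacement per coordinate (nm).
#' @param seed RNG seed; same seed, same frames.
#' @return list of `n` frames.
#' @export
perturb_configurations <- function(fr, n, amplitude, seed = 1) {
  if (amplitude < 0) stop_config("amplitude must be >= 0")
  nat <- nrow(fr$coords)
  out <- vector("list", n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (k in seq_len(n)) {
    fk <- fr
    fk$coords <- fr$coords +
      matrix(stats::runif(3 * nat, -amplitude, amplitude), nat, 3)
    out[[k]] <- fk
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a toy system and optional trajectory as pipeline input files
#'
#' Emits `<prefix>.top` (topology), `<prefix>.gro` (starting structure or
#' trajectory) and `<prefix>.ndx` (groups `all` with every atom, and
#' `termini` with the two terminal atoms).
#'
#' @param sys a system from [make_toy_system()].
#' @param prefix output path prefix.
#' @param frames optional list of frames to write instead of the starting
#'   structure (e.g. from [run_toy_forceclamp()]).
#' @return named character vector of the written paths, invisibly.
#' @export
write_toy_system <- function(sys, prefix, frames = NULL) {
  top_path <- paste0(prefix, ".top")
  gro_path <- paste0(prefix, ".gro")
  ndx_path <- paste0(prefix, ".ndx")
  write_topology(sys$topology, top_path)
  write_gro(if (is.null(frames)) sys$frame else frames, sys$topology,
            gro_path)
  n <- n_atoms(sys$topology)
  writeLines(c("[ all ]",
               paste(seq_len(n), collapse = " "),
               "[ termini ]",
               paste(c(1L, n), collapse = " ")), ndx_path)
  invisible(c(topology = top_path, trajectory = gro_path, index = ndx_path))
}
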