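# Exact decomposition of per-term atomic forces into antisymmetric vector
# pairwise forces, group/cutoff/exclusion-aware nonbonded pair enumeration,
# and the per-frame pairwise-force store.
#
# Convention: a pairwise force record (i, j, vector) is the force exerted
# ON i BY j; the implied force on j is the exact negation.  The store keys
# pairs under (min id, max id) with the vector expressed as the force on
# the lower id.

#' Atom group selection
#'
#' A pairwise force is only computed when the two atoms belong to different
#' groups; to analyse all interactions within one set of atoms, pass the
#' same set as both groups.
#'
#' @param group1,group2 integer vectors of 0-based atom ids, non-empty;
#'   may overlap or be identical.
#' @return an object of class `pf_groups`.
#' @export
group_spec <- function(group1, group2) {
  g1 <- sort(unique(as.integer(group1)))
  g2 <- sort(unique(as.integer(group2)))
  if (!length(g1) || !length(g2))
    stop_config("both atom groups must be non-empty")
  structure(list(group1 = g1, group2 = g2), class = "pf_groups")
}

# cross-group test for atom pairs (vectorised over equal-length id vectors)
in_cross_group <- function(i, j, groups) {
  (i %in% groups$group1 & j %in% groups$group2) |
    (i %in% groups$group2 & j %in% groups$group1)
}

#' Decompose one bonded term into pairwise forces
#'
#' Attributes the analytic atomic forces of a 2-, 3- or 4-body bonded term
#' to atom pairs such that, for every atom of the term, the pairwise forces
#' involving it sum exactly to its analytic force, and every pair is
#' antisymmetric by construction.  Pairwise forces from 3- and 4-body terms
#' are generally not aligned with the pair separation vector.
#'
#' Schemes (atoms in term order): BOND gives the single central pair.
#' ANGLE (i, j, k; j central) solves a 2x2 system in the plane spanned by
#' the unit bond vectors for the two forces on j, the remainder of F_i
#' becoming a generally non-central (i, k) pair; for near-collinear angles
#' (|sin theta| < 1e-6) it falls back to F_ij = F_i, F_kj = F_k (still
#' exact) with a warning.  DIHEDRAL (i, j, k, l) assigns F_ij = F_i,
#' F_lk = F_l, F_jk = F_i + F_j.  CROSS_BOND_BOND gives two central pairs;
#' CROSS_BOND_ANGLE assigns each gradient component to the pair whose
#' separation vector it is parallel to (three central pairs).
#'
#' @param term a [bonded_term()].
#' @param fr a [frame()].
#' @param forces the analytic forces of this term at this frame, as
#'   returned by [eval_bonded_term()] (k x 3 matrix in term-atom order);
#'   computed on the fly when `NULL`.
#' @return data.frame with columns `i`, `j` (0-based atom ids), `fx`, `fy`,
#'   `fz` (force on `i` by `j`, kJ mol^-1 nm^-1) and `itype`.
#' @export
decompose_bonded <- function(term, fr, forces = NULL) {
  if (is.null(forces)) forces <- eval_bonded_term(term, fr)$forces
  a <- term$atoms
  itype <- term_itype(term$kind)
  pair_rows <- function(i, j, v) {
    data.frame(i = i, j = j, fx = v[1], fy = v[2], fz = v[3], itype = itype,
               stringsAsFactors = FALSE)
  }
  switch(term$kind,
    BOND = pair_rows(a[1], a[2], forces[1, ]),
    ANGLE = {
      x <- fr$coords
      g <- angle_coord(x[a[1] + 1L, ], x[a[2] + 1L, ], x[a[3] + 1L, ],
                       fr$box)
      u <- g$rij / g$nij
      v <- g$rkj / g$nkj
      sint2 <- 1 - g$cost^2
      if (sqrt(max(0, sint2)) < 1e-6) {
        warning(warningCondition(
          "near-collinear angle: falling back to central decomposition",
          class = "pf_collinear_fallback"))
        rbind(pair_rows(a[1], a[2], forces[1, ]),
              pair_rows(a[3], a[2], forces[3, ]))
      } else {
        # solve alpha*u + beta*v = -F_j in the (u, v) plane
        fj <- forces[2, ]
        uv <- g$cost
        rhs1 <- -sum(fj * u)
        rhs2 <- -sum(fj * v)
        det <- 1 - uv^2
        alpha <- (rhs1 - uv * rhs2) / det
        beta <- (rhs2 - uv * rhs1) / det
        rbind(pair_rows(a[1], a[2], alpha * u),
              pair_rows(a[3], a[2], beta * v),
              pair_rows(a[1], a[3], forces[1, ] - alpha * u))
      }
    },
    DIHEDRAL_PERIODIC = ,
    IMPROPER_HARMONIC = {
      rbind(pair_rows(a[1], a[2], forces[1, ]),
            pair_rows(a[4], a[3], forces[4, ]),
            pair_rows(a[2], a[3], forces[1, ] + forces[2, ]))
    },
    CROSS_BOND_BOND = {
      rbind(pair_rows(a[1], a[2], forces[1, ]),
            pair_rows(a[3], a[2], forces[3, ]))
    },
    CROSS_BOND_ANGLE = {
      x <- fr$coords
      p <- term$params
      rij <- min_image(x[a[1] + 1L, ], x[a[2] + 1L, ], fr$box)
      rkj <- min_image(x[a[3] + 1L, ], x[a[2] + 1L, ], fr$box)
      rik <- min_image(x[a[1] + 1L, ], x[a[3] + 1L, ], fr$box)
      nij <- vec_norm(rij); nkj <- vec_norm(rkj); nik <- vec_norm(rik)
      s <- (nij - p$r1) + (nkj - p$r2)
      rbind(pair_rows(a[1], a[2], -p$krt * (nik - p$r3) * rij / nij),
            pair_rows(a[3], a[2], -p$krt * (nik - p$r3) * rkj / nkj),
            pair_rows(a[1], a[3], -p$krt * s * rik / nik))
    }
  )
}

#' Enumerate nonbonded pairs between two atom groups
#'
#' Lists every atom pair with one atom in each group (order-agnostic),
#' minimum-image distance within `cutoff` and not excluded, once per
#' interaction kind (LJ and COULOMB).  1-4 pairs carry the topology's fudge
#' factors as their scale; all other pairs have scale 1.  Pairs whose
#' interaction prefactor is identically zero (zero charge product, zero
#' combined epsilon) are omitted.
#'
#' @param fr a [frame()].
#' @param top a [topology()].
#' @param groups a [group_spec()].
#' @param cutoff cutoff distance (nm); must not exceed half the smallest
#'   box length when the frame is periodic.
#' @param check_halfbox set `FALSE` to skip the half-box sanity check
#'   (internal use).
#' @return data.frame with columns `i`, `j` (0-based, `i < j`), `kind`
#'   (`"LJ"` or `"COULOMB"`) and `scale`.
#' @export
build_pair_list <- function(fr, top, groups, cutoff,
                            check_halfbox = TRUE) {
  if (cutoff <= 0) stop_config("cutoff must be positive")
  if (check_halfbox && !is.null(fr$box) && cutoff > min(fr$box) / 2)
    stop_config(sprintf(
      "cutoff %g nm exceeds half the smallest box length (%g nm)",
      cutoff, min(fr$box) / 2))
  # candidate unordered cross-group pairs
  cand <- unique(rbind(
    expand.grid(i = groups$group1, j = groups$group2),
    expand.grid(i = groups$group2, j = groups$group1)))
  keep <- cand$i != cand$j
  cand <- cand[keep, , drop = FALSE]
  ii <- pmin(cand$i, cand$j)
  jj <- pmax(cand$i, cand$j)
  key <- ii * n_atoms(top) + jj
  dup <- duplicated(key)
  ii <- ii[!dup]; jj <- jj[!dup]; key <- key[!dup]
  if (!length(ii)) return(empty_pair_list())

  excl_key <- top$exclusions[, 1] * n_atoms(top) + top$exclusions[, 2]
  sel <- !(key %in% excl_key)
  ii <- ii[sel]; jj <- jj[sel]; key <- key[sel]
  if (!length(ii)) return(empty_pair_list())

  d <- fr$coords[ii + 1L, , drop = FALSE] - fr$coords[jj + 1L, , drop = FALSE]
  if (!is.null(fr$box))
    d <- d - rep(fr$box, each = nrow(d)) * round(d / rep(fr$box, each = nrow(d)))
  within <- rowSums(d * d) <= cutoff^2
  ii <- ii[within]; jj <- jj[within]; key <- key[within]
  if (!length(ii)) return(empty_pair_list())

  p14_key <- top$pairs14[, 1] * n_atoms(top) + top$pairs14[, 2]
  is14 <- key %in% p14_key

  q <- top$atoms$charge
  eps <- top$atoms$epsilon
  has_q <- q[ii + 1L] * q[jj + 1L] != 0
  has_lj <- eps[ii + 1L] * eps[jj + 1L] != 0
  out <- rbind(
    data.frame(i = ii[has_lj], j = jj[has_lj],
               kind = rep("LJ", sum(has_lj)),
               scale = ifelse(is14[has_lj], top$fudge_lj, 1)),
    data.frame(i = ii[has_q], j = jj[has_q],
               kind = rep("COULOMB", sum(has_q)),
               scale = ifelse(is14[has_q], top$fudge_qq, 1)))
  rownames(out) <- NULL
  out
}

empty_pair_list <- function() {
  data.frame(i = integer(0), j = integer(0), kind = character(0),
             scale = numeric(0))
}

#' Compute the pairwise-force store for one frame
#'
#' Evaluates every bonded term and every eligible nonbonded pair, decomposes
#' the forces into atom-pair contributions, applies the two-group selection
#' to each emitted pair, and accumulates the result into a per-frame store.
#' In `SUMMED` mode all contributions between two atoms collapse into one
#' vector; in `DETAILED` mode separate vectors are kept per interaction
#' type.  The store pertains to this frame only; memory does not grow with
#' trajectory length.
#'
#' @inheritParams build_pair_list
#' @param mode `"SUMMED"` or `"DETAILED"`.
#' @param itypes subset of `c("BOND","ANGLE","DIHEDRAL","LJ","COULOMB")` to
#'   include.
#' @return an object of class `pf_store`: a data.frame with columns `i`,
#'   `j` (`i < j`, 0-based), `fx`, `fy`, `fz` (force on `i` by `j`) and, in
#'   DETAILED mode, `itype`; attributes `mode` and `time`.
#' @export
compute_frame_pairwise <- function(fr, top, groups, cutoff = 1.0,
                                   mode = c("SUMMED", "DETAILED"),
                                   itypes = ITYPES) {
  mode <- match.arg(mode)
  itypes <- match.arg(itypes, ITYPES, several.ok = TRUE)
  check_frame_atoms(fr, top)
  chunks <- list()
  for (term in top$terms) {
    if (!(term_itype(term$kind) %in% itypes)) next
    ev <- eval_bonded_term(term, fr)
    pw <- decompose_bonded(term, fr, ev$forces)
    keep <- in_cross_group(pw$i, pw$j, groups)
    if (any(keep)) chunks[[length(chunks) + 1L]] <- pw[keep, , drop = FALSE]
  }
  if (any(c("LJ", "COULOMB") %in% itypes)) {
    pl <- build_pair_list(fr, top, groups, cutoff)
    pl <- pl[pl$kind %in% itypes, , drop = FALSE]
    if (nrow(pl)) {
      vs <- matrix(0, nrow(pl), 3)
      for (r in seq_len(nrow(pl))) {
        vs[r, ] <- eval_nonbonded_pair(pl$i[r], pl$j[r], fr, top,
                                       pl$kind[r], pl$scale[r])$force_i
      }
      chunks[[length(chunks) + 1L]] <-
        data.frame(i = pl$i, j = pl$j, fx = vs[, 1], fy = vs[, 2],
                   fz = vs[, 3], itype = pl$kind,
                   stringsAsFactors = FALSE)
    }
  }
  raw <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(i = integer(0), j = integer(0), fx = numeric(0),
               fy = numeric(0), fz = numeric(0), itype = character(0))
  # canonicalise: store under (min id, max id), vector as force on lower id
  flip <- raw$i > raw$j
  if (any(flip)) {
    tmp <- raw$i[flip]; raw$i[flip] <- raw$j[flip]; raw$j[flip] <- tmp
    raw$fx[flip] <- -raw$fx[flip]
    raw$fy[flip] <- -raw$fy[flip]
    raw$fz[flip] <- -raw$fz[flip]
  }
  keycols <- if (mode == "DETAILED") list(raw$i, raw$j, raw$itype)
             else list(raw$i, raw$j)
  if (nrow(raw)) {
    agg <- aggregate(raw[c("fx", "fy", "fz")], by = keycols, FUN = sum)
    names(agg)[seq_along(keycols)] <-
      if (mode == "DETAILED") c("i", "j", "itype") else c("i", "j")
    agg <- agg[order(agg$i, agg$j), , drop = FALSE]
    if (mode == "DETAILED")
      agg <- agg[c("i", "j", "fx", "fy", "fz", "itype")]
    rownames(agg) <- NULL
  } else {
    agg <- raw[if (mode == "DETAILED")
                 c("i", "j", "fx", "fy", "fz", "itype")
               else c("i", "j", "fx", "fy", "fz")]
  }
  structure(agg, class = c("pf_store", "data.frame"),
            mode = mode, time = fr$time)
}

#' Collapse a DETAILED store to SUMMED
#'
#' Sums the per-interaction-type vectors of each pair into one vector per
#' pair; a SUMMED store is returned unchanged.
#'
#' @param store a `pf_store`.
#' @return a SUMMED `pf_store`.
#' @export
collapse_store <- function(store) {
  if (is.null(store$itype)) return(store)
  if (nrow(store)) {
    agg <- aggregate(store[c("fx", "fy", "fz")],
                     by = list(i = store$i, j = store$j), FUN = sum)
    agg <- agg[order(agg$i, agg$j), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(i = integer(0), j = integer(0), fx = numeric(0),
                      fy = numeric(0), fz = numeric(0))
  }
  structure(agg, class = c("pf_store", "data.frame"),
            mode = "SUMMED", time = attr(store, "time"))
}

#' Look up the pairwise force on atom `i` from atom `j`
#'
#' Antisymmetric query on a store: `pair_force(s, j, i)` is the exact
#' negation of `pair_force(s, i, j)`.  In DETAILED mode the per-itype
#' vectors are summed.
#'
#' @param store a `pf_store` from [compute_frame_pairwise()].
#' @param i,j 0-based atom ids.
#' @return numeric 3-vector (zero if the pair is absent).
#' @export
pair_force <- function(store, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  rows <- store$i == lo & store$j == hi
  v <- c(sum(store$fx[rows]), sum(store$fy[rows]), sum(store$fz[rows]))
  if (i > j) -v else v
}

#' @export
print.pf_store <- function(x, ...) {
  cat(sprintf("<pf_store> %s, t = %g ps, %d pair entries\n",
              attr(x, "mode"), attr(x, "time"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
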