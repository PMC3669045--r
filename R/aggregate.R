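# Derived observables: signed scalar pairwise forces, residue-residue
# pairwise forces, punctual stress and per-entity summaries.
#
# Sign convention for scalars: the angle between the pairwise force on i
# and the separation vector from i toward j decides the sign.  A force
# pointing toward the partner (angle within (-pi/2, pi/2)) is attractive
# and carries a minus sign; pointing away is repulsive, plus sign; an
# exactly perpendicular force is neither and scalarizes to zero.

#' Scalarize pairwise force vectors
#'
#' Converts each vector pairwise force of a store into a signed scalar:
#' in `NORM` mode the magnitude of the vector, in `PROJECTED` mode the
#' magnitude of its projection onto the separation vector, in both cases
#' signed minus for attractive and plus for repulsive.  The perpendicular
#' case is decided with tolerance `|v . dhat| <= 1e-12 ||v||`.
#'
#' @param store a `pf_store` from [compute_frame_pairwise()], or any
#'   data.frame with columns `i`, `j`, `fx`, `fy`, `fz` (and optionally
#'   `itype`).
#' @param fr the [frame()] the store was computed from.
#' @param top the [topology()].
#' @param mode `"NORM"` or `"PROJECTED"`.
#' @param level `"ATOM"` scalarizes atom pairs using the minimum-image atom
#'   separation; `"RESIDUE"` first aggregates to residue pairs (Eq. of
#'   [residue_pairwise()]) and uses the residue center-of-mass separation.
#' @return an object of class `pf_scalars`: data.frame with columns `i`,
#'   `j`, `value` (signed, kJ mol^-1 nm^-1) and, if present in the input,
#'   `itype`; attributes `mode`, `level`, `time`.
#' @export
scalarize <- function(store, fr, top, mode = c("NORM", "PROJECTED"),
                      level = c("ATOM", "RESIDUE")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (level == "RESIDUE") {
    pos <- residue_com(top, fr)
    store <- residue_pairwise(store, top)
    box <- NULL  # COM separations are not minimum-imaged
  } else {
    pos <- fr$coords
    box <- fr$box
  }
  n <- nrow(store)
  value <- numeric(n)
  for (r in seq_len(n)) {
    v <- c(store$fx[r], store$fy[r], store$fz[r])
    d <- min_image(pos[store$j[r] + 1L, ], pos[store$i[r] + 1L, ], box)
    nd <- vec_norm(d)
    if (nd == 0) stop_degenerate("zero separation while scalarizing")
    nv <- vec_norm(v)
    dot <- sum(v * d) / nd
    if (abs(dot) <= 1e-12 * nv) {
      value[r] <- 0
    } else {
      s <- if (dot > 0) -1 else 1  # toward partner = attractive = minus
      value[r] <- s * if (mode == "NORM") nv else abs(dot)
    }
  }
  out <- data.frame(i = store$i, j = store$j, value = value,
                    stringsAsFactors = FALSE)
  if (!is.null(store$itype)) out$itype <- store$itype
  structure(out, class = c("pf_scalars", "data.frame"),
            mode = mode, level = level, time = attr(store, "time"))
}

#' Aggregate atomic pairwise forces to residue pairs
#'
#' The pairwise force between residues ri and rj is the vector sum of the
#' atomic pairwise forces between their member atoms, acting on the residue
#' centers of mass; atom pairs within one residue contribute to no residue
#' pair.  Residue-level antisymmetry is inherited from the atomic level.
#'
#' @param store a `pf_store` (any mode).
#' @param top the [topology()].
#' @return data.frame of class `pf_store` at residue level: columns `i`,
#'   `j` (0-based residue ids, `i < j`), `fx`, `fy`, `fz` (force on
#'   residue `i` by residue `j`).
#' @export
residue_pairwise <- function(store, top) {
  resid <- top$atoms$resid
  ri <- resid[store$i + 1L]
  rj <- resid[store$j + 1L]
  keep <- ri != rj
  ri <- ri[keep]; rj <- rj[keep]
  fx <- store$fx[keep]; fy <- store$fy[keep]; fz <- store$fz[keep]
  flip <- ri > rj
  if (any(flip)) {
    tmp <- ri[flip]; ri[flip] <- rj[flip]; rj[flip] <- tmp
    fx[flip] <- -fx[flip]; fy[flip] <- -fy[flip]; fz[flip] <- -fz[flip]
  }
  if (length(ri)) {
    agg <- aggregate(data.frame(fx = fx, fy = fy, fz = fz),
                     by = list(i = ri, j = rj), FUN = sum)
    agg <- agg[order(agg$i, agg$j), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(i = integer(0), j = integer(0), fx = numeric(0),
                      fy = numeric(0), fz = numeric(0))
  }
  structure(agg, class = c("pf_store", "data.frame"),
            mode = attr(store, "mode"), time = attr(store, "time"),
            level = "RESIDUE")
}

#' Punctual stress
#'
#' The punctual stress on entity i is the sum over its partners j of the
#' absolute scalar pairwise forces |F_ji|.  It has units of force
#' (kJ mol^-1 nm^-1) and is non-negative; entities with no pairs get 0.
#'
#' @param scalars a `pf_scalars` object from [scalarize()] (one frame, one
#'   mode).
#' @param n_entities total number of atoms (level ATOM) or residues (level
#'   RESIDUE), so that isolated entities are reported with stress 0.
#' @return data.frame of class `pf_stress`: columns `id` (0-based) and
#'   `stress`; attributes `level`, `mode`, `time`.
#' @export
punctual_stress <- function(scalars, n_entities) {
  s <- numeric(n_entities)
  av <- abs(scalars$value)
  for (r in seq_len(nrow(scalars))) {
    s[scalars$i[r] + 1L] <- s[scalars$i[r] + 1L] + av[r]
    s[scalars$j[r] + 1L] <- s[scalars$j[r] + 1L] + av[r]
  }
  structure(data.frame(id = 0:(n_entities - 1L), stress = s),
            class = c("pf_stress", "data.frame"),
            level = attr(scalars, "level"), mode = attr(scalars, "mode"),
            time = attr(scalars, "time"))
}

#' Per-entity summary of absolute scalar pairwise forces
#'
#' For every atom (or residue) reports the sum, average, minimum and
#' maximum of the absolute scalar pairwise forces acting on it, plus the
#' pair count.  The sum equals the punctual stress.  Entities with no
#' pairs report 0 for every field.
#'
#' @inheritParams punctual_stress
#' @return data.frame of class `pf_summary`: columns `id`, `sum`, `avg`,
#'   `min`, `max`, `count`.
#' @export
per_atom_summary <- function(scalars, n_entities) {
  sum_ <- numeric(n_entities)
  min_ <- rep(Inf, n_entities)
  max_ <- numeric(n_entities)
  cnt <- integer(n_entities)
  av <- abs(scalars$value)
  for (r in seq_len(nrow(scalars))) {
    for (id in c(scalars$i[r], scalars$j[r])) {
      k <- id + 1L
      sum_[k] <- sum_[k] + av[r]
      min_[k] <- min(min_[k], av[r])
      max_[k] <- max(max_[k], av[r])
      cnt[k] <- cnt[k] + 1L
    }
  }
  avg <- ifelse(cnt > 0, sum_ / cnt, 0)
  min_[cnt == 0] <- 0
  structure(data.frame(id = 0:(n_entities - 1L), sum = sum_, avg = avg,
                       min = min_, max = max_, count = cnt),
            class = c("pf_summary", "data.frame"),
            level = attr(scalars, "level"), mode = attr(scalars, "mode"),
            time = attr(scalars, "time"))
}
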