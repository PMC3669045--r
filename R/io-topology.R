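# Flat-text topology format, sectioned in the style of GROMACS itp files.
# Grammar (one record per line, '#'/';' comments, blank lines ignored):
#
#   [ defaults ]        fudge_lj <x>; fudge_qq <x>        (optional, default 1)
#   [ atoms ]           <id> <name> <resid> <mass> <charge> <sigma> <epsilon>
#   [ residues ]        <id> <name>                       (optional names)
#   [ bonds ]           <i> <j> <k> <b0>
#   [ angles ]          <i> <j> <k> <ktheta> <theta0_deg>       (j central)
#   [ dihedrals ]       <i> <j> <k> <l> <k> <phis_deg> <n>
#   [ impropers ]       <i> <j> <k> <l> <k> <xi0_deg>
#   [ cross_bb ]        <i> <j> <k> <krr> <r1> <r2>             (j central)
#   [ cross_ba ]        <i> <j> <k> <krt> <r1> <r2> <r3>        (j central)
#   [ exclusions ]      <i> <j>
#   [ pairs14 ]         <i> <j>
#
# Atom and residue ids are 0-based.  Angles are degrees in the file and
# radians in memory.  Lengths nm, energies kJ/mol.

stop_parse <- function(path, lineno, msg) {
  stop(errorCondition(
    sprintf("%s:%d: %s", path, lineno, msg),
    class = c("pf_parse_error", "pf_error")))
}

#' Read a topology file
#'
#' Parses the package's flat-text topology format (see the format grammar
#' in the source header and the package vignette) and returns a validated
#' [topology()].  Errors name the offending line.
#'
#' @param path file path.
#' @return a `pf_topology`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("topology file not found: ", path),
                        class = c("pf_parse_error", "pf_error")))
  lines <- readLines(path, warn = FALSE)
  section <- ""
  defaults <- list(fudge_lj = 1, fudge_qq = 1)
  at <- list(); resnames_raw <- list()
  terms <- list()
  excl <- list(); p14 <- list()
  seen_excl <- character(0)

  for (ln in seq_along(lines)) {
    raw <- sub("[#;].*$", "", lines[ln])
    raw <- trimws(raw)
    if (raw == "") next
    if (grepl("^\\[", raw)) {
      section <- trimws(gsub("\\[|\\]", "", raw))
      ok <- c("defaults", "atoms", "residues", "bonds", "angles",
              "dihedrals", "impropers", "cross_bb", "cross_ba",
              "exclusions", "pairs14")
      if (!(section %in% ok))
        stop_parse(path, ln, paste0("unknown section: ", section))
      next
    }
    tok <- strsplit(raw, "[[:space:]]+")[[1]]
    num <- function(k) {
      v <- suppressWarnings(as.numeric(tok[k]))
      if (any(is.na(v))) stop_parse(path, ln, "malformed numeric field")
      v
    }
    need <- function(n) {
      if (length(tok) != n)
        stop_parse(path, ln, sprintf("expected %d fields in [%s], got %d",
                                     n, section, length(tok)))
    }
    switch(section,
      defaults = {
        need(2)
        if (!(tok[1] %in% c("fudge_lj", "fudge_qq")))
          stop_parse(path, ln, paste0("unknown default: ", tok[1]))
        defaults[[tok[1]]] <- num(2)
      },
      atoms = {
        need(7)
        id <- as.integer(num(1))
        if (id != length(at))
          stop_parse(path, ln, sprintf(
            "atom ids must be consecutive from 0; expected %d, got %d",
            length(at), id))
        at[[id + 1L]] <- data.frame(
          name = tok[2], resid = as.integer(num(3)), mass = num(4),
          charge = num(5), sigma = num(6), epsilon = num(7),
          stringsAsFactors = FALSE)
      },
      residues = {
        need(2)
        resnames_raw[[as.character(as.integer(num(1)))]] <- tok[2]
      },
      bonds = {
        need(4)
        terms[[length(terms) + 1L]] <- bonded_term(
          "BOND", num(1:2), list(k = num(3), b0 = num(4)))
      },
      angles = {
        need(5)
        terms[[length(terms) + 1L]] <- bonded_term(
          "ANGLE", num(1:3),
          list(k = num(4), theta0 = num(5) * pi / 180))
      },
      dihedrals = {
        need(7)
        terms[[length(terms) + 1L]] <- bonded_term(
          "DIHEDRAL_PERIODIC", num(1:4),
          list(k = num(5), phis = num(6) * pi / 180, n = num(7)))
      },
      impropers = {
        need(6)
        terms[[length(terms) + 1L]] <- bonded_term(
          "IMPROPER_HARMONIC", num(1:4),
          list(k = num(5), xi0 = num(6) * pi / 180))
      },
      cross_bb = {
        need(6)
        terms[[length(terms) + 1L]] <- bonded_term(
          "CROSS_BOND_BOND", num(1:3),
          list(krr = num(4), r1 = num(5), r2 = num(6)))
      },
      cross_ba = {
        need(7)
        terms[[length(terms) + 1L]] <- bonded_term(
          "CROSS_BOND_ANGLE", num(1:3),
          list(krt = num(4), r1 = num(5), r2 = num(6), r3 = num(7)))
      },
      exclusions = {
        need(2)
        key <- paste(sort(as.integer(num(1:2))), collapse = " ")
        if (key %in% seen_excl)
          stop_parse(path, ln, paste0("duplicate exclusion pair ", key))
        seen_excl <- c(seen_excl, key)
        excl[[length(excl) + 1L]] <- as.integer(num(1:2))
      },
      pairs14 = {
        need(2)
        p14[[length(p14) + 1L]] <- as.integer(num(1:2))
      },
      stop_parse(path, ln, "record outside any section")
    )
  }
  if (!length(at)) stop_parse(path, length(lines), "no [ atoms ] section")
  atoms <- do.call(rbind, at)
  nres <- max(atoms$resid) + 1L
  resnames <- paste0("RES", 0:(nres - 1L))
  for (k in names(resnames_raw)) {
    id <- as.integer(k)
    if (id < 0 || id >= nres)
      stop_parse(path, 0L, sprintf("residue id %d out of range", id))
    resnames[id + 1L] <- resnames_raw[[k]]
  }
  tryCatch(
    topology(atoms, resnames = resnames, terms = terms,
             exclusions = if (length(excl)) do.call(rbind, excl),
             pairs14 = if (length(p14)) do.call(rbind, p14),
             fudge_lj = defaults$fudge_lj, fudge_qq = defaults$fudge_qq),
    pf_config_error = function(e)
      stop(errorCondition(paste0(path, ": ", conditionMessage(e)),
                          class = c("pf_parse_error", "pf_error"))))
}

#' Write a topology file
#'
#' Emits the canonical form of the flat-text topology format;
#' `write_topology()` then [read_topology()] round-trips to an equivalent
#' topology, and re-writing reproduces the same bytes.
#'
#' @param top a `pf_topology`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  fnum <- function(x) sprintf("%.10g", x)
  out <- c("# pairforce topology v1",
           "[ defaults ]",
           paste("fudge_lj", fnum(top$fudge_lj)),
           paste("fudge_qq", fnum(top$fudge_qq)),
           "[ atoms ]",
           "; id name resid mass charge sigma epsilon")
  a <- top$atoms
  out <- c(out, sprintf("%d %s %d %s %s %s %s",
                        0:(nrow(a) - 1L), a$name, a$resid, fnum(a$mass),
                        fnum(a$charge), fnum(a$sigma), fnum(a$epsilon)))
  out <- c(out, "[ residues ]",
           sprintf("%d %s", 0:(n_residues(top) - 1L), top$resnames))
  sect <- function(kind, header, fmt) {
    sel <- Filter(function(t) t$kind == kind, top$terms)
    if (!length(sel)) return(character(0))
    c(header, vapply(sel, fmt, ""))
  }
  out <- c(out,
    sect("BOND", "[ bonds ]", function(t)
      sprintf("%d %d %s %s", t$atoms[1], t$atoms[2],
              fnum(t$params$k), fnum(t$params$b0))),
    sect("ANGLE", "[ angles ]", function(t)
      sprintf("%d %d %d %s %s", t$atoms[1], t$atoms[2], t$atoms[3],
              fnum(t$params$k), fnum(t$params$theta0 * 180 / pi))),
    sect("DIHEDRAL_PERIODIC", "[ dihedrals ]", function(t)
      sprintf("%d %d %d %d %s %s %d", t$atoms[1], t$atoms[2], t$atoms[3],
              t$atoms[4], fnum(t$params$k),
              fnum(t$params$phis * 180 / pi), as.integer(t$params$n))),
    sect("IMPROPER_HARMONIC", "[ impropers ]", function(t)
      sprintf("%d %d %d %d %s %s", t$atoms[1], t$atoms[2], t$atoms[3],
              t$atoms[4], fnum(t$params$k), fnum(t$params$xi0 * 180 / pi))),
    sect("CROSS_BOND_BOND", "[ cross_bb ]", function(t)
      sprintf("%d %d %d %s %s %s", t$atoms[1], t$atoms[2], t$atoms[3],
              fnum(t$params$krr), fnum(t$params$r1), fnum(t$params$r2))),
    sect("CROSS_BOND_ANGLE", "[ cross_ba ]", function(t)
      sprintf("%d %d %d %s %s %s %s", t$atoms[1], t$atoms[2], t$atoms[3],
              fnum(t$params$krt), fnum(t$params$r1), fnum(t$params$r2),
              fnum(t$params$r3))))
  if (nrow(top$exclusions))
    out <- c(out, "[ exclusions ]",
             sprintf("%d %d", top$exclusions[, 1], top$exclusions[, 2]))
  if (nrow(top$pairs14))
    out <- c(out, "[ pairs14 ]",
             sprintf("%d %d", top$pairs14[, 1], top$pairs14[, 2]))
  writeLines(out, path)
  invisible(path)
}
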