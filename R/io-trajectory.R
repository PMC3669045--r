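# Trajectory readers (multi-frame GRO, XYZ) and a GRO writer.  GRO
# coordinates are nm in fixed columns; XYZ coordinates are Angstrom and
# converted to nm on read.  Frames are streamed one at a time so memory
# does not depend on trajectory length.

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("pf_format_error", "pf_error")))
}

#' Open a trajectory for streaming
#'
#' Returns an iterator: a function that yields the next [frame()] on each
#' call and `NULL` past the end.  The format is chosen from the file
#' extension (`.gro` or `.xyz`) unless given explicitly.
#'
#' A GRO box line of three zeros denotes a non-periodic system (`box =
#' NULL`); XYZ frames are always non-periodic.
#'
#' @param path trajectory file path.
#' @param format `"gro"`, `"xyz"` or `"auto"`.
#' @return a function `f()` yielding `pf_frame` or `NULL`; call
#'   `f(close = TRUE)` to release the file early.
#' @export
trajectory_reader <- function(path, format = c("auto", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "gro"
  }
  con <- file(path, "rt")
  idx <- 0L
  done <- FALSE
  finish <- function() {
    if (!done) close(con)
    done <<- TRUE
    NULL
  }
  function(close = FALSE) {
    if (close || done) return(finish())
    idx <<- idx + 1L
    fr <- tryCatch(
      if (format == "gro") read_gro_frame(con, idx)
      else read_xyz_frame(con, idx),
      pf_format_error = function(e) { finish(); stop(e) })
    if (is.null(fr)) finish() else fr
  }
}

#' Read all frames of a trajectory into memory
#'
#' Convenience wrapper around [trajectory_reader()] for small files.
#'
#' @inheritParams trajectory_reader
#' @return list of [frame()] objects.
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "xyz")) {
  rd <- trajectory_reader(path, format)
  frames <- list()
  repeat {
    fr <- rd()
    if (is.null(fr)) break
    frames[[length(frames) + 1L]] <- fr
  }
  frames
}

read_gro_frame <- function(con, idx) {
  title <- readLines(con, n = 1)
  if (!length(title)) return(NULL)
  nl <- readLines(con, n = 1)
  n <- suppressWarnings(as.integer(trimws(nl)))
  if (!length(nl) || is.na(n) || n <= 0)
    stop_format(sprintf("GRO frame %d: bad atom-count line", idx))
  body <- readLines(con, n = n + 1L)
  if (length(body) < n + 1L)
    stop_format(sprintf("GRO frame %d: truncated (expected %d atom lines + box)",
                        idx, n))
  coords <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    ln <- body[a]
    if (nchar(ln) < 44)
      stop_format(sprintf("GRO frame %d: atom line %d too short", idx, a))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
    if (any(is.na(xyz)))
      stop_format(sprintf("GRO frame %d: malformed coordinates on atom line %d",
                          idx, a))
    coords[a, ] <- xyz
  }
  bx <- suppressWarnings(as.numeric(strsplit(trimws(body[n + 1L]),
                                             "[[:space:]]+")[[1]]))
  if (length(bx) < 3 || any(is.na(bx[1:3])))
    stop_format(sprintf("GRO frame %d: malformed box line", idx))
  box <- if (all(bx[1:3] == 0)) NULL else bx[1:3]
  time <- 0
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  frame(coords, time = time, box = box)
}

read_xyz_frame <- function(con, idx) {
  nl <- readLines(con, n = 1)
  if (!length(nl) || trimws(nl) == "") return(NULL)
  n <- suppressWarnings(as.integer(trimws(nl)))
  if (is.na(n) || n <= 0)
    stop_format(sprintf("XYZ frame %d: bad atom-count line", idx))
  body <- readLines(con, n = n + 1L)
  if (length(body) < n + 1L)
    stop_format(sprintf("XYZ frame %d: truncated (expected comment + %d atom lines)",
                        idx, n))
  comment <- body[1]
  coords <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    tok <- strsplit(trimws(body[a + 1L]), "[[:space:]]+")[[1]]
    if (length(tok) < 4)
      stop_format(sprintf("XYZ frame %d: malformed atom line %d", idx, a))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop_format(sprintf("XYZ frame %d: malformed coordinates on atom line %d",
                          idx, a))
    coords[a, ] <- xyz / 10  # Angstrom -> nm
  }
  time <- 0
  tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  frame(coords, time = time, box = NULL)
}

#' Write frames as a multi-frame GRO file
#'
#' @param frames a [frame()] or list of frames.
#' @param top the [topology()] supplying atom and residue names.
#' @param path destination path.
#' @param append append to an existing file instead of truncating.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, top, path, append = FALSE) {
  if (inherits(frames, "pf_frame")) frames <- list(frames)
  con <- file(path, if (append) "at" else "wt")
  on.exit(close(con))
  a <- top$atoms
  resname <- top$resnames[a$resid + 1L]
  for (fr in frames) {
    check_frame_atoms(fr, top)
    n <- nrow(fr$coords)
    writeLines(sprintf("pairforce toy system, t= %.6f", fr$time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       (a$resid %% 100000L) + 1L, substr(resname, 1, 5),
                       substr(a$name, 1, 5), (seq_len(n) - 1L) %% 100000L + 1L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    box <- if (is.null(fr$box)) c(0, 0, 0) else fr$box
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

#' Read two atom groups from a GROMACS NDX index file
#'
#' NDX files list 1-based atom numbers under `[ name ]` headers; the
#' returned [group_spec()] uses the package's 0-based ids.
#'
#' @param path NDX file path.
#' @param name1,name2 group names to select (may be the same name).
#' @param n_atoms total atom count for range validation (optional).
#' @return a [group_spec()].
#' @export
read_index_groups <- function(path, name1, name2, n_atoms = NULL) {
  lines <- readLines(path, warn = FALSE)
  groups <- list()
  current <- NULL
  for (ln in seq_along(lines)) {
    raw <- sub(";.*$", "", lines[ln])
    raw <- trimws(raw)
    if (raw == "") next
    if (grepl("^\\[", raw)) {
      current <- trimws(gsub("\\[|\\]", "", raw))
      if (is.null(groups[[current]])) groups[[current]] <- integer(0)
      next
    }
    if (is.null(current))
      stop_parse(path, ln, "atom numbers before any [ group ] header")
    ids <- suppressWarnings(as.integer(strsplit(raw, "[[:space:]]+")[[1]]))
    if (any(is.na(ids)))
      stop_parse(path, ln, "malformed atom number")
    if (any(ids < 1))
      stop_parse(path, ln, "NDX atom numbers are 1-based; got id < 1")
    groups[[current]] <- c(groups[[current]], ids)
  }
  pick <- function(nm) {
    if (is.null(groups[[nm]]))
      stop_config(sprintf("index group '%s' not found in %s (have: %s)",
                          nm, path, paste(names(groups), collapse = ", ")))
    ids <- groups[[nm]] - 1L  # to 0-based
    if (!is.null(n_atoms) && any(ids >= n_atoms))
      stop_config(sprintf("index group '%s' references atom %d of %d",
                          nm, max(ids) + 1L, n_atoms))
    ids
  }
  group_spec(pick(name1), pick(name2))
}
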