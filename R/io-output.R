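# Streaming per-frame writers for the package's text time-series dialect,
# plus a reader used for round-trip verification.
#
# File layout: comment header naming format version, content, level and
# mode; then one block per frame:
#
#   frame <index> time <ps>
#   <record> ...
#
# Records by content ('itype' column only in DETAILED mode):
#   PAIR_VECTOR:  <i> <j> <fx> <fy> <fz> [<itype>]
#   PAIR_SCALAR:  <i> <j> <value> [<itype>]
#   STRESS:       <id> <stress>
#   SUMMARY:      <id> <sum> <avg> <min> <max> <count>
#
# All ids 0-based; numeric fields formatted %.6e.

OUTPUT_WHAT <- c("PAIR_VECTOR", "PAIR_SCALAR", "STRESS", "SUMMARY")

#' Describe one output stream
#'
#' @param what `"PAIR_VECTOR"`, `"PAIR_SCALAR"`, `"STRESS"` or `"SUMMARY"`.
#' @param level `"ATOM"` or `"RESIDUE"`.
#' @param mode `"SUMMED"` or `"DETAILED"`; DETAILED is only meaningful for
#'   pair outputs (stress and summaries are computed from summed vectors).
#' @param scalar_mode `"NORM"` or `"PROJECTED"` (scalar-valued outputs).
#' @param path destination file path.
#' @return an object of class `pf_output_spec`.
#' @export
output_spec <- function(what, level = "ATOM", mode = "SUMMED",
                        scalar_mode = "NORM", path) {
  what <- match.arg(what, OUTPUT_WHAT)
  level <- match.arg(level, c("ATOM", "RESIDUE"))
  mode <- match.arg(mode, c("SUMMED", "DETAILED"))
  scalar_mode <- match.arg(scalar_mode, c("NORM", "PROJECTED"))
  if (mode == "DETAILED" && !(what %in% c("PAIR_VECTOR", "PAIR_SCALAR")))
    stop_config("DETAILED mode is only valid for pair outputs")
  structure(list(what = what, level = level, mode = mode,
                 scalar_mode = scalar_mode, path = path),
            class = "pf_output_spec")
}

#' Open an output stream
#'
#' Writes the file header and returns a sink object for
#' [write_frame_output()].  The stream appends one block per frame;
#' nothing is buffered across frames.
#'
#' @param spec an [output_spec()].
#' @return an environment of class `pf_output` (fields `spec`, `con`,
#'   `nframes`).
#' @export
open_output <- function(spec) {
  con <- file(spec$path, "wt")
  writeLines(c("# pairforce output v1",
               sprintf("# what %s level %s mode %s scalar %s",
                       spec$what, spec$level, spec$mode, spec$scalar_mode),
               "# ids 0-based; forces kJ/mol/nm; time ps"), con)
  out <- new.env(parent = emptyenv())
  out$spec <- spec
  out$con <- con
  out$nframes <- 0L
  class(out) <- "pf_output"
  out
}

#' Append one frame block to an output stream
#'
#' @param out a `pf_output` from [open_output()].
#' @param data the frame's data: a `pf_store` (PAIR_VECTOR), `pf_scalars`
#'   (PAIR_SCALAR), `pf_stress` (STRESS) or `pf_summary` (SUMMARY).
#' @param frame_index 0-based frame index.
#' @param time frame time (ps).
#' @return `out`, invisibly.
#' @export
write_frame_output <- function(out, data, frame_index, time) {
  spec <- out$spec
  e <- function(x) sprintf("%.6e", x)
  lines <- switch(spec$what,
    PAIR_VECTOR = {
      if (spec$mode == "DETAILED")
        sprintf("%d %d %s %s %s %s", data$i, data$j, e(data$fx),
                e(data$fy), e(data$fz), data$itype)
      else
        sprintf("%d %d %s %s %s", data$i, data$j, e(data$fx),
                e(data$fy), e(data$fz))
    },
    PAIR_SCALAR = {
      if (spec$mode == "DETAILED" && !is.null(data$itype))
        sprintf("%d %d %s %s", data$i, data$j, e(data$value), data$itype)
      else
        sprintf("%d %d %s", data$i, data$j, e(data$value))
    },
    STRESS = sprintf("%d %s", data$id, e(data$stress)),
    SUMMARY = sprintf("%d %s %s %s %s %d", data$id, e(data$sum),
                      e(data$avg), e(data$min), e(data$max), data$count))
  writeLines(c(sprintf("frame %d time %s", frame_index, e(time)), lines),
             out$con)
  out$nframes <- out$nframes + 1L
  invisible(out)
}

#' Close an output stream
#'
#' @param out a `pf_output`.
#' @return number of frame blocks written, invisibly.
#' @export
close_output <- function(out) {
  close(out$con)
  invisible(out$nframes)
}

#' Parse a written output file back into memory
#'
#' Inverse of the writers, used for round-trip checks and downstream
#' time-series analysis.
#'
#' @param path output file path.
#' @return list with `header` (named fields from the comment header) and
#'   `blocks`, a list of `list(index, time, records)` per frame.
#' @export
read_output_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  for (k in seq_along(lines)) {
    g <- regmatches(lines[k],
                    regexec("^# what (\\S+) level (\\S+) mode (\\S+) scalar (\\S+)",
                            lines[k]))[[1]]
    if (length(g) == 5) {
      hdr <- list(what = g[2], level = g[3], mode = g[4], scalar = g[5])
      break
    }
  }
  if (!length(hdr)) stop_format(paste0(path, ": missing format header"))
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  }
  for (ln in lines) {
    if (startsWith(ln, "#") || trimws(ln) == "") next
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (tok[1] == "frame") {
      flush()
      cur <- list(index = as.integer(tok[2]), time = as.numeric(tok[4]),
                  records = list())
      next
    }
    if (is.null(cur)) stop_format(paste0(path, ": record before any frame"))
    cur$records[[length(cur$records) + 1L]] <- tok
  }
  flush()
  parse_records <- function(b) {
    if (!length(b$records)) {
      b$records <- data.frame()
      return(b)
    }
    mat <- do.call(rbind, b$records)
    df <- switch(hdr$what,
      PAIR_VECTOR = {
        d <- data.frame(i = as.integer(mat[, 1]), j = as.integer(mat[, 2]),
                        fx = as.numeric(mat[, 3]), fy = as.numeric(mat[, 4]),
                        fz = as.numeric(mat[, 5]))
        if (ncol(mat) >= 6) d$itype <- mat[, 6]
        d
      },
      PAIR_SCALAR = {
        d <- data.frame(i = as.integer(mat[, 1]), j = as.integer(mat[, 2]),
                        value = as.numeric(mat[, 3]))
        if (ncol(mat) >= 4) d$itype <- mat[, 4]
        d
      },
      STRESS = data.frame(id = as.integer(mat[, 1]),
                          stress = as.numeric(mat[, 2])),
      SUMMARY = data.frame(id = as.integer(mat[, 1]),
                           sum = as.numeric(mat[, 2]),
                           avg = as.numeric(mat[, 3]),
                           min = as.numeric(mat[, 4]),
                           max = as.numeric(mat[, 5]),
                           count = as.integer(mat[, 6])))
    b$records <- df
    b
  }
  list(header = hdr, blocks = lapply(blocks, parse_records))
}
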