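# The streaming rerun: read topology + groups, iterate trajectory frames,
# compute the per-frame pairwise store, aggregate, append outputs.

#' Configuration for a rerun
#'
#' @param topology path to a topology file ([read_topology()] format).
#' @param trajectory path to a multi-frame GRO or XYZ trajectory.
#' @param index path to a GROMACS NDX file, or `NULL` to use all atoms for
#'   both groups.
#' @param groups character vector of the two group names in the NDX file
#'   (one name selects the same group twice).
#' @param cutoff nonbonded cutoff (nm), default 1.0.
#' @param mode `"SUMMED"` or `"DETAILED"` pairwise accumulation.
#' @param scalar_mode `"NORM"` or `"PROJECTED"` scalarization.
#' @param level `"ATOM"`, `"RESIDUE"` or `"BOTH"`.
#' @param itypes interaction classes to include, subset of
#'   `c("BOND","ANGLE","DIHEDRAL","LJ","COULOMB")`.
#' @param out_pairs,out_scalars,out_stress,out_summary output paths (`NULL`
#'   disables an output).  With `level = "BOTH"` each path gets `.atom` /
#'   `.residue` inserted before its extension.
#' @param verbose log per-frame progress to stderr.
#' @return an object of class `pf_run_config`.
#' @export
run_config <- function(topology, trajectory, index = NULL,
                       groups = c("all", "all"), cutoff = 1.0,
                       mode = "SUMMED", scalar_mode = "NORM",
                       level = "ATOM", itypes = ITYPES,
                       out_pairs = NULL, out_scalars = NULL,
                       out_stress = NULL, out_summary = NULL,
                       verbose = FALSE) {
  mode <- match.arg(mode, c("SUMMED", "DETAILED"))
  scalar_mode <- match.arg(scalar_mode, c("NORM", "PROJECTED"))
  level <- match.arg(level, c("ATOM", "RESIDUE", "BOTH"))
  itypes <- match.arg(itypes, ITYPES, several.ok = TRUE)
  if (cutoff <= 0) stop_config("cutoff must be positive")
  if (length(groups) == 1) groups <- c(groups, groups)
  outs <- list(pairs = out_pairs, scalars = out_scalars,
               stress = out_stress, summary = out_summary)
  if (all(vapply(outs, is.null, TRUE)))
    stop_config("at least one output must be requested")
  structure(list(topology = topology, trajectory = trajectory,
                 index = index, groups = groups, cutoff = cutoff,
                 mode = mode, scalar_mode = scalar_mode, level = level,
                 itypes = itypes, outs = outs, verbose = verbose),
            class = "pf_run_config")
}

level_path <- function(path, level, both) {
  if (!both) return(path)
  ext <- tools::file_ext(path)
  suffix <- tolower(level)
  if (ext == "") paste0(path, ".", suffix)
  else sub(paste0("\\.", ext, "$"), paste0(".", suffix, ".", ext), path)
}

#' Run a force-distribution rerun over a trajectory
#'
#' Streams the trajectory frame by frame: computes the pairwise-force
#' store, optionally aggregates to residues, scalarizes, computes punctual
#' stress and summaries, and appends one block per frame to every
#' requested output file.  Memory use is independent of trajectory length.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `n_frames` processed and `outputs`
#'   (named character vector of written files).
#' @export
pf_run <- function(config) {
  top <- read_topology(config$topology)
  groups <- if (is.null(config$index))
    group_spec(0:(n_atoms(top) - 1L), 0:(n_atoms(top) - 1L))
  else
    read_index_groups(config$index, config$groups[1], config$groups[2],
                      n_atoms = n_atoms(top))
  levels <- if (config$level == "BOTH") c("ATOM", "RESIDUE") else config$level
  both <- config$level == "BOTH"

  sinks <- list()
  for (what in names(config$outs)) {
    path <- config$outs[[what]]
    if (is.null(path)) next
    for (lv in levels) {
      spec <- output_spec(
        what = switch(what, pairs = "PAIR_VECTOR", scalars = "PAIR_SCALAR",
                      stress = "STRESS", summary = "SUMMARY"),
        level = lv,
        mode = if (what %in% c("pairs", "scalars")) config$mode
               else "SUMMED",
        scalar_mode = config$scalar_mode,
        path = level_path(path, lv, both))
      sinks[[paste(what, lv, sep = ".")]] <- open_output(spec)
    }
  }
  log <- function(...) if (config$verbose) message(sprintf(...))
  reader <- trajectory_reader(config$trajectory)
  on.exit({
    for (s in sinks) try(close(s$con), silent = TRUE)
    try(reader(close = TRUE), silent = TRUE)
  })
  idx <- 0L
  npairs_total <- 0
  repeat {
    fr <- reader()
    if (is.null(fr)) break
    check_frame_atoms(fr, top)
    store <- compute_frame_pairwise(fr, top, groups, cutoff = config$cutoff,
                                    mode = config$mode,
                                    itypes = config$itypes)
    npairs_total <- npairs_total + nrow(store)
    per_level <- list()
    for (lv in levels) {
      st <- if (lv == "RESIDUE") residue_pairwise(store, top) else store
      nent <- if (lv == "RESIDUE") n_residues(top) else n_atoms(top)
      sc <- if (!is.null(config$outs$scalars))
        scalarize(store, fr, top, mode = config$scalar_mode, level = lv)
      # stress and summaries always derive from the summed per-pair vectors
      sc_sum <- if (!is.null(config$outs$stress) ||
                    !is.null(config$outs$summary))
        scalarize(collapse_store(store), fr, top,
                  mode = config$scalar_mode, level = lv)
      per_level[[lv]] <- list(store = st, scalars = sc,
                              scalars_summed = sc_sum, n = nent)
    }
    for (nm in names(sinks)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      what <- parts[1]; lv <- parts[2]
      d <- per_level[[lv]]
      data <- switch(what,
        pairs = d$store,
        scalars = d$scalars,
        stress = punctual_stress(d$scalars_summed, d$n),
        summary = per_atom_summary(d$scalars_summed, d$n))
      write_frame_output(sinks[[nm]], data, idx, fr$time)
    }
    log("frame %d (t = %g ps): %d pair entries", idx, fr$time, nrow(store))
    idx <- idx + 1L
  }
  for (s in sinks) close_output(s)
  on.exit(NULL)
  log("done: %d frames, %d pair entries total", idx, npairs_total)
  invisible(list(
    n_frames = idx,
    outputs = vapply(sinks, function(s) s$spec$path, "")))
}
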