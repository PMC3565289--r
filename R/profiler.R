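# MD back-end analysis: frame extraction, dynamic per-residue interaction
# profiles, hydrogen-bond occupancy, CSV/plot output and VMD states.

#' Subsample trajectory frames at a fixed interval
#'
#' Keeps frames 1, 1+interval, 1+2*interval, ... with their original times.
#'
#' @param traj a [Trajectory-class].
#' @param interval frame interval (>= 1).
#' @return A [Trajectory-class].
#' @export
extractFrames <- function(traj, interval) {
  if (nFrames(traj) == 0) .afp_stop("empty trajectory", "afp_precondition")
  if (interval < 1) .afp_stop("interval must be >= 1", "afp_precondition")
  idx <- seq(1, nFrames(traj), by = interval)
  trajectory(traj@topology, coords = traj@coords[idx],
             times = traj@times[idx])
}

#' Dynamic per-residue interaction profile
#'
#' Binding-site residues are fixed from the first frame
#' ([bindingSite()] at `config@site_cutoff`); for every frame and site
#' residue the vdW + electrostatic ligand-residue interaction energy is
#' computed (no hydrogen-bond term, matching the per-residue energy
#' definition).  Waters are excluded from the site unless requested.
#'
#' @param traj a [Trajectory-class] with charges on its topology.
#' @param config a [ProfilerConfig-class].
#' @param nb a [NonbondedModel-class].
#' @param ligand optional explicit ligand atom indices (auto-detected from
#'   frame 1 when NULL).
#' @param includeWaters include water residues in the site (default FALSE).
#' @return An [InteractionProfile-class].
#' @export
dynamicProfile <- function(traj, config = profilerConfig(),
                           nb = nonbondedModel(), ligand = NULL,
                           includeWaters = FALSE) {
  if (config@frame_interval > 1L)
    traj <- extractFrames(traj, config@frame_interval)
  f1 <- frameSystem(traj, 1)
  if (nrow(f1@bonds) == 0) f1 <- perceiveBonds(f1)
  if (is.null(ligand)) ligand <- detectLigand(f1)
  site <- bindingSite(f1, ligand, config@site_cutoff,
                      includeWaters = includeWaters)
  if (length(site) == 0)
    .afp_stop("no binding-site residues within the cutoff",
              "afp_precondition")
  labs <- residueLabels(f1)
  res_idx <- lapply(site, function(s) which(labs == s))
  at <- f1@atoms
  nf <- nFrames(traj)
  E <- matrix(0, nf, length(site))
  for (f in seq_len(nf)) {
    xyz <- traj@coords[[f]]
    for (r in seq_along(site))
      E[f, r] <- .pair_energy_sum(xyz, at, ligand, res_idx[[r]], nb)
  }
  lig_id <- unique(at$resname[ligand])[1]
  new("InteractionProfile", times = traj@times, residue_labels = site,
      energies = E, ligand_id = lig_id,
      provenance = c(.MD_PROVENANCE,
                     list(site_cutoff_A = config@site_cutoff)))
}

# resolve an atom selector: integer index, serial number given as
# "serial:<n>", or "chain:resseq:name"
.resolve_atom <- function(system, sel) {
  at <- system@atoms
  if (is.numeric(sel)) {
    if (sel < 1 || sel > nrow(at))
      .afp_stop("atom index out of range", "afp_selection_error")
    return(as.integer(sel))
  }
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] == "serial") {
    i <- which(at$serial == as.integer(parts[2]))
  } else if (length(parts) == 3) {
    i <- which(at$chain == parts[1] & at$resseq == as.integer(parts[2]) &
                 at$name == parts[3])
  } else {
    .afp_stop(paste("cannot parse atom selector:", sel),
              "afp_selection_error")
  }
  if (length(i) != 1)
    .afp_stop(paste("selector does not match exactly one atom:", sel),
              "afp_selection_error")
  i
}

#' Hydrogen-bond occupancy along a trajectory
#'
#' A frame satisfies the bond iff the donor-acceptor distance is at most
#' `config@hbond_distance_max` and, when the donor carries a polar
#' hydrogen, the best D-H...A angle is at least `config@hbond_angle_min`.
#' Reports the occupancy fraction, per-frame flags and the first-break
#' frame/time.
#'
#' @param traj a [Trajectory-class].
#' @param donor,acceptor atom selectors (index, "serial:<n>" or
#'   "chain:resseq:name").
#' @param config a [ProfilerConfig-class].
#' @return list with `occupancy`, `flags`, `first_break_frame` (0-based,
#'   NA when never broken) and `first_break_time_ns`.
#' @export
hbondOccupancy <- function(traj, donor, acceptor, config = profilerConfig()) {
  topo <- traj@topology
  if (nrow(topo@bonds) == 0) topo <- perceiveBonds(topo)
  D <- .resolve_atom(topo, donor)
  A <- .resolve_atom(topo, acceptor)
  bm <- topo@bonds
  hs <- c(bm[bm[, 1] == D, 2], bm[bm[, 2] == D, 1])
  hs <- hs[topo@atoms$element[hs] == "H"]
  nf <- nFrames(traj)
  flags <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- traj@coords[[f]]
    r <- sqrt(sum((xyz[D, ] - xyz[A, ])^2))
    ok <- r <= config@hbond_distance_max
    if (ok && length(hs)) {
      theta <- max(vapply(hs, function(H) {
        v1 <- xyz[D, ] - xyz[H, ]
        v2 <- xyz[A, ] - xyz[H, ]
        ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(min(max(ct, -1), 1)) * 180 / pi
      }, numeric(1)))
      ok <- theta >= config@hbond_angle_min
    }
    flags[f] <- ok
  }
  broken <- which(!flags)
  fb <- if (length(broken)) broken[1] - 1L else NA_integer_
  list(occupancy = mean(flags), flags = flags, first_break_frame = fb,
       first_break_time_ns = if (is.na(fb)) NA_real_ else traj@times[fb + 1L])
}

#' Write an interaction profile as a CSV time series
#'
#' Header `time_ns,<label1>,<label2>,...`, one row per frame.
#'
#' @param profile an [InteractionProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfileCSV <- function(profile, path) {
  df <- data.frame(time_ns = profile@times,
                   profile@energies, check.names = FALSE)
  names(df) <- c("time_ns", profile@residue_labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile CSV written by [writeProfileCSV()]
#' @param path CSV file.
#' @param ligand_id ligand identifier to attach (default the file name).
#' @return An [InteractionProfile-class].
#' @export
readProfileCSV <- function(path, ligand_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_ns")
    .afp_stop("not a profile CSV (missing time_ns column)",
              "afp_format_error")
  if (is.null(ligand_id))
    ligand_id <- sub("\\.csv$", "", basename(path))
  new("InteractionProfile", times = df$time_ns,
      residue_labels = names(df)[-1],
      energies = unname(as.matrix(df[, -1, drop = FALSE])),
      ligand_id = ligand_id, provenance = list(source = path))
}

.VMD_STYLES <- list(
  cartoon = "NewCartoon 0.300000 10.000000 4.100000 0",
  licorice = "Licorice 0.300000 12.000000 12.000000",
  lines = "Lines 1.000000",
  vdw = "VDW 1.000000 12.000000"
)

#' Generate a VMD visualization-state file
#'
#' Emits a Tcl state file that loads the given frame PDBs in order into
#' one molecule and applies a pre-defined representation style.  Purely
#' generative; VMD itself is never executed.
#'
#' @param frame_paths character vector of PDB frame files (>= 1).
#' @param style one of `names(.VMD_STYLES)`: "cartoon", "licorice",
#'   "lines", "vdw".
#' @param path output state file.
#' @return `path`, invisibly.
#' @export
generateVMDState <- function(frame_paths, style = "licorice", path) {
  if (length(frame_paths) == 0)
    .afp_stop("need at least one frame path", "afp_precondition")
  if (!style %in% names(.VMD_STYLES))
    .afp_stop(paste0("unknown style '", style, "'; available: ",
                     paste(names(.VMD_STYLES), collapse = ", ")),
              "afp_usage")
  lines <- c(
    "# VMD visualization state",
    sprintf("mol new {%s} type pdb waitfor all", frame_paths[1]),
    sprintf("mol addfile {%s} type pdb waitfor all",
            frame_paths[-1]),
    "mol delrep 0 top",
    sprintf("mol representation %s", .VMD_STYLES[[style]]),
    "mol color Name",
    "mol selection {all}",
    "mol addrep top",
    "animate goto 0"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Plot dynamic interaction profiles for one residue
#'
#' One curve per profile (energy vs time) with automatic colours and a
#' legend built from the ligand ids; profiles accumulate into the same
#' axes so multiple simulations can be compared.
#'
#' @param profiles list of [InteractionProfile-class] objects.
#' @param residue_label residue to plot, present in every profile.
#' @param path optional output figure file (".pdf" or ".png"); plots to
#'   the active device when NULL.
#' @return invisibly, the matrix of plotted series.
#' @export
plotProfiles <- function(profiles, residue_label, path = NULL) {
  if (is(profiles, "InteractionProfile")) profiles <- list(profiles)
  cols <- lapply(profiles, function(p) {
    j <- match(residue_label, p@residue_labels)
    if (is.na(j))
      .afp_stop(paste0("residue '", residue_label, "' missing from profile '",
                       p@ligand_id, "'"), "afp_selection_error")
    cbind(p@times, p@energies[, j])
  })
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           pdf = grDevices::pdf(path, width = 7, height = 5),
           png = grDevices::png(path, width = 800, height = 570),
           .afp_stop("figure path must end in .pdf or .png", "afp_usage"))
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(max(3, length(cols)), "Dark 3")
  xr <- range(unlist(lapply(cols, function(m) m[, 1])))
  yr <- range(unlist(lapply(cols, function(m) m[, 2])))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time (ns)",
                 ylab = "interaction energy (kcal/mol)",
                 main = residue_label)
  for (i in seq_along(cols))
    graphics::lines(cols[[i]][, 1], cols[[i]][, 2], col = pal[i], lwd = 2)
  graphics::legend("topright",
                   legend = vapply(profiles, function(p) p@ligand_id,
                                   character(1)),
                   col = pal[seq_along(cols)], lwd = 2, bty = "n")
  invisible(cols)
}
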