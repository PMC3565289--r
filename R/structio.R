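# PDB structure / trajectory IO, bond perception, ligand and site detection.

#' Read a PDB file into a Trajectory
#'
#' Parses ATOM/HETATM records; MODEL/ENDMDL blocks become trajectory frames
#' (a single frame when no MODEL records are present).  CONECT records are
#' ignored: connectivity is re-perceived with [perceiveBonds()].  Partial
#' charges default to 0 unless a sidecar CSV (`serial,charge_e`) is given.
#'
#' @param path PDB file.
#' @param multiModel honour MODEL/ENDMDL blocks (default TRUE); when FALSE
#'   only the first model is kept.
#' @param chargeFile optional sidecar CSV with header `serial,charge_e`.
#' @param interval_ns frame time spacing when MODEL blocks are present.
#' @return A [Trajectory-class] (use [frameSystem()] for single structures).
#' @export
readPDB <- function(path, multiModel = TRUE, chargeFile = NULL,
                    interval_ns = 0.01) {
  if (!file.exists(path))
    .afp_stop(paste("file not found:", path), "afp_io_error")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    .afp_stop(paste("no ATOM/HETATM records in", path), "afp_empty_input")

  model_breaks <- which(trimws(rec) == "ENDMDL")
  atom_idx <- which(is_atom)
  # frame id per atom line: count ENDMDL records seen before the line
  frame_of <- findInterval(atom_idx, model_breaks) + 1L

  al <- lines[atom_idx]
  num <- function(s, lo, hi, what) {
    v <- suppressWarnings(as.numeric(substr(s, lo, hi)))
    bad <- which(!is.finite(v))
    if (length(bad))
      .afp_stop(sprintf("unparseable %s field at line %d", what,
                        atom_idx[bad[1]]), "afp_format_error")
    v
  }
  serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
  serial[!is.finite(serial)] <- seq_along(al)[!is.finite(serial)]
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  chain <- trimws(substr(al, 22, 22))
  resseq <- suppressWarnings(as.integer(substr(al, 23, 26)))
  resseq[!is.finite(resseq)] <- 0L
  icode <- trimws(substr(al, 27, 27))
  x <- num(al, 31, 38, "x-coordinate")
  y <- num(al, 39, 46, "y-coordinate")
  z <- num(al, 47, 54, "z-coordinate")
  element <- trimws(substr(al, 77, 78))
  # fall back to the atom-name convention when the element column is blank
  blank <- !nzchar(element)
  element[blank] <- .element_from_name(name[blank])
  hetero <- substr(al, 1, 6) == "HETATM"

  keep <- altloc %in% c(" ", "", "A")
  df <- data.frame(serial = serial, name = name, element = toupper(element),
                   resname = resname, chain = chain, resseq = resseq,
                   icode = icode, x = x, y = y, z = z,
                   charge = 0, hetero = hetero,
                   stringsAsFactors = FALSE)[keep, ]
  frame_of <- frame_of[keep]

  frames <- sort(unique(frame_of))
  if (!multiModel) frames <- frames[1]
  first <- df[frame_of == frames[1], ]
  rownames(first) <- NULL

  if (!is.null(chargeFile)) {
    ch <- utils::read.csv(chargeFile, stringsAsFactors = FALSE)
    if (!all(c("serial", "charge_e") %in% names(ch)))
      .afp_stop("charge sidecar needs columns serial,charge_e",
                "afp_format_error")
    j <- match(first$serial, ch$serial)
    first$charge[!is.na(j)] <- ch$charge_e[j[!is.na(j)]]
  }

  sys <- molecularSystem(first)
  coord_list <- lapply(frames, function(f) {
    sub <- df[frame_of == f, c("x", "y", "z")]
    if (nrow(sub) != nrow(first))
      .afp_stop(sprintf("model %d has %d atoms, expected %d", f, nrow(sub),
                        nrow(first)), "afp_format_error")
    m <- as.matrix(sub)
    dimnames(m) <- NULL
    m
  })
  trajectory(sys, coords = coord_list, interval_ns = interval_ns)
}

.element_from_name <- function(name) {
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "CA")
  up <- toupper(name)
  el <- substr(gsub("[^A-Za-z].*", "", up), 1, 1)
  head2 <- substr(up, 1, 2)
  el[head2 %in% two] <- head2[head2 %in% two]
  # digits-first hydrogen names like 1HB
  el[grepl("^[0-9]*H", up)] <- "H"
  el
}

#' Write a system or trajectory as PDB
#'
#' Multi-frame trajectories are written as MODEL/ENDMDL blocks; coordinates
#' use the format's fixed 3-decimal columns.
#'
#' @param x a [MolecularSystem-class] or [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  traj <- if (is(x, "MolecularSystem")) trajectory(x) else x
  at <- traj@topology@atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(traj@coords) > 1
  for (f in seq_along(traj@coords)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- traj@coords[[f]]
    rectype <- ifelse(at$hetero, "HETATM", "ATOM  ")
    aname <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                    sprintf("%-4s", at$name))
    lines <- sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rectype, at$serial %% 100000L, aname, at$resname,
                     substr(paste0(at$chain, " "), 1, 1), at$resseq %% 10000L,
                     substr(paste0(at$icode, " "), 1, 1),
                     m[, 1], m[, 2], m[, 3], 1.0, 0.0, at$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a sidecar charge table
#' @param system a [MolecularSystem-class].
#' @param path output CSV (`serial,charge_e`).
#' @return `path`, invisibly.
#' @export
writeChargeTable <- function(system, path) {
  utils::write.csv(data.frame(serial = system@atoms$serial,
                              charge_e = system@atoms$charge),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff their distance is at most
#' r_cov(i) + r_cov(j) + slack, using the bundled covalent-radius table.
#' H-H pairs are never bonded.
#'
#' @param system a [MolecularSystem-class].
#' @param slack distance slack in A (default 0.45).
#' @param overrides optional parameter overrides (see [elementParams()]).
#' @return the system with its `bonds` slot filled.
#' @export
perceiveBonds <- function(system, slack = 0.45, overrides = NULL) {
  at <- system@atoms
  n <- nrow(at)
  if (n < 2) {
    system@bonds <- matrix(integer(), ncol = 2)
    return(system)
  }
  rc <- elementParams(at$element, overrides)$covalent_radius
  xyz <- coords(system)
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rc, rc, "+") + slack
  adj <- d <= thr & upper.tri(d)
  hh <- outer(at$element == "H", at$element == "H", "&")
  adj[hh] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  system@bonds <- matrix(as.integer(idx), ncol = 2,
                         dimnames = NULL)[order(idx[, 1], idx[, 2]), ,
                                          drop = FALSE]
  system
}

# connected components over the bond graph restricted to `subset` indices
.components <- function(n, bond_mat, subset = seq_len(n)) {
  comp <- rep(NA_integer_, n)
  in_sub <- logical(n)
  in_sub[subset] <- TRUE
  adj <- vector("list", n)
  if (nrow(bond_mat) > 0) {
    keep <- in_sub[bond_mat[, 1]] & in_sub[bond_mat[, 2]]
    bm <- bond_mat[keep, , drop = FALSE]
    for (k in seq_len(nrow(bm))) {
      i <- bm[k, 1]; j <- bm[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  cid <- 0L
  for (s in subset) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Detect the ligand-like molecule
#'
#' Returns the largest connected component of hetero atoms after excluding
#' waters (HOH/WAT/TIP/...) and single-atom ions.  Ties break to the
#' component containing the lowest atom serial.
#'
#' @param system a [MolecularSystem-class] with bonds perceived.
#' @return integer vector of atom indices (the ligand selection).
#' @export
detectLigand <- function(system) {
  at <- system@atoms
  cand <- which(at$hetero & !(at$resname %in% .WATER_RESNAMES))
  if (length(cand) == 0)
    .afp_stop("no ligand-like molecule found (apo structure?)", "afp_no_ligand")
  comp <- .components(nrow(at), system@bonds, cand)
  sizes <- table(comp[cand])
  # drop single-atom components (ions)
  sizes <- sizes[sizes > 1]
  if (length(sizes) == 0)
    .afp_stop("no ligand-like molecule found (only ions/waters)",
              "afp_no_ligand")
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1) {
    min_serial <- vapply(best, function(b)
      min(at$serial[which(comp == b)]), numeric(1))
    best <- best[which.min(min_serial)]
  }
  sort(which(comp == best))
}

#' Binding-site residues within a cutoff of the ligand
#'
#' A residue is part of the site iff the minimum distance between any of
#' its atoms and any ligand atom is at most `cutoff` (default 8 A).  The
#' ligand's own residue (and optionally waters) are excluded; residues are
#' ordered by chain then sequence number.
#'
#' @param system a [MolecularSystem-class].
#' @param ligand integer atom indices of the ligand.
#' @param cutoff distance cutoff in A (default 8.0).
#' @param includeWaters include water residues (default FALSE).
#' @return character vector of residue labels ("chain:resname:resseq").
#' @export
bindingSite <- function(system, ligand, cutoff = 8.0, includeWaters = FALSE) {
  if (length(ligand) == 0)
    .afp_stop("empty ligand selection", "afp_precondition")
  if (cutoff <= 0) .afp_stop("cutoff must be positive", "afp_precondition")
  at <- system@atoms
  labs <- residueLabels(system)
  lig_labs <- unique(labs[ligand])
  other <- setdiff(seq_len(nrow(at)), ligand)
  other <- other[!(labs[other] %in% lig_labs)]
  if (!includeWaters) other <- other[!(at$resname[other] %in% .WATER_RESNAMES)]
  if (length(other) == 0) return(character())
  xyz <- coords(system)
  lig_xyz <- xyz[ligand, , drop = FALSE]
  d2min <- vapply(other, function(i) {
    dx <- lig_xyz[, 1] - xyz[i, 1]
    dy <- lig_xyz[, 2] - xyz[i, 2]
    dz <- lig_xyz[, 3] - xyz[i, 3]
    min(dx * dx + dy * dy + dz * dz)
  }, numeric(1))
  near <- other[d2min <= cutoff^2]
  hits <- unique(labs[near])
  if (length(hits) == 0) return(character())
  ord <- order(at$chain[match(hits, labs)], at$resseq[match(hits, labs)])
  hits[ord]
}

#' Atom indices of a residue label
#' @param system a [MolecularSystem-class].
#' @param label residue label "chain:resname:resseq".
#' @return integer vector of atom indices.
#' @export
residueAtomIndices <- function(system, label) {
  which(residueLabels(system) == label)
}

# is bond k part of a ring?  yes iff its endpoints stay connected after
# removing the bond.
.bond_in_ring <- function(n, bond_mat, k) {
  reduced <- bond_mat[-k, , drop = FALSE]
  i <- bond_mat[k, 1]; j <- bond_mat[k, 2]
  comp <- .components(n, reduced)
  comp[i] == comp[j]
}

#' Count rotatable bonds of a (ligand) molecule
#'
#' Rotatable = acyclic single bond between two heavy atoms, each of which
#' carries at least one additional heavy neighbour; amide C-N bonds
#' (carbon bearing a carbonyl-length C=O contact) are excluded.
#'
#' @param system a ligand-only [MolecularSystem-class] with bonds perceived.
#' @param selection optional atom indices restricting the molecule.
#' @return integer count.
#' @export
countRotatableBonds <- function(system, selection = NULL) {
  at <- system@atoms
  bm <- system@bonds
  if (!is.null(selection)) {
    keep <- bm[, 1] %in% selection & bm[, 2] %in% selection
    bm <- bm[keep, , drop = FALSE]
  } else {
    selection <- seq_len(nrow(at))
  }
  if (nrow(bm) == 0) return(0L)
  heavy <- at$element != "H"
  xyz <- coords(system)
  heavy_nb <- function(i) {
    nb <- c(bm[bm[, 1] == i, 2], bm[bm[, 2] == i, 1])
    nb[heavy[nb]]
  }
  n_rot <- 0L
  for (k in seq_len(nrow(bm))) {
    i <- bm[k, 1]; j <- bm[k, 2]
    if (!heavy[i] || !heavy[j]) next
    if (length(setdiff(heavy_nb(i), j)) < 1) next
    if (length(setdiff(heavy_nb(j), i)) < 1) next
    if (.bond_in_ring(nrow(at), bm, k)) next
    # amide: C-N single bond where the C has a short (carbonyl-like) C-O
    is_amide <- FALSE
    for (pair in list(c(i, j), c(j, i))) {
      ci <- pair[1]; ni <- pair[2]
      if (at$element[ci] == "C" && at$element[ni] == "N") {
        onb <- heavy_nb(ci)
        onb <- onb[at$element[onb] == "O"]
        if (length(onb)) {
          dco <- sqrt(rowSums((xyz[onb, , drop = FALSE] -
                                 matrix(xyz[ci, ], length(onb), 3,
                                        byrow = TRUE))^2))
          if (any(dco <= 1.30)) is_amide <- TRUE
        }
      }
    }
    if (is_amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

#' Assign crude fallback partial charges
#'
#' Electronegativity-equalisation-style one-pass scheme: each bond shifts
#' charge proportionally to the electronegativity difference of its atoms.
#' Intended only as a stand-in when no sidecar charge table is available;
#' the provenance is recorded in the returned system's metadata attribute.
#'
#' @param system a [MolecularSystem-class] with bonds perceived.
#' @param scale charge transferred per unit electronegativity difference.
#' @return the system with `charge` filled.
#' @export
assignFallbackCharges <- function(system, scale = 0.16) {
  chi <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19,
           F = 3.98, CL = 3.16, BR = 2.96, I = 2.66, NA. = 0.93, K = 0.82,
           MG = 1.31, CA = 1.00, ZN = 1.65, FE = 1.83)
  names(chi)[names(chi) == "NA."] <- "NA"
  at <- system@atoms
  x <- chi[at$element]
  x[is.na(x)] <- 2.5
  q <- rep(0, nrow(at))
  bm <- system@bonds
  for (k in seq_len(nrow(bm))) {
    i <- bm[k, 1]; j <- bm[k, 2]
    dq <- scale * (x[j] - x[i])
    q[i] <- q[i] + dq
    q[j] <- q[j] - dq
  }
  system@atoms$charge <- q
  attr(system, "charge_provenance") <- "fallback-electronegativity"
  system
}
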