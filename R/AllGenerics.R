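# Accessor generics and show methods.

#' Atom table of a system or trajectory topology
#' @param x a MolecularSystem or Trajectory.
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "MolecularSystem", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' Bond index pairs
#' @param x a MolecularSystem.
#' @return two-column integer matrix.
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname bonds
#' @export
setMethod("bonds", "MolecularSystem", function(x) x@bonds)

#' Number of atoms
#' @param x a MolecularSystem or Trajectory.
#' @return integer.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' Number of frames in a trajectory
#' @param x a Trajectory.
#' @return integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@coords))

#' Frame times (ns)
#' @param x a Trajectory or InteractionProfile.
#' @return numeric vector.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "InteractionProfile", function(x) x@times)

#' Extract a single frame as a MolecularSystem
#' @param x a Trajectory.
#' @param i frame index (1-based).
#' @return a MolecularSystem whose coordinates are frame i.
#' @export
setGeneric("frameSystem", function(x, i) standardGeneric("frameSystem"))

#' @rdname frameSystem
#' @export
setMethod("frameSystem", "Trajectory", function(x, i) {
  sys <- x@topology
  sys@atoms[, c("x", "y", "z")] <- x@coords[[i]]
  sys
})

#' Coordinates of a system (n x 3 matrix, A)
#' @param x a MolecularSystem.
#' @return numeric matrix.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "MolecularSystem", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' Residue labels ("chain:resname:resseq", insertion code appended if set)
#' @param x a MolecularSystem.
#' @return character vector, one entry per atom.
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' @rdname residueLabels
#' @export
setMethod("residueLabels", "MolecularSystem", function(x) {
  at <- x@atoms
  lab <- paste(at$chain, at$resname, at$resseq, sep = ":")
  has_icode <- nzchar(at$icode)
  lab[has_icode] <- paste0(lab[has_icode], at$icode[has_icode])
  lab
})

#' Members of a model family
#' @param x a ModelFamily.
#' @return list of SurrogateModel objects.
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))

#' @rdname familyMembers
#' @export
setMethod("familyMembers", "ModelFamily", function(x) x@members)

#' Interaction-energy matrix (time x residue, kcal/mol)
#' @param x an InteractionProfile.
#' @return numeric matrix with residue labels as column names.
#' @export
setGeneric("profileEnergies", function(x) standardGeneric("profileEnergies"))

#' @rdname profileEnergies
#' @export
setMethod("profileEnergies", "InteractionProfile", function(x) {
  m <- x@energies
  colnames(m) <- x@residue_labels
  m
})

setMethod("show", "MolecularSystem", function(object) {
  at <- object@atoms
  nres <- length(unique(residueLabels(object)))
  cat("MolecularSystem:", nrow(at), "atoms,", nres, "residues,",
      nrow(object@bonds), "bonds\n")
  if (nrow(at) > 0)
    cat("  hetero atoms:", sum(at$hetero),
        " | elements:", paste(sort(unique(at$element)), collapse = " "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@coords), "frames x",
      nrow(object@topology@atoms), "atoms; t =",
      sprintf("%.4g..%.4g ns\n", min(object@times), max(object@times)))
})

setMethod("show", "Envelope", function(object) {
  cat("Envelope:", nrow(object@positions), "particles (spacing",
      object@spacing, "A, offset", round(object@offset, 2), "A)\n")
})

setMethod("show", "SurrogateModel", function(object) {
  tab <- table(factor(PROPERTY_LABELS[object@labels], levels = PROPERTY_LABELS))
  cat("SurrogateModel:", length(object@labels), "particles; induced-fit level",
      object@induced_fit_scenario, "; solvation scenario",
      object@solvation_scenario, "\n")
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "ModelFamily", function(object) {
  cat("ModelFamily:", length(object@members), "members,",
      nrow(object@envelope@positions), "particles; seed", object@seed, "\n")
})

setMethod("show", "QsarDataset", function(object) {
  cat("QsarDataset:", length(object@ids), "ligands (",
      sum(object@split == "train"), "train /", sum(object@split == "test"),
      "test ); pIC50 range",
      sprintf("%.2f..%.2f\n", min(object@pic50), max(object@pic50)))
})

setMethod("show", "InteractionProfile", function(object) {
  cat("InteractionProfile:", length(object@times), "frames x",
      length(object@residue_labels), "residues; ligand", object@ligand_id, "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: q2 = %.3f, predictive r2 = %.3f, within factor 10 = %.0f%%\n",
              object@q2, object@r2_pred, 100 * object@fraction_within_factor10))
  if (length(object@yscramble_q2))
    cat(sprintf("  Y-scrambling: mean q2 = %.3f over %d rounds\n",
                mean(object@yscramble_q2), length(object@yscramble_q2)))
})

setMethod("show", "AffinityEstimate", function(object) {
  cat(sprintf("AffinityEstimate: dG = %.2f kcal/mol, pIC50 = %.2f +/- %.2f\n",
              object@delta_g, object@pic50, object@uncertainty))
})
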