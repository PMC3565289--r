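#' @import methods
NULL

# Atom table column template.  Every MolecularSystem carries one row per atom:
# serial, name, element, resname, chain, resseq, icode, x, y, z, charge, hetero.
.ATOM_COLS <- c("serial", "name", "element", "resname", "chain", "resseq",
                "icode", "x", "y", "z", "charge", "hetero")

.empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             resname = character(), chain = character(), resseq = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             charge = numeric(), hetero = logical(),
             stringsAsFactors = FALSE)
}

#' MolecularSystem: atoms, bonds and residue identity
#'
#' Container for one structure: an ordered atom table (coordinates in
#' Angstrom, partial charges in elementary charge units) and a set of
#' unordered bonded atom-index pairs.  Residues are the grouping of atoms by
#' (chain, residue number, insertion code, residue name).
#'
#' @slot atoms data.frame with columns serial, name, element, resname, chain,
#'   resseq, icode, x, y, z, charge, hetero.
#' @slot bonds two-column integer matrix of bonded atom indices (i < j).
#' @export
setClass("MolecularSystem",
         representation(atoms = "data.frame", bonds = "matrix"),
         prototype(atoms = .empty_atoms(),
                   bonds = matrix(integer(), ncol = 2)))

setValidity("MolecularSystem", function(object) {
  at <- object@atoms
  if (!all(.ATOM_COLS %in% names(at)))
    return(paste("atoms must contain columns:", paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(at) > 0) {
    if (any(!nzchar(at$element)) || anyNA(at$element))
      return("every atom needs a non-empty element")
    if (!all(is.finite(c(at$x, at$y, at$z))))
      return("atom positions must be finite")
    if (!all(is.finite(at$charge)))
      return("partial charges must be finite")
  }
  b <- object@bonds
  if (ncol(b) != 2) return("bonds must be a two-column matrix")
  if (nrow(b) > 0) {
    if (any(b < 1L) || any(b > nrow(at)))
      return("bond indices out of range")
    if (any(b[, 1] == b[, 2])) return("self-bonds not allowed")
  }
  TRUE
})

#' Construct a MolecularSystem
#'
#' @param atoms atom data.frame (see [MolecularSystem-class]); missing
#'   optional columns (icode, charge, hetero) are filled with defaults.
#' @param bonds two-column matrix of bonded atom index pairs.
#' @return A [MolecularSystem-class] object.
#' @export
molecularSystem <- function(atoms, bonds = matrix(integer(), ncol = 2)) {
  if (is.null(atoms$icode)) atoms$icode <- rep("", nrow(atoms))
  if (is.null(atoms$charge)) atoms$charge <- rep(0, nrow(atoms))
  if (is.null(atoms$hetero)) atoms$hetero <- rep(FALSE, nrow(atoms))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$serial <- as.integer(atoms$serial)
  atoms <- atoms[, .ATOM_COLS]
  b <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(b) > 0) b <- t(apply(b, 1, sort))
  new("MolecularSystem", atoms = atoms, bonds = b)
}

#' Trajectory: ordered frames sharing one topology
#'
#' Frames are coordinate snapshots of a single [MolecularSystem-class]
#' topology; times are in nanoseconds and strictly increasing.
#'
#' @slot topology the shared MolecularSystem (coordinates = frame 1).
#' @slot coords list of n_atoms x 3 coordinate matrices, one per frame.
#' @slot times numeric vector of frame times (ns).
#' @export
setClass("Trajectory",
         representation(topology = "MolecularSystem", coords = "list",
                        times = "numeric"))

setValidity("Trajectory", function(object) {
  n <- nrow(object@topology@atoms)
  if (length(object@coords) == 0) return("trajectory needs at least one frame")
  ok <- vapply(object@coords, function(m) is.matrix(m) && nrow(m) == n &&
                 ncol(m) == 3 && all(is.finite(m)), logical(1))
  if (!all(ok)) return("every frame must be a finite n_atoms x 3 matrix")
  if (length(object@times) != length(object@coords))
    return("times and frames must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  TRUE
})

#' Construct a Trajectory
#' @param topology a [MolecularSystem-class].
#' @param coords list of coordinate matrices; default the topology's own.
#' @param times frame times in ns; default 0-based at `interval_ns` spacing.
#' @param interval_ns snapshot interval used when `times` is missing.
#' @return A [Trajectory-class].
#' @export
trajectory <- function(topology, coords = NULL, times = NULL, interval_ns = 0.01) {
  if (is.null(coords))
    coords <- list(as.matrix(topology@atoms[, c("x", "y", "z")]))
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  })
  if (is.null(times)) times <- (seq_along(coords) - 1) * interval_ns
  new("Trajectory", topology = topology, coords = coords, times = as.numeric(times))
}

#' Nonbonded interaction model settings
#'
#' Houses the Coulomb constant, dielectric treatment, nonbonded cutoff and
#' the thermodynamic constants (T = 300 K, R in kcal/(mol K)) used for
#' Boltzmann weighting and the pIC50 conversion.
#'
#' @slot coulomb_constant kcal A / (mol e^2); 332.06.
#' @slot dielectric_mode "constant" or "distance" (distance-dependent
#'   effective dielectric, eps_eff = dielectric_value * r).
#' @slot dielectric_value dimensionless, >= 1.
#' @slot cutoff nonbonded cutoff in Angstrom.
#' @slot temperature Kelvin.
#' @slot gas_constant kcal/(mol K).
#' @export
setClass("NonbondedModel",
         representation(coulomb_constant = "numeric", dielectric_mode = "character",
                        dielectric_value = "numeric", cutoff = "numeric",
                        temperature = "numeric", gas_constant = "numeric"))

setValidity("NonbondedModel", function(object) {
  if (object@cutoff <= 0) return("cutoff must be positive")
  if (object@dielectric_value < 1) return("dielectric_value must be >= 1")
  if (!object@dielectric_mode %in% c("constant", "distance"))
    return("dielectric_mode must be 'constant' or 'distance'")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' Construct a NonbondedModel
#' @param coulomb_constant Coulomb prefactor, kcal A/(mol e^2).
#' @param dielectric_mode "constant" or "distance".
#' @param dielectric_value relative dielectric (>= 1).
#' @param cutoff nonbonded cutoff (A).
#' @param temperature K.
#' @param gas_constant kcal/(mol K).
#' @return A [NonbondedModel-class].
#' @export
nonbondedModel <- function(coulomb_constant = 332.06, dielectric_mode = "constant",
                           dielectric_value = 1, cutoff = 12,
                           temperature = 300, gas_constant = 0.0019872) {
  new("NonbondedModel", coulomb_constant = coulomb_constant,
      dielectric_mode = dielectric_mode, dielectric_value = dielectric_value,
      cutoff = cutoff, temperature = temperature, gas_constant = gas_constant)
}

#' Binding free-energy components
#'
#' The decomposition summed into the binding free energy: ligand-protein
#' interaction energy, internal strain, desolvation cost, rotor-entropy
#' cost (as T*dS), and induced-fit energy.  Costs enter with positive sign;
#' favourable binding gives a negative total.
#'
#' @slot e_interaction kcal/mol (negative when favourable).
#' @slot e_strain kcal/mol, >= 0.
#' @slot dg_desolvation kcal/mol.
#' @slot tds_rotors kcal/mol, >= 0.
#' @slot e_induced_fit kcal/mol.
#' @export
setClass("EnergyComponents",
         representation(e_interaction = "numeric", e_strain = "numeric",
                        dg_desolvation = "numeric", tds_rotors = "numeric",
                        e_induced_fit = "numeric"))

setValidity("EnergyComponents", function(object) {
  v <- c(object@e_interaction, object@e_strain, object@dg_desolvation,
         object@tds_rotors, object@e_induced_fit)
  if (!all(is.finite(v))) return("all components must be finite")
  if (object@e_strain < 0) return("e_strain must be >= 0")
  if (object@tds_rotors < 0) return("tds_rotors must be >= 0")
  TRUE
})

#' Construct EnergyComponents
#' @param e_interaction,e_strain,dg_desolvation,tds_rotors,e_induced_fit
#'   components in kcal/mol.
#' @return An [EnergyComponents-class].
#' @export
energyComponents <- function(e_interaction = 0, e_strain = 0, dg_desolvation = 0,
                             tds_rotors = 0, e_induced_fit = 0) {
  new("EnergyComponents", e_interaction = e_interaction, e_strain = e_strain,
      dg_desolvation = dg_desolvation, tds_rotors = tds_rotors,
      e_induced_fit = e_induced_fit)
}

#' Affinity estimate (binding free energy and pIC50)
#' @slot delta_g kcal/mol.
#' @slot pic50 -log10 IC50 [M].
#' @slot uncertainty pIC50 units (sd over a model family; 0 when single).
#' @export
setClass("AffinityEstimate",
         representation(delta_g = "numeric", pic50 = "numeric",
                        uncertainty = "numeric"))

#' Pose ensemble for one ligand (the 4D axis)
#'
#' Up to `maxPoses` docking poses of one ligand, each a ligand-only
#' [MolecularSystem-class], with per-pose conformational energies used for
#' Boltzmann weighting.
#'
#' @slot ligand_id text identifier.
#' @slot poses list of ligand-only MolecularSystem objects.
#' @slot conf_energies kcal/mol per pose.
#' @export
setClass("PoseEnsemble",
         representation(ligand_id = "character", poses = "list",
                        conf_energies = "numeric"))

setValidity("PoseEnsemble", function(object) {
  n <- length(object@poses)
  if (n < 1) return("ensemble needs at least one pose")
  if (length(object@conf_energies) != n)
    return("conf_energies length must equal pose count")
  if (!all(is.finite(object@conf_energies)))
    return("conf_energies must be finite")
  if (!all(vapply(object@poses, is, logical(1), "MolecularSystem")))
    return("poses must be MolecularSystem objects")
  TRUE
})

#' Construct a PoseEnsemble
#' @param ligand_id identifier.
#' @param poses list of ligand-only [MolecularSystem-class] poses.
#' @param conf_energies per-pose conformational energies (kcal/mol).
#' @param maxPoses cap on pose count (default 8); excess poses beyond the
#'   `maxPoses` lowest-energy ones are dropped.
#' @return A [PoseEnsemble-class].
#' @export
poseEnsemble <- function(ligand_id, poses, conf_energies, maxPoses = 8) {
  if (length(poses) > maxPoses) {
    keep <- order(conf_energies)[seq_len(maxPoses)]
    keep <- sort(keep)
    poses <- poses[keep]
    conf_energies <- conf_energies[keep]
  }
  new("PoseEnsemble", ligand_id = as.character(ligand_id), poses = poses,
      conf_energies = as.numeric(conf_energies))
}

#' Receptor-surrogate envelope
#'
#' Property-particle positions on the solvent-contact surface of the union
#' of the training pose ensembles.  Shared by all members of a model family.
#'
#' @slot positions n_particles x 3 matrix (A).
#' @slot center 3-vector, centroid of the enveloped atoms.
#' @slot spacing particle deduplication resolution (A).
#' @slot offset radial offset from the van der Waals surface (A).
#' @export
setClass("Envelope",
         representation(positions = "matrix", center = "numeric",
                        spacing = "numeric", offset = "numeric"))

setValidity("Envelope", function(object) {
  if (ncol(object@positions) != 3) return("positions must be n x 3")
  if (nrow(object@positions) < 1) return("envelope needs particles")
  if (length(object@center) != 3) return("center must be a 3-vector")
  TRUE
})

# Property alphabet of the surrogate particles.
PROPERTY_LABELS <- c("hydrophobic", "donor", "acceptor", "positive",
                     "negative", "neutral", "void")

#' Quasi-atomistic surrogate model
#'
#' One member of a model family: a property label per envelope particle,
#' a discrete induced-fit scenario (envelope dilation level 0..5, i.e.
#' 0 to 0.5 A in 0.1 A steps, each carrying a linear energy penalty) and a
#' solvation scenario (0 = buried site, 1 = solvent-exposed site).
#'
#' @slot envelope an [Envelope-class].
#' @slot labels integer vector (1..7) indexing [PROPERTY_LABELS] per particle.
#' @slot induced_fit_scenario integer 0..5.
#' @slot solvation_scenario integer 0..1.
#' @slot induced_fit_penalty kcal/mol per A of envelope dilation.
#' @slot base_energy scaffold reference energy (kcal/mol) added to every
#'   pose score; fixed, not evolved.
#' @export
setClass("SurrogateModel",
         representation(envelope = "Envelope", labels = "integer",
                        induced_fit_scenario = "integer",
                        solvation_scenario = "integer",
                        induced_fit_penalty = "numeric",
                        base_energy = "numeric"))

setValidity("SurrogateModel", function(object) {
  if (length(object@labels) != nrow(object@envelope@positions))
    return("one property label per envelope particle required")
  if (any(object@labels < 1L) || any(object@labels > length(PROPERTY_LABELS)))
    return("labels must index the property alphabet")
  if (object@induced_fit_scenario < 0L || object@induced_fit_scenario > 5L)
    return("induced_fit_scenario must be in 0..5")
  if (object@solvation_scenario < 0L || object@solvation_scenario > 1L)
    return("solvation_scenario must be 0 or 1")
  TRUE
})

#' Construct a SurrogateModel
#' @param envelope an [Envelope-class].
#' @param labels integer labels (1..7) per particle, or character vector of
#'   property names.
#' @param induced_fit_scenario dilation level 0..5.
#' @param solvation_scenario 0 (buried) or 1 (exposed).
#' @param induced_fit_penalty kcal/mol per A of dilation.
#' @param base_energy scaffold reference energy, kcal/mol.
#' @return A [SurrogateModel-class].
#' @export
surrogateModel <- function(envelope, labels,
                           induced_fit_scenario = 0L, solvation_scenario = 0L,
                           induced_fit_penalty = 2.0, base_energy = -8.9) {
  if (is.character(labels)) labels <- match(labels, PROPERTY_LABELS)
  new("SurrogateModel", envelope = envelope, labels = as.integer(labels),
      induced_fit_scenario = as.integer(induced_fit_scenario),
      solvation_scenario = as.integer(solvation_scenario),
      induced_fit_penalty = induced_fit_penalty, base_energy = base_energy)
}

#' Family of surrogate models evaluated in consensus mode
#'
#' @slot envelope the shared [Envelope-class].
#' @slot members list of [SurrogateModel-class] objects (default family
#'   size 200).
#' @slot config list of GA settings used for training.
#' @slot seed integer training seed.
#' @export
setClass("ModelFamily",
         representation(envelope = "Envelope", members = "list",
                        config = "list", seed = "integer"))

setValidity("ModelFamily", function(object) {
  if (length(object@members) < 1) return("family must be non-empty")
  if (!all(vapply(object@members, is, logical(1), "SurrogateModel")))
    return("members must be SurrogateModel objects")
  np <- nrow(object@envelope@positions)
  same <- vapply(object@members,
                 function(m) nrow(m@envelope@positions) == np, logical(1))
  if (!all(same)) return("all members must share one envelope geometry")
  TRUE
})

#' QSAR dataset: pose ensembles with affinity labels and split
#'
#' @slot ids ligand identifiers.
#' @slot ensembles list of [PoseEnsemble-class] objects.
#' @slot pic50 experimental pIC50 per ligand.
#' @slot split factor with levels train/test.
#' @export
setClass("QsarDataset",
         representation(ids = "character", ensembles = "list",
                        pic50 = "numeric", split = "factor"))

setValidity("QsarDataset", function(object) {
  n <- length(object@ids)
  if (length(object@ensembles) != n || length(object@pic50) != n ||
      length(object@split) != n)
    return("ids, ensembles, pic50 and split must have equal length")
  if (!all(is.finite(object@pic50))) return("pic50 must be finite")
  if (!all(levels(object@split) %in% c("train", "test")))
    return("split levels must be train/test")
  if (anyDuplicated(object@ids)) return("ligand ids must be unique")
  TRUE
})

#' Construct a QsarDataset
#' @param ids ligand identifiers.
#' @param ensembles list of [PoseEnsemble-class].
#' @param pic50 experimental pIC50 values.
#' @param split character/factor "train"/"test" per ligand.
#' @return A [QsarDataset-class].
#' @export
qsarDataset <- function(ids, ensembles, pic50, split) {
  new("QsarDataset", ids = as.character(ids), ensembles = ensembles,
      pic50 = as.numeric(pic50),
      split = factor(as.character(split), levels = c("train", "test")))
}

#' Validation report for a trained model family
#' @slot q2 cross-validated r2 (1 - PRESS/SS_tot on held-out predictions).
#' @slot r2_pred predictive r2 on the external test set.
#' @slot fraction_within_factor10 fraction of test compounds predicted
#'   within 1.0 pIC50 unit.
#' @slot yscramble_q2 q2 values from Y-scrambling rounds (may be empty).
#' @export
setClass("ValidationReport",
         representation(q2 = "numeric", r2_pred = "numeric",
                        fraction_within_factor10 = "numeric",
                        yscramble_q2 = "numeric"))

#' Dynamic per-residue interaction profile
#'
#' Time series of ligand-residue interaction energies (vdW + electrostatic,
#' kcal/mol) over the binding-site residues fixed at frame 1.
#'
#' @slot times ns per frame.
#' @slot residue_labels "chain:resname:resseq" labels, unique, site order.
#' @slot energies matrix time x residue (kcal/mol).
#' @slot ligand_id text.
#' @slot provenance list of protocol constants recorded for traceability.
#' @export
setClass("InteractionProfile",
         representation(times = "numeric", residue_labels = "character",
                        energies = "matrix", ligand_id = "character",
                        provenance = "list"))

setValidity("InteractionProfile", function(object) {
  if (nrow(object@energies) != length(object@times))
    return("energy matrix rows must match times")
  if (ncol(object@energies) != length(object@residue_labels))
    return("energy matrix columns must match residue labels")
  if (anyDuplicated(object@residue_labels))
    return("residue labels must be unique")
  TRUE
})

#' Profiler configuration
#' @slot site_cutoff binding-site cutoff (A), default 8.
#' @slot frame_interval frame subsampling interval, default 1.
#' @slot hbond_distance_max donor-acceptor distance criterion (A), default 3.5.
#' @slot hbond_angle_min D-H...A angle criterion (degrees), default 120.
#' @export
setClass("ProfilerConfig",
         representation(site_cutoff = "numeric", frame_interval = "integer",
                        hbond_distance_max = "numeric", hbond_angle_min = "numeric"))

setValidity("ProfilerConfig", function(object) {
  v <- c(object@site_cutoff, object@frame_interval,
         object@hbond_distance_max, object@hbond_angle_min)
  if (any(v <= 0)) return("all profiler settings must be positive")
  TRUE
})

#' Construct a ProfilerConfig
#' @param site_cutoff binding-site cutoff in A (default 8.0).
#' @param frame_interval frame subsampling interval (default 1).
#' @param hbond_distance_max H-bond D...A distance maximum (default 3.5 A).
#' @param hbond_angle_min H-bond D-H...A angle minimum (default 120 deg).
#' @return A [ProfilerConfig-class].
#' @export
profilerConfig <- function(site_cutoff = 8.0, frame_interval = 1L,
                           hbond_distance_max = 3.5, hbond_angle_min = 120) {
  new("ProfilerConfig", site_cutoff = site_cutoff,
      frame_interval = as.integer(frame_interval),
      hbond_distance_max = hbond_distance_max, hbond_angle_min = hbond_angle_min)
}
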