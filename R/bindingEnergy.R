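# Binding free-energy decomposition: SASA-based desolvation, rotor-entropy
# penalty, strain, pose-window filtering and the dG <-> pIC50 conversion.

# deterministic unit sphere points (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA from deterministic sphere-point sampling: points on each
#' atom's expanded sphere (vdW radius + probe) are tested against all
#' neighbouring expanded spheres.
#'
#' @param system a [MolecularSystem-class].
#' @param probe probe radius in A (default 1.4).
#' @param points sphere points per atom (default 960).
#' @param overrides optional parameter overrides (vdW radii).
#' @return numeric vector, one area (A^2) per atom.
#' @export
atomSASA <- function(system, probe = 1.4, points = 960, overrides = NULL) {
  at <- system@atoms
  n <- nrow(at)
  if (n == 0) return(numeric())
  rad <- elementParams(at$element, overrides)$vdw_radius + probe
  xyz <- coords(system)
  sp <- .sphere_points(points)
  sasa <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sp * rad[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    if (length(nb)) {
      exposed <- rep(TRUE, points)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        exposed <- exposed & dj2 > rad[j]^2
      }
      frac <- sum(exposed) / points
    } else {
      frac <- 1
    }
    sasa[i] <- frac * 4 * pi * rad[i]^2
  }
  sasa
}

#' SASA-based desolvation cost
#'
#' Continuum-solvation surrogate: sum over atoms of the element's atomic
#' solvation parameter times its solvent-accessible area, evaluated on the
#' designated reference (global-minimum) conformer.
#'
#' @param system reference conformer as a [MolecularSystem-class].
#' @param probe probe radius (A).
#' @param points sphere points per atom.
#' @param overrides optional parameter overrides.
#' @return kcal/mol (cost, >= 0 with the bundled parameters).
#' @export
desolvationEnergy <- function(system, probe = 1.4, points = 960,
                              overrides = NULL) {
  if (nrow(system@atoms) == 0) return(0)
  sp <- elementParams(system@atoms$element, overrides)$solvation_parameter
  sum(sp * atomSASA(system, probe, points, overrides))
}

#' Rotor-entropy penalty
#'
#' Binding-entropy loss approximated as a fixed cost per rotatable bond
#' constrained upon binding.
#'
#' @param n_rotors number of rotatable bonds (>= 0).
#' @param per_rotor cost per constrained rotor, kcal/mol (default 0.4).
#' @param fraction_constrained fraction of rotors immobilised (default 1).
#' @return kcal/mol (>= 0).
#' @export
entropyPenalty <- function(n_rotors, per_rotor = 0.4, fraction_constrained = 1.0) {
  stopifnot(n_rotors >= 0, per_rotor >= 0,
            fraction_constrained >= 0, fraction_constrained <= 1)
  n_rotors * fraction_constrained * per_rotor
}

#' Internal strain energy of a bound pose
#'
#' Conformational energy of the pose relative to the global minimum,
#' clamped at zero.  A pose below the reference by more than `tol` raises
#' an inconsistent-reference warning.
#'
#' @param pose_conf_energy pose conformational energy (kcal/mol).
#' @param global_min_energy global-minimum energy (kcal/mol).
#' @param tol tolerance before warning (default 1e-6).
#' @return kcal/mol, >= 0.
#' @export
strainEnergy <- function(pose_conf_energy, global_min_energy, tol = 1e-6) {
  stopifnot(is.finite(pose_conf_energy), is.finite(global_min_energy))
  if (pose_conf_energy < global_min_energy - tol)
    .afp_warn("pose energy below the designated global minimum; check the reference conformer",
              "afp_inconsistent_reference")
  max(0, pose_conf_energy - global_min_energy)
}

#' Energy-window pose filter
#'
#' Retains poses within `window` kcal/mol of the lowest-energy pose
#' (default 10), preserving the original order.
#'
#' @param conf_energies numeric vector of pose conformational energies.
#' @param window energy window in kcal/mol (default 10).
#' @return integer indices of retained poses (1-based).
#' @export
poseFilter <- function(conf_energies, window = 10) {
  if (length(conf_energies) == 0)
    .afp_stop("empty energy list", "afp_precondition")
  if (window <= 0) .afp_stop("window must be positive", "afp_precondition")
  which(conf_energies <= min(conf_energies) + window)
}

# ln(10) * R * T, the kcal/mol per pIC50 unit
.pic50_slope <- function(model) log(10) * model@gas_constant * model@temperature

#' Binding free energy from its components and the pIC50 conversion
#'
#' dG = interaction + strain + desolvation + rotor entropy + induced fit,
#' with costs entered positive and favourable interaction negative;
#' pIC50 = -dG / (ln(10) R T), treating IC50 as a Kd proxy.
#'
#' @param components an [EnergyComponents-class].
#' @param model a [NonbondedModel-class] (houses R and T).
#' @param uncertainty optional pIC50 uncertainty carried through.
#' @return An [AffinityEstimate-class].
#' @export
bindingFreeEnergy <- function(components, model = nonbondedModel(),
                              uncertainty = 0) {
  dg <- components@e_interaction + components@e_strain +
    components@dg_desolvation + components@tds_rotors +
    components@e_induced_fit
  new("AffinityEstimate", delta_g = dg, pic50 = -dg / .pic50_slope(model),
      uncertainty = uncertainty)
}

#' Serialize components + estimates as CSV rows
#' @param components named list of [EnergyComponents-class] keyed by
#'   compound id.
#' @param path output CSV.
#' @param model a [NonbondedModel-class] for the pIC50 conversion.
#' @return the written data.frame, invisibly.
#' @export
writeComponentsCSV <- function(components, path, model = nonbondedModel()) {
  rows <- lapply(names(components), function(id) {
    cm <- components[[id]]
    est <- bindingFreeEnergy(cm, model)
    data.frame(compound_id = id, e_interaction = cm@e_interaction,
               e_strain = cm@e_strain, dg_desolvation = cm@dg_desolvation,
               tds_rotors = cm@tds_rotors, e_induced_fit = cm@e_induced_fit,
               delta_g = est@delta_g, pic50 = est@pic50)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
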