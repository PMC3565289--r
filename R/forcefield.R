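# Nonbonded energy terms and ligand-residue / ligand-protein energies.
#
# Committed functional forms: 12-6 Lennard-Jones with arithmetic-mean sigma
# and geometric-mean epsilon combining; Coulomb with k = 332.06
# kcal A/(mol e^2) and either a constant or distance-dependent dielectric;
# a directional 10-12 hydrogen-bond term gated by cos^2(theta).
# Polarization and metal-ligand terms of the original scoring function are
# not implemented (logged once per session).

.note_unimplemented_terms <- local({
  done <- FALSE
  function() {
    if (!done) {
      message("note: polarization and metal-ligand terms are not implemented")
      done <<- TRUE
    }
  }
})

#' Lennard-Jones 12-6 van der Waals energy of an atom pair
#'
#' @param params_i,params_j lists/rows with `sigma` (A) and `epsilon`
#'   (kcal/mol) for the two atoms.
#' @param r interatomic distance (A), may be a vector.
#' @param cutoff energies are 0 beyond this distance (default Inf).
#' @return kcal/mol.
#' @export
vdwEnergy <- function(params_i, params_j, r, cutoff = Inf) {
  if (any(r <= 0))
    .afp_stop("vdW energy singular at r = 0", "afp_singularity")
  sig <- (params_i$sigma + params_j$sigma) / 2
  eps <- sqrt(params_i$epsilon * params_j$epsilon)
  sr6 <- (sig / r)^6
  e <- 4 * eps * (sr6^2 - sr6)
  e[r > cutoff] <- 0
  e
}

#' Coulomb electrostatic energy of a charge pair
#'
#' Constant mode: k q_i q_j / (eps r).  Distance-dependent mode uses an
#' effective dielectric eps * r.
#'
#' @param q_i,q_j partial charges (e).
#' @param r distance (A), may be a vector.
#' @param model a [NonbondedModel-class].
#' @return kcal/mol.
#' @export
elecEnergy <- function(q_i, q_j, r, model = nonbondedModel()) {
  if (any(r <= 0))
    .afp_stop("electrostatic energy singular at r = 0", "afp_singularity")
  eps_eff <- if (model@dielectric_mode == "distance")
    model@dielectric_value * r else model@dielectric_value
  e <- model@coulomb_constant * q_i * q_j / (eps_eff * r)
  e[r > model@cutoff] <- 0
  e
}

#' Directional hydrogen-bond energy
#'
#' 10-12 radial well, eps_hb * (5 (sigma/r)^12 - 6 (sigma/r)^10), scaled by
#' cos^2(theta) for D-H...A angles >= 90 degrees and zero otherwise.  At
#' r = sigma_hb and theta = 180 the term is exactly -eps_hb.
#'
#' @param r_DA donor-acceptor distance (A).
#' @param theta_DHA D-H...A angle in degrees (vertex at H).
#' @param eps_hb well depth, kcal/mol (default 2.0).
#' @param sigma_hb optimum D-A distance, A (default 2.9).
#' @param cutoff zero beyond this distance (default 5.0 A).
#' @return kcal/mol.
#' @export
hbondEnergy <- function(r_DA, theta_DHA, eps_hb = 2.0, sigma_hb = 2.9,
                        cutoff = 5.0) {
  if (any(r_DA <= 0))
    .afp_stop("hydrogen-bond energy singular at r = 0", "afp_singularity")
  sr <- sigma_hb / r_DA
  radial <- eps_hb * (5 * sr^12 - 6 * sr^10)
  ang <- cos(theta_DHA * pi / 180)^2
  e <- radial * ang
  e[theta_DHA < 90] <- 0
  e[r_DA > cutoff] <- 0
  e
}

# vectorised pair energy between two atom index sets of one system/frame;
# returns the summed vdW + electrostatic energy.
.pair_energy_sum <- function(xyz, at, idx_a, idx_b, model, overrides = NULL) {
  pa <- elementParams(at$element[idx_a], overrides)
  pb <- elementParams(at$element[idx_b], overrides)
  A <- xyz[idx_a, , drop = FALSE]
  B <- xyz[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-9))
    .afp_stop("overlapping atoms (r = 0) in pair energy", "afp_singularity")
  sig <- outer(pa$sigma, pb$sigma, "+") / 2
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  sr6 <- (sig / d)^6
  evdw <- 4 * eps * (sr6^2 - sr6)
  eps_eff <- if (model@dielectric_mode == "distance")
    model@dielectric_value * d else model@dielectric_value
  eel <- model@coulomb_constant *
    outer(at$charge[idx_a], at$charge[idx_b]) / (eps_eff * d)
  mask <- d <= model@cutoff
  sum((evdw + eel)[mask])
}

#' Ligand-residue interaction energy
#'
#' Sum of pairwise van der Waals and electrostatic terms over all
#' ligand x residue atom pairs.  No hydrogen-bond term is included here,
#' matching the per-residue energy definition used for dynamic profiles.
#'
#' @param system a [MolecularSystem-class] with charges assigned.
#' @param ligand integer atom indices of the ligand.
#' @param residue integer atom indices of the residue, or a residue label.
#' @param model a [NonbondedModel-class].
#' @param overrides optional parameter overrides.
#' @return kcal/mol.
#' @export
residueInteraction <- function(system, ligand, residue,
                               model = nonbondedModel(), overrides = NULL) {
  if (is.character(residue)) residue <- residueAtomIndices(system, residue)
  if (length(ligand) == 0 || length(residue) == 0)
    .afp_stop("empty selection in residueInteraction", "afp_precondition")
  .pair_energy_sum(coords(system), system@atoms, ligand, residue, model,
                   overrides)
}

# hydrogen-bond geometry detection between two atom sets.  Donors are N/O
# with a bonded H; acceptors are N/O.  Returns data.frame of D, H, A
# indices with distances and angles.
.find_hbond_pairs <- function(system, set_a, set_b, max_da = 5.0) {
  at <- system@atoms
  bm <- system@bonds
  xyz <- coords(system)
  h_of <- function(i) {
    nb <- c(bm[bm[, 1] == i, 2], bm[bm[, 2] == i, 1])
    nb[at$element[nb] == "H"]
  }
  polar <- function(set) set[at$element[set] %in% c("N", "O")]
  res <- list()
  for (dir in 1:2) {
    dset <- polar(if (dir == 1) set_a else set_b)
    aset <- polar(if (dir == 1) set_b else set_a)
    dset <- dset[vapply(dset, function(i) length(h_of(i)) > 0, logical(1))]
    for (D in dset) {
      for (A in aset) {
        r <- sqrt(sum((xyz[D, ] - xyz[A, ])^2))
        if (r > max_da || r < 1e-6) next
        best <- -Inf
        for (H in h_of(D)) {
          v1 <- xyz[D, ] - xyz[H, ]
          v2 <- xyz[A, ] - xyz[H, ]
          ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
          if (theta > best) best <- theta
        }
        res[[length(res) + 1]] <- data.frame(donor = D, acceptor = A,
                                             r = r, theta = best)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(donor = integer(), acceptor = integer(),
                      r = numeric(), theta = numeric()))
  do.call(rbind, res)
}

#' Total ligand-protein interaction energy
#'
#' Sum of [residueInteraction()] over all non-ligand residues plus the
#' directional hydrogen-bond term over detected donor-acceptor pairs
#' between ligand and protein.
#'
#' @param system a [MolecularSystem-class] with bonds perceived and charges
#'   assigned.
#' @param ligand integer atom indices of the ligand.
#' @param model a [NonbondedModel-class].
#' @param eps_hb,sigma_hb hydrogen-bond well parameters.
#' @param overrides optional parameter overrides.
#' @param includeWaters include water residues (default FALSE).
#' @return list with `total`, `vdw_elec`, `hbond` (kcal/mol) and the
#'   per-residue breakdown.
#' @export
ligandProteinEnergy <- function(system, ligand, model = nonbondedModel(),
                                eps_hb = 2.0, sigma_hb = 2.9,
                                overrides = NULL, includeWaters = FALSE) {
  .note_unimplemented_terms()
  labs <- residueLabels(system)
  lig_labs <- unique(labs[ligand])
  other_labs <- setdiff(unique(labs), lig_labs)
  if (!includeWaters) {
    rn <- system@atoms$resname[match(other_labs, labs)]
    other_labs <- other_labs[!(rn %in% .WATER_RESNAMES)]
  }
  per_res <- vapply(other_labs, function(lab)
    residueInteraction(system, ligand, lab, model, overrides), numeric(1))
  prot_idx <- which(labs %in% other_labs)
  hb <- .find_hbond_pairs(system, ligand, prot_idx)
  e_hb <- if (nrow(hb)) sum(hbondEnergy(hb$r, hb$theta, eps_hb, sigma_hb))
          else 0
  list(total = sum(per_res) + e_hb, vdw_elec = sum(per_res), hbond = e_hb,
       per_residue = stats::setNames(per_res, other_labs))
}
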