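# Receptor-surrogate envelope construction and pose scoring.

# classify heavy ligand atoms into the interaction classes used by the
# particle-property compatibility table.  Hydrogens get NA (they are
# represented through their heavy donor).
.atom_classes <- function(system) {
  at <- system@atoms
  bm <- system@bonds
  has_h <- rep(FALSE, nrow(at))
  if (nrow(bm) > 0) {
    ish <- at$element == "H"
    has_h[bm[ish[bm[, 2]], 1]] <- TRUE
    has_h[bm[ish[bm[, 1]], 2]] <- TRUE
  }
  cls <- rep(NA_integer_, nrow(at))
  for (i in seq_len(nrow(at))) {
    el <- at$element[i]
    if (el == "H") next
    q <- at$charge[i]
    cls[i] <- if (q >= 0.5) 4L
    else if (q <= -0.5) 5L
    else if (el %in% c("N", "O") && has_h[i]) 2L
    else if (el %in% c("N", "O")) 3L
    else 1L
  }
  cls
}

# greedy minimum-distance thinning; factor calibrated so the retained
# areal density is ~1/spacing^2 on a sphere
.THIN_FACTOR <- 0.93

#' Build the surrogate envelope from training pose ensembles
#'
#' Particles are placed on the solvent-contact surface (vdW radius + probe
#' offset) of the union of all poses of all training ligands, then thinned
#' to the requested `spacing` resolution.  Deterministic for a fixed input
#' order.
#'
#' @param ensembles list of [PoseEnsemble-class] objects (>= 1).
#' @param spacing particle spacing in A (default 0.8).
#' @param probe radial offset from the vdW surface (default 1.4 A, the
#'   solvent-contact surface).
#' @param oversample candidate sphere points generated per retained
#'   particle (default 10; controls surface sampling density).
#' @param overrides optional parameter overrides.
#' @return An [Envelope-class].
#' @export
buildEnvelope <- function(ensembles, spacing = 0.8, probe = 1.4,
                          oversample = 10, overrides = NULL) {
  if (length(ensembles) == 0)
    .afp_stop("need at least one pose ensemble", "afp_precondition")
  if (spacing <= 0) .afp_stop("spacing must be positive", "afp_precondition")
  if (is(ensembles, "PoseEnsemble")) ensembles <- list(ensembles)
  systems <- unlist(lapply(ensembles, function(e) e@poses))
  xyz <- do.call(rbind, lapply(systems, coords))
  elements <- unlist(lapply(systems, function(s) s@atoms$element))
  heavy <- elements != "H"
  xyz <- xyz[heavy, , drop = FALSE]
  rad <- elementParams(elements[heavy], overrides)$vdw_radius + probe
  # near-coincident atoms (heavily overlapping poses) contribute the same
  # surface: merge them to keep the candidate set tractable
  gk <- paste(round(xyz[, 1] / 0.25), round(xyz[, 2] / 0.25),
              round(xyz[, 3] / 0.25), round(rad, 2))
  keep_atom <- !duplicated(gk)
  xyz <- xyz[keep_atom, , drop = FALSE]
  rad <- rad[keep_atom]

  # candidate points on each expanded sphere, dropped when inside another
  cand <- vector("list", nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    n_i <- max(64L, min(6000L,
                        ceiling(oversample * 4 * pi * rad[i]^2 / spacing^2)))
    pts <- sweep(.sphere_points(n_i) * rad[i], 2, xyz[i, ], "+")
    inside <- rep(FALSE, nrow(pts))
    dc2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(dc2 < (rad[i] + rad)^2 & seq_len(nrow(xyz)) != i)
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      inside <- inside | dj2 < (rad[j] - 1e-6)^2
    }
    cand[[i]] <- pts[!inside, , drop = FALSE]
  }
  pts <- do.call(rbind, cand)
  if (nrow(pts) == 0)
    .afp_stop("no surface points survive; degenerate geometry",
              "afp_precondition")

  # sequential greedy thinning with cell hashing
  min_d <- .THIN_FACTOR * spacing
  cell <- floor(pts / min_d)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  kept <- matrix(numeric(), 0, 3)
  kept_keys <- new.env(hash = TRUE, parent = emptyenv())
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keep_idx <- logical(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    ok <- TRUE
    for (o in seq_len(27)) {
      kk <- paste(cell[k, 1] + offs[o, 1], cell[k, 2] + offs[o, 2],
                  cell[k, 3] + offs[o, 3])
      prev <- kept_keys[[kk]]
      if (!is.null(prev)) {
        d2 <- (pts[prev, 1] - pts[k, 1])^2 + (pts[prev, 2] - pts[k, 2])^2 +
          (pts[prev, 3] - pts[k, 3])^2
        if (any(d2 < min_d^2)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      keep_idx[k] <- TRUE
      kk <- key[k]
      kept_keys[[kk]] <- c(kept_keys[[kk]], k)
    }
  }
  new("Envelope", positions = pts[keep_idx, , drop = FALSE],
      center = colMeans(xyz), spacing = spacing, offset = probe)
}

# dilated particle positions for an induced-fit scenario (0..5 ->
# 0..0.5 A radially outward from the envelope center)
.dilated_positions <- function(envelope, scenario) {
  d <- 0.1 * scenario
  if (d == 0) return(envelope@positions)
  v <- sweep(envelope@positions, 2, envelope@center, "-")
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm < 1e-9] <- 1
  envelope@positions + v / nrm * d
}

# P x 7 matrix of per-particle, per-property contributions for one pose:
# row p = compat[, class(nearest heavy atom)] * contact_weight(distance),
# zero when no heavy atom lies within the interaction range.
.pose_feature_matrix <- function(pose, envelope, scenario = 0L) {
  cls <- .atom_classes(pose)
  heavy <- which(!is.na(cls))
  if (length(heavy) == 0)
    .afp_stop("pose has no classifiable heavy atoms", "afp_param_missing")
  pp <- .dilated_positions(envelope, scenario)
  axyz <- coords(pose)[heavy, , drop = FALSE]
  d2 <- outer(rowSums(pp^2), rowSums(axyz^2), "+") - 2 * pp %*% t(axyz)
  nn <- max.col(-d2, ties.method = "first")
  dn <- sqrt(pmax(d2[cbind(seq_len(nrow(pp)), nn)], 0))
  w <- .contact_weight(dn)
  M <- t(.COMPAT_TABLE[, cls[heavy][nn], drop = FALSE]) * w
  dimnames(M) <- NULL
  M  # P x 7
}

# solvation proxy of a pose (used by the solvent-exposed scenario)
.pose_solv_proxy <- function(pose) {
  desolvationEnergy(pose, probe = 1.4, points = 480)
}

.SOLV_SCENARIO_SCALE <- c(0, -0.25)  # buried, solvent-exposed

#' Score one pose against a surrogate model
#'
#' Sum over envelope particles of the property-compatibility energy with
#' the nearest ligand heavy atom within the interaction range (void
#' particles contribute 0), plus the induced-fit dilation penalty, the
#' solvation-scenario surface correction and the scaffold base energy.
#'
#' @param model a [SurrogateModel-class].
#' @param pose a ligand-only [MolecularSystem-class] with bonds perceived
#'   and charges assigned.
#' @return kcal/mol (a pseudo binding free energy; negative = favourable).
#' @export
scorePose <- function(model, pose) {
  M <- .pose_feature_matrix(pose, model@envelope, model@induced_fit_scenario)
  part <- sum(M[cbind(seq_along(model@labels), model@labels)])
  pen <- model@induced_fit_penalty * 0.1 * model@induced_fit_scenario
  solv <- .SOLV_SCENARIO_SCALE[model@solvation_scenario + 1L] *
    .pose_solv_proxy(pose)
  model@base_energy + part + pen + solv
}
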