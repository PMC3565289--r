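# Bundled element parameter tables and error helpers.
#
# The tables are deliberately minimal (organic elements + halogens + common
# ions): sigma/epsilon are OPLS-flavoured Lennard-Jones parameters, covalent
# radii are the classic single-bond values, vdW radii are Bondi, and the
# atomic solvation parameters (kcal/(mol A^2)) price the cost of stripping
# the first hydration shell from exposed surface (polar atoms cost more).

.afp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "afp_error"), call = call))
}

.afp_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "afp_warning")))
}

.ELEMENTS <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
              "NA", "K", "MG", "CA", "ZN", "FE"),
  covalent_radius = c(0.37, 0.77, 0.75, 0.66, 1.04, 1.10, 0.71, 0.99,
                      1.14, 1.33, 1.54, 1.96, 1.36, 1.74, 1.25, 1.25),
  vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75,
                 1.85, 1.98, 2.27, 2.75, 1.73, 2.31, 1.39, 1.40),
  sigma = c(2.50, 3.50, 3.25, 3.12, 3.55, 3.74, 2.94, 3.40,
            3.47, 3.55, 3.33, 4.06, 2.91, 3.47, 2.46, 2.59),
  epsilon = c(0.030, 0.066, 0.170, 0.170, 0.250, 0.200, 0.061, 0.300,
              0.470, 0.600, 0.003, 0.0003, 0.875, 0.450, 0.250, 0.013),
  solvation_parameter = c(0.000, 0.005, 0.022, 0.025, 0.015, 0.015, 0.010,
                          0.008, 0.008, 0.008, 0.030, 0.030, 0.040, 0.040,
                          0.040, 0.040),
  stringsAsFactors = FALSE
)

.norm_element <- function(element) toupper(trimws(element))

#' Bundled per-element force-field parameters
#'
#' Looks up Lennard-Jones sigma/epsilon, covalent and van der Waals radii
#' and the atomic solvation parameter for one or more elements.  User
#' overrides can be supplied as a data.frame with an `element` column plus
#' any of the parameter columns.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param overrides optional data.frame of overrides (columns `element`,
#'   then any of `sigma`, `epsilon`, `covalent_radius`, `vdw_radius`,
#'   `solvation_parameter`).
#' @return data.frame with one row per requested element.
#' @export
elementParams <- function(element, overrides = NULL) {
  tab <- .ELEMENTS
  if (!is.null(overrides)) {
    ov <- overrides
    ov$element <- .norm_element(ov$element)
    for (i in seq_len(nrow(ov))) {
      j <- match(ov$element[i], tab$element)
      cols <- intersect(names(ov), setdiff(names(tab), "element"))
      if (is.na(j)) {
        row <- tab[1, ]
        row$element <- ov$element[i]
        row[cols] <- ov[i, cols]
        tab <- rbind(tab, row)
      } else {
        tab[j, cols] <- ov[i, cols]
      }
    }
  }
  el <- .norm_element(element)
  j <- match(el, tab$element)
  if (anyNA(j))
    .afp_stop(paste("no parameters for element(s):",
                    paste(unique(el[is.na(j)]), collapse = ", ")),
              "afp_param_missing")
  out <- tab[j, ]
  rownames(out) <- NULL
  out
}

#' Read a parameter override file
#'
#' CSV with header `element,sigma,epsilon,solvation_parameter` (any subset
#' of the value columns is allowed).
#'
#' @param path CSV file path.
#' @return data.frame suitable for the `overrides` argument of
#'   [elementParams()].
#' @export
readParamOverrides <- function(path) {
  ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"element" %in% names(ov))
    .afp_stop("override file needs an 'element' column", "afp_format_error")
  ov
}

# Water residue names and the ligand-candidacy exclusions.
.WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "SOL")

# Particle-property vs ligand-atom-class compatibility energies (kcal/mol).
# Rows follow PROPERTY_LABELS, columns the atom classes.  Favourable
# pairings (hydrophobic contact, donor<->acceptor, salt bridges) are
# negative; mismatches (polar group against a hydrophobic particle, like
# charges) carry a positive desolvation-like penalty; void rows are inert.
.ATOM_CLASSES <- c("nonpolar", "donor", "acceptor", "positive", "negative")

.COMPAT_TABLE <- matrix(c(
  # nonpolar  donor  acceptor positive negative
    -0.45,    0.35,   0.35,    0.55,    0.55,   # hydrophobic
     0.25,    0.45,  -0.90,    0.60,   -0.30,   # donor particle
     0.25,   -0.90,   0.45,   -0.30,    0.60,   # acceptor particle
     0.40,   -0.10,  -0.35,    1.10,   -1.30,   # positive
     0.40,   -0.35,  -0.10,   -1.30,    1.10,   # negative
    -0.05,   -0.05,  -0.05,   -0.05,   -0.05,   # neutral
     0.00,    0.00,   0.00,    0.00,    0.00    # void
), nrow = 7, byrow = TRUE,
  dimnames = list(PROPERTY_LABELS, .ATOM_CLASSES)) * 0.35
# the 0.35 factor calibrates the per-contact magnitudes so that toy-ligand
# affinity spreads match the 3.7..8.6 pIC50 range typical of a mannoside
# inhibitor series

#' Particle-atom property compatibility table
#'
#' The bundled pairwise energy table (kcal/mol) used by the surrogate
#' scoring: particle property label (rows) against ligand atom class
#' (columns).
#'
#' @return numeric matrix 7 x 5.
#' @export
compatibilityTable <- function() .COMPAT_TABLE

# Distance response of a particle-atom contact: 1 at the optimum distance,
# Gaussian falloff, hard zero beyond the interaction range.
.CONTACT_R_OPT <- 3.0
.CONTACT_WIDTH <- 1.5
.CONTACT_RANGE <- 6.0

.contact_weight <- function(r) {
  w <- exp(-(r - .CONTACT_R_OPT)^2 / (2 * .CONTACT_WIDTH^2))
  w[r > .CONTACT_RANGE] <- 0
  w
}

# MD protocol provenance constants (recorded in profile metadata only;
# simulations themselves are out of scope).
.MD_PROVENANCE <- list(
  water_model = "TIP3P", box_margin_A = 10, salt_M = 0.15,
  minimization_gradient_kcal_mol_A = 1.0, ensemble = "NPT",
  temperature_K = 300, force_field = "OPLS2005-like (vdW + electrostatic)",
  relaxation_ps = 24
)
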