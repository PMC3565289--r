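# shared in-code fixtures; no files, everything generated at test time

atom_row <- function(serial, name, element, x, y, z, charge = 0,
                     resname = "LIG", chain = "A", resseq = 1L,
                     hetero = TRUE) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, chain = chain, resseq = as.integer(resseq),
             icode = "", x = x, y = y, z = z, charge = charge,
             hetero = hetero, stringsAsFactors = FALSE)
}

# a straight heavy-atom chain along x (element vector, spacing in A)
chain_system <- function(elements, spacing = 1.54, charges = 0, ...) {
  n <- length(elements)
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    atom_row(i, paste0(elements[i], i), elements[i],
             (i - 1) * spacing, 0, 0,
             charge = rep_len(charges, n)[i], ...)))
  perceiveBonds(molecularSystem(df))
}

single_atom_system <- function(element = "C", charge = 0, x = 0, y = 0,
                               z = 0) {
  molecularSystem(atom_row(1L, element, element, x, y, z, charge))
}

# a one-particle envelope at a fixed position, for scoring unit tests
point_envelope <- function(positions, center = c(0, 0, 0), spacing = 1) {
  new("Envelope", positions = matrix(positions, ncol = 3, byrow = TRUE),
      center = center, spacing = spacing, offset = 1.4)
}

# the kcal/mol per pIC50 unit at the default 300 K, computed independently
PIC50_SLOPE <- log(10) * 0.0019872 * 300
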