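# Side-chain measurement and rebuilding in chi-angle space.

#' Measure the chi dihedrals of one residue
#' @param structure a `ComplexStructure`.
#' @param rid global residue id (row of `structure$topology$residues`).
#' @return numeric vector of chi angles in degrees (length 0 for ALA/GLY).
#' @export
measure_chi <- function(structure, rid) {
  top <- structure$topology
  rows <- top$chi_table[top$chi_table[, 1] == rid, , drop = FALSE]
  if (nrow(rows) == 0) return(numeric(0))
  xyz <- get_coords(structure)
  out <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    ii <- rows[i, 3:6]
    out[rows[i, 2]] <- dihedral_angle(xyz[ii[1], ], xyz[ii[2], ],
                                      xyz[ii[3], ], xyz[ii[4], ])
  }
  out
}

#' Rebuild the side chain of one residue at given chi angles
#'
#' Side-chain atoms are rebuilt from the residue's current backbone with
#' ideal template geometry; backbone atoms are untouched.
#'
#' @param structure a `ComplexStructure`.
#' @param rid global residue id.
#' @param chi chi angles in degrees (length must match the residue type).
#' @return the updated `ComplexStructure`.
#' @export
set_residue_chi <- function(structure, rid, chi) {
  top <- structure$topology
  rn <- top$residues$resname[rid]
  if (length(chi) != n_chi(rn))
    abort_rc("EmptyLibrary", "residue %s expects %d chi angles, got %d",
             rn, n_chi(rn), length(chi))
  am <- top$amap[[rid]]
  xyz <- get_coords(structure)
  sc <- build_sidechain_coords(rn, xyz[am[["N"]], ], xyz[am[["CA"]], ],
                               xyz[am[["C"]], ], chi)
  for (nm in names(sc)) {
    i <- am[[nm]]
    if (!is.null(i) && !is.na(i)) xyz[i, ] <- sc[[nm]]
  }
  set_coords(structure, xyz)
}

# global residue id for (chain, resi) pairs
residue_id <- function(structure, chain, resi) {
  rt <- structure$topology$residues
  match(paste(chain, resi), paste(rt$chain, rt$resi))
}
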