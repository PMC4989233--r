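# ComplexStructure: the internal representation of one protein-protein
# complex model, plus PDB input/output and Cn-symmetry operations.

#' Construct a ComplexStructure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (author numbering),
#'   `resi` (sequential 1..N per chain), `resname`, `name`, `x`, `y`, `z`.
#' @param provenance free-text tag recording where the structure came from.
#' @return an object of class `ComplexStructure`: a list with the completed
#'   atom table (element, backbone flag, partial charge, vdW parameters,
#'   mass added), per-chain sequences, and a cached molecular-mechanics
#'   topology.
#' @export
new_complex_structure <- function(atoms, provenance = "constructed") {
  req <- c("chain", "resno", "resi", "resname", "name", "x", "y", "z")
  stopifnot(all(req %in% names(atoms)))
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resi), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  if (anyDuplicated(paste(atoms$chain, atoms$resi, atoms$name)))
    abort_rc("MalformedPDB", "duplicate (chain, residue, atom) records")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    abort_rc("MalformedPDB", "non-finite coordinates")
  # every residue must carry the full backbone
  rid <- paste(atoms$chain, atoms$resi)
  for (r in unique(rid)) {
    nms <- atoms$name[rid == r]
    miss <- setdiff(BACKBONE_ATOMS, nms)
    if (length(miss))
      abort_rc("IncompleteBackbone", "residue %s is missing backbone atom(s) %s",
               r, paste(miss, collapse = ","))
  }
  atoms$element <- element_of(atoms$name)
  bad <- !atoms$element %in% names(ELEMENT_PARAMS)
  if (any(bad))
    abort_rc("ParameterMissing", "unknown element for atom(s) %s",
             paste(unique(atoms$name[bad]), collapse = ","))
  atoms$backbone <- atoms$name %in% BACKBONE_ATOMS
  ep <- ELEMENT_PARAMS[atoms$element]
  atoms$mass <- vapply(ep, `[[`, numeric(1), "mass")
  atoms$radius <- vapply(ep, `[[`, numeric(1), "radius")
  atoms$eps <- vapply(ep, `[[`, numeric(1), "eps")
  atoms$charge <- mapply(atom_charge, atoms$resname, atoms$name)

  x <- list(atoms = atoms,
            sequences = chain_sequences_from_atoms(atoms),
            provenance = provenance,
            topology = build_topology(atoms))
  class(x) <- "ComplexStructure"
  x
}

chain_sequences_from_atoms <- function(atoms) {
  ca <- atoms[atoms$name == "CA", ]
  split_seq <- split(ca$resname, ca$chain)
  vapply(split_seq[unique(atoms$chain)],
         function(rn) paste(AA1[rn], collapse = ""), character(1))
}

#' @export
print.ComplexStructure <- function(x, ...) {
  nres <- sum(x$atoms$name == "CA")
  cat(sprintf("ComplexStructure: %d chains (%s), %d residues, %d atoms [%s]\n",
              length(x$sequences), paste(names(x$sequences), collapse = ","),
              nres, nrow(x$atoms), x$provenance))
  invisible(x)
}

#' Extract the coordinate matrix of a structure
#' @param structure a `ComplexStructure`.
#' @return an n x 3 numeric matrix (Angstrom).
#' @export
get_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure a `ComplexStructure`.
#' @param xyz n x 3 matrix matching the atom table.
#' @param provenance optional new provenance tag.
#' @return the updated `ComplexStructure` (topology is retained: atom
#'   identities are unchanged).
#' @export
set_coords <- function(structure, xyz, provenance = NULL) {
  stopifnot(nrow(xyz) == nrow(structure$atoms))
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  if (!is.null(provenance)) structure$provenance <- provenance
  structure
}

chain_ids <- function(structure) unique(structure$atoms$chain)

# atom indices of one chain
chain_atom_idx <- function(structure, chain) which(structure$atoms$chain == chain)

# indices of CA atoms of one chain, ordered by residue
chain_ca_idx <- function(structure, chain) {
  a <- structure$atoms
  which(a$chain == chain & a$name == "CA")
}

STANDARD_ALTLOC <- c("", " ", "A")

#' Read a protein complex model from a PDB file
#'
#' Hydrogens are dropped, alternate locations are resolved to altloc "A" or
#' blank, HETATM / non-standard residues are skipped with a warning, and
#' residues are re-indexed sequentially per chain (author numbering is kept
#' for output). Every residue must carry a complete N/CA/C/O backbone.
#'
#' @param path PDB file path.
#' @param mode `"heteromer"` (default) or `"symmetric"`; symmetric mode
#'   additionally requires all chains to share one sequence.
#' @return a [new_complex_structure()] object.
#' @export
read_pdb <- function(path, mode = c("heteromer", "symmetric")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort_rc("MalformedPDB", "file not found: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort_rc("MalformedPDB",
                                               "cannot parse %s: %s", path,
                                               conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% STANDARD_ALTLOC, , drop = FALSE]
  nonstd <- !at$resid %in% AA3
  if (any(nonstd)) {
    warning(sprintf("skipping %d atoms in non-standard residues (%s)",
                    sum(nonstd), paste(unique(at$resid[nonstd]), collapse = ",")))
    at <- at[!nonstd, , drop = FALSE]
  }
  # drop hydrogens and atoms outside the heavy-atom templates (e.g. OXT)
  is_h <- grepl("^[0-9]*H", at$elety)
  at <- at[!is_h, , drop = FALSE]
  keep <- mapply(function(rn, nm) nm %in% residue_atom_names(rn),
                 at$resid, at$elety)
  if (any(!keep))
    warning(sprintf("dropping %d atoms outside residue templates (%s)",
                    sum(!keep), paste(unique(at$elety[!keep]), collapse = ",")))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) abort_rc("MalformedPDB", "no usable ATOM records in %s", path)
  chains <- unique(at$chain)
  if (length(chains) < 2)
    abort_rc("ChainCountError", "need >= 2 chains, found %d", length(chains))
  # sequential residue index per chain, in order of appearance
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resname = at$resid, name = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$resi <- NA_integer_
  for (ch in chains) {
    sel <- atoms$chain == ch
    atoms$resi[sel] <- match(atoms$resno[sel], unique(atoms$resno[sel]))
  }
  s <- new_complex_structure(atoms, provenance = basename(path))
  if (mode == "symmetric" && length(unique(s$sequences)) != 1)
    abort_rc("SequenceMismatch", "symmetric mode requires identical chain sequences")
  s
}

#' Write a structure as a PDB file
#'
#' Emits standard ATOM records (3-decimal coordinates), TER records between
#' chains and a terminating END record, preserving chain identifiers and
#' author residue numbering.
#'
#' @param structure a `ComplexStructure`.
#' @param path output file path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  n <- nrow(a)
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = as.integer(a$resno), resid = a$resname,
                     eleno = seq_len(n), elety = a$name,
                     chain = a$chain, o = rep(1, n), b = rep(0, n),
                     chainter = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    abort_rc("IOError", "cannot write PDB to %s", path)
  invisible(NULL)
}

#' Estimate the Cn symmetry transforms of a homo-oligomer
#'
#' For each chain k, computes the least-squares rigid transform (Kabsch
#' superposition over CA atoms) mapping chain 1 onto chain k. Transform 1 is
#' exactly the identity.
#'
#' @param structure a `ComplexStructure` whose chains share one sequence.
#' @return a `SymmetryGroup`: list with `n_copies`, `transforms` (list of
#'   `list(R, t)`), and `fit_rmsd` (per-chain fit residual, Angstrom).
#' @export
estimate_symmetry <- function(structure) {
  if (length(unique(structure$sequences)) != 1)
    abort_rc("SequenceMismatch", "chains differ in sequence")
  chains <- chain_ids(structure)
  xyz <- get_coords(structure)
  ca1 <- chain_ca_idx(structure, chains[1])
  if (length(ca1) < 3) abort_rc("DegenerateGeometry", "chain with < 3 CA atoms")
  transforms <- list(list(R = diag(3), t = c(0, 0, 0)))
  fit_rmsd <- 0
  for (k in seq_along(chains)[-1]) {
    cak <- chain_ca_idx(structure, chains[k])
    if (length(cak) != length(ca1))
      abort_rc("SequenceMismatch", "chains differ in residue count")
    fit <- kabsch(xyz[ca1, , drop = FALSE], xyz[cak, , drop = FALSE])
    transforms[[k]] <- list(R = fit$R, t = fit$t)
    fit_rmsd[k] <- fit$rmsd
  }
  g <- list(n_copies = length(chains), transforms = transforms,
            fit_rmsd = fit_rmsd, chains = chains)
  class(g) <- "SymmetryGroup"
  g
}

#' @export
print.SymmetryGroup <- function(x, ...) {
  cat(sprintf("SymmetryGroup: C%d, fit RMSD %s A\n", x$n_copies,
              paste(sprintf("%.3g", x$fit_rmsd), collapse = "/")))
  invisible(x)
}

# map atoms of chain k onto the atom order of chain 1 (by residue index +
# atom name); returns an index vector into the structure's atom table
chain_atom_map <- function(structure, chain, ref_key) {
  idx <- chain_atom_idx(structure, chain)
  key <- paste(structure$atoms$resi[idx], structure$atoms$name[idx])
  idx[match(ref_key, key)]
}

#' Project a structure onto exact Cn symmetry
#'
#' Maps every chain into chain 1's frame with the inverse symmetry
#' transforms, averages the coordinates over chains (the consensus chain),
#' and re-applies the transforms, yielding chains that are exactly related
#' by the group's transforms.
#'
#' @param structure a `ComplexStructure`.
#' @param group a `SymmetryGroup` from [estimate_symmetry()] with
#'   `n_copies` equal to the chain count.
#' @return the symmetrized `ComplexStructure` (same atoms, new coordinates).
#' @export
enforce_symmetry <- function(structure, group) {
  chains <- chain_ids(structure)
  if (length(chains) != group$n_copies)
    abort_rc("GroupMismatch", "structure has %d chains, group expects %d",
             length(chains), group$n_copies)
  xyz <- get_coords(structure)
  idx1 <- chain_atom_idx(structure, chains[1])
  ref_key <- paste(structure$atoms$resi[idx1], structure$atoms$name[idx1])
  maps <- lapply(chains, function(ch) chain_atom_map(structure, ch, ref_key))
  if (any(vapply(maps, anyNA, logical(1))))
    abort_rc("GroupMismatch", "chains do not share a common atom set")
  consensus <- matrix(0, length(idx1), 3)
  for (k in seq_along(chains)) {
    tr <- group$transforms[[k]]
    inv <- invert_transform(tr$R, tr$t)
    consensus <- consensus +
      apply_transform(xyz[maps[[k]], , drop = FALSE], inv$R, inv$t)
  }
  consensus <- consensus / length(chains)
  out <- xyz
  for (k in seq_along(chains)) {
    tr <- group$transforms[[k]]
    out[maps[[k]], ] <- apply_transform(consensus, tr$R, tr$t)
  }
  set_coords(structure, out)
}
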