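# CAPRI-style model quality assessment: ligand RMSD, interface RMSD,
# fraction of native contacts, and the high/medium/acceptable/incorrect
# classification.

BB_RMSD_ATOMS <- c("N", "CA", "C", "O")

#' Build the chain mapping between a model and a reference
#'
#' Pairs model and reference chains (by chain id when the id sets match,
#' else by order), checks that mapped residues agree in type, and assigns
#' receptor/ligand roles: the receptor is the larger chain set by atom
#' count (tie: the first chain) unless roles are given explicitly.
#'
#' @param model,reference `ComplexStructure` objects.
#' @param receptor_chains,ligand_chains optional character vectors of
#'   reference chain ids fixing the roles.
#' @return a `ChainMapping`: list with `chains` (model id per reference id),
#'   `receptor`, `ligand` (reference chain ids) and `atom_map` (model atom
#'   index for each reference atom, NA if absent).
#' @export
chain_mapping <- function(model, reference, receptor_chains = NULL,
                          ligand_chains = NULL) {
  rch <- chain_ids(reference)
  mch <- chain_ids(model)
  if (length(rch) != length(mch))
    abort_rc("MappingError", "model and reference differ in chain count")
  chains <- if (setequal(rch, mch)) setNames(rch, rch) else setNames(mch, rch)
  ra <- reference$atoms
  ma <- model$atoms
  rkey <- paste(ra$chain, ra$resi, ra$name)
  mkey <- paste(chains[ra$chain], ra$resi, ra$name)
  atom_map <- match(mkey, paste(ma$chain, ma$resi, ma$name))
  # mapped residues must share amino-acid type
  ok <- !is.na(atom_map)
  if (!any(ok)) abort_rc("MappingError", "no common atoms between model and reference")
  if (any(ra$resname[ok] != ma$resname[atom_map[ok]]))
    abort_rc("MappingError", "mapped residues differ in amino-acid type")
  if (is.null(receptor_chains)) {
    counts <- table(ra$chain)[rch]
    receptor_chains <- rch[which.max(counts)]
    ligand_chains <- setdiff(rch, receptor_chains)
  } else if (is.null(ligand_chains)) {
    ligand_chains <- setdiff(rch, receptor_chains)
  }
  structure(list(chains = chains, receptor = receptor_chains,
                 ligand = ligand_chains, atom_map = atom_map),
            class = "ChainMapping")
}

# paired backbone coordinates for a subset of reference atoms
paired_coords <- function(model, reference, mapping, ref_idx) {
  mi <- mapping$atom_map[ref_idx]
  keep <- !is.na(mi)
  list(ref = get_coords(reference)[ref_idx[keep], , drop = FALSE],
       mod = get_coords(model)[mi[keep], , drop = FALSE])
}

#' Ligand RMSD
#'
#' Superposes the model onto the reference by least squares over the
#' receptor backbone (N, CA, C, O) and returns the backbone RMSD over the
#' ligand chains.
#' @param model,reference `ComplexStructure` objects.
#' @param mapping a [chain_mapping()]; built automatically if `NULL`.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model, reference, mapping = NULL) {
  if (is.null(mapping)) mapping <- chain_mapping(model, reference)
  ra <- reference$atoms
  rec <- which(ra$chain %in% mapping$receptor & ra$name %in% BB_RMSD_ATOMS)
  lig <- which(ra$chain %in% mapping$ligand & ra$name %in% BB_RMSD_ATOMS)
  pr <- paired_coords(model, reference, mapping, rec)
  if (nrow(pr$ref) < 3) abort_rc("MappingError", "receptor has < 3 mapped backbone atoms")
  fit <- kabsch(pr$mod, pr$ref)
  pl <- paired_coords(model, reference, mapping, lig)
  coord_rmsd(apply_transform(pl$mod, fit$R, fit$t), pl$ref)
}

# residues forming the reference interface: any inter-chain heavy-atom
# contact below `cutoff`
reference_interface_residues <- function(reference, cutoff) {
  a <- reference$atoms
  xyz <- get_coords(reference)
  ridx <- reference$topology$residue_index
  rt <- reference$topology$residues
  members <- rep(FALSE, nrow(rt))
  for (ch in unique(a$chain)) {
    i <- which(a$chain == ch)
    j <- which(a$chain != ch)
    di <- xyz[i, , drop = FALSE]; dj <- xyz[j, , drop = FALSE]
    d2 <- outer(rowSums(di^2), rowSums(dj^2), "+") - 2 * di %*% t(dj)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) members[unique(ridx[i[hit[, 1]]])] <- TRUE
  }
  which(members)
}

#' Interface RMSD
#'
#' Interface residues are defined on the reference (any inter-chain
#' heavy-atom contact within `interface_cutoff`); the model is superposed
#' on the backbone atoms of those residues and the backbone RMSD over them
#' is returned.
#' @inheritParams ligand_rmsd
#' @param interface_cutoff heavy-atom contact cutoff, Angstrom.
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(model, reference, mapping = NULL,
                           interface_cutoff = 10.0) {
  if (is.null(mapping)) mapping <- chain_mapping(model, reference)
  rids <- reference_interface_residues(reference, interface_cutoff)
  if (length(rids) == 0) abort_rc("EmptyInterface", "reference has no interface")
  ra <- reference$atoms
  ridx <- reference$topology$residue_index
  sel <- which(ridx %in% rids & ra$name %in% BB_RMSD_ATOMS)
  pr <- paired_coords(model, reference, mapping, sel)
  fit <- kabsch(pr$mod, pr$ref)
  coord_rmsd(apply_transform(pr$mod, fit$R, fit$t), pr$ref)
}

# inter-chain residue contact pairs (any heavy-atom pair < cutoff);
# returns character keys "chain resi|chain resi" with the two sides ordered
residue_contacts <- function(s, cutoff, xyz = get_coords(s)) {
  a <- s$atoms
  ridx <- s$topology$residue_index
  rt <- s$topology$residues
  keys <- character(0)
  chs <- unique(a$chain)
  for (p in seq_len(length(chs) - 1)) for (q in (p + 1):length(chs)) {
    i <- which(a$chain == chs[p]); j <- which(a$chain == chs[q])
    di <- xyz[i, , drop = FALSE]; dj <- xyz[j, , drop = FALSE]
    d2 <- outer(rowSums(di^2), rowSums(dj^2), "+") - 2 * di %*% t(dj)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      ri <- ridx[i[hit[, 1]]]; rj <- ridx[j[hit[, 2]]]
      keys <- c(keys, unique(paste(rt$chain[ri], rt$resi[ri], "|",
                                   rt$chain[rj], rt$resi[rj])))
    }
  }
  unique(keys)
}

#' Fraction of native contacts
#'
#' Native contacts are inter-chain residue pairs with any heavy-atom pair
#' below `contact_cutoff` in the reference; returns the fraction of those
#' reproduced by the model (residues mapped through the chain mapping).
#' @inheritParams ligand_rmsd
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom.
#' @return fraction in `[0, 1]`.
#' @export
fraction_native_contacts <- function(model, reference, mapping = NULL,
                                     contact_cutoff = 5.0) {
  if (is.null(mapping)) mapping <- chain_mapping(model, reference)
  native <- residue_contacts(reference, contact_cutoff)
  if (length(native) == 0) abort_rc("NoNativeContacts", "reference has no contacts")
  # model contacts expressed in reference chain ids
  inv <- setNames(names(mapping$chains), mapping$chains)
  mk <- residue_contacts(model, contact_cutoff)
  remap <- vapply(strsplit(mk, " \\| "), function(pp) {
    aa <- strsplit(pp, " ")
    k1 <- paste(inv[aa[[1]][1]], aa[[1]][2])
    k2 <- paste(inv[aa[[2]][1]], aa[[2]][2])
    paste(sort(c(k1, k2)), collapse = " | ")
  }, character(1))
  native_sorted <- vapply(strsplit(native, " \\| "), function(pp)
    paste(sort(pp), collapse = " | "), character(1))
  mean(native_sorted %in% remap)
}

#' CAPRI model-quality classification
#'
#' Applies the standard tiers with strict inequalities, in order of
#' precedence: high if L-RMSD or I-RMSD < 1.0 A with F_nat > 0.5; medium if
#' L-RMSD < 5.0 A or I-RMSD < 2.0 A with F_nat > 0.3; acceptable if
#' L-RMSD < 10.0 A or I-RMSD < 4.0 A with F_nat > 0.1; else incorrect.
#'
#' @param l_rmsd,i_rmsd non-negative RMSDs in Angstrom.
#' @param f_nat fraction of native contacts in `[0, 1]`.
#' @return one of `"high"`, `"medium"`, `"acceptable"`, `"incorrect"`.
#' @export
capri_classify <- function(l_rmsd, i_rmsd, f_nat) {
  if (any(c(l_rmsd, i_rmsd) < 0) || f_nat < 0 || f_nat > 1 ||
      any(!is.finite(c(l_rmsd, i_rmsd, f_nat))))
    abort_rc("DomainError", "metrics out of domain")
  if ((l_rmsd < 1.0 || i_rmsd < 1.0) && f_nat > 0.5) return("high")
  if ((l_rmsd < 5.0 || i_rmsd < 2.0) && f_nat > 0.3) return("medium")
  if ((l_rmsd < 10.0 || i_rmsd < 4.0) && f_nat > 0.1) return("acceptable")
  "incorrect"
}

# all chain re-labelings of the model consistent with sequence identity
candidate_mappings <- function(model, reference, receptor_chains = NULL,
                               ligand_chains = NULL) {
  rch <- chain_ids(reference)
  mch <- chain_ids(model)
  perms <- all_permutations(seq_along(mch))
  out <- list()
  for (p in seq_len(nrow(perms))) {
    asg <- mch[perms[p, ]]
    seq_ok <- all(reference$sequences[rch] == model$sequences[asg])
    if (!seq_ok) next
    m <- tryCatch({
      mp <- chain_mapping(model, reference, receptor_chains, ligand_chains)
      mp$chains <- setNames(asg, rch)
      ra <- reference$atoms
      mp$atom_map <- match(paste(mp$chains[ra$chain], ra$resi, ra$name),
                           paste(model$atoms$chain, model$atoms$resi,
                                 model$atoms$name))
      mp
    }, refinecomplex_error = function(e) NULL)
    if (!is.null(m)) out[[length(out) + 1]] <- m
  }
  if (length(out) == 0) abort_rc("MappingError", "no sequence-consistent chain mapping")
  out
}

all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

#' Assess a model against a reference complex
#'
#' Computes L-RMSD, I-RMSD and F_nat and the CAPRI class. For homo-complexes
#' (identical sequences) all sequence-consistent chain re-labelings are
#' tried and the best-scoring mapping (lowest L-RMSD) is reported.
#'
#' @param model,reference `ComplexStructure` objects.
#' @param receptor_chains,ligand_chains optional role assignment
#'   (reference chain ids).
#' @return a `QualityMetrics` list: `l_rmsd`, `i_rmsd`, `f_nat`,
#'   `capri_class`.
#' @export
assess_model <- function(model, reference, receptor_chains = NULL,
                         ligand_chains = NULL) {
  sym <- length(unique(reference$sequences)) == 1 &&
    length(reference$sequences) >= 2
  maps <- if (sym)
    candidate_mappings(model, reference, receptor_chains, ligand_chains)
  else
    list(chain_mapping(model, reference, receptor_chains, ligand_chains))
  best <- NULL
  for (mp in maps) {
    l <- ligand_rmsd(model, reference, mp)
    if (is.null(best) || l < best$l_rmsd) {
      best <- list(l_rmsd = l,
                   i_rmsd = interface_rmsd(model, reference, mp),
                   f_nat = fraction_native_contacts(model, reference, mp),
                   mapping = mp)
    }
  }
  out <- list(l_rmsd = best$l_rmsd, i_rmsd = best$i_rmsd, f_nat = best$f_nat,
              capri_class = capri_classify(best$l_rmsd, best$i_rmsd,
                                           best$f_nat))
  class(out) <- "QualityMetrics"
  out
}

#' @export
print.QualityMetrics <- function(x, ...) {
  cat(sprintf("L-RMSD %.3f A | I-RMSD %.3f A | F_nat %.3f | %s\n",
              x$l_rmsd, x$i_rmsd, x$f_nat, x$capri_class))
  invisible(x)
}
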