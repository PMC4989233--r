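# The hybrid refinement energy: a linear combination of physics-based
# terms, knowledge-based terms and restraint terms, with per-term
# breakdown and analytic gradients of the smooth terms.

# assemble the coordinate-independent arguments of the C++ core
energy_call <- function(structure, restraints, weights, vdw_scale,
                        want_grad, xyz = get_coords(structure)) {
  top <- structure$topology
  a <- structure$atoms
  fc <- FF_CONST
  sasa_ref <- 4 * pi * (a$radius + fc$probe_radius)^2
  rd <- as.matrix(restraints$distance[, c("i", "j", "d0", "weight")])
  if (nrow(rd) == 0) rd <- matrix(0, 0, 4)
  rp <- as.matrix(restraints$position[, c("i", "x0", "y0", "z0", "weight")])
  if (nrow(rp) == 0) rp <- matrix(0, 0, 5)
  w8 <- unname(weights[c("bonded", "vdw", "coulomb", "solv_polar",
                         "solv_nonpolar", "hbond", "restraint_distance",
                         "restraint_position")])
  energy_core(xyz, top$bonds, top$bonds_b0, fc$kb,
              top$angles, top$angles_th0, fc$ka,
              top$torsions,
              a$charge, a$radius, a$eps,
              as.numeric(top$excl_keys), as.numeric(top$p14_keys),
              fc$cutoff, fc$coul_const, fc$scale14,
              top$hb_donors, top$hb_acceptors,
              fc$hb_strength, fc$hb_r0, fc$hb_sigma,
              top$residue_index,
              fc$solv_kpol, fc$solv_gamma, fc$solv_sigma, fc$solv_b0,
              sasa_ref, rd, rp, vdw_scale, w8, want_grad)
}

# statistical lookup terms (piecewise-constant; no gradient contribution)
statistical_terms <- function(structure, tables) {
  top <- structure$topology
  xyz <- get_coords(structure)
  rt <- top$residues
  # backbone torsion statistics
  e_rama <- 0
  for (r in seq_len(nrow(rt))) {
    pp <- top$phipsi[[r]]
    if (anyNA(pp$phi) || anyNA(pp$psi)) next
    phi <- dihedral_angle(xyz[pp$phi[1], ], xyz[pp$phi[2], ],
                          xyz[pp$phi[3], ], xyz[pp$phi[4], ])
    psi <- dihedral_angle(xyz[pp$psi[1], ], xyz[pp$psi[2], ],
                          xyz[pp$psi[3], ], xyz[pp$psi[4], ])
    e_rama <- e_rama + rama_lookup(tables$rama, rt$resname[r], phi, psi)
  }
  # side-chain rotamer statistics: -log p of the nearest library rotamer
  e_rot <- 0
  lib <- tables$rotamers
  for (r in seq_len(nrow(rt))) {
    rn <- rt$resname[r]
    if (is.null(lib[[rn]])) next
    chi <- measure_chi(structure, r)
    if (length(chi) == 0) next
    dev <- apply(lib[[rn]]$chi, 1, function(rc)
      max(abs(ang_diff(chi[seq_along(rc)], rc))))
    e_rot <- e_rot - log(lib[[rn]]$prob[which.min(dev)])
  }
  # pairwise residue-residue statistical potential on Cbeta distances
  e_pair <- 0
  ps <- tables$pairstat
  if (length(ps$energy) > 0) {
    cb <- integer(nrow(rt))
    for (r in seq_len(nrow(rt))) {
      am <- top$amap[[r]]
      cb[r] <- if ("CB" %in% names(am)) am[["CB"]] else am[["CA"]]
    }
    pos <- xyz[cb, , drop = FALSE]
    for (p in seq_len(nrow(rt) - 1)) for (q in (p + 1):nrow(rt)) {
      same_chain <- rt$chain[p] == rt$chain[q]
      if (same_chain && abs(rt$resi[p] - rt$resi[q]) <= 1) next
      d <- vnorm(pos[p, ] - pos[q, ])
      bin <- findInterval(d, ps$breaks)
      if (bin < 1 || bin >= length(ps$breaks)) next
      key <- pairstat_key(rt$resname[p], rt$resname[q])
      ev <- ps$energy[[key]]
      if (!is.null(ev)) e_pair <- e_pair + ev[bin]
    }
  }
  c(pairstat = e_pair, rama = e_rama, rotamer = e_rot)
}

default_tables <- function() {
  if (is.null(.rc_cache$tables)) {
    .rc_cache$tables <- list(rama = default_rama_tables(),
                             rotamers = default_rotamer_library(),
                             pairstat = flat_pairstat_table())
  }
  .rc_cache$tables
}

#' Evaluate the total refinement energy with per-term breakdown
#'
#' @param structure a `ComplexStructure`.
#' @param restraints a `RestraintSet` (use [empty_restraints()] for none).
#' @param weights named weight vector from [default_energy_weights()].
#' @param vdw_scale multiplier on all van der Waals radii in `(0, 1]`
#'   (0.7 during repacking to tolerate small clashes).
#' @param tables parameter tables (`rama`, `rotamers`, `pairstat`);
#'   defaults to the packaged set.
#' @param tsv_log optional path: the per-term breakdown is appended to this
#'   tab-separated log (header written when the file does not yet exist).
#' @return an `EnergyBreakdown`: list with `terms` (raw per-term energies),
#'   `weights`, and `total` = sum of weight * term.
#' @export
total_energy <- function(structure, restraints, weights = default_energy_weights(),
                         vdw_scale = 1.0, tables = default_tables(),
                         tsv_log = NULL) {
  stopifnot(vdw_scale > 0, vdw_scale <= 1)
  check_restraints(structure, restraints)
  sm <- energy_call(structure, restraints, weights, vdw_scale, FALSE)
  terms <- c(sm$terms, statistical_terms(structure, tables))
  terms <- terms[ENERGY_TERMS]
  out <- list(terms = terms, weights = weights[ENERGY_TERMS],
              total = sum(terms * weights[ENERGY_TERMS]))
  class(out) <- "EnergyBreakdown"
  if (!is.null(tsv_log)) {
    row <- data.frame(provenance = structure$provenance,
                      vdw_scale = vdw_scale, total = out$total,
                      as.list(setNames(as.numeric(terms), names(terms))))
    utils::write.table(row, tsv_log, sep = "\t", row.names = FALSE,
                       col.names = !file.exists(tsv_log), append =
                         file.exists(tsv_log), quote = FALSE)
  }
  out
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat("EnergyBreakdown (total", sprintf("%.4f", x$total), "):\n")
  for (nm in names(x$terms))
    cat(sprintf("  %-20s %12.4f  (w=%g)\n", nm, x$terms[nm], x$weights[nm]))
  invisible(x)
}

#' Analytic gradient of the total energy
#'
#' Gradient of the weighted total with respect to all atomic coordinates.
#' The statistical lookup terms are piecewise constant in coordinates and
#' contribute zero gradient; all smooth terms are differentiated
#' analytically.
#'
#' @inheritParams total_energy
#' @return n x 3 matrix, energy/Angstrom.
#' @export
energy_gradient <- function(structure, restraints,
                            weights = default_energy_weights(),
                            vdw_scale = 1.0) {
  check_restraints(structure, restraints)
  energy_call(structure, restraints, weights, vdw_scale, TRUE)$grad
}

check_restraints <- function(structure, restraints) {
  n <- nrow(structure$atoms)
  idx <- c(restraints$distance$i, restraints$distance$j,
           restraints$position$i)
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    abort_rc("AtomMismatch", "restraint atom index out of range")
  invisible(NULL)
}

#' Restraint energies of a structure
#'
#' @param structure a `ComplexStructure` with atoms matching the restraint
#'   set's references.
#' @param restraints a `RestraintSet`.
#' @return named vector `c(distance =, position =)`: the harmonic sums
#'   sum w (d - d0)^2 and sum w ||r - r0||^2.
#' @export
restraint_energy <- function(structure, restraints) {
  check_restraints(structure, restraints)
  xyz <- get_coords(structure)
  d <- restraints$distance
  ed <- if (nrow(d)) {
    dd <- sqrt(rowSums((xyz[d$i, , drop = FALSE] - xyz[d$j, , drop = FALSE])^2))
    sum(d$weight * (dd - d$d0)^2)
  } else 0
  p <- restraints$position
  ep <- if (nrow(p)) {
    dev <- xyz[p$i, , drop = FALSE] - as.matrix(p[, c("x0", "y0", "z0")])
    sum(p$weight * rowSums(dev^2))
  } else 0
  c(distance = ed, position = ep)
}

#' Steric acceptability of a set of side chains
#'
#' Checks every heavy-atom pair in which at least one atom belongs to the
#' side chain of a listed residue. Returns `TRUE` iff no such pair is
#' closer than `overlap_factor * (r_i + r_j) * vdw_scale` (strict
#' inequality: a pair exactly at the limit is not a clash); 1-2 and 1-3
#' bonded pairs are excluded.
#'
#' @param structure a `ComplexStructure`.
#' @param residues data.frame with columns `chain`, `resi` (the residues
#'   whose side chains are checked).
#' @param vdw_scale radius scale factor (0.7 during repacking).
#' @param overlap_factor allowed overlap fraction of summed scaled radii.
#' @return `TRUE` if clash-free, `FALSE` otherwise.
#' @export
clash_check <- function(structure, residues, vdw_scale = 0.7,
                        overlap_factor = 0.8) {
  top <- structure$topology
  a <- structure$atoms
  rids <- residue_id(structure, residues$chain, residues$resi)
  if (anyNA(rids)) abort_rc("MappingError", "unknown residue in clash check")
  sel <- which(top$residue_index %in% rids & !a$backbone)
  if (length(sel) == 0) return(TRUE)
  xyz <- get_coords(structure)
  n <- nrow(a)
  lim_i <- a$radius[sel]
  d2 <- outer(rowSums(xyz[sel, , drop = FALSE]^2), rowSums(xyz^2), "+") -
    2 * xyz[sel, , drop = FALSE] %*% t(xyz)
  lim <- outer(lim_i, a$radius, "+") * vdw_scale * overlap_factor
  hit <- which(d2 < lim^2 - 1e-8, arr.ind = TRUE)
  if (nrow(hit) == 0) return(TRUE)
  for (h in seq_len(nrow(hit))) {
    i <- sel[hit[h, 1]]; j <- hit[h, 2]
    if (i == j) next
    lo <- min(i, j); hi <- max(i, j)
    key <- (lo - 1) * n + (hi - 1)
    if (key %in% top$excl_keys) next
    return(FALSE)
  }
  TRUE
}
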