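# Synthetic fixture generation: idealized helical toy complexes, decoys of
# controlled accuracy, and parameter tables. Everything is deterministic
# given a seed, so the whole pipeline is testable without external data.

# Heptad-patterned sequence: rotatable hydrophobics (LEU/ILE) on one helix
# face so that interface repacking has real work to do.
FIXTURE_HEPTAD <- c("LEU", "GLU", "ALA", "ILE", "SER", "LYS", "ALA")

fixture_sequence <- function(chain_length) {
  FIXTURE_HEPTAD[(seq_len(chain_length) - 1) %% 7 + 1]
}

#' Fixture specification
#'
#' @param chain_length residues per chain (>= 5).
#' @param n_chains number of chains (2 for a dimer; with `symmetry = n`,
#'   `n` copies of one chain).
#' @param symmetry `NULL` for a heteromer-style dimer or an integer n >= 2
#'   for a Cn homo-oligomer.
#' @param sequence vector of 3-letter residue names, or `NULL` for the
#'   default heptad pattern.
#' @param seed integer seed.
#' @return a `FixtureSpec` list.
#' @export
fixture_spec <- function(chain_length = 14, n_chains = 2, symmetry = NULL,
                         sequence = NULL, seed = 1) {
  if (chain_length < 5) abort_rc("PackingFailure", "chain_length must be >= 5")
  if (!is.null(symmetry)) n_chains <- as.integer(symmetry)
  if (is.null(sequence)) sequence <- fixture_sequence(chain_length)
  structure(list(chain_length = chain_length, n_chains = n_chains,
                 symmetry = symmetry, sequence = sequence, seed = seed),
            class = "FixtureSpec")
}

# Build one ideal alpha-helical chain (phi=-57, psi=-47) as an atom table.
build_helix_chain <- function(sequence, chain_id = "A", phi = -57, psi = -47,
                              chi = NULL) {
  L <- length(sequence)
  bb <- vector("list", L)
  N <- c(0, 0, 0); CA <- c(BB_GEOM$b_N_CA, 0, 0)
  th <- BB_GEOM$a_N_CA_C * DEG2RAD
  C <- CA + BB_GEOM$b_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      Np <- bb[[i - 1]]$N; CAp <- bb[[i - 1]]$CA; Cp <- bb[[i - 1]]$C
      N <- place_atom(Np, CAp, Cp, BB_GEOM$b_C_N, BB_GEOM$a_CA_C_N, psi)
      CA <- place_atom(CAp, Cp, N, BB_GEOM$b_N_CA, BB_GEOM$a_C_N_CA, 180)
      C <- place_atom(Cp, N, CA, BB_GEOM$b_CA_C, BB_GEOM$a_N_CA_C, phi)
    }
    O <- place_atom(N, CA, C, BB_GEOM$b_C_O, BB_GEOM$a_CA_C_O, psi + 180)
    bb[[i]] <- list(N = N, CA = CA, C = C, O = O)
  }
  rows <- list()
  for (i in seq_len(L)) {
    rn <- sequence[i]
    pos <- bb[[i]]
    ci <- if (is.null(chi)) DEFAULT_CHI[[rn]] else chi[[i]]
    sc <- build_sidechain_coords(rn, pos$N, pos$CA, pos$C, ci)
    pos <- c(pos, sc)
    for (nm in names(pos)) {
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain_id, resno = i, resi = i, resname = rn, name = nm,
        x = pos[[nm]][1], y = pos[[nm]][2], z = pos[[nm]][3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Center a chain's CA centroid at the origin, align its helix axis with +z
# (first principal component, N-terminus at -z), and rotate about z so the
# mean side-chain direction of the large hydrophobics points along +y.
orient_helix <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ca <- xyz[atoms$name == "CA", , drop = FALSE]
  cen <- colMeans(ca)
  xyz <- sweep(xyz, 2, cen)
  pc <- prcomp(sweep(ca, 2, cen))$rotation[, 1]
  if (sum((ca[nrow(ca), ] - cen) * pc) < 0) pc <- -pc
  # rotation taking pc -> z
  z <- c(0, 0, 1)
  v <- pracma_cross(pc, z)
  if (vnorm(v) < 1e-8) R1 <- diag(3) else {
    ang <- acos(max(-1, min(1, sum(pc * z)))) / DEG2RAD
    R1 <- rotation_about_axis(v, ang)
  }
  xyz <- xyz %*% t(R1)
  # azimuth: mean CB-CA direction of the heptad-a leucines projected on xy
  big <- atoms$resname %in% c("LEU", "PHE")
  cbs <- xyz[atoms$name == "CB" & big, , drop = FALSE]
  cas <- xyz[atoms$name == "CA" & big, , drop = FALSE]
  d <- colMeans(cbs - cas)
  theta <- atan2(d[2], d[1]) / DEG2RAD
  R2 <- rotation_about_axis(c(0, 0, 1), 90 - theta)
  xyz <- xyz %*% t(R2)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# Steric clash pairs on a bare atom table. Pairs within one residue and
# backbone-backbone pairs of sequence neighbors are covalently constrained
# and excluded. Returns a data.frame of offending pairs.
atom_clash_pairs <- function(atoms, overlap = 0.8) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vapply(ELEMENT_PARAMS[element_of(atoms$name)], `[[`, numeric(1),
                "radius")
  n <- nrow(atoms)
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(rad, rad, "+") * overlap
  hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(i = integer(0), j = integer(0), gap = numeric(0)))
  i <- hit[, 1]; j <- hit[, 2]
  same_res <- atoms$chain[i] == atoms$chain[j] & atoms$resi[i] == atoms$resi[j]
  bb <- atoms$name %in% BACKBONE_ATOMS
  adj_bb <- atoms$chain[i] == atoms$chain[j] &
    abs(atoms$resi[i] - atoms$resi[j]) == 1 & bb[i] & bb[j]
  # CB sits 1-3 from the neighboring peptide N/C
  adj_cb <- atoms$chain[i] == atoms$chain[j] &
    abs(atoms$resi[i] - atoms$resi[j]) == 1 &
    ((atoms$name[i] == "CB" & bb[j]) | (atoms$name[j] == "CB" & bb[i]))
  keep <- !(same_res | adj_bb | adj_cb)
  data.frame(i = i[keep], j = j[keep],
             gap = (lim[hit] - d[hit])[keep])
}

interchain_clash <- function(atoms, overlap = 0.8) {
  cp <- atom_clash_pairs(atoms, overlap)
  any(atoms$chain[cp$i] != atoms$chain[cp$j])
}

# Greedy rotamer repair: while clashes involving repackable side chains
# remain, rebuild the worst offender's side chain with the library rotamer
# minimizing the total clash severity. Deterministic. Returns the repaired
# atom table or NULL if the geometry cannot be fixed.
repair_rotamers <- function(atoms, library, overlap = 0.8, max_pass = 40,
                            symmetric_chains = FALSE) {
  rebuild_one <- function(at, chain, resi, chi) {
    sel <- at$chain == chain & at$resi == resi
    rn <- at$resname[sel][1]
    bb <- function(nm) as.numeric(at[sel & at$name == nm, c("x", "y", "z")])
    sc <- build_sidechain_coords(rn, bb("N"), bb("CA"), bb("C"), chi)
    for (nm in names(sc)) {
      row <- which(sel & at$name == nm)
      at[row, c("x", "y", "z")] <- as.list(sc[[nm]])
    }
    at
  }
  rebuild <- function(at, chain, resi, chi) {
    chains <- if (symmetric_chains) unique(at$chain) else chain
    for (ch in chains) at <- rebuild_one(at, ch, resi, chi)
    at
  }
  severity <- function(at) {
    cp <- atom_clash_pairs(at, overlap)
    sum(cp$gap)
  }
  for (pass in seq_len(max_pass)) {
    cp <- atom_clash_pairs(atoms, overlap)
    if (nrow(cp) == 0) return(atoms)
    sc_i <- !atoms$name[cp$i] %in% BACKBONE_ATOMS
    sc_j <- !atoms$name[cp$j] %in% BACKBONE_ATOMS
    cand <- unique(c(cp$i[sc_i], cp$j[sc_j]))
    cand <- cand[atoms$resname[cand] %in% names(library)]
    if (length(cand) == 0) return(NULL)
    # try candidate residues in order of summed clash gap; take the first
    # rotamer replacement that strictly lowers the total severity
    gaps <- vapply(cand, function(a) {
      sum(cp$gap[cp$i == a | cp$j == a])
    }, numeric(1))
    cand <- cand[order(-gaps)]
    cur_sev <- severity(atoms)
    best <- NULL
    for (w in cand) {
      ch <- atoms$chain[w]; ri <- atoms$resi[w]
      rot <- library[[atoms$resname[w]]]
      best_sev <- cur_sev
      for (k in seq_len(nrow(rot$chi))) {
        trial <- rebuild(atoms, ch, ri, rot$chi[k, ])
        sev <- severity(trial)
        if (sev < best_sev - 1e-9) {
          best <- trial; best_sev <- sev
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) return(NULL)
    atoms <- best
  }
  if (nrow(atom_clash_pairs(atoms, overlap)) == 0) atoms else NULL
}

count_interface_residues <- function(atoms, cutoff = 8) {
  ca <- atoms[atoms$name == "CA", ]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  inter <- outer(ca$chain, ca$chain, "!=")
  members <- apply(d < cutoff & inter, 1, any)
  tapply(members, ca$chain, sum)
}

#' Build an idealized reference complex
#'
#' Chains are ideal alpha-helices (phi = -57, psi = -47) with side chains at
#' canonical rotamers, posed as an antiparallel packed dimer or as a Cn ring
#' about the z axis. The inter-chain separation is the smallest (on a 0.25 A
#' grid) with no inter-chain steric overlap at full van der Waals radii and
#' at least 5 interfacial residues per chain.
#'
#' @param spec a [fixture_spec()].
#' @return a `ComplexStructure`.
#' @export
make_reference_complex <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  base <- orient_helix(build_helix_chain(spec$sequence, "A"))
  n <- spec$n_chains
  place <- function(sep) {
    if (is.null(spec$symmetry)) {
      b <- base
      xyzB <- as.matrix(b[, c("x", "y", "z")]) %*%
        t(rotation_about_axis(c(1, 0, 0), 180))
      xyzB <- sweep(xyzB, 2, c(0, sep, 0), "+")
      b$x <- xyzB[, 1]; b$y <- xyzB[, 2]; b$z <- xyzB[, 3]
      b$chain <- "B"
      rbind(base, b)
    } else {
      # Cn ring: each copy at radius `sep`, interface face toward the ring
      out <- list()
      for (k in seq_len(n)) {
        b <- base
        xyz <- as.matrix(b[, c("x", "y", "z")])
        xyz <- sweep(xyz, 2, c(0, -sep, 0), "+")   # face (+y) points inward
        xyz <- xyz %*% t(rotation_about_axis(c(0, 0, 1), 360 * (k - 1) / n))
        b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
        b$chain <- LETTERS[k]
        out[[k]] <- b
      }
      do.call(rbind, out)
    }
  }
  lib <- default_rotamer_library()
  seps <- seq(if (is.null(spec$symmetry)) 8 else 5, 20, by = 0.5)
  for (sep in seps) {
    atoms <- place(sep)
    ni <- count_interface_residues(atoms)
    if (any(ni < 5)) next        # interface only shrinks as sep grows
    fixed <- repair_rotamers(atoms, lib,
                             symmetric_chains = !is.null(spec$symmetry))
    if (is.null(fixed)) next
    if (any(count_interface_residues(fixed) < 5)) next
    s <- new_complex_structure(fixed, provenance = sprintf(
      "fixture(len=%d,n=%d,%s,sep=%.2f)", spec$chain_length, n,
      if (is.null(spec$symmetry)) "dimer" else paste0("C", n), sep))
    return(s)
  }
  abort_rc("PackingFailure", "could not place chains without clashes")
}

#' Generate a decoy of controlled deviation from a reference complex
#'
#' The ligand chain (the last chain) is rigidly rotated about a random axis
#' through its CA centroid and translated along a random direction by the
#' requested magnitudes; a requested fraction of interfacial residues (on
#' any chain) have their side chains reassigned to random library rotamers.
#'
#' @param reference a `ComplexStructure`.
#' @param rotation rigid rotation magnitude, degrees.
#' @param translation rigid translation magnitude, Angstrom.
#' @param scramble fraction in `[0, 1]` of interfacial residues whose side
#'   chains are randomized.
#' @param seed integer seed.
#' @param library rotamer library for scrambling.
#' @return list with `structure` (the decoy) and `metrics` (its
#'   [QualityMetrics][assess_model()] against the reference).
#' @export
make_decoy <- function(reference, rotation = 0, translation = 0,
                       scramble = 0, seed = 1,
                       library = default_rotamer_library()) {
  s <- reference
  with_seed(seed, {
    chains <- chain_ids(s)
    lig <- chains[length(chains)]
    idx <- chain_atom_idx(s, lig)
    xyz <- get_coords(s)
    if (rotation != 0 || translation != 0) {
      cen <- colMeans(xyz[intersect(idx, which(s$atoms$name == "CA")), ,
                          drop = FALSE])
      axis <- stats::rnorm(3)
      R <- rotation_about_axis(axis, rotation)
      tdir <- stats::rnorm(3); tdir <- tdir / vnorm(tdir)
      xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, cen) %*% t(R),
                          2, cen + translation * tdir, "+")
      s <- set_coords(s, xyz)
    }
    if (scramble > 0) {
      iface <- detect_interface(reference)
      mem <- iface$members
      rids <- residue_id(s, mem$chain, mem$resi)
      rn <- s$topology$residues$resname[rids]
      rids <- rids[vapply(rn, n_chi, integer(1)) > 0 & rn %in% names(library)]
      pick <- sample(rids, size = max(0, round(scramble * length(rids))))
      for (rid in pick) {
        rn <- s$topology$residues$resname[rid]
        rot <- library[[rn]]
        k <- sample.int(nrow(rot$chi), 1, prob = rot$prob)
        s <- set_residue_chi(s, rid, rot$chi[k, ])
      }
    }
  })
  s$provenance <- sprintf("decoy(rot=%g,trans=%g,scramble=%g,seed=%d)",
                          rotation, translation, scramble, seed)
  list(structure = s, metrics = assess_model(s, reference))
}
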