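# Residue topology templates and force-field topology construction.
#
# Each of the 20 standard amino acids is described by an internal-coordinate
# (Z-matrix style) template for its side-chain heavy atoms, a set of ring
# closure bonds, and a set of planarity quadruples used as periodic torsion
# terms. Bond and angle equilibrium values for side-chain terms are measured
# from a reference build of each template so that ideally-built structures
# carry zero bonded strain; backbone equilibria are fixed constants
# (Engh-Huber-like values).

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Backbone geometry constants (Angstrom / degrees)
BB_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_O = 1.231, b_C_N = 1.329,
  a_N_CA_C = 111.2, a_CA_C_O = 120.8, a_CA_C_N = 116.2,
  a_O_C_N = 123.0, a_C_N_CA = 121.7,
  # torsion placing CB: dihedral C-N-CA-CB for an L-amino acid
  t_CB = -122.6, a_N_CA_CB = 110.5, b_CA_CB = 1.530
)

# Side-chain Z-matrix rows: atom, parent, angle-ref, torsion-ref,
# bond (A), angle (deg), torsion (number or "X<k>[+/-offset]").
sc_row <- function(atom, parent, aref, tref, bond, angle, tors) {
  list(atom = atom, parent = parent, aref = aref, tref = tref,
       bond = bond, angle = angle, tors = tors)
}

residue_templates <- function() {
  tpl <- list()
  add <- function(res, rows, closures = list(), planar = list(),
                  charges = c()) {
    tpl[[res]] <<- list(rows = rows, closures = closures, planar = planar,
                        charges = charges)
  }
  CB <- sc_row("CB", "CA", "N", "C", BB_GEOM$b_CA_CB, BB_GEOM$a_N_CA_CB,
               BB_GEOM$t_CB)

  add("GLY", list())
  add("ALA", list(CB))
  add("SER", list(CB, sc_row("OG", "CB", "CA", "N", 1.417, 110.8, "X1")),
      charges = c(CB = 0.25, OG = -0.25))
  add("CYS", list(CB, sc_row("SG", "CB", "CA", "N", 1.808, 113.8, "X1")),
      charges = c(CB = 0.15, SG = -0.15))
  add("THR", list(CB,
                  sc_row("OG1", "CB", "CA", "N", 1.433, 109.6, "X1"),
                  sc_row("CG2", "CB", "CA", "N", 1.521, 110.5, "X1-120")),
      charges = c(CB = 0.25, OG1 = -0.25))
  add("VAL", list(CB,
                  sc_row("CG1", "CB", "CA", "N", 1.527, 110.5, "X1"),
                  sc_row("CG2", "CB", "CA", "N", 1.527, 110.5, "X1+120")))
  add("LEU", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.530, 116.3, "X1"),
                  sc_row("CD1", "CG", "CB", "CA", 1.521, 110.7, "X2"),
                  sc_row("CD2", "CG", "CB", "CA", 1.521, 110.7, "X2+120")))
  add("ILE", list(CB,
                  sc_row("CG1", "CB", "CA", "N", 1.530, 110.4, "X1"),
                  sc_row("CG2", "CB", "CA", "N", 1.521, 110.5, "X1-120"),
                  sc_row("CD1", "CG1", "CB", "CA", 1.513, 113.9, "X2")))
  add("MET", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "X1"),
                  sc_row("SD", "CG", "CB", "CA", 1.803, 112.7, "X2"),
                  sc_row("CE", "SD", "CG", "CB", 1.791, 100.9, "X3")),
      charges = c(CG = 0.1, SD = -0.2, CE = 0.1))
  add("PRO", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.492, 104.5, "X1"),
                  sc_row("CD", "CG", "CB", "CA", 1.503, 106.1, "X2")),
      closures = list(c("CD", "N")))
  add("PHE", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.502, 113.8, "X1"),
                  sc_row("CD1", "CG", "CB", "CA", 1.384, 120.8, "X2"),
                  sc_row("CD2", "CG", "CB", "CA", 1.384, 120.8, "X2+180"),
                  sc_row("CE1", "CD1", "CG", "CB", 1.382, 120.8, 180),
                  sc_row("CE2", "CD2", "CG", "CB", 1.382, 120.8, 180),
                  sc_row("CZ", "CE1", "CD1", "CG", 1.382, 120.0, 0)),
      closures = list(c("CZ", "CE2")),
      planar = list(c("CB", "CG", "CD1", "CE1"), c("CB", "CG", "CD2", "CE2"),
                    c("CG", "CD1", "CE1", "CZ"), c("CG", "CD2", "CE2", "CZ"),
                    c("CD1", "CE1", "CZ", "CE2"), c("CD2", "CE2", "CZ", "CE1"),
                    c("CD1", "CG", "CD2", "CE2")))
  tyr_rows <- c(tpl[["PHE"]]$rows,
                list(sc_row("OH", "CZ", "CE1", "CD1", 1.376, 119.9, 180)))
  add("TYR", tyr_rows, closures = list(c("CZ", "CE2")),
      planar = c(tpl[["PHE"]]$planar, list(c("CD1", "CE1", "CZ", "OH"))),
      charges = c(CZ = 0.25, OH = -0.25))
  add("TRP", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.499, 113.6, "X1"),
                  sc_row("CD1", "CG", "CB", "CA", 1.365, 126.9, "X2"),
                  sc_row("CD2", "CG", "CB", "CA", 1.433, 126.7, "X2+180"),
                  sc_row("NE1", "CD1", "CG", "CB", 1.374, 110.2, 180),
                  sc_row("CE2", "NE1", "CD1", "CG", 1.370, 109.0, 0),
                  sc_row("CE3", "CD2", "CG", "CD1", 1.398, 133.9, 180),
                  sc_row("CZ2", "CE2", "NE1", "CD1", 1.394, 130.1, 180),
                  sc_row("CZ3", "CE3", "CD2", "CG", 1.382, 118.6, 180),
                  sc_row("CH2", "CZ2", "CE2", "NE1", 1.368, 117.5, 180)),
      closures = list(c("CD2", "CE2"), c("CZ3", "CH2")),
      planar = list(c("CB", "CG", "CD1", "NE1"), c("CB", "CG", "CD2", "CE2"),
                    c("CG", "CD1", "NE1", "CE2"), c("CD1", "NE1", "CE2", "CD2"),
                    c("CG", "CD2", "CE2", "NE1"), c("CD1", "CG", "CD2", "CE3"),
                    c("CG", "CD2", "CE3", "CZ3"), c("CD2", "CE3", "CZ3", "CH2"),
                    c("CE3", "CZ3", "CH2", "CZ2"), c("CZ3", "CH2", "CZ2", "CE2"),
                    c("CH2", "CZ2", "CE2", "CD2"), c("NE1", "CE2", "CZ2", "CH2")),
      charges = c(CD1 = 0.1, NE1 = -0.2, CE2 = 0.1))
  add("HIS", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.492, 113.7, "X1"),
                  sc_row("ND1", "CG", "CB", "CA", 1.380, 122.7, "X2"),
                  sc_row("CD2", "CG", "CB", "CA", 1.356, 131.0, "X2+180"),
                  sc_row("CE1", "ND1", "CG", "CB", 1.321, 109.0, 180),
                  sc_row("NE2", "CD2", "CG", "CB", 1.374, 107.2, 180)),
      closures = list(c("CE1", "NE2")),
      planar = list(c("CB", "CG", "ND1", "CE1"), c("CB", "CG", "CD2", "NE2"),
                    c("CG", "ND1", "CE1", "NE2"), c("CG", "CD2", "NE2", "CE1"),
                    c("ND1", "CE1", "NE2", "CD2"), c("ND1", "CG", "CD2", "NE2")),
      charges = c(CG = 0.2, ND1 = -0.36, CE1 = 0.32, CD2 = 0.2, NE2 = -0.36))
  add("ASP", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.516, 112.6, "X1"),
                  sc_row("OD1", "CG", "CB", "CA", 1.250, 118.4, "X2"),
                  sc_row("OD2", "CG", "CB", "CA", 1.250, 118.4, "X2+180")),
      planar = list(c("CB", "CG", "OD1", "OD2")),
      charges = c(CG = 0.6, OD1 = -0.8, OD2 = -0.8))
  add("ASN", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.516, 112.6, "X1"),
                  sc_row("OD1", "CG", "CB", "CA", 1.231, 120.8, "X2"),
                  sc_row("ND2", "CG", "CB", "CA", 1.328, 116.4, "X2+180")),
      planar = list(c("CB", "CG", "OD1", "ND2")),
      charges = c(CG = 0.55, OD1 = -0.55))
  add("GLU", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "X1"),
                  sc_row("CD", "CG", "CB", "CA", 1.516, 112.6, "X2"),
                  sc_row("OE1", "CD", "CG", "CB", 1.250, 118.4, "X3"),
                  sc_row("OE2", "CD", "CG", "CB", 1.250, 118.4, "X3+180")),
      planar = list(c("CG", "CD", "OE1", "OE2")),
      charges = c(CD = 0.6, OE1 = -0.8, OE2 = -0.8))
  add("GLN", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "X1"),
                  sc_row("CD", "CG", "CB", "CA", 1.516, 112.6, "X2"),
                  sc_row("OE1", "CD", "CG", "CB", 1.231, 120.8, "X3"),
                  sc_row("NE2", "CD", "CG", "CB", 1.328, 116.4, "X3+180")),
      planar = list(c("CG", "CD", "OE1", "NE2")),
      charges = c(CD = 0.55, OE1 = -0.55))
  add("LYS", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "X1"),
                  sc_row("CD", "CG", "CB", "CA", 1.520, 111.3, "X2"),
                  sc_row("CE", "CD", "CG", "CB", 1.520, 111.3, "X3"),
                  sc_row("NZ", "CE", "CD", "CG", 1.489, 111.9, "X4")),
      charges = c(CE = 0.2, NZ = 0.8))
  add("ARG", list(CB,
                  sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "X1"),
                  sc_row("CD", "CG", "CB", "CA", 1.520, 111.3, "X2"),
                  sc_row("NE", "CD", "CG", "CB", 1.461, 112.0, "X3"),
                  sc_row("CZ", "NE", "CD", "CG", 1.329, 124.2, "X4"),
                  sc_row("NH1", "CZ", "NE", "CD", 1.326, 120.0, 0),
                  sc_row("NH2", "CZ", "NE", "CD", 1.326, 120.0, 180)),
      planar = list(c("NE", "CZ", "NH1", "NH2"), c("CD", "NE", "CZ", "NH1"),
                    c("CD", "NE", "CZ", "NH2")),
      charges = c(NE = -0.2, CZ = 0.6, NH1 = 0.3, NH2 = 0.3))
  tpl
}

# Default chi angles used for template reference builds and initial
# side-chain placement (degrees; the most common rotamer of each type).
DEFAULT_CHI <- list(
  ALA = numeric(0), GLY = numeric(0),
  SER = -65, CYS = -65, THR = -60, VAL = 175, PRO = c(25, -30),
  LEU = c(-65, 175), ILE = c(-65, 170), MET = c(-65, 180, 75),
  PHE = c(-65, 90), TYR = c(-65, 90), TRP = c(-65, 95), HIS = c(-65, -70),
  ASP = c(-70, -15), ASN = c(-65, -20), GLU = c(-65, 180, -10),
  GLN = c(-65, 180, 0), LYS = c(-65, 180, 180, 180),
  ARG = c(-65, 180, 180, 85)
)

# chi-angle atom-name quadruples per residue type
chi_defs <- function(resname) {
  g1 <- switch(resname, SER = "OG", CYS = "SG", THR = "OG1", VAL = "CG1",
               ILE = "CG1", "CG")
  defs <- list()
  if (resname %in% c("ALA", "GLY")) return(defs)
  defs[[1]] <- c("N", "CA", "CB", g1)
  d2 <- switch(resname,
               LEU = "CD1", ILE = "CD1", MET = "SD", PHE = "CD1",
               TYR = "CD1", TRP = "CD1", HIS = "ND1", ASP = "OD1",
               ASN = "OD1", GLU = "CD", GLN = "CD", LYS = "CD",
               ARG = "CD", PRO = "CD", NULL)
  if (!is.null(d2)) defs[[2]] <- c("CA", "CB", g1, d2)
  d3 <- switch(resname, MET = c("CB", "CG", "SD", "CE"),
               GLU = c("CB", "CG", "CD", "OE1"),
               GLN = c("CB", "CG", "CD", "OE1"),
               LYS = c("CB", "CG", "CD", "CE"),
               ARG = c("CB", "CG", "CD", "NE"), NULL)
  if (!is.null(d3)) defs[[3]] <- d3
  d4 <- switch(resname, LYS = c("CG", "CD", "CE", "NZ"),
               ARG = c("CG", "CD", "NE", "CZ"), NULL)
  if (!is.null(d4)) defs[[4]] <- d4
  defs
}

n_chi <- function(resname) length(chi_defs(resname))

element_of <- function(atom_name) substr(atom_name, 1, 1)

ELEMENT_PARAMS <- list(
  C = list(mass = 12.011, radius = 1.80, eps = 0.08),
  N = list(mass = 14.007, radius = 1.70, eps = 0.17),
  O = list(mass = 15.999, radius = 1.60, eps = 0.12),
  S = list(mass = 32.060, radius = 1.90, eps = 0.30)
)

BACKBONE_CHARGES <- c(N = -0.30, CA = 0.30, C = 0.50, O = -0.50)

# Evaluate a symbolic torsion spec ("X1", "X2+120", or a number) given chi
eval_torsion_spec <- function(spec, chi) {
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^X([0-9])([+-][0-9.]+)?$", spec))[[1]]
  if (length(m) == 0) stop("bad torsion spec: ", spec)
  k <- as.integer(m[2])
  off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
  if (k > length(chi)) stop("chi index out of range for spec ", spec)
  chi[k] + off
}

# Build side-chain coordinates for one residue given its backbone N/CA/C
# positions and chi angles. Returns a named list of 3-vectors.
build_sidechain_coords <- function(resname, bbN, bbCA, bbC, chi = NULL) {
  tpl <- get_templates()[[resname]]
  if (is.null(tpl)) abort_rc("ParameterMissing", "no template for residue %s", resname)
  if (is.null(chi)) chi <- DEFAULT_CHI[[resname]]
  pos <- list(N = bbN, CA = bbCA, C = bbC)
  for (r in tpl$rows) {
    tors <- eval_torsion_spec(r$tors, chi)
    pos[[r$atom]] <- place_atom(pos[[r$tref]], pos[[r$aref]], pos[[r$parent]],
                                r$bond, r$angle, tors)
  }
  pos[setdiff(names(pos), c("N", "CA", "C"))]
}

# Package-level caches
.rc_cache <- new.env(parent = emptyenv())

get_templates <- function() {
  if (is.null(.rc_cache$templates)) .rc_cache$templates <- residue_templates()
  .rc_cache$templates
}

# Reference build of one residue type (backbone + side chain, ideal
# geometry, default chi). Used to measure side-chain bond/angle equilibria.
reference_residue <- function(resname) {
  key <- paste0("ref_", resname)
  if (!is.null(.rc_cache[[key]])) return(.rc_cache[[key]])
  N <- c(0, 0, 0)
  CA <- c(BB_GEOM$b_N_CA, 0, 0)
  th <- BB_GEOM$a_N_CA_C * DEG2RAD
  d <- c(cos(th), sin(th), 0) * BB_GEOM$b_CA_C
  C <- CA + c(-d[1], d[2], 0)  # angle N-CA-C = a_N_CA_C
  sc <- build_sidechain_coords(resname, N, CA, C)
  out <- c(list(N = N, CA = CA, C = C), sc)
  .rc_cache[[key]] <- out
  out
}

# Intra-residue heavy-atom bond list (pairs of atom names) for a type,
# including CB attachment and ring closures. Backbone N-CA, CA-C, C-O
# included; C-O handled by caller since O is built by the chain builder.
residue_bonds <- function(resname) {
  tpl <- get_templates()[[resname]]
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  for (r in tpl$rows) bonds[[length(bonds) + 1]] <- c(r$parent, r$atom)
  for (cl in tpl$closures) bonds[[length(bonds) + 1]] <- cl
  bonds
}

sidechain_atom_names <- function(resname) {
  vapply(get_templates()[[resname]]$rows, function(r) r$atom, character(1))
}

residue_atom_names <- function(resname) {
  c(BACKBONE_ATOMS, sidechain_atom_names(resname))
}

atom_charge <- function(resname, atom) {
  if (atom %in% names(BACKBONE_CHARGES)) return(unname(BACKBONE_CHARGES[atom]))
  ch <- get_templates()[[resname]]$charges
  if (!is.null(ch) && atom %in% names(ch)) return(unname(ch[atom]))
  0
}

# Measured equilibrium geometry tables per residue type: named vectors
# keyed "A1|A2" (bonds) and "A1|A2|A3" (angles) over intra-residue terms
# that involve at least one side-chain atom.
residue_geometry_table <- function(resname) {
  key <- paste0("geom_", resname)
  if (!is.null(.rc_cache[[key]])) return(.rc_cache[[key]])
  ref <- reference_residue(resname)
  bonds <- residue_bonds(resname)
  nbr <- list()
  for (b in bonds) {
    nbr[[b[1]]] <- union(nbr[[b[1]]], b[2])
    nbr[[b[2]]] <- union(nbr[[b[2]]], b[1])
  }
  bl <- c(); al <- c()
  for (b in bonds) {
    if (all(b %in% BACKBONE_ATOMS)) next
    if (!all(b %in% names(ref))) next
    bl[paste(sort(b), collapse = "|")] <- vnorm(ref[[b[1]]] - ref[[b[2]]])
  }
  for (j in names(nbr)) {
    nb <- nbr[[j]]
    if (length(nb) < 2) next
    for (ii in seq_len(length(nb) - 1)) for (kk in (ii + 1):length(nb)) {
      a <- nb[ii]; ck <- nb[kk]
      trip <- c(a, j, ck)
      if (all(trip %in% BACKBONE_ATOMS)) next
      if (!all(trip %in% names(ref))) next
      ends <- sort(c(a, ck))
      al[paste(ends[1], j, ends[2], sep = "|")] <-
        bond_angle(ref[[a]], ref[[j]], ref[[ck]])
    }
  }
  out <- list(bonds = bl, angles = al)
  .rc_cache[[key]] <- out
  out
}

# Force constants (kcal/mol/A^2, kcal/mol/rad^2, kcal/mol); the bonded
# stiffness is capped so that a 4-fs heavy-atom timestep remains stable
# under Langevin integration.
FF_CONST <- list(kb = 250, ka = 40, kt_planar = 10, kt_omega = 8,
                 scale14 = 0.5, cutoff = 12.0, coul_const = 332.0637,
                 hb_strength = 1.5, hb_r0 = 2.9, hb_sigma = 0.3,
                 solv_kpol = 0.03, solv_gamma = 0.005, solv_sigma = 3.5,
                 solv_b0 = 6.0, probe_radius = 1.4)

#' Build the molecular-mechanics topology for a structure
#'
#' Derives bonds, angles, periodic torsions (planarity + peptide omega),
#' nonbonded exclusions (1-2/1-3) and scaled 1-4 pairs, hydrogen-bond
#' donor/acceptor lists, and per-residue chi / phi / psi dihedral atom
#' indices from the atom table of a complex structure.
#'
#' @param atoms atom data.frame with columns `chain`, `resi`, `resname`,
#'   `name` (one row per heavy atom, residues contiguous).
#' @return list of index matrices and parameter vectors used by the
#'   energy core (0-based indices for the C++ side are produced later).
#' @keywords internal
build_topology <- function(atoms) {
  n <- nrow(atoms)
  rid <- paste(atoms$chain, atoms$resi, sep = "|")
  ridx <- match(rid, unique(rid))                 # global residue id
  aidx <- function(r, nm) {
    i <- which(ridx == r & atoms$name == nm)
    if (length(i) != 1) NA_integer_ else i
  }
  nres <- max(ridx)
  res_tab <- data.frame(rid = seq_len(nres))
  res_tab$chain <- atoms$chain[match(res_tab$rid, ridx)]
  res_tab$resi <- atoms$resi[match(res_tab$rid, ridx)]
  res_tab$resname <- atoms$resname[match(res_tab$rid, ridx)]

  # fast per-residue atom-name -> index maps
  amap <- vector("list", nres)
  for (i in seq_len(n)) {
    r <- ridx[i]
    amap[[r]][atoms$name[i]] <- i
  }
  gidx <- function(r, nm) {
    v <- amap[[r]][nm]
    if (is.na(v)) NA_integer_ else unname(v)
  }

  bonds_i <- integer(0); bonds_j <- integer(0); bonds_b0 <- numeric(0)
  add_bond <- function(i, j, b0) {
    bonds_i[length(bonds_i) + 1] <<- i
    bonds_j[length(bonds_j) + 1] <<- j
    bonds_b0[length(bonds_b0) + 1] <<- b0
  }
  tors <- list()
  add_tor <- function(i, j, k, l, kt, per, delta) {
    tors[[length(tors) + 1]] <<- c(i, j, k, l, kt, per, delta)
  }

  for (r in seq_len(nres)) {
    rn <- res_tab$resname[r]
    geom <- residue_geometry_table(rn)
    for (b in residue_bonds(rn)) {
      i <- gidx(r, b[1]); j <- gidx(r, b[2])
      if (is.na(i) || is.na(j)) next
      keyb <- paste(sort(b), collapse = "|")
      b0 <- if (keyb %in% names(geom$bonds)) geom$bonds[[keyb]] else {
        switch(paste(sort(b), collapse = "-"),
               "CA-N" = BB_GEOM$b_N_CA, "C-CA" = BB_GEOM$b_CA_C,
               "C-O" = BB_GEOM$b_C_O, stop("no bond length for ", keyb))
      }
      add_bond(i, j, b0)
    }
    # peptide bond to next residue in the same chain
    if (r < nres && res_tab$chain[r + 1] == res_tab$chain[r]) {
      i <- gidx(r, "C"); j <- gidx(r + 1, "N")
      add_bond(i, j, BB_GEOM$b_C_N)
      # omega torsion CA-C-N(+1)-CA(+1): trans-planar peptide
      ca1 <- gidx(r, "CA"); ca2 <- gidx(r + 1, "CA")
      add_tor(ca1, i, j, ca2, FF_CONST$kt_omega, 1, 0)
      add_tor(ca1, i, j, ca2, FF_CONST$kt_omega, 2, 180)
      # carbonyl O planarity: CA, N(+1), C, O coplanar
      o1 <- gidx(r, "O")
      add_tor(ca1, j, i, o1, FF_CONST$kt_planar, 2, 180)
    }
    # side-chain planarity quadruples
    for (q in get_templates()[[rn]]$planar) {
      ii <- vapply(q, function(nm) gidx(r, nm), integer(1))
      if (anyNA(ii)) next
      add_tor(ii[1], ii[2], ii[3], ii[4], FF_CONST$kt_planar, 2, 180)
    }
  }

  # bond adjacency
  adj <- vector("list", n)
  for (b in seq_along(bonds_i)) {
    i <- bonds_i[b]; j <- bonds_j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  # angles from the bond graph
  ang_i <- integer(0); ang_j <- integer(0); ang_k <- integer(0)
  ang_th0 <- numeric(0)
  std_angle <- function(a, j, k) {
    # authored backbone / cross-residue values, else measured table
    nms <- c(atoms$name[a], atoms$name[j], atoms$name[k])
    same_res <- ridx[a] == ridx[j] && ridx[j] == ridx[k]
    if (same_res && !all(nms %in% BACKBONE_ATOMS)) {
      geom <- residue_geometry_table(atoms$resname[j])
      ends <- sort(nms[c(1, 3)])
      key <- paste(ends[1], nms[2], ends[2], sep = "|")
      if (key %in% names(geom$angles)) return(geom$angles[[key]])
    }
    key2 <- paste(sort(nms[c(1, 3)]), collapse = "-")
    v <- switch(paste(nms[2], key2, sep = ":"),
                "CA:C-N" = BB_GEOM$a_N_CA_C,
                "C:CA-O" = BB_GEOM$a_CA_C_O,
                "C:CA-N" = BB_GEOM$a_CA_C_N,
                "C:N-O" = BB_GEOM$a_O_C_N,
                "N:C-CA" = BB_GEOM$a_C_N_CA,
                "N:C-CD" = 125.0,      # proline N
                "CA:CB-N" = BB_GEOM$a_N_CA_CB,
                NULL)
    if (!is.null(v)) return(v)
    # fallback: tetrahedral-ish
    111.0
  }
  for (j in seq_len(n)) {
    nb <- unique(adj[[j]])
    if (length(nb) < 2) next
    for (p in seq_len(length(nb) - 1)) for (q in (p + 1):length(nb)) {
      a <- nb[p]; k <- nb[q]
      ang_i[length(ang_i) + 1] <- a
      ang_j[length(ang_j) + 1] <- j
      ang_k[length(ang_k) + 1] <- k
      ang_th0[length(ang_th0) + 1] <- std_angle(a, j, k)
    }
  }

  # exclusions (1-2, 1-3) and 1-4 pairs
  key_of <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    (lo - 1) * n + (hi - 1)
  }
  excl <- key_of(bonds_i, bonds_j)
  excl <- c(excl, key_of(ang_i, ang_k))
  excl <- unique(excl)
  # 1-4: endpoints of paths of length 3
  p14 <- c()
  for (b in seq_along(bonds_i)) {
    j <- bonds_i[b]; k <- bonds_j[b]
    for (a in adj[[j]]) for (l in adj[[k]]) {
      if (a == k || l == j || a == l) next
      p14 <- c(p14, key_of(a, l))
    }
  }
  p14 <- setdiff(unique(p14), excl)

  # hydrogen-bond donor/acceptor lists: all N (donor), all O (acceptor,
  # with its bonded heavy-atom antecedent for the angle term)
  don <- which(element_of(atoms$name) == "N")
  acc <- which(element_of(atoms$name) == "O")
  accC <- vapply(acc, function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0) NA_integer_ else nb[1]
  }, integer(1))
  keep <- !is.na(accC)
  acc <- acc[keep]; accC <- accC[keep]

  # chi / phi / psi dihedral index tables
  chi_rows <- list()
  for (r in seq_len(nres)) {
    defs <- chi_defs(res_tab$resname[r])
    for (k in seq_along(defs)) {
      ii <- vapply(defs[[k]], function(nm) gidx(r, nm), integer(1))
      if (anyNA(ii)) next
      chi_rows[[length(chi_rows) + 1]] <- c(r, k, ii)
    }
  }
  phipsi <- list()
  for (r in seq_len(nres)) {
    phi <- rep(NA_integer_, 4); psi <- rep(NA_integer_, 4)
    if (r > 1 && res_tab$chain[r - 1] == res_tab$chain[r])
      phi <- c(gidx(r - 1, "C"), gidx(r, "N"), gidx(r, "CA"), gidx(r, "C"))
    if (r < nres && res_tab$chain[r + 1] == res_tab$chain[r])
      psi <- c(gidx(r, "N"), gidx(r, "CA"), gidx(r, "C"), gidx(r + 1, "N"))
    phipsi[[r]] <- list(phi = phi, psi = psi)
  }

  tor_mat <- if (length(tors)) do.call(rbind, tors) else matrix(0, 0, 7)

  list(
    n_atoms = n,
    residue_index = ridx,
    residues = res_tab,
    amap = amap,
    bonds = cbind(i = bonds_i, j = bonds_j),
    bonds_b0 = bonds_b0,
    angles = cbind(i = ang_i, j = ang_j, k = ang_k),
    angles_th0 = ang_th0 * DEG2RAD,
    torsions = tor_mat,   # i j k l kt per delta(deg)
    excl_keys = sort(excl),
    p14_keys = sort(p14),
    hb_donors = don,
    hb_acceptors = cbind(o = acc, c = accC),
    chi_table = if (length(chi_rows)) do.call(rbind, chi_rows) else matrix(0, 0, 6),
    phipsi = phipsi
  )
}
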