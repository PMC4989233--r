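# Packaged parameter tables: rotamer library, backbone (phi/psi) torsion
# statistics, and the pluggable pairwise statistical potential.
#
# The shipped tables are deliberately small: a coarse rotamer library with
# canonical gauche-/trans/gauche+ chi values, and 10-degree phi/psi grids
# that are uniform except for enhanced probability near ideal helix and
# sheet basins. The pairwise statistical potential defaults to a flat zero
# table; it is an architectural slot into which a fitted potential can be
# loaded.

# ---- rotamer library -------------------------------------------------------

ROTAMER_ROWS <- list(
  # resname, chi (deg), probability
  list("SER", c(-65), 0.45), list("SER", c(180), 0.30), list("SER", c(65), 0.25),
  list("CYS", c(-65), 0.50), list("CYS", c(180), 0.30), list("CYS", c(65), 0.20),
  list("THR", c(-60), 0.45), list("THR", c(60), 0.45), list("THR", c(180), 0.10),
  list("VAL", c(175), 0.60), list("VAL", c(-60), 0.25), list("VAL", c(65), 0.15),
  list("LEU", c(-65, 175), 0.60), list("LEU", c(175, 65), 0.30),
  list("LEU", c(-85, 65), 0.10),
  list("ILE", c(-65, 170), 0.60), list("ILE", c(-57, -60), 0.20),
  list("ILE", c(62, 170), 0.20),
  list("MET", c(-65, 180, 75), 0.40), list("MET", c(-65, 180, 180), 0.30),
  list("MET", c(180, 180, 75), 0.30),
  list("PHE", c(-65, 90), 0.50), list("PHE", c(180, 80), 0.35),
  list("PHE", c(65, 90), 0.15),
  list("TYR", c(-65, 90), 0.50), list("TYR", c(180, 80), 0.35),
  list("TYR", c(65, 90), 0.15),
  list("TRP", c(-65, 95), 0.40), list("TRP", c(180, -105), 0.30),
  list("TRP", c(65, -90), 0.30),
  list("HIS", c(-65, -70), 0.40), list("HIS", c(180, 60), 0.30),
  list("HIS", c(-65, 80), 0.30),
  list("ASP", c(-70, -15), 0.50), list("ASP", c(180, 0), 0.30),
  list("ASP", c(65, -15), 0.20),
  list("ASN", c(-65, -20), 0.45), list("ASN", c(180, 30), 0.30),
  list("ASN", c(65, -20), 0.25),
  list("GLU", c(-65, 180, -10), 0.40), list("GLU", c(180, 180, 0), 0.35),
  list("GLU", c(-65, -65, -40), 0.25),
  list("GLN", c(-65, 180, 0), 0.40), list("GLN", c(180, 180, 0), 0.35),
  list("GLN", c(-65, -65, -40), 0.25),
  list("LYS", c(-65, 180, 180, 180), 0.40), list("LYS", c(180, 180, 180, 180), 0.35),
  list("LYS", c(65, 180, 180, 180), 0.25),
  list("ARG", c(-65, 180, 180, 85), 0.40), list("ARG", c(180, 180, 180, 180), 0.35),
  list("ARG", c(65, 180, 180, -85), 0.25)
)

rotamer_library_from_rows <- function(rows) {
  lib <- list()
  for (r in rows) {
    rn <- r[[1]]
    if (is.null(lib[[rn]])) lib[[rn]] <- list(chi = NULL, prob = numeric(0))
    lib[[rn]]$chi <- rbind(lib[[rn]]$chi, r[[2]])
    lib[[rn]]$prob <- c(lib[[rn]]$prob, r[[3]])
  }
  for (rn in names(lib)) {
    lib[[rn]]$prob <- lib[[rn]]$prob / sum(lib[[rn]]$prob)
    rownames(lib[[rn]]$chi) <- NULL
  }
  class(lib) <- "RotamerLibrary"
  lib
}

#' The packaged rotamer library
#'
#' One coarse rotamer set per side-chain type with rotatable chi dihedrals
#' (ALA/GLY/PRO carry no entries and are never repacked). Probabilities per
#' type sum to 1.
#'
#' @return a `RotamerLibrary`: named list with per-type `chi` matrix
#'   (rotamers x chi, degrees) and `prob` vector.
#' @export
default_rotamer_library <- function() {
  if (is.null(.rc_cache$rotamers)) {
    path <- system.file("extdata", "rotamers.tsv", package = "refinecomplex")
    .rc_cache$rotamers <- if (nzchar(path) && file.exists(path))
      read_rotamer_library(path)
    else
      rotamer_library_from_rows(ROTAMER_ROWS)
  }
  .rc_cache$rotamers
}

#' Read a rotamer library from a plain-text table
#'
#' Format: tab-separated with header `resname chi1 chi2 chi3 chi4 prob`;
#' unused chi columns are `NA`.
#' @param path file path.
#' @return a `RotamerLibrary`.
#' @export
read_rotamer_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    chis <- as.numeric(df[i, c("chi1", "chi2", "chi3", "chi4")])
    list(df$resname[i], chis[!is.na(chis)], df$prob[i])
  })
  rotamer_library_from_rows(rows)
}

#' Write a rotamer library to a plain-text table
#' @param library a `RotamerLibrary`. @param path output path.
#' @export
write_rotamer_library <- function(library, path) {
  rows <- list()
  for (rn in names(library)) {
    ch <- library[[rn]]$chi
    for (i in seq_len(nrow(ch))) {
      v <- rep(NA_real_, 4)
      v[seq_len(ncol(ch))] <- ch[i, ]
      rows[[length(rows) + 1]] <- data.frame(resname = rn, chi1 = v[1],
                                             chi2 = v[2], chi3 = v[3],
                                             chi4 = v[4],
                                             prob = library[[rn]]$prob[i])
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}

# ---- phi/psi (Ramachandran-style) statistics ------------------------------

RAMA_GRID <- seq(-180, 170, by = 10)

# wrapped 2D gaussian blob on the torus
rama_blob <- function(phi, psi, mu_phi, mu_psi, sd) {
  dphi <- ang_diff(phi, mu_phi)
  dpsi <- ang_diff(psi, mu_psi)
  exp(-(dphi^2 + dpsi^2) / (2 * sd^2))
}

make_rama_grid <- function(class) {
  g <- expand.grid(phi = RAMA_GRID, psi = RAMA_GRID)
  base <- 0.15
  p <- rep(base, nrow(g))
  if (class == "GLY") {
    p <- p + 2.0 * rama_blob(g$phi, g$psi, 80, -170, 35) +
      2.0 * rama_blob(g$phi, g$psi, -80, 170, 35) +
      1.5 * rama_blob(g$phi, g$psi, -63, -43, 30) +
      1.5 * rama_blob(g$phi, g$psi, 63, 43, 30)
  } else if (class == "PRO") {
    p <- p + 3.0 * rama_blob(g$phi, g$psi, -60, -30, 25) +
      2.0 * rama_blob(g$phi, g$psi, -60, 140, 30)
  } else {
    p <- p + 3.0 * rama_blob(g$phi, g$psi, -63, -43, 30) +
      2.0 * rama_blob(g$phi, g$psi, -120, 130, 40) +
      0.5 * rama_blob(g$phi, g$psi, 60, 45, 25)
  }
  p <- p / sum(p)
  # energy relative to the uniform distribution: 0 for a flat table
  e <- -log(p * length(p))
  matrix(e, nrow = length(RAMA_GRID), ncol = length(RAMA_GRID))
}

#' The packaged backbone torsion-statistics tables
#'
#' Minus-log-probability lookups on a 10-degree phi/psi grid, relative to a
#' uniform background (a flat table scores 0 everywhere), for three residue
#' classes: general, glycine and proline.
#' @return named list of 36 x 36 energy matrices.
#' @export
default_rama_tables <- function() {
  if (is.null(.rc_cache$rama)) {
    path <- system.file("extdata", "rama.tsv", package = "refinecomplex")
    .rc_cache$rama <- if (nzchar(path) && file.exists(path))
      read_rama_tables(path)
    else
      list(general = make_rama_grid("general"), GLY = make_rama_grid("GLY"),
           PRO = make_rama_grid("PRO"))
  }
  .rc_cache$rama
}

# matrix layout: one row per (class, phi) with 36 psi-bin energies
read_rama_tables <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, ]
    m <- as.matrix(sub[order(match(sub$phi, RAMA_GRID)), -(1:2)])
    dimnames(m) <- NULL
    out[[cl]] <- m
  }
  out
}

write_rama_tables <- function(tables, path) {
  rows <- do.call(rbind, lapply(names(tables), function(cl) {
    m <- round(tables[[cl]], 4)
    cbind(data.frame(class = cl, phi = RAMA_GRID), as.data.frame(m))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

rama_class <- function(resname) {
  if (resname == "GLY") "GLY" else if (resname == "PRO") "PRO" else "general"
}

rama_lookup <- function(tables, resname, phi, psi) {
  m <- tables[[rama_class(resname)]]
  i <- findInterval(phi, c(RAMA_GRID, 180), rightmost.closed = TRUE)
  j <- findInterval(psi, c(RAMA_GRID, 180), rightmost.closed = TRUE)
  m[max(1, min(36, i)), max(1, min(36, j))]
}

# ---- pairwise statistical potential (dDFIRE-like slot) --------------------

PAIRSTAT_BREAKS <- seq(0, 15, by = 0.5)

#' A flat (zero) pairwise statistical potential
#'
#' The pairwise residue-residue term is an architectural slot: energies are
#' looked up per residue-type pair and Cbeta-Cbeta distance bin. The shipped
#' default is identically zero; [make_parameter_tables()] builds a synthetic
#' non-zero table for exercising the slot.
#' @return a `PairStatTable`: list with `breaks` and a named list `energy`
#'   of per-pair bin vectors (missing pairs score 0).
#' @export
flat_pairstat_table <- function() {
  structure(list(breaks = PAIRSTAT_BREAKS, energy = list()),
            class = "PairStatTable")
}

pairstat_key <- function(r1, r2) paste(sort(c(r1, r2)), collapse = "-")

#' Generate the packaged parameter tables
#'
#' Returns a self-consistent set of parameter tables covering every residue
#' type the fixture generator emits: the per-element force-field constants,
#' the rotamer library, the phi/psi statistics and a synthetic (seeded)
#' pairwise statistical potential.
#'
#' @param seed integer seed for the synthetic pairwise table.
#' @return list with `forcefield`, `rotamers`, `rama`, `pairstat`.
#' @export
make_parameter_tables <- function(seed = 1) {
  ps <- flat_pairstat_table()
  nbin <- length(PAIRSTAT_BREAKS) - 1
  ps$energy <- with_seed(seed, {
    keys <- outer(AA3, AA3, Vectorize(pairstat_key))
    keys <- unique(as.vector(keys))
    setNames(lapply(keys, function(k) round(stats::rnorm(nbin, 0, 0.1), 4)), keys)
  })
  list(forcefield = list(elements = ELEMENT_PARAMS, constants = FF_CONST,
                         backbone = BB_GEOM),
       rotamers = rotamer_library_from_rows(ROTAMER_ROWS),
       rama = list(general = make_rama_grid("general"),
                   GLY = make_rama_grid("GLY"), PRO = make_rama_grid("PRO")),
       pairstat = ps)
}

# ---- energy weights --------------------------------------------------------

ENERGY_TERMS <- c("bonded", "vdw", "coulomb", "solv_polar", "solv_nonpolar",
                  "hbond", "pairstat", "rama", "rotamer",
                  "restraint_distance", "restraint_position")

#' Default energy-term weights
#'
#' One weight per term of the hybrid refinement energy (a linear
#' combination of physics-based, knowledge-based and restraint terms). All
#' weights default to 1; the restraint terms carry their own per-restraint
#' force constants, so these weights act as term-level switches.
#'
#' @param ... named overrides, e.g. `default_energy_weights(vdw = 0.5)`.
#' @return named numeric vector over all energy terms.
#' @export
default_energy_weights <- function(...) {
  w <- setNames(rep(1, length(ENERGY_TERMS)), ENERGY_TERMS)
  ov <- list(...)
  bad <- setdiff(names(ov), ENERGY_TERMS)
  if (length(bad)) abort_rc("WeightError", "unknown energy term(s): %s",
                            paste(bad, collapse = ","))
  for (nm in names(ov)) w[nm] <- ov[[nm]]
  if (any(w < 0)) abort_rc("WeightError", "energy weights must be >= 0")
  w
}
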