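# Interface detection and restraint construction.
#
# Interfacial residues are those within 8 A CA-CA distance of any residue
# of another chain. Restraints tether the model to its input geometry:
# harmonic distance restraints on CA-CA and backbone N-O pairs below 10 A
# (interface pairs with a much smaller weight), and, under protocol 2,
# harmonic position restraints on every CA.

#' Detect interfacial residues
#'
#' @param structure a `ComplexStructure` with >= 2 chains.
#' @param cutoff CA-CA distance cutoff in Angstrom (strict inequality).
#' @return an `InterfaceSet`: list with `members` (data.frame `chain`,
#'   `resi`) and `cutoff`.
#' @export
detect_interface <- function(structure, cutoff = 8.0) {
  a <- structure$atoms
  if (length(unique(a$chain)) < 2)
    abort_rc("ChainCountError", "interface detection needs >= 2 chains")
  ca <- which(a$name == "CA")
  rt <- structure$topology$residues
  if (length(ca) != nrow(rt)) abort_rc("MissingCA", "residue without CA atom")
  xyz <- get_coords(structure)[ca, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  inter <- outer(rt$chain, rt$chain, "!=")
  hit <- (d < cutoff) & inter
  members <- rt[apply(hit, 1, any), c("chain", "resi"), drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, cutoff = cutoff), class = "InterfaceSet")
}

#' @export
print.InterfaceSet <- function(x, ...) {
  cat(sprintf("InterfaceSet: %d residues at %.1f A CA-CA cutoff\n",
              nrow(x$members), x$cutoff))
  invisible(x)
}

#' Default restraint weights
#'
#' Harmonic force constants in energy/A^2. The interface distance weight is
#' much smaller than the non-interface weight so that interface geometry can
#' move, and the position weight is small to allow global changes in the
#' inter-protein orientation.
#' @param w_non non-interface distance weight.
#' @param w_intf interface distance weight (must be < `w_non`).
#' @param w_pos CA position-restraint weight (protocol 2).
#' @return named list of weights.
#' @export
restraint_weights <- function(w_non = 1.0, w_intf = 0.1, w_pos = 0.05) {
  if (w_non <= 0 || w_intf <= 0 || w_pos <= 0)
    abort_rc("WeightError", "restraint weights must be positive")
  if (w_intf >= w_non)
    abort_rc("WeightError", "interface weight must be smaller than non-interface")
  list(w_non = w_non, w_intf = w_intf, w_pos = w_pos)
}

#' Build the restraint set for a refinement protocol
#'
#' Distance restraints are placed on every CA-CA pair and every backbone
#' amide-N / carbonyl-O pair (different residues, sequence-adjacent pairs
#' excluded for N-O) with reference distance below 10 A in the input
#' structure; pairs with an interfacial endpoint get the smaller interface
#' weight. Protocol 2 adds a position restraint on every CA anchored at its
#' input position.
#'
#' @param structure the input `ComplexStructure` (restraint references).
#' @param interface an `InterfaceSet` computed on the same structure.
#' @param protocol 1 (distance only) or 2 (distance + position).
#' @param weights a [restraint_weights()] list.
#' @param dmax reference-distance cutoff in Angstrom (strict).
#' @return a `RestraintSet`: list with data.frames `distance` (`i`, `j`
#'   atom indices, `d0`, `weight`, `interface`) and `position` (`i`, `x0`,
#'   `y0`, `z0`, `weight`), plus `protocol`.
#' @export
build_restraints <- function(structure, interface, protocol = 1,
                             weights = restraint_weights(), dmax = 10.0) {
  stopifnot(protocol %in% c(1L, 2L))
  a <- structure$atoms
  xyz <- get_coords(structure)
  rt <- structure$topology$residues
  ridx <- structure$topology$residue_index
  ifkey <- paste(interface$members$chain, interface$members$resi)
  res_if <- paste(rt$chain, rt$resi) %in% ifkey

  pair_rows <- function(ii, jj) {
    # all (ii x jj) atom pairs below dmax, annotated with interface flag
    di <- xyz[ii, , drop = FALSE]
    dj <- xyz[jj, , drop = FALSE]
    d2 <- outer(rowSums(di^2), rowSums(dj^2), "+") - 2 * di %*% t(dj)
    d2[d2 < 0] <- 0
    keep <- which(sqrt(d2) < dmax, arr.ind = TRUE)
    if (nrow(keep) == 0) return(NULL)
    data.frame(i = ii[keep[, 1]], j = jj[keep[, 2]],
               d0 = sqrt(d2)[keep])
  }

  ca <- which(a$name == "CA")
  rows <- list()
  # CA-CA: unordered pairs
  pr <- pair_rows(ca, ca)
  if (!is.null(pr)) rows$ca <- pr[pr$i < pr$j, , drop = FALSE]
  # N-O: backbone amide N to backbone carbonyl O, different residues,
  # |i - j| > 1 within a chain
  nn <- which(a$name == "N")
  oo <- which(a$name == "O")
  pr <- pair_rows(nn, oo)
  if (!is.null(pr)) {
    ri <- ridx[pr$i]; rj <- ridx[pr$j]
    same_chain <- rt$chain[ri] == rt$chain[rj]
    adj <- same_chain & abs(rt$resi[ri] - rt$resi[rj]) <= 1
    rows$no <- pr[ri != rj & !adj, , drop = FALSE]
  }
  dist <- do.call(rbind, rows)
  if (is.null(dist)) dist <- data.frame(i = integer(0), j = integer(0),
                                        d0 = numeric(0))
  iface <- res_if[ridx[dist$i]] | res_if[ridx[dist$j]]
  dist$weight <- ifelse(iface, weights$w_intf, weights$w_non)
  dist$interface <- iface
  rownames(dist) <- NULL

  if (protocol == 2) {
    pos <- data.frame(i = ca, x0 = xyz[ca, 1], y0 = xyz[ca, 2],
                      z0 = xyz[ca, 3], weight = weights$w_pos)
  } else {
    pos <- data.frame(i = integer(0), x0 = numeric(0), y0 = numeric(0),
                      z0 = numeric(0), weight = numeric(0))
  }
  structure(list(distance = dist, position = pos, protocol = protocol),
            class = "RestraintSet")
}

#' An empty restraint set (no tethering)
#' @export
empty_restraints <- function() {
  structure(list(distance = data.frame(i = integer(0), j = integer(0),
                                       d0 = numeric(0), weight = numeric(0),
                                       interface = logical(0)),
                 position = data.frame(i = integer(0), x0 = numeric(0),
                                       y0 = numeric(0), z0 = numeric(0),
                                       weight = numeric(0)),
                 protocol = 1L), class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf("RestraintSet (protocol %d): %d distance (%d interface), %d position\n",
              x$protocol, nrow(x$distance), sum(x$distance$interface),
              nrow(x$position)))
  invisible(x)
}

#' Write a restraint set to a tab-separated file
#' @param restraints a `RestraintSet`. @param path output path.
#' @export
write_restraints <- function(restraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protocol\t%d", restraints$protocol), con)
  d <- restraints$distance
  writeLines("type\ti\tj\td0\tx0\ty0\tz0\tweight\tinterface", con)
  if (nrow(d))
    writeLines(sprintf("dist\t%d\t%d\t%.6f\tNA\tNA\tNA\t%.6f\t%d",
                       d$i, d$j, d$d0, d$weight, as.integer(d$interface)), con)
  p <- restraints$position
  if (nrow(p))
    writeLines(sprintf("pos\t%d\tNA\tNA\t%.6f\t%.6f\t%.6f\t%.6f\t0",
                       p$i, p$x0, p$y0, p$z0, p$weight), con)
  invisible(NULL)
}

#' Read a restraint set written by [write_restraints()]
#' @param path file path.
#' @return a `RestraintSet`.
#' @export
read_restraints <- function(path) {
  first <- readLines(path, n = 1)
  protocol <- as.integer(sub("# protocol\t", "", first))
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  d <- df[df$type == "dist", ]
  p <- df[df$type == "pos", ]
  structure(list(
    distance = data.frame(i = d$i, j = d$j, d0 = d$d0, weight = d$weight,
                          interface = as.logical(d$interface)),
    position = data.frame(i = p$i, x0 = p$x0, y0 = p$y0, z0 = p$z0,
                          weight = p$weight),
    protocol = protocol), class = "RestraintSet")
}
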