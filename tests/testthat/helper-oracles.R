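# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive double loops (and bio3d superposition where a rigid
# fit is needed), sharing no code path with the package internals they
# check.

oracle_interface <- function(s, cutoff = 8) {
  a <- s$atoms
  ca <- a[a$name == "CA", ]
  hits <- list()
  for (i in seq_len(nrow(ca))) {
    found <- FALSE
    for (j in seq_len(nrow(ca))) {
      if (ca$chain[i] == ca$chain[j]) next
      d <- sqrt(sum((as.numeric(ca[i, c("x", "y", "z")]) -
                     as.numeric(ca[j, c("x", "y", "z")]))^2))
      if (d < cutoff) { found <- TRUE; break }
    }
    if (found) hits[[length(hits) + 1]] <- c(ca$chain[i], ca$resi[i])
  }
  if (length(hits) == 0) return(character(0))
  sort(vapply(hits, paste, character(1), collapse = " "))
}

# all restrained atom pairs (CA-CA and N-O) below dmax, as sorted key strings
oracle_restraint_pairs <- function(s, dmax = 10) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  keys <- character(0)
  ca <- which(a$name == "CA")
  for (p in seq_along(ca)) for (q in seq_along(ca)) {
    if (p >= q) next
    d <- sqrt(sum((xyz[ca[p], ] - xyz[ca[q], ])^2))
    if (d < dmax) keys <- c(keys, paste(ca[p], ca[q]))
  }
  nn <- which(a$name == "N")
  oo <- which(a$name == "O")
  for (i in nn) for (j in oo) {
    same_res <- a$chain[i] == a$chain[j] & a$resi[i] == a$resi[j]
    adj <- a$chain[i] == a$chain[j] & abs(a$resi[i] - a$resi[j]) <= 1
    if (same_res || adj) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < dmax) keys <- c(keys, paste(i, j))
  }
  sort(keys)
}

# naive per-term energy sums (smooth terms)
oracle_energy_terms <- function(s, rs, vdw_scale = 1) {
  top <- s$topology
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  fc <- refinecomplex:::FF_CONST
  dih <- function(i, j, k, l)
    refinecomplex:::dihedral_angle(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ])
  ang <- function(i, j, k)
    refinecomplex:::bond_angle(xyz[i, ], xyz[j, ], xyz[k, ])
  dd <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  e_bond <- 0
  for (b in seq_len(nrow(top$bonds)))
    e_bond <- e_bond + fc$kb * (dd(top$bonds[b, 1], top$bonds[b, 2]) -
                                  top$bonds_b0[b])^2
  for (q in seq_len(nrow(top$angles)))
    e_bond <- e_bond + fc$ka *
      (ang(top$angles[q, 1], top$angles[q, 2], top$angles[q, 3]) * pi / 180 -
         top$angles_th0[q])^2
  for (t in seq_len(nrow(top$torsions))) {
    tr <- top$torsions[t, ]
    phi <- dih(tr[1], tr[2], tr[3], tr[4]) * pi / 180
    e_bond <- e_bond + tr[5] * (1 + cos(tr[6] * phi - tr[7] * pi / 180))
  }

  in_set <- function(i, j, keys) ((min(i, j) - 1) * n + max(i, j) - 1) %in% keys
  e_lj <- 0; e_coul <- 0
  burial <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- dd(i, j)
    if (r >= fc$cutoff) next
    burial[i] <- burial[i] + exp(-r^2 / (2 * fc$solv_sigma^2))
    burial[j] <- burial[j] + exp(-r^2 / (2 * fc$solv_sigma^2))
    if (in_set(i, j, top$excl_keys)) next
    sc <- if (in_set(i, j, top$p14_keys)) fc$scale14 else 1
    sig <- (a$radius[i] + a$radius[j]) * vdw_scale
    eps <- sqrt(a$eps[i] * a$eps[j])
    e_lj <- e_lj + sc * 4 * eps * ((sig / r)^12 - (sig / r)^6)
    e_coul <- e_coul + sc * fc$coul_const * a$charge[i] * a$charge[j] / (4 * r^2)
  }
  e_pol <- sum(fc$solv_kpol * a$charge^2 * burial)
  sasa <- 4 * pi * (a$radius + fc$probe_radius)^2
  e_np <- sum(fc$solv_gamma * sasa * exp(-burial / fc$solv_b0))

  e_hb <- 0
  for (iN in top$hb_donors) for (b in seq_len(nrow(top$hb_acceptors))) {
    iO <- top$hb_acceptors[b, 1]; iC <- top$hb_acceptors[b, 2]
    if (top$residue_index[iN] == top$residue_index[iO]) next
    if (in_set(iN, iO, top$excl_keys)) next
    r <- dd(iN, iO)
    if (r > 4.2 || r < 1e-3) next
    fd <- exp(-((r - fc$hb_r0) / fc$hb_sigma)^2)
    costh <- sum((xyz[iC, ] - xyz[iO, ]) * (xyz[iN, ] - xyz[iO, ])) /
      (dd(iC, iO) * r)
    e_hb <- e_hb - fc$hb_strength * fd * 0.5 * (1 - costh)
  }

  e_rd <- 0
  d <- rs$distance
  for (k in seq_len(nrow(d)))
    e_rd <- e_rd + d$weight[k] * (dd(d$i[k], d$j[k]) - d$d0[k])^2
  e_rp <- 0
  p <- rs$position
  for (k in seq_len(nrow(p)))
    e_rp <- e_rp + p$weight[k] *
      sum((xyz[p$i[k], ] - c(p$x0[k], p$y0[k], p$z0[k]))^2)

  c(bonded = e_bond, vdw = e_lj, coulomb = e_coul, solv_polar = e_pol,
    solv_nonpolar = e_np, hbond = e_hb, restraint_distance = e_rd,
    restraint_position = e_rp)
}

# bio3d-based superposition RMSD oracles
oracle_lrmsd <- function(model, reference) {
  ra <- reference$atoms; ma <- model$atoms
  bb <- c("N", "CA", "C", "O")
  counts <- table(ra$chain)
  rec <- names(counts)[which.max(counts)]
  lig <- setdiff(unique(ra$chain), rec)
  sel_r <- which(ra$chain %in% rec & ra$name %in% bb)
  sel_l <- which(ra$chain %in% lig & ra$name %in% bb)
  rxyz <- as.numeric(t(as.matrix(ra[, c("x", "y", "z")])))
  mxyz <- as.numeric(t(as.matrix(ma[, c("x", "y", "z")])))
  fit <- bio3d::fit.xyz(fixed = rxyz, mobile = mxyz,
                        fixed.inds = bio3d::atom2xyz(sel_r),
                        mobile.inds = bio3d::atom2xyz(sel_r))
  sqrt(mean((matrix(fit, ncol = 3, byrow = TRUE)[sel_l, ] -
               matrix(rxyz, ncol = 3, byrow = TRUE)[sel_l, ])^2 * 3))
}

oracle_fnat <- function(model, reference, cutoff = 5) {
  ra <- reference$atoms; ma <- model$atoms
  contacts <- function(a) {
    keys <- character(0)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
      if (a$chain[i] >= a$chain[j]) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff)
        keys <- c(keys, paste(a$chain[i], a$resi[i], a$chain[j], a$resi[j]))
    }
    unique(keys)
  }
  nat <- contacts(ra)
  length(intersect(nat, contacts(ma))) / length(nat)
}
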