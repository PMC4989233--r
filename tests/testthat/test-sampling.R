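test_that("minimization is monotone and solves closed-form problems", {
  s <- fx_small_dimer()
  rs <- build_restraints(s, detect_interface(s), protocol = 2)
  e_in <- total_energy(s, rs)$total
  sm <- minimize(s, rs)
  expect_lte(total_energy(sm, rs)$total, e_in)
  # a second call is (close to) a fixed point
  sm2 <- minimize(sm, rs)
  expect_lte(total_energy(sm2, rs)$total, total_energy(sm, rs)$total)
  expect_lt(refinecomplex:::coord_rmsd(get_coords(sm2), get_coords(sm)), 0.3)
})

test_that("a displaced atom under one position restraint returns to its anchor", {
  s <- fx_small_dimer()
  ca <- which(s$atoms$name == "CA")[3]
  xyz <- get_coords(s)
  rs <- empty_restraints()
  rs$position <- data.frame(i = ca, x0 = xyz[ca, 1], y0 = xyz[ca, 2],
                            z0 = xyz[ca, 3], weight = 0.5)
  w <- default_energy_weights(bonded = 0, vdw = 0, coulomb = 0,
                              solv_polar = 0, solv_nonpolar = 0, hbond = 0,
                              pairstat = 0, rama = 0, rotamer = 0,
                              restraint_distance = 0)
  xyz[ca, 1] <- xyz[ca, 1] + 1
  sm <- minimize(set_coords(s, xyz), rs, w, tol = 1e-8)
  expect_equal(unname(get_coords(sm)[ca, 1]), rs$position$x0,
               tolerance = 1e-4)
})

test_that("a Lennard-Jones pair relaxes to its analytic separation", {
  sig <- 2 * 1.80
  s <- toy_pair_structure(0.9 * sig * 2^(1 / 6))
  w <- default_energy_weights(coulomb = 0, solv_polar = 0, solv_nonpolar = 0,
                              hbond = 0, pairstat = 0, rama = 0, rotamer = 0)
  sm <- minimize(s, empty_restraints(), w, max_steps = 2000, tol = 1e-10)
  dfin <- sqrt(sum((get_coords(sm)[1, ] - get_coords(sm)[2, ])^2))
  expect_equal(dfin, sig * 2^(1 / 6), tolerance = 1e-3)
})

test_that("zero-duration MD is the identity", {
  s <- fx_small_dimer()
  out <- md_relax(s, empty_restraints(), params = md_params(4, 0))
  expect_identical(get_coords(out$structure), get_coords(s))
})

test_that("Langevin MD equipartitions a harmonic system", {
  s <- fx_small_dimer()
  xyz <- get_coords(s)
  rs <- empty_restraints()
  rs$position <- data.frame(i = seq_len(nrow(xyz)), x0 = xyz[, 1],
                            y0 = xyz[, 2], z0 = xyz[, 3], weight = 0.5)
  w <- default_energy_weights(bonded = 0, vdw = 0, coulomb = 0,
                              solv_polar = 0, solv_nonpolar = 0, hbond = 0,
                              pairstat = 0, rama = 0, rotamer = 0,
                              restraint_distance = 0)
  md <- md_relax(s, rs, w, md_params(4, 20, 300, friction = 2, seed = 17))
  kBT2 <- 0.0019872041 * 300 / 2
  expect_equal(md$mean_ke_per_dof, kBT2, tolerance = 0.1)
})

test_that("zero-temperature high-friction MD descends in energy", {
  s <- perturb_structure(fx_small_dimer(), sd = 0.05, seed = 8)
  rs <- build_restraints(fx_small_dimer(), detect_interface(fx_small_dimer()))
  e0 <- total_energy(s, rs)$total
  md <- md_relax(s, rs, params = md_params(2, 0.4, 0, friction = 20, seed = 1))
  expect_lt(total_energy(md$structure, rs)$total, e0)
})

test_that("MD with a fixed seed is bit-for-bit reproducible", {
  s <- fx_small_dimer()
  rs <- build_restraints(s, detect_interface(s))
  m1 <- md_relax(s, rs, params = md_params(4, 0.2, 300, seed = 99))
  m2 <- md_relax(s, rs, params = md_params(4, 0.2, 300, seed = 99))
  expect_identical(get_coords(m1$structure), get_coords(m2$structure))
  m3 <- md_relax(s, rs, params = md_params(4, 0.2, 300, seed = 100))
  expect_false(identical(get_coords(m1$structure), get_coords(m3$structure)))
})

test_that("symmetric MD yields exactly symmetric output", {
  s <- fx_c2()
  g <- estimate_symmetry(s)
  rs <- build_restraints(s, detect_interface(s))
  md <- md_relax(s, rs, params = md_params(4, 0.2, 300, seed = 3),
                 symmetry = g)
  xyz <- get_coords(md$structure)
  idxA <- refinecomplex:::chain_atom_idx(md$structure, "A")
  idxB <- refinecomplex:::chain_atom_idx(md$structure, "B")
  tr <- g$transforms[[2]]
  expect_lt(max(abs(xyz[idxB, ] -
                      refinecomplex:::apply_transform(xyz[idxA, ], tr$R, tr$t))),
            1e-9)
})

test_that("cluster selection picks nearest interfacial neighbors", {
  s <- fx_dimer()
  iface <- detect_interface(s)
  cl <- select_clusters(iface, s, n_clusters = 3, max_size = 5, seed = 4)
  expect_length(cl, 3)
  mem <- iface$members
  rids <- refinecomplex:::residue_id(s, mem$chain, mem$resi)
  ca <- vapply(rids, function(r) s$topology$amap[[r]][["CA"]], integer(1))
  pos <- get_coords(s)[ca, , drop = FALSE]
  seeds_seen <- character(0)
  for (cc in cl) {
    expect_lte(nrow(cc), 5)
    # the cluster's seed is its first row; members must be the seed's
    # nearest interfacial residues (brute force)
    skey <- paste(cc$chain[1], cc$resi[1])
    seeds_seen <- c(seeds_seen, skey)
    si <- match(skey, paste(mem$chain, mem$resi))
    d <- sqrt(rowSums(sweep(pos, 2, pos[si, ])^2))
    want <- paste(mem$chain, mem$resi)[order(d)[1:5]]
    expect_setequal(paste(cc$chain, cc$resi), want)
  }
  expect_equal(length(unique(seeds_seen)), 3)  # distinct seeds
  # degenerate cases
  tiny <- iface
  tiny$members <- iface$members[1, , drop = FALSE]
  cl1 <- select_clusters(tiny, s, n_clusters = 3, seed = 1)
  expect_length(cl1, 3)
  for (cc in cl1) expect_equal(nrow(cc), 1)
})

test_that("repacking moves only interface side chains and is seed-deterministic", {
  s <- fx_dimer()
  iface <- detect_interface(s)
  rs <- build_restraints(s, iface)
  r1 <- repack_interface(s, iface, seed = 2, restraints = rs)
  r2 <- repack_interface(s, iface, seed = 2, restraints = rs)
  expect_identical(get_coords(r1$structure), get_coords(r2$structure))
  bb <- s$atoms$backbone
  expect_identical(get_coords(r1$structure)[bb, ], get_coords(s)[bb, ])
  # non-interface atoms are untouched
  ridx <- s$topology$residue_index
  rt <- s$topology$residues
  ifkey <- paste(iface$members$chain, iface$members$resi)
  non_if <- !(paste(rt$chain, rt$resi)[ridx] %in% ifkey)
  expect_identical(get_coords(r1$structure)[non_if, ], get_coords(s)[non_if, ])
})

test_that("repacking an unrotatable interface is the identity", {
  s <- two_residue_pair(6, "ALA")
  iface <- detect_interface(s)
  expect_equal(nrow(iface$members), 2)
  out <- repack_interface(s, iface, seed = 1)
  expect_identical(get_coords(out$structure), get_coords(s))
})

test_that("with one clashing rotamer, only the clash-free one is ever adopted", {
  # single SER residue pair: a two-rotamer library where one rotamer is
  # built to clash with the partner chain; scan separations for a geometry
  # where exactly that split exists
  chis <- seq(-180, 170, by = 10)
  s <- NULL
  for (sep in seq(4.2, 7, by = 0.2)) {
    cand <- two_residue_pair(sep, "SER")
    ok_try <- vapply(chis, function(ch) {
      s2 <- set_residue_chi(cand, 1, ch)
      clash_check(s2, data.frame(chain = "A", resi = 1), vdw_scale = 0.7)
    }, logical(1))
    if (any(ok_try) && any(!ok_try) &&
        nrow(detect_interface(cand)$members) == 2) {
      s <- cand; ok <- ok_try; break
    }
  }
  expect_false(is.null(s))
  iface <- detect_interface(s)
  lib <- list(SER = list(chi = rbind(chis[which(!ok)[1]], chis[which(ok)[1]]),
                         prob = c(0.5, 0.5)))
  class(lib) <- "RotamerLibrary"
  for (seed in 1:5) {
    out <- repack_interface(s, iface, library = lib, n_mc_steps = 5,
                            n_clusters = 1, seed = seed)
    chi_now <- measure_chi(out$structure, 1)
    if (out$n_accepted > 0)
      expect_equal(chi_now, chis[which(ok)[1]], tolerance = 1e-6)
  }
})

test_that("rebuilt side chains reproduce the requested chi angles", {
  s <- fx_dimer()
  rt <- s$topology$residues
  lys <- which(rt$resname == "LYS")[1]
  skip_if(is.na(lys))
  chi <- c(-70, 170, -170, 60)
  s2 <- set_residue_chi(s, lys, chi)
  expect_equal(measure_chi(s2, lys), chi, tolerance = 1e-6)
  # backbone of that residue untouched
  bb_idx <- which(s$topology$residue_index == lys & s$atoms$backbone)
  expect_identical(get_coords(s2)[bb_idx, ], get_coords(s)[bb_idx, ])
})
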