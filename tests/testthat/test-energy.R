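w_dflt <- default_energy_weights()

test_that("restraint terms vanish on the unperturbed input structure", {
  s <- fx_dimer()
  rs <- build_restraints(s, detect_interface(s), protocol = 2)
  eb <- total_energy(s, rs, w_dflt)
  expect_equal(unname(eb$terms["restraint_distance"]), 0, tolerance = 1e-12)
  expect_equal(unname(eb$terms["restraint_position"]), 0, tolerance = 1e-12)
})

test_that("an isolated Lennard-Jones pair reaches its closed-form minimum", {
  # two neutral carbon-like atoms at sigma * 2^(1/6): LJ term exactly -eps
  sig <- 2 * 1.80
  s <- toy_pair_structure(sig * 2^(1 / 6))
  eb <- total_energy(s, empty_restraints(), default_energy_weights())
  expect_equal(unname(eb$terms["vdw"]), -0.08, tolerance = 1e-9)
  # the gradient vanishes at the minimum
  g <- energy_gradient(s, empty_restraints(),
                       default_energy_weights(coulomb = 0, solv_polar = 0,
                                              solv_nonpolar = 0))
  expect_lt(max(abs(g)), 1e-9)
  # repulsive wall: halving the distance makes the term large and positive
  s2 <- toy_pair_structure(sig * 2^(1 / 6) / 2)
  expect_gt(total_energy(s2, empty_restraints())$terms[["vdw"]], 100)
})

test_that("all smooth terms match naive double-loop sums on random structures", {
  s0 <- fx_small_dimer()
  rs <- build_restraints(s0, detect_interface(s0), protocol = 2)
  for (seed in 1:5) {
    s <- perturb_structure(s0, sd = 0.25, seed = seed)
    got <- refinecomplex:::energy_call(s, rs, w_dflt, 1, FALSE)$terms
    want <- oracle_energy_terms(s, rs, 1)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
    # reduced radii during repacking
    got07 <- refinecomplex:::energy_call(s, rs, w_dflt, 0.7, FALSE)$terms
    want07 <- oracle_energy_terms(s, rs, 0.7)
    expect_equal(got07[["vdw"]], want07[["vdw"]], tolerance = 1e-9)
  }
})

test_that("analytic gradients agree with central differences", {
  s0 <- fx_small_dimer()
  rs <- build_restraints(s0, detect_interface(s0), protocol = 2)
  s <- perturb_structure(s0, sd = 0.15, seed = 3)
  xyz <- get_coords(s)
  g <- energy_gradient(s, rs, w_dflt)
  h <- 1e-5
  set.seed(12)
  for (i in sample(nrow(xyz), 8)) for (q in 1:3) {
    xp <- xyz; xp[i, q] <- xp[i, q] + h
    xm <- xyz; xm[i, q] <- xm[i, q] - h
    ep <- refinecomplex:::energy_call(s, rs, w_dflt, 1, FALSE, xyz = xp)$terms
    em <- refinecomplex:::energy_call(s, rs, w_dflt, 1, FALSE, xyz = xm)$terms
    fd <- sum((ep - em) * w_dflt[names(ep)]) / (2 * h)
    expect_equal(g[i, q], fd, tolerance = 1e-4)
  }
})

test_that("a single displaced position restraint has gradient 2 w delta", {
  s <- fx_small_dimer()
  ca <- which(s$atoms$name == "CA")[1]
  rs <- empty_restraints()
  xyz <- get_coords(s)
  rs$position <- data.frame(i = ca, x0 = xyz[ca, 1] - 1, y0 = xyz[ca, 2],
                            z0 = xyz[ca, 3], weight = 0.05)
  w <- default_energy_weights(bonded = 0, vdw = 0, coulomb = 0,
                              solv_polar = 0, solv_nonpolar = 0, hbond = 0,
                              pairstat = 0, rama = 0, rotamer = 0,
                              restraint_distance = 0)
  g <- energy_gradient(s, rs, w)
  expect_equal(g[ca, ], c(0.1, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  g[ca, ] <- 0
  expect_equal(max(abs(g)), 0)   # all other atoms: zero gradient
})

test_that("stretching one distance restraint reproduces w (d - d0)^2", {
  s <- two_residue_pair(5)
  rs <- empty_restraints()
  iA <- 2; iB <- refinecomplex:::chain_atom_idx(s, "B")[2]
  rs$distance <- data.frame(i = iA, j = iB, d0 = 5, weight = 1.0,
                            interface = FALSE)
  xyz <- get_coords(s)
  bidx <- refinecomplex:::chain_atom_idx(s, "B")
  xyz[bidx, 1] <- xyz[bidx, 1] + 1   # 5 -> 6 A
  e <- restraint_energy(set_coords(s, xyz), rs)
  expect_equal(unname(e["distance"]), 1.0, tolerance = 1e-12)
})

test_that("distance restraints are rigid-motion invariant, position restraints are not", {
  s <- fx_small_dimer()
  rs <- build_restraints(s, detect_interface(s), protocol = 2)
  t <- c(1.3, -0.7, 2.1)
  s2 <- set_coords(s, sweep(get_coords(s), 2, t, "+"))
  e <- restraint_energy(s2, rs)
  expect_equal(unname(e["distance"]), 0, tolerance = 1e-9)
  expect_equal(unname(e["position"]),
               sum(rs$position$weight) * sum(t^2), tolerance = 1e-9)
  # physics terms are invariant under the same motion
  R <- refinecomplex:::rotation_about_axis(c(0, 1, 1), 40)
  s3 <- set_coords(s, sweep(get_coords(s) %*% t(R), 2, t, "+"))
  e0 <- total_energy(s, empty_restraints(), w_dflt)
  e3 <- total_energy(s3, empty_restraints(), w_dflt)
  expect_equal(e3$terms[c("bonded", "vdw", "coulomb", "solv_polar",
                          "solv_nonpolar", "hbond")],
               e0$terms[c("bonded", "vdw", "coulomb", "solv_polar",
                          "solv_nonpolar", "hbond")], tolerance = 1e-8)
})

test_that("weights act linearly: zeroing a term removes it, total is the dot product", {
  s <- perturb_structure(fx_small_dimer(), sd = 0.1, seed = 2)
  rs <- build_restraints(fx_small_dimer(), detect_interface(fx_small_dimer()),
                         protocol = 2)
  eb <- total_energy(s, rs, w_dflt)
  expect_equal(eb$total, sum(eb$terms * eb$weights), tolerance = 1e-9)
  w0 <- default_energy_weights(vdw = 0)
  eb0 <- total_energy(s, rs, w0)
  expect_equal(eb0$total, eb$total - eb$terms[["vdw"]], tolerance = 1e-9)
  expect_equal(eb0$terms[["vdw"]], eb$terms[["vdw"]])  # raw term still reported
})

test_that("reduced vdW radii never increase pair repulsion", {
  s <- perturb_structure(fx_small_dimer(), sd = 0.2, seed = 6)
  e1 <- total_energy(s, empty_restraints(), w_dflt, vdw_scale = 1.0)
  e7 <- total_energy(s, empty_restraints(), w_dflt, vdw_scale = 0.7)
  expect_lt(e7$terms[["vdw"]], e1$terms[["vdw"]])
})

test_that("steric check is strict at the overlap boundary", {
  s <- fx_small_dimer()
  res <- data.frame(chain = "A", resi = 1)
  # a side-chain atom rammed into a backbone atom of the other chain
  xyz <- get_coords(s)
  cb <- which(s$atoms$chain == "A" & s$atoms$resi == 1 & s$atoms$name == "CB")
  target <- which(s$atoms$chain == "B" & s$atoms$name == "CA")[1]
  xyz2 <- xyz
  xyz2[cb, ] <- xyz[target, ] + c(0.5, 0, 0)
  expect_false(clash_check(set_coords(s, xyz2), res, vdw_scale = 1.0))
  # boundary exactness on an isolated two-atom pair (side-chain carbons)
  res1 <- data.frame(chain = "A", resi = 1)
  lim <- 0.8 * (1.80 + 1.80)
  expect_true(clash_check(toy_pair_structure(lim, name = "CB"), res1,
                          vdw_scale = 1.0))          # exactly at: no clash
  expect_false(clash_check(toy_pair_structure(lim - 1e-3, name = "CB"), res1,
                           vdw_scale = 1.0))         # just inside: clash
  expect_true(clash_check(toy_pair_structure(lim + 1e-3, name = "CB"), res1,
                          vdw_scale = 1.0))
  # reduced radii shrink the clash limit proportionally
  expect_true(clash_check(toy_pair_structure(lim * 0.7 + 1e-3, name = "CB"),
                          res1, vdw_scale = 0.7))
  expect_false(clash_check(toy_pair_structure(lim * 0.7 - 1e-3, name = "CB"),
                           res1, vdw_scale = 0.7))
})

test_that("verbose evaluation appends a per-term TSV row", {
  s <- fx_small_dimer()
  f <- withr::local_tempfile(fileext = ".tsv")
  e1 <- total_energy(s, empty_restraints(), tsv_log = f)
  e2 <- total_energy(s, empty_restraints(), vdw_scale = 0.7, tsv_log = f)
  log <- read.delim(f)
  expect_equal(nrow(log), 2)
  expect_equal(log$total, c(e1$total, e2$total), tolerance = 1e-9)
  expect_true(all(c("vdw", "rama", "restraint_distance") %in% names(log)))
})

test_that("unknown atom types raise ParameterMissing", {
  at <- refinecomplex:::build_helix_chain(rep("ALA", 5), "A")
  at$name[at$name == "CB"] <- "XX"
  expect_error(new_complex_structure(at), class = "ParameterMissing")
})
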