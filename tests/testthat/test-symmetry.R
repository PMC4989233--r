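test_that("a constructed C2 rotation is recovered exactly", {
  s <- fx_c2()
  g <- estimate_symmetry(s)
  expect_equal(g$n_copies, 2)
  # transform 1 is exactly the identity
  expect_identical(g$transforms[[1]]$R, diag(3))
  expect_identical(g$transforms[[1]]$t, c(0, 0, 0))
  # C2: rotation by 180 degrees has trace -1
  expect_equal(sum(diag(g$transforms[[2]]$R)), -1, tolerance = 1e-6)
  expect_lt(g$fit_rmsd[2], 1e-6)
  # orthonormality and unit determinant
  R <- g$transforms[[2]]$R
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-6)
  expect_equal(det(R), 1, tolerance = 1e-6)
})

test_that("noisy C3 symmetry estimation matches an independent Kabsch fit", {
  s <- perturb_structure(fx_c3(), sd = 0.2, seed = 21)
  g <- estimate_symmetry(s)
  # fit rmsd is of the order of the added noise
  expect_gt(g$fit_rmsd[2], 0.05)
  expect_lt(g$fit_rmsd[2], 0.6)
  ang <- acos((sum(diag(g$transforms[[2]]$R)) - 1) / 2) * 180 / pi
  expect_equal(ang, 120, tolerance = 1)
  # against bio3d's least-squares superposition of chain 1 onto chain 2
  a <- s$atoms
  ca1 <- which(a$chain == "A" & a$name == "CA")
  ca2 <- which(a$chain == "B" & a$name == "CA")
  xyz <- as.numeric(t(get_coords(s)))
  fit <- bio3d::fit.xyz(fixed = xyz, mobile = xyz,
                        fixed.inds = bio3d::atom2xyz(ca2),
                        mobile.inds = bio3d::atom2xyz(ca1))
  moved_pkg <- refinecomplex:::apply_transform(get_coords(s)[ca1, ],
                                               g$transforms[[2]]$R,
                                               g$transforms[[2]]$t)
  moved_bio3d <- matrix(fit[bio3d::atom2xyz(ca1)], ncol = 3, byrow = TRUE)
  expect_equal(moved_pkg, moved_bio3d, tolerance = 1e-6)
})

test_that("symmetry estimation rejects degenerate or mismatched input", {
  expect_error(estimate_symmetry(fx_small_dimer()), NA)  # identical chains ok
  s <- two_residue_pair(20)
  expect_error(estimate_symmetry(s), class = "DegenerateGeometry")
})

test_that("enforce_symmetry projects onto exact symmetry and is idempotent", {
  s <- fx_c3()
  g <- estimate_symmetry(s)
  # already-symmetric structure is a fixed point
  s1 <- enforce_symmetry(s, g)
  expect_lt(max(abs(get_coords(s1) - get_coords(s))), 1e-9)
  # random perturbation: output is exactly symmetric
  sp <- perturb_structure(s, sd = 0.3, seed = 5)
  s2 <- enforce_symmetry(sp, g)
  xyz <- get_coords(s2)
  idxA <- refinecomplex:::chain_atom_idx(s2, "A")
  for (ch in c("B", "C")) {
    k <- match(ch, refinecomplex:::chain_ids(s2))
    tr <- g$transforms[[k]]
    idx <- refinecomplex:::chain_atom_idx(s2, ch)
    expect_lt(max(abs(xyz[idx, ] -
                        refinecomplex:::apply_transform(xyz[idxA, ], tr$R, tr$t))),
              1e-9)
  }
  # idempotence and atom preservation
  s3 <- enforce_symmetry(s2, g)
  expect_lt(max(abs(get_coords(s3) - get_coords(s2))), 1e-9)
  expect_identical(s2$atoms$name, sp$atoms$name)
  expect_identical(nrow(s2$atoms), nrow(sp$atoms))
  # re-estimated group matches the enforced one
  g2 <- estimate_symmetry(s2)
  expect_equal(g2$transforms[[2]]$R, g$transforms[[2]]$R, tolerance = 1e-6)
})

test_that("two-copy averaging splits a single-atom displacement", {
  s <- fx_c2()
  g <- estimate_symmetry(s)
  xyz <- get_coords(s)
  i <- refinecomplex:::chain_atom_idx(s, "B")[1]
  delta <- c(0.4, 0, 0)
  xyz[i, ] <- xyz[i, ] + delta
  s2 <- enforce_symmetry(set_coords(s, xyz), g)
  # the corresponding chain-1 atom moves by inv(R2) delta / 2
  j <- refinecomplex:::chain_atom_idx(s, "A")[1]
  inv <- refinecomplex:::invert_transform(g$transforms[[2]]$R,
                                          g$transforms[[2]]$t)
  expected_shift <- as.vector(inv$R %*% delta) / 2
  expect_equal(get_coords(s2)[j, ] - get_coords(s)[j, ], expected_shift,
               tolerance = 1e-9, ignore_attr = TRUE)
  # and the perturbed atom itself ends halfway back
  expect_equal(get_coords(s2)[i, ] - get_coords(s)[i, ], delta / 2,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("group/chain-count mismatch is a named error", {
  g <- estimate_symmetry(fx_c3())
  expect_error(enforce_symmetry(fx_c2(), g), class = "GroupMismatch")
})
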