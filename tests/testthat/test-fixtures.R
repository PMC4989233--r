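test_that("reference complexes are deterministic, packed and interfacial", {
  s1 <- make_reference_complex(fixture_spec(seed = 3))
  s2 <- make_reference_complex(fixture_spec(seed = 3))
  expect_identical(get_coords(s1), get_coords(s2))
  # at least 5 interfacial residues per chain, no steric overlap
  iface <- detect_interface(s1)
  counts <- table(iface$members$chain)
  expect_true(all(counts >= 5))
  # the generator's steric contract: no overlapping pairs at full radii
  # (covalently constrained within-residue / neighbor pairs excluded)
  expect_equal(nrow(refinecomplex:::atom_clash_pairs(s1$atoms)), 0)
  # operational check at the repacking radii used by the protocol
  all_res <- s1$topology$residues[, c("chain", "resi")]
  expect_true(clash_check(s1, all_res, vdw_scale = 0.7))
})

test_that("a C2 reference recovers its constructed symmetry", {
  s <- fx_c2()
  g <- estimate_symmetry(s)
  expect_equal(sum(diag(g$transforms[[2]]$R)), -1, tolerance = 1e-6)
  expect_lt(max(g$fit_rmsd), 1e-6)
})

test_that("zero perturbation yields a perfect decoy", {
  s <- fx_small_dimer()
  d <- make_decoy(s, 0, 0, 0, seed = 1)
  expect_equal(d$metrics$l_rmsd, 0, tolerance = 1e-9)
  expect_equal(d$metrics$f_nat, 1)
  expect_identical(d$metrics$capri_class, "high")
  expect_identical(get_coords(d$structure), get_coords(s))
})

test_that("a pure translation yields exactly that ligand RMSD", {
  s <- fx_small_dimer()
  for (t in c(2, 6)) {
    d <- make_decoy(s, translation = t, seed = 4)
    expect_equal(d$metrics$l_rmsd, t, tolerance = 1e-9)
  }
})

test_that("stored decoy metrics equal independently recomputed ones", {
  s <- fx_small_dimer()
  d <- make_decoy(s, rotation = 12, translation = 3, scramble = 0.4, seed = 8)
  q <- assess_model(d$structure, s)
  expect_equal(d$metrics$l_rmsd, q$l_rmsd, tolerance = 1e-12)
  expect_equal(d$metrics$i_rmsd, q$i_rmsd, tolerance = 1e-12)
  expect_equal(d$metrics$f_nat, q$f_nat)
  # and against the naive oracles
  expect_equal(d$metrics$f_nat, oracle_fnat(d$structure, s), tolerance = 1e-9)
})

test_that("a translation sweep spans the CAPRI accuracy classes", {
  s <- fx_dimer()
  classes <- vapply(c(0.5, 3, 8, 14), function(t)
    make_decoy(s, translation = t, seed = 2)$metrics$capri_class,
    character(1))
  expect_true(all(c("acceptable", "incorrect") %in% classes))
  expect_gte(length(unique(classes)), 3)
})

test_that("side-chain scrambling moves only interfacial side chains", {
  s <- fx_dimer()
  d <- make_decoy(s, scramble = 1.0, seed = 5)
  bb <- s$atoms$backbone
  expect_identical(get_coords(d$structure)[bb, ], get_coords(s)[bb, ])
  expect_false(identical(get_coords(d$structure), get_coords(s)))
  expect_equal(d$metrics$l_rmsd, 0, tolerance = 1e-9)  # backbone untouched
})

test_that("parameter tables are complete and normalized", {
  tabs <- make_parameter_tables(seed = 2)
  lib <- tabs$rotamers
  for (rn in names(lib))
    expect_equal(sum(lib[[rn]]$prob), 1, tolerance = 1e-9)
  # every rotatable residue type has entries
  rotatable <- setdiff(refinecomplex:::AA3, c("ALA", "GLY", "PRO"))
  expect_true(all(rotatable %in% names(lib)))
  # chi arity matches the residue's rotatable dihedral count
  for (rn in rotatable)
    expect_equal(ncol(lib[[rn]]$chi), refinecomplex:::n_chi(rn))
  # flat statistical table scores zero; the synthetic one does not
  s <- fx_small_dimer()
  e_flat <- total_energy(s, empty_restraints())$terms[["pairstat"]]
  expect_equal(e_flat, 0)
  tables2 <- refinecomplex:::default_tables()
  tables2$pairstat <- tabs$pairstat
  e_syn <- total_energy(s, empty_restraints(),
                        tables = tables2)$terms[["pairstat"]]
  expect_false(e_syn == 0)
})

test_that("an ideal fixture scores lower than a clashed variant", {
  s <- fx_small_dimer()
  xyz <- get_coords(s)
  bidx <- refinecomplex:::chain_atom_idx(s, "B")
  xyz[bidx, 2] <- xyz[bidx, 2] - 2.5   # drive the chains into each other
  clashed <- set_coords(s, xyz)
  e_ok <- total_energy(s, empty_restraints())$total
  e_bad <- total_energy(clashed, empty_restraints())$total
  expect_true(is.finite(e_ok))
  expect_gt(e_bad, e_ok)
})

test_that("rotamer libraries round-trip through their text format", {
  lib <- default_rotamer_library()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rotamer_library(lib, f)
  lib2 <- read_rotamer_library(f)
  expect_setequal(names(lib2), names(lib))
  for (rn in names(lib)) {
    expect_equal(lib2[[rn]]$chi, lib[[rn]]$chi, ignore_attr = TRUE)
    expect_equal(lib2[[rn]]$prob, lib[[rn]]$prob)
  }
})
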