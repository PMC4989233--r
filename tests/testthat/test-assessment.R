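test_that("identity models score perfectly", {
  s <- fx_small_dimer()
  q <- assess_model(s, s)
  expect_equal(q$l_rmsd, 0, tolerance = 1e-9)
  expect_equal(q$i_rmsd, 0, tolerance = 1e-9)
  expect_equal(q$f_nat, 1)
  expect_equal(q$capri_class, "high")
})

test_that("a pure ligand translation gives the Pythagorean L-RMSD", {
  s <- fx_small_dimer()
  xyz <- get_coords(s)
  bidx <- refinecomplex:::chain_atom_idx(s, "B")
  xyz[bidx, ] <- sweep(xyz[bidx, ], 2, c(3, 4, 0), "+")
  model <- set_coords(s, xyz)
  mp <- chain_mapping(model, s, receptor_chains = "A")
  expect_equal(ligand_rmsd(model, s, mp), 5.0, tolerance = 1e-9)
})

test_that("metrics agree with independent bio3d/brute-force oracles", {
  s <- fx_small_dimer()
  for (seed in 1:6) {
    set.seed(seed)
    model <- make_decoy(s, rotation = runif(1, 0, 20),
                        translation = runif(1, 0, 5),
                        scramble = runif(1, 0, 0.5), seed = seed)$structure
    mp <- chain_mapping(model, s, receptor_chains = "A")
    expect_equal(ligand_rmsd(model, s, mp), oracle_lrmsd(model, s),
                 tolerance = 1e-6)
    expect_equal(fraction_native_contacts(model, s, mp),
                 oracle_fnat(model, s), tolerance = 1e-9)
  }
})

test_that("interface RMSD ignores displaced non-interface regions", {
  # two helices in staggered contact so several residues sit far from the
  # 10 A heavy-atom interface
  one <- refinecomplex:::orient_helix(
    refinecomplex:::build_helix_chain(rep(c("LEU", "ALA", "GLU"), 5), "A"))
  two <- one
  two$chain <- "B"
  two$y <- two$y + 9
  two$z <- two$z + 14
  s <- new_complex_structure(rbind(one, two), "staggered dimer")
  rids <- refinecomplex:::reference_interface_residues(s, 10)
  rt <- s$topology$residues
  outside <- setdiff(seq_len(nrow(rt)), rids)
  expect_gt(length(outside), 0)
  xyz <- get_coords(s)
  mv <- which(s$topology$residue_index %in% outside)
  xyz[mv, ] <- xyz[mv, ] + 10
  model <- set_coords(s, xyz)
  mp <- chain_mapping(model, s, receptor_chains = "A")
  expect_equal(interface_rmsd(model, s, mp), 0, tolerance = 1e-9)
  expect_gt(ligand_rmsd(model, s, mp), 0)
})

test_that("f_nat falls to zero when the ligand is removed from contact", {
  s <- fx_small_dimer()
  xyz <- get_coords(s)
  bidx <- refinecomplex:::chain_atom_idx(s, "B")
  xyz[bidx, 1] <- xyz[bidx, 1] + 50
  model <- set_coords(s, xyz)
  mp <- chain_mapping(model, s, receptor_chains = "A")
  expect_equal(fraction_native_contacts(model, s, mp), 0)
})

test_that("f_nat decreases monotonically along a translation sweep", {
  s <- fx_small_dimer()
  mp0 <- NULL
  vals <- vapply(c(0, 1, 2, 4, 8, 16), function(t) {
    d <- make_decoy(s, translation = t, seed = 1)
    d$metrics$f_nat
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("the CAPRI tier rule matches a direct transcription on a dense grid", {
  transcribe <- function(l, i, f) {
    if ((l < 1.0 || i < 1.0) && f > 0.5) "high"
    else if ((l < 5.0 || i < 2.0) && f > 0.3) "medium"
    else if ((l < 10.0 || i < 4.0) && f > 0.1) "acceptable"
    else "incorrect"
  }
  for (l in seq(0.5, 15, by = 0.5))
    for (i in seq(0.5, 6, by = 0.5))
      for (f in seq(0, 1, by = 0.1))
        expect_identical(capri_classify(l, i, f), transcribe(l, i, f))
  # boundary exactness: thresholds are strict
  expect_identical(capri_classify(1.0, 1.0, 0.6), "medium")
  expect_identical(capri_classify(0.9, 5.0, 0.5), "medium")
  expect_identical(capri_classify(5.0, 2.0, 0.4), "acceptable")
  expect_identical(capri_classify(10.0, 4.0, 0.2), "incorrect")
})

test_that("the HIV-1 integrase example metrics classify as medium", {
  expect_identical(capri_classify(1.55, 1.09, 0.841), "medium")
})

test_that("classification is monotone when any one metric improves", {
  lv <- c("incorrect", "acceptable", "medium", "high")
  rank_of <- function(cl) match(cl, lv)
  set.seed(31)
  for (k in 1:200) {
    l <- runif(1, 0, 15); i <- runif(1, 0, 6); f <- runif(1, 0, 1)
    base <- rank_of(capri_classify(l, i, f))
    expect_gte(rank_of(capri_classify(max(0, l - runif(1, 0, 3)), i, f)), base)
    expect_gte(rank_of(capri_classify(l, max(0, i - runif(1, 0, 2)), f)), base)
    expect_gte(rank_of(capri_classify(l, i, min(1, f + runif(1, 0, 0.3)))), base)
  }
})

test_that("metrics are invariant under a common rigid motion of the model", {
  s <- fx_small_dimer()
  d <- make_decoy(s, rotation = 10, translation = 2, seed = 9)
  m <- d$structure
  R <- refinecomplex:::rotation_about_axis(c(2, -1, 1), 67)
  m2 <- set_coords(m, sweep(get_coords(m) %*% t(R), 2, c(8, 1, -4), "+"))
  q1 <- assess_model(m, s)
  q2 <- assess_model(m2, s)
  expect_equal(q1$l_rmsd, q2$l_rmsd, tolerance = 1e-8)
  expect_equal(q1$i_rmsd, q2$i_rmsd, tolerance = 1e-8)
  expect_equal(q1$f_nat, q2$f_nat)
})

test_that("symmetric homo-complex assessment picks the best chain relabeling", {
  s <- fx_c3()
  # cyclic relabeling of chains: metrics must be near-perfect
  a <- s$atoms
  relabeled <- a
  relabeled$chain <- c(B = "A", C = "B", A = "C")[a$chain]
  m <- new_complex_structure(relabeled, "relabeled")
  q <- assess_model(m, s)
  expect_lt(q$l_rmsd, 1e-6)
  expect_equal(q$f_nat, 1)
})

test_that("mismatched sequences raise MappingError", {
  s <- fx_small_dimer()
  a <- s$atoms
  mut <- a$chain == "A" & a$resi == 3 & a$resname == "ALA"
  skip_if(!any(mut))
  a$resname[mut] <- "GLY"
  a <- a[!(mut & a$name == "CB"), ]
  other <- new_complex_structure(a, "mutant")
  expect_error(chain_mapping(other, s), class = "MappingError")
})

test_that("domain violations are rejected by the classifier", {
  expect_error(capri_classify(-1, 2, 0.5), class = "DomainError")
  expect_error(capri_classify(2, 2, 1.5), class = "DomainError")
})
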