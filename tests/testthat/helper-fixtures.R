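# Shared fixtures, built once per test run.

.fx <- new.env()

fx_dimer <- function() {
  if (is.null(.fx$dimer)) .fx$dimer <- make_reference_complex(fixture_spec())
  .fx$dimer
}

fx_small_dimer <- function() {
  if (is.null(.fx$small))
    .fx$small <- make_reference_complex(fixture_spec(chain_length = 10))
  .fx$small
}

fx_c2 <- function() {
  if (is.null(.fx$c2))
    .fx$c2 <- make_reference_complex(fixture_spec(symmetry = 2))
  .fx$c2
}

fx_c3 <- function() {
  if (is.null(.fx$c3))
    .fx$c3 <- make_reference_complex(fixture_spec(symmetry = 3))
  .fx$c3
}

# minimized native used by the refinement-mechanism tests
fx_native <- function() {
  if (is.null(.fx$native))
    .fx$native <- minimize(fx_dimer(), empty_restraints(), max_steps = 2000)
  .fx$native
}

# random coordinate perturbation of a structure (keeps topology valid)
perturb_structure <- function(s, sd = 0.1, seed = 1) {
  set.seed(seed)
  set_coords(s, get_coords(s) + matrix(rnorm(3 * nrow(s$atoms), sd = sd),
                                       ncol = 3))
}

# a bare two-atom system (one carbon-like atom per "chain") for testing
# closed-form nonbonded behavior in isolation
toy_pair_structure <- function(sep, name = "CA") {
  atoms <- data.frame(chain = c("A", "B"), resno = c(1L, 1L), resi = c(1L, 1L),
                      resname = "ALA", name = name,
                      x = c(0, sep), y = 0, z = 0,
                      element = "C", backbone = name %in% c("N", "CA", "C", "O"),
                      mass = 12.011, radius = 1.80, eps = 0.08, charge = 0,
                      stringsAsFactors = FALSE)
  top <- list(n_atoms = 2L, residue_index = c(1L, 2L),
              residues = data.frame(rid = 1:2, chain = c("A", "B"),
                                    resi = c(1L, 1L), resname = "ALA"),
              amap = list(setNames(1L, name), setNames(2L, name)),
              bonds = matrix(0L, 0, 2), bonds_b0 = numeric(0),
              angles = matrix(0L, 0, 3), angles_th0 = numeric(0),
              torsions = matrix(0, 0, 7),
              excl_keys = numeric(0), p14_keys = numeric(0),
              hb_donors = integer(0), hb_acceptors = matrix(0L, 0, 2),
              chi_table = matrix(0, 0, 6),
              phipsi = list(list(phi = NA, psi = NA),
                            list(phi = NA, psi = NA)))
  structure(list(atoms = atoms, sequences = c(A = "A", B = "A"),
                 provenance = "toy pair", topology = top),
            class = "ComplexStructure")
}

# two single-residue chains with an exact CA-CA distance (chain B is a
# translated copy along x)
two_residue_pair <- function(ca_dist, resname = "ALA") {
  one <- refinecomplex:::build_helix_chain(resname, "A")
  two <- one
  two$chain <- "B"
  two$x <- two$x + ca_dist
  new_complex_structure(rbind(one, two), "two-residue toy")
}
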