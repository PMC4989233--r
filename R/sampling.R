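# Conformational sampling primitives: local energy minimization, short
# Langevin (BAOAB) molecular-dynamics relaxation with an optional symmetry
# projection after every step, and Monte Carlo repacking of interface side
# chains from a rotamer library.

# internal MD units: kcal/mol, Angstrom, amu; 1 time unit = 48.88821 fs
TIME_UNIT_FS <- 48.88821
KBOLTZ <- 0.0019872041  # kcal/mol/K

#' Local energy minimization
#'
#' L-BFGS minimization of the smooth part of the refinement energy using
#' the analytic gradient. The returned structure never has a higher total
#' energy than the input (if the line search terminates uphill on the
#' statistical terms, the input is returned unchanged).
#'
#' @param structure a `ComplexStructure`.
#' @param restraints a `RestraintSet`.
#' @param weights energy weights.
#' @param max_steps iteration cap.
#' @param tol projected-gradient tolerance (energy/Angstrom).
#' @param vdw_scale van der Waals radius scale.
#' @return the minimized `ComplexStructure`.
#' @export
minimize <- function(structure, restraints = empty_restraints(),
                     weights = default_energy_weights(), max_steps = 500,
                     tol = 1e-3, vdw_scale = 1.0) {
  x0 <- as.vector(get_coords(structure))
  fn <- function(p) {
    xyz <- matrix(p, ncol = 3)
    e <- energy_call(structure, restraints, weights, vdw_scale, FALSE,
                     xyz = xyz)$terms
    sum(e * weights[names(e)])
  }
  gr <- function(p) {
    xyz <- matrix(p, ncol = 3)
    as.vector(energy_call(structure, restraints, weights, vdw_scale, TRUE,
                          xyz = xyz)$grad)
  }
  e0 <- fn(x0)
  if (!is.finite(e0)) abort_rc("NonFiniteEnergy", "non-finite energy at input")
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_steps, pgtol = tol,
                                     factr = 10))
  out <- set_coords(structure, matrix(res$par, ncol = 3))
  # guard on the full objective including statistical terms
  t_in <- total_energy(structure, restraints, weights, vdw_scale)$total
  t_out <- total_energy(out, restraints, weights, vdw_scale)$total
  if (!is.finite(t_out) || t_out > t_in) return(structure)
  out
}

#' MD relaxation parameters
#'
#' @param timestep_fs integration timestep, femtoseconds.
#' @param duration_ps run length, picoseconds.
#' @param temperature_K thermostat temperature, Kelvin.
#' @param friction Langevin friction, 1/ps.
#' @param seed integer seed.
#' @return an `MDParams` list.
#' @export
md_params <- function(timestep_fs = 4.0, duration_ps = 0.6,
                      temperature_K = 300, friction = 1.0, seed = 1) {
  stopifnot(timestep_fs > 0, duration_ps >= 0)
  structure(list(timestep_fs = timestep_fs, duration_ps = duration_ps,
                 temperature_K = temperature_K, friction = friction,
                 seed = seed), class = "MDParams")
}

#' Short Langevin MD relaxation
#'
#' BAOAB-splitting Langevin dynamics on the smooth energy terms. If a
#' `SymmetryGroup` is supplied, the structure is projected onto exact Cn
#' symmetry after every integration step. With `temperature_K = 0` the
#' integrator is a damped descent.
#'
#' @param structure a `ComplexStructure`.
#' @param restraints a `RestraintSet`.
#' @param weights energy weights.
#' @param params an [md_params()] object.
#' @param symmetry optional `SymmetryGroup` to enforce each step.
#' @param vdw_scale van der Waals radius scale.
#' @return list with `structure` (the relaxed structure) and
#'   `mean_ke_per_dof` (time-averaged kinetic energy per degree of
#'   freedom, kcal/mol).
#' @export
md_relax <- function(structure, restraints = empty_restraints(),
                     weights = default_energy_weights(), params = md_params(),
                     symmetry = NULL, vdw_scale = 1.0) {
  nsteps <- round(params$duration_ps * 1000 / params$timestep_fs)
  if (nsteps == 0)
    return(list(structure = structure, mean_ke_per_dof = NA_real_))
  dt <- params$timestep_fs / TIME_UNIT_FS
  gamma <- params$friction * TIME_UNIT_FS / 1000   # 1/ps -> 1/time-unit
  kT <- KBOLTZ * params$temperature_K
  m <- structure$atoms$mass
  n <- length(m)
  x <- get_coords(structure)
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(pmax(0, (1 - c1^2))) * sqrt(kT / m)
  force <- function(xyz) -energy_call(structure, restraints, weights,
                                      vdw_scale, TRUE, xyz = xyz)$grad
  ke_sum <- 0
  with_seed(params$seed, {
    v <- if (kT > 0) matrix(stats::rnorm(3 * n, sd = rep(sqrt(kT / m), 3)),
                            ncol = 3)
         else matrix(0, n, 3)
    f <- force(x)
    for (s in seq_len(nsteps)) {
      v <- v + (0.5 * dt) * f / m
      x <- x + (0.5 * dt) * v
      v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), ncol = 3)
      x <- x + (0.5 * dt) * v
      if (!all(is.finite(x)))
        abort_rc("NonFiniteEnergy", "MD integration diverged at step %d", s)
      if (!is.null(symmetry))
        x <- get_coords(enforce_symmetry(set_coords(structure, x), symmetry))
      f <- force(x)
      v <- v + (0.5 * dt) * f / m
      ke_sum <- ke_sum + sum(0.5 * m * rowSums(v^2))
    }
  })
  list(structure = set_coords(structure, x),
       mean_ke_per_dof = ke_sum / (nsteps * 3 * n))
}

#' Select repacking clusters of interfacial residues
#'
#' Each cluster is a randomly chosen seed residue plus its `max_size - 1`
#' nearest interfacial residues by CA distance. Seed residues are distinct
#' whenever the interface has at least `n_clusters` members.
#'
#' @param interface an `InterfaceSet`.
#' @param structure the `ComplexStructure`.
#' @param n_clusters number of clusters.
#' @param max_size cluster size cap.
#' @param seed integer seed.
#' @return list of data.frames (`chain`, `resi`) of cluster members.
#' @export
select_clusters <- function(interface, structure, n_clusters = 3,
                            max_size = 5, seed = 1) {
  mem <- interface$members
  if (nrow(mem) == 0) return(list())
  rids <- residue_id(structure, mem$chain, mem$resi)
  xyz <- get_coords(structure)
  ca <- vapply(rids, function(r) structure$topology$amap[[r]][["CA"]],
               integer(1))
  pos <- xyz[ca, , drop = FALSE]
  with_seed(seed, {
    seeds <- if (nrow(mem) >= n_clusters)
      sample(seq_len(nrow(mem)), n_clusters)
    else
      sample(seq_len(nrow(mem)), n_clusters, replace = TRUE)
    lapply(seeds, function(s) {
      d <- sqrt(rowSums(sweep(pos, 2, pos[s, ])^2))
      take <- order(d)[seq_len(min(max_size, nrow(mem)))]
      take <- union(s, take)[seq_len(min(max_size, nrow(mem)))]
      mem[take, , drop = FALSE]
    })
  })
}

#' Monte Carlo repacking of interface side chains
#'
#' For each of `n_clusters` clusters of up to five interfacial residues,
#' runs `n_mc_steps` Metropolis steps. Each step proposes library rotamers
#' jointly for the cluster's repackable residues, rejects proposals that
#' fail the steric check at reduced van der Waals radii, and otherwise
#' accepts by the Metropolis criterion on the total energy (evaluated at
#' the same reduced radii). Backbone atoms and non-interface side chains
#' are never moved.
#'
#' @param structure a `ComplexStructure`.
#' @param interface an `InterfaceSet` (if empty, identity with a warning).
#' @param library a `RotamerLibrary`.
#' @param n_mc_steps Metropolis steps per cluster.
#' @param n_clusters number of clusters.
#' @param vdw_scale reduced radius scale used for clash and energy.
#' @param seed integer seed.
#' @param temperature_K Metropolis temperature.
#' @param restraints restraint set entering the energy.
#' @param weights energy weights.
#' @return list with `structure` and `n_accepted` (accepted moves).
#' @export
repack_interface <- function(structure, interface,
                             library = default_rotamer_library(),
                             n_mc_steps = 3, n_clusters = 3, vdw_scale = 0.7,
                             seed = 1, temperature_K = 300,
                             restraints = empty_restraints(),
                             weights = default_energy_weights()) {
  if (nrow(interface$members) == 0) {
    warning("empty interface: repacking is the identity")
    return(list(structure = structure, n_accepted = 0L))
  }
  clusters <- select_clusters(interface, structure, n_clusters = n_clusters,
                              seed = seed)
  kT <- KBOLTZ * max(temperature_K, 1e-6)
  n_acc <- 0L
  with_seed(seed + 104729, {
    e_cur <- total_energy(structure, restraints, weights, vdw_scale)$total
    for (cl in clusters) {
      rids <- residue_id(structure, cl$chain, cl$resi)
      rn <- structure$topology$residues$resname[rids]
      nchis <- vapply(rn, n_chi, integer(1))
      packable <- which(nchis > 0 & rn %in% names(library))
      miss <- rn[nchis > 0 & !rn %in% names(library)]
      if (length(miss))
        abort_rc("EmptyLibrary", "no rotamers for residue type(s) %s",
                 paste(unique(miss), collapse = ","))
      if (length(packable) == 0) next
      for (step in seq_len(n_mc_steps)) {
        cand <- structure
        for (p in packable) {
          rot <- library[[rn[p]]]
          k <- sample.int(nrow(rot$chi), 1, prob = rot$prob)
          cand <- set_residue_chi(cand, rids[p], rot$chi[k, ])
        }
        if (!clash_check(cand, cl[packable, , drop = FALSE], vdw_scale))
          next
        e_new <- total_energy(cand, restraints, weights, vdw_scale)$total
        if (e_new <= e_cur ||
            stats::runif(1) < exp(-(e_new - e_cur) / kT)) {
          structure <- cand
          e_cur <- e_new
          n_acc <- n_acc + 1L
        }
      }
    }
  })
  list(structure = structure, n_accepted = n_acc)
}
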