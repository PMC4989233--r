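# Pipeline orchestration: initial relaxation, repeated repack+relax cycles
# under an annealing schedule, final minimization, two restraint protocols,
# ensemble generation and lowest-energy model selection.

#' Refinement configuration
#'
#' Defaults reproduce the standard schedule: initial minimization and a
#' 1.2-ps relaxation at 300 K, 22 cycles of (3-cluster / 3-step MC repack
#' at 70% van der Waals radii + 0.6-ps relaxation) totalling 13.2 ps, with
#' the temperature held at 300 K and annealed linearly to 50 K over the
#' last 6 cycles, a final minimization, 16 runs per protocol and selection
#' of the 5 lowest-energy models per protocol (ranks 1-5 for protocol 1,
#' 6-10 for protocol 2).
#'
#' @param n_cycles repack+relax cycles per run.
#' @param init_md_ps initial relaxation length, ps.
#' @param cycle_md_ps per-cycle relaxation length, ps.
#' @param timestep_fs MD timestep, fs.
#' @param T_high,T_low annealing start/end temperatures, K.
#' @param n_anneal_cycles number of final cycles over which the
#'   temperature descends to `T_low` (defaults to 6, capped at `n_cycles`).
#' @param n_models_per_protocol ensemble size per protocol.
#' @param n_select models selected per protocol.
#' @param protocols integer subset of `c(1, 2)`.
#' @param symmetric enforce Cn symmetry during relaxation.
#' @param master_seed integer master seed (sub-seeds are derived per run).
#' @param n_mc_steps,n_clusters Monte Carlo repacking schedule.
#' @param repack_vdw_scale reduced radius scale during repacking.
#' @param friction Langevin friction, 1/ps.
#' @param weights energy-term weights.
#' @param restraint_w [restraint_weights()] list.
#' @param min_steps,min_tol final/initial minimization controls.
#' @param select_with_restraints include restraint terms in the selection
#'   energy.
#' @return a `RefinementConfig` list.
#' @export
refinement_config <- function(n_cycles = 22, init_md_ps = 1.2,
                              cycle_md_ps = 0.6, timestep_fs = 4.0,
                              T_high = 300, T_low = 50,
                              n_anneal_cycles = min(6, n_cycles),
                              n_models_per_protocol = 16, n_select = 5,
                              protocols = c(1, 2), symmetric = FALSE,
                              master_seed = 1, n_mc_steps = 3,
                              n_clusters = 3, repack_vdw_scale = 0.7,
                              friction = 1.0,
                              weights = default_energy_weights(),
                              restraint_w = restraint_weights(),
                              min_steps = 300, min_tol = 1e-3,
                              select_with_restraints = TRUE) {
  stopifnot(n_anneal_cycles <= n_cycles, n_select <= n_models_per_protocol,
            all(protocols %in% c(1, 2)))
  structure(as.list(environment()), class = "RefinementConfig")
}

#' Annealing temperature at a given cycle
#'
#' `T_high` for cycles 1..(n_cycles - n_anneal_cycles), then a linear
#' descent reaching `T_low` at the final cycle.
#'
#' @param cycle_index cycle number in `1..n_cycles`.
#' @param config a `RefinementConfig`.
#' @return temperature in Kelvin.
#' @export
anneal_temperature <- function(cycle_index, config) {
  n <- config$n_cycles
  na <- config$n_anneal_cycles
  if (cycle_index < 1 || cycle_index > n)
    abort_rc("IndexError", "cycle index %d outside 1..%d", cycle_index, n)
  hold <- n - na
  if (cycle_index <= hold) return(config$T_high)
  config$T_high - (config$T_high - config$T_low) * (cycle_index - hold) / na
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(master, protocol, run, salt = 0) {
  as.integer((as.numeric(master) * 7919 + protocol * 1299709 +
                run * 15485863 + salt * 32452843) %% 2147483629)
}

#' Execute one refinement run
#'
#' In order: detect the interface and build the protocol's restraints from
#' the INPUT structure (references stay anchored to the input throughout);
#' minimize; relax for `init_md_ps` at `T_high`; then `n_cycles` times
#' repack the interface and relax for `cycle_md_ps` at the annealing-
#' schedule temperature; minimize; evaluate the final energy at full van
#' der Waals radii.
#'
#' @param structure the input `ComplexStructure`.
#' @param config a `RefinementConfig`.
#' @param protocol_id 1 (distance restraints only) or 2 (+ position).
#' @param run_seed integer seed for this run.
#' @return a `RefinedModel`: list with `structure`, `final_energy`
#'   (an `EnergyBreakdown`), `selection_energy`, `protocol`, `run_index`,
#'   `rank` (NA until ranked) and `log` (per-stage data.frame).
#' @export
refine_once <- function(structure, config, protocol_id = 1, run_seed = 1) {
  iface <- detect_interface(structure)
  restraints <- build_restraints(structure, iface, protocol = protocol_id,
                                 weights = config$restraint_w)
  symmetry <- if (config$symmetric) estimate_symmetry(structure) else NULL
  w <- config$weights
  log <- list()
  push_log <- function(stage, cycle, temp, md_ps, acc) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, cycle = cycle,
                                          temperature_K = temp,
                                          md_ps = md_ps,
                                          n_clusters = config$n_clusters,
                                          n_mc_steps = config$n_mc_steps,
                                          repack_vdw_scale = config$repack_vdw_scale,
                                          accepted_moves = acc)
  }

  s <- minimize(structure, restraints, w, config$min_steps, config$min_tol)
  push_log("initial_minimization", NA, NA, NA, NA)
  if (config$init_md_ps > 0) {
    s <- md_relax(s, restraints, w,
                  md_params(config$timestep_fs, config$init_md_ps,
                            config$T_high, config$friction,
                            seed = derive_seed(run_seed, protocol_id, 0, 1)),
                  symmetry = symmetry)$structure
    push_log("initial_relaxation", NA, config$T_high, config$init_md_ps, NA)
  }
  for (cyc in seq_len(config$n_cycles)) {
    temp <- anneal_temperature(cyc, config)
    rp <- repack_interface(s, iface,
                           n_mc_steps = config$n_mc_steps,
                           n_clusters = config$n_clusters,
                           vdw_scale = config$repack_vdw_scale,
                           seed = derive_seed(run_seed, protocol_id, cyc, 2),
                           temperature_K = temp, restraints = restraints,
                           weights = w)
    s <- rp$structure
    if (config$cycle_md_ps > 0)
      s <- md_relax(s, restraints, w,
                    md_params(config$timestep_fs, config$cycle_md_ps, temp,
                              config$friction,
                              seed = derive_seed(run_seed, protocol_id, cyc, 3)),
                    symmetry = symmetry)$structure
    push_log("repack_relax", cyc, temp, config$cycle_md_ps, rp$n_accepted)
  }
  s <- minimize(s, restraints, w, config$min_steps, config$min_tol)
  push_log("final_minimization", NA, NA, NA, NA)
  if (!is.null(symmetry)) s <- enforce_symmetry(s, symmetry)

  fe <- total_energy(s, restraints, w, vdw_scale = 1.0)
  sel <- if (config$select_with_restraints) fe$total else
    fe$total - sum(fe$terms[c("restraint_distance", "restraint_position")] *
                     fe$weights[c("restraint_distance", "restraint_position")])
  out <- list(structure = s, final_energy = fe, selection_energy = sel,
              protocol = protocol_id, run_index = NA_integer_,
              rank = NA_integer_, log = do.call(rbind, log))
  class(out) <- "RefinedModel"
  out
}

#' @export
print.RefinedModel <- function(x, ...) {
  cat(sprintf("RefinedModel: protocol %d, run %s, rank %s, energy %.4f\n",
              x$protocol, x$run_index, x$rank, x$selection_energy))
  invisible(x)
}

#' Run the full refinement pipeline
#'
#' Per enabled protocol, performs `n_models_per_protocol` independent runs
#' with distinct derived sub-seeds, selects the `n_select` lowest
#' selection-energy models (ties broken by lower run index) and ranks them:
#' protocol 1 gets ranks 1..n_select, protocol 2 the following block (or
#' 1..n_select when it is the only protocol). A run that diverges is
#' retried once with a fresh sub-seed and halved timestep, then dropped.
#'
#' @param structure the input `ComplexStructure`.
#' @param config a `RefinementConfig`.
#' @return list of ranked `RefinedModel`s (length n_select x #protocols).
#' @export
run_pipeline <- function(structure, config = refinement_config()) {
  selected <- list()
  run_log <- list()
  for (p in sort(config$protocols)) {
    runs <- list()
    for (r in seq_len(config$n_models_per_protocol)) {
      seed_r <- derive_seed(config$master_seed, p, r)
      m <- tryCatch(refine_once(structure, config, p, seed_r),
                    NonFiniteEnergy = function(e) NULL)
      if (is.null(m)) {
        cfg2 <- config
        cfg2$timestep_fs <- config$timestep_fs / 2
        m <- tryCatch(refine_once(structure, cfg2, p,
                                  derive_seed(config$master_seed, p, r, 99)),
                      NonFiniteEnergy = function(e) NULL)
      }
      if (!is.null(m)) {
        m$run_index <- r
        runs[[length(runs) + 1]] <- m
      }
    }
    if (length(runs) == 0) abort_rc("AllRunsFailed", "all runs of protocol %d failed", p)
    en <- vapply(runs, `[[`, numeric(1), "selection_energy")
    ri <- vapply(runs, `[[`, numeric(1), "run_index")
    run_log[[as.character(p)]] <- data.frame(protocol = p, run_index = ri,
                                             selection_energy = en)
    ord <- order(en, ri)
    take <- ord[seq_len(min(config$n_select, length(runs)))]
    selected[[as.character(p)]] <- runs[take]
  }
  out <- list()
  rank <- 0
  for (p in names(selected)) for (m in selected[[p]]) {
    rank <- rank + 1
    m$rank <- as.integer(rank)
    out[[rank]] <- m
  }
  attr(out, "runs") <- do.call(rbind, run_log)
  out
}
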