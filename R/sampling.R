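# Langevin dynamics and temperature replica exchange.
#
# The integrator is BAOAB-discretized Langevin dynamics with a seeded,
# self-contained noise stream, so trajectories are bit-reproducible for
# fixed inputs. Replica exchange attempts neighbour swaps at a fixed
# interval, alternating even/odd pairs, with Metropolis acceptance
# min(1, exp[(beta_i - beta_j)(E_i - E_j)]) and velocity rescaling by
# sqrt(T_new/T_old) on accepted swaps.

#' Default replica-exchange temperature ladder
#'
#' Eight rungs, approximately geometric between 290 and 370 K, adjusted so
#' that 310 K (37 C, the analysis temperature) is an exact rung.
#'
#' @param n Number of rungs (default 8).
#' @param Tmin,Tmax Ladder ends in K (defaults 290 and 370).
#' @param include Temperature forced onto the nearest rung (default 310).
#' @return Numeric vector of temperatures, strictly ascending.
#' @export
default_ladder <- function(n = 8, Tmin = 290, Tmax = 370, include = 310) {
  ladder <- Tmin * (Tmax / Tmin)^(seq(0, n - 1) / (n - 1))
  if (!is.null(include) && include > Tmin && include < Tmax) {
    ladder[which.min(abs(ladder - include))] <- include
  }
  sort(ladder)
}

#' Langevin dynamics at a single temperature
#'
#' @param conf A `cg_conformation` (topology, optional scaffold, tether).
#' @param temperature Bath temperature in K (>= 0).
#' @param steps Number of integration steps.
#' @param dt Time step in fs (default 8).
#' @param friction Friction coefficient in ps^-1 (default 1).
#' @param seed Integer seed for the noise stream.
#' @param n_save Save a frame every `n_save` steps (default 100).
#' @return A `cg_trajectory`: list with `frames` (n x 3 x n_frames array,
#'   frame 1 = the input conformation), `energies` (potential energy per
#'   frame, kcal/mol), `temperature`, `dt`, `friction`, `seed`, `n_save`,
#'   `final` (final coordinates) and references `chain` and `scaffold`.
#' @export
langevin_run <- function(conf, temperature, steps, dt = 8, friction = 1,
                         seed = 1, n_save = 100) {
  stopifnot(inherits(conf, "cg_conformation"))
  if (dt <= 0) stop("dt must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  res <- cpp_langevin(unname(conf$xyz), .topo_cpp(conf$topology),
                      .scaffold_cpp(conf$scaffold), .params_cpp(conf),
                      conf$chain$beads$mass, conf$chain$beads$radius,
                      temperature, as.integer(steps), dt, friction,
                      as.integer(seed), as.integer(n_save))
  structure(list(frames = res$frames, energies = res$energies,
                 temperature = temperature, dt = dt, friction = friction,
                 seed = seed, n_save = n_save, steps = steps,
                 final = res$final_xyz,
                 chain = conf$chain, scaffold = conf$scaffold,
                 topology = conf$topology, params = conf$params,
                 tether = conf$tether),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$frames)[3], "frames at", x$temperature, "K",
      "(", x$steps, "steps, dt =", x$dt, "fs )\n")
  invisible(x)
}

#' Temperature replica-exchange Langevin dynamics
#'
#' Runs one replica per ladder rung from the same start, attempting
#' neighbour swaps every `swap_interval` steps. Frame storage can be
#' restricted to a subset of rungs to bound memory.
#'
#' @inheritParams langevin_run
#' @param ladder Ascending temperature ladder in K ([default_ladder()]).
#' @param swap_interval Steps between swap attempts (default 1000).
#' @param save_rungs Rung indices whose frames are stored (default: all).
#'   Per-frame energies are stored for every rung regardless.
#' @param equil_frac Fraction of each trajectory discarded as equilibration
#'   by downstream statistics (default 0.2).
#' @param xyz_alt Optional alternative starting coordinates (n x 3).
#' @param alt_rungs Rung indices started from `xyz_alt` instead of
#'   `conf$xyz` (default none). Starting the hot rungs from an unfolded
#'   conformation and the cold rungs from the native one lets the
#'   ensemble approach equilibrium from both sides, shortening the
#'   relaxation transient.
#' @return A `replica_ensemble`: list with `ladder`, `trajectories` (one
#'   `cg_trajectory` per rung; `frames` is `NULL` for unsaved rungs),
#'   `swap_log` (data frame: step, pair_lo, delta, accepted), `equil_frac`
#'   and the run metadata.
#' @export
replica_exchange_run <- function(conf, ladder = default_ladder(),
                                 steps = 200000, swap_interval = 1000,
                                 dt = 8, friction = 1, seed = 1,
                                 n_save = 100, save_rungs = seq_along(ladder),
                                 equil_frac = 0.2, xyz_alt = NULL,
                                 alt_rungs = integer(0)) {
  stopifnot(inherits(conf, "cg_conformation"))
  if (is.unsorted(ladder, strictly = TRUE)) {
    stop("temperature ladder must be strictly ascending")
  }
  if (swap_interval < 1) stop("swap_interval must be >= 1")
  if (is.null(xyz_alt)) xyz_alt <- matrix(numeric(0), 0, 3)
  res <- cpp_replica_exchange(unname(conf$xyz), .topo_cpp(conf$topology),
                              .scaffold_cpp(conf$scaffold), .params_cpp(conf),
                              conf$chain$beads$mass, conf$chain$beads$radius,
                              ladder, as.integer(steps),
                              as.integer(swap_interval), dt, friction,
                              as.integer(seed), as.integer(n_save),
                              as.integer(save_rungs),
                              unname(as.matrix(xyz_alt)),
                              as.integer(alt_rungs))
  trajectories <- lapply(seq_along(ladder), function(r) {
    fr <- res$frames[[r]]
    structure(list(frames = if (length(fr) > 0) fr else NULL,
                   energies = res$energies[[r]],
                   temperature = ladder[r], dt = dt, friction = friction,
                   seed = seed, n_save = n_save, steps = steps,
                   chain = conf$chain, scaffold = conf$scaffold,
                   topology = conf$topology, params = conf$params,
                   tether = conf$tether),
              class = "cg_trajectory")
  })
  structure(list(ladder = ladder, trajectories = trajectories,
                 swap_log = res$swap_log, equil_frac = equil_frac,
                 steps = steps, swap_interval = swap_interval,
                 dt = dt, friction = friction, seed = seed,
                 n_save = n_save, chain = conf$chain,
                 scaffold = conf$scaffold, topology = conf$topology,
                 params = conf$params, tether = conf$tether),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat("Replica ensemble:", length(x$ladder), "rungs,",
      paste0(round(min(x$ladder)), "-", round(max(x$ladder)), " K,"),
      x$steps, "steps/replica\n")
  if (nrow(x$swap_log) > 0) {
    cat("Swap acceptance:", round(mean(x$swap_log$accepted), 3), "\n")
  }
  invisible(x)
}

#' Find the rung index of a temperature in an ensemble
#' @param ensemble A `replica_ensemble`.
#' @param temperature Temperature in K.
#' @return Integer rung index.
#' @export
rung_index <- function(ensemble, temperature) {
  r <- which(abs(ensemble$ladder - temperature) < 1e-6)
  if (length(r) != 1) {
    stop("ladder has no rung at ", temperature,
         " K (rungs: ", paste(round(ensemble$ladder, 1), collapse = ", "), ")")
  }
  r
}

#' Low-temperature (glassy) continuation run
#'
#' Starts from a randomly selected (seeded) folded frame at the analysis
#' rung of a replica ensemble and runs single-temperature Langevin dynamics
#' just above the water glass-transition temperature, where the folded
#' domain is kinetically trapped and samples a narrow region of the tunnel.
#'
#' @param ensemble A `replica_ensemble` whose analysis rung has saved
#'   frames and at least one folded-classified frame.
#' @param temperature Run temperature in K (default 140).
#' @param steps Number of integration steps.
#' @param seed Integer seed (frame selection and noise).
#' @param analysis_T Rung used to harvest the folded start (default 310 K).
#' @param n_save Frame save interval (default 100).
#' @return A `cg_trajectory` at `temperature`.
#' @export
glass_run <- function(ensemble, temperature = 140, steps = 100000, seed = 1,
                      analysis_T = 310, n_save = 100) {
  stopifnot(inherits(ensemble, "replica_ensemble"))
  r <- rung_index(ensemble, analysis_T)
  traj <- ensemble$trajectories[[r]]
  if (is.null(traj$frames)) {
    stop("no saved frames at the ", analysis_T, " K rung")
  }
  cls <- classify_trajectory(traj)
  idx <- equil_indices(length(cls), ensemble$equil_frac)
  folded <- idx[cls[idx] == "folded"]
  if (length(folded) == 0) {
    stop("no folded frame available at the ", analysis_T, " K rung")
  }
  set.seed(seed)
  pick <- folded[sample.int(length(folded), 1)]
  xyz <- traj$frames[, , pick]
  conf <- conformation(ensemble$chain, ensemble$topology, xyz = xyz,
                       scaffold = ensemble$scaffold,
                       params = ensemble$params,
                       tether = isTRUE(ensemble$tether))
  langevin_run(conf, temperature = temperature, steps = steps,
               dt = ensemble$dt, friction = ensemble$friction,
               seed = seed, n_save = n_save)
}

#' Write a trajectory as XYZ plus a per-frame energy CSV
#'
#' One XYZ block per frame (element `C` for every bead); energies and the
#' frame temperature go to `<path>.energy.csv`.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output XYZ path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- dim(traj$frames)[1]
  nf <- dim(traj$frames)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(n), paste("frame", f)), con)
    xyz <- traj$frames[, , f]
    writeLines(sprintf("C %.4f %.4f %.4f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  write.csv(data.frame(frame = seq_len(nf), energy = traj$energies,
                       temperature = traj$temperature),
            paste0(path, ".energy.csv"), row.names = FALSE)
  invisible(path)
}

#' Write ensemble metadata as JSON
#' @param ensemble A `replica_ensemble`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ensemble, path) {
  jsonlite::write_json(
    list(ladder = ensemble$ladder, steps = ensemble$steps,
         swap_interval = ensemble$swap_interval, dt_fs = ensemble$dt,
         friction_ps = ensemble$friction, seed = ensemble$seed,
         n_save = ensemble$n_save, equil_frac = ensemble$equil_frac,
         swap_acceptance = if (nrow(ensemble$swap_log) > 0)
           mean(ensemble$swap_log$accepted) else NA),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
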