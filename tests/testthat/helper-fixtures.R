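# Shared fixtures: tiny chains, an empty topology skeleton, and a cache for
# the expensive simulation products reused across the acceptance checks.

# minimal chain with n beads at given coordinates (one residue per bead)
tiny_chain <- function(xyz, annot = "domain") {
  n <- nrow(xyz)
  beads <- data.frame(resno = seq_len(n), role = "backbone", mass = 110,
                      radius = 2, annot = annot, stringsAsFactors = FALSE)
  tunnelfold:::new_cg_chain(beads, xyz, rep("ALA", n), probe = 1L, L = 0L)
}

empty_topology <- function(n) {
  structure(list(
    bonds = data.frame(i = numeric(0), j = numeric(0), k = numeric(0),
                       r0 = numeric(0)),
    angles = data.frame(i = numeric(0), j = numeric(0), k = numeric(0),
                        k_theta = numeric(0), theta0 = numeric(0)),
    dihedrals = data.frame(i = numeric(0), j = numeric(0), k = numeric(0),
                           l = numeric(0), k1 = numeric(0), k2 = numeric(0),
                           phi0 = numeric(0)),
    contacts = data.frame(i = numeric(0), j = numeric(0), eps = numeric(0),
                          sigma = numeric(0)),
    lambda = 1, n = n), class = "cg_topology")
}

# a distant dummy scaffold: provides an anchor without touching the chain
far_scaffold <- function(anchor = c(0, 0, 0)) {
  tunnelfold:::new_scaffold(matrix(c(1e6, 1e6, 1e6), 1, 3), 2,
                            anchor, anchor + c(0, 0, -100))
}

# write a PDB text fixture and return its path
write_pdb_fixture <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# ---------------------------------------------------------------------------
# lazy cache for simulation products shared by the acceptance checks
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# calibrated well-depth scale of the default toy domain
get_calibration <- function() {
  cached("calibration", {
    dom <- make_toy_domain()
    calibrate_stability(dom, steps = 100000, final_steps = 1000000,
                        refine_iter = 4, refine_equil = 0.3, seed = 1)
  })
}

# replica-exchange ensemble of the tethered chain at one tether length
run_tethered <- function(L, lambda, steps = 400000, seed = 31) {
  dom <- make_toy_domain()
  tun <- make_toy_tunnel()
  ch <- attach_linker(dom, L)
  topo <- set_lambda(build_native_topology(ch), lambda)
  conf <- conformation(ch, topo, xyz = initial_tethered_xyz(ch, tun),
                       scaffold = tun, tether = TRUE)
  replica_exchange_run(conf, steps = steps, swap_interval = 500,
                       seed = seed, n_save = 300, save_rungs = 3)
}

get_length_scan <- function() {
  lambda <- get_calibration()$lambda
  cached("length_scan", {
    Ls <- c(20, 22, 24, 26, 28, 30, 32, 34)
    ens <- lapply(Ls, function(L) run_tethered(L, lambda, seed = 31 + L))
    names(ens) <- Ls
    ens
  })
}

get_l25_trajectory <- function() {
  lambda <- get_calibration()$lambda
  cached("l25", {
    ens <- run_tethered(25, lambda, steps = 600000, seed = 77)
    ens$trajectories[[rung_index(ens, 310)]]
  })
}
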