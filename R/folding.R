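# Folded/unfolded classification, P_fold(L) curves, stability calibration
# and probe-anchor distance distributions.

#' Optimal-superposition RMSD to the native structure
#'
#' Least-squares RMSD over the domain backbone beads after optimal rigid
#' superposition (Kabsch algorithm, proper rotations only). Linker beads
#' are excluded: the comparison is between the isolated domains.
#'
#' @param frame An n x 3 coordinate matrix for the whole chain (or already
#'   subset to the domain backbone beads).
#' @param chain The `cg_chain` holding the native reference coordinates.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_native <- function(frame, chain) {
  stopifnot(inherits(chain, "cg_chain"))
  dom <- which(chain$beads$annot == "domain" &
                 chain$beads$role == "backbone")
  ref <- chain$xyz[dom, , drop = FALSE]
  frame <- as.matrix(frame)
  if (nrow(frame) == nrow(chain$beads)) {
    frame <- frame[dom, , drop = FALSE]
  }
  if (nrow(frame) != nrow(ref)) {
    stop("frame does not match the domain bead set")
  }
  if (nrow(ref) < 3) stop("need at least 3 beads for superposition")
  kabsch_rmsd(frame, ref)
}

#' Kabsch superposition RMSD between two coordinate sets
#'
#' @param P,Q Matched n x 3 coordinate matrices.
#' @return RMSD in Angstrom after optimal proper-rotation superposition.
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pr <- P %*% t(R)
  sqrt(mean(rowSums((Pr - Q)^2)))
}

#' Classify a frame by RMSD to the native structure
#'
#' Frames below 3.5 A are folded, above 5.5 A unfolded, in between
#' intermediate.
#'
#' @param rmsd RMSD value(s) in Angstrom (>= 0).
#' @param folded_below,unfolded_above Class thresholds in Angstrom
#'   (defaults 3.5 and 5.5).
#' @return Character vector: `"folded"`, `"intermediate"` or `"unfolded"`.
#' @export
classify_frame <- function(rmsd, folded_below = 3.5, unfolded_above = 5.5) {
  if (any(rmsd < 0)) stop("rmsd must be >= 0")
  ifelse(rmsd < folded_below, "folded",
         ifelse(rmsd > unfolded_above, "unfolded", "intermediate"))
}

#' Classify every frame of a trajectory
#'
#' @param traj A `cg_trajectory` with saved frames.
#' @param ... Passed to [classify_frame()].
#' @return Character vector, one class per frame.
#' @export
classify_trajectory <- function(traj, ...) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(traj$frames)) stop("trajectory has no saved frames")
  nf <- dim(traj$frames)[3]
  r <- vapply(seq_len(nf), function(f) {
    rmsd_to_native(traj$frames[, , f], traj$chain)
  }, numeric(1))
  classify_frame(r, ...)
}

# post-equilibration frame indices
equil_indices <- function(n_frames, equil_frac = 0.2) {
  start <- floor(equil_frac * n_frames) + 1L
  seq.int(start, n_frames)
}

#' Folding probability as a function of tether length
#'
#' For every ensemble, counts folded and unfolded frames at the analysis
#' rung over the post-equilibration portion and reports
#' `P_fold = n_folded / n_total`. Intermediate frames count in the
#' denominator but in neither class.
#'
#' @param ensembles Named list of `replica_ensemble` objects; names (or the
#'   chains' `L` fields) give the tether lengths.
#' @param temperature Analysis temperature in K (default 310).
#' @return A `folding_profile` data frame with columns `L`, `n_folded`,
#'   `n_unfolded`, `n_total`, `P_fold`, ordered by `L`, with attribute
#'   `temperature`.
#' @export
pfold_curve <- function(ensembles, temperature = 310) {
  Ls <- names(ensembles)
  if (is.null(Ls) || any(Ls == "")) {
    Ls <- vapply(ensembles, function(e) e$chain$L, integer(1))
  }
  Ls <- as.numeric(Ls)
  rows <- lapply(seq_along(ensembles), function(k) {
    ens <- ensembles[[k]]
    r <- rung_index(ens, temperature)
    traj <- ens$trajectories[[r]]
    if (is.null(traj$frames)) {
      stop("ensemble at L = ", Ls[k], " has no saved frames at ",
           temperature, " K")
    }
    cls <- classify_trajectory(traj)
    idx <- equil_indices(length(cls), ens$equil_frac)
    cls <- cls[idx]
    data.frame(L = Ls[k],
               n_folded = sum(cls == "folded"),
               n_unfolded = sum(cls == "unfolded"),
               n_total = length(cls),
               P_fold = mean(cls == "folded"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$L), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "temperature") <- temperature
  class(out) <- c("folding_profile", "data.frame")
  out
}

#' Midpoint of a folding profile
#'
#' Least-squares logistic fit `P(L) = 1 / (1 + exp(-(L - L_mid)/w))`, with
#' linear interpolation of the first 0.5 crossing as a fallback when the
#' fit does not converge.
#'
#' @param profile A `folding_profile` (or data frame with `L`, `P_fold`).
#' @return `L_mid` (numeric), with attributes `w` (fit width, `NA` for the
#'   interpolation fallback) and `method`.
#' @export
midpoint <- function(profile) {
  L <- profile$L; P <- profile$P_fold
  o <- order(L); L <- L[o]; P <- P[o]
  if (all(P < 0.5) || all(P > 0.5)) {
    stop("no midpoint: P_fold does not cross 0.5 over the sampled range")
  }
  if (P[1] > 0.5 && P[length(P)] < 0.5) {
    stop("profile decreases with L; expected folding to increase with ",
         "tether length")
  }
  start <- list(L_mid = L[which.min(abs(P - 0.5))[1]], w = 1.5)
  fit <- tryCatch(
    nls(P ~ 1 / (1 + exp(-(L - L_mid) / w)), start = start,
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # bounded Levenberg-Marquardt is more forgiving on noisy profiles
    fit <- tryCatch(
      minpack.lm::nlsLM(P ~ 1 / (1 + exp(-(L - L_mid) / w)),
                        data = data.frame(L = L, P = P), start = start,
                        lower = c(min(L), 0.3), upper = c(max(L), 8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- coef(fit)
    if (cf[["w"]] > 0 && cf[["L_mid"]] >= min(L) && cf[["L_mid"]] <= max(L)) {
      return(structure(unname(cf[["L_mid"]]), w = unname(cf[["w"]]),
                       method = "logistic"))
    }
  }
  i <- which(P >= 0.5)[1]
  if (i == 1L) {
    lm <- L[1]
  } else {
    lm <- L[i - 1] + (0.5 - P[i - 1]) * (L[i] - L[i - 1]) / (P[i] - P[i - 1])
  }
  structure(lm, w = NA_real_, method = "interpolation")
}

#' Two-state folding free energy from state counts
#'
#' `dG = -kB T ln(n_folded / n_unfolded)`, the free energy of the folded
#' relative to the unfolded state.
#'
#' @param n_folded,n_unfolded State counts (or probabilities).
#' @param temperature Temperature in K (default 310).
#' @return Free energy in kcal/mol (negative = folded is more stable).
#' @export
#' @examples
#' two_state_dG(963, 37)  # about -2.0 kcal/mol at 310 K
two_state_dG <- function(n_folded, n_unfolded, temperature = 310) {
  if (n_folded <= 0 || n_unfolded <= 0) {
    stop("need at least one frame in each state")
  }
  -.kB * temperature * log(n_folded / n_unfolded)
}

#' Measure the folding free energy of an isolated domain
#'
#' Runs replica exchange on the isolated (untethered, scaffold-free) domain
#' at the given contact well-depth scale and estimates the two-state free
#' energy from folded/unfolded populations at the analysis rung, with a
#' block-bootstrap standard error.
#'
#' @param chain A `cg_chain` (domain only).
#' @param lambda Contact well-depth scale.
#' @param temperature Analysis temperature in K (default 310).
#' @param ladder Temperature ladder (default [default_ladder()]).
#' @param steps Steps per replica (default 200000).
#' @param seed Integer seed.
#' @param n_save Frame save interval (default 200).
#' @param swap_interval Steps between swap attempts (default 500).
#' @param equil_frac Equilibration fraction discarded (default 0.2).
#' @param n_boot Bootstrap resamples (default 200).
#' @param contact_cutoff Native-contact build cutoff, A (default 8).
#' @param n_runs Number of independent replicate runs (default 1). With
#'   several replicates the folded/unfolded counts are pooled and the
#'   standard error comes from the between-replicate spread; replicate
#'   runs decorrelate the slow replica-flow modes that a single long run
#'   cannot average out.
#' @return List with `dG`, `se`, `P_fold`, `n_folded`, `n_unfolded`,
#'   `n_total` and `lambda`.
#' @export
measure_dG <- function(chain, lambda, temperature = 310,
                       ladder = default_ladder(), steps = 200000,
                       seed = 1, n_save = 200, swap_interval = 500,
                       equil_frac = 0.2, n_boot = 200, contact_cutoff = 8,
                       n_runs = 1) {
  if (n_runs == 1) {
    m <- .dG_run(chain, lambda, temperature, ladder, steps, seed, n_save,
                 swap_interval, equil_frac, n_boot, contact_cutoff)
    return(m[c("dG", "se", "P_fold", "n_folded", "n_unfolded", "n_total",
               "lambda")])
  }
  runs <- lapply(seq_len(n_runs), function(k) {
    .dG_run(chain, lambda, temperature, ladder, steps,
            seed + 7919L * (k - 1L), n_save, swap_interval, equil_frac,
            n_boot, contact_cutoff)
  })
  nf <- sum(vapply(runs, `[[`, numeric(1), "n_folded"))
  nu <- sum(vapply(runs, `[[`, numeric(1), "n_unfolded"))
  ntot <- sum(vapply(runs, `[[`, numeric(1), "n_total"))
  dG <- -.kB * temperature * log(max(nf, 0.5) / max(nu, 0.5))
  per_run <- vapply(runs, `[[`, numeric(1), "dG")
  list(dG = dG, se = sd(per_run) / sqrt(n_runs), P_fold = nf / ntot,
       n_folded = nf, n_unfolded = nu, n_total = ntot, lambda = lambda,
       dG_runs = per_run)
}

# replica-exchange run + two-state statistics at the analysis rung; also
# returns per-frame class labels and native-contact energies so the caller
# can reweight the populations to nearby lambda values
.dG_run <- function(chain, lambda, temperature = 310,
                    ladder = default_ladder(), steps = 200000, seed = 1,
                    n_save = 200, swap_interval = 500, equil_frac = 0.2,
                    n_boot = 200, contact_cutoff = 8) {
  topo <- set_lambda(build_native_topology(chain, contact_cutoff), lambda)
  conf <- conformation(chain, topo)
  rung <- which(abs(ladder - temperature) < 1e-6)
  if (length(rung) != 1) stop("ladder must contain the analysis temperature")
  # deeper contact wells mean stiffer pair interactions; shrink the time
  # step accordingly so trial runs at large lambda stay stable
  dt <- 8 / sqrt(max(1, lambda))
  # cold half of the ladder starts native, hot half extended: the
  # ensemble approaches the folded/unfolded balance from both sides
  n <- nrow(chain$beads)
  ext <- cbind(0.5 * (-1)^seq_len(n), 0, 3.6 * seq_len(n))
  ens <- replica_exchange_run(conf, ladder = ladder, steps = steps,
                              swap_interval = swap_interval, seed = seed,
                              dt = dt, n_save = n_save, save_rungs = rung,
                              equil_frac = equil_frac, xyz_alt = ext,
                              alt_rungs = seq.int(length(ladder) %/% 2 + 1,
                                                  length(ladder)))
  traj <- ens$trajectories[[rung]]
  keep <- equil_indices(dim(traj$frames)[3], equil_frac)
  cls <- classify_trajectory(traj)[keep]
  Ec <- vapply(keep, function(f) {
    unname(cpp_energy(traj$frames[, , f], .topo_cpp(topo),
                      list(), .params_cpp(conf),
                      chain$beads$mass, chain$beads$radius)["contact"])
  }, numeric(1))
  nf <- sum(cls == "folded"); nu <- sum(cls == "unfolded")
  ntot <- length(cls)
  # clamp so a one-sided sample still yields a finite estimate
  dG <- -.kB * temperature * log(max(nf, 0.5) / max(nu, 0.5))
  # block bootstrap over contiguous trajectory blocks
  nblock <- min(20L, ntot)
  blockid <- cut(seq_along(cls), nblock, labels = FALSE)
  blocks <- split(cls, blockid)
  bs <- replicate(n_boot, {
    b <- unlist(blocks[sample.int(nblock, nblock, replace = TRUE)])
    -.kB * temperature * log(max(sum(b == "folded"), 0.5) /
                               max(sum(b == "unfolded"), 0.5))
  })
  list(dG = dG, se = sd(bs), P_fold = nf / ntot,
       n_folded = nf, n_unfolded = nu, n_total = ntot, lambda = lambda,
       cls = cls, Ec = Ec, temperature = temperature)
}

# free-energy estimate at a nearby lambda by thermodynamic perturbation:
# the contact energy is linear in lambda, so frames sampled at lambda0 are
# reweighted by exp(-beta (lambda'/lambda0 - 1) E_contact)
.dG_reweight <- function(run, lambda_new) {
  beta <- 1 / (.kB * run$temperature)
  scale <- lambda_new / run$lambda - 1
  lw <- -beta * scale * run$Ec
  w <- exp(lw - max(lw))
  wf <- sum(w[run$cls == "folded"]); wu <- sum(w[run$cls == "unfolded"])
  wmin <- min(w[w > 0], 1)
  -.kB * run$temperature * log(max(wf, wmin / 2) / max(wu, wmin / 2))
}

#' Calibrate the contact well depth to a target stability
#'
#' Bisects on the global well-depth scale lambda until the measured
#' two-state folding free energy of the isolated domain matches the target
#' (default -2.0 kcal/mol at 310 K, emulating the stabilizing effect of the
#' structural ligand without representing it explicitly). The initial
#' bracket is expanded by factors of 2 (up to twice) if it does not
#' bracket the target.
#'
#' @inheritParams measure_dG
#' @param target_dG Target folding free energy, kcal/mol (default -2.0).
#' @param tolerance Convergence tolerance on dG, kcal/mol (default 0.15).
#' @param bracket Initial lambda bracket (default `c(0.5, 3)`).
#' @param max_iter Maximum bisection iterations (default 8).
#' @param steps Steps per replica for each bisection trial run.
#' @param final_steps Steps per replica for the refinement runs (default
#'   `8 * steps`): the folding transition is steep in lambda, so the last
#'   stage needs longer runs and sub-bisection resolution.
#' @param refine_equil Equilibration fraction for the refinement runs
#'   (default 0.35, deeper than the usual 0.2: replicas start from the
#'   native structure, and the transient of unfolded configurations
#'   flowing down the ladder takes a few hundred thousand steps to
#'   decay).
#' @param refine_iter Maximum perturbation-refinement rounds (default 3;
#'   at least 2 are always run so the pooled estimate rests on more than
#'   one long run).
#' @return List with `lambda` (the calibrated scale: the root of the
#'   pooled reweighted free-energy curve over all refinement runs), `dG`
#'   and `se` measured in the best refinement run (run at `lambda_last`),
#'   and `history` (data frame of all evaluations, with a `stage`
#'   column).
#' @export
calibrate_stability <- function(chain, target_dG = -2.0, temperature = 310,
                                tolerance = 0.15, bracket = c(0.5, 3),
                                ladder = default_ladder(), steps = 150000,
                                final_steps = 8 * steps, max_iter = 8,
                                refine_iter = 3, refine_equil = 0.35,
                                seed = 1, n_save = 200,
                                swap_interval = 500, equil_frac = 0.2,
                                contact_cutoff = 8) {
  hist <- list()
  eval_dG <- function(lambda, nsteps, s, stage) {
    m <- .dG_run(chain, lambda, temperature = temperature,
                 ladder = ladder, steps = nsteps, seed = s,
                 n_save = n_save, swap_interval = swap_interval,
                 equil_frac = if (stage == "refine") refine_equil
                              else equil_frac,
                 contact_cutoff = contact_cutoff)
    hist[[length(hist) + 1L]] <<- data.frame(
      lambda = lambda, dG = m$dG, se = m$se, P_fold = m$P_fold,
      steps = nsteps, stage = stage)
    m
  }
  lo <- bracket[1]; hi <- bracket[2]
  m_lo <- eval_dG(lo, steps, seed + 101L, "bracket")
  m_hi <- eval_dG(hi, steps, seed + 102L, "bracket")
  # dG decreases with lambda: need dG(lo) > target > dG(hi)
  expand <- 0
  while ((m_lo$dG < target_dG || m_hi$dG > target_dG) && expand < 2) {
    expand <- expand + 1
    if (m_lo$dG < target_dG) {
      lo <- lo / 2
      m_lo <- eval_dG(lo, steps, seed + 100L + 10L * expand, "bracket")
    }
    if (m_hi$dG > target_dG) {
      hi <- hi * 2
      m_hi <- eval_dG(hi, steps, seed + 105L + 10L * expand, "bracket")
    }
  }
  if (m_lo$dG < target_dG || m_hi$dG > target_dG) {
    stop("calibration failure: lambda interval [", lo, ", ", hi,
         "] does not bracket the target stability after expansion")
  }
  # stage 1: bisection down to a narrow lambda interval
  for (it in seq_len(max_iter)) {
    if (hi - lo < 0.02) break
    mid <- 0.5 * (lo + hi)
    m <- eval_dG(mid, steps, seed + 200L + it, "bisection")
    if (m$dG > target_dG) lo <- mid else hi <- mid
  }
  # stage 2: long runs + thermodynamic perturbation in lambda.
  # dG is steep in lambda (its slope is roughly the native-contact energy
  # gap between the states), so the root is polished by reweighting the
  # populations of each long run to nearby lambda values; all refinement
  # runs are pooled (inverse-variance weights) when locating the root.
  lambda0 <- 0.5 * (lo + hi)
  runs <- list()
  best <- NULL
  # perturbation is only trustworthy close to the sampled lambda: beyond a
  # few percent the reweighted ensemble collapses onto a handful of frames
  trust <- 0.02
  pooled_root <- function() {
    grid <- seq(lambda0 * (1 - trust), lambda0 * (1 + trust),
                length.out = 201)
    w <- vapply(runs, function(r) 1 / max(r$se, 0.05)^2, numeric(1))
    pooled <- vapply(grid, function(l) {
      use <- vapply(runs, function(r)
        abs(l - r$lambda) <= trust * r$lambda, logical(1))
      if (!any(use)) return(NA_real_)
      dg <- vapply(runs[use], function(r) .dG_reweight(r, l), numeric(1))
      sum(dg * w[use]) / sum(w[use])
    }, numeric(1))
    ok <- !is.na(pooled)
    grid[ok][which.min(abs(pooled[ok] - target_dG))]
  }
  for (it in seq_len(refine_iter)) {
    m <- eval_dG(lambda0, final_steps, seed + 300L + it, "refine")
    runs[[length(runs) + 1L]] <- m
    if (is.null(best) ||
        abs(m$dG - target_dG) < abs(best$dG - target_dG)) best <- m
    lambda0 <- pooled_root()
  }
  lambda_star <- lambda0
  list(lambda = lambda_star, dG = best$dG, se = best$se,
       lambda_last = best$lambda,
       history = do.call(rbind, hist))
}

#' Probe-anchor distance histogram
#'
#' Per retained frame, the Euclidean distance between the probe residue's
#' backbone bead and the scaffold anchor (the P-site tether point,
#' standing in for the 3'-terminal phosphorus of the P-site tRNA), binned
#' in 2 A bins aligned to zero.
#'
#' @param traj A `cg_trajectory` in a scaffold.
#' @param class_filter `"folded"`, `"unfolded"` or `"all"`; intermediate
#'   frames never enter a filtered histogram.
#' @param equil_frac Equilibration fraction discarded (default 0.2).
#' @param bin_width Bin width in Angstrom (default 2).
#' @return A `distance_histogram`: list with `breaks`, `counts`, `mids`,
#'   `distances` (the retained raw distances), `class_filter`,
#'   `temperature` and `L`.
#' @export
distance_histogram <- function(traj, class_filter = c("folded", "unfolded",
                                                      "all"),
                               equil_frac = 0.2, bin_width = 2) {
  class_filter <- match.arg(class_filter)
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(traj$scaffold)) stop("trajectory has no scaffold/anchor")
  probe <- traj$chain$probe
  anchor <- traj$scaffold$anchor
  idx <- equil_indices(dim(traj$frames)[3], equil_frac)
  if (class_filter != "all") {
    cls <- classify_trajectory(traj)
    idx <- idx[cls[idx] == class_filter]
  }
  if (length(idx) == 0) {
    warning("no frames match the class filter; empty histogram")
    d <- numeric(0)
  } else {
    d <- vapply(idx, function(f) {
      sqrt(sum((traj$frames[probe, , f] - anchor)^2))
    }, numeric(1))
  }
  hi <- if (length(d) > 0) bin_width * (floor(max(d) / bin_width) + 1)
        else bin_width
  breaks <- seq(0, hi, by = bin_width)
  counts <- if (length(d) > 0) {
    tabulate(findInterval(d, breaks, rightmost.closed = FALSE),
             nbins = length(breaks) - 1)
  } else {
    integer(length(breaks) - 1)
  }
  structure(list(breaks = breaks, counts = counts,
                 mids = breaks[-length(breaks)] + bin_width / 2,
                 distances = d, class_filter = class_filter,
                 temperature = traj$temperature, L = traj$chain$L),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat("Probe-anchor distance histogram (", x$class_filter, " frames, ",
      x$temperature, " K, L = ", x$L, "): ", length(x$distances),
      " frames\n", sep = "")
  if (length(x$distances) > 0) {
    q <- quantile(x$distances, c(0.05, 0.5, 0.95))
    cat(sprintf("5%% / median / 95%%: %.1f / %.1f / %.1f A\n",
                q[1], q[2], q[3]))
  }
  invisible(x)
}

#' Write a folding profile or distance histogram to CSV
#' @param x A `folding_profile` or `distance_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  if (inherits(x, "distance_histogram")) {
    write.csv(data.frame(bin_lo = x$breaks[-length(x$breaks)],
                         bin_hi = x$breaks[-1], count = x$counts),
              path, row.names = FALSE)
  } else {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' Initial tethered conformation threaded through the tunnel
#'
#' Places the chain as an extended zigzag strand along the tunnel axis,
#' last bead at the anchor, so tethered simulations start unfolded and
#' inside the tunnel. The zigzag (rather than a straight line) keeps the
#' starting geometry away from collinear bond angles.
#'
#' @param chain A `cg_chain` (domain + linker).
#' @param scaffold A `ribosome_scaffold`.
#' @param spacing Axial bead spacing (default 3.6 A; with the 0.5 A
#'   zigzag the bond lengths are ~3.63 A).
#' @return An n x 3 coordinate matrix.
#' @export
initial_tethered_xyz <- function(chain, scaffold, spacing = 3.6) {
  n <- nrow(chain$beads)
  dirv <- scaffold$axis$direction
  anchor <- scaffold$anchor
  # a unit vector perpendicular to the axis
  ref <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- ref - sum(ref * dirv) * dirv
  perp <- perp / sqrt(sum(perp^2))
  t(vapply(seq_len(n), function(i) {
    anchor + dirv * spacing * (n - i) + perp * 0.5 * (-1)^i * (i < n)
  }, numeric(3)))
}

#' Initial tethered conformation with the domain pre-folded in the tunnel
#'
#' Places the native domain on the tunnel axis, C-terminus facing the
#' anchor, at the shallowest depth where the local tunnel radius clears
#' the folded cross-section, and threads a slack zigzag linker back to
#' the anchor. Together with [initial_tethered_xyz()] this supports
#' two-sided starts of tethered replica ensembles: cold rungs begin
#' folded, hot rungs extended, so the folded/unfolded balance is
#' approached from both sides.
#'
#' @param chain A `cg_chain` (domain + linker).
#' @param scaffold A `ribosome_scaffold`.
#' @param clearance Tunnel radius (A) needed by the folded domain
#'   (default 9.5: the ~5 A cross-section circumradius plus the wall
#'   exclusion layer).
#' @return An n x 3 coordinate matrix.
#' @export
initial_tethered_folded_xyz <- function(chain, scaffold, clearance = 9.5) {
  dom <- which(chain$beads$annot == "domain")
  lnk <- which(chain$beads$annot == "linker")
  dirv <- scaffold$axis$direction
  anchor <- scaffold$anchor
  xyz_dom <- chain$xyz[dom, , drop = FALSE]
  ctr <- colMeans(xyz_dom)
  cterm <- xyz_dom[nrow(xyz_dom), ]
  # rotate the native domain so centroid -> C-terminus points at the anchor
  a <- cterm - ctr; a <- a / sqrt(sum(a^2))
  b <- -dirv
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  R <- if (sum(v^2) < 1e-12) {
    diag(3) * sign(cth)
  } else {
    vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
    diag(3) + vx + vx %*% vx / (1 + cth)
  }
  xyz_dom <- sweep(xyz_dom, 2, ctr) %*% t(R)
  # depth: shallowest axis position, distal to the constriction, whose
  # radius clears the folded domain (the entrance may be wide enough but
  # is walled off by the constriction)
  len <- scaffold$axis$length
  t_fit <- if (is.function(scaffold$profile)) {
    ts <- seq(1, len, by = 0.5)
    prof <- scaffold$profile(-ts)
    t_min <- ts[which.min(prof)]
    ts[which(ts >= t_min & prof >= clearance)[1]]
  } else {
    0.7 * len
  }
  if (is.na(t_fit)) t_fit <- 0.8 * len
  half <- max(xyz_dom %*% (-dirv))   # extent of the domain toward the anchor
  # keep the linker reachable: its contour must span anchor to C-terminus
  t_ctr <- min(t_fit + half, 3.5 * (length(lnk) + 1) + half)
  ctr_pos <- anchor + dirv * t_ctr
  out <- matrix(NA_real_, nrow(chain$xyz), 3)
  out[dom, ] <- sweep(xyz_dom, 2, ctr_pos, "+")
  if (length(lnk) > 0) {
    cpos <- out[dom[length(dom)], ]
    span <- anchor - cpos
    nb <- length(lnk)               # bead L sits exactly on the anchor
    adv <- sqrt(sum(span^2)) / nb
    amp <- sqrt(max(0, 3.8^2 - adv^2)) / 2
    ref <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- ref - sum(ref * dirv) * dirv
    perp <- perp / sqrt(sum(perp^2))
    for (k in seq_along(lnk)) {
      out[lnk[k], ] <- cpos + span * (k / nb) + perp * amp * (-1)^k *
        (k < nb)
    }
  }
  out
}
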