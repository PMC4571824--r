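# RMSD, frame classification, folding curves, stability formula and
# distance histograms.

test_that("rmsd to native is zero for the native and any rigid motion of it", {
  dom <- make_toy_domain()
  expect_equal(rmsd_to_native(dom$xyz, dom), 0, tolerance = 1e-8)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- sweep(dom$xyz %*% R, 2, c(30, -12, 5), "+")
  expect_lt(rmsd_to_native(moved, dom), 1e-6)
})

test_that("kabsch rmsd matches a brute-force rotation-grid search", {
  set.seed(6)
  P <- matrix(rnorm(12, sd = 2), 4, 3)
  Q <- matrix(rnorm(12, sd = 2), 4, 3)
  got <- kabsch_rmsd(P, Q)
  # oracle: exhaustive search over ZYZ Euler angles
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rotz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                            c(0, 0, 1))
  roty <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                            c(-sin(a), 0, cos(a)))
  best <- Inf
  coarse <- expand.grid(a = seq(0, 2 * pi, length.out = 25),
                        b = seq(0, pi, length.out = 13),
                        c = seq(0, 2 * pi, length.out = 25))
  eval_abc <- function(a, b, c) {
    R <- rotz(a) %*% roty(b) %*% rotz(c)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  vals <- mapply(eval_abc, coarse$a, coarse$b, coarse$c)
  k <- which.min(vals)
  # refine around the coarse optimum
  fine <- expand.grid(
    a = coarse$a[k] + seq(-0.15, 0.15, length.out = 13),
    b = coarse$b[k] + seq(-0.15, 0.15, length.out = 13),
    c = coarse$c[k] + seq(-0.15, 0.15, length.out = 13))
  best <- min(mapply(eval_abc, fine$a, fine$b, fine$c))
  expect_equal(got, best, tolerance = 1e-3)
  expect_lte(got, best + 1e-9)  # Kabsch is the true optimum
})

test_that("kabsch agrees with the bio3d superposition rmsd", {
  set.seed(7)
  P <- matrix(rnorm(30, sd = 3), 10, 3)
  Q <- P + matrix(rnorm(30, sd = 0.8), 10, 3)
  ref <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
  expect_equal(kabsch_rmsd(P, Q), ref, tolerance = 1e-3)
})

test_that("frames classify by the 3.5/5.5 A thresholds", {
  expect_equal(classify_frame(3.4), "folded")
  expect_equal(classify_frame(5.6), "unfolded")
  expect_equal(classify_frame(4.5), "intermediate")
  expect_equal(classify_frame(c(0, 3.6, 10)),
               c("folded", "intermediate", "unfolded"))
  expect_error(classify_frame(-1), ">= 0")
})

test_that("pfold_curve counts planted two-state frames like a hand count", {
  dom <- make_toy_domain()
  n <- nrow(dom$xyz)
  set.seed(9)
  mk_frames <- function(n_nat, n_jit, sd_jit) {
    frames <- array(NA_real_, c(n, 3, n_nat + n_jit))
    for (f in seq_len(n_nat)) frames[, , f] <- dom$xyz
    for (f in seq_len(n_jit)) {
      frames[, , n_nat + f] <- dom$xyz + matrix(rnorm(3 * n, sd = sd_jit),
                                                n, 3)
    }
    frames
  }
  fake_ens <- function(frames) {
    ladder <- default_ladder()
    trajs <- vector("list", length(ladder))
    trajs[[3]] <- structure(list(frames = frames, temperature = 310,
                                 chain = dom, scaffold = NULL),
                            class = "cg_trajectory")
    structure(list(ladder = ladder, trajectories = trajs, equil_frac = 0,
                   chain = dom),
              class = "replica_ensemble")
  }
  e1 <- fake_ens(mk_frames(15, 5, 4))   # mostly native + heavily jittered
  e2 <- fake_ens(mk_frames(5, 15, 4))
  prof <- pfold_curve(list(`10` = e1, `12` = e2), temperature = 310)
  # oracle: direct per-frame count
  count_folded <- function(frames) {
    sum(vapply(seq_len(dim(frames)[3]), function(f)
      classify_frame(rmsd_to_native(frames[, , f], dom)) == "folded",
      logical(1)))
  }
  expect_equal(prof$L, c(10, 12))
  expect_equal(prof$n_folded[1], count_folded(e1$trajectories[[3]]$frames))
  expect_equal(prof$P_fold, prof$n_folded / prof$n_total)
  expect_equal(prof$n_total, c(20, 20))
  expect_true(all(prof$n_folded + prof$n_unfolded <= prof$n_total))
})

test_that("midpoint: symmetric crossing, logistic recovery and orientation", {
  prof <- data.frame(L = c(20, 24, 28, 32, 36), P_fold = c(0, 0, 0.5, 1, 1))
  expect_equal(as.numeric(midpoint(prof)), 28, tolerance = 1e-6)

  L <- 20:34
  prof2 <- data.frame(L = L, P_fold = 1 / (1 + exp(-(L - 26.5) / 1.5)))
  expect_equal(as.numeric(midpoint(prof2)), 26.5, tolerance = 0.05)

  dec <- data.frame(L = L, P_fold = rev(prof2$P_fold))
  expect_error(midpoint(dec), "decreases")
  flat <- data.frame(L = L, P_fold = rep(0.2, length(L)))
  expect_error(midpoint(flat), "cross")
})

test_that("the two-state free energy formula inverts planted counts", {
  kB <- tf_constants()[["kB"]]
  expect_equal(two_state_dG(963, 37), -kB * 310 * log(963 / 37))
  expect_equal(two_state_dG(963, 37), -2.008, tolerance = 1e-3)
  expect_equal(two_state_dG(50, 50), 0)
  # inversion: dG -> P -> dG
  dG <- -1.3
  K <- exp(-dG / (kB * 310))
  P <- K / (1 + K)
  expect_equal(two_state_dG(P, 1 - P), dG, tolerance = 1e-12)
  expect_error(two_state_dG(0, 10), "at least one")
})

test_that("distance histograms use 2 A bins aligned to zero", {
  dom <- make_toy_domain()
  sc <- far_scaffold()
  n <- nrow(dom$xyz)
  # single frame with the probe bead at exactly 66.0 A from the anchor
  xyz <- dom$xyz
  xyz <- sweep(xyz, 2, xyz[dom$probe, ]) # probe at origin
  xyz[, 3] <- xyz[, 3] - 66
  frames <- array(xyz, c(n, 3, 1))
  traj <- structure(list(frames = frames, energies = 0, temperature = 310,
                         chain = dom, scaffold = sc, n_save = 1),
                    class = "cg_trajectory")
  h <- distance_histogram(traj, class_filter = "all", equil_frac = 0)
  expect_equal(unique(diff(h$breaks)), 2)
  expect_equal(h$breaks[1], 0)
  expect_equal(sum(h$counts), 1)
  bin <- which(h$counts == 1)
  expect_equal(h$breaks[bin], 66)      # count falls in [66, 68)
  expect_equal(h$distances, 66, tolerance = 1e-9)
})

test_that("histogram counts equal a hand-binned reference on planted distances", {
  dom <- make_toy_domain()
  sc <- far_scaffold()
  n <- nrow(dom$xyz)
  set.seed(12)
  d_planted <- runif(100, 40, 90)
  frames <- array(NA_real_, c(n, 3, 100))
  for (f in 1:100) {
    xyz <- sweep(dom$xyz, 2, dom$xyz[dom$probe, ])
    xyz[, 3] <- xyz[, 3] - d_planted[f]
    frames[, , f] <- xyz
  }
  traj <- structure(list(frames = frames, energies = numeric(100),
                         temperature = 310, chain = dom, scaffold = sc,
                         n_save = 1),
                    class = "cg_trajectory")
  h <- distance_histogram(traj, class_filter = "all", equil_frac = 0)
  ref <- table(cut(d_planted, breaks = h$breaks, right = FALSE))
  expect_equal(unname(h$counts), unname(as.integer(ref)))
  # class filtering excludes everything when no frame matches
  expect_warning(hh <- distance_histogram(traj, class_filter = "unfolded",
                                          equil_frac = 0), "empty")
  expect_equal(sum(hh$counts), 0)
})

test_that("the pre-folded tethered start is geometrically sane", {
  dom <- make_toy_domain()
  tun <- make_toy_tunnel()
  ch <- attach_linker(dom, 25)
  xyz <- initial_tethered_folded_xyz(ch, tun)
  # intact native domain, bonded linker, last bead on the anchor
  expect_lt(rmsd_to_native(xyz, ch), 1e-6)
  d <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(d > 1.8 & d < 4.2))
  expect_lt(sqrt(sum((xyz[nrow(xyz), ] - tun$anchor)^2)), 1e-6)
  # domain sits distal to the constriction, inside the tunnel
  dom_z <- xyz[ch$beads$annot == "domain", 3]
  expect_true(all(dom_z < -40))
  expect_true(mean(dom_z) > -100)
  # the conformation is energetically relaxed enough to integrate
  topo <- set_lambda(build_native_topology(ch), 0.35)
  conf <- conformation(ch, topo, xyz = xyz, scaffold = tun, tether = TRUE)
  e <- energy(conf)
  expect_lt(unname(e["total"]), 200)
  expect_true(all(is.finite(e)))
})
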