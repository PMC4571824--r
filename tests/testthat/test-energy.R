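# Potential energy terms, analytic forces and the lambda scale.

test_that("a single native contact at its minimum contributes -lambda*eps", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  ch <- tiny_chain(xyz)
  topo <- empty_topology(2)
  topo$contacts <- data.frame(i = 1, j = 2, eps = 1, sigma = 5)
  e <- energy(conformation(ch, topo))
  expect_equal(unname(e["contact"]), -1)  # 5 - 6 = -1 at r = sigma
  # lambda linearity, exactly
  e2 <- energy(conformation(ch, set_lambda(topo, 2)))
  expect_equal(unname(e2["contact"]), -2)
  e05 <- energy(conformation(ch, set_lambda(topo, 0.5)))
  expect_equal(unname(e05["contact"]), -0.5)
})

test_that("the native conformation has zero bonded energy and -lambda*sum(eps)", {
  dom <- make_toy_domain()
  topo <- build_native_topology(dom)
  e <- energy(conformation(dom, topo))
  expect_equal(unname(e["bond"]), 0, tolerance = 1e-10)
  expect_equal(unname(e["angle"]), 0, tolerance = 1e-10)
  expect_equal(unname(e["dihedral"]), 0, tolerance = 1e-10)
  expect_equal(unname(e["contact"]), -sum(topo$contacts$eps))
  expect_equal(unname(e["total"]), sum(e[names(e) != "total"]),
               tolerance = 1e-12)
  # scaling the well depth scales only the contact term
  e15 <- energy(conformation(dom, set_lambda(topo, 1.5)))
  expect_equal(unname(e15["contact"]), 1.5 * unname(e["contact"]))
  expect_equal(unname(e15["bond"]), unname(e["bond"]))
})

test_that("energy equals an independent term-by-term recomputation", {
  # direct R implementation of every term on a random 5-bead conformation
  set.seed(4)
  xyz <- matrix(rnorm(15, sd = 3), 5, 3)
  xyz[2, ] <- xyz[1, ] + c(3.5, 0, 0)   # keep bonded pairs in sane ranges
  xyz[3, ] <- xyz[2, ] + c(0.5, 3.4, 0)
  xyz[4, ] <- xyz[3, ] + c(-2, 1, 2.5)
  xyz[5, ] <- xyz[4, ] + c(1, -3, 1)
  ch <- tiny_chain(xyz)
  native <- tiny_chain(matrix(rnorm(15, sd = 4), 5, 3))
  topo <- build_native_topology(native, contact_cutoff = 30)
  conf <- conformation(ch, topo, xyz = xyz)
  e <- energy(conf)

  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  ang <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  # harmonic in theta over [0.5, 2.8] rad, continued linearly in cos(theta)
  # outside (value- and slope-matched), exactly as the engine defines it
  angle_U <- function(th, kf, th0) {
    if (th < 0.5) {
      b1 <- kf * (0.5 - th0) / sin(0.5)
      0.5 * kf * (0.5 - th0)^2 - b1 * (1 - cos(0.5)) + b1 * (1 - cos(th))
    } else if (th <= 2.8) {
      0.5 * kf * (th - th0)^2
    } else {
      b0 <- -kf * (2.8 - th0) / sin(2.8)
      0.5 * kf * (2.8 - th0)^2 - b0 * (1 + cos(2.8)) + b0 * (1 + cos(th))
    }
  }
  eb <- sum(0.5 * topo$bonds$k *
              (mapply(d, topo$bonds$i, topo$bonds$j) - topo$bonds$r0)^2)
  ea <- sum(mapply(function(i, j, k, kf, th0)
    angle_U(ang(i, j, k), kf, th0),
    topo$angles$i, topo$angles$j, topo$angles$k,
    topo$angles$k_theta, topo$angles$theta0))
  dihf <- tunnelfold:::.dihedral_angle
  ed <- sum(mapply(function(i, j, k, l, k1, k2, phi0) {
    dphi <- dihf(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ]) - phi0
    k1 * (1 - cos(dphi)) + k2 * (1 - cos(3 * dphi))
  }, topo$dihedrals$i, topo$dihedrals$j, topo$dihedrals$k, topo$dihedrals$l,
     topo$dihedrals$k1, topo$dihedrals$k2, topo$dihedrals$phi0))
  ec <- sum(mapply(function(i, j, eps, sig) {
    r <- d(i, j)
    if (r > 12) return(0)
    eps * (5 * (sig / r)^12 - 6 * (sig / r)^10)
  }, topo$contacts$i, topo$contacts$j, topo$contacts$eps,
     topo$contacts$sigma)) * topo$lambda

  expect_equal(unname(e["bond"]), eb, tolerance = 1e-9)
  expect_equal(unname(e["angle"]), ea, tolerance = 1e-9)
  expect_equal(unname(e["dihedral"]), ed, tolerance = 1e-9)
  expect_equal(unname(e["contact"]), ec, tolerance = 1e-9)
})

test_that("forces are the negative finite-difference gradient", {
  dom <- make_toy_domain()
  topo <- build_native_topology(dom)
  tun <- make_toy_tunnel(length = 60)
  set.seed(11)
  h <- 1e-5
  for (rep in 1:20) {
    xyz <- dom$xyz + matrix(rnorm(nrow(dom$xyz) * 3, sd = 0.25),
                            nrow(dom$xyz), 3)
    scaf <- if (rep %% 2 == 0) tun else NULL
    conf <- conformation(dom, topo, xyz = xyz, scaffold = scaf,
                         tether = !is.null(scaf))
    f <- forces(conf)
    # spot-check 6 random coordinates per conformation
    for (k in seq_len(6)) {
      i <- sample.int(nrow(xyz), 1); ax <- sample.int(3, 1)
      xp <- xyz; xp[i, ax] <- xp[i, ax] + h
      xm <- xyz; xm[i, ax] <- xm[i, ax] - h
      num <- -(energy(conformation(dom, topo, xyz = xp, scaffold = scaf,
                                   tether = !is.null(scaf)))["total"] -
               energy(conformation(dom, topo, xyz = xm, scaffold = scaf,
                                   tether = !is.null(scaf)))["total"]) / (2 * h)
      expect_equal(f[i, ax], unname(num), tolerance = 1e-4)
    }
  }
})

test_that("net force vanishes under translation; energy is rigid-motion invariant", {
  dom <- make_toy_domain()
  topo <- build_native_topology(dom)
  set.seed(2)
  xyz <- dom$xyz + matrix(rnorm(87, sd = 0.4), 29, 3)
  f <- forces(conformation(dom, topo, xyz = xyz))
  expect_lt(max(abs(colSums(f))), 1e-9)

  e0 <- energy(conformation(dom, topo, xyz = xyz))["total"]
  shifted <- sweep(xyz, 2, c(13.2, -8.1, 4.4), "+")
  expect_equal(unname(energy(conformation(dom, topo, xyz = shifted))["total"]),
               unname(e0), tolerance = 1e-9)
  th <- 0.77
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(unname(energy(conformation(dom, topo, xyz = xyz %*% R))["total"]),
               unname(e0), tolerance = 1e-9)
})

test_that("the native structure is force-free and set_lambda validates", {
  dom <- make_toy_domain()
  topo <- build_native_topology(dom)
  f <- forces(conformation(dom, topo))
  expect_lt(max(abs(f)), 1e-6)
  expect_error(set_lambda(topo, 0), "positive")
  expect_error(set_lambda(topo, -1), "positive")
  # identity at lambda = 1
  expect_equal(energy(conformation(dom, set_lambda(topo, 1))),
               energy(conformation(dom, topo)))
})

test_that("overlapping beads raise a singular-geometry error", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1e-8), c(5, 0, 0))
  ch <- tiny_chain(xyz)
  topo <- empty_topology(3)
  expect_error(energy(conformation(ch, topo, xyz = xyz)), "singular")
})

test_that("topology/parameter JSON round trip preserves the model", {
  dom <- make_toy_domain()
  topo <- set_lambda(build_native_topology(dom), 0.42)
  path <- tempfile(fileext = ".json")
  write_topology_json(topo, cg_params(k_tether = 7), path)
  back <- read_topology_json(path)
  expect_equal(back$topology$lambda, 0.42)
  expect_equal(back$topology$contacts, topo$contacts, tolerance = 1e-12)
  expect_equal(back$params$k_tether, 7)
})
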