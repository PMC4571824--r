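# Synthetic structures: an idealized compact zinc-finger-like domain and a
# toy exit-tunnel scaffold with entrance, constriction and vestibule.

#' Build a compact toy native domain
#'
#' Constructs a deterministic, compact native structure emulating a small
#' zinc-finger fold: an ideal beta-hairpin packed against an ideal
#' alpha-helix, with C-alpha virtual bonds of 3.8 A. At the default size
#' (29 residues) the structure fits in a sphere of radius <= 12 A. The
#' distance-probe residue defaults to position 21 (the position homologous
#' to His21 of ADR1a) and the sequence carries a Cys2His2-like motif for
#' flavor; the model is sequence-independent.
#'
#' @param n_res Number of residues (>= 8; default 29).
#' @param seed Integer seed for the tiny symmetry-breaking jitter
#'   (0.002 A s.d.) applied to the ideal coordinates.
#' @param probe Probe residue position (default 21, clamped to `n_res`).
#' @return A `cg_chain` (one bead per residue).
#' @export
#' @examples
#' dom <- make_toy_domain()
#' dom
make_toy_domain <- function(n_res = 29, seed = 1, probe = 21) {
  if (n_res < 8) stop("n_res must be >= 8")
  n_hp <- min(14L, 2L * ((n_res %/% 2L - 1L) %/% 2L) + 2L)  # hairpin size
  n_strand <- (n_hp - 2L) %/% 2L
  n_helix <- n_res - n_hp

  xyz <- matrix(NA_real_, n_res, 3)
  # strand A: zigzag up the z axis (real beta-strand C-alpha angles ~130
  # degrees; perfectly straight strands would put the native angle at the
  # 1/sin(theta) singularity of the harmonic angle force)
  a <- 0.8                      # zigzag amplitude
  h <- sqrt(3.8^2 - (2 * a)^2)  # axial rise per residue
  for (i in seq_len(n_strand)) {
    xyz[i, ] <- c(a * (-1)^i, 0, (i - 1) * h)
  }
  ztop <- (n_strand - 1) * h
  sep <- 4.6  # inter-strand distance
  # two turn beads, arched sideways in y, exact 3.8 A steps
  xA <- a * (-1)^n_strand                 # strand A end x
  xB <- sep - a                           # strand B start x
  x1 <- (xA + xB) / 2 - 1.9; x2 <- x1 + 3.8
  y1 <- sqrt(max(0.25, 3.8^2 - (x1 - xA)^2))
  xyz[n_strand + 1L, ] <- c(x1, y1, ztop)
  xyz[n_strand + 2L, ] <- c(x2, y1, ztop)
  # strand B: zigzag back down
  for (k in seq_len(n_strand)) {
    xyz[n_strand + 2L + k, ] <- c(sep + a * (-1)^k, 0, ztop - (k - 1) * h)
  }
  bend <- xyz[n_hp, 1:2]  # hairpin C-terminal bead (z = 0)
  # ideal alpha-helix: rise 1.5 A, 100 degrees per residue, radius chosen so
  # consecutive C-alpha distances are exactly 3.8 A
  rise <- 1.5
  r_hel <- sqrt(3.8^2 - rise^2) / (2 * sin(50 * pi / 180))
  xc <- sep / 2; yc <- 5.0
  # helix start points toward the hairpin C-terminus, 3.8 A away
  repeat {
    th0 <- atan2(bend[2] - yc, bend[1] - xc)
    p0 <- c(xc + r_hel * cos(th0), yc + r_hel * sin(th0))
    dz2 <- 3.8^2 - sum((p0 - bend)^2)
    if (dz2 > 0.25) break
    yc <- yc - 0.2
    if (yc < 3) { dz2 <- 0.25; break }
  }
  z0 <- sqrt(dz2)
  for (k in seq_len(n_helix)) {
    th <- th0 + (k - 1) * 100 * pi / 180
    xyz[n_hp + k, ] <- c(xc + r_hel * cos(th), yc + r_hel * sin(th),
                         z0 + (k - 1) * rise)
  }

  # seeded sub-bond-length jitter to break exact symmetries
  set.seed(seed)
  xyz <- xyz + matrix(rnorm(3 * n_res, sd = 0.002), n_res, 3)
  xyz <- sweep(xyz, 2, colMeans(xyz))  # center at origin

  seqs <- rep("ALA", n_res)
  seqs[c(5, 8)] <- "CYS"
  probe <- min(probe, n_res)
  seqs[probe] <- "HIS"
  if (probe + 4 <= n_res) seqs[probe + 4] <- "HIS"

  beads <- data.frame(resno = seq_len(n_res), role = "backbone",
                      mass = 110, radius = 2, annot = "domain",
                      stringsAsFactors = FALSE)
  new_cg_chain(beads, xyz, seqs, probe, L = 0L)
}

#' Build a toy exit-tunnel scaffold
#'
#' A synthetic stand-in for the large-subunit exit tunnel: a tube of static
#' repulsive beads along the -z axis from the P-site anchor at the origin,
#' ~100 A long, with a wide entrance, a constriction and a distal vestibule
#' that widens toward the open exit. The radius profile is
#' `entrance_radius` for z in \[0, -25\], tapers linearly to
#' `constriction_radius` over \[-25, -40\], then widens linearly to
#' `vestibule_radius` over \[-40, -length\]. A bead disk 4 A above the
#' anchor closes the entrance so the chain cannot leave past the P site;
#' the exit end is open.
#'
#' @param length Tunnel length in Angstrom (anchor to exit; default 100).
#' @param entrance_radius,constriction_radius,vestibule_radius Radius
#'   profile in Angstrom (defaults 10, 6, 22). The vestibule default is
#'   set so the folded toy domain (cross-section circumradius ~5 A plus
#'   the ~3.5 A wall exclusion layer) fits the distal vestibule but never
#'   the constriction, and so that tethered simulations actually reach
#'   the folded state at long tethers within desk-scale sampling.
#' @param bead_spacing Spacing of wall beads on the surface (default 3 A).
#' @param bead_radius Repulsive radius of wall beads (default 1.5 A; the
#'   3 A lattice stays impermeable while keeping the effective wall
#'   exclusion close to the nominal radius profile).
#' @return A `ribosome_scaffold` with anchor `c(0,0,0)` and exit
#'   `c(0,0,-length)`.
#' @export
#' @examples
#' tun <- make_toy_tunnel()
#' tun
make_toy_tunnel <- function(length = 100, entrance_radius = 10,
                            constriction_radius = 6, vestibule_radius = 22,
                            bead_spacing = 3, bead_radius = 1.5) {
  if (entrance_radius <= 0 || constriction_radius <= 0 ||
      vestibule_radius <= 0 || length <= 45 || bead_spacing <= 0) {
    stop("degenerate tunnel geometry")
  }
  if (constriction_radius >= vestibule_radius) {
    stop("constriction_radius must be smaller than vestibule_radius")
  }
  prof <- function(z) {  # z <= 0
    d <- -z
    ifelse(d <= 25, entrance_radius,
      ifelse(d <= 40,
        entrance_radius + (constriction_radius - entrance_radius) *
          (d - 25) / 15,
        constriction_radius + (vestibule_radius - constriction_radius) *
          (d - 40) / (length - 40)))
  }
  # ring positions, always including the profile breakpoints and the exit
  zs <- sort(unique(c(seq(0, -length, by = -bead_spacing),
                      -25, -40, -length)), decreasing = TRUE)
  pts <- list()
  for (z in zs) {
    r <- prof(z)
    nth <- max(6L, ceiling(2 * pi * r / bead_spacing))
    th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
    pts[[length(pts) + 1L]] <- cbind(r * cos(th), r * sin(th), z)
  }
  # entrance cap: bead disk at z = +4 covering the entrance opening
  zcap <- 4
  for (r in seq(0, entrance_radius + 4, by = bead_spacing)) {
    if (r == 0) {
      pts[[length(pts) + 1L]] <- cbind(0, 0, zcap)
    } else {
      nth <- max(6L, ceiling(2 * pi * r / bead_spacing))
      th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
      pts[[length(pts) + 1L]] <- cbind(r * cos(th), r * sin(th), zcap)
    }
  }
  xyz <- do.call(rbind, pts)
  sc <- new_scaffold(xyz, rep(bead_radius, nrow(xyz)),
                     anchor = c(0, 0, 0), exit = c(0, 0, -length),
                     profile = prof)
  sc
}
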