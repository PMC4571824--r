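# Structure input, coarse graining, native topology and ribosome scaffolds.

#' Read atoms from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that returns a plain atom table
#' with coordinates in Angstrom. Alternate locations are resolved
#' deterministically (the first altloc encountered in file order wins) and
#' insertion-coded residues are kept in file order.
#'
#' @param path Path to a PDB coordinate file.
#' @param chain Optional character vector of chain identifiers to keep.
#' @param resno Optional integer vector of residue numbers to keep.
#' @param hetatm Keep HETATM records? Default `TRUE`.
#'
#' @return A data frame of class `atomset` with columns `elety` (atom name),
#'   `elesy` (element symbol), `resno`, `resid`, `chain`, `insert`,
#'   `x`, `y`, `z` and `type`.
#' @export
#' @examples
#' pdb <- system.file("extdata", "toy3.pdb", package = "tunnelfold")
#' read_pdb(pdb)
read_pdb <- function(path, chain = NULL, resno = NULL, hetatm = TRUE) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path)
  }
  .validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!is.null(resno)) at <- at[at$resno %in% resno, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty selection: no atoms match the selectors")
  # first altloc wins, per (chain, resno, insert, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[!duplicated(key), , drop = FALSE]
  out <- data.frame(
    elety = at$elety,
    elesy = at$elesy,
    resno = at$resno,
    resid = at$resid,
    chain = at$chain,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    type = at$type,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("non-finite coordinates in PDB file")
  }
  class(out) <- c("atomset", "data.frame")
  out
}

# cheap format validation so malformed coordinate lines are reported by line
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed PDB coordinate line ", i, ": record too short")
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop("malformed PDB coordinate line ", i, ": cannot parse coordinates")
    }
  }
  invisible(TRUE)
}

#' Coarse-grain an atom set into a bead chain
#'
#' Places one backbone bead at each C-alpha. In two-bead mode an additional
#' side-chain bead is placed at the centroid of the side-chain heavy atoms
#' (glycine gets no side-chain bead).
#'
#' @param atoms An `atomset` from [read_pdb()].
#' @param mode `"one_bead"` (default) or `"two_bead"`.
#' @param mass Bead mass in Da (default 110, an average residue mass).
#' @param radius Repulsive bead radius in Angstrom (default 2).
#' @param probe 1-based residue position of the distance-probe residue
#'   (default 21, the position homologous to His21 of ADR1a); clamped to the
#'   chain if shorter.
#'
#' @return A `cg_chain` object: list with elements `beads` (data frame:
#'   `resno`, `role`, `mass`, `radius`, `annot`), `xyz` (native coordinates,
#'   one row per bead), `sequence` (three-letter codes), `probe` (bead index
#'   of the probe residue's backbone bead) and `L` (linker length, 0 here).
#' @export
coarse_grain <- function(atoms, mode = c("one_bead", "two_bead"),
                         mass = 110, radius = 2, probe = 21) {
  mode <- match.arg(mode)
  stopifnot(inherits(atoms, "atomset") || is.data.frame(atoms))
  grp <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  ugrp <- unique(grp)
  beads <- list(); xyz <- list(); seqs <- character(0)
  backbone <- c("N", "CA", "C", "O", "OXT")
  ri <- 0L
  for (g in ugrp) {
    ri <- ri + 1L
    res <- atoms[grp == g, , drop = FALSE]
    ca <- res[res$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      stop("residue ", res$resid[1], res$resno[1], " lacks a CA atom")
    }
    beads[[length(beads) + 1L]] <- data.frame(
      resno = ri, role = "backbone", mass = mass, radius = radius,
      annot = "domain", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- c(ca$x[1], ca$y[1], ca$z[1])
    seqs[ri] <- res$resid[1]
    if (mode == "two_bead" && res$resid[1] != "GLY") {
      sc <- res[!(res$elety %in% backbone) & res$elesy != "H", , drop = FALSE]
      if (nrow(sc) > 0L) {
        beads[[length(beads) + 1L]] <- data.frame(
          resno = ri, role = "sidechain", mass = mass, radius = radius,
          annot = "domain", stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <- c(mean(sc$x), mean(sc$y), mean(sc$z))
      }
    }
  }
  beads <- do.call(rbind, beads)
  xyz <- do.call(rbind, xyz)
  rownames(beads) <- rownames(xyz) <- NULL
  probe_res <- min(probe, ri)
  probe_idx <- which(beads$resno == probe_res & beads$role == "backbone")[1]
  new_cg_chain(beads, xyz, seqs, probe_idx, L = 0L)
}

new_cg_chain <- function(beads, xyz, sequence, probe, L) {
  structure(list(beads = beads, xyz = xyz, sequence = sequence,
                 probe = as.integer(probe), L = as.integer(L)),
            class = "cg_chain")
}

#' @export
print.cg_chain <- function(x, ...) {
  nres <- length(unique(x$beads$resno))
  cat("Coarse-grained chain: ", nres, " residues, ", nrow(x$beads),
      " beads (", sum(x$beads$annot == "linker"), " linker beads, L = ",
      x$L, ")\n", sep = "")
  cat("Probe bead index:", x$probe,
      "| roles:", paste(unique(x$beads$role), collapse = ", "), "\n")
  invisible(x)
}

#' Append an unstructured linker to a coarse-grained domain
#'
#' Adds `L` linker beads C-terminally to the domain. Linker beads carry
#' generic bonded terms when a topology is built (3.8 A virtual bonds,
#' 110 degree angles, no torsions) and no native contacts. The last linker
#' bead is the tether point that is anchored at the P-site during tethered
#' simulations.
#'
#' @param chain A `cg_chain` (domain only).
#' @param L Number of linker residues (integer, >= 0).
#' @return A new `cg_chain` with `L` additional beads annotated `"linker"`.
#' @export
attach_linker <- function(chain, L) {
  stopifnot(inherits(chain, "cg_chain"))
  L <- as.integer(L)
  if (L < 0) stop("L must be >= 0")
  if (L == 0L) return(chain)
  if (any(chain$beads$annot == "linker")) {
    stop("chain already has a linker")
  }
  nres <- max(chain$beads$resno)
  last <- chain$xyz[nrow(chain$xyz), ]
  dir <- last - colMeans(chain$xyz)
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-6) dir <- c(0, 0, 1) else dir <- dir / nd
  lx <- t(sapply(seq_len(L), function(k) last + 3.8 * k * dir))
  lb <- data.frame(resno = nres + seq_len(L), role = "backbone",
                   mass = chain$beads$mass[1], radius = chain$beads$radius[1],
                   annot = "linker", stringsAsFactors = FALSE)
  new_cg_chain(rbind(chain$beads, lb), rbind(chain$xyz, lx),
               c(chain$sequence, rep("GLY", L)), chain$probe, L)
}

#' Build the native (Go-type) topology of a coarse-grained chain
#'
#' Bonds connect consecutive backbone beads at their native separations;
#' angles and torsions run over backbone triples/quadruples with native
#' equilibria. Native contacts are domain-domain bead pairs at least three
#' residues apart whose native distance is below `contact_cutoff`; each
#' contact gets the native distance as its Lennard-Jones minimum `sigma`
#' and a base well depth `eps` of 1 kcal/mol, scaled globally by `lambda`.
#' Linker beads get generic bonded equilibria (r0 = 3.8 A, theta0 = 110
#' degrees, no torsion) and never participate in native contacts.
#'
#' @param chain A `cg_chain` with native coordinates.
#' @param contact_cutoff Native-contact distance cutoff in Angstrom
#'   (default 8, a common C-alpha contact definition).
#' @param k_bond,k_angle Harmonic force constants (kcal/mol/A^2,
#'   kcal/mol/rad^2).
#' @param k_dih1,k_dih2 Torsion force constants (kcal/mol) of the 1- and
#'   3-fold terms.
#' @return A `cg_topology`: list of data frames `bonds` (i, j, k, r0),
#'   `angles` (i, j, k, k_theta, theta0), `dihedrals` (i, j, k, l, k1, k2,
#'   phi0), `contacts` (i, j, eps, sigma), plus `lambda` and `n`.
#' @export
build_native_topology <- function(chain, contact_cutoff = 8,
                                  k_bond = 50, k_angle = 20,
                                  k_dih1 = 0.5, k_dih2 = 0.25) {
  stopifnot(inherits(chain, "cg_chain"))
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  bb <- which(chain$beads$role == "backbone")
  if (length(bb) < 2) stop("chain must have at least 2 residues")
  xyz <- chain$xyz
  annot <- chain$beads$annot
  is_lnk <- function(i) any(annot[i] == "linker")

  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  # bonds between consecutive backbone beads
  bonds <- do.call(rbind, lapply(seq_len(length(bb) - 1), function(k) {
    i <- bb[k]; j <- bb[k + 1]
    r0 <- if (is_lnk(c(i, j))) 3.8 else dist_ij(i, j)
    c(i = i, j = j, k = k_bond, r0 = r0)
  }))
  # side-chain beads bond to their own backbone bead
  sc <- which(chain$beads$role == "sidechain")
  if (length(sc) > 0) {
    scb <- do.call(rbind, lapply(sc, function(i) {
      j <- bb[match(chain$beads$resno[i], chain$beads$resno[bb])]
      c(i = j, j = i, k = k_bond, r0 = dist_ij(i, j))
    }))
    bonds <- rbind(bonds, scb)
  }

  angles <- NULL
  if (length(bb) >= 3) {
    angles <- do.call(rbind, lapply(seq_len(length(bb) - 2), function(k) {
      i <- bb[k]; j <- bb[k + 1]; l <- bb[k + 2]
      if (is_lnk(c(i, j, l))) {
        th0 <- 110 * pi / 180
      } else {
        u <- xyz[i, ] - xyz[j, ]; v <- xyz[l, ] - xyz[j, ]
        th0 <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
      }
      c(i = i, j = j, k = l, k_theta = k_angle, theta0 = th0)
    }))
  }

  dihedrals <- NULL
  if (length(bb) >= 4) {
    rows <- lapply(seq_len(length(bb) - 3), function(k) {
      q <- bb[k:(k + 3)]
      if (is_lnk(q)) return(NULL)  # no torsion terms on the linker
      phi0 <- .dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
      c(i = q[1], j = q[2], k = q[3], l = q[4],
        k1 = k_dih1, k2 = k_dih2, phi0 = phi0)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) > 0) dihedrals <- do.call(rbind, rows)
  }

  # native contacts: domain beads only, residue separation >= 3
  dom <- which(annot == "domain")
  contacts <- NULL
  if (length(dom) > 0) {
    resno <- chain$beads$resno
    rows <- list()
    for (a in seq_along(dom)) {
      for (b in seq_along(dom)) {
        if (b <= a) next
        i <- dom[a]; j <- dom[b]
        if (abs(resno[i] - resno[j]) < 3) next
        d <- dist_ij(i, j)
        if (d < contact_cutoff) {
          rows[[length(rows) + 1L]] <- c(i = i, j = j, eps = 1, sigma = d)
        }
      }
    }
    if (length(rows) > 0) contacts <- do.call(rbind, rows)
  }

  as_df <- function(m, cols) {
    if (is.null(m)) {
      m <- matrix(numeric(0), ncol = length(cols))
    }
    m <- as.data.frame(m)
    names(m) <- cols
    m
  }
  structure(list(
    bonds = as_df(bonds, c("i", "j", "k", "r0")),
    angles = as_df(angles, c("i", "j", "k", "k_theta", "theta0")),
    dihedrals = as_df(dihedrals, c("i", "j", "k", "l", "k1", "k2", "phi0")),
    contacts = as_df(contacts, c("i", "j", "eps", "sigma")),
    lambda = 1,
    n = nrow(chain$beads)
  ), class = "cg_topology")
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  m <- c(b1[2] * b2[3] - b1[3] * b2[2],
         b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  n <- c(b2[2] * b3[3] - b2[3] * b3[2],
         b2[3] * b3[1] - b2[1] * b3[3],
         b2[1] * b3[2] - b2[2] * b3[1])
  atan2(sum(m * b3) * sqrt(sum(b2^2)), sum(m * n))
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("Go-model topology: ", nrow(x$bonds), " bonds, ", nrow(x$angles),
      " angles, ", nrow(x$dihedrals), " torsions, ", nrow(x$contacts),
      " native contacts (lambda = ", signif(x$lambda, 4), ")\n", sep = "")
  invisible(x)
}

#' Build a static ribosome scaffold from an atom set
#'
#' Places one repulsive bead per heavy atom, drops beads farther than
#' `keep_within` from the tunnel axis (a performance filter), and records
#' the P-site anchor (tether point) and tunnel exit.
#'
#' For a synthetic scaffold use [make_toy_tunnel()] instead.
#'
#' @param atoms An `atomset` (heavy atoms are used; hydrogens ignored).
#' @param anchor Numeric length-3 anchor coordinate, or a list
#'   `list(elety =, resno =, chain =)` selecting exactly one atom (e.g. the
#'   3'-terminal phosphorus of the P-site tRNA).
#' @param exit Numeric length-3 tunnel-exit coordinate.
#' @param cg_radius Repulsive bead radius in Angstrom (default 2.5).
#' @param keep_within Retain only beads within this distance (Angstrom) of
#'   the anchor-exit axis. Default `Inf` keeps everything.
#' @return A `ribosome_scaffold`: list with `xyz`, `radius`, `anchor`,
#'   `exit` and an `axis` descriptor.
#' @export
build_scaffold <- function(atoms, anchor, exit, cg_radius = 2.5,
                           keep_within = Inf) {
  stopifnot(is.data.frame(atoms))
  at <- atoms[atoms$elesy != "H", , drop = FALSE]
  if (is.list(anchor) && !is.numeric(anchor)) {
    sel <- rep(TRUE, nrow(at))
    if (!is.null(anchor$elety)) sel <- sel & at$elety == anchor$elety
    if (!is.null(anchor$resno)) sel <- sel & at$resno == anchor$resno
    if (!is.null(anchor$chain)) sel <- sel & at$chain == anchor$chain
    hit <- which(sel)
    if (length(hit) == 0L) stop("anchor selector matches no atom")
    if (length(hit) > 1L) stop("ambiguous anchor selection: ",
                               length(hit), " atoms match")
    anchor <- c(at$x[hit], at$y[hit], at$z[hit])
  }
  anchor <- as.numeric(anchor); exit <- as.numeric(exit)
  stopifnot(length(anchor) == 3, length(exit) == 3)
  xyz <- cbind(at$x, at$y, at$z)
  if (is.finite(keep_within)) {
    d <- .dist_to_axis(xyz, anchor, exit)
    xyz <- xyz[d <= keep_within, , drop = FALSE]
  }
  if (nrow(xyz) == 0L) stop("empty scaffold after filtering")
  new_scaffold(xyz, rep(cg_radius, nrow(xyz)), anchor, exit)
}

.dist_to_axis <- function(xyz, a, b) {
  u <- b - a
  u <- u / sqrt(sum(u^2))
  rel <- sweep(xyz, 2, a)
  t <- as.numeric(rel %*% u)
  proj <- outer(t, u)
  sqrt(rowSums((rel - proj)^2))
}

new_scaffold <- function(xyz, radius, anchor, exit, profile = NULL) {
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz, radius = radius,
                 anchor = anchor, exit = exit,
                 axis = list(origin = anchor,
                             direction = (exit - anchor) /
                               sqrt(sum((exit - anchor)^2)),
                             length = sqrt(sum((exit - anchor)^2))),
                 profile = profile),
            class = "ribosome_scaffold")
}

#' @export
print.ribosome_scaffold <- function(x, ...) {
  cat("Ribosome scaffold:", nrow(x$xyz), "static repulsive beads\n")
  cat("Anchor-to-exit distance:", round(x$axis$length, 2), "A\n")
  invisible(x)
}

#' Write a coarse-grained chain to a PDB file
#'
#' Backbone beads are written as CA records (side-chain beads as CB) so the
#' model can be inspected in standard viewers and re-read with [read_pdb()].
#'
#' @param chain A `cg_chain`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "cg_chain"))
  b <- chain$beads
  elety <- ifelse(b$role == "backbone", "CA", "CB")
  resid <- chain$sequence[b$resno]
  bio3d::write.pdb(file = path, xyz = as.numeric(t(chain$xyz)),
                   resno = b$resno, resid = resid, elety = elety,
                   chain = rep("A", nrow(b)))
  invisible(path)
}

#' Write the native-contact table to CSV
#'
#' @param topology A `cg_topology`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(topology, path) {
  stopifnot(inherits(topology, "cg_topology"))
  write.csv(topology$contacts, path, row.names = FALSE)
  invisible(path)
}
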