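# Potential-energy surface of the tethered coarse-grained chain.
#
# Terms: harmonic bonds and angles, 1+3-fold torsions, 12-10 Lennard-Jones
# native contacts scaled by the global well-depth factor lambda, r^-12
# repulsion between all other bead pairs and against the static scaffold,
# and a harmonic tether of the last bead to the P-site anchor. The ligand
# (e.g. Zn2+) is implicit: its only effect is through lambda.

#' Simulation parameters
#'
#' @param eps_rep Repulsive prefactor, kcal/mol (default 1).
#' @param k_tether Tether spring constant, kcal/mol/A^2 (default 10).
#' @param rep_cut_factor Repulsion cutoff as a multiple of the pair
#'   radius sum (default 2; the truncated tail is below 2.5e-4 kcal/mol).
#'   With the default 8 A contact build cutoff this also makes the native
#'   state exactly force-free: every non-contact pair sits beyond its
#'   repulsion cutoff there. Set `Inf` for exact pairwise evaluation.
#' @param contact_cutoff Native-contact interaction cutoff, A (default 12).
#' @return A `cg_params` list.
#' @export
cg_params <- function(eps_rep = 1, k_tether = 10, rep_cut_factor = 2,
                      contact_cutoff = 12) {
  structure(list(eps_rep = eps_rep, k_tether = k_tether,
                 rep_cut_factor = rep_cut_factor,
                 contact_cutoff = contact_cutoff),
            class = "cg_params")
}

#' Create a simulation-ready conformation
#'
#' Bundles bead coordinates with the chain, its topology, an optional
#' scaffold and parameters. When a scaffold is given the chain is tethered:
#' its last bead is restrained to the scaffold anchor.
#'
#' @param chain A `cg_chain`.
#' @param topology A `cg_topology` for that chain.
#' @param xyz Coordinates (defaults to the chain's native coordinates).
#' @param scaffold Optional `ribosome_scaffold`.
#' @param params A `cg_params` (defaults).
#' @param tether `TRUE` to restrain the last bead to the anchor; defaults
#'   to `TRUE` when a scaffold is present.
#' @return A `cg_conformation`.
#' @export
conformation <- function(chain, topology, xyz = chain$xyz, scaffold = NULL,
                         params = cg_params(), tether = !is.null(scaffold)) {
  stopifnot(inherits(chain, "cg_chain"), inherits(topology, "cg_topology"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(chain$beads) || ncol(xyz) != 3) {
    stop("coordinate matrix must be n_beads x 3")
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (tether && is.null(scaffold)) {
    stop("tethering requires a scaffold (for the anchor point)")
  }
  structure(list(xyz = xyz, chain = chain, topology = topology,
                 scaffold = scaffold, params = params, tether = tether),
            class = "cg_conformation")
}

.topo_cpp <- function(topology) {
  list(bonds = as.matrix(topology$bonds),
       angles = as.matrix(topology$angles),
       dihedrals = as.matrix(topology$dihedrals),
       contacts = as.matrix(topology$contacts),
       lambda = topology$lambda)
}

.scaffold_cpp <- function(scaffold) {
  if (is.null(scaffold)) return(list())
  list(xyz = unname(as.matrix(scaffold$xyz)), radius = scaffold$radius)
}

.params_cpp <- function(conf) {
  p <- conf$params
  list(eps_rep = p$eps_rep, k_tether = p$k_tether,
       rep_cut_factor = if (is.finite(p$rep_cut_factor))
         p$rep_cut_factor else 1e6,
       contact_cutoff = if (is.finite(p$contact_cutoff))
         p$contact_cutoff else 1e6,
       tether_on = isTRUE(conf$tether),
       anchor = if (is.null(conf$scaffold)) c(0, 0, 0)
                else conf$scaffold$anchor)
}

#' Potential energy of a conformation, by term
#'
#' @param conf A `cg_conformation`.
#' @return An `energy_breakdown`: named numeric vector with components
#'   `bond`, `angle`, `dihedral`, `contact` (native 12-10 term, already
#'   scaled by lambda), `repulsion` (non-native chain pairs), `scaffold`
#'   (chain-scaffold repulsion), `tether` and `total`, in kcal/mol.
#' @export
#' @examples
#' dom <- make_toy_domain()
#' topo <- build_native_topology(dom)
#' energy(conformation(dom, topo))
energy <- function(conf) {
  stopifnot(inherits(conf, "cg_conformation"))
  out <- cpp_energy(unname(conf$xyz), .topo_cpp(conf$topology),
                    .scaffold_cpp(conf$scaffold), .params_cpp(conf),
                    conf$chain$beads$mass, conf$chain$beads$radius)
  class(out) <- c("energy_breakdown", class(out))
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  y <- unclass(x)
  cat("Potential energy (kcal/mol):\n")
  print(round(y, 4))
  invisible(x)
}

#' Forces on every mobile bead
#'
#' Analytic negative gradient of [energy()]. Scaffold beads are static and
#' receive no force.
#'
#' @param conf A `cg_conformation`.
#' @return An n x 3 matrix of forces in kcal/mol/A.
#' @export
forces <- function(conf) {
  stopifnot(inherits(conf, "cg_conformation"))
  cpp_forces(unname(conf$xyz), .topo_cpp(conf$topology),
             .scaffold_cpp(conf$scaffold), .params_cpp(conf),
             conf$chain$beads$mass, conf$chain$beads$radius)
}

#' Scale the native-contact well depth
#'
#' Sets the global multiplier lambda so every native contact has effective
#' depth `lambda * eps_ij`. This is the implicit-ligand stability dial:
#' structural ions are not represented explicitly, their stabilizing effect
#' is folded into lambda.
#'
#' @param topology A `cg_topology`.
#' @param lambda Positive scale factor.
#' @return The topology with the new lambda.
#' @export
set_lambda <- function(topology, lambda) {
  stopifnot(inherits(topology, "cg_topology"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("lambda must be a single positive number")
  }
  topology$lambda <- lambda
  topology
}

#' Serialize a topology and parameters to a JSON config
#'
#' @param topology A `cg_topology`.
#' @param params A `cg_params`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, params = cg_params(), path) {
  jsonlite::write_json(
    list(bonds = topology$bonds, angles = topology$angles,
         dihedrals = topology$dihedrals, contacts = topology$contacts,
         lambda = topology$lambda, n = topology$n,
         params = unclass(params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a topology JSON config written by [write_topology_json()]
#'
#' @param path JSON path.
#' @return List with elements `topology` (`cg_topology`) and `params`
#'   (`cg_params`).
#' @export
read_topology_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- structure(list(
    bonds = as.data.frame(x$bonds), angles = as.data.frame(x$angles),
    dihedrals = as.data.frame(x$dihedrals),
    contacts = as.data.frame(x$contacts),
    lambda = x$lambda, n = x$n), class = "cg_topology")
  params <- do.call(cg_params, as.list(x$params))
  list(topology = topo, params = params)
}
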