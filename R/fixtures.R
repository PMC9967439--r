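# Synthetic fixtures: analytic promolecular systems with documented
# expected topology, used by the test-suite and as runnable examples.

.fixture_names <- c("single_atom", "homodiatomic", "heterodiatomic",
                    "methane_td", "ethane_like", "fcc_ag_periodic",
                    "two_bump_sphere_field")

#' Generate a named synthetic fixture
#'
#' Deterministic geometries with analytic promolecular densities (exact
#' value/gradient/Hessian) and a companion analytic kinetic-energy density
#' (Thomas-Fermi plus one ninth von Weizsaecker).  Each fixture documents
#' its expected topology; the test-suite verifies it.
#'
#' Available fixtures and main parameters:
#' \describe{
#'   \item{single_atom}{`element` ("C"): one atom at the origin.}
#'   \item{homodiatomic}{`element` ("H"), `distance` (1.4 bohr).}
#'   \item{heterodiatomic}{`elements` (c("C","O")), `distance` (2.132).}
#'   \item{methane_td}{`element_center` ("C"), `element_outer` ("H"),
#'     `bond` (2.06 bohr): perfect Td.}
#'   \item{ethane_like}{staggered ethane, C-C 2.903 bohr, C-H 2.062 bohr.}
#'   \item{fcc_ag_periodic}{`a` (7.72 bohr): conventional cubic FCC cell,
#'     4 Ag atoms, periodic.}
#'   \item{two_bump_sphere_field}{synthetic condensed field on an icosphere
#'     (`level`, `sigma`): two antipodal Gaussian bumps; not a 3D field.}
#' }
#'
#' @param name fixture name
#' @param ... fixture parameters (see Details)
#' @return object of class `bb_fixture`: `name`, `geometry`, `field`
#'   (density), `ked`, `expected` (list of documented facts).  The
#'   two-bump fixture instead carries a synthetic `bb_condensed`.
#' @export
generate_fixture <- function(name, ...) {
  if (!name %in% .fixture_names) {
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixture_names, collapse = ", "))
  }
  args <- list(...)
  arg <- function(key, default) {
    if (!is.null(args[[key]])) args[[key]] else default
  }
  if (name == "two_bump_sphere_field") {
    level <- arg("level", 3L)
    sigma <- arg("sigma", 0.6)
    mesh <- icosphere(level)
    axis <- c(0, 0, 1)
    cen <- mesh$vertices[mesh$faces[, 1], ] +
      mesh$vertices[mesh$faces[, 2], ] + mesh$vertices[mesh$faces[, 3], ]
    cen <- cen / sqrt(rowSums(cen^2))
    dens <- exp(-rowSums(sweep(cen, 2, axis)^2) / (2 * sigma^2)) +
      exp(-rowSums(sweep(cen, 2, -axis)^2) / (2 * sigma^2)) + 0.05
    sphere <- structure(list(atom = 1L, center = c(0, 0, 0), dr = 1,
                             mesh = mesh, paths = NULL, field = NULL,
                             cps = NULL, control = path_control()),
                        class = "bb_sphere")
    cf <- structure(list(sphere = sphere, kind = "other",
                         values = dens * mesh$areas, areas = mesh$areas,
                         density = dens, levels_per_decade = NA,
                         refinements = 0L),
                    class = "bb_condensed")
    return(structure(list(name = name, condensed = cf,
                          expected = list(n_basins = 2L, alpha = c(0.5, 0.5))),
                     class = "bb_fixture"))
  }

  geom <- switch(name,
    single_atom = {
      el <- arg("element", "C")
      mol_geometry(el, matrix(0, 1, 3))
    },
    homodiatomic = {
      el <- arg("element", "H")
      d <- arg("distance", 1.4)
      mol_geometry(c(el, el), rbind(c(0, 0, 0), c(0, 0, d)))
    },
    heterodiatomic = {
      els <- arg("elements", c("C", "O"))
      d <- arg("distance", 2.132)
      mol_geometry(els, rbind(c(0, 0, 0), c(0, 0, d)))
    },
    methane_td = {
      b <- arg("bond", 2.06)
      dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                    c(-1, -1, 1)) / sqrt(3)
      mol_geometry(c(arg("element_center", "C"),
                     rep(arg("element_outer", "H"), 4)),
                   rbind(c(0, 0, 0), dirs * b))
    },
    ethane_like = {
      dcc <- arg("cc", 2.903)
      dch <- arg("ch", 2.062)
      ct <- -1 / 3                       # cos(109.47 deg)
      st <- sqrt(1 - ct^2)
      h1 <- t(vapply(c(0, 120, 240) * pi / 180, function(phi) {
        dch * c(st * cos(phi), st * sin(phi), ct)
      }, numeric(3)))
      h2 <- t(vapply(c(60, 180, 300) * pi / 180, function(phi) {
        c(0, 0, dcc) + dch * c(st * cos(phi), st * sin(phi), -ct)
      }, numeric(3)))
      mol_geometry(c("C", "C", rep("H", 6)),
                   rbind(c(0, 0, 0), c(0, 0, dcc), h1, h2))
    },
    fcc_ag_periodic = {
      a <- arg("a", 7.72)
      pos <- rbind(c(0, 0, 0), c(a / 2, a / 2, 0), c(a / 2, 0, a / 2),
                   c(0, a / 2, a / 2))
      mol_geometry(rep("Ag", 4), pos, lattice = diag(a, 3))
    })
  field <- promolecular_field(geom, params = arg("params", NULL))
  ked <- derived_field(field, "tfvw", lambda = arg("vw_fraction", 1 / 9))
  expected <- switch(name,
    single_atom = list(n_nuclear = 1L, n_bond = 0L,
                       electrons = field$electrons),
    homodiatomic = list(n_nuclear = 2L, n_bond = 1L,
                        bcp = c(0, 0, arg("distance", 1.4) / 2)),
    heterodiatomic = list(n_nuclear = 2L, n_bond = 1L),
    methane_td = list(n_nuclear = 5L, n_bond = 4L, n_wedges_center = 4L),
    ethane_like = list(n_nuclear = 8L, n_bond = 7L, n_wedges_h = 1L),
    fcc_ag_periodic = list(n_nn = 12L, nn_dist = arg("a", 7.72) / sqrt(2),
                           # the promolecular metal forms one wedge per
                           # nearest neighbor; self-consistent Ag instead
                           # forms 6 octahedral-hole wedges
                           n_wedges_per_atom = 12L,
                           cp_counts = c(nuclear = 4L, bond = 24L,
                                         ring = 32L, cage = 12L)))
  structure(list(name = name, geometry = geom, field = field, ked = ked,
                 expected = expected),
            class = "bb_fixture")
}

#' @export
print.bb_fixture <- function(x, ...) {
  cat(sprintf("<bb_fixture> %s\n", x$name))
  invisible(x)
}

#' Standard small-molecule geometries
#'
#' Equilibrium geometries of the prototype molecules used throughout the
#' package documentation: experimental bond lengths for the hydrocarbons,
#' and the reported rectangular/square geometries for cyclobutadiene
#' (C-C 156.3 / 133.0 pm for the D2h form, 143.3 pm for D4h).
#'
#' @param name one of "acetylene", "ethylene", "benzene", "ethane",
#'   "methane", "cyclobutadiene_d4h", "cyclobutadiene_d2h"
#' @return a [mol_geometry()]
#' @export
standard_geometry <- function(name) {
  deg <- pi / 180
  switch(name,
    acetylene = {
      cc <- 1.203; ch <- 1.063
      mol_geometry(c("C", "C", "H", "H"),
                   rbind(c(0, 0, 0), c(0, 0, cc), c(0, 0, -ch),
                         c(0, 0, cc + ch)), unit = "angstrom")
    },
    ethylene = {
      cc <- 1.339; ch <- 1.087; a <- 121.3 * deg
      hx <- ch * sin(a); hz <- ch * cos(a)  # hz < 0: away from the partner
      mol_geometry(c("C", "C", "H", "H", "H", "H"),
                   rbind(c(0, 0, 0), c(0, 0, cc),
                         c(hx, 0, hz), c(-hx, 0, hz),
                         c(hx, 0, cc - hz), c(-hx, 0, cc - hz)),
                   unit = "angstrom")
    },
    benzene = {
      cc <- 1.391; ch <- 1.084
      th <- (0:5) * pi / 3
      C <- cbind(cc * cos(th), cc * sin(th), 0)
      H <- cbind((cc + ch) * cos(th), (cc + ch) * sin(th), 0)
      mol_geometry(c(rep("C", 6), rep("H", 6)), rbind(C, H),
                   unit = "angstrom")
    },
    ethane = generate_fixture("ethane_like")$geometry,
    methane = generate_fixture("methane_td")$geometry,
    cyclobutadiene_d4h = .cbd_geometry(1.433, 1.433),
    cyclobutadiene_d2h = .cbd_geometry(1.563, 1.330),
    stop("unknown geometry '", name, "'"))
}

# rectangular C4H4 in the xy plane: dx along x, dy along y; H along the
# center-to-corner diagonal
.cbd_geometry <- function(dx, dy, ch = 1.079) {
  C <- rbind(c(dx/2, dy/2, 0), c(-dx/2, dy/2, 0), c(-dx/2, -dy/2, 0),
             c(dx/2, -dy/2, 0))
  u <- C / sqrt(rowSums(C^2))
  H <- C + u * ch
  mol_geometry(c(rep("C", 4), rep("H", 4)), rbind(C, H), unit = "angstrom")
}
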