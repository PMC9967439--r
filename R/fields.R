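# Molecular geometries and evaluable 3D scalar fields.

.BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Molecular geometry
#'
#' @param symbols character vector of element symbols
#' @param positions numeric n x 3 matrix of nuclear positions
#' @param unit unit of `positions`: "bohr" (default), "angstrom" or "pm"
#' @param lattice optional 3 x 3 matrix whose rows are lattice vectors (same
#'   unit as `positions`); implies a periodic system
#' @param Z optional integer vector of nuclear charges (defaults to the
#'   element's atomic number)
#' @return an object of class `bb_geometry` with positions in bohr
#' @export
mol_geometry <- function(symbols, positions, unit = c("bohr", "angstrom", "pm"),
                         lattice = NULL, Z = NULL) {
  unit <- match.arg(unit)
  positions <- matrix(as.numeric(positions), ncol = 3)
  fac <- switch(unit, bohr = 1, angstrom = .BOHR_PER_ANGSTROM,
                pm = .BOHR_PER_ANGSTROM / 100)
  positions <- positions * fac
  if (!all(is.finite(positions))) stop("non-finite atomic positions")
  if (is.null(Z)) Z <- element_z(symbols)
  if (any(Z < 1)) stop("nuclear charges must be >= 1")
  if (length(symbols) != nrow(positions)) {
    stop("length(symbols) must equal nrow(positions)")
  }
  if (!is.null(lattice)) {
    lattice <- matrix(as.numeric(lattice), 3, 3) * fac
    if (abs(det(lattice)) < 1e-12) stop("lattice is singular")
  }
  structure(list(symbols = as.character(symbols), positions = positions,
                 Z = as.integer(Z), lattice = lattice,
                 periodic = !is.null(lattice)),
            class = "bb_geometry")
}

#' @export
print.bb_geometry <- function(x, ...) {
  cat(sprintf("<bb_geometry> %d atoms (%s)%s\n", nrow(x$positions),
              paste(unique(x$symbols), collapse = ","),
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

.new_field <- function(ptr, kind, geometry, extra = list()) {
  structure(c(list(ptr = ptr, kind = kind, geometry = geometry), extra),
            class = "bb_field")
}

#' @export
print.bb_field <- function(x, ...) {
  cat(sprintf("<bb_field> kind=%s source=%s\n", x$kind,
              if (!is.null(x$grid)) "grid" else
                if (!is.null(x$base)) "derived" else "promolecular"))
  invisible(x)
}

#' Promolecular density field
#'
#' Builds the analytic superposition of spherically symmetric atomic
#' densities (Slater-type shells) for a geometry.  Value, gradient and
#' Hessian are exact.  For periodic geometries, lattice images are summed
#' over all shells that contribute above an absolute tail tolerance.
#'
#' @param geometry a [mol_geometry()]
#' @param params element parameter list (default [element_params()] for the
#'   geometry's elements)
#' @param tail_tol absolute shell value below which lattice images are
#'   truncated
#' @return a `bb_field` of kind "density"
#' @export
promolecular_field <- function(geometry, params = NULL, tail_tol = 1e-14) {
  stopifnot(inherits(geometry, "bb_geometry"))
  if (is.null(params)) params <- element_params(unique(geometry$symbols))
  missing <- setdiff(geometry$symbols, names(params))
  if (length(missing) > 0) {
    stop("no promolecular parameters for element(s): ",
         paste(unique(missing), collapse = ", "))
  }
  shells <- lapply(geometry$symbols, function(s) {
    m <- params[[s]]
    matrix(as.numeric(m[, c("c", "p", "a")]), ncol = 3)
  })
  ptr <- .cpp_promol_field(geometry$positions, shells,
                           if (geometry$periodic) geometry$lattice else NULL,
                           tail_tol)
  nelec <- sum(vapply(geometry$symbols,
                      function(s) attr(params[[s]], "electrons"), 0))
  .new_field(ptr, "density", geometry, list(electrons = nelec))
}

#' Grid-interpolated field
#'
#' Wraps a 3D array of values on a (possibly non-orthogonal) uniform grid as
#' an evaluable field with C1 tricubic (Catmull-Rom) interpolation.  Stored
#' node values are reproduced exactly at grid nodes.  Aperiodic grids signal
#' out-of-domain evaluation via [field_in_domain()]; periodic grids wrap.
#'
#' @param values 3D numeric array (nx x ny x nz)
#' @param origin position of node (1,1,1), bohr
#' @param axes 3 x 3 matrix; rows are the voxel step vectors, bohr
#' @param geometry optional [mol_geometry()]
#' @param periodic logical
#' @param kind field kind tag ("density", "ked", "unit", "other")
#' @return a `bb_field`
#' @export
grid_field <- function(values, origin, axes, geometry = NULL,
                       periodic = FALSE, kind = "density") {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3)
  axes <- matrix(as.numeric(axes), 3, 3)
  ptr <- .cpp_grid_field(as.numeric(origin), axes, dim(values),
                         as.numeric(values), periodic)
  .new_field(ptr, kind, geometry,
             list(grid = list(values = values, origin = as.numeric(origin),
                              axes = axes, periodic = periodic)))
}

#' Pointwise-derived field
#'
#' Derives a new field from an existing one: `scale` (c f), `shift` (f + c),
#' `power` (c f^k), `tf` (Thomas-Fermi kinetic-energy density of a density
#' field), `vw` (von Weizsaecker gradient kinetic-energy density
#' \eqn{|\nabla\rho|^2 / 8\rho}) or `tfvw` (tf + lambda vw).
#'
#' @param field base `bb_field`
#' @param kind one of "scale", "shift", "power", "tf", "vw", "tfvw"
#' @param c,k,lambda numeric parameters (see kinds above)
#' @param out_kind kind tag of the derived field
#' @return a `bb_field`
#' @export
derived_field <- function(field, kind = c("scale", "shift", "power", "tf",
                                          "vw", "tfvw"),
                          c = 1, k = 1, lambda = 1,
                          out_kind = if (kind %in% c("tf", "vw", "tfvw"))
                            "ked" else field$kind) {
  kind <- match.arg(kind)
  stopifnot(inherits(field, "bb_field"))
  ptr <- .cpp_derived_field(field$ptr, kind, c, k, lambda)
  .new_field(ptr, out_kind, field$geometry, list(base = field))
}

#' Evaluate a field
#'
#' @param field a `bb_field`
#' @param points numeric n x 3 matrix (or length-3 vector), bohr
#' @return numeric vector of values
#' @export
field_value <- function(field, points) {
  points <- .as_points(points)
  .cpp_field_eval(field$ptr, points, FALSE, FALSE)$value
}

#' @rdname field_value
#' @return for [field_gradient()], an n x 3 matrix
#' @export
field_gradient <- function(field, points) {
  points <- .as_points(points)
  .cpp_field_eval(field$ptr, points, TRUE, FALSE)$gradient
}

#' @rdname field_value
#' @return for [field_hessian()], a 3 x 3 x n array
#' @export
field_hessian <- function(field, points) {
  points <- .as_points(points)
  h <- .cpp_field_eval(field$ptr, points, FALSE, TRUE)$hessian
  array(h, c(3, 3, nrow(points)))
}

#' @rdname field_value
#' @return for [field_in_domain()], a logical vector
#' @export
field_in_domain <- function(field, points) {
  points <- .as_points(points)
  .cpp_in_domain(field$ptr, points)
}

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

#' Sample a field onto a regular grid
#'
#' @param field a `bb_field`
#' @param origin grid origin (bohr)
#' @param spacing scalar voxel pitch (bohr) for an axis-aligned cubic grid
#' @param dim integer length-3 vector of node counts
#' @param periodic mark the resulting grid periodic
#' @return a grid `bb_field`
#' @export
as_grid_field <- function(field, origin, spacing, dim, periodic = FALSE) {
  dim <- as.integer(dim)
  ax <- seq_len(dim[1]) - 1L
  ay <- seq_len(dim[2]) - 1L
  az <- seq_len(dim[3]) - 1L
  pts <- cbind(origin[1] + rep(ax, times = dim[2] * dim[3]) * spacing,
               origin[2] + rep(rep(ay, each = dim[1]), times = dim[3]) * spacing,
               origin[3] + rep(az, each = dim[1] * dim[2]) * spacing)
  vals <- array(field_value(field, pts), dim)
  grid_field(vals, origin, diag(spacing, 3), geometry = field$geometry,
             periodic = periodic, kind = field$kind)
}

#' Check value/gradient/Hessian consistency by central differences
#'
#' @param field a `bb_field`
#' @param points n x 3 matrix of test points
#' @param h finite-difference step (bohr)
#' @return list with max absolute gradient and Hessian deviations
#' @export
field_consistency <- function(field, points, h = 1e-4) {
  points <- .as_points(points)
  g <- field_gradient(field, points)
  gerr <- 0
  for (d in 1:3) {
    e <- matrix(0, nrow(points), 3)
    e[, d] <- h
    fd <- (field_value(field, points + e) - field_value(field, points - e)) /
      (2 * h)
    gerr <- max(gerr, max(abs(fd - g[, d])))
  }
  H <- field_hessian(field, points)
  herr <- 0
  for (d in 1:3) {
    e <- matrix(0, nrow(points), 3)
    e[, d] <- h
    fd <- (field_gradient(field, points + e) -
             field_gradient(field, points - e)) / (2 * h)
    herr <- max(herr, max(abs(fd - t(H[d, , ]))))
  }
  list(gradient = gerr, hessian = herr)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count, comment, then `symbol x y z` records in
#' angstrom.
#'
#' @param path file path
#' @return a [mol_geometry()]
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header (line 1): expected atom count")
  if (length(lines) < n + 2) stop("truncated XYZ file: expected ", n, " atoms")
  rec <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  sym <- vapply(rec, `[`, "", 1)
  pos <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  mol_geometry(sym, pos, unit = "angstrom")
}
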