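# Reference spheres, differential gradient bundles, and condensation of 3D
# scalar fields onto the sphere (one value per mesh element).

#' Build a reference sphere with its gradient paths
#'
#' Centers an icosphere of radius `dr` on an atom's nucleus and traces, for
#' every mesh vertex, the outward (descent) gradient path from the sphere
#' surface to its terminus (truncation isovalue, cage critical point, or
#' domain boundary).  Together with the radial stub from the nucleus to the
#' surface this is the full gradient path G(theta, phi) indexed by that
#' vertex.  The sphere interior is treated analytically during condensation.
#'
#' The mesh is rotated by a fixed non-symmetric orientation by default so
#' that no vertex falls exactly on a separatrix (e.g. a bond path) of a
#' symmetric molecule.
#'
#' @param field density `bb_field`
#' @param atom atom index in the field's geometry
#' @param dr sphere radius (bohr); must be below half the nearest-neighbor
#'   distance
#' @param level icosphere subdivision level
#' @param cps `bb_cps` table (recommended: enables step clamping near CPs
#'   and capture at termini)
#' @param control [path_control()]
#' @param orient 3 x 3 rotation applied to the mesh, or "default" for the
#'   fixed jitter rotation, or "none"
#' @return object of class `bb_sphere`
#' @export
build_reference_sphere <- function(field, atom, dr = 0.2, level = 4L,
                                   cps = NULL, control = path_control(),
                                   orient = "default") {
  geom <- field$geometry
  stopifnot(!is.null(geom), atom >= 1, atom <= nrow(geom$positions))
  center <- geom$positions[atom, ]
  if (nrow(geom$positions) > 1) {
    if (isTRUE(geom$periodic)) {
      others <- seq_len(nrow(geom$positions))
      dd <- vapply(others, function(j) {
        d <- .min_image_dist(geom$positions[j, ] - center, geom$lattice)
        if (j == atom) {
          # own periodic images
          l <- sqrt(rowSums(geom$lattice^2))
          min(l)
        } else d
      }, 0)
      nn <- min(dd)
    } else {
      d <- sqrt(rowSums(sweep(geom$positions[-atom, , drop = FALSE], 2,
                              center)^2))
      nn <- min(d)
    }
    if (dr >= nn / 2) {
      stop("dr = ", dr, " is not below half the nearest-neighbor distance (",
           signif(nn, 4), ")")
    }
  }
  mesh <- icosphere(level)
  R <- if (is.matrix(orient)) orient
  else if (identical(orient, "none")) diag(3)
  else .rotation_matrix(c(0.2357022, 0.5892557, 0.7726342), 0.4321)
  mesh$vertices <- mesh$vertices %*% t(R)
  cpm <- .cp_matrix(cps, geom)
  seeds <- sweep(mesh$vertices * dr, 2, center, "+")
  paths <- .cpp_trace_batch(field$ptr, seeds, -1L, control, cpm$pos, cpm$sig)
  bad <- which(vapply(paths, function(p) p$status == "maxsteps", TRUE))
  for (b in bad) {
    ok <- FALSE
    for (try in 1:3) {
      u <- mesh$vertices[b, ] + stats::rnorm(3, sd = 2e-3 * try)
      u <- u / sqrt(sum(u^2))
      p <- .cpp_trace_path(field$ptr, center + dr * u, -1L, control,
                           cpm$pos, cpm$sig)
      if (p$status != "maxsteps") {
        paths[[b]] <- p
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("gradient path from sphere vertex ", b, " of atom ", atom,
           " did not terminate (after perturbed retries)")
    }
  }
  # directions from the nucleus to the bond CPs of this atom's bond paths;
  # the pierced mesh elements contain separatrices of the descent flow and
  # get a dedicated quadrature during condensation
  bond_dirs <- matrix(0, 0, 3)
  if (!is.null(cps) && any(cps$class == "bond")) {
    for (bcp in suppressWarnings(.bond_cp_atoms(field, cps, control))) {
      if (!atom %in% bcp$atoms) next
      d <- bcp$pos - center
      if (isTRUE(geom$periodic)) d <- .min_image_vec(d, geom$lattice)
      bond_dirs <- rbind(bond_dirs, d / sqrt(sum(d^2)))
    }
  }
  structure(list(atom = atom, center = center, dr = dr, mesh = mesh,
                 paths = paths, field = field, cps = cps,
                 control = control, bond_dirs = bond_dirs),
            class = "bb_sphere")
}

#' @export
print.bb_sphere <- function(x, ...) {
  cat(sprintf(
    "<bb_sphere> atom %d, dr=%.3g bohr, level %d (%d vertices, %d elements)\n",
    x$atom, x$dr, x$mesh$level, nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  invisible(x)
}

#' Full gradient path through a sphere vertex
#'
#' Concatenates the radial stub from the nucleus with the traced outward
#' path, giving the arc-length parameterized G from nucleus to terminus.
#'
#' @param sphere a `bb_sphere`
#' @param vertex vertex index
#' @param n_stub number of stub sample points inside the sphere
#' @return a `bb_path`-like list (points, rho, s, status)
#' @export
full_gradient_path <- function(sphere, vertex, n_stub = 8L) {
  p <- sphere$paths[[vertex]]
  u <- sphere$mesh$vertices[vertex, ]
  r <- seq(0, sphere$dr, length.out = n_stub + 1L)[-(n_stub + 1L)]
  stub <- sweep(outer(r, u), 2, sphere$center, "+")
  rho <- field_value(sphere$field, stub)
  pts <- rbind(stub, p$points)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  list(points = pts, rho = c(rho, p$rho), s = c(0, cumsum(d)),
       status = p$status, cp_index = p$cp_index)
}

# caps of mesh elements around each bond-path direction: all elements
# within a fixed angular radius of the direction (level-independent, so
# refinement levels treat the same region), with the perimeter vertices
# (those also belonging to non-cap elements) that bound the cap's
# revolution quadrature.  Caps apply only where the separatrix opens onto
# the truncation surface (molecular fans); caged crystal fans ending at
# ring/cage critical points keep the standard element quadrature.
.separatrix_caps <- function(sphere, cap_angle = 0.15) {
  bd <- sphere$bond_dirs
  if (is.null(bd) || nrow(bd) == 0) return(list())
  mesh <- sphere$mesh
  faces <- mesh$faces
  cen <- mesh$vertices[faces[, 1], , drop = FALSE] +
    mesh$vertices[faces[, 2], , drop = FALSE] +
    mesh$vertices[faces[, 3], , drop = FALSE]
  cen <- cen / sqrt(rowSums(cen^2))
  cpm <- .cp_matrix(sphere$cps, sphere$field$geometry)
  caps <- list()
  taken <- logical(nrow(faces))
  for (i in seq_len(nrow(bd))) {
    u <- as.numeric(bd[i, ])
    sep <- .cpp_trace_path(sphere$field$ptr, sphere$center + sphere$dr * u,
                           -1L, sphere$control, cpm$pos, cpm$sig)
    if (!sep$status %in% c("truncated", "boundary")) next
    f0 <- .pierced_face(mesh, u)
    cf <- unique(c(f0, which(acos(pmin(1, cen %*% u)) < cap_angle)))
    cf <- cf[!taken[cf]]
    if (length(cf) == 0) next
    taken[cf] <- TRUE
    capv <- unique(as.integer(faces[cf, ]))
    outv <- unique(as.integer(faces[-cf, ]))
    perim <- intersect(capv, outv)
    if (length(perim) < 3) next
    caps[[length(caps) + 1L]] <- list(dir = u,
                                      faces = as.integer(cf),
                                      perim = as.integer(perim),
                                      areas = mesh$areas[cf])
  }
  caps
}

# composite-Simpson radial quadrature of f(center + r u) r^2 on [0, dr]
.inner_ball_integrals <- function(field, center, dirs, dr, n = 41L) {
  if (n %% 2 == 0) n <- n + 1L
  r <- seq(0, dr, length.out = n)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w <- w * (dr / (n - 1)) / 3
  nd <- nrow(dirs)
  pts <- matrix(0, nd * n, 3)
  for (k in seq_len(n)) {
    pts[((k - 1) * nd + 1):(k * nd), ] <- sweep(dirs * r[k], 2, center, "+")
  }
  v <- field_value(field, pts)
  vm <- matrix(v, nd, n)
  as.numeric(vm %*% (w * r^2))
}

#' Condense a 3D scalar field onto a reference sphere
#'
#' Evaluates, for every mesh element, the integral of `f` over the
#' differential gradient bundle generated by that element: the three vertex
#' paths are re-parameterized at common rho levels, the triangle of
#' same-level path points approximates the bundle cross-section, and the
#' integral accumulates (mean f) x (cross-section area) x (step length).
#' The sphere interior (r < dr) is added per element as the radial cone
#' integral.  The level density is refined (doubled) until the total change
#' is below `tol` or `max_refine` doublings are reached.
#'
#' For `f = NULL` the unit field is condensed, giving bundle volumes
#' (`kind = "V"`).  `f` equal to the sphere's own density gives the
#' condensed charge density P; a kinetic-energy density gives T.
#'
#' @param sphere a `bb_sphere`
#' @param f a `bb_field`, or NULL for the unit field
#' @param kind value tag: "P", "T", "E", "V" or "other" (defaults from the
#'   field kind)
#' @param levels_per_decade rho-level station density
#' @param tol relative parent/child acceptance tolerance of the adaptive
#'   subdivision
#' @param max_depth maximum face-subdivision depth
#' @param fan_threshold station-spread ratio beyond which a face is treated
#'   as fanning onto an interatomic surface and subdivided
#' @return object of class `bb_condensed`: per-element `values`, spherical
#'   `areas`, per-steradian `density`, and refinement diagnostics
#' @export
condense_field <- function(sphere, f = NULL, kind = NULL,
                           levels_per_decade = 48, tol = 1e-3,
                           max_depth = 4L, fan_threshold = 3) {
  stopifnot(inherits(sphere, "bb_sphere"))
  unit <- is.null(f)
  if (is.null(kind)) {
    kind <- if (unit) "V"
    else if (identical(f$kind, "density")) "P"
    else if (identical(f$kind, "ked")) "T"
    else "other"
  }
  paths <- sphere$paths
  rho0 <- vapply(paths, function(p) p$rho[1], 0)
  top <- max(rho0)
  # levels end at the truncation isovalue; paths ending above it (e.g. at
  # cage critical points) are clamped during re-parameterization, and the
  # sliver between the isovalue and a path's final sub-isovalue point is
  # negligible by construction
  bottom <- sphere$control$trunc
  if (!unit) {
    v0 <- field_value(f, sweep(sphere$mesh$vertices * sphere$dr, 2,
                               sphere$center, "+"))
    if (!all(is.finite(v0))) {
      stop("field is not finite on the reference sphere of atom ",
           sphere$atom)
    }
  }
  nlev <- max(16L, ceiling(log10(top / bottom) * levels_per_decade))
  levels <- exp(seq(log(top), log(bottom), length.out = nlev))
  cpm <- .cp_matrix(sphere$cps, sphere$field$geometry)
  caps <- .separatrix_caps(sphere)
  res <- .cpp_condense_adaptive(
    sphere$field$ptr, if (unit) NULL else f$ptr, unit,
    sphere$mesh$vertices, sphere$mesh$faces, paths, sphere$center,
    sphere$dr, levels, sphere$control, cpm$pos, cpm$sig,
    tol, 1e-9, as.integer(max_depth), fan_threshold, caps)
  vals <- res$values
  if (!all(is.finite(vals))) {
    stop("non-finite condensed element value on atom ", sphere$atom)
  }
  # analytic interior: per-element cone of the inner ball
  fc <- sphere$mesh$vertices[sphere$mesh$faces[, 1], ] +
    sphere$mesh$vertices[sphere$mesh$faces[, 2], ] +
    sphere$mesh$vertices[sphere$mesh$faces[, 3], ]
  fc <- fc / sqrt(rowSums(fc^2))
  if (unit) {
    inner <- sphere$mesh$areas * sphere$dr^3 / 3
  } else {
    inner <- sphere$mesh$areas *
      .inner_ball_integrals(f, sphere$center, fc, sphere$dr)
  }
  values <- vals + inner
  structure(list(sphere = sphere, kind = kind, values = values,
                 areas = sphere$mesh$areas,
                 density = values / sphere$mesh$areas,
                 levels_per_decade = levels_per_decade,
                 n_traced = res$n_traced, n_vertices = res$n_vertices),
            class = "bb_condensed")
}

#' @export
print.bb_condensed <- function(x, ...) {
  cat(sprintf("<bb_condensed> %s on atom %d: total %.6g over %d elements\n",
              x$kind, x$sphere$atom, sum(x$values), length(x$values)))
  invisible(x)
}

#' Steepest-ascent links of a condensed field
#'
#' Links every mesh element to its steepest-ascent neighbor (by per-area
#' condensed density), marking local maxima.  Plateau elements (all
#' neighbors equal) are linked to the lowest-index equal neighbor and
#' flagged.
#'
#' @param cf a `bb_condensed`
#' @param mode "maxima" (ascent) or "minima" (descent)
#' @param smooth passes of area-weighted neighbor averaging applied to the
#'   density before the links are computed (0 = none); useful for nearly
#'   flat condensed fields (metals) where per-element quadrature noise is
#'   comparable to the real structure
#' @return list: `link` (0 = extremum), `extrema` indices, `plateau` flags
#' @export
condensed_gradient_paths <- function(cf, mode = c("maxima", "minima"),
                                     smooth = 0L) {
  mode <- match.arg(mode)
  d <- .smooth_density(cf, smooth)
  if (mode == "minima") d <- -d
  adj <- cf$sphere$mesh$adjacency
  nf <- length(d)
  link <- integer(nf)
  plateau <- logical(nf)
  for (i in seq_len(nf)) {
    nb <- adj[i, ]
    nb <- nb[!is.na(nb)]
    dm <- max(d[nb])
    best <- min(nb[d[nb] == dm])  # deterministic tie-break: lowest index
    if (dm > d[i]) {
      link[i] <- best
    } else if (dm == d[i] && best < i) {
      link[i] <- best
      plateau[i] <- TRUE
    } else {
      link[i] <- 0L
    }
  }
  list(link = link, extrema = which(link == 0L), plateau = plateau,
       mode = mode, density = d)
}

.smooth_density <- function(cf, smooth) {
  d <- cf$density
  if (smooth <= 0) return(d)
  adj <- cf$sphere$mesh$adjacency
  w <- cf$areas
  for (it in seq_len(smooth)) {
    acc <- d * w
    ws <- w
    for (j in seq_len(ncol(adj))) {
      nb <- adj[, j]
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + d[nb[ok]] * w[nb[ok]]
      ws[ok] <- ws[ok] + w[nb[ok]]
    }
    d <- acc / ws
  }
  d
}
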