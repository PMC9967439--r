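# Critical points of the density, gradient paths, Bader basin assignment.

#' Path-tracing control parameters
#'
#' @param h0 initial step (bohr)
#' @param hmax maximum step (bohr)
#' @param hmin minimum step before a stall is declared (bohr)
#' @param gtol gradient-norm stationarity tolerance (a.u.)
#' @param trunc truncation isovalue at which descent paths stop (density
#'   units); the default is far below the usual 1e-3 display isosurface so
#'   that condensed populations conserve electron counts
#' @param capture capture radius around terminal critical points (bohr)
#' @param nudge separatrix continuation displacement at a saddle (bohr)
#' @param max_steps step budget per path
#' @return a list of control parameters
#' @export
path_control <- function(h0 = 0.02, hmax = 0.2, hmin = 1e-6, gtol = 1e-8,
                         trunc = 1e-6, capture = 1e-4, nudge = 5e-3,
                         max_steps = 40000L) {
  stopifnot(h0 > 0, hmax > 0, hmin > 0, gtol > 0, trunc > 0, capture > 0,
            nudge > 0, max_steps > 0)
  list(h0 = h0, hmax = hmax, hmin = hmin, gtol = gtol, trunc = trunc,
       capture = capture, nudge = nudge, max_steps = as.integer(max_steps))
}

.cp_class_name <- function(sig) {
  c(`-3` = "nuclear", `-1` = "bond", `1` = "ring", `3` = "cage",
    `0` = "degenerate")[as.character(sig)]
}

.empty_cps <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             rho = numeric(0), signature = integer(0), class = character(0),
             atom = integer(0), stringsAsFactors = FALSE)
}

# minimum-image replication of CP positions for periodic clamping
.cp_matrix <- function(cps, geometry = NULL) {
  if (is.null(cps) || nrow(cps) == 0) {
    return(list(pos = matrix(0, 0, 3), sig = integer(0)))
  }
  pos <- as.matrix(cps[, c("x", "y", "z")])
  sig <- as.integer(cps$signature)
  if (!is.null(geometry) && isTRUE(geometry$periodic)) {
    sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% geometry$lattice
    pos <- do.call(rbind, lapply(seq_len(nrow(sh)), function(i) {
      sweep(pos, 2, -sh[i, ])
    }))
    sig <- rep(sig, nrow(sh))
  }
  list(pos = pos, sig = sig)
}

#' Locate and classify critical points of a density field
#'
#' Candidate seeds (nuclei, inter-nuclear midpoints, triple centroids, and
#' optionally jittered random points) are refined by Newton iteration on the
#' gradient; converged points are deduplicated and classified by the signs of
#' the Hessian eigenvalues: nuclear (3,-3), bond (3,-1), ring (3,+1), cage
#' (3,+3).  Near-singular Hessians are flagged "degenerate".
#'
#' @param field a density `bb_field` with an associated geometry
#' @param extra_seeds optional n x 3 matrix of additional seed points
#' @param n_random number of random seeds scattered around the atoms
#' @param seed RNG seed for the random scatter
#' @param gtol convergence tolerance on the gradient norm (a.u.)
#' @param merge_tol coalescing radius for duplicate critical points (bohr)
#' @param max_iter Newton iteration budget per seed
#' @param nucleus_radius capture radius for associating a maximum to a
#'   nucleus (bohr)
#' @param rho_min density floor below which stationary points are ignored
#'   (suppresses far-field noise where the gradient is numerically zero)
#' @param n_grid per-axis count of uniform fractional-cell seeds (periodic
#'   systems; interstitial ring/cage CPs are unreachable from atom-pair
#'   seeds alone)
#'
#' @details Nuclear maxima are cusps of the density (the gradient does not
#' vanish there), so every nucleus is recorded directly as a (3,-3)
#' nuclear CP; Newton refinement is used for the smooth bond/ring/cage
#' points and for non-nuclear maxima.
#'
#' @return data.frame of class `bb_cps`: position, rho, Hessian signature,
#'   class and (for nuclear CPs) atom index
#' @export
find_critical_points <- function(field, extra_seeds = NULL, n_random = 200L,
                                 seed = 1L, gtol = 1e-8, merge_tol = 1e-3,
                                 max_iter = 80L, nucleus_radius = 0.1,
                                 rho_min = 1e-4,
                                 n_grid = if (isTRUE(field$geometry$periodic))
                                   8L else 0L) {
  geom <- field$geometry
  if (is.null(geom)) stop("field has no geometry; cannot seed the CP search")
  pos <- geom$positions
  n <- nrow(pos)
  seeds <- pos
  if (n > 1) {
    pr <- utils::combn(n, 2)
    mids <- (pos[pr[1, ], , drop = FALSE] + pos[pr[2, ], , drop = FALSE]) / 2
    keep <- sqrt(rowSums((pos[pr[1, ], , drop = FALSE] -
                            pos[pr[2, ], , drop = FALSE])^2)) < 8
    seeds <- rbind(seeds, mids[keep, , drop = FALSE])
  }
  if (n > 2) {
    tr <- utils::combn(n, 3)
    cent <- (pos[tr[1, ], , drop = FALSE] + pos[tr[2, ], , drop = FALSE] +
               pos[tr[3, ], , drop = FALSE]) / 3
    seeds <- rbind(seeds, cent)
    if (n > 3) seeds <- rbind(seeds, matrix(colMeans(pos), 1))
  }
  if (n_random > 0) {
    set.seed(seed)
    base <- pos[sample.int(n, n_random, replace = TRUE), , drop = FALSE]
    seeds <- rbind(seeds, base + matrix(stats::rnorm(3 * n_random, sd = 1.2),
                                        ncol = 3))
  }
  if (n_grid > 0 && isTRUE(geom$periodic)) {
    fr <- (seq_len(n_grid) - 0.5) / n_grid
    gg <- as.matrix(expand.grid(fr, fr, fr)) %*% geom$lattice
    seeds <- rbind(seeds, gg)
  }
  if (!is.null(extra_seeds)) seeds <- rbind(seeds, .as_points(extra_seeds))

  found <- list()
  warn_nonconv <- 0L
  for (i in seq_len(nrow(seeds))) {
    x <- seeds[i, ]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      g <- drop(field_gradient(field, x))
      if (!all(is.finite(g))) break
      if (sqrt(sum(g^2)) < gtol) { ok <- TRUE; break }
      H <- field_hessian(field, x)[, , 1]
      step <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(step)) break
      sl <- sqrt(sum(step^2))
      if (sl > 0.5) step <- step * 0.5 / sl
      x <- x + step
      if (!all(is.finite(x)) || sl < 1e-14) {
        if (sl < 1e-14) ok <- sqrt(sum(g^2)) < sqrt(gtol)
        break
      }
    }
    if (!ok) { warn_nonconv <- warn_nonconv + 1L; next }
    found[[length(found) + 1L]] <- x
  }
  nuc_rows <- data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    rho = field_value(field, pos), signature = -3L,
    class = "nuclear", atom = seq_len(n), stringsAsFactors = FALSE)
  if (length(found) == 0) {
    out <- nuc_rows[order(-nuc_rows$rho), ]
    rownames(out) <- NULL
    return(structure(out, class = c("bb_cps", "data.frame")))
  }
  pts <- do.call(rbind, found)
  if (isTRUE(geom$periodic)) {
    # map into the home cell before deduplication
    frac <- pts %*% solve(geom$lattice)
    frac <- round(frac - floor(frac + 1e-7), 7) %% 1
    pts <- frac %*% geom$lattice
  }
  # deduplicate within merge_tol (minimum-image metric when periodic)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      later <- (i + 1):nrow(pts)
      dd <- pts[later, , drop = FALSE] -
        matrix(pts[i, ], length(later), 3, byrow = TRUE)
      if (isTRUE(geom$periodic)) {
        fr <- dd %*% solve(geom$lattice)
        dd <- (fr - round(fr)) %*% geom$lattice
      }
      keep[later[sqrt(rowSums(dd^2)) < merge_tol]] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  # drop refined points that are really the nuclear cusps, and far-field
  # noise below the density floor
  rho <- field_value(field, pts)
  near_nuc <- vapply(seq_len(nrow(pts)), function(i) {
    pp <- pts[i, ]
    if (isTRUE(geom$periodic)) {
      min(apply(pos, 1, function(q) .min_image_dist(pp - q, geom$lattice)))
    } else {
      min(sqrt(rowSums(sweep(pos, 2, pp)^2)))
    }
  }, 0) < nucleus_radius
  keep2 <- !near_nuc & rho >= rho_min
  pts <- pts[keep2, , drop = FALSE]
  rho <- rho[keep2]
  if (nrow(pts) > 0) {
    H <- field_hessian(field, pts)
    sig <- integer(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      ev <- .cpp_eig3(as.numeric(H[, , i]))$values
      if (min(abs(ev)) < 1e-6 * max(abs(ev))) {
        sig[i] <- 0L  # degenerate
      } else {
        sig[i] <- sum(sign(ev))
      }
    }
    cls <- .cp_class_name(sig)
    cls[sig == -3L] <- "nonnuclear_max"  # smooth maxima away from nuclei
    out <- rbind(nuc_rows,
                 data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                            rho = rho, signature = sig, class = cls,
                            atom = NA_integer_, stringsAsFactors = FALSE))
  } else {
    out <- nuc_rows
  }
  out <- out[order(-out$rho), ]
  rownames(out) <- NULL
  structure(out, class = c("bb_cps", "data.frame"),
            n_nonconverged = warn_nonconv)
}

.min_image_dist <- function(d, lattice) {
  frac <- d %*% solve(lattice)
  frac <- frac - round(frac)
  sqrt(sum((frac %*% lattice)^2))
}

#' Poincare-Hopf index sum of a critical-point set
#'
#' For an isolated molecule the alternating count
#' nuclear - bond + ring - cage must equal 1.
#'
#' @param cps a `bb_cps` data.frame
#' @return integer index sum
#' @export
poincare_hopf <- function(cps) {
  s <- table(factor(cps$class, levels = c("nuclear", "nonnuclear_max",
                                          "bond", "ring", "cage")))
  as.integer(s["nuclear"] + s["nonnuclear_max"] - s["bond"] + s["ring"] -
               s["cage"])
}

#' Trace a gradient path
#'
#' Integrates dr/ds = +/- grad(rho)/|grad(rho)| with adaptive Runge-Kutta
#' steps, a per-step monotonicity guard on rho, step clamping near critical
#' points, and separatrix continuation at saddles.  Termination: capture at
#' a terminal critical point, the truncation isovalue (descent), the domain
#' boundary of an aperiodic grid, or the step budget.
#'
#' @param field a density `bb_field`
#' @param seed length-3 starting point (bohr); must not itself be a CP
#' @param direction "ascent" (toward maxima) or "descent"
#' @param cps optional `bb_cps` table used for capture and step clamping
#' @param control a [path_control()] list
#' @return object of class `bb_path`: points, rho, arc length `s`, `status`
#'   ("cp", "truncated", "boundary", "maxsteps", "stalled") and `cp_index`
#' @export
trace_gradient_path <- function(field, seed, direction = c("ascent",
                                                           "descent"),
                                cps = NULL, control = path_control()) {
  direction <- match.arg(direction)
  cpm <- .cp_matrix(cps, field$geometry)
  g0 <- drop(field_gradient(field, seed))
  if (sqrt(sum(g0^2)) < control$gtol) {
    stop("seed point is itself a critical point")
  }
  r <- .cpp_trace_path(field$ptr, as.numeric(seed),
                       if (direction == "ascent") 1L else -1L,
                       control, cpm$pos, cpm$sig)
  if (r$status == "maxsteps") {
    stop("non-terminating gradient path: budget of ", control$max_steps,
         " steps exhausted at rho = ", signif(r$rho[length(r$rho)], 4),
         "; last point (", paste(signif(r$points[nrow(r$points), ], 4),
                                 collapse = ", "), ")")
  }
  structure(r, class = "bb_path", direction = direction)
}

#' Assign points to Bader atomic basins
#'
#' Traces an ascent path from each point; the terminal nuclear maximum's
#' atom index is the basin label.  Points whose ascent ends at a non-nuclear
#' attractor get `NA` and a "non-nuclear attractor" warning.
#'
#' @param field a density `bb_field` with geometry
#' @param points n x 3 matrix
#' @param cps optional `bb_cps` (defaults to the nuclei of the geometry)
#' @param control a [path_control()]; the capture radius is widened to the
#'   nucleus scale
#' @return integer vector of atom indices (NA = unassigned)
#' @export
assign_bader_basin <- function(field, points, cps = NULL,
                               control = path_control(capture = 5e-3)) {
  geom <- field$geometry
  points <- .as_points(points)
  if (!is.null(cps)) {
    nucs <- cps[cps$class == "nuclear" & !is.na(cps$atom), , drop = FALSE]
    nucpos <- as.matrix(nucs[, c("x", "y", "z")])
    map <- nucs$atom
  } else {
    nucpos <- geom$positions
    map <- seq_len(nrow(nucpos))
  }
  if (isTRUE(geom$periodic)) {
    sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% geom$lattice
    nucpos <- do.call(rbind, lapply(seq_len(nrow(sh)), function(i) {
      sweep(nucpos, 2, -sh[i, ])
    }))
    map <- rep(map, nrow(sh))
  }
  idx <- .cpp_ascend_to_nucleus(field$ptr, points, control, nucpos)
  out <- ifelse(is.na(idx), NA_integer_, map[idx])
  if (anyNA(out)) {
    warning(sum(is.na(out)), " point(s) ended at a non-nuclear attractor ",
            "or left the domain; labeled NA")
  }
  out
}

#' Voxel steepest-ascent basin labels (grid oracle)
#'
#' A grid-native Bader assignment: every voxel points to its steepest uphill
#' neighbor (26-neighborhood); labels propagate downhill from local maxima.
#' Maxima within `nucleus_radius` of a nucleus take that atom's label;
#' other maxima become non-nuclear attractor labels (negative integers).
#'
#' @param values 3D density array
#' @param origin,spacing grid geometry (axis-aligned, bohr)
#' @param nuclei n x 3 nuclear positions
#' @param periodic wrap at the box edges
#' @param nucleus_radius matching radius for nuclear maxima (bohr)
#' @return list: `labels` (3D integer array), `populations` (per atom,
#'   density sum times voxel volume), `volumes` (bohr^3)
#' @export
voxel_basin_labels <- function(values, origin, spacing, nuclei,
                               periodic = FALSE, nucleus_radius = 0.35) {
  values <- as.array(values)
  dims <- dim(values)
  uphill <- .cpp_voxel_uphill(as.numeric(values), dims, periodic)
  ord <- order(as.numeric(values), decreasing = TRUE)
  lab <- integer(length(values))
  nuclei <- .as_points(nuclei)
  nextneg <- 0L
  for (fi in ord) {
    b <- uphill[fi]
    if (b == 0L) {
      i3 <- arrayInd(fi, dims)
      p <- origin + (i3 - 1) * spacing
      d <- sqrt(rowSums(sweep(nuclei, 2, p)^2))
      if (min(d) < nucleus_radius) {
        lab[fi] <- which.min(d)
      } else {
        nextneg <- nextneg - 1L
        lab[fi] <- nextneg
      }
    } else {
      lab[fi] <- lab[b]
    }
  }
  vol <- spacing^3
  natom <- nrow(nuclei)
  pops <- vapply(seq_len(natom), function(a) {
    sum(values[lab == a]) * vol
  }, 0)
  vols <- vapply(seq_len(natom), function(a) sum(lab == a) * vol, 0)
  list(labels = array(lab, dims), populations = pops, volumes = vols,
       n_attractors = -nextneg)
}

#' Export a critical-point table
#' @param cps a `bb_cps`
#' @param path output path; ".json" writes JSON, anything else CSV
#' @return `path`, invisibly
#' @export
write_cps <- function(cps, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(cps), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(cps), path, row.names = FALSE)
  }
  invisible(path)
}
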