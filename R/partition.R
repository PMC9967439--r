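# Watershed segmentation of condensed fields into basins (bond wedges,
# energy basins), solid angles, and bond-bundle assembly.

#' Segment a condensed field into basins
#'
#' Discrete watershed: every mesh element follows its steepest-ascent link
#' (see [condensed_gradient_paths()]) to a local extremum; elements sharing
#' an extremum form a basin.  Shallow basins are merged into the neighbor
#' across their highest connecting saddle (mesh-noise suppression): in
#' "maxima" mode a basin is shallow when its peak rises less than
#' `prominence` (relative) above that saddle -- a scale-free criterion,
#' since condensed densities carry integrable singularities along
#' bond-path directions that make any fixed fraction of the field range
#' meaningless -- and in "minima" mode when the depth below the saddle is
#' less than `prominence` times the field range.
#'
#' @param cf a `bb_condensed`
#' @param mode segment around "maxima" (bond wedges for P) or "minima"
#' @param prominence relative prominence threshold for basin merging
#' @param min_elements basins with fewer mesh elements than this merge into
#'   the neighbor across their highest saddle; condensed densities have
#'   integrable singularities along bond-path directions where per-element
#'   quadrature noise is far above any fixed prominence fraction, and such
#'   noise basins are always a handful of elements
#' @param smooth smoothing passes for the watershed ordering (see
#'   [condensed_gradient_paths()]); basin populations and areas always sum
#'   the raw element values
#' @return object of class `bb_basins`: per-element `labels` (1..k),
#'   `n`, per-basin element lists, solid angles `alpha`, summed `values`,
#'   and a `degenerate` flag for an all-plateau field
#' @export
segment_condensed_basins <- function(cf, mode = c("maxima", "minima"),
                                     prominence = 0.25, min_elements = 8L,
                                     smooth = 0L) {
  mode <- match.arg(mode)
  gp <- condensed_gradient_paths(cf, mode, smooth = smooth)
  d <- if (mode == "maxima") gp$density else -gp$density
  nf <- length(d)
  degenerate <- length(unique(d)) == 1L
  if (degenerate) {
    return(structure(list(labels = rep(1L, nf), n = 1L,
                          elements = list(`1` = seq_len(nf)),
                          alpha = 1, values = sum(cf$values), kind = cf$kind,
                          mode = mode, cf = cf, degenerate = TRUE),
                     class = "bb_basins"))
  }
  # resolve links to roots
  labels <- integer(nf)
  roots <- gp$extrema
  root_id <- integer(nf)
  root_id[roots] <- seq_along(roots)
  ord <- order(d, decreasing = TRUE)
  for (i in ord) {
    if (gp$link[i] == 0L) {
      labels[i] <- root_id[i]
    } else {
      labels[i] <- labels[gp$link[i]]
    }
  }
  # prominence merging
  rng <- diff(range(d))
  if (rng > 0 && length(roots) > 1) {
    repeat {
      k <- max(labels)
      peak <- vapply(seq_len(k), function(b) max(d[labels == b]), 0)
      adj <- cf$sphere$mesh$adjacency
      # saddle height between basin pairs: highest min(d_i, d_j) over
      # boundary edges
      ii <- rep(seq_len(nf), ncol(adj))
      jj <- as.integer(adj)
      ok <- !is.na(jj) & labels[ii] != labels[jj]
      if (!any(ok)) break
      ii <- ii[ok]; jj <- jj[ok]
      smin <- pmin(d[ii], d[jj])
      key <- paste(pmin(labels[ii], labels[jj]),
                   pmax(labels[ii], labels[jj]))
      sad <- tapply(smin, key, max)
      # basin prominence = peak - highest saddle to any neighbor
      bsad <- rep(-Inf, k)
      pairs <- strsplit(names(sad), " ")
      nb_of <- vector("list", k)
      for (p in seq_along(pairs)) {
        a <- as.integer(pairs[[p]][1]); b <- as.integer(pairs[[p]][2])
        if (sad[p] > bsad[a]) { bsad[a] <- sad[p] }
        if (sad[p] > bsad[b]) { bsad[b] <- sad[p] }
        nb_of[[a]] <- rbind(nb_of[[a]], c(b, sad[p]))
        nb_of[[b]] <- rbind(nb_of[[b]], c(a, sad[p]))
      }
      prom <- peak - bsad
      size <- tabulate(labels, nbins = k)
      shallow <- if (mode == "maxima") {
        prom < prominence * pmax(bsad, 1e-300)
      } else {
        prom < prominence * rng
      }
      cand <- which(is.finite(prom) & (shallow | size < min_elements))
      if (length(cand) == 0) break
      # merge the smallest offender first
      b <- cand[order(size[cand], prom[cand])][1]
      nbs <- nb_of[[b]]
      target <- nbs[which.max(nbs[, 2]), 1]
      labels[labels == b] <- target
      # compact labels
      labels <- match(labels, sort(unique(labels)))
      if (max(labels) == 1L) break
    }
  }
  k <- max(labels)
  elements <- split(seq_len(nf), labels)
  alpha <- vapply(elements, function(e) sum(cf$areas[e]), 0) / (4 * pi)
  vals <- vapply(elements, function(e) sum(cf$values[e]), 0)
  structure(list(labels = labels, n = k, elements = elements,
                 alpha = as.numeric(alpha), values = as.numeric(vals),
                 kind = cf$kind, mode = mode, cf = cf,
                 degenerate = degenerate),
            class = "bb_basins")
}

#' @export
print.bb_basins <- function(x, ...) {
  cat(sprintf("<bb_basins> %d basin(s) of condensed %s on atom %d%s\n",
              x$n, x$kind, x$cf$sphere$atom,
              if (x$degenerate) " [degenerate]" else ""))
  for (b in seq_len(x$n)) {
    cat(sprintf("  basin %d: alpha=%.4f value=%.6g\n", b, x$alpha[b],
                x$values[b]))
  }
  invisible(x)
}

#' Solid angle fraction of basins
#'
#' The fraction of the reference sphere's surface a basin covers; fractions
#' over one sphere sum to 1 exactly.
#'
#' @param basins a `bb_basins`
#' @param which optional basin index (default: all)
#' @return numeric vector of fractions in [0, 1]
#' @export
solid_angle <- function(basins, which = NULL) {
  if (is.null(which)) return(basins$alpha)
  if (any(which < 1 | which > basins$n)) stop("no such basin")
  if (any(lengths(basins$elements[which]) == 0)) stop("empty basin")
  basins$alpha[which]
}

# index of the mesh face pierced by direction u (unit vector): the face
# whose centroid is nearest to u (faces are small and near-equilateral, so
# this matches the containing face up to boundary-grazing directions, which
# the interior test downstream handles)
.pierced_face <- function(mesh, u) {
  f <- mesh$faces
  cen <- mesh$vertices[f[, 1], , drop = FALSE] +
    mesh$vertices[f[, 2], , drop = FALSE] +
    mesh$vertices[f[, 3], , drop = FALSE]
  which.max((cen %*% u) / sqrt(rowSums(cen^2)))
}

#' Basin containing a given direction from the sphere center
#'
#' Convenience lookup: the wedge whose spherical patch is pierced by the
#' ray from the nucleus along `direction` (e.g. toward a bond critical
#' point or a neighboring atom).
#'
#' @param basins a `bb_basins`
#' @param direction length-3 vector (need not be normalized)
#' @return list: `wedge` (basin index), `alpha`, `value`
#' @export
wedge_toward <- function(basins, direction) {
  u <- direction / sqrt(sum(direction^2))
  face <- .pierced_face(basins$cf$sphere$mesh, u)
  w <- basins$labels[face]
  list(wedge = w, alpha = basins$alpha[w], value = basins$values[w])
}

# bond CPs with the two atoms their bond paths connect
.bond_cp_atoms <- function(field, cps, control = path_control()) {
  bonds <- which(cps$class == "bond")
  out <- list()
  for (bi in bonds) {
    x <- as.numeric(cps[bi, c("x", "y", "z")])
    H <- field_hessian(field, x)[, , 1]
    e <- .cpp_eig3(as.numeric(H))
    # ascending eigendirection = most positive eigenvalue
    u <- e$vectors[, 3]
    ats <- vapply(c(1, -1), function(s) {
      r <- assign_bader_basin(field, x + s * 2 * control$nudge * u,
                              cps = cps, control = path_control(
                                capture = 5e-3, trunc = control$trunc))
      as.integer(r)
    }, 1L)
    out[[length(out) + 1L]] <- list(cp = bi, pos = x, atoms = ats)
  }
  out
}

#' Assemble bond bundles from per-atom bond wedges
#'
#' Each wedge (a condensed-density basin on one atom's sphere) is matched
#' to the bond critical point whose bond path pierces the interior of the
#' wedge's spherical patch; wedges sharing a bond CP form a two-center
#' bundle.  Wedges pierced by no bond path are grouped by the ring or cage
#' CP whose direction from the nucleus they contain (multi-center bundles,
#' e.g. around octahedral holes in FCC metals); failing that they are
#' flagged unassigned (lone-pair-like).
#'
#' @param wedge_list named/indexed list: for each atom, the `bb_basins`
#'   segmentation of its condensed density
#' @param cps `bb_cps` table for the field
#' @param field the density `bb_field`
#' @param control [path_control()] used when walking bond paths
#' @return object of class `bb_bundles`: data.frame `wedges` (atom, wedge,
#'   alpha, value, bundle, type) and list `bundles`
#' @export
assemble_bond_bundles <- function(wedge_list, cps, field,
                                  control = path_control()) {
  geom <- field$geometry
  atoms <- as.integer(names(wedge_list))
  if (length(atoms) == 0 || anyNA(atoms)) {
    atoms <- seq_along(wedge_list)
    names(wedge_list) <- atoms
  }
  bcp <- .bond_cp_atoms(field, cps, control)
  # wedge table
  wt <- do.call(rbind, lapply(atoms, function(a) {
    b <- wedge_list[[as.character(a)]]
    data.frame(atom = a, wedge = seq_len(b$n), alpha = b$alpha,
               value = b$values)
  }))
  wt$key <- paste(wt$atom, wt$wedge)
  # interior faces of each wedge (all neighbors in same wedge)
  interior_wedge <- function(bas, face) {
    adj <- bas$cf$sphere$mesh$adjacency[face, ]
    adj <- adj[!is.na(adj)]
    lab <- bas$labels[face]
    if (all(bas$labels[adj] == lab)) lab else NA_integer_
  }
  assign_cp <- rep(NA_integer_, nrow(wt))     # index into bcp
  assign_other <- rep(NA_integer_, nrow(wt))  # row in cps (ring/cage)
  for (wi in seq_len(nrow(wt))) {
    a <- wt$atom[wi]
    bas <- wedge_list[[as.character(a)]]
    sph <- bas$cf$sphere
    hits <- integer(0)
    for (k in seq_along(bcp)) {
      if (!a %in% bcp[[k]]$atoms) next
      d <- bcp[[k]]$pos - sph$center
      if (isTRUE(geom$periodic)) d <- .min_image_vec(d, geom$lattice)
      u <- d / sqrt(sum(d^2))
      face <- .pierced_face(sph$mesh, u)
      lab <- interior_wedge(bas, face)
      if (!is.na(lab) && lab == wt$wedge[wi]) hits <- c(hits, k)
    }
    if (length(hits) == 1) {
      assign_cp[wi] <- hits
    } else if (length(hits) == 0) {
      # multi-center grouping: the ring/cage CP nearest (by angle) to the
      # wedge's area centroid direction, provided it lands inside the wedge
      rc <- which(cps$class %in% c("ring", "cage"))
      if (length(rc) > 0) {
        el <- bas$elements[[wt$wedge[wi]]]
        fc <- sph$mesh$faces[el, , drop = FALSE]
        cen <- sph$mesh$vertices[fc[, 1], , drop = FALSE] +
          sph$mesh$vertices[fc[, 2], , drop = FALSE] +
          sph$mesh$vertices[fc[, 3], , drop = FALSE]
        wdir <- colSums((cen / sqrt(rowSums(cen^2))) *
                          sph$mesh$areas[el])
        wdir <- wdir / sqrt(sum(wdir^2))
        best <- NA_integer_
        bdot <- 0.5  # require within 60 degrees of the wedge centroid
        for (ci in rc) {
          d <- as.numeric(cps[ci, c("x", "y", "z")]) - sph$center
          if (isTRUE(geom$periodic)) d <- .min_image_vec(d, geom$lattice)
          u <- d / sqrt(sum(d^2))
          dp <- sum(u * wdir)
          if (dp > bdot &&
              bas$labels[.pierced_face(sph$mesh, u)] == wt$wedge[wi]) {
            bdot <- dp
            best <- ci
          }
        }
        assign_other[wi] <- best
      }
    } else {
      # several bond paths pierce the wedge interior (e.g. unresolved
      # multi-center); fall back to the strongest-rho bond CP
      rhos <- vapply(hits, function(k) cps$rho[bcp[[k]]$cp], 0)
      assign_cp[wi] <- hits[which.max(rhos)]
    }
  }
  # build bundles
  bundle_id <- rep(NA_integer_, nrow(wt))
  bundles <- list()
  for (k in seq_along(bcp)) {
    mem <- which(assign_cp == k)
    if (length(mem) == 0) next
    bundles[[length(bundles) + 1L]] <- list(
      type = "2-center", center_cp = bcp[[k]]$cp,
      atoms = wt$atom[mem], wedges = wt$wedge[mem],
      population = sum(wt$value[mem]), alpha = wt$alpha[mem])
    bundle_id[mem] <- length(bundles)
  }
  if (any(!is.na(assign_other))) {
    centers <- unique(assign_other[!is.na(assign_other)])
    for (ci in centers) {
      mem <- which(!is.na(assign_other) & assign_other == ci)
      bundles[[length(bundles) + 1L]] <- list(
        type = "multi-center", center_cp = ci,
        atoms = wt$atom[mem], wedges = wt$wedge[mem],
        population = sum(wt$value[mem]), alpha = wt$alpha[mem])
      bundle_id[mem] <- length(bundles)
    }
  }
  wt$bundle <- bundle_id
  wt$type <- ifelse(is.na(bundle_id), "unassigned",
                    vapply(bundle_id, function(b)
                      if (is.na(b)) "unassigned" else bundles[[b]]$type, ""))
  wt$key <- NULL
  structure(list(wedges = wt, bundles = bundles, cps = cps),
            class = "bb_bundles")
}

.min_image_vec <- function(d, lattice) {
  frac <- d %*% solve(lattice)
  frac <- frac - round(frac)
  as.numeric(frac %*% lattice)
}

#' @export
print.bb_bundles <- function(x, ...) {
  cat(sprintf("<bb_bundles> %d bundle(s), %d wedge(s)\n",
              length(x$bundles), nrow(x$wedges)))
  for (i in seq_along(x$bundles)) {
    b <- x$bundles[[i]]
    cat(sprintf("  bundle %d (%s): atoms {%s}, population %.4f\n", i,
                b$type, paste(b$atoms, collapse = ","), b$population))
  }
  invisible(x)
}

#' Compare boundaries of two segmentations of one sphere
#'
#' Boundary edges (element pairs with different labels) of each
#' segmentation are collected; for every boundary edge midpoint of `ba`
#' the geodesic distance to the nearest boundary edge midpoint of `bb` is
#' computed (and vice versa).
#'
#' @param ba,bb two `bb_basins` on the same mesh (e.g. P and E basins)
#' @return list: `mean`, `max` symmetric boundary distances (radian),
#'   `n_a`, `n_b` basin counts, `count_match` logical
#' @export
compare_P_E_boundaries <- function(ba, bb) {
  mesh <- ba$cf$sphere$mesh
  stopifnot(nrow(mesh$faces) == length(bb$labels))
  bmid <- function(bas) {
    adj <- mesh$adjacency
    nf <- nrow(mesh$faces)
    ii <- rep(seq_len(nf), ncol(adj))
    jj <- as.integer(adj)
    ok <- !is.na(jj) & ii < jj & bas$labels[ii] != bas$labels[jj]
    if (!any(ok)) return(matrix(0, 0, 3))
    cen <- function(fs) {
      v <- mesh$vertices[mesh$faces[fs, 1], , drop = FALSE] +
        mesh$vertices[mesh$faces[fs, 2], , drop = FALSE] +
        mesh$vertices[mesh$faces[fs, 3], , drop = FALSE]
      v / sqrt(rowSums(v^2))
    }
    m <- cen(ii[ok]) + cen(jj[ok])
    m / sqrt(rowSums(m^2))
  }
  ma <- bmid(ba)
  mb <- bmid(bb)
  if (nrow(ma) == 0 && nrow(mb) == 0) {
    return(list(mean = 0, max = 0, n_a = ba$n, n_b = bb$n,
                count_match = ba$n == bb$n))
  }
  if (nrow(ma) == 0 || nrow(mb) == 0) {
    return(list(mean = NA_real_, max = NA_real_, n_a = ba$n, n_b = bb$n,
                count_match = ba$n == bb$n))
  }
  dmat <- acos(pmin(pmax(ma %*% t(mb), -1), 1))
  d_ab <- apply(dmat, 1, min)
  d_ba <- apply(dmat, 2, min)
  list(mean = mean(c(d_ab, d_ba)), max = max(c(d_ab, d_ba)),
       n_a = ba$n, n_b = bb$n, count_match = ba$n == bb$n)
}
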