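# Subdivided-icosahedron meshes on the unit sphere.

#' Icosphere mesh
#'
#' Subdivides a regular icosahedron `level` times (vertex count
#' 10 * 4^level + 2, face count 20 * 4^level) and projects onto the unit
#' sphere.  Face areas are spherical (they sum to 4 pi exactly up to
#' floating point), so solid-angle fractions partition unity.
#'
#' @param level subdivision level (0-6)
#' @return list of class `bb_mesh`: `vertices` (V x 3 unit vectors),
#'   `faces` (F x 3 1-based indices), `areas` (spherical areas, steradian),
#'   `adjacency` (F x 3 face neighbors across each edge)
#' @export
icosphere <- function(level = 4L) {
  stopifnot(level >= 0, level <= 6)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- mid_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- vlist[[a]] + vlist[[b]]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      idx <- length(vlist)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  areas <- .spherical_areas(v, f)
  adj <- .face_adjacency(f)
  structure(list(vertices = v, faces = f, areas = areas, adjacency = adj,
                 level = level),
            class = "bb_mesh")
}

# van Oosterom & Strackee solid angle of each spherical triangle
.spherical_areas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  triple <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  ab <- rowSums(a * b); bc <- rowSums(b * c); ca <- rowSums(c * a)
  2 * atan2(abs(triple), 1 + ab + bc + ca)
}

.face_adjacency <- function(f) {
  nf <- nrow(f)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                 cbind(f[, 3], f[, 1]))
  keys <- ekey(edges[, 1], edges[, 2])
  face_of <- rep(seq_len(nf), 3)
  sp <- split(face_of, keys)
  adj <- matrix(NA_integer_, nf, 3)
  fill <- integer(nf)
  for (pair in sp) {
    if (length(pair) != 2) next
    i <- pair[1]; j <- pair[2]
    fill[i] <- fill[i] + 1L; adj[i, fill[i]] <- j
    fill[j] <- fill[j] + 1L; adj[j, fill[j]] <- i
  }
  adj
}

.flat_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c - a
  n1 <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  n2 <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  n3 <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(n1^2 + n2^2 + n3^2)
}

# rotation matrix from axis-angle
.rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
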