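# Shared, lazily built fixtures.  Sphere construction and condensation are
# the expensive steps, so anything reused across test files is memoized.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

h2_case <- function() {
  memo("h2", {
    fx <- generate_fixture("homodiatomic")
    cps <- find_critical_points(fx$field, n_random = 50)
    s1 <- build_reference_sphere(fx$field, 1, dr = 0.2, level = 3, cps = cps)
    P1 <- condense_field(s1, fx$field)
    list(fx = fx, cps = cps, s1 = s1, P1 = P1)
  })
}

methane_case <- function(level = 3L) {
  memo(paste0("methane", level), {
    fx <- generate_fixture("methane_td")
    cps <- find_critical_points(fx$field, n_random = 100)
    s <- build_reference_sphere(fx$field, 1, dr = 0.2, level = level,
                                cps = cps)
    P <- condense_field(s, fx$field)
    b <- segment_condensed_basins(P)
    list(fx = fx, cps = cps, s = s, P = P, b = b)
  })
}

# radial quadrature of a spherically symmetric promolecular atom: the
# independent normalization oracle (dense trapezoid on [0, rmax])
radial_integral <- function(field, center = c(0, 0, 0), rmax = 25,
                            n = 20000) {
  r <- seq(0, rmax, length.out = n)
  v <- field_value(field, cbind(center[1] + r, center[2], center[3]))
  4 * pi * sum((v * r^2)[-1] + (v * r^2)[-n]) / 2 * (r[2] - r[1])
}

# voxels at least two voxels away from any label change: where the
# grid-native oracle is unambiguous (its basin boundary is quantized to
# the voxel lattice, so label comparisons within one voxel of it test the
# quantization, not the assignment)
single_label_mask <- function(labels, erode = 2L) {
  dims <- dim(labels)
  boundary <- array(FALSE, dims)
  for (d in 1:3) {
    ia <- lapply(dims, seq_len)
    ib <- ia
    ia[[d]] <- seq_len(dims[d] - 1L)
    ib[[d]] <- 2:dims[d]
    diff <- do.call(`[`, c(list(labels), ia)) !=
      do.call(`[`, c(list(labels), ib))
    boundary <- do.call(`[<-`, c(list(boundary), ia, list(
      do.call(`[`, c(list(boundary), ia)) | diff)))
    boundary <- do.call(`[<-`, c(list(boundary), ib, list(
      do.call(`[`, c(list(boundary), ib)) | diff)))
  }
  # dilate the boundary mask (covers diagonal adjacency and one extra ring)
  for (it in seq_len(erode)) {
    grown <- boundary
    for (d in 1:3) {
      ia <- lapply(dims, seq_len)
      ib <- ia
      ia[[d]] <- seq_len(dims[d] - 1L)
      ib[[d]] <- 2:dims[d]
      ba <- do.call(`[`, c(list(boundary), ia))
      bb <- do.call(`[`, c(list(boundary), ib))
      grown <- do.call(`[<-`, c(list(grown), ia, list(
        do.call(`[`, c(list(grown), ia)) | bb)))
      grown <- do.call(`[<-`, c(list(grown), ib, list(
        do.call(`[`, c(list(grown), ib)) | ba)))
    }
    boundary <- grown
  }
  !boundary
}

.rotation_matrix_test <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# voxel grid + steepest-ascent oracle for a molecular field; the grid is
# offset so nuclei never coincide with nodes (a node on a density cusp
# makes the midpoint rule wildly overweight that cell)
voxel_oracle <- function(field, pad = 6, h = 0.15) {
  g <- field$geometry
  lo <- apply(g$positions, 2, min) - pad + 0.37 * h
  hi <- apply(g$positions, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  pts <- cbind(
    lo[1] + (rep(seq_len(dims[1]), times = dims[2] * dims[3]) - 1) * h,
    lo[2] + (rep(rep(seq_len(dims[2]), each = dims[1]),
                 times = dims[3]) - 1) * h,
    lo[3] + (rep(seq_len(dims[3]), each = dims[1] * dims[2]) - 1) * h)
  rho <- array(field_value(field, pts), dims)
  vb <- voxel_basin_labels(rho, lo, h, g$positions)
  list(rho = rho, lo = lo, h = h, dims = dims, labels = vb$labels,
       populations = vb$populations, volumes = vb$volumes, pts = pts)
}
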