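# Critical points, gradient paths, Bader basins.

test_that("a single spherical atom has exactly one (nuclear) CP", {
  fx <- generate_fixture("single_atom")
  cps <- find_critical_points(fx$field, n_random = 20)
  expect_equal(nrow(cps), 1L)
  expect_equal(cps$class, "nuclear")
  expect_equal(as.numeric(cps[1, c("x", "y", "z")]), c(0, 0, 0))
  expect_equal(cps$atom, 1L)
})

test_that("homonuclear diatomic: two maxima and a midpoint bond CP", {
  h2 <- h2_case()
  cps <- h2$cps
  expect_equal(sum(cps$class == "nuclear"), 2L)
  expect_equal(sum(cps$class == "bond"), 1L)
  expect_equal(nrow(cps), 3L)
  # 1D brute-force scan along the internuclear axis locates the minimum
  z <- seq(0.1, 1.3, by = 1e-4)
  rz <- field_value(h2$fx$field, cbind(0, 0, z))
  z_min <- z[which.min(rz)]
  bcp <- cps[cps$class == "bond", ]
  expect_equal(bcp$z, z_min, tolerance = 1e-3)
  expect_equal(c(bcp$x, bcp$y), c(0, 0), tolerance = 1e-6)
})

test_that("methane CP set satisfies the Poincare-Hopf relation", {
  m <- methane_case()
  tab <- table(m$cps$class)
  expect_equal(as.integer(tab["nuclear"]), 5L)
  expect_equal(as.integer(tab["bond"]), 4L)
  expect_equal(poincare_hopf(m$cps), 1L)
})

test_that("CP classes are invariant under rigid rotation", {
  fx <- generate_fixture("methane_td")
  cps <- methane_case()$cps
  R <- .rotation_matrix_test(c(1, 2, 3), 0.7)
  g2 <- mol_geometry(fx$geometry$symbols, fx$geometry$positions %*% t(R))
  f2 <- promolecular_field(g2)
  cps2 <- find_critical_points(f2, n_random = 100)
  expect_equal(sort(table(cps2$class)), sort(table(cps$class)))
  # bond CPs co-rotate: rotated original positions match the new set
  b1 <- as.matrix(cps[cps$class == "bond", c("x", "y", "z")]) %*% t(R)
  b2 <- as.matrix(cps2[cps2$class == "bond", c("x", "y", "z")])
  d <- vapply(seq_len(nrow(b1)), function(i) {
    min(sqrt(rowSums(sweep(b2, 2, b1[i, ])^2)))
  }, 0)
  expect_lt(max(d), 1e-5)
})

test_that("ascent paths on a spherical atom are radial", {
  fx <- generate_fixture("single_atom")
  seed <- c(1.5, 0.8, -0.4)
  p <- trace_gradient_path(fx$field, seed, "ascent",
                           cps = find_critical_points(fx$field,
                                                      n_random = 0),
                           control = path_control(capture = 1e-3))
  ends <- p$points[nrow(p$points), ]
  expect_lt(sqrt(sum(ends^2)), 5e-3)
  # every path point lies on the seed ray
  u <- seed / sqrt(sum(seed^2))
  perp <- p$points - (p$points %*% u) %*% t(u)
  expect_lt(max(sqrt(rowSums(perp^2))), 1e-6)
  # rho increases monotonically along ascent
  expect_true(all(diff(p$rho) > 0))
})

test_that("descent from the mirror plane of a diatomic stays in it", {
  h2 <- h2_case()
  seed <- c(0.4, 0.2, 0.7)  # on the perpendicular bisector plane z = 0.7
  p <- trace_gradient_path(h2$fx$field, seed, "descent", cps = h2$cps)
  expect_lt(max(abs(p$points[, 3] - 0.7)), 1e-6)
  expect_true(all(diff(p$rho) < 0))
  expect_true(p$status %in% c("truncated", "cp"))
})

test_that("seeding at a critical point is rejected", {
  h2 <- h2_case()
  bcp <- as.numeric(h2$cps[h2$cps$class == "bond", c("x", "y", "z")])
  expect_error(trace_gradient_path(h2$fx$field, bcp, "ascent",
                                   cps = h2$cps), "critical point")
})

test_that("Bader assignment matches the voxel steepest-ascent oracle", {
  fx <- generate_fixture("heterodiatomic")
  cps <- find_critical_points(fx$field, n_random = 50)
  vo <- voxel_oracle(fx$field, pad = 5.5, h = 0.17)
  set.seed(5)
  idx <- sample(which(vo$rho > 1e-4 & single_label_mask(vo$labels)), 300)
  pts <- vo$pts[idx, , drop = FALSE]
  lab_path <- suppressWarnings(assign_bader_basin(fx$field, pts, cps = cps))
  lab_vox <- as.integer(vo$labels)[idx]
  ok <- !is.na(lab_path) & lab_vox > 0
  expect_gt(mean(lab_path[ok] == lab_vox[ok]), 0.99)
  # single atom: everything maps to atom 1
  f1 <- generate_fixture("single_atom")$field
  p1 <- matrix(rnorm(15), ncol = 3)
  expect_equal(assign_bader_basin(f1, p1), rep(1L, 5))
})

test_that("diatomic basin populations split the electrons evenly", {
  h2 <- h2_case()
  g <- h2$fx$geometry
  # box symmetric about the bond midpoint, with the mirror plane falling
  # between node planes so no voxel sheet sits exactly on the boundary
  h <- 0.15
  n <- 81L   # x, y: node at 0
  nz <- 80L  # z: planes straddle z = 0.7
  lo <- c(-6, -6, 0.7 - (nz / 2 - 0.5) * h)
  pts <- cbind(
    lo[1] + (rep(seq_len(n), times = n * nz) - 1) * h,
    lo[2] + (rep(rep(seq_len(n), each = n), times = nz) - 1) * h,
    lo[3] + (rep(seq_len(nz), each = n * n) - 1) * h)
  rho <- array(field_value(h2$fx$field, pts), c(n, n, nz))
  vb <- voxel_basin_labels(rho, lo, h, g$positions)
  expect_equal(vb$populations[1], vb$populations[2], tolerance = 1e-6)
  expect_equal(sum(vb$populations), sum(rho) * h^3, tolerance = 1e-9)
})

test_that("critical point tables export to CSV and JSON", {
  cps <- methane_case()$cps
  tmp <- tempfile(fileext = ".csv")
  write_cps(cps, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(nrow(back), nrow(cps))
  tmpj <- tempfile(fileext = ".json")
  write_cps(cps, tmpj)
  expect_equal(length(jsonlite::fromJSON(tmpj)$class), nrow(cps))
})
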