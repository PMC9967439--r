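# Watershed segmentation, solid angles, bond bundles, boundary comparison.

test_that("two antipodal bumps segment into two equal hemispheres", {
  fx <- generate_fixture("two_bump_sphere_field")
  b <- segment_condensed_basins(fx$condensed)
  expect_equal(b$n, 2L)
  expect_equal(sort(b$alpha), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(b$alpha), 1, tolerance = 1e-12)
})

test_that("solid angles partition unity and reject bad requests", {
  b <- segment_condensed_basins(generate_fixture("two_bump_sphere_field")$
                                  condensed)
  expect_equal(sum(solid_angle(b)), 1, tolerance = 1e-12)
  expect_error(solid_angle(b, 5), "no such basin")
  # hemisphere element set covers half the sphere
  mesh <- b$cf$sphere$mesh
  cen <- mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
    mesh$vertices[mesh$faces[, 3], ]
  upper <- sum(mesh$areas[cen[, 3] > 0]) / (4 * pi)
  # centroid-based selection misassigns part of the equatorial face band
  expect_lt(abs(upper - 0.5), 0.04)
})

test_that("methane carbon splits into four equal bond wedges", {
  m <- methane_case()
  expect_equal(m$b$n, 4L)
  expect_equal(m$b$alpha, rep(0.25, 4), tolerance = 0.02)
  expect_equal(sum(m$b$alpha), 1, tolerance = 1e-12)
  # wedge populations sum to the condensed (basin) population exactly
  expect_equal(sum(m$b$values), sum(m$P$values), tolerance = 1e-12)
  # each wedge is pierced by one C-H bond direction
  dirs <- m$fx$geometry$positions[2:5, ]
  labs <- vapply(seq_len(4), function(i) {
    u <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    face <- which.max((m$s$mesh$vertices[m$s$mesh$faces[, 1], ] +
                         m$s$mesh$vertices[m$s$mesh$faces[, 2], ] +
                         m$s$mesh$vertices[m$s$mesh$faces[, 3], ]) %*% u)
    m$b$labels[face]
  }, 1L)
  expect_equal(sort(labs), 1:4)
})

test_that("rigid rotation permutes wedges without changing solid angles", {
  m <- methane_case()
  fx <- m$fx
  R <- .rotation_matrix_test(c(0.3, -1, 0.5), 1.1)
  g2 <- mol_geometry(fx$geometry$symbols, fx$geometry$positions %*% t(R))
  f2 <- promolecular_field(g2)
  cps2 <- find_critical_points(f2, n_random = 100)
  s2 <- build_reference_sphere(f2, 1, dr = 0.2, level = 3, cps = cps2)
  P2 <- condense_field(s2, f2)
  b2 <- segment_condensed_basins(P2)
  expect_equal(b2$n, m$b$n)
  expect_equal(sort(b2$alpha), sort(m$b$alpha), tolerance = 0.02)
  expect_equal(sort(b2$values), sort(m$b$values), tolerance = 0.02)
})

test_that("a homonuclear diatomic forms one two-center bundle", {
  h2 <- h2_case()
  s2 <- build_reference_sphere(h2$fx$field, 2, dr = 0.2, level = 3,
                               cps = h2$cps)
  P2 <- condense_field(s2, h2$fx$field)
  basins <- list(`1` = segment_condensed_basins(h2$P1),
                 `2` = segment_condensed_basins(P2))
  bb <- assemble_bond_bundles(basins, h2$cps, h2$fx$field)
  expect_equal(length(bb$bundles), 1L)
  expect_equal(bb$bundles[[1]]$type, "2-center")
  expect_equal(sort(bb$bundles[[1]]$atoms), c(1L, 2L))
  expect_equal(bb$bundles[[1]]$population,
               sum(h2$P1$values) + sum(P2$values), tolerance = 1e-9)
  # bundle membership is a partition of the assigned wedges
  expect_true(all(table(bb$wedges$bundle) >= 1))
})

test_that("ethane forms one C-C and six C-H bundles", {
  res <- memo("ethane_pipeline", {
    fx <- generate_fixture("ethane_like")
    cfg <- analysis_config(mesh_level = 2, atoms = NULL)
    run_analysis(cfg, fx$field)
  })
  sym <- c("C", "C", rep("H", 6))
  kind <- vapply(res$bundles$bundles, function(b) {
    paste(sort(sym[b$atoms]), collapse = "-")
  }, "")
  expect_equal(sum(kind == "C-C"), 1L)
  expect_equal(sum(kind == "C-H"), 6L)
  expect_equal(length(res$bundles$bundles), 7L)
  expect_true(all(vapply(res$bundles$bundles, function(b) b$type, "") ==
                    "2-center"))
})

test_that("identical segmentations have coincident boundaries", {
  fx <- generate_fixture("two_bump_sphere_field")
  b <- segment_condensed_basins(fx$condensed)
  cmp <- compare_P_E_boundaries(b, b)
  expect_lt(cmp$mean, 1e-6)
  expect_lt(cmp$max, 1e-6)
  expect_true(cmp$count_match)
})

test_that("boundary distances match an exhaustive matching oracle", {
  fx <- generate_fixture("two_bump_sphere_field", level = 2)
  cf <- fx$condensed
  b1 <- segment_condensed_basins(cf)
  # perturbed copy: shift the bump axis slightly
  mesh <- cf$sphere$mesh
  cen <- mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
    mesh$vertices[mesh$faces[, 3], ]
  cen <- cen / sqrt(rowSums(cen^2))
  ax <- c(sin(0.15), 0, cos(0.15))
  d2 <- exp(-rowSums(sweep(cen, 2, ax)^2) / (2 * 0.6^2)) +
    exp(-rowSums(sweep(cen, 2, -ax)^2) / (2 * 0.6^2)) + 0.05
  cf2 <- cf
  cf2$density <- d2
  cf2$values <- d2 * mesh$areas
  b2 <- segment_condensed_basins(cf2)
  cmp <- compare_P_E_boundaries(b1, b2)
  # oracle: exhaustive nearest-boundary-midpoint matching
  bmids <- function(bas) {
    adj <- mesh$adjacency
    nf <- nrow(mesh$faces)
    ii <- rep(seq_len(nf), 3)
    jj <- as.integer(adj)
    ok <- !is.na(jj) & ii < jj & bas$labels[ii] != bas$labels[jj]
    m <- cen[ii[ok], , drop = FALSE] + cen[jj[ok], , drop = FALSE]
    m / sqrt(rowSums(m^2))
  }
  m1 <- bmids(b1)
  m2 <- bmids(b2)
  dall <- c(
    vapply(seq_len(nrow(m1)), function(i) {
      min(acos(pmin(1, pmax(-1, m2 %*% m1[i, ]))))
    }, 0),
    vapply(seq_len(nrow(m2)), function(i) {
      min(acos(pmin(1, pmax(-1, m1 %*% m2[i, ]))))
    }, 0))
  expect_equal(cmp$mean, mean(dall), tolerance = 1e-10)
  expect_equal(cmp$max, max(dall), tolerance = 1e-10)
  expect_gt(cmp$mean, 0)
})
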