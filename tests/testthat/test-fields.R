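# Scalar fields: promolecular densities, grids, cube I/O, derived fields.

test_that("promolecular hydrogen is the normalized Slater density", {
  f <- promolecular_field(mol_geometry("H", matrix(0, 1, 3)))
  r <- c(0.3, 0.5, 1.7, 3.2)
  expect_equal(field_value(f, cbind(r, 0, 0)), exp(-2 * r) / pi,
               tolerance = 1e-12)
  expect_equal(radial_integral(f), 1, tolerance = 1e-6)
})

test_that("superposition: two atoms double the integral, midpoint adds", {
  d <- 1.4
  f2 <- promolecular_field(mol_geometry(c("H", "H"),
                                        rbind(c(0, 0, 0), c(0, 0, d))))
  # whole-space integral by summing two radial integrals centered anywhere
  # the molecule is covered: use a coarse 3D trapezoid oracle
  h <- 0.2
  x <- seq(-8, 8 + d, by = h)
  pts <- as.matrix(expand.grid(seq(-8, 8, by = h), seq(-8, 8, by = h), x))
  tot <- sum(field_value(f2, pts)) * h^3
  expect_equal(tot, 2, tolerance = 5e-3)
  # midpoint value equals the closed-form sum of the two 1s terms
  mid <- field_value(f2, c(0, 0, d / 2))
  expect_equal(mid, 2 * exp(-2 * (d / 2)) / pi, tolerance = 1e-12)
})

test_that("element parameters integrate to the electron count", {
  for (el in c("C", "O", "Ag")) {
    f <- promolecular_field(mol_geometry(el, matrix(0, 1, 3)))
    expect_equal(radial_integral(f), element_z(el), tolerance = 1e-4)
  }
  expect_error(promolecular_field(
    mol_geometry("C", matrix(0, 1, 3)),
    params = element_params("H")), "C")
})

test_that("value/gradient/Hessian are mutually consistent", {
  fx <- generate_fixture("heterodiatomic")
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 1.5), ncol = 3)
  pts[, 3] <- pts[, 3] + 1   # around the molecule
  cons <- field_consistency(fx$field, pts)
  expect_lt(cons$gradient, 1e-6)
  expect_lt(cons$hessian, 1e-5)
  # gradient of a single atom points at the nucleus
  f1 <- generate_fixture("single_atom")$field
  g <- field_gradient(f1, c(1, 0, 0))
  expect_lt(g[1], 0)
  expect_equal(g[2:3], c(0, 0), tolerance = 1e-12)
})

test_that("periodic promolecular fields are lattice periodic", {
  fx <- generate_fixture("fcc_ag_periodic")
  lat <- fx$geometry$lattice
  set.seed(11)
  pts <- matrix(runif(15, 0, 7.72), ncol = 3)
  for (k in 1:3) {
    shifted <- sweep(pts, 2, lat[k, ], "+")
    expect_equal(field_value(fx$field, shifted), field_value(fx$field, pts),
                 tolerance = 1e-9)
  }
})

test_that("element parameter JSON round-trips with normalization", {
  p <- element_params(c("H", "C"))
  tmp <- tempfile(fileext = ".json")
  write_element_params(p, tmp)
  p2 <- read_element_params(tmp)
  expect_equal(p2$C[, "a"], p$C[, "a"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(p2$C[, "c"], p$C[, "c"], tolerance = 1e-9,
               ignore_attr = TRUE)
  # a deliberately mis-scaled shell set is renormalized at load
  raw <- jsonlite::fromJSON(tmp, simplifyVector = TRUE)
  raw$H$shells$c <- raw$H$shells$c * 3
  jsonlite::write_json(raw, tmp, auto_unbox = TRUE, digits = NA)
  p3 <- read_element_params(tmp)
  f <- promolecular_field(mol_geometry("H", matrix(0, 1, 3)),
                          params = p3["H"])
  expect_equal(radial_integral(f), 1, tolerance = 1e-6)
})

test_that("cube files round-trip node-for-node", {
  fx <- generate_fixture("methane_td")
  gf <- as_grid_field(fx$field, c(-4, -4, -4), 0.5, c(17, 17, 17))
  gf$geometry <- fx$geometry
  tmp <- tempfile(fileext = ".cube")
  write_cube(gf, tmp)
  rc <- read_cube(tmp)
  expect_equal(rc$field$grid$values, gf$grid$values, tolerance = 1e-7)
  expect_equal(rc$geometry$positions, fx$geometry$positions,
               tolerance = 1e-5)
  expect_equal(rc$geometry$Z, fx$geometry$Z)
  # maximum node is the one nearest the carbon nucleus
  idx <- arrayInd(which.max(rc$field$grid$values), dim(rc$field$grid$values))
  node <- c(-4, -4, -4) + (idx - 1) * 0.5
  expect_lt(sqrt(sum(node^2)), 0.5)
})

test_that("cube parser reports malformed and truncated input", {
  fx <- generate_fixture("single_atom")
  gf <- as_grid_field(fx$field, c(-2, -2, -2), 0.5, c(9, 9, 9))
  gf$geometry <- fx$geometry
  tmp <- tempfile(fileext = ".cube")
  write_cube(gf, tmp)
  lines <- readLines(tmp)
  writeLines(lines[1:(length(lines) - 5)], tmp)
  expect_error(read_cube(tmp), "truncated")
  writeLines(c(lines[1:2], "not a header", lines[4:length(lines)]), tmp)
  expect_error(read_cube(tmp), "line 3")
  empty <- grid_field(array(1, c(2, 2, 2)), c(0, 0, 0), diag(0.5, 3))
  empty$grid$values <- array(numeric(0), c(0, 0, 0))
  expect_error(write_cube(empty, tmp), "empty")
})

test_that("all-ones cube integrates to the cell volume", {
  n <- 8L
  sp <- 0.25
  gf <- grid_field(array(1, c(n, n, n)), c(0, 0, 0), diag(sp, 3))
  vals <- gf$grid$values
  # trapezoidal weights: half on faces, quarter on edges ...
  w <- rep(1, n)
  w[c(1, n)] <- 0.5
  W <- outer(outer(w, w), w)
  expect_equal(sum(vals * W) * sp^3, ((n - 1) * sp)^3, tolerance = 1e-12)
})

test_that("tricubic grid interpolation is node-exact, C1, domain-aware", {
  fx <- generate_fixture("heterodiatomic")
  sp <- 0.3
  orig <- c(-4, -4, -4)
  gf <- as_grid_field(fx$field, orig, sp, c(28, 28, 32))
  # node exactness
  node <- orig + c(5, 7, 9) * sp
  expect_equal(field_value(gf, node), gf$grid$values[6, 8, 10],
               tolerance = 1e-13)
  # continuity across a cell face: values just left/right agree
  x0 <- orig + c(10 * sp, 5.3 * sp, 6.7 * sp)
  eps <- 1e-7
  v1 <- field_value(gf, x0 - c(eps, 0, 0))
  v2 <- field_value(gf, x0 + c(eps, 0, 0))
  expect_lt(abs(v1 - v2), 1e-6)
  # finite-difference gradient oracle at interior random points
  set.seed(3)
  pts <- matrix(runif(15, -2, 2), ncol = 3)
  g <- field_gradient(gf, pts)
  for (d in 1:3) {
    e <- matrix(0, nrow(pts), 3)
    e[, d] <- 1e-5
    fd <- (field_value(gf, pts + e) - field_value(gf, pts - e)) / 2e-5
    expect_equal(g[, d], fd, tolerance = 1e-5)
  }
  # out-of-domain is signaled, not extrapolated silently
  expect_false(field_in_domain(gf, c(50, 0, 0)))
  expect_true(field_in_domain(gf, c(0, 0, 0)))
})

test_that("derived fields follow their defining formulas", {
  f <- generate_fixture("single_atom")$field
  p <- c(0.8, -0.3, 0.4)
  rho <- field_value(f, p)
  g <- drop(field_gradient(f, p))
  expect_equal(field_value(derived_field(f, "scale", c = 2.5), p), 2.5 * rho)
  expect_equal(field_value(derived_field(f, "power", c = 1, k = 5 / 3), p),
               rho^(5 / 3))
  ctf <- 3 / 10 * (3 * pi^2)^(2 / 3)
  expect_equal(field_value(derived_field(f, "tf"), p), ctf * rho^(5 / 3),
               tolerance = 1e-12)
  expect_equal(field_value(derived_field(f, "vw"), p),
               sum(g^2) / (8 * rho), tolerance = 1e-12)
  expect_equal(field_value(derived_field(f, "tfvw", lambda = 1 / 9), p),
               ctf * rho^(5 / 3) + sum(g^2) / (72 * rho), tolerance = 1e-12)
})

test_that("XYZ files read into bohr geometries", {
  tmp <- tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule",
               "H 0.0 0.0 0.0", "H 0.0 0.0 0.74"), tmp)
  g <- read_xyz(tmp)
  expect_equal(g$symbols, c("H", "H"))
  expect_equal(g$positions[2, 3], 0.74 / 0.529177210903, tolerance = 1e-10)
  writeLines(c("5", "truncated", "H 0 0 0"), tmp)
  expect_error(read_xyz(tmp), "truncated")
})
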