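# Virial energies, core/valence splits, bond energies, distortion report.

test_that("atomic reference defaults: noble-gas cores, Ag 4d-block core", {
  ref <- atomic_reference(c("H", "C", "N", "O", "Ag"))
  expect_equal(ref$n_core, c(0L, 2L, 2L, 2L, 28L))
  expect_equal(ref$e_atom[ref$symbol == "C"], 37.749)
  expect_error(atomic_reference("C", core = c(C = 7L)), "core counts")
  ref2 <- atomic_reference("Ag", core = c(Ag = 36L), energy = c(Ag = 5200))
  expect_equal(ref2$n_core, 36L)
  expect_equal(ref2$e_atom, 5200)
})

test_that("a constant kinetic-energy density gives T = c * volume", {
  fx <- generate_fixture("single_atom")
  cps <- find_critical_points(fx$field, n_random = 0)
  s <- build_reference_sphere(fx$field, 1, dr = 0.2, level = 2, cps = cps)
  P <- condense_field(s, fx$field)
  b <- segment_condensed_basins(P)
  const <- derived_field(derived_field(fx$field, "scale", c = 0),
                         "shift", c = 0.37, out_kind = "ked")
  e <- virial_energy(b, const)
  expect_equal(e$T_w, 0.37 * e$V_w, tolerance = 1e-9)
  expect_equal(e$E_w, -e$T_w)
})

test_that("core/valence split follows the solid-angle share of the core", {
  ref <- atomic_reference(c("C", "H"))
  # worked example: published D4h cyclobutadiene C-H wedge values
  w <- cyclobutadiene_reference("wedges")
  w <- w[w$config == "D4h" & w$wedge %in% c("C of C-H", "H of C-H"), ]
  nv <- core_valence_split(w$P, w$alpha, w$symbol, ref)
  expect_equal(sum(nv), 2.291, tolerance = 5e-4)
  # H wedge with no core keeps its whole population
  expect_equal(core_valence_split(0.924, 1, "H", ref), 0.924,
               ignore_attr = TRUE)
  # a wedge holding exactly its core share has zero valence
  expect_equal(core_valence_split(0.25 * 2, 0.25, "C", ref), 0,
               ignore_attr = TRUE)
  expect_warning(core_valence_split(0.1, 1, "C", ref), "unphysical")
})

test_that("bond energy vanishes when wedges match the atomic reference", {
  ref <- atomic_reference("C")
  w <- data.frame(symbol = "C", T_w = 0.3 * 37.749, alpha = 0.3)
  expect_equal(bond_energy(w, ref), 0, tolerance = 1e-10)
  # two-wedge synthetic bundle against a hand-summed expression
  ref2 <- atomic_reference(c("C", "H"), energy = c(H = 0.5))
  w2 <- data.frame(symbol = c("C", "H"), T_w = c(12.9, 0.55),
                   alpha = c(0.34, 1))
  hand <- (12.9 - 0.34 * 37.749) + (0.55 - 1 * 0.5)
  expect_equal(bond_energy(w2, ref2, unit = "Ha"), hand, tolerance = 1e-12)
  expect_equal(bond_energy(w2, ref2), hand * 2625.4996, tolerance = 1e-9)
  expect_equal(bond_energy(w2, ref2, unit = "eV"), hand * 27.2114,
               tolerance = 1e-9)
  expect_error(bond_energy(data.frame(symbol = "N", T_w = 1, alpha = 0.1),
                           atomic_reference("N")), "isolated-atom energy")
})

test_that("a missing reference energy can be back-solved from a bond", {
  ref <- atomic_reference(c("C", "H"), energy = c(H = 0.472))
  w <- data.frame(symbol = c("C", "H"), T_w = c(12.916, 0.553),
                  alpha = c(0.343, 1))
  be <- bond_energy(w, ref)
  solved <- solve_reference_energy(w, atomic_reference(c("C", "H")),
                                   unknown = "H", be_known = be)
  expect_equal(solved, 0.472, tolerance = 1e-10)
})

test_that("fragment sums reproduce the published distortion energies", {
  w <- cyclobutadiene_reference("wedges")
  a <- w[w$config == "D4h", ]
  b <- w[w$config == "D2h", ]
  mk <- function(x) data.frame(symbol = x$symbol, T_w = x$minus_E_Ha,
                               alpha = x$alpha)
  rep <- fragment_and_distortion_report(mk(a), mk(b), multiplicity = 4L)
  expect_equal(rep$fragment_energy_a, -38.416, tolerance = 1e-3)
  expect_equal(rep$fragment_energy_b, -38.425, tolerance = 1e-3)
  expect_equal(rep$distortion_fragment, 0.009, tolerance = 1e-6)
  expect_equal(rep$distortion_molecule, 0.036, tolerance = 1e-6)
  expect_equal(rep$distortion_molecule_ev, 0.036 * 27.2114,
               tolerance = 1e-6)
  # identical configurations give zero distortion
  rep0 <- fragment_and_distortion_report(mk(a), mk(a), multiplicity = 4L)
  expect_equal(rep0$distortion_molecule, 0)
  # incomplete wedge coverage is an error
  bad <- mk(a)[1:2, ]
  expect_error(fragment_and_distortion_report(bad, mk(b)), "coverage")
})

test_that("wedge and bundle reports format and write", {
  ref <- atomic_reference(c("C", "H"), energy = c(H = 0.405))
  w <- cyclobutadiene_reference("wedges")
  a <- w[w$config == "D4h", ]
  tab <- wedge_report(data.frame(atom = 1, symbol = a$symbol,
                                 wedge = seq_len(nrow(a)), P_w = a$P,
                                 T_w = a$minus_E_Ha, alpha = a$alpha))
  expect_equal(tab$minus_E_Ha, a$minus_E_Ha)
  ch <- a[a$wedge %in% c("C of C-H", "H of C-H"), ]
  br <- bundle_report(list(`C-H` = data.frame(symbol = ch$symbol,
                                              P_w = ch$P,
                                              T_w = ch$minus_E_Ha,
                                              alpha = ch$alpha)),
                      ref, labels = "C-H")
  expect_equal(br$valence_electrons, 2.291, tolerance = 5e-4)
  tmp <- tempfile(fileext = ".json")
  bundle_report(list(ch = data.frame(symbol = ch$symbol, P_w = ch$P,
                                     T_w = ch$minus_E_Ha,
                                     alpha = ch$alpha)), ref, path = tmp)
  expect_true(file.exists(tmp))
})
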