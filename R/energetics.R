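# Virial regional energies, core/valence splits, and bond energies relative
# to isolated atoms.

#' Reference bond-wedge and bond-bundle tables for cyclobutadiene
#'
#' Published per-wedge condensed populations, virial energies (as the
#' positive magnitude -E, hartree) and solid angles for square (D4h) and
#' rectangular (D2h) cyclobutadiene from an all-electron GGA (PBE,
#' triple-zeta) gradient-bundle analysis, together with the corresponding
#' bundle-level valence electron counts and bond energies.  Shipped as
#' plain-CSV reference data; used as worked-example input for the
#' core/valence, bond-energy and distortion arithmetic.
#'
#' @param table "wedges" (per-wedge P, -E, alpha) or "bundles" (per-bundle
#'   valence electrons and bond energy, kJ/mol)
#' @return a data.frame
#' @export
cyclobutadiene_reference <- function(table = c("wedges", "bundles")) {
  table <- match.arg(table)
  path <- system.file("extdata",
                      sprintf("cyclobutadiene_%s.csv", table),
                      package = "bondbundles", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Unit conversions
#' @format Conversion factors from hartree.
#' @name units
NULL

#' @rdname units
#' @export
HA_TO_KJMOL <- 2625.4996

#' @rdname units
#' @export
HA_TO_EV <- 27.2114

#' Atomic reference data
#'
#' Per-element core-electron counts and isolated-atom energies used for
#' valence counts and bond energies.  Energies are stored as the magnitude
#' of the isolated atom's kinetic energy T_atom (equal to -E_atom by the
#' virial theorem), in hartree.  A reference value for carbon (37.749 Ha,
#' from an all-electron GGA calculation) ships with the package; other
#' elements must be supplied by the caller.
#'
#' @param symbols character vector of element symbols
#' @param core optional named integer vector overriding
#'   [core_electron_count()] defaults
#' @param energy optional named numeric vector of isolated-atom energy
#'   magnitudes (hartree)
#' @return object of class `bb_atomic_reference` (data.frame: symbol, Z,
#'   n_core, e_atom)
#' @export
atomic_reference <- function(symbols, core = NULL, energy = NULL) {
  symbols <- unique(symbols)
  nc <- core_electron_count(symbols)
  if (!is.null(core)) nc[names(core)] <- core
  z <- element_z(symbols)
  if (any(nc < 0 | nc > z)) stop("core counts must be in [0, Z]")
  ea <- rep(NA_real_, length(symbols))
  names(ea) <- symbols
  shipped <- c(C = 37.749)
  hit <- intersect(names(shipped), symbols)
  ea[hit] <- shipped[hit]
  if (!is.null(energy)) {
    if (any(!is.finite(energy))) stop("non-finite isolated-atom energy")
    ea[names(energy)] <- energy
  }
  structure(data.frame(symbol = symbols, Z = z, n_core = as.integer(nc),
                       e_atom = as.numeric(ea), stringsAsFactors = FALSE),
            class = c("bb_atomic_reference", "data.frame"))
}

.ref_lookup <- function(ref, symbol, what) {
  i <- match(symbol, ref$symbol)
  if (anyNA(i)) {
    stop("no atomic reference entry for element(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  v <- ref[[what]][i]
  if (what == "e_atom" && anyNA(v)) {
    stop("missing isolated-atom energy for element(s): ",
         paste(unique(symbol[is.na(v)]), collapse = ", "))
  }
  v
}

#' Virial energies of bond wedges
#'
#' Condenses a kinetic-energy density onto a sphere, sums it over each
#' wedge, and applies the regional virial theorem E = -T (valid over
#' zero-flux-bounded volumes with force-free nuclei; the exchange-
#' correlation kinetic-energy correction is not applied).
#'
#' @param basins a `bb_basins` segmentation (bond wedges) of an atom
#' @param ked a kinetic-energy-density `bb_field`; omitting it (with no
#'   precomputed `cT`) is an error ("energetics unavailable") rather than a
#'   silent zero
#' @param cT,cV optional precomputed condensed kinetic-energy / unit fields
#'   on the same sphere (avoids recondensing)
#' @param ... passed to [condense_field()]
#' @return data.frame: wedge, T_w (hartree), E_w = -T_w (hartree),
#'   V_w (bohr^3)
#' @export
virial_energy <- function(basins, ked = NULL, cT = NULL, cV = NULL, ...) {
  if (is.null(cT) && is.null(ked)) {
    stop("energetics unavailable: no kinetic-energy-density field supplied")
  }
  sphere <- basins$cf$sphere
  if (is.null(cT)) cT <- condense_field(sphere, ked, kind = "T", ...)
  if (is.null(cV)) cV <- condense_field(sphere, NULL, ...)
  Tw <- vapply(basins$elements, function(e) sum(cT$values[e]), 0)
  Vw <- vapply(basins$elements, function(e) sum(cV$values[e]), 0)
  data.frame(wedge = seq_len(basins$n), T_w = as.numeric(Tw),
             E_w = -as.numeric(Tw), V_w = as.numeric(Vw))
}

#' Core/valence electron split of a bond wedge
#'
#' The wedge core count is alpha * N_core(element) -- the solid-angle share
#' of the isolated atom's core electrons -- and the valence count is the
#' wedge population minus that share.
#'
#' @param population wedge electron count P_w
#' @param alpha wedge solid-angle fraction
#' @param symbol element of the wedge's atom
#' @param ref an [atomic_reference()]
#' @param tol tolerance before a negative valence count is flagged
#' @return numeric valence electron count (attribute `flagged` marks
#'   unphysical negatives)
#' @export
core_valence_split <- function(population, alpha, symbol, ref,
                               tol = 1e-6) {
  ncore <- .ref_lookup(ref, symbol, "n_core")
  nval <- population - alpha * ncore
  flagged <- nval < -tol
  if (any(flagged)) {
    warning("negative valence electron count for ",
            paste(symbol[flagged], collapse = ", "),
            " (unphysical input)")
  }
  attr(nval, "flagged") <- flagged
  nval
}

#' Bond energy of a bundle relative to isolated atoms
#'
#' Each member wedge contributes T_w - alpha * T_atom: its (positive)
#' virial kinetic energy minus the solid-angle share of the isolated-atom
#' energy magnitude.  The sum, converted to kJ/mol, is the bundle's bond
#' energy; positive values mean stabilization relative to the isolated
#' atoms.
#'
#' @param wedges data.frame with columns `symbol`, `T_w` (hartree) and
#'   `alpha` -- one row per member wedge
#' @param ref an [atomic_reference()] supplying T_atom per element
#' @param unit "kJ/mol" (default), "Ha" or "eV"
#' @return bond energy (scalar)
#' @export
bond_energy <- function(wedges, ref, unit = c("kJ/mol", "Ha", "eV")) {
  unit <- match.arg(unit)
  ta <- .ref_lookup(ref, wedges$symbol, "e_atom")
  be <- sum(wedges$T_w - wedges$alpha * ta)
  switch(unit, `kJ/mol` = be * HA_TO_KJMOL, Ha = be, eV = be * HA_TO_EV)
}

#' Back-solve one missing isolated-atom energy from a known bond energy
#'
#' Given a bundle's bond energy and references for all member elements but
#' one, solves the linear bond-energy expression for the missing element's
#' isolated-atom energy magnitude.
#'
#' @param wedges as in [bond_energy()]
#' @param ref an [atomic_reference()] (the unknown element's `e_atom` may
#'   be NA)
#' @param unknown element symbol to solve for
#' @param be_known the known bond energy
#' @param unit unit of `be_known`
#' @return solved T_atom (hartree)
#' @export
solve_reference_energy <- function(wedges, ref, unknown, be_known,
                                   unit = c("kJ/mol", "Ha", "eV")) {
  unit <- match.arg(unit)
  be_ha <- switch(unit, `kJ/mol` = be_known / HA_TO_KJMOL, Ha = be_known,
                  eV = be_known / HA_TO_EV)
  is_unk <- wedges$symbol == unknown
  if (!any(is_unk)) stop("no wedge of element ", unknown, " in the bundle")
  known <- wedges[!is_unk, , drop = FALSE]
  kn <- if (nrow(known) > 0) {
    sum(known$T_w - known$alpha * .ref_lookup(ref, known$symbol, "e_atom"))
  } else 0
  # be = kn + sum_unk (T_w) - T_unk * sum_unk(alpha)
  (sum(wedges$T_w[is_unk]) + kn - be_ha) / sum(wedges$alpha[is_unk])
}

#' Fragment sums and distortion energy between two geometries
#'
#' Sums wedge energies (`T_w`, as the positive magnitude -E) per fragment
#' for two configurations of the same system, multiplies by the fragment
#' multiplicity, and reports the distortion (stabilization) energy.
#'
#' @param wedges_a,wedges_b data.frames with columns `symbol`, `T_w`,
#'   `alpha` -- complete wedge tables of one fragment in configurations A
#'   and B
#' @param multiplicity number of symmetry-equivalent fragments per molecule
#' @param check_alpha verify that per-atom solid angles sum to 1
#' @return list: per-fragment energies (Ha), per-molecule energies (Ha),
#'   distortion per fragment and per molecule (Ha), and in eV
#' @export
fragment_and_distortion_report <- function(wedges_a, wedges_b,
                                           multiplicity = 1L,
                                           check_alpha = TRUE) {
  chk <- function(w, nm) {
    if (!check_alpha) return(invisible())
    s <- tapply(w$alpha, w$symbol, sum)
    # every atom's wedge set must cover its sphere (tolerating the rounding
    # of printed solid angles)
    bad <- abs(s - round(s)) > 5e-3 | round(s) < 1
    if (any(bad)) {
      stop("incomplete wedge coverage in ", nm, ": per-element alpha sums (",
           paste(sprintf("%s=%.4f", names(s), s), collapse = ", "),
           ") are not whole sphere counts")
    }
  }
  chk(wedges_a, "configuration A")
  chk(wedges_b, "configuration B")
  ea <- -sum(wedges_a$T_w)  # E = -T
  eb <- -sum(wedges_b$T_w)
  d_frag <- ea - eb         # positive when B is more stable
  list(fragment_energy_a = ea, fragment_energy_b = eb,
       molecule_energy_a = ea * multiplicity,
       molecule_energy_b = eb * multiplicity,
       distortion_fragment = d_frag,
       distortion_molecule = d_frag * multiplicity,
       distortion_molecule_ev = d_frag * multiplicity * HA_TO_EV)
}

#' Wedge-level report (condensed population, energy, solid angle)
#'
#' @param wedge_df data.frame with columns atom, symbol, wedge, P_w, T_w,
#'   alpha
#' @param path optional output path (".json" or CSV)
#' @return the formatted data.frame, invisibly if written
#' @export
wedge_report <- function(wedge_df, path = NULL) {
  out <- data.frame(atom = wedge_df$atom, symbol = wedge_df$symbol,
                    wedge = wedge_df$wedge, P = wedge_df$P_w,
                    minus_E_Ha = wedge_df$T_w, alpha = wedge_df$alpha)
  if (is.null(path)) return(out)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(out)
}

#' Bundle-level report (valence electrons and bond energy)
#'
#' @param bundle_wedges list of data.frames (one per bundle) with columns
#'   `symbol`, `P_w`, `T_w`, `alpha`
#' @param ref an [atomic_reference()]
#' @param labels optional bundle names
#' @param path optional output path (".json" or CSV)
#' @return data.frame: bundle, valence electrons, bond energy (kJ/mol)
#' @export
bundle_report <- function(bundle_wedges, ref, labels = NULL, path = NULL) {
  rows <- lapply(seq_along(bundle_wedges), function(i) {
    w <- bundle_wedges[[i]]
    nv <- sum(core_valence_split(w$P_w, w$alpha, w$symbol, ref))
    be <- tryCatch(bond_energy(w, ref), error = function(e) NA_real_)
    data.frame(bundle = if (is.null(labels)) as.character(i) else labels[i],
               valence_electrons = nv, bond_energy_kjmol = be)
  })
  out <- do.call(rbind, rows)
  if (is.null(path)) return(out)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(out)
}
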