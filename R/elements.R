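# Element data: symbols, ground-state configurations, Slater-type shell
# parameters for promolecular densities, and default core-electron counts.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

#' Atomic number for an element symbol
#' @param symbol character vector of element symbols (e.g. "C")
#' @return integer vector of nuclear charges
#' @export
element_z <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(z)], collapse = ", "))
  }
  z
}

# ground-state subshell occupations (n, l, occ), aufbau + d-block exceptions
.subshell_config <- function(Z) {
  order <- list(
    c(1, 0), c(2, 0), c(2, 1), c(3, 0), c(3, 1), c(4, 0), c(3, 2),
    c(4, 1), c(5, 0), c(4, 2), c(5, 1), c(6, 0), c(4, 3), c(5, 2), c(6, 1))
  caps <- c(2, 2, 6, 2, 6, 2, 10, 6, 2, 10, 6, 2, 14, 10, 6)
  occ <- integer(length(order))
  left <- Z
  for (i in seq_along(order)) {
    if (left <= 0) break
    occ[i] <- min(left, caps[i])
    left <- left - occ[i]
  }
  # s -> d promotions for the usual exceptions
  promote <- list(`24` = 1L, `29` = 1L, `41` = 1L, `42` = 1L, `44` = 1L,
                  `45` = 1L, `46` = 2L, `47` = 1L)
  pr <- promote[[as.character(Z)]]
  if (!is.null(pr)) {
    if (Z <= 30) { s_i <- 6L; d_i <- 7L } else { s_i <- 9L; d_i <- 10L }
    occ[s_i] <- occ[s_i] - pr
    occ[d_i] <- occ[d_i] + pr
  }
  cfg <- do.call(rbind, lapply(seq_along(order), function(i) {
    c(n = order[[i]][1], l = order[[i]][2], occ = occ[i])
  }))
  cfg[cfg[, "occ"] > 0, , drop = FALSE]
}

# Slater shielding groups: (1s)(2s,2p)(3s,3p)(3d)(4s,4p)(4d)(4f)(5s,5p)...
.slater_groups <- function(Z) {
  cfg <- .subshell_config(Z)
  type <- ifelse(cfg[, "l"] <= 1, "sp", ifelse(cfg[, "l"] == 2, "d", "f"))
  key <- paste0(cfg[, "n"], type)
  agg <- tapply(cfg[, "occ"], key, sum)
  n <- as.integer(substr(names(agg), 1, 1))
  t <- substr(names(agg), 2, 10)
  o <- order(n + ifelse(t == "sp", 0, ifelse(t == "d", 0.5, 0.75)))
  data.frame(n = n[o], type = t[o], occ = as.integer(agg[o]),
             stringsAsFactors = FALSE)
}

.nstar <- c(1, 2, 3, 3.7, 4.0, 4.2)

# Slater-rules effective exponents -> density shells c * r^p * exp(-a r)
# (each group contributes occ * |R_n*(r)|^2 / 4pi, normalized to occ electrons)
.slater_shells <- function(Z) {
  g <- .slater_groups(Z)
  m <- nrow(g)
  out <- matrix(0, m, 3, dimnames = list(NULL, c("c", "p", "a")))
  for (i in seq_len(m)) {
    s <- if (g$n[i] == 1) 0.30 * (g$occ[i] - 1) else 0.35 * (g$occ[i] - 1)
    for (j in seq_len(m)) {
      if (j == i) next
      if (g$type[i] == "sp") {
        if (g$n[j] == g$n[i] - 1) s <- s + 0.85 * g$occ[j]
        else if (g$n[j] <= g$n[i] - 2) s <- s + 1.00 * g$occ[j]
      } else {
        inner <- g$n[j] < g$n[i] ||
          (g$n[j] == g$n[i] && g$type[j] == "sp") ||
          (g$n[j] == g$n[i] && g$type[i] == "f" && g$type[j] == "d")
        if (inner) s <- s + 1.00 * g$occ[j]
      }
    }
    ns <- .nstar[g$n[i]]
    zeta <- (Z - s) / ns
    if (zeta <= 0) stop("non-positive effective exponent for Z = ", Z)
    a <- 2 * zeta
    p <- 2 * ns - 2
    out[i, ] <- c(g$occ[i] * a^(p + 3) / (4 * pi * gamma(p + 3)), p, a)
  }
  out
}

# analytic whole-space integral of a shell matrix
.shell_integral <- function(shells) {
  sum(4 * pi * shells[, "c"] * gamma(shells[, "p"] + 3) /
        shells[, "a"]^(shells[, "p"] + 3))
}

#' Promolecular element parameters
#'
#' Returns, per element, the Slater-type radial shells whose superposition is
#' the neutral-atom electron density: \eqn{\rho(r) = \sum_k c_k r^{p_k}
#' e^{-a_k r}}.  Parameters derive from Slater's screening rules; each
#' element's density is normalized so it integrates exactly to its electron
#' count.
#'
#' @param symbols character vector of element symbols
#' @return named list; each entry a matrix with columns \code{c}, \code{p},
#'   \code{a} and attribute \code{electrons}
#' @examples
#' p <- element_params("H")
#' # a hydrogen atom is a single 1s shell: rho(r) = exp(-2 r) / pi
#' @export
element_params <- function(symbols) {
  z <- element_z(symbols)
  out <- lapply(seq_along(symbols), function(i) {
    sh <- .slater_shells(z[i])
    # enforce normalization to the electron count
    sh[, "c"] <- sh[, "c"] * z[i] / .shell_integral(sh)
    attr(sh, "electrons") <- as.numeric(z[i])
    sh
  })
  names(out) <- symbols
  out[!duplicated(names(out))]
}

#' Read element parameters from a JSON file
#'
#' The schema is a named object:
#' \code{{"C": {"electrons": 6, "shells": [{"c":..,"p":..,"a":..}, ...]}, ...}}.
#' Shell coefficients are rescaled at load so each element integrates to its
#' stated electron count.
#'
#' @param path JSON file path
#' @return named list of shell matrices, as [element_params()]
#' @export
read_element_params <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(el) {
    e <- raw[[el]]
    sh <- as.matrix(e$shells[, c("c", "p", "a")])
    colnames(sh) <- c("c", "p", "a")
    ne <- as.numeric(e$electrons)
    if (!is.finite(ne) || ne <= 0) {
      stop("element ", el, ": missing or invalid electron count")
    }
    sh[, "c"] <- sh[, "c"] * ne / .shell_integral(sh)
    attr(sh, "electrons") <- ne
    sh
  })
  names(out) <- names(raw)
  out
}

#' Write element parameters to JSON
#' @param params named list of shell matrices (see [element_params()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_element_params <- function(params, path) {
  obj <- lapply(params, function(sh) {
    list(electrons = attr(sh, "electrons"),
         shells = as.data.frame(sh))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.noble_z <- c(2L, 10L, 18L, 36L, 54L, 86L)

#' Default core-electron counts
#'
#' Main-group elements use the noble-gas core (H: 0, C: 2, ...).  For the
#' 4d transition metals the default treats the 4d and 5s shells as valence,
#' so the core is the 28-electron [Ar]3d10 configuration (e.g. Ag: 28).
#' Counts can be overridden wherever an [atomic_reference()] is accepted.
#'
#' @param symbols character vector of element symbols
#' @return named integer vector of core-electron counts
#' @export
core_electron_count <- function(symbols) {
  z <- element_z(symbols)
  core <- vapply(z, function(zz) {
    below <- .noble_z[.noble_z < zz]
    if (length(below) == 0L) 0L else max(below)
  }, integer(1))
  core[z >= 39 & z <= 48] <- 28L  # 4d block: [Ar]3d10 core
  names(core) <- symbols
  core
}
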