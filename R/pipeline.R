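# End-to-end analysis pipeline, configuration and reports.

#' Analysis configuration
#'
#' @param dr reference-sphere radius (bohr)
#' @param mesh_level icosphere subdivision level
#' @param trunc truncation isovalue terminating descent paths (e/bohr^3);
#'   keep well below the 1e-3 display isosurface for conserving populations
#' @param prominence watershed prominence threshold
#' @param levels_per_decade condensation station density
#' @param gtol,capture,nudge path-tracing tolerances (see [path_control()])
#' @param core named integer vector of core-count overrides
#' @param atom_energies named numeric vector of isolated-atom energy
#'   magnitudes (hartree)
#' @param seed RNG seed for stochastic CP-search seeding
#' @param atoms optional subset of atoms to build spheres for
#' @return list of class `bb_config`
#' @export
analysis_config <- function(dr = 0.2, mesh_level = 4L, trunc = 1e-6,
                            prominence = 0.25, levels_per_decade = 48,
                            gtol = 1e-8, capture = 1e-4, nudge = 5e-3,
                            core = NULL, atom_energies = NULL, seed = 1L,
                            atoms = NULL) {
  stopifnot(dr > 0, trunc > 0, prominence > 0, levels_per_decade > 0,
            gtol > 0, capture > 0, mesh_level %in% 0:6)
  structure(list(dr = dr, mesh_level = as.integer(mesh_level), trunc = trunc,
                 prominence = prominence,
                 levels_per_decade = levels_per_decade, gtol = gtol,
                 capture = capture, nudge = nudge, core = core,
                 atom_energies = atom_energies, seed = as.integer(seed),
                 atoms = atoms),
            class = "bb_config")
}

#' Write / read a configuration as flat key-value text
#'
#' Round-trips losslessly: numeric values are written at full precision,
#' named vectors as `name:value` comma lists.
#'
#' @param config a [analysis_config()]
#' @param path file path
#' @return for [read_config()], a `bb_config`
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) return("NULL")
    if (!is.null(names(v))) {
      return(paste(sprintf("%s:%s", names(v), format(v, digits = 17)),
                   collapse = ","))
    }
    paste(format(v, digits = 17), collapse = ",")
  }
  keys <- setdiff(names(config), "")
  writeLines(sprintf("%s = %s", keys,
                     vapply(keys, function(k) fmt(config[[k]]), "")), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- analysis_config()
  ints <- c("mesh_level", "seed")
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(p[2])
    if (val == "NULL") { out[key] <- list(NULL); next }
    if (grepl(":", val)) {
      items <- strsplit(strsplit(val, ",")[[1]], ":")
      v <- as.numeric(vapply(items, `[`, "", 2))
      names(v) <- vapply(items, `[`, "", 1)
      out[[key]] <- if (key == "core") stats::setNames(as.integer(v),
                                                       names(v)) else v
    } else {
      v <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (key %in% ints) v <- as.integer(v)
      if (key == "atoms") v <- as.integer(v)
      out[[key]] <- v
    }
  }
  class(out) <- "bb_config"
  out
}

# order-stable polynomial hash of the serialized configuration
.config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full gradient-bundle analysis pipeline
#'
#' Critical points, per-atom reference spheres, condensed P/T/V fields,
#' wedge segmentation, bundle assembly, energetics (when a kinetic-energy
#' density is given), and wedge/bundle reports, written as CSV and JSON
#' side by side.  Deterministic for a fixed configuration and inputs; the
#' configuration hash is recorded in every output.
#'
#' @param config a [analysis_config()]
#' @param density a density `bb_field` (or path to a cube file)
#' @param ked optional kinetic-energy-density `bb_field` (or cube path)
#' @param outdir output directory (created); NULL skips writing
#' @return list of class `bb_result`: cps, spheres, condensed, basins,
#'   bundles, wedge table, energetics, log
#' @export
run_analysis <- function(config, density, ked = NULL, outdir = NULL) {
  t_all <- proc.time()[3]
  log <- list(config_hash = .config_hash(config),
              package_version = as.character(utils::packageVersion(
                "bondbundles")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " -- check the inputs listed in ?run_analysis", call. = FALSE)
    })
    log$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 3))
    r
  }
  if (is.character(density)) density <- read_cube(density)$field
  if (is.character(ked)) ked <- read_cube(ked, kind = "ked")$field
  geom <- density$geometry
  if (is.null(geom)) stop("density field carries no geometry")
  control <- path_control(gtol = config$gtol, trunc = config$trunc,
                          capture = config$capture, nudge = config$nudge)

  cps <- stage("topology", find_critical_points(density, seed = config$seed,
                                                gtol = config$gtol))
  log$stages$topology$n_cps <- nrow(cps)

  atoms <- if (is.null(config$atoms)) seq_len(nrow(geom$positions))
  else config$atoms
  spheres <- stage("spheres", lapply(atoms, function(a) {
    build_reference_sphere(density, a, dr = config$dr,
                           level = config$mesh_level, cps = cps,
                           control = control)
  }))
  names(spheres) <- atoms
  condensed <- stage("condense", lapply(spheres, function(s) {
    list(P = condense_field(s, density,
                            levels_per_decade = config$levels_per_decade),
         V = condense_field(s, NULL,
                            levels_per_decade = config$levels_per_decade),
         T = if (!is.null(ked))
           condense_field(s, ked,
                          levels_per_decade = config$levels_per_decade))
  }))
  basins <- stage("partition", lapply(condensed, function(cl) {
    segment_condensed_basins(cl$P, prominence = config$prominence)
  }))
  bundles <- stage("bundles", assemble_bond_bundles(basins, cps, density,
                                                    control = control))
  wt <- bundles$wedges
  wt$symbol <- geom$symbols[wt$atom]
  wt <- wt[, c("atom", "symbol", "wedge", "alpha", "value", "bundle",
               "type")]
  names(wt)[names(wt) == "value"] <- "P_w"
  energetics <- NULL
  if (!is.null(ked)) {
    energetics <- stage("energetics", {
      ed <- do.call(rbind, lapply(as.character(atoms), function(a) {
        e <- virial_energy(basins[[a]], cT = condensed[[a]]$T,
                           cV = condensed[[a]]$V)
        e$atom <- as.integer(a)
        e
      }))
      merge(wt, ed, by = c("atom", "wedge"))
    })
  }
  log$stages$condense$n_elements <- sum(vapply(
    spheres, function(s) nrow(s$mesh$faces), 0))
  log$seconds_total <- round(proc.time()[3] - t_all, 3)
  res <- structure(list(cps = cps, spheres = spheres, condensed = condensed,
                        basins = basins, bundles = bundles,
                        wedge_table = wt, energetics = energetics,
                        config = config, log = log),
                   class = "bb_result")
  if (!is.null(outdir)) write_result(res, outdir)
  res
}

#' Write a `bb_result` to disk (CSV + JSON side by side)
#' @param res a `bb_result`
#' @param outdir output directory
#' @return `outdir`, invisibly
#' @export
write_result <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- res$log$config_hash
  wcps <- as.data.frame(res$cps)
  wcps$config_hash <- hash
  utils::write.csv(wcps, file.path(outdir, "cps.csv"), row.names = FALSE)
  wt <- res$wedge_table
  wt$config_hash <- hash
  utils::write.csv(wt, file.path(outdir, "wedges.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash,
         bundles = lapply(res$bundles$bundles, function(b) {
           b[c("type", "atoms", "wedges", "population", "alpha")]
         })),
    file.path(outdir, "bundles.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$energetics)) {
    en <- res$energetics
    en$config_hash <- hash
    utils::write.csv(en, file.path(outdir, "energetics.csv"),
                     row.names = FALSE)
  }
  for (a in names(res$condensed)) {
    write_condensed_csv(res$condensed[[a]],
                        file.path(outdir, sprintf("condensed_atom%s.csv", a)),
                        labels = res$basins[[a]]$labels)
  }
  jsonlite::write_json(res$log, file.path(outdir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Export condensed fields of one sphere as per-element CSV
#'
#' Columns: element id, direction angles theta/phi (of the element
#' centroid, radian), area fraction, P, V and (when available) T and
#' E = -T, plus optional basin labels.
#'
#' @param cl list with `$P`, `$V` and optionally `$T` condensed fields (as
#'   produced by [run_analysis()]), or a single `bb_condensed`
#' @param path output CSV path
#' @param labels optional per-element basin labels
#' @return `path`, invisibly
#' @export
write_condensed_csv <- function(cl, path, labels = NULL) {
  if (inherits(cl, "bb_condensed")) cl <- list(P = cl)
  cf <- cl[[1]]
  mesh <- cf$sphere$mesh
  cen <- mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
    mesh$vertices[mesh$faces[, 3], ]
  cen <- cen / sqrt(rowSums(cen^2))
  out <- data.frame(element = seq_len(nrow(mesh$faces)),
                    theta = acos(pmin(1, pmax(-1, cen[, 3]))),
                    phi = atan2(cen[, 2], cen[, 1]),
                    area_fraction = mesh$areas / (4 * pi))
  for (k in names(cl)) {
    if (!is.null(cl[[k]])) out[[k]] <- cl[[k]]$values
  }
  if (!is.null(out$T)) out$E <- -out$T
  if (!is.null(labels)) out$basin <- labels
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a condensed field as a PLY mesh for visualization
#'
#' Vertices carry the sphere geometry (scaled to `dr` around the atom);
#' faces carry the per-element condensed density as a grayscale property.
#'
#' @param cf a `bb_condensed`
#' @param path output `.ply` path
#' @return `path`, invisibly
#' @export
write_condensed_ply <- function(cf, path) {
  mesh <- cf$sphere$mesh
  v <- sweep(mesh$vertices * cf$sphere$dr, 2, cf$sphere$center, "+")
  f <- mesh$faces - 1L
  d <- cf$density
  gray <- as.integer(round(255 * (d - min(d)) /
                             max(max(d) - min(d), 1e-300)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d %d %d %d", f[, 1], f[, 2], f[, 3],
                     gray, gray, gray), con)
  invisible(path)
}

#' @export
print.bb_result <- function(x, ...) {
  cat(sprintf("<bb_result> %d CPs, %d sphere(s), %d bundle(s) [hash %s]\n",
              nrow(x$cps), length(x$spheres), length(x$bundles$bundles),
              x$log$config_hash))
  invisible(x)
}
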