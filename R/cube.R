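# Gaussian cube file input/output.
#
# Header: two comment lines; "natoms ox oy oz"; three axis records
# "n vx vy vz"; natoms atom records "Z charge x y z"; values with z fastest.
# Sign conventions: negative natoms flags an extra data-set-count line;
# negative axis counts mean the header lengths are in angstrom.  Both are
# accepted on read; writing always uses the positive (bohr) dialect.

#' Read a Gaussian cube file
#'
#' @param path cube file path
#' @param periodic mark the grid periodic
#' @param kind field kind tag for the values ("density", "ked", ...)
#' @return list with elements `field` (a grid [grid_field()]) and
#'   `geometry` (a [mol_geometry()])
#' @export
read_cube <- function(path, periodic = FALSE, kind = "density") {
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed cube file: fewer than 6 header lines")
  comment <- lines[1:2]
  parse_num <- function(i, n, what) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) < n || anyNA(v[1:n])) {
      stop("malformed cube header at line ", i, " (", what, ")")
    }
    v
  }
  h <- parse_num(3, 4, "atom count and origin")
  natoms <- as.integer(h[1])
  has_dset <- natoms < 0
  natoms <- abs(natoms)
  origin <- h[2:4]
  axes <- matrix(0, 3, 3)
  dims <- integer(3)
  ang <- FALSE
  for (a in 1:3) {
    v <- parse_num(3 + a, 4, "axis record")
    dims[a] <- abs(as.integer(v[1]))
    if (v[1] < 0) ang <- TRUE
    axes[a, ] <- v[2:4]
  }
  if (ang) {
    axes <- axes * .BOHR_PER_ANGSTROM
    origin <- origin * .BOHR_PER_ANGSTROM
  }
  zs <- integer(natoms)
  pos <- matrix(0, natoms, 3)
  for (i in seq_len(natoms)) {
    v <- parse_num(6 + i, 5, "atom record")
    zs[i] <- as.integer(v[1])
    pos[i, ] <- v[3:5]
  }
  if (ang) pos <- pos * .BOHR_PER_ANGSTROM
  first_val <- 7 + natoms + if (has_dset) 1L else 0L
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[first_val:length(lines)]), "\\s+"))))
  nexp <- prod(dims)
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric cube value near entry ", bad,
         " (value block starts at line ", first_val, ")")
  }
  if (length(vals) != nexp) {
    stop("truncated cube value block: expected ", nexp, " values, found ",
         length(vals), " (value block starts at line ", first_val, ")")
  }
  sym <- .element_symbols[zs]
  geom <- mol_geometry(sym, pos, unit = "bohr", Z = zs)
  # cube order is z fastest; R arrays are x fastest
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  fld <- grid_field(arr, origin, axes, geometry = geom, periodic = periodic,
                    kind = kind)
  fld$comment <- comment
  list(field = fld, geometry = geom)
}

#' Write a Gaussian cube file
#'
#' Writes the positive-count bohr dialect.  A periodic flag is recorded in
#' the comment line only; the grid layout is unchanged.
#'
#' @param field a grid `bb_field` (see [grid_field()])
#' @param path output path
#' @param comment first header line text
#' @return `path`, invisibly
#' @export
write_cube <- function(field, path, comment = "bondbundles grid field") {
  if (is.null(field$grid)) stop("write_cube() needs a grid field")
  vals <- field$grid$values
  if (length(vals) == 0) stop("empty grid")
  if (!all(is.finite(vals))) stop("non-finite grid values")
  geom <- field$geometry
  if (is.null(geom)) {
    geom <- mol_geometry(character(0), matrix(0, 0, 3))
  }
  con <- file(path, "w")
  on.exit(close(con))
  dims <- dim(vals)
  writeLines(c(comment,
               sprintf("kind=%s periodic=%s", field$kind,
                       field$grid$periodic)), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(geom$positions),
                     field$grid$origin[1], field$grid$origin[2],
                     field$grid$origin[3]), con)
  for (a in 1:3) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dims[a],
                       field$grid$axes[a, 1], field$grid$axes[a, 2],
                       field$grid$axes[a, 3]), con)
  }
  for (i in seq_len(nrow(geom$positions))) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", geom$Z[i],
                       as.numeric(geom$Z[i]), geom$positions[i, 1],
                       geom$positions[i, 2], geom$positions[i, 3]), con)
  }
  # cube order: x outermost, z innermost, 6 values per record, one (x,y)
  # scanline of z values per record group
  v <- as.numeric(aperm(vals, c(3, 2, 1)))
  chunks <- split(v, rep(seq_len(dims[1] * dims[2]), each = dims[3]))
  for (ch in chunks) {
    full <- seq_len(length(ch) %/% 6L * 6L)
    if (length(full) > 0) {
      m <- matrix(ch[full], ncol = 6, byrow = TRUE)
      writeLines(apply(m, 1, function(r) paste(sprintf("%16.8e", r),
                                               collapse = " ")), con)
    }
    rest <- ch[setdiff(seq_along(ch), full)]
    if (length(rest) > 0) {
      writeLines(paste(sprintf("%16.8e", rest), collapse = " "), con)
    }
  }
  invisible(path)
}
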