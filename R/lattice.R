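# Lattice and density-field containers for the master-equation solver.
#
# All spatial book-keeping is done in lattice units of a/2, where a = 2.7 nm
# is the step size per added actin subunit projected on the membrane normal.
# Dimensionless coordinates (xbar, rbar, ybar) are integers; ybar = 0 is the
# undeformed membrane plane and rbar = 0 the symmetry axis.

#' Actin subunit step size (nm)
#'
#' Length added along the membrane normal per polymerized subunit.
#' @export
A_STEP <- 2.7

#' Lattice spacing (nm): half the subunit step, a/2
#' @export
LATTICE_DELTA <- A_STEP / 2

#' Thermal energy at room temperature (pN nm)
#' @export
KT_PN_NM <- 4.1

#' Create a lattice specification
#'
#' Defines the discrete grid on which F-actin density fields live.  The
#' spacing is a/2 = 1.35 nm in both directions.  Planar lattices carry a
#' lateral coordinate `xbar` running over `x_lo:(x_lo + nx - 1)`; cylindrical
#' lattices carry a radial coordinate `rbar` running over `0:(nr - 1)`.
#' The vertical coordinate `ybar` runs over `y_lo:(y_lo + ny - 1)`.
#'
#' @param geometry `"planar"` (x, y) or `"cylindrical"` (r, y).
#' @param nx,nr number of lateral/radial sites (one of the two, per geometry).
#' @param ny number of vertical sites.
#' @param x_lo lowest lateral index (planar only).
#' @param y_lo lowest vertical index.
#' @param spacing lattice spacing in nm; defaults to a/2.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(geometry = c("planar", "cylindrical"),
                         nx = NULL, nr = NULL, ny,
                         x_lo = 0L, y_lo = 0L,
                         spacing = LATTICE_DELTA) {
  geometry <- match.arg(geometry)
  if (spacing <= 0) stop("lattice spacing must be positive")
  n_lat <- if (geometry == "planar") nx else nr
  if (is.null(n_lat)) stop("supply nx (planar) or nr (cylindrical)")
  if (n_lat < 2L || ny < 2L) stop("site counts must be at least 2")
  structure(list(geometry = geometry,
                 n_lat = as.integer(n_lat),
                 ny = as.integer(ny),
                 x_lo = as.integer(if (geometry == "planar") x_lo else 0L),
                 y_lo = as.integer(y_lo),
                 spacing = spacing),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s, %d x %d sites, spacing %.3f nm, ybar %d..%d\n",
              x$geometry, x$n_lat, x$ny, x$spacing,
              x$y_lo, x$y_lo + x$ny - 1L))
  invisible(x)
}

lat_ybar <- function(lattice) lattice$y_lo + seq_len(lattice$ny) - 1L
lat_xbar <- function(lattice) lattice$x_lo + seq_len(lattice$n_lat) - 1L
lat_rbar <- function(lattice) seq_len(lattice$n_lat) - 1L

# Annular site count per radial cell: the number of lattice sites an annulus
# of width one lattice unit contains (2*pi*rbar); the on-axis cell is a disk
# of radius 1/2.
annulus_sites <- function(lattice) {
  rb <- lat_rbar(lattice)
  a <- 2 * pi * rb
  a[1] <- pi / 4
  a
}

new_density_field <- function(lattice, values, time, class2) {
  if (is.null(values)) {
    values <- matrix(0, lattice$n_lat, lattice$ny)
  }
  values <- as.matrix(values)
  if (nrow(values) != lattice$n_lat || ncol(values) != lattice$ny)
    stop("values dimensions do not match the lattice")
  if (any(values < 0)) stop("density values must be non-negative")
  structure(list(values = values, lattice = lattice, time = time),
            class = c(class2, "density_field"))
}

#' Planar F-actin density field
#'
#' Expected subunit count per lattice site, indexed (xbar, ybar).
#'
#' @param lattice a planar [lattice_spec()].
#' @param values matrix of per-site counts (`n_lat` x `ny`), default zero.
#' @param time field time in seconds.
#' @return Object of class `density_field_2d`.
#' @export
density_field_2d <- function(lattice, values = NULL, time = 0) {
  if (lattice$geometry != "planar") stop("need a planar lattice")
  new_density_field(lattice, values, time, "density_field_2d")
}

#' Azimuthally symmetric F-actin density field
#'
#' Expected subunit count per annular cell, indexed (rbar, ybar).  The
#' 2*pi*r measure is absorbed into the stored counts, so the total F-actin
#' is the plain sum of the cell values; the number density per lattice site
#' at rbar > 0 is count / (2*pi*rbar).
#'
#' @inheritParams density_field_2d
#' @return Object of class `density_field_3d`.
#' @export
density_field_3d <- function(lattice, values = NULL, time = 0) {
  if (lattice$geometry != "cylindrical") stop("need a cylindrical lattice")
  new_density_field(lattice, values, time, "density_field_3d")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<%s> t = %.4g s, total F-actin = %.6g subunits\n",
              class(x)[1], x$time, total_factin(x)))
  print(x$lattice)
  invisible(x)
}

#' Total F-actin count of a density field
#'
#' Sum of all site (planar) or annular-cell (cylindrical) subunit counts.
#'
#' @param field a `density_field_2d` or `density_field_3d`.
#' @return Total subunit count (non-negative scalar).
#' @export
total_factin <- function(field) {
  stopifnot(inherits(field, "density_field"))
  sum(field$values)
}

# Extend a field downward (and/or upward) by whole rows, filling with zeros.
extend_field_rows <- function(field, add_below = 0L, add_above = 0L) {
  if (add_below <= 0L && add_above <= 0L) return(field)
  add_below <- max(0L, as.integer(add_below))
  add_above <- max(0L, as.integer(add_above))
  lat <- field$lattice
  nlat <- lat$n_lat
  vals <- cbind(matrix(0, nlat, add_below), field$values,
                matrix(0, nlat, add_above))
  lat$y_lo <- lat$y_lo - add_below
  lat$ny <- lat$ny + add_below + add_above
  field$lattice <- lat
  field$values <- vals
  field
}

#' Write a density snapshot as delimited text
#'
#' Header lines carry the lattice geometry, dimensions, spacing and time;
#' the body holds the row-major counts at full double precision so that
#' [read_density_snapshot()] round-trips bit-exactly.
#'
#' @param field a density field.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density_snapshot <- function(field, path) {
  lat <- field$lattice
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# actinME density snapshot",
               sprintf("geometry %s", lat$geometry),
               sprintf("n_lat %d", lat$n_lat),
               sprintf("ny %d", lat$ny),
               sprintf("x_lo %d", lat$x_lo),
               sprintf("y_lo %d", lat$y_lo),
               sprintf("spacing_nm %.17g", lat$spacing),
               sprintf("time_s %.17g", field$time)), con)
  utils::write.table(format(field$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a density snapshot written by [write_density_snapshot()]
#'
#' @param path file path.
#' @return A `density_field_2d` or `density_field_3d`.
#' @export
read_density_snapshot <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "# actinME density snapshot")
    stop("not an actinME density snapshot: ", path)
  hdr <- strsplit(lines[2:8], " ", fixed = TRUE)
  key <- vapply(hdr, `[`, "", 1L)
  val <- vapply(hdr, `[`, "", 2L)
  names(val) <- key
  geometry <- val[["geometry"]]
  n_lat <- as.integer(val[["n_lat"]])
  ny <- as.integer(val[["ny"]])
  lat <- lattice_spec(geometry,
                      nx = if (geometry == "planar") n_lat else NULL,
                      nr = if (geometry == "cylindrical") n_lat else NULL,
                      ny = ny,
                      x_lo = as.integer(val[["x_lo"]]),
                      y_lo = as.integer(val[["y_lo"]]),
                      spacing = as.numeric(val[["spacing_nm"]]))
  vals <- matrix(scan(text = lines[-(1:8)], quiet = TRUE), n_lat, ny,
                 byrow = TRUE)
  ctor <- if (geometry == "planar") density_field_2d else density_field_3d
  ctor(lat, vals, time = as.numeric(val[["time_s"]]))
}
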