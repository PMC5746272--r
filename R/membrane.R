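# Pretabulated family of equilibrium membrane shapes under turgor pressure.
#
# Solving the axisymmetric Helfrich shape equations is outside the scope of
# this package: the endocytosis model only consumes a pretabulated family of
# equilibrium profiles indexed by invagination depth, each carrying the
# pulling force that sustains it.  A synthetic ("stand-in") generator
# produces a physically shaped family -- shallow domes turning into Omega
# (neck-under-bulb) profiles at depth, with a continuous force curve rising
# to a single maximum and then decreasing on the Omega branch -- and a
# reader/writer pair handles externally computed tables in the same format.

#' Membrane mechanical parameters
#'
#' @param turgor osmotic pressure difference across the membrane (Pa).
#' @param bending_modulus membrane bending rigidity (J).
#' @param R_Pi membrane length scale indexing the tabulated shape heights
#'   (nm); the family spans depths 0.1 to 8 R_Pi.
#' @param f_max maximum pulling force along the family (pN).
#' @param d_fmax depth at which the force curve attains `f_max` (nm); must
#'   be one of the tabulated depths.
#' @param rise_exponent shape exponent of the initial force rise; values
#'   below 1 make the curve steep near zero depth, reflecting the turgor
#'   cost of even shallow deformations.
#' @param d_omega smallest depth at which profiles are Omega-shaped (nm).
#' @param neck_radius Omega-branch neck radius (nm).
#' @param bulb_radius Omega-branch bulb radius (nm).
#' @param dome_width Gaussian width of shallow dome profiles (nm).
#' @param r_plateau outer radius to which profiles are tabulated (nm).
#' @return Object of class `membrane_params`.
#' @export
membrane_params <- function(turgor = 0.2e6, bending_modulus = 2e-19,
                            R_Pi = 10, f_max = 725, d_fmax = 40,
                            rise_exponent = 0.5,
                            d_omega = 35, neck_radius = 10,
                            bulb_radius = 14, dome_width = 10,
                            r_plateau = 200) {
  if (turgor <= 0 || R_Pi <= 0) stop("turgor and R_Pi must be positive")
  if (neck_radius >= bulb_radius) stop("neck must be narrower than bulb")
  structure(list(turgor = turgor, bending_modulus = bending_modulus,
                 R_Pi = R_Pi, f_max = f_max, d_fmax = d_fmax,
                 rise_exponent = rise_exponent,
                 d_omega = d_omega, neck_radius = neck_radius,
                 bulb_radius = bulb_radius, dome_width = dome_width,
                 r_plateau = r_plateau),
            class = "membrane_params")
}

#' Membrane shape
#'
#' An equilibrium membrane profile sampled along arclength, with its
#' invagination depth and the pulling force that sustains it.
#'
#' @param s arclength samples (nm), ordered from the tip outward.
#' @param r radial coordinate of each sample (nm).
#' @param y height of each sample (nm); the outer plateau sits at 0.
#' @param y_I invagination depth (nm): tip height above the plateau.
#' @param f_in pulling force sustaining the shape (pN).
#' @return Object of class `membrane_shape`.
#' @export
membrane_shape <- function(s, r, y, y_I, f_in) {
  if (is.unsorted(s)) stop("samples must be ordered in arclength")
  if (f_in < 0) stop("f_in must be non-negative")
  structure(list(samples = data.frame(s = s, r = r, y = y),
                 y_I = y_I, f_in = f_in),
            class = "membrane_shape")
}

#' Flat (undeformed) membrane shape
#'
#' @param r_max outer radius of the tabulated profile (nm).
#' @return A `membrane_shape` with zero depth and zero force.
#' @export
flat_shape <- function(r_max = 200) {
  membrane_shape(s = c(0, r_max), r = c(0, r_max), y = c(0, 0),
                 y_I = 0, f_in = 0)
}

arclength <- function(r, y) {
  c(0, cumsum(sqrt(diff(r)^2 + diff(y)^2)))
}

# Dome profile: Gaussian bump of depth d and width w.
dome_profile <- function(d, w, r_plateau) {
  r <- c(seq(0, 4 * w, by = 0.5), seq(4 * w + 5, r_plateau, by = 5))
  y <- d * exp(-r^2 / (2 * w^2))
  list(r = r, y = y)
}

# Omega profile: spherical bulb of radius Rb whose tip reaches height d,
# joined to a vertical neck of radius rn and a cosine flare to the plateau.
omega_profile <- function(d, rn, Rb, r_plateau, y_flare = 5) {
  yc <- d - Rb
  phi_n <- -acos(rn / Rb)
  phi <- seq(pi / 2, phi_n, length.out = 60)
  r_b <- Rb * cos(phi)
  y_b <- yc + Rb * sin(phi)
  y_neck_top <- yc - sqrt(Rb^2 - rn^2)
  y_n <- seq(y_neck_top, y_flare, length.out = 12)
  r_fl <- seq(rn, 3 * Rb, length.out = 30)
  y_f <- y_flare * 0.5 * (1 + cos(pi * (r_fl - rn) / (3 * Rb - rn)))
  r_pl <- seq(3 * Rb + 5, r_plateau, by = 5)
  r <- c(r_b, rep(rn, length(y_n)), r_fl[-1], r_pl)
  y <- c(y_b, y_n, y_f[-1], rep(0, length(r_pl)))
  list(r = r, y = y)
}

# Continuous pulling-force curve: rises steeply from zero depth (turgor
# makes even shallow invaginations expensive) to f_max at depth d_fmax,
# then falls on the Omega branch (snap-through-like) toward 0.3 f_max.
family_force_curve <- function(y_I, params) {
  f <- numeric(length(y_I))
  up <- y_I <= params$d_fmax
  u_up <- (pmax(y_I[up], 0) / params$d_fmax)^params$rise_exponent
  f[up] <- params$f_max * sin(pi * u_up / 2)
  y_max <- 8 * params$R_Pi
  u <- (y_I[!up] - params$d_fmax) / (y_max - params$d_fmax)
  f[!up] <- params$f_max * (0.3 + 0.7 * 0.5 * (1 + cos(pi * u)))
  f
}

#' Synthetic stand-in shape family
#'
#' Generates 80 equilibrium profiles at depths `0.1 R_Pi, 0.2 R_Pi, ...,
#' 8 R_Pi`: Gaussian domes below `d_omega`, Omega (neck-under-bulb) shapes
#' beyond it, with a continuous force curve `f_in(y_I)` that vanishes at
#' zero depth, attains its single maximum `f_max` (default 725 pN) at
#' `d_fmax`, and decreases on the Omega branch.
#'
#' @param params a [membrane_params()].
#' @return Object of class `shape_family`.
#' @export
stand_in_family <- function(params = membrane_params()) {
  depths <- params$R_Pi * seq(0.1, 8.0, by = 0.1)
  forces <- family_force_curve(depths, params)
  shapes <- lapply(seq_along(depths), function(i) {
    d <- depths[i]
    pr <- if (d >= params$d_omega)
      omega_profile(d, params$neck_radius, params$bulb_radius,
                    params$r_plateau)
    else dome_profile(d, params$dome_width, params$r_plateau)
    membrane_shape(arclength(pr$r, pr$y), pr$r, pr$y,
                   y_I = d, f_in = forces[i])
  })
  structure(list(shapes = shapes, depths = depths, forces = forces,
                 R_Pi = params$R_Pi, f_max = params$f_max),
            class = "shape_family")
}

#' @export
print.shape_family <- function(x, ...) {
  cat(sprintf("<shape_family> %d shapes, depths %.3g..%.3g nm (R_Pi = %g nm), peak force %.4g pN\n",
              length(x$shapes), min(x$depths), max(x$depths), x$R_Pi,
              max(x$forces)))
  invisible(x)
}

validate_family <- function(depths, R_Pi) {
  expected <- R_Pi * seq(0.1, 8.0, by = 0.1)
  if (length(depths) != 80L)
    stop(sprintf("shape family must hold 80 depth levels, found %d",
                 length(depths)))
  if (any(abs(depths - expected) > 1e-6 * R_Pi))
    stop("shape family depths must be 0.1 R_Pi .. 8 R_Pi in steps of 0.1 R_Pi")
}

#' Write a shape family as delimited text
#'
#' @param family a `shape_family`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shape_family <- function(family, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# actinME shape family",
               sprintf("R_Pi %.10g", family$R_Pi),
               sprintf("f_max %.10g", family$f_max),
               sprintf("n_shapes %d", length(family$shapes))), con)
  for (sh in family$shapes) {
    writeLines(sprintf("SHAPE %.10g %.10g %d", sh$y_I, sh$f_in,
                       nrow(sh$samples)), con)
    writeLines(sprintf("%.10g %.10g %.10g", sh$samples$s, sh$samples$r,
                       sh$samples$y), con)
  }
  invisible(path)
}

#' Read a shape family written by [write_shape_family()]
#'
#' Shapes are reordered by depth; the family must hold the full 80 depth
#' levels `0.1 R_Pi .. 8 R_Pi`.
#'
#' @param path file path.
#' @return A `shape_family`.
#' @export
load_shape_family <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "# actinME shape family")
    stop("not an actinME shape family file: ", path)
  getval <- function(i) strsplit(lines[i], " ", fixed = TRUE)[[1]][2]
  R_Pi <- as.numeric(getval(2))
  f_max <- as.numeric(getval(3))
  n_shapes <- as.integer(getval(4))
  shapes <- vector("list", n_shapes)
  i <- 5L
  for (k in seq_len(n_shapes)) {
    if (i > length(lines) || !startsWith(lines[i], "SHAPE "))
      stop("malformed shape family: expected SHAPE header at line ", i)
    hd <- as.numeric(strsplit(lines[i], " ", fixed = TRUE)[[1]][-1])
    npts <- as.integer(hd[3])
    block <- lines[(i + 1L):(i + npts)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    shapes[[k]] <- membrane_shape(m[, 1], m[, 2], m[, 3],
                                  y_I = hd[1], f_in = hd[2])
    i <- i + npts + 1L
  }
  depths <- vapply(shapes, function(s) s$y_I, 0)
  ord <- order(depths)
  shapes <- shapes[ord]
  depths <- depths[ord]
  validate_family(depths, R_Pi)
  structure(list(shapes = shapes, depths = depths,
                 forces = vapply(shapes, function(s) s$f_in, 0),
                 R_Pi = R_Pi, f_max = f_max),
            class = "shape_family")
}

#' Select the membrane shape and interpolated force for a depth
#'
#' Returns the tabulated shape whose depth is closest to `y_I`, and the
#' pulling force linearly interpolated between the two bracketing tabulated
#' depths (with a virtual flat, zero-force shape at depth 0).  Depths
#' outside the tabulated range are clamped with a warning.
#'
#' @param family a `shape_family`.
#' @param y_I requested invagination depth (nm), >= 0.
#' @return List with elements `shape` (a `membrane_shape`) and `f_in` (pN).
#' @export
select_shape <- function(family, y_I) {
  if (y_I < 0) stop("y_I must be non-negative")
  dmax <- max(family$depths)
  if (y_I > dmax) {
    warning(sprintf("y_I = %.3g nm beyond tabulated depth %.3g nm; clamped",
                    y_I, dmax))
    y_I <- dmax
  }
  grid_d <- c(0, family$depths)
  grid_f <- c(0, family$forces)
  f_in <- stats::approx(grid_d, grid_f, xout = y_I, rule = 2)$y
  step <- family$depths[1]
  if (y_I < step / 2) {
    shape <- flat_shape()
  } else {
    idx <- which.min(abs(family$depths - y_I))
    shape <- family$shapes[[idx]]
  }
  list(shape = shape, f_in = f_in)
}

#' Is a membrane shape Omega-shaped?
#'
#' `TRUE` when the profile overhangs: somewhere along the path from the tip
#' outward the radius decreases, i.e. a neck is narrower than the bulb
#' above it.
#'
#' @param shape a `membrane_shape`.
#' @return Logical scalar.
#' @export
is_omega <- function(shape) {
  r <- shape$samples$r[order(shape$samples$s)]
  any(r < cummax(r) - 1e-9)
}
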