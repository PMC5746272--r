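# Master-equation dynamics for branched actin networks.
#
# The F-actin distribution rho evolves under three processes: branching
# (a directional spreading term: a mother subunit at height ybar + yp can
# seed a daughter filament at +/-45 degrees whose subunits reach laterally
# displaced sites yp rows below), spontaneous nucleation, and first-order
# severing.  A new branch polymerizes instantly to its (force-dependent)
# final length, so a single branching event deposits subunits along the
# whole +/-45-degree diagonal below the mother.

#' Branch length profile
#'
#' Integer filament length (in subunits) for daughter branches whose tip row
#' is `ybar`, bounded by `lbar_max`.  A scalar profile applies to all rows.
#'
#' @param lbar integer vector (per lattice row, bottom row first) or scalar.
#' @param lbar_max ceiling on the branch length (default 60, the zero-force
#'   length k_on * G / k_cap rounded to the configured value).
#' @return Object of class `length_profile`.
#' @export
length_profile_spec <- function(lbar, lbar_max = 60L) {
  lbar <- as.integer(lbar)
  if (any(lbar < 0L) || any(lbar > lbar_max))
    stop("lbar values must lie in [0, lbar_max]")
  structure(list(lbar = lbar, lbar_max = as.integer(lbar_max)),
            class = "length_profile")
}

# Expand a length profile to one value per lattice row (target-row indexed).
lbar_by_row <- function(lprof, lattice) {
  lb <- lprof$lbar
  if (length(lb) == 1L) rep(lb, lattice$ny)
  else if (length(lb) == lattice$ny) lb
  else stop("length profile does not match the lattice rows")
}

#' Planar branching source field
#'
#' Per-site production rate (subunits per second) generated by branching.
#' The source at site (xbar, ybar) collects contributions from mother
#' subunits at (xbar -/+ yp, ybar + yp) for yp = 1..lbar(ybar), with the
#' branching rate evaluated at the mother subunit's position and the
#' factor N/2 splitting the two lateral branch directions.  Evaluating
#' the rate at the mother (rather than the deposited daughter site) lets
#' branches born in the NPF region deposit their subunits beyond it --
#' the F-actin distribution spreads outside the NPF footprint by up to one
#' filament length, as it must for a network of finite-length branches.
#' Mother sites outside the lattice contribute zero.
#'
#' @param rho a [density_field_2d()].
#' @param kbr branching-rate matrix (s^-1 per mother subunit per NPF) with
#'   the same dimensions as `rho$values`.
#' @param N NPF (Las17) count; must be non-negative.
#' @param lprof a [length_profile_spec()].
#' @return Matrix of per-site source rates (same dimensions as the field).
#' @export
branch_source_2d <- function(rho, kbr, N, lprof) {
  stopifnot(inherits(rho, "density_field_2d"))
  if (!is.matrix(kbr) || !all(dim(kbr) == dim(rho$values)))
    stop("mismatched lattices: kbr does not match the density field")
  if (N < 0) stop("NPF count N must be non-negative")
  lat <- rho$lattice
  nx <- lat$n_lat
  ny <- lat$ny
  lbar <- lbar_by_row(lprof, lat)
  src <- matrix(0, nx, ny)
  if (N == 0 || all(lbar == 0L)) return(src)
  w <- kbr * rho$values          # rate-weighted mother density
  mother_cols <- which(colSums(w) > 0)
  if (!length(mother_cols)) return(src)
  max_lb <- max(lbar)
  for (yp in seq_len(max_lb)) {
    jm <- mother_cols[mother_cols - yp >= 1L]
    if (!length(jm)) next
    jt <- jm - yp
    keep <- lbar[jt] >= yp
    jm <- jm[keep]; jt <- jt[keep]
    if (!length(jm)) next
    m <- w[, jm, drop = FALSE]
    zl <- matrix(0, yp, length(jm))
    # value at target x from mother x - yp (shift down) and x + yp (shift up)
    sh_minus <- rbind(zl, m[seq_len(nx - yp), , drop = FALSE])
    sh_plus <- rbind(m[(yp + 1L):nx, , drop = FALSE], zl)
    src[, jt] <- src[, jt] + (N / 2) * (sh_minus + sh_plus)
  }
  src
}

#' Radial coordinate of a branch base
#'
#' For a daughter branch whose end sits at radius `r` and whose mother lies
#' `yprime` rows higher, the base (mother) radius at azimuthal offset `theta`
#' is `sqrt(yprime^2 + r^2 - 2 r yprime cos(theta))`.
#'
#' @param r end (target) radius, lattice units, >= 0.
#' @param yprime vertical offset to the mother, lattice units, >= 0.
#' @param theta azimuthal angle in radians.
#' @return Base radius (same units as `r`), always >= 0.
#' @export
azimuthal_base_radius <- function(r, yprime, theta) {
  if (any(r < 0) || any(yprime < 0)) stop("r and yprime must be non-negative")
  sqrt(pmax(0, yprime^2 + r^2 - 2 * r * yprime * cos(theta)))
}

# Azimuthal spreading operators: for each vertical offset yp, a matrix W
# mapping the mother-row number-density profile (per site) to the per-cell
# deposition profile at the target row.  Row i (target rbar = i-1) holds the
# annulus site count times the trapezoid-average of linearly interpolated
# number density at base radii R(rbar, yp, theta_k).
build_azimuthal_weights <- function(nr, lbar_max, ntheta) {
  rb <- seq_len(nr) - 1
  area <- 2 * pi * rb
  area[1] <- pi / 4
  theta <- 2 * pi * (seq_len(ntheta) - 0.5) / ntheta
  lapply(seq_len(lbar_max), function(yp) {
    w <- matrix(0, nr, nr)
    for (th in theta) {
      R <- sqrt(pmax(0, yp^2 + rb^2 - 2 * rb * yp * cos(th)))
      lo <- floor(R)
      fr <- R - lo
      i <- seq_len(nr)
      ok <- lo <= nr - 1
      w[cbind(i[ok], lo[ok] + 1L)] <- w[cbind(i[ok], lo[ok] + 1L)] +
        (1 - fr[ok]) / ntheta
      ok2 <- lo <= nr - 2
      w[cbind(i[ok2], lo[ok2] + 2L)] <- w[cbind(i[ok2], lo[ok2] + 2L)] +
        fr[ok2] / ntheta
    }
    w * area
  })
}

# Cache of spreading operators, keyed by (nr, lbar_max, ntheta).
.weights_cache <- new.env(parent = emptyenv())

azimuthal_weights <- function(nr, lbar_max, ntheta) {
  key <- sprintf("%d_%d_%d", nr, lbar_max, ntheta)
  w <- .weights_cache[[key]]
  if (is.null(w)) {
    w <- build_azimuthal_weights(nr, lbar_max, ntheta)
    .weights_cache[[key]] <- w
  }
  w
}

#' Cylindrical branching source field
#'
#' Azimuthally symmetric analogue of [branch_source_2d()]: the deposition at
#' cell (rbar, ybar) averages the rate-weighted mother number density over
#' the circle of base radii `R(rbar, yp, theta)` by uniform `ntheta`-point
#' quadrature with linear radial interpolation, and converts back to
#' annular-cell counts.  As in 2D, the branching rate is evaluated at the
#' mother's position, so deposition spreads beyond the NPF ring.
#'
#' @param phi a [density_field_3d()].
#' @param kbr branching-rate matrix over (rbar, ybar), s^-1 per subunit per
#'   NPF, evaluated at the mother subunit.
#' @param N NPF count.
#' @param lprof a [length_profile_spec()].
#' @param ntheta number of azimuthal quadrature points (>= 8, default 64).
#' @return Matrix of per-cell source rates.
#' @export
branch_source_3d <- function(phi, kbr, N, lprof, ntheta = 64L) {
  stopifnot(inherits(phi, "density_field_3d"))
  if (ntheta < 8L) stop("ntheta must be at least 8")
  if (!is.matrix(kbr) || !all(dim(kbr) == dim(phi$values)))
    stop("mismatched lattices: kbr does not match the density field")
  if (N < 0) stop("NPF count N must be non-negative")
  lat <- phi$lattice
  nr <- lat$n_lat
  lbar <- lbar_by_row(lprof, lat)
  src <- matrix(0, nr, lat$ny)
  if (N == 0 || all(lbar == 0L) || all(phi$values == 0)) return(src)
  area <- annulus_sites(lat)
  wnd <- (kbr * phi$values) / area   # rate-weighted mother number density
  mother_cols <- which(colSums(wnd) > 0)
  if (!length(mother_cols)) return(src)
  wts <- azimuthal_weights(nr, max(lbar), ntheta)
  for (yp in seq_len(max(lbar))) {
    jm <- mother_cols[mother_cols - yp >= 1L]
    if (!length(jm)) next
    jt <- jm - yp
    keep <- lbar[jt] >= yp
    jm <- jm[keep]; jt <- jt[keep]
    if (!length(jm)) next
    avg <- wts[[yp]] %*% wnd[, jm, drop = FALSE]
    src[, jt] <- src[, jt] + N * avg
  }
  src
}

#' Advance a density field by one explicit time step
#'
#' First-order update `rho' = rho + dt * (source + knuc - ksev * rho)`.
#' The total-count change equals `dt * (sum(source) + sum(knuc) -
#' ksev * sum(rho))` to numerical precision.  Values driven below zero by
#' roundoff (by less than 1e-12) are clamped to zero; a genuinely negative
#' update aborts.
#'
#' @param rho a density field (2D or 3D).
#' @param source branching source matrix (per site/cell rate), or 0.
#' @param knuc nucleation matrix (subunits per second per site/cell), or 0.
#' @param ksev severing rate (s^-1).
#' @param dt time step (s); requires `ksev * dt < 1` for stability.
#' @return The updated field, with `time` advanced by `dt`.
#' @export
step_field <- function(rho, source = 0, knuc = 0, ksev = 0, dt) {
  stopifnot(inherits(rho, "density_field"))
  if (dt < 0) stop("dt must be non-negative")
  if (ksev * dt >= 1)
    stop(sprintf("unstable explicit update: ksev * dt = %.3g >= 1", ksev * dt))
  v <- rho$values + dt * (source + knuc - ksev * rho$values)
  neg <- v < 0
  if (any(neg)) {
    if (any(v[neg] < -1e-12))
      stop("density driven negative beyond roundoff tolerance")
    v[neg] <- 0
  }
  rho$values <- v
  rho$time <- rho$time + dt
  rho
}
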