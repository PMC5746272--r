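# Spatial branching/nucleation rate fields on the ring + spot NPF geometry,
# and the forbidden zone defined by the membrane profile.
#
# Las17 (the dominant NPF) occupies an annular ring on the membrane; branch
# nucleation is confined to a thin Gaussian layer riding on the membrane
# plane at the ring radii.  Spontaneous (NPF-independent) nucleation feeds a
# central spot that rides on the invagination tip.  The forbidden zone is
# the region on the extracellular side of the membrane profile, which
# filaments cannot occupy; density leaking into it generates the pushing
# force through a linear repulsion.

#' Region geometry of the endocytic site
#'
#' @param rL_in,rL_out inner/outer radii of the Las17 ring (nm).
#' @param r_nuc outer radius of the spontaneous-nucleation spot (nm).
#' @param yL membrane height at the ring radii (nm).
#' @param yS membrane height at the spot center, i.e. the invagination tip (nm).
#' @param sigma_br Gaussian width of the branching layer (nm).
#' @param sigma_nuc Gaussian width of the nucleation layer (nm).
#' @param y_br vertical cutoff of the branching/nucleation layers (nm).
#' @param y_nuc height of the nucleation layer used by the per-filament
#'   pulling-force estimator (nm).
#' @return Object of class `region_geometry`.
#' @export
region_geometry <- function(rL_in = 32, rL_out = 64, r_nuc = 21,
                            yL = 0, yS = 0,
                            sigma_br = 30, sigma_nuc = 10,
                            y_br = 4 * sigma_br, y_nuc = 2 * sigma_nuc) {
  if (!(rL_in > 0 && rL_out > rL_in)) stop("need 0 < rL_in < rL_out")
  if (r_nuc > rL_in) stop("nucleation spot must lie inside the ring (r_nuc <= rL_in)")
  if (sigma_br <= 0 || sigma_nuc <= 0 || y_br <= 0 || y_nuc <= 0)
    stop("layer widths and cutoffs must be positive")
  structure(list(rL_in = rL_in, rL_out = rL_out, r_nuc = r_nuc,
                 yL = yL, yS = yS, sigma_br = sigma_br,
                 sigma_nuc = sigma_nuc, y_br = y_br, y_nuc = y_nuc),
            class = "region_geometry")
}

#' Kinetic rate parameters (scaled form)
#'
#' Branching and nucleation maxima are dimensionless scaled rates: per
#' lattice site, per second (and per NPF molecule for branching).
#'
#' @param kbr_max scaled maximum branching rate (s^-1), default 2.59e-3.
#' @param knuc_max scaled maximum nucleation rate (s^-1), default 15e-3.
#' @param ksev severing rate (s^-1), default 0.36.
#' @return Object of class `rate_params`.
#' @export
rate_params <- function(kbr_max = 2.59e-3, knuc_max = 15e-3, ksev = 0.36) {
  if (kbr_max < 0 || knuc_max < 0 || ksev < 0)
    stop("rates must be non-negative")
  structure(list(kbr_max = kbr_max, knuc_max = knuc_max, ksev = ksev),
            class = "rate_params")
}

gaussian_layer <- function(y, y0, sigma, y_cut, vmax) {
  ifelse(y > y0 & y < y0 + y_cut,
         vmax * exp(-(y - y0)^2 / (2 * sigma^2)), 0)
}

#' Branching rate field on a cylindrical lattice
#'
#' `kbr = kbr_max * exp(-(y - yL)^2 / (2 sigma_br^2))` inside the ring
#' annulus `rL_in < r < rL_out` and the slab `yL < y < yL + y_br`;
#' zero elsewhere.
#'
#' @param geom a [region_geometry()].
#' @param params a [rate_params()].
#' @param lattice a cylindrical [lattice_spec()].
#' @return Matrix over (rbar, ybar) of per-site branching rates.
#' @export
kbr_field <- function(geom, params, lattice) {
  r_nm <- lat_rbar(lattice) * lattice$spacing
  y_nm <- lat_ybar(lattice) * lattice$spacing
  radial <- r_nm > geom$rL_in & r_nm < geom$rL_out
  vert <- gaussian_layer(y_nm, geom$yL, geom$sigma_br, geom$y_br,
                         params$kbr_max)
  outer(radial, vert)
}

#' Spontaneous-nucleation rate field on a cylindrical lattice
#'
#' Mirrors the branching layer: `knuc = knuc_max *
#' exp(-(y - yS)^2 / (2 sigma_nuc^2))` for `r < r_nuc` and
#' `yS < y < yS + y_br`; zero elsewhere.  The layer rides on the
#' invagination tip height `yS`.
#'
#' @inheritParams kbr_field
#' @return Matrix over (rbar, ybar) of per-site nucleation rates
#'   (subunits per second per site).
#' @export
knuc_field <- function(geom, params, lattice) {
  r_nm <- lat_rbar(lattice) * lattice$spacing
  y_nm <- lat_ybar(lattice) * lattice$spacing
  radial <- r_nm < geom$r_nuc
  vert <- gaussian_layer(y_nm, geom$yS, geom$sigma_nuc, geom$y_br,
                         params$knuc_max)
  outer(radial, vert)
}

# ---------------------------------------------------------------------------
# Membrane columns: vertical crossings of the (possibly overhanging) profile.
#
# For each radial lattice column the membrane profile is reduced to the
# sorted heights at which the profile polyline crosses that radius.  Counting
# crossings from below (even-odd rule), the forbidden region in a column is
# (-Inf, c1] U [c2, c3] U ...  This represents Omega shapes (neck narrower
# than bulb) exactly; a flat membrane gives a single crossing at its height.

membrane_crossings <- function(shape, lattice, offset = 0) {
  r <- shape$samples$r
  y <- shape$samples$y + offset
  n <- length(r)
  r1 <- r[-n]; r2 <- r[-1]
  y1 <- y[-n]; y2 <- y[-1]
  dr <- r2 - r1
  seg <- which(abs(dr) > 1e-12)
  rcols <- lat_rbar(lattice) * lattice$spacing
  out <- vector("list", length(rcols))
  rmax <- max(r)
  ylast <- y[which.max(r)]
  for (i in seq_along(rcols)) {
    rc <- rcols[i]
    hit <- seg[(pmin(r1[seg], r2[seg]) <= rc) & (pmax(r1[seg], r2[seg]) > rc)]
    cr <- y1[hit] + (rc - r1[hit]) * (y2[hit] - y1[hit]) / dr[hit]
    if (rc >= rmax) cr <- c(cr, ylast)  # plateau continues outward
    out[[i]] <- sort(cr)
  }
  out
}

# Per-column forbidden intervals as (bottom, top) pairs; bottom of the first
# interval is -Inf.
forbidden_intervals <- function(crossings) {
  lapply(crossings, function(cr) {
    k <- length(cr)
    if (k == 0L) return(matrix(numeric(0), 0, 2))
    idx <- seq_len(k)
    tops <- cr[idx %% 2L == 1L]
    bots <- c(-Inf, cr[idx %% 2L == 0L])[seq_along(tops)]
    cbind(bottom = bots, top = tops)
  })
}

#' Forbidden-zone mask for a membrane shape
#'
#' Logical matrix marking lattice cells strictly inside the membrane (on the
#' extracellular side of the profile).  The mask is used for the pushing-force
#' overlap, not as a hard zero on the density: the master-equation dynamics
#' deliberately let a small component of rho penetrate the membrane.
#'
#' @param shape a [membrane_shape()].
#' @param lattice a cylindrical [lattice_spec()].
#' @param offset vertical offset (nm) added to the profile (the plateau
#'   height in the simulation frame).
#' @return Logical matrix over (rbar, ybar); `TRUE` inside the membrane.
#' @export
forbidden_zone_mask <- function(shape, lattice, offset = 0) {
  ints <- forbidden_intervals(membrane_crossings(shape, lattice, offset))
  y_nm <- lat_ybar(lattice) * lattice$spacing
  mask <- matrix(FALSE, lattice$n_lat, lattice$ny)
  for (i in seq_along(ints)) {
    iv <- ints[[i]]
    for (k in seq_len(nrow(iv)))
      mask[i, y_nm > iv[k, 1] & y_nm < iv[k, 2]] <- TRUE
  }
  mask
}

# Depth (nm) of each lattice cell below the top of its forbidden interval;
# zero outside the forbidden zone.  `intervals` from forbidden_intervals().
overlap_depth <- function(intervals, lattice, offset = 0) {
  y_nm <- lat_ybar(lattice) * lattice$spacing
  d <- matrix(0, lattice$n_lat, lattice$ny)
  for (i in seq_along(intervals)) {
    iv <- intervals[[i]]
    for (k in seq_len(nrow(iv))) {
      inside <- y_nm > iv[k, 1] + offset & y_nm < iv[k, 2] + offset
      d[i, inside] <- (iv[k, 2] + offset) - y_nm[inside]
    }
  }
  d
}

#' Update region heights from a membrane shape
#'
#' Sets the ring height `yL` to the membrane height in the outer (plateau)
#' region and the spot height `yS` to the membrane height on the symmetry
#' axis (the invagination tip).  Radii are unchanged.
#'
#' @param geom a [region_geometry()].
#' @param shape a [membrane_shape()].
#' @param offset vertical offset of the profile plateau (nm).
#' @return The updated `region_geometry`.
#' @export
update_regions <- function(geom, shape, offset = 0) {
  s <- shape$samples
  geom$yL <- s$y[which.max(s$r)] + offset
  geom$yS <- s$y[which.min(s$r)] + offset
  geom
}
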