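# Shared fixtures: tiny lattices and fields built in code.

tiny_lat2 <- function(nx = 11L, ny = 11L, x_lo = -5L, y_lo = 0L)
  lattice_spec("planar", nx = nx, ny = ny, x_lo = x_lo, y_lo = y_lo)

tiny_lat3 <- function(nr = 30L, ny = 24L, y_lo = 0L)
  lattice_spec("cylindrical", nr = nr, ny = ny, y_lo = y_lo)

# a single unit count at dimensionless coordinates (xbar, ybar)
point_field_2d <- function(lat, xbar, ybar) {
  v <- matrix(0, lat$n_lat, lat$ny)
  v[xbar - lat$x_lo + 1L, ybar - lat$y_lo + 1L] <- 1
  density_field_2d(lat, v)
}

# brute-force 2D branching source: enumerate every (mother, offset,
# direction) triple directly from the definition
brute_source_2d <- function(rho, kbr, N, lbar_vec) {
  lat <- rho$lattice
  nx <- lat$n_lat; ny <- lat$ny
  src <- matrix(0, nx, ny)
  for (ix in seq_len(nx)) for (jy in seq_len(ny)) {
    lb <- lbar_vec[jy]
    if (lb < 1L) next
    for (yp in seq_len(lb)) {
      jm <- jy + yp
      if (jm > ny) next
      for (s in c(-1L, 1L)) {
        im <- ix + s * yp
        if (im < 1L || im > nx) next
        src[ix, jy] <- src[ix, jy] + (N / 2) * kbr[im, jm] * rho$values[im, jm]
      }
    }
  }
  src
}

# fast coarse configuration for full-model tests
coarse_config <- function() {
  cfg <- default_config()
  cfg$run$dt <- 0.02
  cfg$run$record_dt <- 0.1
  cfg$lattice$ntheta <- 32L
  cfg
}
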