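# Master-equation core: branching stencil, stepping, mass balance,
# azimuthal quadrature and the 2D/3D correspondence.

test_that("2D branching from a single mother matches the hand-enumerated stencil", {
  lat <- tiny_lat2()
  rho <- point_field_2d(lat, 0L, 5L)
  kbr <- matrix(2, lat$n_lat, lat$ny)
  src <- branch_source_2d(rho, kbr, N = 1, length_profile_spec(2L))
  nz <- which(src != 0, arr.ind = TRUE)
  coords <- cbind(x = nz[, 1] - 1L + lat$x_lo, y = nz[, 2] - 1L + lat$y_lo)
  expect_setequal(paste(coords[, "x"], coords[, "y"]),
                  c("-1 4", "1 4", "-2 3", "2 3"))
  # each site receives k/2; the total production rate is k * lbar
  expect_equal(unname(src[nz]), rep(1, 4))
  expect_equal(sum(src), 2 * 2)
})

test_that("empty fields and zero-length branches give a zero source", {
  lat <- tiny_lat2()
  kbr <- matrix(1, lat$n_lat, lat$ny)
  expect_equal(sum(branch_source_2d(density_field_2d(lat), kbr, 3,
                                    length_profile_spec(4L))), 0)
  rho <- point_field_2d(lat, 0L, 5L)
  expect_equal(sum(branch_source_2d(rho, kbr, 3, length_profile_spec(0L))), 0)
  expect_error(branch_source_2d(rho, kbr, -1, length_profile_spec(2L)),
               "non-negative")
  expect_error(branch_source_2d(rho, matrix(1, 3, 3), 1,
                                length_profile_spec(2L)), "mismatched")
})

test_that("2D source matches brute-force enumeration on random fields", {
  set.seed(42)
  lat <- tiny_lat2(nx = 17L, ny = 15L, x_lo = -8L)
  for (rep in 1:5) {
    vals <- matrix(stats::rexp(17 * 15), 17, 15)
    rho <- density_field_2d(lat, vals)
    kbr <- matrix(stats::runif(17 * 15), 17, 15)
    lbar <- sample(0:3, 15, replace = TRUE)
    src <- branch_source_2d(rho, kbr, N = 2.5,
                            length_profile_spec(lbar, 3L))
    expect_equal(src, brute_source_2d(rho, kbr, 2.5, lbar),
                 tolerance = 1e-12)
  }
})

test_that("branching preserves the checkerboard sublattice", {
  lat <- tiny_lat2(nx = 21L, ny = 21L, x_lo = -10L)
  rho <- point_field_2d(lat, 0L, 10L)   # even sublattice: x + y even
  kbr <- matrix(1e-3, 21, 21)
  f <- rho
  for (i in 1:3) {
    src <- branch_source_2d(f, kbr, 50, length_profile_spec(4L))
    f <- step_field(f, src, 0, 0, dt = 0.5)
  }
  nz <- which(f$values > 0, arr.ind = TRUE)
  parity <- (nz[, 1] - 1L + lat$x_lo + nz[, 2] - 1L + lat$y_lo) %% 2L
  expect_true(all(parity == 0L))
})

test_that("explicit stepping conserves the mass-balance identity", {
  set.seed(7)
  lat <- tiny_lat2(nx = 15L, ny = 15L, x_lo = -7L)
  rho <- density_field_2d(lat, matrix(stats::rexp(225), 15, 15))
  kbr <- matrix(stats::runif(225) * 5e-3, 15, 15)
  knuc <- matrix(stats::runif(225) * 1e-2, 15, 15)
  ksev <- 0.36
  dt <- 0.01
  for (i in 1:20) {
    src <- branch_source_2d(rho, kbr, 30, length_profile_spec(5L))
    F0 <- total_factin(rho)
    rho2 <- step_field(rho, src, knuc, ksev, dt)
    dF_expected <- dt * (sum(src) + sum(knuc) - ksev * F0)
    expect_equal(total_factin(rho2) - F0, dF_expected,
                 tolerance = 1e-9)
    expect_true(all(rho2$values >= 0))
    rho <- rho2
  }
})

test_that("severing-only evolution decays exponentially at k_sev = 0.36/s", {
  lat <- tiny_lat2()
  rho <- density_field_2d(lat, matrix(1, lat$n_lat, lat$ny))
  F0 <- total_factin(rho)
  ksev <- 0.36
  dt <- 0.005
  for (i in seq_len(400)) rho <- step_field(rho, 0, 0, ksev, dt)
  expect_equal(total_factin(rho), F0 * exp(-ksev * 2), tolerance = 2e-3)
})

test_that("relaxation toward the nucleation/severing balance", {
  lat <- tiny_lat2()
  c_nuc <- 0.4; ksev <- 0.8
  knuc <- matrix(c_nuc, lat$n_lat, lat$ny)
  rho <- density_field_2d(lat)
  dt <- 0.002
  for (i in seq_len(5000)) rho <- step_field(rho, 0, knuc, ksev, dt)
  expect_equal(max(abs(rho$values - c_nuc / ksev)), 0, tolerance = 1e-3)
})

test_that("step guards: dt = 0 identity, instability rejected", {
  lat <- tiny_lat2()
  rho <- density_field_2d(lat, matrix(2, lat$n_lat, lat$ny))
  same <- step_field(rho, 0, 0, 0.36, dt = 0)
  expect_equal(same$values, rho$values)
  expect_error(step_field(rho, 0, 0, ksev = 10, dt = 0.2), "unstable")
})

test_that("azimuthal base radius follows the law of cosines", {
  expect_equal(azimuthal_base_radius(3, 4, pi), 7)
  expect_equal(azimuthal_base_radius(3, 4, 0), 1)
  expect_equal(azimuthal_base_radius(5, 0, 1.234), 5)
  expect_error(azimuthal_base_radius(-1, 2, 0), "non-negative")
})

test_that("3D source reduces to 2D for laterally uniform density", {
  lat3 <- tiny_lat3(nr = 60L, ny = 40L)
  area <- actinME:::annulus_sites(lat3)
  nd_rows <- numeric(40); nd_rows[25:35] <- 2
  phi <- density_field_3d(lat3, outer(area, nd_rows))
  kbr3 <- matrix(0, 60, 40); kbr3[, 25:35] <- 3e-3
  src3 <- branch_source_3d(phi, kbr3, 5, length_profile_spec(10L), 64)
  persite <- src3 / area

  lat2 <- tiny_lat2(nx = 41L, ny = 40L, x_lo = -20L)
  rho2 <- density_field_2d(lat2, matrix(rep(nd_rows, each = 41), 41, 40))
  kbr2 <- matrix(0, 41, 40); kbr2[, 25:35] <- 3e-3
  src2 <- branch_source_2d(rho2, kbr2, 5, length_profile_spec(10L))
  ok_r <- 1:(60 - 11)    # away from the radial truncation edge
  for (j in which(src2[21, ] > 0)) {
    expect_lt(max(abs(persite[ok_r, j] - src2[21, j])) / src2[21, j], 0.01)
  }
})

test_that("azimuthal quadrature is converged at ntheta = 64", {
  lat3 <- tiny_lat3(nr = 50L, ny = 30L)
  vals <- matrix(0, 50, 30)
  vals[15, 16:25] <- 3   # ring-seeded column
  phi <- density_field_3d(lat3, vals)
  kbr <- matrix(0, 50, 30); kbr[, 16:25] <- 2e-3
  s64 <- sum(branch_source_3d(phi, kbr, 5, length_profile_spec(8L), 64))
  s128 <- sum(branch_source_3d(phi, kbr, 5, length_profile_spec(8L), 128))
  expect_lt(abs(s128 - s64) / s64, 1e-3)
  expect_error(branch_source_3d(phi, kbr, 5, length_profile_spec(8L), 4),
               "ntheta")
})

test_that("total F-actin sums sites and respects the seeding protocol", {
  lat <- lattice_spec("planar", nx = 200L, ny = 60L, x_lo = -60L, y_lo = 0L)
  fil <- actinME:::seed_filament_table(400L, 50L, 0L, 47L)
  sub <- actinME:::filament_subunits(fil)
  vals <- matrix(0, lat$n_lat, lat$ny)
  for (k in seq_len(nrow(sub))) {
    i <- sub$x[k] - lat$x_lo + 1L; j <- sub$y[k] - lat$y_lo + 1L
    vals[i, j] <- vals[i, j] + 1
  }
  f <- density_field_2d(lat, vals)
  expect_equal(total_factin(f), 400 * 50)
  expect_equal(total_factin(density_field_2d(lat)), 0)
})

test_that("density snapshots round-trip bit-exactly", {
  set.seed(3)
  lat <- tiny_lat3(nr = 12L, ny = 9L, y_lo = -2L)
  phi <- density_field_3d(lat, matrix(stats::rexp(108), 12, 9),
                          time = 1.234567)
  path <- tempfile(fileext = ".txt")
  write_density_snapshot(phi, path)
  back <- read_density_snapshot(path)
  expect_identical(back$values, phi$values)
  expect_identical(back$time, phi$time)
  expect_identical(back$lattice$y_lo, lat$y_lo)
})
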