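# Unit pieces of the endocytosis model: NPF feedback, forces, lengths,
# clutch, per-filament pull, and the decay limit of the full driver.

test_that("branch flux sums rate against counts over the slab", {
  lat <- lattice_spec("cylindrical", nr = 20L, ny = 10L)
  vals <- matrix(0, 20, 10); vals[5, 4] <- 1
  phi <- density_field_3d(lat, vals)
  kbr <- matrix(0, 20, 10); kbr[5, 4] <- 2.59e-3
  expect_equal(branch_flux(phi, kbr), 2.59e-3)
  phi2 <- phi; phi2$values <- phi$values * 7
  expect_equal(branch_flux(phi2, kbr), 7 * branch_flux(phi, kbr))
  expect_equal(branch_flux(density_field_3d(lat), kbr), 0)
})

test_that("Las17 follows the logistic closed form without feedback", {
  npf <- npf_state(N = 20, N_full = 150, k_0 = 2e-3, alpha = 0)
  dt <- 0.01
  n <- npf
  for (i in seq_len(30 / dt)) n <- step_npf(n, F_br = 0, dt = dt)
  r <- 2e-3 / 2 * 150
  closed <- 150 * 20 * exp(r * 30) / (150 + 20 * (exp(r * 30) - 1))
  expect_equal(n$N, closed, tolerance = 2e-3)
  # long-time limit is the packing cap
  for (i in seq_len(3000)) n <- step_npf(n, 0, dt = 0.03)
  expect_equal(n$N, 150, tolerance = 1e-3)
})

test_that("Las17 feedback: equilibrium point, clamping, and alpha sign", {
  npf <- npf_state(N = 50, N_full = 150, k_0 = 2e-3, alpha = 0.082)
  # stationary when (k_0/2)(N_full - N) = alpha F_br
  F_eq <- (2e-3 / 2) * (150 - 50) / 0.082
  n2 <- step_npf(npf, F_eq, dt = 0.01)
  expect_equal(n2$N, 50, tolerance = 1e-12)
  # enormous flux drives N toward zero but never below
  n <- npf
  for (i in 1:2000) n <- step_npf(n, F_br = 1e3, dt = 0.01)
  expect_gte(n$N, 0)
  expect_lt(n$N, 1e-6)
  # increasing alpha strictly lowers the steady N at fixed flux
  steady_N <- function(alpha) {
    n <- npf_state(N = 50, N_full = 150, k_0 = 2e-3, alpha = alpha)
    for (i in 1:4000) n <- step_npf(n, F_br = 0.5, dt = 0.05)
    n$N
  }
  expect_gt(steady_N(0.05), steady_N(0.1))
  expect_error(step_npf(npf_state(k_0 = 1), 0, dt = 1), "dt too large")
})

test_that("pushing force is the linear overlap repulsion", {
  lat <- lattice_spec("cylindrical", nr = 10L, ny = 8L, y_lo = -4L)
  vals <- matrix(0, 10, 8)
  vals[3, 2] <- 1           # one subunit at ybar = -3, depth 3 * 1.35 nm
  phi <- density_field_3d(lat, vals)
  depth <- actinME:::overlap_depth(
    actinME:::forbidden_intervals(
      actinME:::membrane_crossings(flat_shape(), lat)), lat)
  expect_equal(pushing_force(phi, depth, k_rep = 2), 2 * 3 * LATTICE_DELTA)
  phi$values <- phi$values * 2
  expect_equal(pushing_force(phi, depth, 2), 2 * 2 * 3 * LATTICE_DELTA)
  expect_equal(pushing_force(density_field_3d(lat), depth, 2), 0)
})

test_that("force-dependent length follows the Brownian ratchet", {
  mech <- mech_params()
  expect_equal(length_profile(0, mech)$lbar, 60L)
  f_half <- mech$kT * log(2) / mech$delta_y
  expect_equal(length_profile(f_half, mech)$lbar, 30L)
  expect_equal(length_profile(1e5, mech)$lbar, 0L)
  expect_error(length_profile(-1, mech), "non-negative")
  # monotone non-increasing in force
  ls <- vapply(seq(0, 40, by = 2),
               function(f) length_profile(f, mech)$lbar, 0L)
  expect_true(all(diff(ls) <= 0))
})

test_that("molecular clutch gates on F_min and integrates the velocity gap", {
  expect_equal(clutch_update(999, 10, 0, 1000, 25, 0.5), 0)
  expect_equal(clutch_update(1500, 3, 3, 1000, 25, 0.5), 25)
  expect_equal(clutch_update(1500, 4, 2, 1000, 25, 0.5), 26)
  expect_equal(clutch_update(1500, 0, 50, 1000, 1, 0.5), 0)  # floored
  expect_error(clutch_update(1500, 1, 1, 1000, 0, 0), "positive")
})

test_that("per-filament pull scales inversely with the inner count", {
  lat <- lattice_spec("cylindrical", nr = 60L, ny = 20L)
  geom <- region_geometry(rL_in = 32, y_nuc = 20)
  vals <- matrix(0, 60, 20)
  inner_cols <- which((seq_len(60) - 1) * LATTICE_DELTA < 32)
  vals[inner_cols[1:5], 3] <- 10    # 50 subunits inside the ring
  phi <- density_field_3d(lat, vals)
  n_fil <- 50 / (2 * 20 / A_STEP)
  expect_equal(pull_per_filament(phi, geom, 725), 725 / n_fil)
  phi2 <- phi; phi2$values <- phi$values / 2
  expect_equal(pull_per_filament(phi2, geom, 725),
               2 * pull_per_filament(phi, geom, 725))
  expect_equal(pull_per_filament(phi, geom, 0), 0)
  expect_equal(pull_per_filament(density_field_3d(lat), geom, 10), Inf)
})

test_that("with branching and nucleation off, F decays at k_sev and the membrane stays flat", {
  cfg <- coarse_config()
  cfg$rates$knuc_max <- 0
  cfg$rates$kbr_max <- 0
  cfg$run$T <- 5
  run <- run_endocytosis(cfg)
  tc <- run$timecourse
  F0 <- tc$F[1]
  expect_equal(tc$F[nrow(tc)], F0 * exp(-0.36 * max(tc$t)), tolerance = 0.02)
  expect_true(all(tc$y_I == 0))
  expect_true(all(tc$f_in == 0))
})

test_that("endocytosis runs are deterministic for identical configurations", {
  cfg <- coarse_config()
  cfg$run$T <- 4
  r1 <- run_endocytosis(cfg)
  r2 <- run_endocytosis(cfg)
  expect_identical(r1$timecourse, r2$timecourse)
})
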