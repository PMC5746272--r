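# Coupled mechanochemical model of clathrin-mediated endocytosis (CME).
#
# The pieces: the 3D master equation for the F-actin distribution; a rate
# equation for the Las17 (NPF) count with negative feedback from branching;
# a molecular clutch that couples network growth to membrane invagination
# once the F-actin count exceeds a threshold; a pretabulated membrane shape
# family supplying the pulling force f_in at each invagination depth; and a
# force balance positioning the membrane so that the pushing force f_out
# from actin overlapping the forbidden zone equals f_in.

#' NPF (Las17) state
#'
#' @param N current Las17 count.
#' @param N_full maximal Las17 count from 2-d packing of the ring.
#' @param k_0 recruitment rate constant (s^-1), default 7.24e-5.
#' @param alpha probability that a branching event dissociates a Las17
#'   molecule from the membrane, default 0.082.
#' @return Object of class `npf_state`.
#' @export
npf_state <- function(N = 20, N_full = 2800, k_0 = 7.24e-5, alpha = 0.082) {
  if (N < 0 || N > N_full) stop("need 0 <= N <= N_full")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(N = N, N_full = N_full, k_0 = k_0, alpha = alpha),
            class = "npf_state")
}

#' Mechanical and polymerization parameters
#'
#' @param F_min molecular-clutch engagement threshold (F-actin subunits).
#' @param k_rep linear repulsion stiffness between actin and membrane
#'   (pN per subunit per nm of penetration).
#' @param kT thermal energy (pN nm).
#' @param delta_y Brownian-ratchet step (nm), a/2.
#' @param k_on actin on-rate constant (uM^-1 s^-1).
#' @param G free G-actin concentration (uM).
#' @param k_cap capping rate (s^-1).
#' @param lbar_max zero-force branch length in subunits; the configured
#'   rounding of k_on G / k_cap (default 60).
#' @param f_pin nominal membrane-network contact force (pN).  Before the
#'   clutch engages the net force on the network vanishes; the membrane is
#'   kept in contact with the network edge by balancing this small nominal
#'   force instead, which regularizes the zero-force contact problem on the
#'   lattice.  Negligible against the pulling forces (hundreds of pN).
#' @return Object of class `mech_params`.
#' @export
mech_params <- function(F_min = 1000, k_rep = 0.35, kT = KT_PN_NM,
                        delta_y = LATTICE_DELTA, k_on = 11.6, G = 5.3,
                        k_cap = 1, lbar_max = 60L, f_pin = 1) {
  vals <- c(F_min, k_rep, kT, delta_y, k_on, G, k_cap, lbar_max, f_pin)
  if (any(vals <= 0)) stop("all mechanical parameters must be positive")
  structure(list(F_min = F_min, k_rep = k_rep, kT = kT, delta_y = delta_y,
                 k_on = k_on, G = G, k_cap = k_cap,
                 lbar_max = as.integer(lbar_max), f_pin = f_pin),
            class = "mech_params")
}

#' Branch flux per NPF molecule
#'
#' Number of new branches created per unit time per Las17 molecule:
#' the branching-rate field summed against the F-actin distribution over
#' the branching slab.  On stored annular counts the 2 pi r dr measure is
#' already absorbed, and the a/2 step equals one lattice unit, so the flux
#' is the plain sum of `kbr * counts`.
#'
#' @param phi a [density_field_3d()] (or 2D field for the strip variant).
#' @param kbr branching-rate matrix aligned with `phi`.
#' @return Branches per second per Las17 molecule (>= 0).
#' @export
branch_flux <- function(phi, kbr) {
  if (!all(dim(kbr) == dim(phi$values))) stop("fields not aligned")
  sum(kbr * phi$values)
}

#' Advance the Las17 count by one explicit step
#'
#' `dN/dt = (k_0 / 2) N (N_full - N) - alpha N F_br`: logistic recruitment
#' toward the packing limit, minus the negative feedback of branching
#' (each branching event dissociates a Las17 with probability alpha).
#' The result is clamped to `[0, N_full]`.
#'
#' @param npf an [npf_state()].
#' @param F_br branch flux per Las17 (s^-1), from [branch_flux()].
#' @param dt time step (s); requires `k_0 * N_full * dt < 0.1`.
#' @return The updated `npf_state`.
#' @export
step_npf <- function(npf, F_br, dt) {
  if (npf$k_0 * npf$N_full * dt >= 0.1)
    stop("dt too large for the NPF update: k_0 * N_full * dt >= 0.1")
  dN <- (npf$k_0 / 2) * npf$N * (npf$N_full - npf$N) - npf$alpha * npf$N * F_br
  npf$N <- min(npf$N_full, max(0, npf$N + dt * dN))
  npf
}

#' Pushing force from membrane overlap
#'
#' Linear repulsion between the membrane and the portion of the actin
#' density that has penetrated the forbidden zone:
#' `f_out = k_rep * sum(count * depth)` over penetrating cells.
#'
#' @param phi a density field.
#' @param depth matrix of penetration depths (nm) below the membrane,
#'   zero outside the forbidden zone (see [forbidden_zone_mask()]).
#' @param k_rep repulsion stiffness (pN per subunit per nm).
#' @return Pushing force in pN (>= 0).
#' @export
pushing_force <- function(phi, depth, k_rep) {
  if (!all(dim(depth) == dim(phi$values))) stop("fields not aligned")
  k_rep * sum(phi$values * depth)
}

#' Force-dependent branch length
#'
#' Brownian-ratchet compression of the zero-force length:
#' `lbar = floor(lbar_max * exp(-f_share * delta_y / kT))`.
#'
#' @param f_share opposing force per growing tip (pN), >= 0.
#' @param mech a [mech_params()].
#' @return A [length_profile_spec()] with the uniform compressed length.
#' @export
length_profile <- function(f_share, mech) {
  if (f_share < 0) stop("f_share must be non-negative")
  lb <- floor(mech$lbar_max * exp(-f_share * mech$delta_y / mech$kT))
  length_profile_spec(as.integer(lb), lbar_max = mech$lbar_max)
}

# Row-resolved branch length: the local linear repulsion of the membrane
# acts on tips that would land a depth below it, Boltzmann-suppressing the
# insertion of further subunits.  This confines deposition to within a
# couple of lattice rows of the membrane.  The external load is not added
# on top: it is transmitted to the tips through this same repulsion (the
# force balance sets the membrane position), so adding a shared tip load
# here would count the load twice.
lbar_row_profile <- function(lattice, mech, membrane_y, lbar_free = NULL) {
  if (is.null(lbar_free)) lbar_free <- mech$lbar_max
  y_nm <- lat_ybar(lattice) * lattice$spacing
  depth <- pmax(0, membrane_y - y_nm)
  f_loc <- mech$k_rep * depth
  pmax(0L, as.integer(floor(lbar_free *
                              exp(-f_loc * mech$delta_y / mech$kT))))
}

#' Molecular-clutch update of the invagination depth
#'
#' Below the engagement threshold `F_min` the invagination vanishes; above
#' it the network is treated as rigid and the depth is driven by the
#' difference between the outer (ring) and inner (spot) polymerization
#' velocities, floored at zero.
#'
#' @param F total F-actin count.
#' @param v_out,v_in outer/inner polymerization velocities (nm/s).
#' @param F_min clutch threshold (subunits).
#' @param y_I current invagination depth (nm).
#' @param dt time step (s).
#' @return The updated depth (nm).
#' @export
clutch_update <- function(F, v_out, v_in, F_min, y_I, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (F < F_min) return(0)
  max(0, y_I + dt * (v_out - v_in))
}

#' Pulling force per membrane-attached filament
#'
#' The total pulling force divided by the number of pulling filaments,
#' estimated as the F-actin count inside the ring inner radius divided by
#' the dimensionless nucleation-layer height `2 y_nuc / a`.
#'
#' @param phi a [density_field_3d()].
#' @param geom a [region_geometry()].
#' @param f_in total pulling force (pN).
#' @return Force per filament (pN); 0 when `f_in = 0`, `Inf` (rupture flag)
#'   when the inner count vanishes while `f_in > 0`.
#' @export
pull_per_filament <- function(phi, geom, f_in) {
  if (f_in == 0) return(0)
  lat <- phi$lattice
  inner <- lat_rbar(lat) * lat$spacing < geom$rL_in
  F_in <- sum(phi$values[inner, ])
  if (F_in <= 0) return(Inf)
  n_fil <- F_in / (2 * geom$y_nuc / A_STEP)
  f_in / n_fil
}

# ---------------------------------------------------------------------------
# Force balance: vertical placement of the membrane profile.

# Forbidden intervals repacked as NA-padded (n_lat x kmax) matrices of
# interval tops and bottoms, so the overlap force can be evaluated without
# touching the list-of-matrices representation in the bisection loop.
interval_matrices <- function(intervals) {
  kmax <- max(vapply(intervals, nrow, 0L))
  nlat <- length(intervals)
  tops <- matrix(NA_real_, nlat, kmax)
  bots <- matrix(NA_real_, nlat, kmax)
  for (i in seq_len(nlat)) {
    iv <- intervals[[i]]
    if (nrow(iv)) {
      tops[i, seq_len(nrow(iv))] <- iv[, 2]
      bots[i, seq_len(nrow(iv))] <- iv[, 1]
    }
  }
  list(tops = tops, bots = bots)
}

# Pushing force at membrane offset b from the repacked intervals.
overlap_force_at <- function(values, y_nm, imat, b, k_rep) {
  f <- 0
  for (k in seq_len(ncol(imat$tops))) {
    tops <- imat$tops[, k]
    has <- which(!is.na(tops))
    if (!length(has)) next
    v <- if (length(has) == nrow(values)) values
         else values[has, , drop = FALSE]
    d <- outer(tops[has] + b, y_nm, "-")
    d[d < 0] <- 0
    bots <- imat$bots[has, k]
    if (any(is.finite(bots))) {
      d[outer(bots + b, y_nm, ">=")] <- 0
    }
    f <- f + sum(v * d)
  }
  k_rep * f
}

# Solve overlap_force(b) = f_target for the membrane offset b (monotone
# non-decreasing, piecewise linear in b).
solve_membrane_offset <- function(values, y_nm, imat, f_target, k_rep,
                                  b_lo, b_hi, tol = 1e-5) {
  f_hi <- overlap_force_at(values, y_nm, imat, b_hi, k_rep)
  while (f_hi < f_target && b_hi < b_lo + 1000) {
    b_hi <- b_hi + 20
    f_hi <- overlap_force_at(values, y_nm, imat, b_hi, k_rep)
  }
  f_lo <- overlap_force_at(values, y_nm, imat, b_lo, k_rep)
  while (f_lo > f_target && b_lo > b_hi - 1000) {
    b_lo <- b_lo - 20
    f_lo <- overlap_force_at(values, y_nm, imat, b_lo, k_rep)
  }
  for (it in seq_len(45)) {
    b_mid <- (b_lo + b_hi) / 2
    if (overlap_force_at(values, y_nm, imat, b_mid, k_rep) > f_target)
      b_hi <- b_mid
    else b_lo <- b_mid
    if (b_hi - b_lo < tol) break
  }
  (b_lo + b_hi) / 2
}

# ---------------------------------------------------------------------------
# Main simulation driver.

#' Run the coupled endocytosis simulation
#'
#' Integrates the 3D master equation for the F-actin distribution together
#' with the Las17 feedback equation, the molecular clutch, membrane shape
#' selection and force balance.  Per time step: (1) the density field is
#' advanced (branching source, spontaneous nucleation, severing); (2) the
#' Las17 count is updated with the branch-flux feedback; (3) the membrane is
#' repositioned so the overlap pushing force balances the current pulling
#' force, and the tip loads set the force-dependent branch length; (4) the
#' clutch drives the invagination depth; (5) the shape and pulling force for
#' the new depth are selected from the pretabulated family; (6) the
#' branching and nucleation fields are rebuilt on the new geometry.
#' The run is fully deterministic for a given configuration.
#'
#' @param config a configuration list from [default_config()] (possibly
#'   modified); see that function for the parameter groups.
#' @param family optionally, a pre-built [stand_in_family()] (rebuilt from
#'   `config$membrane` when omitted).
#' @return An object of class `endo_run`: list with `timecourse`
#'   (data frame: t, F, N, y_I, f_in, f_out, pull, lbar, v_out, v_in,
#'   membrane_offset, omega, balanced), summary scalars (`F_max`, `N_max`,
#'   `y_I_max`, `omega_time`, `pull_max`), the final density field, and the
#'   configuration.
#' @export
run_endocytosis <- function(config = default_config(), family = NULL) {
  geom <- do.call(region_geometry, config$geometry)
  rates <- do.call(rate_params, config$rates)
  mech <- do.call(mech_params, config$mech)
  npf <- do.call(npf_state, config$npf)
  if (is.null(family))
    family <- stand_in_family(do.call(membrane_params, config$membrane))
  dt <- config$run$dt
  Tend <- config$run$T
  ntheta <- config$lattice$ntheta
  delta <- LATTICE_DELTA

  nr <- config$lattice$nr
  y_hi <- max(mech$lbar_max + 5L,
              as.integer(ceiling((8 * family$R_Pi + geom$y_br) / delta)) + 5L)
  lat <- lattice_spec("cylindrical", nr = nr, ny = y_hi + 16L, y_lo = -15L)

  # initial condition: a ring of filaments at the ring inner radius,
  # one subunit per cell over yL < y < yL + lbar_max * a/2
  vals <- matrix(0, lat$n_lat, lat$ny)
  r_ring <- round(geom$rL_in / delta)
  rows0 <- which(lat_ybar(lat) >= 1 & lat_ybar(lat) <= mech$lbar_max)
  vals[r_ring + 1L, rows0] <- 1
  phi <- density_field_3d(lat, vals)

  shape <- flat_shape(config$membrane$r_plateau)
  b <- 0          # vertical offset of the profile plateau (nm)
  y_I <- 0
  f_in <- 0
  f_out <- 0
  lbar_free <- mech$lbar_max
  f_share_out <- 0
  pull <- 0
  v_out <- 0
  v_in <- 0
  engaged <- FALSE
  area <- annulus_sites(lat)
  intervals <- forbidden_intervals(membrane_crossings(shape, lat))
  imat <- interval_matrices(intervals)
  konG <- mech$lbar_max * mech$k_cap   # zero-force tip speed in subunits/s

  n_steps <- as.integer(round(Tend / dt))
  rec_every <- max(1L, as.integer(round(config$run$record_dt / dt)))
  n_rec <- floor(n_steps / rec_every) + 1L
  rec <- matrix(NA_real_, n_rec, 13)
  colnames(rec) <- c("t", "F", "N", "y_I", "f_in", "f_out", "pull", "lbar",
                     "v_out", "v_in", "membrane_offset", "omega", "balanced")
  rec[1, ] <- c(0, total_factin(phi), npf$N, 0, 0, 0, 0, lbar_free,
                0, 0, b, 0, 0)
  ri <- 1L

  snap_times <- config$run$snapshot_times
  snapshots <- list()

  for (step in seq_len(n_steps)) {
    lat <- phi$lattice
    y_nm <- lat_ybar(lat) * delta

    # (6 of previous iteration / initial) rate fields on current geometry
    geom$yL <- b
    geom$yS <- b + y_I
    kbr <- kbr_field(geom, rates, lat)
    knuc_cells <- knuc_field(geom, rates, lat) * area

    # (1) master-equation step with membrane-limited branch lengths
    lb_rows <- lbar_row_profile(lat, mech, b)
    lprof <- length_profile_spec(lb_rows, mech$lbar_max)
    src <- branch_source_3d(phi, kbr, npf$N, lprof, ntheta)
    phi <- step_field(phi, src, knuc_cells, rates$ksev, dt)

    # (2) NPF feedback
    F_br <- branch_flux(phi, kbr)
    npf <- step_npf(npf, F_br, dt)
    F_tot <- total_factin(phi)

    # (3) force balance and tip loads.  Before the clutch engages, turgor
    # presses the membrane flat against the cell wall and it stays pinned;
    # the network grows against the static wall.  Once the clutch engages,
    # the membrane is repositioned each step so the overlap repulsion
    # balances the pulling force (floored at the small nominal contact
    # force f_pin, which regularizes the zero-force contact at the moment
    # of engagement): it then recedes from the growing network at a
    # deposition-limited rate, capped by the free ratchet speed.
    b_prev <- b
    engaged <- F_tot >= mech$F_min
    # only the outer-region (ring) network pushes: the spot filaments are
    # the pulling attachment, so the balance must not ride on them
    ring_rows <- lat_rbar(lat) * delta > geom$rL_in
    vals_ring <- phi$values
    vals_ring[!ring_rows, ] <- 0
    balanced <- FALSE
    if (engaged) {
      f_target <- max(f_in, mech$f_pin)
      jw <- which(y_nm > b - 60 & y_nm < b + y_I + 5)
      b_new <- solve_membrane_offset(vals_ring[, jw, drop = FALSE],
                                     y_nm[jw], imat, f_target,
                                     mech$k_rep, b_lo = b - 10, b_hi = b + 10)
      b <- max(b_new, b - konG * delta * dt)  # ratchet-limited recession
      balanced <- abs(b - b_new) < 1e-9
    }
    jo <- which(y_nm > b - 60 & y_nm < b + y_I + 5)
    f_out <- overlap_force_at(vals_ring[, jo, drop = FALSE], y_nm[jo],
                              imat, b, mech$k_rep)
    j_adj <- which.min(abs(y_nm - (b + delta)))
    n_tips <- max(sum(vals_ring[, j_adj]), 1e-9)
    f_share_out <- f_out / n_tips
    lbar_free <- max(0L, as.integer(floor(
      mech$lbar_max * exp(-f_share_out * mech$delta_y / mech$kT))))

    # (4) molecular clutch.  The outer polymerization velocity is the
    # membrane recession the force balance actually admits (the network
    # intercalates new subunits at the contact at a deposition-limited
    # rate); the inner velocity is the ratchet speed of the sparse
    # spot filaments under their per-filament pulling load.
    pull <- pull_per_filament(phi, geom, f_in)
    v_out <- max(0, (b_prev - b) / dt)
    v_in <- delta * konG * exp(-min(pull, 1e6) * mech$delta_y / mech$kT)
    y_I <- clutch_update(F_tot, v_out, v_in, mech$F_min, y_I, dt)
    # engagement intercalates the first subunit row; thereafter the depth
    # rides on the force-balance recession of the membrane plane
    if (engaged) y_I <- max(y_I, delta / 2)

    # (5) shape selection for the updated depth
    sel <- select_shape(family, y_I)
    if (!identical(sel$shape$y_I, shape$y_I)) {
      shape <- sel$shape
      intervals <- forbidden_intervals(membrane_crossings(shape, lat))
      imat <- interval_matrices(intervals)
    }
    f_in <- sel$f_in

    # lattice housekeeping: keep rows below the receding membrane
    if ((b / delta) - lat$y_lo < 12) {
      phi <- extend_field_rows(phi, add_below = 40L)
      intervals <- forbidden_intervals(membrane_crossings(shape, phi$lattice))
      imat <- interval_matrices(intervals)
    }

    t_now <- step * dt
    if (step %% rec_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(t_now, F_tot, npf$N, y_I, f_in, f_out,
                     if (is.finite(pull)) pull else NA_real_, lbar_free,
                     v_out, v_in, b, as.numeric(is_omega(shape)),
                     as.numeric(balanced))
    }
    if (length(snap_times) && any(abs(snap_times - t_now) < dt / 2)) {
      snapshots[[sprintf("t%.3f", t_now)]] <- phi
    }
  }

  tc <- as.data.frame(rec[seq_len(ri), , drop = FALSE])
  tc$omega <- tc$omega > 0
  tc$balanced <- tc$balanced > 0
  attr(tc, "config_hash") <- config_hash(config)
  with_y <- tc$y_I > 0
  structure(list(
    timecourse = tc,
    F_max = max(tc$F),
    N_max = max(tc$N),
    y_I_max = max(tc$y_I),
    omega_time = if (any(tc$omega)) min(tc$t[tc$omega]) else NA_real_,
    pull_max = if (any(with_y)) max(tc$pull[with_y], na.rm = TRUE)
               else NA_real_,
    phi = phi,
    snapshots = snapshots,
    config = config
  ), class = "endo_run")
}

#' @export
print.endo_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<endo_run> T = %.3g s: F_max = %.0f subunits, N_max = %.1f,\n",
    "  max invagination = %.1f nm, Omega onset = %s s, ",
    "peak pull per filament = %s pN\n"),
    max(x$timecourse$t), x$F_max, x$N_max, x$y_I_max,
    if (is.na(x$omega_time)) "never" else sprintf("%.2f", x$omega_time),
    if (is.na(x$pull_max)) "n/a" else sprintf("%.1f", x$pull_max)))
  invisible(x)
}

#' Scan a perturbation of branching, polymerization or nucleation
#'
#' Runs the endocytosis model once per scan fraction with the named
#' parameter(s) scaled down: `branch` scales the maximum branching rate
#' (CK-666-like), `polymerization` scales `k_on G` via the zero-force
#' length `lbar_max` (LatA acting on monomers only), `both` scales the two
#' together, and `nucleation` scales the spontaneous-nucleation rate.
#'
#' @param kind one of `"branch"`, `"polymerization"`, `"both"`,
#'   `"nucleation"`.
#' @param fractions vector of remaining-activity fractions in (0, 1].
#' @param config base configuration.
#' @param family optional pre-built shape family (shared across runs).
#' @return Data frame with one row per fraction: `fraction`, `F_max`,
#'   `N_max`, `y_I_max`, `pull_max`.
#' @export
scan_experiment <- function(kind = c("branch", "polymerization", "both",
                                     "nucleation"),
                            fractions, config = default_config(),
                            family = NULL) {
  kind <- match.arg(kind)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.null(family))
    family <- stand_in_family(do.call(membrane_params, config$membrane))
  rows <- lapply(fractions, function(fr) {
    cfg <- config
    if (kind %in% c("branch", "both"))
      cfg$rates$kbr_max <- cfg$rates$kbr_max * fr
    if (kind %in% c("polymerization", "both"))
      cfg$mech$lbar_max <- max(1L, as.integer(round(cfg$mech$lbar_max * fr)))
    if (kind == "nucleation")
      cfg$rates$knuc_max <- cfg$rates$knuc_max * fr
    run <- run_endocytosis(cfg, family = family)
    data.frame(fraction = fr, F_max = run$F_max, N_max = run$N_max,
               y_I_max = run$y_I_max, pull_max = run$pull_max)
  })
  do.call(rbind, rows)
}
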