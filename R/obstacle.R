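# Constant-force obstacle protocol: the validation workhorse.
#
# A branched network grows against a flat rigid obstacle that opposes
# polymerization with a constant external force.  The obstacle carries a
# strip of NPF (the 2D analogue of the Las17 ring); the branching layer
# rides on the obstacle.  At every step the obstacle is positioned so that
# the linear repulsion from actin penetrating past it balances the external
# force.  NPF feedback and severing are switched off, isolating branched
# network growth and force generation.

# Deterministic seed: n filaments of len subunits anchored across the strip
# with alternating directions.  A filament record (x0, y0, dir, len) holds
# subunits at (x0 + dir*j, y0 - j), j = 1..len, so the barbed (growing) end
# is the bottom subunit.
seed_filament_table <- function(n_init, len_init, strip_lo, strip_hi) {
  xs <- strip_lo + (seq_len(n_init) - 1L) %% (strip_hi - strip_lo + 1L)
  dirs <- rep_len(c(1L, -1L), n_init)
  data.frame(x0 = xs - dirs, y0 = len_init + 1L, dir = dirs,
             len = len_init)
}

filament_subunits <- function(fil) {
  j <- sequence(fil$len)
  i <- rep.int(seq_len(nrow(fil)), fil$len)
  data.frame(x = fil$x0[i] + fil$dir[i] * j, y = fil$y0[i] - j)
}

# Obstacle lattice for the strip geometry.
obstacle_lattice <- function(strip_sites, len_init, lbar_max, ny_extra = 30L) {
  margin <- len_init + lbar_max + 10L
  lattice_spec("planar", nx = strip_sites + 2L * margin,
               ny = len_init + ny_extra, x_lo = -margin,
               y_lo = -(ny_extra %/% 2L))
}

# Solve k_rep * sum_j h_j * (y - y_j)^+ = force for the obstacle height y,
# given the per-row subunit histogram h on rows at heights y_nm (ascending).
solve_obstacle_height <- function(h, y_nm, force, k_rep) {
  keep <- h > 0
  if (!any(keep)) stop("cannot balance an empty network")
  h <- h[keep]; y <- y_nm[keep]
  C <- cumsum(h)
  S <- cumsum(h * y)
  # force at the top of each interval
  f_at <- k_rep * (C * c(y[-1], Inf) - S)
  k <- which(f_at >= force)[1]
  (force / k_rep + S[k]) / C[k]
}

#' Master-equation obstacle run
#'
#' Evolves the 2D strip master equation against a flat obstacle exerting a
#' constant opposing force, with branch lengths limited by the
#' Brownian-ratchet load per tip and by the membrane repulsion, and the
#' obstacle repositioned each step by force balance.  Severing and NPF
#' feedback are disabled (validation protocol).
#'
#' @param force external force opposing polymerization (pN).
#' @param T run duration (s).
#' @param config configuration list; uses the `validation`, `geometry`,
#'   `rates` and `mech` groups.
#' @param record_dt trace recording interval (s).
#' @return List with `trace` (data frame: t, count, y_obs, lbar),
#'   `steady_count` (final F-actin count), and `velocity` (obstacle advance
#'   speed, nm/s, measured over the second half of the run).
#' @export
run_obstacle_me <- function(force, T = 60, config = default_config(),
                            record_dt = 0.5) {
  if (force <= 0) stop("the obstacle force must be positive")
  v <- config$validation
  geom <- do.call(region_geometry, config$geometry)
  mech <- do.call(mech_params, config$mech)
  kbr_max <- config$rates$kbr_max
  dt <- v$dt_me
  delta <- LATTICE_DELTA

  lat <- obstacle_lattice(v$strip_sites, v$len_init, mech$lbar_max)
  fil <- seed_filament_table(v$n_init, v$len_init, 0L, v$strip_sites - 1L)
  sub <- filament_subunits(fil)
  vals <- matrix(0, lat$n_lat, lat$ny)
  ix <- cbind(sub$x - lat$x_lo + 1L, sub$y - lat$y_lo + 1L)
  for (k in seq_len(nrow(ix))) vals[ix[k, 1], ix[k, 2]] <-
    vals[ix[k, 1], ix[k, 2]] + 1
  phi <- density_field_2d(lat, vals)

  strip <- lat_xbar(lat) >= 0 & lat_xbar(lat) <= v$strip_sites - 1L
  y_obs <- 0
  f_share <- 0
  n_steps <- as.integer(round(T / dt))
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  rec <- matrix(NA_real_, n_steps %/% rec_every + 2L, 4)
  colnames(rec) <- c("t", "count", "y_obs", "lbar")
  y_nm0 <- lat_ybar(lat) * delta
  rec[1, ] <- c(0, total_factin(phi),
                solve_obstacle_height(colSums(phi$values), y_nm0, force,
                                      mech$k_rep), mech$lbar_max)
  ri <- 1L

  for (step in seq_len(n_steps)) {
    lat <- phi$lattice
    y_nm <- lat_ybar(lat) * delta
    h <- colSums(phi$values)
    y_obs <- solve_obstacle_height(h, y_nm, force, mech$k_rep)
    j_adj <- which(y_nm > y_obs)[1]
    n_tips <- max(sum(phi$values[, j_adj]), 1e-9)
    f_share <- force / n_tips
    gvec <- gaussian_layer(y_nm, y_obs, geom$sigma_br, geom$y_br, kbr_max)
    kbr <- outer(strip, gvec)
    lb_rows <- lbar_row_profile(lat, mech, y_obs)
    lprof <- length_profile_spec(lb_rows, mech$lbar_max)
    src <- branch_source_2d(phi, kbr, v$N_val, lprof)
    phi <- step_field(phi, src, 0, 0, dt)
    if (step %% rec_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(step * dt, total_factin(phi), y_obs,
                     max(lb_rows))
    }
    if ((y_obs / delta) - lat$y_lo < 12) phi <- extend_field_rows(phi, 60L)
  }
  tr <- as.data.frame(rec[seq_len(ri), , drop = FALSE])
  half <- tr$t >= max(tr$t) / 2
  vel <- -stats::coef(stats::lm(y_obs ~ t, data = tr[half, ]))[["t"]]
  list(trace = tr, steady_count = tr$count[nrow(tr)], velocity = vel)
}
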