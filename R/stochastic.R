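# Explicit-filament stochastic simulator of branched network growth against
# a constant-force obstacle: the validation oracle for the master equation.
#
# Filaments live on the same lattice as the ME (+/-45 degree diagonals,
# lattice spacing a/2).  Branching events are drawn per mother subunit by
# fixed-increment tau-leaping; new branches appear instantly at their
# (force- and membrane-limited) final length, exactly mirroring the ME's
# instantaneous-polymerization assumption.  An optional explicit mode grows
# branches subunit by subunit with capping, to probe that approximation.

#' Stochastic obstacle-run configuration
#'
#' @param n_init number of seed filaments (default 400).
#' @param len_init seed filament length in subunits (default 50).
#' @param strip_sites width of the NPF strip in lattice sites.
#' @param N_val fixed NPF count on the obstacle (no feedback).
#' @param T run duration (s).
#' @param dt_stoch tau-leap increment (s).
#' @param dt_me ME time step used by the matching deterministic run (s).
#' @param n_runs ensemble size.
#' @param forces external force values (pN) for the validation scan.
#' @return A plain list (merged into the main configuration).
#' @export
stoch_config <- function(n_init = 400L, len_init = 50L, strip_sites = 48L,
                         N_val = 20, T = 60, dt_stoch = 0.02, dt_me = 0.02,
                         n_runs = 25L, forces = c(250, 500, 1000, 2000)) {
  stopifnot(n_init > 0, len_init > 0, strip_sites > 1, N_val > 0,
            T > 0, dt_stoch > 0, dt_me > 0, n_runs > 0, all(forces > 0))
  list(n_init = as.integer(n_init), len_init = as.integer(len_init),
       strip_sites = as.integer(strip_sites), N_val = N_val, T = T,
       dt_stoch = dt_stoch, dt_me = dt_me, n_runs = as.integer(n_runs),
       forces = forces)
}

# Allowed deposition length for a branch from mother row index jm (lattice
# row index): offsets j satisfying the row-resolved length limit
# j <= lbar(target row), which is contiguous from j = 1 because lbar is
# non-increasing toward the membrane.  The branching rate is evaluated at
# the mother subunit (as in the ME), so the NPF strip does not truncate
# deposition.  Returns the last allowed offset (0 = no branch).
branch_run_length <- function(jm, lb_rows, lbar_max) {
  jmax <- min(lbar_max, jm - 1L)
  if (jmax < 1L) return(0L)
  j <- seq_len(jmax)
  bad <- which(j > lb_rows[jm - j])
  if (length(bad)) bad[1] - 1L else jmax
}

#' Single stochastic obstacle run
#'
#' @param force external force (pN).
#' @param config configuration list (uses `validation`, `geometry`,
#'   `rates`, `mech` groups), see [default_config()].
#' @param seed RNG seed for this run.
#' @param mode `"instant"` (branches appear at final length; mirrors the
#'   ME) or `"explicit"` (branches start at one subunit, elongate at
#'   `k_on G` and cap at `k_cap`).
#' @param record_dt trace recording interval (s).
#' @return List with `trace` (t, count, y_obs, n_filaments),
#'   `steady_count`, `velocity` (nm/s) and the final filament table.
#' @export
run_stochastic_obstacle <- function(force, config = default_config(),
                                    seed = 1L, mode = c("instant",
                                                        "explicit"),
                                    record_dt = 0.5) {
  mode <- match.arg(mode)
  if (force <= 0) stop("the obstacle force must be positive")
  set.seed(seed)
  v <- config$validation
  geom <- do.call(region_geometry, config$geometry)
  mech <- do.call(mech_params, config$mech)
  kbr_max <- config$rates$kbr_max
  dt <- v$dt_stoch
  if (kbr_max * v$N_val * dt > 0.1)
    stop("dt_stoch too large: per-subunit branching probability > 0.1")
  if (mode == "explicit" && mech$k_on * mech$G * dt > 0.1)
    stop("dt_stoch too large for explicit polymerization")
  delta <- LATTICE_DELTA
  lat <- obstacle_lattice(v$strip_sites, v$len_init, mech$lbar_max)
  strip_lo <- 0L
  strip_hi <- v$strip_sites - 1L

  fil <- seed_filament_table(v$n_init, v$len_init, strip_lo, strip_hi)
  n_fil <- nrow(fil)
  cap <- 4L * n_fil
  x0 <- c(fil$x0, integer(cap)); y0 <- c(fil$y0, integer(cap))
  dir <- c(fil$dir, integer(cap)); len <- c(fil$len, integer(cap))
  capped <- c(rep(TRUE, n_fil), logical(cap))

  # per-row subunit histogram on lattice row indices
  ny <- lat$ny
  hist_rows <- numeric(ny)
  sub <- filament_subunits(fil)
  jrows <- sub$y - lat$y_lo + 1L
  for (j in jrows) hist_rows[j] <- hist_rows[j] + 1
  count <- nrow(sub)

  grow_store <- function() {
    extra <- length(x0)
    x0 <<- c(x0, integer(extra)); y0 <<- c(y0, integer(extra))
    dir <<- c(dir, integer(extra)); len <<- c(len, integer(extra))
    capped <<- c(capped, logical(extra))
  }
  extend_rows <- function(n_add) {
    hist_rows <<- c(numeric(n_add), hist_rows)
    lat$y_lo <<- lat$y_lo - n_add
    lat$ny <<- lat$ny + n_add
    ny <<- lat$ny
  }

  n_steps <- as.integer(round(v$T / dt))
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  rec <- matrix(NA_real_, n_steps %/% rec_every + 2L, 4)
  colnames(rec) <- c("t", "count", "y_obs", "n_filaments")
  y_nm0 <- (lat$y_lo + seq_len(ny) - 1L) * delta
  rec[1, ] <- c(0, count,
                solve_obstacle_height(hist_rows, y_nm0, force, mech$k_rep),
                n_fil)
  ri <- 1L
  konG_p <- mech$k_on * mech$G * dt
  kcap_p <- mech$k_cap * dt

  for (step in seq_len(n_steps)) {
    y_nm <- (lat$y_lo + seq_len(ny) - 1L) * delta
    y_obs <- solve_obstacle_height(hist_rows, y_nm, force, mech$k_rep)
    j_adj <- which(y_nm > y_obs)[1]
    n_tips <- max(hist_rows[j_adj], 1e-9)
    f_share <- force / n_tips
    g <- gaussian_layer(y_nm, y_obs, geom$sigma_br, geom$y_br, 1)
    cg <- c(0, cumsum(g))
    lb_rows <- lbar_row_profile(lat, mech, y_obs)

    # per-filament branching propensity: sum of the gaussian layer weight
    # over the filament's subunits that lie inside the NPF strip (the rate
    # is evaluated at the mother subunit).  The in-strip subunit indices
    # form a contiguous range because x moves monotonically along a branch.
    act <- seq_len(n_fil)
    j1s <- ifelse(dir[act] > 0L, strip_lo - x0[act], x0[act] - strip_hi)
    j2s <- ifelse(dir[act] > 0L, strip_hi - x0[act], x0[act] - strip_lo)
    j1s <- pmax(1L, j1s); j2s <- pmin(len[act], j2s)
    jtop <- y0[act] - 1L - lat$y_lo + 1L   # row index of subunit j = 1
    hi_idx <- jtop - j1s + 1L
    lo_idx <- jtop - j2s + 1L
    has <- j2s >= j1s & hi_idx >= 1L
    w <- numeric(n_fil)
    w[has] <- cg[pmax(hi_idx[has], 0L) + 1L] -
      cg[pmax(lo_idx[has] - 1L, 0L) + 1L]
    rate <- kbr_max * v$N_val * w
    nbr <- stats::rpois(n_fil, rate * dt)
    for (i in which(nbr > 0L)) {
      for (rep_k in seq_len(nbr[i])) {
        jt <- y0[i] - 1L - lat$y_lo + 1L
        rows <- (jt - j2s[i] + 1L):(jt - j1s[i] + 1L)
        wts <- g[rows]
        if (sum(wts) <= 0) next
        row_m <- if (length(rows) == 1L) rows else
          sample(rows, 1L, prob = wts)
        jsub <- jt - row_m + 1L           # subunit index on the mother
        xm <- x0[i] + dir[i] * jsub
        s <- sample(c(-1L, 1L), 1L)
        ltarget <- branch_run_length(row_m, lb_rows, mech$lbar_max)
        if (mode == "explicit") ltarget <- min(ltarget, 1L)
        if (ltarget < 1L) next
        n_fil <- n_fil + 1L
        if (n_fil > length(x0)) grow_store()
        x0[n_fil] <- xm; y0[n_fil] <- row_m + lat$y_lo - 1L
        dir[n_fil] <- s; len[n_fil] <- ltarget
        capped[n_fil] <- mode == "instant"
        new_rows <- row_m - seq_len(ltarget)
        hist_rows[new_rows] <- hist_rows[new_rows] + 1
        count <- count + ltarget
      }
    }

    if (mode == "explicit") {
      unc <- which(!capped[seq_len(n_fil)])
      if (length(unc)) {
        grow <- unc[stats::runif(length(unc)) < konG_p]
        for (i in grow) {
          jm_row <- y0[i] - lat$y_lo + 1L
          lnew <- branch_run_length(jm_row, lb_rows, mech$lbar_max)
          if (lnew >= len[i] + 1L) {
            len[i] <- len[i] + 1L
            r_new <- jm_row - len[i]
            hist_rows[r_new] <- hist_rows[r_new] + 1
            count <- count + 1L
          }
        }
        still <- which(!capped[seq_len(n_fil)])
        capped[still[stats::runif(length(still)) < kcap_p]] <- TRUE
      }
    }

    if (step %% rec_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(step * dt, count, y_obs, n_fil)
    }
    if ((y_obs / delta) - lat$y_lo < mech$lbar_max + 5L) extend_rows(60L)
  }

  tr <- as.data.frame(rec[seq_len(ri), , drop = FALSE])
  half <- tr$t >= max(tr$t) / 2
  vel <- if (sum(half) >= 3)
    -stats::coef(stats::lm(y_obs ~ t, data = tr[half, ]))[["t"]]
  else NA_real_
  list(trace = tr, steady_count = tr$count[nrow(tr)], velocity = vel,
       filaments = data.frame(x0 = x0[seq_len(n_fil)],
                              y0 = y0[seq_len(n_fil)],
                              dir = dir[seq_len(n_fil)],
                              len = len[seq_len(n_fil)],
                              capped = capped[seq_len(n_fil)]))
}

#' Stochastic ensemble against a constant force
#'
#' Runs `n_runs` independently seeded stochastic obstacle simulations and
#' returns the ensemble mean and standard deviation of the F-actin count
#' trace and of the obstacle velocity.
#'
#' @param force external force (pN).
#' @param config configuration list.
#' @param n_runs ensemble size (defaults to `config$validation$n_runs`).
#' @param seed base seed; run k uses `seed + k`.
#' @param record_dt trace recording interval (s).
#' @return List with `t`, `mean`, `sd` (count trace), `velocity_mean`,
#'   `velocity_sd`, and the matrix of per-run counts.
#' @export
run_ensemble <- function(force, config = default_config(), n_runs = NULL,
                         seed = 1L, record_dt = 0.5) {
  if (is.null(n_runs)) n_runs <- config$validation$n_runs
  counts <- NULL
  vels <- numeric(n_runs)
  tgrid <- NULL
  for (k in seq_len(n_runs)) {
    run <- run_stochastic_obstacle(force, config, seed = seed + k,
                                   record_dt = record_dt)
    if (is.null(counts)) {
      tgrid <- run$trace$t
      counts <- matrix(NA_real_, length(tgrid), n_runs)
    }
    counts[, k] <- run$trace$count
    vels[k] <- run$velocity
  }
  list(t = tgrid, mean = rowMeans(counts), sd = apply(counts, 1, stats::sd),
       velocity_mean = mean(vels), velocity_sd = stats::sd(vels),
       counts = counts)
}
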