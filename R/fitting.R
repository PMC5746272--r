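# Model fitting: normalized mean-square loss over Las17 and F-actin time
# courses, and a random accept-if-lower search over the four fitting
# parameters (k_0, kbr_max, ksev, alpha).  A synthetic-target generator
# stands in for measured fluorescence time courses, enabling
# parameter-recovery tests without external data.

#' Fitting targets
#'
#' Time-stamped Las17 and F-actin counts; either column may carry missing
#' values, but at least two points of each are required.
#'
#' @param t sample times (s).
#' @param N Las17 counts (NA allowed).
#' @param F F-actin counts (NA allowed).
#' @return Object of class `fit_targets`.
#' @export
fit_targets <- function(t, N, F) {
  if (sum(!is.na(N)) < 2L || sum(!is.na(F)) < 2L)
    stop("need at least two Las17 and two F-actin target points")
  if (max(N, na.rm = TRUE) <= 0 || max(F, na.rm = TRUE) <= 0)
    stop("target maxima must be positive")
  structure(list(t = t, N = N, F = F), class = "fit_targets")
}

#' Normalized mean-square loss against target time courses
#'
#' `eps = mean((N_mod - N_exp)^2) / max(N_exp)^2 +
#'        mean((F_mod - F_exp)^2) / max(F_exp)^2`,
#' each mean over that observable's target points, with the model curves
#' linearly interpolated at the target times.
#'
#' @param model_tc a model time course (data frame with columns t, N, F).
#' @param targets a [fit_targets()].
#' @return Non-negative loss value.
#' @export
fit_loss <- function(model_tc, targets) {
  part <- function(obs, col) {
    keep <- !is.na(obs)
    if (!any(keep)) return(0)
    tt <- targets$t[keep]
    if (min(tt) < min(model_tc$t) - 1e-9 || max(tt) > max(model_tc$t) + 1e-9)
      stop("model trace does not cover the target times")
    mod <- stats::approx(model_tc$t, model_tc[[col]], xout = tt)$y
    mean((mod - obs[keep])^2) / max(obs[keep])^2
  }
  part(targets$N, "N") + part(targets$F, "F")
}

#' Synthesize fitting targets from a forward run
#'
#' Runs the endocytosis model at the supplied parameters, samples the Las17
#' and F-actin curves at regular intervals and applies multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` (seeded).
#'
#' @param params named list overriding the four fitting parameters
#'   (`k_0`, `kbr_max`, `ksev`, `alpha`); defaults are the core values.
#' @param noise_cv coefficient of variation of the noise (0 = exact).
#' @param seed RNG seed.
#' @param config base configuration for the forward model.
#' @param spacing_s sample spacing (s), default 1.
#' @return A [fit_targets()].
#' @export
synthesize_targets <- function(params = list(), noise_cv = 0.02, seed = 1L,
                               config = default_config(), spacing_s = 1) {
  cfg <- apply_fit_params(config, params)
  run <- run_endocytosis(cfg)
  tt <- seq(spacing_s, max(run$timecourse$t), by = spacing_s)
  N <- stats::approx(run$timecourse$t, run$timecourse$N, xout = tt)$y
  F <- stats::approx(run$timecourse$t, run$timecourse$F, xout = tt)$y
  if (noise_cv > 0) {
    set.seed(seed)
    N <- N * (1 + noise_cv * stats::rnorm(length(N)))
    F <- F * (1 + noise_cv * stats::rnorm(length(F)))
  }
  fit_targets(tt, pmax(N, 0), pmax(F, 0))
}

apply_fit_params <- function(config, params) {
  allowed <- c("k_0", "kbr_max", "ksev", "alpha")
  bad <- setdiff(names(params), allowed)
  if (length(bad)) stop("unknown fitting parameter(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(params$k_0)) config$npf$k_0 <- params$k_0
  if (!is.null(params$alpha)) config$npf$alpha <- params$alpha
  if (!is.null(params$kbr_max)) config$rates$kbr_max <- params$kbr_max
  if (!is.null(params$ksev)) config$rates$ksev <- params$ksev
  config
}

#' Random accept-if-lower parameter search
#'
#' Perturbs the four fitting parameters with independent log-normal
#' proposals, accepting a proposal only when it strictly lowers the loss,
#' and stops after `stop_after` consecutive rejections (or `max_eval`
#' forward evaluations).  Proposals whose forward model fails are rejected
#' and counted as failures.
#'
#' @param targets a [fit_targets()].
#' @param start named list of starting values for `k_0`, `kbr_max`,
#'   `ksev`, `alpha` (defaults: the core values).
#' @param config base configuration for the forward model.
#' @param proposal_scale log-normal proposal scale (fractional, default 0.1).
#' @param stop_after consecutive-rejection stopping count (default 300).
#' @param max_eval hard cap on forward evaluations.
#' @param seed RNG seed.
#' @param family optional pre-built shape family shared across evaluations.
#' @return List with `params` (best values), `eps` (final loss),
#'   `eps_trace` (loss after each accepted move, non-increasing),
#'   `n_eval`, and `n_accept`.
#' @export
random_search_fit <- function(targets, start = list(), config = default_config(),
                              proposal_scale = 0.1, stop_after = 300L,
                              max_eval = 1000L, seed = 1L, family = NULL) {
  if (stop_after < 1L) stop("stop_after must be at least 1")
  defaults <- list(k_0 = config$npf$k_0, kbr_max = config$rates$kbr_max,
                   ksev = config$rates$ksev, alpha = config$npf$alpha)
  cur <- utils::modifyList(defaults, start)
  if (any(unlist(cur) <= 0)) stop("fitting parameters must be positive")
  if (is.null(family))
    family <- stand_in_family(do.call(membrane_params, config$membrane))
  set.seed(seed)
  forward <- function(p) {
    tc <- run_endocytosis(apply_fit_params(config, p), family = family)$timecourse
    fit_loss(tc, targets)
  }
  eps <- forward(cur)
  eps_trace <- eps
  n_eval <- 1L
  n_accept <- 0L
  fails <- 0L
  while (fails < stop_after && n_eval < max_eval) {
    # joint log-normal perturbations with a shrinking scale: full-scale
    # moves ride the kbr/ksev compensation ridge down in coordinated
    # steps, then two refinement phases close in on the minimum
    frac_used <- n_eval / max_eval
    sc <- proposal_scale *
      if (frac_used < 0.5) 1 else if (frac_used < 0.8) 0.5 else 0.25
    prop <- lapply(cur, function(x) x * exp(sc * stats::rnorm(1)))
    e <- tryCatch(forward(prop), error = function(e) Inf)
    n_eval <- n_eval + 1L
    if (e < eps) {          # ties count as rejections: strict descent
      cur <- prop
      eps <- e
      eps_trace <- c(eps_trace, eps)
      n_accept <- n_accept + 1L
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
  }
  list(params = cur, eps = eps, eps_trace = eps_trace,
       n_eval = n_eval, n_accept = n_accept)
}

#' Write / read fitting targets as delimited text
#'
#' Three tab-separated columns (t, N, F) with `NA` for missing values.
#'
#' @param targets a [fit_targets()].
#' @param path file path.
#' @return `path` invisibly / the `fit_targets`.
#' @export
write_fit_targets <- function(targets, path) {
  df <- data.frame(t = targets$t, N = targets$N, F = targets$F)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_targets
#' @export
read_fit_targets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fit_targets(df$t, df$N, df$F)
}
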