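# Loss function, synthetic targets, and the accept-if-lower search
# machinery (the expensive recovery experiment lives in the acceptance
# suite).

make_tc <- function(t, N, F) data.frame(t = t, N = N, F = F)

test_that("loss vanishes iff the model matches the targets", {
  t <- 0:10
  tc <- make_tc(t, N = 20 + t, F = 100 * t)
  tg <- fit_targets(t, N = 20 + t, F = 100 * t)
  expect_equal(fit_loss(tc, tg), 0)
  # constant offset on N only: eps = delta^2 / max(N)^2
  tg2 <- fit_targets(t, N = 20 + t + 3, F = 100 * t)
  expect_equal(fit_loss(tc, tg2), 9 / max(20 + t + 3)^2)
})

test_that("loss arithmetic on a 3-point fixture and reorder invariance", {
  tc <- make_tc(c(0, 1, 2), N = c(10, 20, 40), F = c(100, 200, 400))
  tg <- fit_targets(c(0, 1, 2), N = c(5, 10, 20), F = c(50, 100, 200))
  # model is targets x2: residuals equal the targets themselves
  eps_expected <- mean(c(5, 10, 20)^2) / 20^2 + mean(c(50, 100, 200)^2) / 200^2
  expect_equal(fit_loss(tc, tg), eps_expected)
  perm <- c(3, 1, 2)
  tg_perm <- fit_targets(c(0, 1, 2)[perm], N = c(5, 10, 20)[perm],
                         F = c(50, 100, 200)[perm])
  expect_equal(fit_loss(tc, tg_perm), fit_loss(tc, tg))
})

test_that("loss handles missing values per column and coverage errors", {
  tc <- make_tc(0:5, N = rep(10, 6), F = rep(50, 6))
  tg <- fit_targets(0:5, N = c(10, NA, 10, NA, 10, 10),
                    F = c(NA, 50, 50, 50, NA, 50))
  expect_equal(fit_loss(tc, tg), 0)
  tg_out <- fit_targets(c(0, 10), N = c(10, 10), F = c(50, 50))
  expect_error(fit_loss(tc, tg_out), "cover")
  expect_error(fit_targets(0:1, N = c(1, NA), F = c(1, 2)), "at least two")
})

test_that("targets files round-trip through delimited text", {
  tg <- fit_targets(1:6, N = c(20, 25, NA, 40, 40, 30),
                    F = c(NA, 100, 600, 4000, 3000, 1000))
  path <- tempfile(fileext = ".tsv")
  write_fit_targets(tg, path)
  back <- read_fit_targets(path)
  expect_equal(back$t, tg$t)
  expect_equal(back$N, tg$N)
  expect_equal(back$F, tg$F)
})

fit_test_cfg <- function() {
  cfg <- default_config()
  cfg$run$dt <- 0.05
  cfg$run$record_dt <- 0.2
  cfg$run$T <- 5
  cfg$lattice$ntheta <- 8L
  cfg$lattice$nr <- 70L
  cfg
}

test_that("synthetic targets are seeded and exact at zero noise", {
  cfg <- fit_test_cfg()
  tg0 <- synthesize_targets(noise_cv = 0, seed = 1, config = cfg)
  run <- run_endocytosis(cfg)
  expect_equal(tg0$N,
               stats::approx(run$timecourse$t, run$timecourse$N, tg0$t)$y)
  tg1 <- synthesize_targets(noise_cv = 0.05, seed = 9, config = cfg)
  tg2 <- synthesize_targets(noise_cv = 0.05, seed = 9, config = cfg)
  expect_identical(tg1$F, tg2$F)
  tg3 <- synthesize_targets(noise_cv = 0.05, seed = 10, config = cfg)
  expect_false(identical(tg1$F, tg3$F))
  # noise scale: coefficient of variation of the residuals ~ 5%
  cv <- stats::sd(tg1$F / pmax(tg0$F, 1e-9) - 1)
  expect_gt(cv, 0.025)
  expect_lt(cv, 0.10)
})

test_that("random search descends strictly and stays at a perfect start", {
  cfg <- fit_test_cfg()
  tg <- synthesize_targets(noise_cv = 0, seed = 1, config = cfg)
  fit <- random_search_fit(tg, config = cfg, stop_after = 5L,
                           max_eval = 12L, seed = 2)
  # started at the generating parameters: loss is already ~0
  expect_lt(fit$eps, 1e-12)
  expect_true(all(diff(fit$eps_trace) <= 0))
  fit2 <- random_search_fit(tg, start = list(kbr_max = 2.59e-3 * 1.3),
                            config = cfg, stop_after = 6L, max_eval = 25L,
                            seed = 3)
  expect_true(all(diff(fit2$eps_trace) <= 0))
  expect_gte(fit2$n_eval, 2L)
})
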