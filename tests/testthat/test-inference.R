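test_that("MAP fitting recovers a well-separated generating set at small scale", {
  p <- cliff_params_preset("WT")
  sims <- lapply(1:2, function(i) simulate_session(p, n_steps = 1500, seed = i)$series)
  fit <- cliff_hmm(sims, K = 3, starts = 2, seed = 1, se = FALSE,
                   control = list(maxit_stage1 = 15, maxit = 150))
  est <- coef(fit)
  expect_lt(abs(est[["m1"]] - 0.3) / 0.3, 0.1)
  expect_lt(abs(est[["m2"]] - 1.2) / 1.2, 0.1)
  expect_lt(abs(est[["m3"]] - 2.2) / 2.2, 0.1)
  expect_lt(abs(est[["rho_cliff2"]] - 0.8), 0.1)
  # ordering constraint holds by construction
  expect_true(all(diff(fit$par$step_mean) > 0))
  # the multi-start trace is sorted non-decreasing (monotone acceptance)
  expect_true(!is.unsorted(fit$opt_trace))
})

test_that("refitting with the same seed and data is deterministic", {
  p <- cliff_params_preset("OF")
  sims <- list(simulate_session(p, n_steps = 800, seed = 3)$series)
  f1 <- cliff_hmm(sims, starts = 2, seed = 5, se = FALSE,
                  control = list(maxit_stage1 = 10, maxit = 40))
  f2 <- cliff_hmm(sims, starts = 2, seed = 5, se = FALSE,
                  control = list(maxit_stage1 = 10, maxit = 40))
  expect_identical(f1$theta, f2$theta)
  expect_identical(coef(f1), coef(f2))
})

test_that("Laplace intervals bracket the point estimates and draws are usable", {
  p <- cliff_params_preset("WT")
  sims <- list(simulate_session(p, n_steps = 1200, seed = 4)$series)
  fit <- cliff_hmm(sims, starts = 1, seed = 2, se = TRUE, n_draws = 200,
                   control = list(maxit_stage1 = 10, maxit = 120))
  expect_true(all(fit$ci$lower <= fit$ci$estimate + 1e-9))
  expect_true(all(fit$ci$upper >= fit$ci$estimate - 1e-9))
  draws <- parameter_draws(fit, 5)
  expect_length(draws, 5)
  expect_s3_class(draws[[1]], "cliffhmm_pars")
  # draws satisfy the same structural constraints
  for (d in draws) expect_true(all(diff(d$step_mean) > 0))
})

test_that("single-state data fitted with K = 3 collapses the extra states", {
  # one gamma, one concentration, no covariate structure
  p1 <- cliff_hmm_params(step_mean = 1.0, step_shape = 3,
                         rho = matrix(0.5, 1, 4))
  sims <- lapply(1:2, function(i) simulate_session(p1, n_steps = 1500, seed = 90 + i)$series)
  fit <- cliff_hmm(sims, K = 3, starts = 2, seed = 3, se = FALSE,
                   control = list(maxit_stage1 = 10, maxit = 120))
  dec <- decode(fit$series, fit$par, mode = "local")
  occ <- as.numeric(table(factor(dec$state, 1:3))) / nrow(dec)
  # occupancy concentrates: the surplus states decay to small weight
  expect_gt(max(occ), 0.55)
  expect_lt(sort(occ)[1], 0.25)
  # and the occupied states' means are near the single truth
  k <- which.max(occ)
  expect_lt(abs(fit$par$step_mean[k] - 1.0) / 1.0, 0.25)
})

test_that("partial pooling shrinks animal estimates toward the group mean", {
  p <- cliff_params_preset("OF")
  sessions <- lapply(1:3, function(i)
    list(simulate_session(p, n_steps = 900, seed = 20 + i)$series))
  pooled <- fit_hierarchical(sessions, K = 3, seed = 7, starts = 1,
                             control = list(maxit_stage1 = 10, maxit = 80))
  expect_length(pooled$fits, 3)
  th <- t(vapply(pooled$fits, `[[`, pooled$fits[[1]]$theta, "theta"))
  sh <- t(vapply(pooled$shrunk, function(s) cliffhmm:::pack_params(s),
                 pooled$fits[[1]]$theta))
  mu <- colMeans(th)
  # per-parameter spread never increases under shrinkage
  v_raw <- apply(th, 2, var)
  v_shr <- apply(sweep(sh, 2, cliffhmm:::pack_params(pooled$group_params)), 2, var)
  expect_true(mean(v_shr <= v_raw + 1e-12) > 0.95)
  # single animal falls back with a warning
  expect_warning(
    fit_hierarchical(sessions[1], K = 3, seed = 7, starts = 1, se = FALSE,
                     control = list(maxit_stage1 = 5, maxit = 30)),
    "one animal")
})

test_that("mixture screen prefers the generating complexity", {
  set.seed(101)
  # 3-component gamma data at the canonical movement scales
  n <- 3000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))
  mns <- c(0.3, 1.2, 2.2)[comp]
  x <- rgamma(n, shape = 8, rate = 8 / mns)   # well-separated movement scales
  scr <- mixture_screen(x, families = "gamma", max_components = 3, seed = 2)
  expect_equal(scr$components[scr$recommended], 3)
  # single-gamma data: one component wins
  x1 <- rgamma(2000, shape = 3, rate = 3)
  scr1 <- mixture_screen(x1, families = "gamma", max_components = 3, seed = 3)
  expect_equal(scr1$components[scr1$recommended], 1)
  # 2-component wrapped-Cauchy angles: two components preferred over one
  phi <- c(rwrapped_cauchy(1500, 0.85), rwrapped_cauchy(1500, 0.1))
  scr2 <- mixture_screen(phi, families = "wrapped_cauchy", max_components = 3,
                         seed = 4)
  aic <- scr2$aicc
  expect_lt(aic[scr2$components == 2], aic[scr2$components == 1])
  # mixing ratios sum to one
  fits <- attr(scr2, "fits")
  expect_equal(sum(fits$wrapped_cauchy_2$par$w), 1, tolerance = 1e-9)
})

test_that("posterior predictive replication reproduces the model's own data", {
  p <- cliff_params_preset("WT")
  sims <- list(simulate_session(p, n_steps = 2500, seed = 5)$series)
  fit <- cliff_hmm(sims, starts = 1, seed = 6, se = FALSE,
                   control = list(maxit_stage1 = 10, maxit = 150))
  ppc <- posterior_predictive(fit, n_draws = 20, seed = 3)
  # observed histogram inside the replicate envelope for nearly every bin
  inside <- ppc$hist_l$observed >= ppc$hist_l$lower - 1 &
    ppc$hist_l$observed <= ppc$hist_l$upper + 1
  expect_gt(mean(inside), 0.95)
  inside_phi <- ppc$hist_phi$observed >= ppc$hist_phi$lower - 1 &
    ppc$hist_phi$observed <= ppc$hist_phi$upper + 1
  expect_gte(mean(inside_phi), 0.85)
  # no draws: empty summary without error
  ppc0 <- posterior_predictive(fit, n_draws = 0)
  expect_length(ppc0$replicates, 0)
  # seeded determinism
  a <- posterior_predictive(fit, n_draws = 3, seed = 11)
  b <- posterior_predictive(fit, n_draws = 3, seed = 11)
  expect_identical(a$replicates, b$replicates)
})

test_that("posterior predictive ACF tracks the observed autocorrelation", {
  p <- cliff_params_preset("WT")
  sim <- simulate_session(p, n_steps = 3000, seed = 12)
  fit <- cliff_hmm(list(sim$series), starts = 1, seed = 2, se = FALSE,
                   control = list(maxit_stage1 = 10, maxit = 150))
  obs_acf <- acf_series(sim$series$l, max_lag = 10)$acf
  set.seed(9)
  rep_acf <- replicate(15, {
    r <- cliffhmm:::replicate_series(list(sim$series), fit$par)
    acf_series(r$l, max_lag = 10)$acf
  })
  lo <- apply(rep_acf, 1, min); hi <- apply(rep_acf, 1, max)
  expect_gt(mean(obs_acf >= lo - 0.02 & obs_acf <= hi + 0.02), 0.9)
})

test_that("sample ACF satisfies its defining properties", {
  set.seed(102)
  # white noise: negligible autocorrelation at positive lags
  w <- acf_series(rnorm(10000), max_lag = 20)
  expect_equal(w$acf[1], 1)
  expect_true(all(abs(w$acf[-1]) < 0.03))
  # AR(1) with coefficient 0.5: lag-1 autocorrelation about 0.5
  x <- as.numeric(arima.sim(list(ar = 0.5), 20000))
  a <- acf_series(x, max_lag = 5)
  expect_lt(abs(a$acf[2] - 0.5), 0.02)
  expect_error(acf_series(rep(1, 100), 10), "constant")
  expect_error(acf_series(rnorm(10), 20), "length")
})

test_that("Metropolis refinement runs deterministically behind its flag", {
  p <- cliff_params_preset("OF")
  sims <- list(simulate_session(p, n_steps = 600, seed = 6)$series)
  f1 <- cliff_hmm(sims, starts = 1, seed = 4, se = TRUE, n_draws = 50,
                  mcmc = TRUE, mcmc_iter = 300,
                  control = list(maxit_stage1 = 5, maxit = 60))
  f2 <- cliff_hmm(sims, starts = 1, seed = 4, se = TRUE, n_draws = 50,
                  mcmc = TRUE, mcmc_iter = 300,
                  control = list(maxit_stage1 = 5, maxit = 60))
  expect_identical(f1$draws, f2$draws)
  expect_true(isTRUE(f1$mcmc))
  expect_equal(nrow(f1$theta_draws), 50)
})
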