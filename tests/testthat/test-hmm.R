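test_that("wrapped-Cauchy density: uniform limit, closed forms, normalization", {
  # rho = 0: circular uniform, density 1/(2*pi) = 0.159 at three decimals
  expect_equal(dwrapped_cauchy(c(-3, 0, 1, pi), 0), rep(1 / (2 * pi), 4))
  expect_equal(round(dwrapped_cauchy(0, 0), 3), 0.159)
  # rho = 0.5 at phi = 0: (1 + rho) / ((1 - rho) * 2 * pi) = 3 / (2 * pi)
  expect_equal(dwrapped_cauchy(0, 0.5), 3 / (2 * pi), tolerance = 1e-12)
  expect_equal(dwrapped_cauchy(0, 0.5), 0.47746, tolerance = 1e-4)
  # integrates to 1 across concentrations
  for (rho in c(0, 0.3, 0.8, 0.95)) {
    z <- integrate(dwrapped_cauchy, -pi, pi, rho = rho, rel.tol = 1e-10)
    expect_equal(z$value, 1, tolerance = 1e-8)
  }
  # sampler matches the density: first circular moment is rho
  set.seed(31)
  draws <- rwrapped_cauchy(2e4, 0.6)
  expect_lt(abs(mean(cos(draws)) - 0.6), 0.02)
  expect_lt(abs(mean(sin(draws))), 0.02)
})

test_that("gamma step emission has the stated mean and normalizes", {
  p <- cliff_params_preset("WT")
  p$step_mean <- c(0.3, 1.2, 2.2); p$step_shape <- c(2, 2, 6)
  # Monte-Carlo oracle: sampling from the density recovers the mean
  set.seed(32)
  draws <- rgamma(1e5, shape = 2, rate = 2 / 1.2)
  expect_lt(abs(mean(draws) - 1.2) / 1.2, 0.02)
  # density integrates to 1
  z <- integrate(function(l) exp(step_logpdf(l, 2, p)), 0, Inf)
  expect_equal(z$value, 1, tolerance = 1e-6)
  # large shape concentrates at the mean
  p$step_shape[3] <- 5e4
  mode_region <- integrate(function(l) exp(step_logpdf(l, 3, p)), 2.15, 2.25)$value
  expect_gt(mode_region, 0.99)
  expect_true(is.na(step_logpdf(0, 1, p)))
})

test_that("effective rho blends on the atanh scale with edge precedence", {
  p <- cliff_params_preset("WT")
  # no influences: basal
  expect_equal(effective_rho(1:3, 0, 0, 0, p), p$rho[, "basal"])
  # saturated edge: edge value regardless of the others
  expect_equal(effective_rho(1:3, 0.7, 1, 0.9, p), p$rho[, "edge"])
  # half cliff, nothing else: tanh(0.5 atanh(rho_cliff) + 0.5 atanh(rho_basal))
  p$rho[2, "basal"] <- 0.4; p$rho[2, "cliff"] <- 0.8
  got <- effective_rho(2, 0.5, 0, 0, p)
  expect_equal(got, tanh(0.5 * atanh(0.8) + 0.5 * atanh(0.4)), tolerance = 1e-12)
  expect_equal(round(got, 5), 0.64174)
  # monotone in each component concentration and bounded by the largest
  set.seed(33)
  for (i in 1:20) {
    I <- runif(3)
    rr <- sort(runif(4, 0, 0.95))
    p$rho[1, ] <- rr
    v <- effective_rho(1, I[1], I[2], I[3], p)
    expect_lte(v, max(rr) + 1e-12)
    p2 <- p
    p2$rho[1, ] <- pmin(p$rho[1, ] + c(0, 0.05, 0, 0), 0.99)  # raise rho_cliff
    expect_gte(effective_rho(1, I[1], I[2], I[3], p2), v - 1e-12)
  }
})

test_that("transition matrices are banded, row-stochastic softmax rows", {
  p0 <- cliff_params_preset("WT")
  p0$tpm_alpha[] <- 0; p0$tpm_beta[] <- 0
  G <- build_tpm(0.3, 0.6, 0.1, p0)
  expect_equal(G[1, ], c(1/2, 1/2, 0))
  expect_equal(G[2, ], c(1/3, 1/3, 1/3))
  expect_equal(G[3, ], c(0, 1/2, 1/2))
  # deeply negative intercept shuts a transition
  p0$tpm_alpha[1, 2] <- -20
  G2 <- build_tpm(0, 0, 0, p0)
  expect_equal(G2[1, 2], exp(-20) / (1 + exp(-20)), tolerance = 1e-15)
  expect_equal(G2[1, 1], 1, tolerance = 1e-8)
  # structural zeros and row sums across random parameter draws
  for (s in 1:25) {
    p <- random_params(seed = s)
    I <- runif(3)
    G3 <- build_tpm(I[1], I[2], I[3], p)
    expect_identical(G3[1, 3], 0)
    expect_identical(G3[3, 1], 0)
    expect_equal(rowSums(G3), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("stationary distribution solves pi Gamma = pi", {
  # doubly stochastic banded matrix: uniform
  G <- matrix(c(0.6, 0.4, 0, 0.4, 0.2, 0.4, 0, 0.4, 0.6), 3, 3, byrow = TRUE)
  expect_equal(stationary(G), rep(1/3, 3), tolerance = 1e-12)
  # frozen linear-solve oracle for the uniform-score banded TPM
  G2 <- matrix(c(0.5, 0.5, 0, 1/3, 1/3, 1/3, 0, 0.5, 0.5), 3, 3, byrow = TRUE)
  pi2 <- stationary(G2)
  expect_equal(pi2, c(2, 3, 2) / 7, tolerance = 1e-12)
  expect_equal(as.numeric(pi2 %*% G2), pi2, tolerance = 1e-12)
  # composition: stationary of the zero-coefficient TPM equals the same vector
  p0 <- cliff_params_preset("WT"); p0$tpm_alpha[] <- 0; p0$tpm_beta[] <- 0
  expect_equal(stationary(build_tpm(0.5, 0.5, 0.5, p0)),
               c(0.2857, 0.4286, 0.2857), tolerance = 1e-4)
  # reducible chain is refused with the absorbing state named
  Gr <- matrix(c(1, 0, 0, 0.5, 0.25, 0.25, 0, 0.5, 0.5), 3, 3, byrow = TRUE)
  expect_error(stationary(Gr), "absorbing")
  # property: pi reproduces itself under Gamma for random TPMs
  for (s in 1:25) {
    p <- random_params(seed = 100 + s)
    G4 <- build_tpm(runif(1), runif(1), runif(1), p)
    pi4 <- stationary(G4)
    expect_equal(as.numeric(pi4 %*% G4), pi4, tolerance = 1e-10)
    expect_true(all(pi4 >= 0))
  }
})

test_that("forward log-likelihood matches brute-force path enumeration", {
  # 50 random tiny instances, compiled and R routes against the oracle
  for (s in 1:50) {
    p <- random_params(seed = 200 + s)
    series <- make_toy_series(6, seed = 300 + s)
    bf <- brute_force_loglik(series, p)
    expect_equal(forward_loglik(series, p), bf, tolerance = 1e-10)
    expect_equal(cliffhmm:::forward_r(series, p)$loglik, bf, tolerance = 1e-10)
  }
  # varying lengths T <= 8
  for (Tn in c(1, 2, 5, 8)) {
    p <- random_params(seed = 400 + Tn)
    series <- make_toy_series(Tn, seed = 500 + Tn)
    expect_equal(forward_loglik(series, p), brute_force_loglik(series, p),
                 tolerance = 1e-10)
  }
})

test_that("K = 1 reduces to the sum of emission log densities", {
  p1 <- cliff_hmm_params(step_mean = 1.1, step_shape = 2.5,
                         rho = matrix(c(0.4, 0.5, 0.6, 0.3), 1, 4))
  series <- make_toy_series(40, seed = 35)
  direct <- sum(step_logpdf(series$l, 1, p1)) +
    sum(angle_logpdf(series$phi[series$w_angle > 0], 1,
                     series$I_cliff[series$w_angle > 0],
                     series$I_edge[series$w_angle > 0],
                     series$I_center[series$w_angle > 0], p1))
  expect_equal(forward_loglik(series, p1), direct, tolerance = 1e-9)
})

test_that("an impossible observation drives the likelihood to -Inf", {
  p <- cliff_params_preset("WT")
  series <- make_toy_series(10, seed = 36)
  series$l[5] <- 1e12    # essentially zero density in every state
  expect_equal(forward_loglik(series, p), -Inf)
})

test_that("likelihood is invariant to relabelling states", {
  p <- random_params(seed = 600)
  series <- make_toy_series(60, seed = 601)
  ll <- forward_loglik(series, p)
  # reverse the state order everywhere (bypasses the ordering constraint,
  # which exists only to anchor labels)
  K <- p$K; rev_i <- K:1
  p2 <- p
  p2$step_mean <- p$step_mean[rev_i]
  p2$step_shape <- p$step_shape[rev_i]
  p2$rho <- p$rho[rev_i, , drop = FALSE]
  p2$tpm_alpha <- p$tpm_alpha[rev_i, rev_i]
  for (f in dimnames(p$tpm_beta)[[3]])
    p2$tpm_beta[, , f] <- p$tpm_beta[rev_i, rev_i, f]
  expect_equal(forward_loglik(series, p2), ll, tolerance = 1e-9)
})

test_that("global decoding matches exhaustive path maximisation", {
  for (s in 1:12) {
    p <- random_params(seed = 700 + s)
    series <- make_toy_series(6, seed = 800 + s)
    dec <- decode(series, p, mode = "global")
    expect_equal(dec$state, brute_force_viterbi(series, p))
  }
})

test_that("posterior probabilities sum to one and ties break low", {
  p <- random_params(seed = 900)
  series <- make_toy_series(50, seed = 901)
  dec <- decode(series, p, mode = "local")
  expect_equal(unname(rowSums(dec[, c("p1", "p2", "p3")])), rep(1, 50), tolerance = 1e-10)
  expect_true(all(dec$state %in% 1:3))
  # identical emissions + symmetric TPM: posterior follows transitions only,
  # and the uniform-score chain makes state 2 most likely; forcing an exact
  # tie between states 1 and 3 picks state 1
  pe <- cliff_hmm_params(step_mean = c(1, 1 + 1e-12, 2e-12 + 1),
                         step_shape = rep(2, 3),
                         rho = matrix(0.5, 3, 4))
  se <- make_toy_series(10, seed = 902)
  de <- decode(se, pe, mode = "local")
  expect_equal(de$p1, de$p3, tolerance = 1e-6)
  expect_true(all(de$state %in% c(1, 2)))
})

test_that("well-separated states are decoded with high agreement", {
  p <- cliff_params_preset("WT")
  p$step_shape <- c(8, 30, 60)   # high shape: little emission overlap
  sim <- simulate_session(p, n_steps = 3000, seed = 37)
  dec <- decode(sim$series, p, mode = "global")
  expect_gt(mean(dec$state == sim$states$state), 0.9)
})
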