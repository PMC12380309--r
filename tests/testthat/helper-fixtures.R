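# Fixtures and independent oracles shared across tests.

# write a minimal pose CSV (DeepLabCut dialect) and return its path
write_dlc_fixture <- function(bodyparts = "bodycenter",
                              frames = 0:2,
                              coords = NULL,
                              likelihood = 1,
                              path = tempfile(fileext = ".csv")) {
  n <- length(frames)
  if (is.null(coords))
    coords <- lapply(bodyparts, function(b) cbind(x = seq_len(n), y = seq_len(n) * 2))
  lik <- rep_len(likelihood, n)
  hdr1 <- c("scorer", rep("model", 3 * length(bodyparts)))
  hdr2 <- c("bodyparts", rep(bodyparts, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(bodyparts)))
  rows <- cbind(frames, do.call(cbind, lapply(seq_along(bodyparts), function(i)
    cbind(coords[[i]][, 1], coords[[i]][, 2], lik))))
  con <- file(path, "w")
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  writeLines(apply(rows, 1, paste, collapse = ","), con)
  close(con)
  path
}

# standard_track straight from coordinates (already standardised, cm frame)
make_std_track <- function(x, y, fps = 10, geometry = arena_geometry()) {
  n <- length(x)
  structure(data.frame(time = (seq_len(n) - 1) / fps, x = x, y = y,
                       frame = seq_len(n) - 1L, likelihood = rep(1, n)),
            geometry = geometry, fps = fps,
            class = c("standard_track", "data.frame"))
}

# a small movement series with arbitrary (but in-arena) covariates, used for
# likelihood oracles where the spatial layout is irrelevant
make_toy_series <- function(Tn, seed = 1, geometry = arena_geometry()) {
  set.seed(seed)
  r <- 0.8 * geometry$radius * sqrt(runif(Tn))
  ang <- runif(Tn, -pi, pi)
  x0 <- r * cos(ang); y0 <- r * sin(ang)
  d <- arena_distances(x0, y0, geometry)
  s <- data.frame(time = seq_len(Tn) - 1, x0 = x0, y0 = y0,
                  l = rgamma(Tn, 2, 2), theta = runif(Tn, -pi, pi),
                  phi = runif(Tn, -pi, pi),
                  w_step = 1, w_angle = c(0, rep(1, Tn - 1L)), d)
  s <- add_influences(s, influence_params())
  structure(s, geometry = geometry, class = c("movement_series", "data.frame"))
}

# random valid parameter set (banded, ordered means)
random_params <- function(K = 3, seed = 1) {
  set.seed(seed)
  m <- sort(exp(rnorm(K, log(1), 0.5)))
  while (any(diff(m) < 1e-3)) m <- m + cumsum(rep(0.1, K))
  tr <- cliffhmm:::allowed_transitions(K)
  al <- matrix(0, K, K); al[tr] <- rnorm(nrow(tr), -1, 0.7)
  be <- array(0, c(K, K, 3), dimnames = list(NULL, NULL, c("cliff", "edge", "center")))
  for (f in 1:3) { b <- matrix(0, K, K); b[tr] <- rnorm(nrow(tr), 0, 0.5); be[, , f] <- b }
  cliff_hmm_params(step_mean = m, step_shape = runif(K, 1.5, 6),
                   rho = matrix(runif(4 * K, 0.05, 0.9), K, 4),
                   tpm_alpha = al, tpm_beta = be,
                   infl = influence_params(x_edge = runif(1, 2, 5),
                                           beta_edge = -runif(1, 1, 3),
                                           x_center = runif(1, 4, 12),
                                           beta_center = -runif(1, 1, 3)))
}

# ---- independent oracles ----

# brute-force HMM log-likelihood: sum over all K^T state paths
brute_force_loglik <- function(series, params) {
  series <- cliffhmm:::refresh_influences(series, params)
  lp <- cliffhmm:::emission_logprob(series, params)
  G <- cliffhmm:::tpm_series(series, params)
  Tn <- nrow(series); K <- params$K
  pi0 <- stationary(G[, , 1])
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  total <- -Inf
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    lpath <- log(pi0[st[1]]) + lp[1, st[1]]
    if (Tn > 1) for (t in 2:Tn)
      lpath <- lpath + log(G[st[t - 1], st[t], t]) + lp[t, st[t]]
    total <- max(total, lpath) + log1p(exp(min(total, lpath) - max(total, lpath)))
  }
  total
}

# brute-force most probable path
brute_force_viterbi <- function(series, params) {
  series <- cliffhmm:::refresh_influences(series, params)
  lp <- cliffhmm:::emission_logprob(series, params)
  G <- cliffhmm:::tpm_series(series, params)
  Tn <- nrow(series); K <- params$K
  pi0 <- stationary(G[, , 1])
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    lpath <- log(pi0[st[1]]) + lp[1, st[1]]
    if (Tn > 1) for (t in 2:Tn)
      lpath <- lpath + log(G[st[t - 1], st[t], t]) + lp[t, st[t]]
    if (lpath > best + 1e-12) { best <- lpath; best_path <- unname(st) }
  }
  best_path
}

# algebraic least-squares circle fit (Kasa), independent of the grid search
kasa_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  c(cx = sol[1], cy = sol[2], r = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}
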