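#' Simulate a session from the generative movement model
#'
#' Generates a trajectory in the circular arena from the full model: at each
#' step the influences at the current position feed the transition matrix,
#' the next state is sampled, a step length is drawn from the state's gamma
#' distribution and a turning increment from the wrapped Cauchy with the
#' effective concentration; the heading is updated and the position advanced.
#' Proposed positions leaving the arena are specularly reflected at the wall
#' and the realized step is recomputed from the realized positions, so the
#' recorded series is exactly what feature extraction would produce (a known
#' model/simulator mismatch confined to near-wall steps). Dropout frames get
#' a likelihood drawn uniformly below the 0.9 confidence threshold; all
#' others get 1.
#'
#' @param params [cliff_hmm_params()] (e.g. [cliff_params_preset()]).
#' @param n_steps Number of steps (>= 10); the track has `n_steps + 1`
#'   positions.
#' @param seed Integer seed; the whole session is reproducible from it.
#' @param geometry Standardised [arena_geometry()] (default 30 cm radius,
#'   centre at origin, cliff on `x = 0`).
#' @param start Start position (default the arena centre, where the entry
#'   platform sits).
#' @param heading0 Initial heading, radians (default `pi`: facing the shallow
#'   side).
#' @param fps Frame rate of the emitted track (default 10, the analysis rate
#'   after thinning a 30 fps video by 3).
#' @param noise Per-frame isotropic coordinate jitter s.d. (cm), default 0.
#' @param dropout Fraction of frames marked as low-confidence, default 0.
#' @return A list with `track` (a `raw_track` in standardised cm
#'   coordinates), `states` (true `state_sequence`-like data frame with
#'   `t`, `state`, `x`, `y`), `series` (the realized `movement_series`),
#'   `geometry`, and `params`.
#' @export
simulate_session <- function(params, n_steps = 6000, seed = 1,
                             geometry = arena_geometry(),
                             start = c(0, 0), heading0 = pi,
                             fps = 10, noise = 0, dropout = 0) {
  stopifnot(n_steps >= 10)
  if (max(params$step_mean) >= geometry$radius)
    stop("state step means must be smaller than the arena radius")
  if (sqrt(sum(start^2)) >= geometry$radius)
    stop("start position must lie inside the arena")
  set.seed(seed)
  K <- params$K
  r <- geometry$radius
  x <- numeric(n_steps + 1L); y <- numeric(n_steps + 1L)
  state <- integer(n_steps)
  x[1] <- start[1]; y[1] <- start[2]
  heading <- heading0
  s_cur <- NA_integer_
  for (t in seq_len(n_steps)) {
    d <- arena_distances(x[t], y[t], geometry)
    Ic <- influence(d$d_cliff, params$infl$cliff[["x"]], params$infl$cliff[["beta"]])
    Ie <- influence(d$d_edge, params$infl$edge[["x"]], params$infl$edge[["beta"]])
    Ict <- influence(d$d_center, params$infl$center[["x"]], params$infl$center[["beta"]])
    G <- build_tpm(Ic, Ie, Ict, params)
    s_cur <- if (t == 1L) sample.int(K, 1L, prob = stationary(G))
             else sample.int(K, 1L, prob = G[s_cur, ])
    state[t] <- s_cur
    l <- rgamma(1, shape = params$step_shape[s_cur],
                rate = params$step_shape[s_cur] / params$step_mean[s_cur])
    rho <- effective_rho(s_cur, Ic, Ie, Ict, params)
    heading <- .wrap_angle(heading + rwrapped_cauchy(1, rho))
    prop <- c(x[t] + l * cos(heading), y[t] + l * sin(heading))
    nxt <- reflect_into_arena(c(x[t], y[t]), prop, geometry)
    # realized heading after a reflection keeps the chain consistent with the
    # observable track
    if (!isTRUE(all.equal(nxt, prop)) && any(nxt != c(x[t], y[t])))
      heading <- atan2(nxt[2] - y[t], nxt[1] - x[t])
    x[t + 1L] <- nxt[1]; y[t + 1L] <- nxt[2]
  }
  if (noise > 0) {
    x <- x + rnorm(n_steps + 1L, 0, noise)
    y <- y + rnorm(n_steps + 1L, 0, noise)
    out <- sqrt(x^2 + y^2) > r
    if (any(out)) {
      sc <- (r - 1e-9) / sqrt(x[out]^2 + y[out]^2)
      x[out] <- x[out] * sc; y[out] <- y[out] * sc
    }
  }
  lik <- rep(1, n_steps + 1L)
  if (dropout > 0) {
    low <- runif(n_steps + 1L) < dropout
    lik[low] <- runif(sum(low), 0, 0.9)
  }
  frame <- 0:n_steps
  track <- new_raw_track(data.frame(frame = frame, time = frame / fps,
                                    x = x, y = y, likelihood = lik),
                         fps = fps)
  strack <- structure(data.frame(time = frame / fps, x = x, y = y,
                                 frame = frame, likelihood = lik),
                      geometry = geometry, fps = fps,
                      class = c("standard_track", "data.frame"))
  series <- movement_steps(strack, params$infl)
  list(track = track,
       states = data.frame(t = frame[-length(frame)] / fps, state = state,
                           x = x[-length(x)], y = y[-length(y)]),
       series = series, geometry = geometry, params = params)
}

#' Reflect a proposed position back into the arena
#'
#' Specular reflection across the tangent at the point where the movement
#' segment crosses the circular wall. Repeated reflections handle rare long
#' proposals; the result is strictly inside the arena.
#'
#' @param position Current position (inside the arena).
#' @param proposed Proposed next position.
#' @param geometry [arena_geometry()].
#' @return The realized position.
#' @export
reflect_into_arena <- function(position, proposed, geometry) {
  r <- geometry$radius * (1 - 1e-9)
  p <- as.numeric(position); q <- as.numeric(proposed)
  for (it in 1:20) {
    if (sum(q^2) < r^2) return(q)
    d <- q - p
    aa <- sum(d^2)
    if (aa == 0) return(p)
    bb <- 2 * sum(p * d)
    cc <- sum(p^2) - r^2
    disc <- bb^2 - 4 * aa * cc
    tt <- if (disc <= 0) 0 else (-bb + sqrt(disc)) / (2 * aa)
    hit <- p + tt * d                       # wall crossing
    nrm <- hit / sqrt(sum(hit^2))           # outward normal
    v <- q - hit
    v <- v - 2 * sum(v * nrm) * nrm         # reflect remainder across tangent
    p <- hit * (1 - 1e-12)
    q <- hit + v
  }
  q * (r * 0.999) / sqrt(sum(q^2))          # pathological fallback: pull inside
}

#' Simulate a batch of sessions and optionally write them to disk
#'
#' Convenience wrapper over [simulate_session()]: one call per session with
#' seeds `seed_base + 1 .. seed_base + n_sessions`, optionally writing each
#' session's pose CSV and truth table (t, state, x, y).
#'
#' @param params [cliff_hmm_params()].
#' @param n_sessions Number of sessions.
#' @param n_steps Steps per session.
#' @param seed_base Session `i` uses seed `seed_base + i`.
#' @param out_dir Optional output directory for CSV files.
#' @param ... Passed to [simulate_session()].
#' @return A list of [simulate_session()] results.
#' @export
simulate_batch <- function(params, n_sessions = 12, n_steps = 6000,
                           seed_base = 0, out_dir = NULL, ...) {
  sims <- lapply(seq_len(n_sessions), function(i)
    simulate_session(params, n_steps = n_steps, seed = seed_base + i, ...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(sims)) {
      write_pose_csv(sims[[i]]$track,
                     file.path(out_dir, sprintf("session%02d.csv", i)))
      write.csv(sims[[i]]$states,
                file.path(out_dir, sprintf("session%02d_truth.csv", i)),
                row.names = FALSE)
    }
  }
  sims
}
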