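#' Construct a synthetic spatial path through the arena
#'
#' Paths probe the fitted model: at every point the stationary state
#' distribution of the local transition matrix summarises behaviour "pinned"
#' to that location. Two stock kinds are provided, with marked comparison
#' points `a` and `b`:
#'
#' * `"horizontal"` — spans the diameter along `y = 0`, crossing centre and
#'   cliff line; default marks: `a` in the deep-end region (`x = 0.9 r`), `b`
#'   at the centre.
#' * `"circular"` — a circle of given `radius` (default the 30 cm wall, where
#'   edge and centre influences are constant and only the cliff influence
#'   varies); default marks: `a` at the cliff-line crossing `(0, radius)`,
#'   `b` at the shallow-side point farthest from the cliff `(-radius, 0)`.
#'
#' @param kind `"horizontal"`, `"circular"`, or `"custom"` (supply `points`).
#' @param geometry [arena_geometry()].
#' @param n_points Number of path points (default 361).
#' @param radius Circle radius for `kind = "circular"` (default the arena
#'   radius; must not exceed it).
#' @param a,b Optional custom marks: coordinates (length-2) snapped to the
#'   nearest path point.
#' @param points For `kind = "custom"`: a 2-column matrix of in-arena points.
#' @return A `spatial_path`: data frame `x`, `y` with attributes `a_index`,
#'   `b_index`, `kind`, `geometry`.
#' @export
make_path <- function(kind = c("horizontal", "circular", "custom"),
                      geometry = arena_geometry(), n_points = 361,
                      radius = NULL, a = NULL, b = NULL, points = NULL) {
  kind <- match.arg(kind)
  r <- geometry$radius
  if (kind == "horizontal") {
    xs <- seq(-r, r, length.out = n_points)
    pts <- cbind(x = xs, y = 0)
    a <- a %||% c(0.9 * r, 0)
    b <- b %||% c(0, 0)
  } else if (kind == "circular") {
    radius <- radius %||% r
    if (radius > r) stop("path radius exceeds the arena radius")
    ang <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    # start at the cliff-line crossing (0, radius) and run counter-clockwise
    pts <- cbind(x = radius * cos(ang + pi / 2), y = radius * sin(ang + pi / 2))
    a <- a %||% c(0, radius)
    b <- b %||% c(-radius, 0)
  } else {
    if (is.null(points)) stop("custom paths need `points`")
    pts <- as.matrix(points)
    colnames(pts) <- c("x", "y")
    if (is.null(a) || is.null(b)) stop("custom paths need explicit marks a and b")
  }
  if (any(pts[, 1]^2 + pts[, 2]^2 > (r + 1e-9)^2))
    stop("path leaves the arena")
  snap <- function(p) which.min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
  structure(as.data.frame(pts), a_index = snap(a), b_index = snap(b),
            kind = kind, geometry = geometry,
            class = c("spatial_path", "data.frame"))
}

#' Stationary state fractions along a path
#'
#' At each path point the spatial influences are evaluated, the local
#' transition matrix built, and its stationary distribution computed; the
#' profile of these distributions shows how the model redistributes
#' behavioural states across space.
#'
#' @param path A [make_path()] result.
#' @param params [cliff_hmm_params()].
#' @return A `state_profile`: matrix with one row per path point and one
#'   column per state (rows sum to 1), attributes `path` and `labels`.
#' @export
state_profile <- function(path, params) {
  geometry <- attr(path, "geometry")
  d <- arena_distances(path$x, path$y, geometry)
  Ic <- influence(d$d_cliff, params$infl$cliff[["x"]], params$infl$cliff[["beta"]])
  Ie <- influence(d$d_edge, params$infl$edge[["x"]], params$infl$edge[["beta"]])
  Ict <- influence(d$d_center, params$infl$center[["x"]], params$infl$center[["beta"]])
  prof <- t(vapply(seq_len(nrow(path)), function(i) {
    G <- build_tpm(Ic[i], Ie[i], Ict[i], params)
    tryCatch(stationary(G),
             error = function(e) stop(sprintf("point %d: %s", i, conditionMessage(e))))
  }, numeric(params$K)))
  colnames(prof) <- state_labels(params$K)
  structure(prof, path = path, labels = state_labels(params$K),
            class = c("state_profile", "matrix"))
}

#' @export
plot.state_profile <- function(x, ...) {
  K <- ncol(x)
  cols <- c("firebrick", "steelblue", "forestgreen", "orange", "purple")[seq_len(K)]
  matplot(seq_len(nrow(x)), unclass(x), type = "l", lty = 1, col = cols,
          xlab = "path point", ylab = "stationary fraction", ylim = c(0, 1), ...)
  path <- attr(x, "path")
  abline(v = c(attr(path, "a_index"), attr(path, "b_index")), lty = 3)
  legend("topright", colnames(x), col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' The cliff-effect statistic
#'
#' Per-state difference in stationary fractions between the marked path
#' points `a` (near the cliff) and `b` (reference):
#' `delta_k = pi_k(a) - pi_k(b)`. The components sum to zero by construction.
#' When posterior parameter draws are supplied the full posterior of each
#' difference is summarised by its 89% interval.
#'
#' @param profile A [state_profile()] (its path carries the marks), or a
#'   `cliff_hmm` fit (then `path` must be given and draws are taken from the
#'   fit).
#' @param path Required when `profile` is a fit.
#' @param draws Optional list of [cliff_hmm_params()] posterior draws.
#' @return A `cliff_effect` data frame: `state`, `delta`, and `lower`,
#'   `upper` (89%) when draws are available.
#' @export
cliff_effect <- function(profile, path = NULL, draws = NULL) {
  if (inherits(profile, "cliff_hmm")) {
    fit <- profile
    if (is.null(path)) stop("supply a path when computing the cliff effect from a fit")
    if (is.null(draws) && !is.null(fit$theta_draws))
      draws <- parameter_draws(fit, 400)
    profile <- state_profile(path, fit$par)
  }
  p <- attr(profile, "path")
  ia <- attr(p, "a_index"); ib <- attr(p, "b_index")
  if (is.null(ia) || is.null(ib)) stop("path has no marked points a and b")
  delta <- unclass(profile)[ia, ] - unclass(profile)[ib, ]
  out <- data.frame(state = colnames(profile), delta = as.numeric(delta))
  if (!is.null(draws)) {
    dd <- vapply(draws, function(par) {
      pr <- state_profile(p, par)
      unclass(pr)[ia, ] - unclass(pr)[ib, ]
    }, numeric(ncol(profile)))
    out$lower <- apply(dd, 1, quantile, 0.055)
    out$upper <- apply(dd, 1, quantile, 0.945)
  }
  structure(out, a = unlist(p[ia, ]), b = unlist(p[ib, ]),
            class = c("cliff_effect", "data.frame"))
}

#' Shallow-side rate
#'
#' The traditional visual-cliff preference metric: the fraction of retained
#' frames with the animal on the shallow (table) side, `x < 0`. In windowed
#' mode the cumulative running mean over time is returned as well.
#'
#' @param track A `standard_track` (or any data frame with `x` and `time`).
#' @param window Optional window length in seconds: return the running
#'   average sampled at multiples of `window`.
#' @return The overall fraction; with `window`, a list with `rate` and a
#'   data frame `running` (`time`, `rate`).
#' @export
shallow_side_rate <- function(track, window = NULL) {
  if (nrow(track) == 0L) stop("empty track: shallow-side rate undefined")
  shallow <- track$x < 0
  rate <- mean(shallow)
  if (is.null(window)) return(rate)
  stopifnot(window > 0)
  cum <- cumsum(shallow) / seq_along(shallow)
  at <- seq(window, max(track$time), by = window)
  idx <- vapply(at, function(tt) max(which(track$time <= tt)), 1L)
  list(rate = rate, running = data.frame(time = at, rate = cum[idx]))
}

#' Split a movement series into consecutive time windows
#'
#' Cuts the series on time boundaries (default 180 s = 3 min) so each window
#' can be fitted independently, e.g. to expose temporal drift in state
#' definitions. A step belongs to the window containing its start time;
#' windows never split a step.
#'
#' @param series A `movement_series`.
#' @param interval Window length in seconds (default 180).
#' @return A list of `movement_series`, one per non-empty window.
#' @export
window_split <- function(series, interval = 180) {
  stopifnot(interval > 0)
  t0 <- series$time[1]
  idx <- floor((series$time - t0) / interval)
  out <- lapply(split(seq_len(nrow(series)), idx), function(i) {
    w <- series[i, , drop = FALSE]
    rownames(w) <- NULL
    structure(w, geometry = attr(series, "geometry"),
              influence_params = attr(series, "influence_params"),
              class = class(series))
  })
  names(out) <- NULL
  out
}
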