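#' Logistic spatial influence function
#'
#' Maps a distance to a feature (cliff, edge, or centre) into `[0, 1]`:
#' `I(d) = 1 / (1 + exp(-beta * (d - x)))`. With a negative slope `beta` the
#' influence is close to 1 at the feature, exactly 0.5 at `d = x`, and decays
#' to 0 far away. The cliff influence uses the fixed pair `x = 6` cm,
#' `beta = -1` per cm.
#'
#' @param d Distance(s), cm, non-negative.
#' @param x Offset (cm): distance at which the influence is one half.
#' @param beta Slope (1/cm), negative for a decaying influence.
#' @return Influence value(s) in `[0, 1]`.
#' @export
influence <- function(d, x, beta) {
  stopifnot(all(d >= 0))
  plogis(beta * (d - x))
}

#' Influence-function parameters
#'
#' One offset/slope pair per spatial feature. The cliff pair is fixed at
#' `x = 6` cm, `beta = -1` (estimating it produces spurious effects in
#' cliff-free controls), while the edge and centre pairs are free parameters.
#'
#' @param x_cliff,beta_cliff Fixed cliff pair (do not change for fitting).
#' @param x_edge,beta_edge Edge influence offset (cm) and slope (1/cm).
#' @param x_center,beta_center Centre influence offset (cm) and slope (1/cm).
#' @return An `influence_params` list.
#' @export
influence_params <- function(x_cliff = 6, beta_cliff = -1,
                             x_edge = 3.2, beta_edge = -2,
                             x_center = 6.1, beta_center = -2) {
  stopifnot(x_cliff > 0, x_edge > 0, x_center > 0,
            beta_cliff < 0, beta_edge < 0, beta_center < 0)
  structure(list(
    cliff = c(x = unname(x_cliff), beta = unname(beta_cliff)),
    edge = c(x = unname(x_edge), beta = unname(beta_edge)),
    center = c(x = unname(x_center), beta = unname(beta_center))
  ), class = "influence_params")
}

#' Step lengths, headings and turning increments of a standardised track
#'
#' Each consecutive pair of retained positions defines a step with length
#' `l_t` (cm) and heading `theta_t` (four-quadrant arctangent); consecutive
#' headings define the wrapped turning increment `phi_t` in `(-pi, pi]`.
#' Spatial distances are evaluated at the step's start point (the state in
#' force decides the upcoming movement). Zero-length steps have no defined
#' heading: the previous heading is carried forward and the affected turning
#' increments get weight 0 so they are excluded from the angular likelihood;
#' the zero step length itself gets weight 0 for the step-length likelihood.
#'
#' @param track A `standard_track` (single gap-free segment, >= 3 rows).
#' @param params [influence_params()] used to attach influence covariates.
#' @return A `movement_series` data frame with one row per step: `time`,
#'   `x0`, `y0` (step start), `l`, `theta`, `phi`, `w_step`, `w_angle`,
#'   `d_cliff`, `d_edge`, `d_center`, `theta_edge`, `I_cliff`, `I_edge`,
#'   `I_center`; attribute `geometry`.
#' @export
movement_steps <- function(track, params = influence_params()) {
  n <- nrow(track)
  if (n < 3L)
    stop("need at least 3 positions (two headings) to build a movement series")
  geometry <- attr(track, "geometry")
  dx <- diff(track$x); dy <- diff(track$y)
  l <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  w_step <- as.numeric(l > 0)
  # carry headings across zero-length steps
  carried <- l == 0
  th <- theta
  for (t in seq_along(th)) {
    if (carried[t]) th[t] <- if (t > 1L) th[t - 1L] else NA_real_
  }
  nstep <- length(l)
  phi <- rep(0, nstep)
  w_angle <- rep(0, nstep)
  if (nstep >= 2L) {
    dphi <- .wrap_angle(th[-1L] - th[-nstep])
    phi[-1L] <- ifelse(is.na(dphi), 0, dphi)
    # an increment is usable only if this step has a real heading and a
    # (possibly carried) reference heading exists
    w_angle[-1L] <- as.numeric(!carried[-1L] & !is.na(th[-nstep]) & !is.na(dphi))
  }
  d <- arena_distances(track$x[-n], track$y[-n], geometry, heading = th)
  out <- data.frame(
    time = track$time[-n],
    x0 = track$x[-n], y0 = track$y[-n],
    l = l, theta = theta, phi = phi,
    w_step = w_step, w_angle = w_angle,
    d
  )
  out <- add_influences(out, params)
  structure(out, geometry = geometry, influence_params = params,
            class = c("movement_series", "data.frame"))
}

#' Attach influence covariates to a movement series
#'
#' @param series A `movement_series` (or data frame with `d_cliff`, `d_edge`,
#'   `d_center`).
#' @param params [influence_params()].
#' @return The series with `I_cliff`, `I_edge`, `I_center` columns
#'   (re)computed.
#' @export
add_influences <- function(series, params = influence_params()) {
  series$I_cliff <- influence(series$d_cliff, params$cliff["x"], params$cliff["beta"])
  series$I_edge <- influence(series$d_edge, params$edge["x"], params$edge["beta"])
  series$I_center <- influence(series$d_center, params$center["x"], params$center["beta"])
  attr(series, "influence_params") <- params
  series
}

#' Export a movement series as plain CSV
#'
#' @param series A `movement_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(series, path) {
  cols <- c("time", "l", "theta", "phi", "w_step", "w_angle",
            "d_cliff", "d_edge", "d_center", "I_cliff", "I_edge", "I_center")
  write.csv(as.data.frame(series)[, cols], path, row.names = FALSE)
  invisible(path)
}
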