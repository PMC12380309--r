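#' Arena geometry
#'
#' Container for the circular arena's calibration: centre and radius in the
#' source frame, the cliff-line angle relative to the vertical axis, and the
#' pixel-to-centimetre scale.
#'
#' @param center Numeric length-2, arena centre `(xc, yc)`.
#' @param radius Arena radius (same units as `center`).
#' @param cliff_angle Angle (radians) between the cliff line and the vertical
#'   axis, in `(-pi/2, pi/2]`.
#' @param px_per_cm Scale factor; `NULL` means "derive from the fitted radius
#'   and the known 30 cm arena radius" at standardisation time.
#' @return An `arena_geometry` object.
#' @export
arena_geometry <- function(center = c(0, 0), radius = 30, cliff_angle = 0,
                           px_per_cm = NULL) {
  stopifnot(length(center) == 2, is.finite(center), radius > 0)
  if (cliff_angle <= -pi / 2 || cliff_angle > pi / 2)
    stop("cliff_angle must lie in (-pi/2, pi/2]")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 cliff_angle = cliff_angle, px_per_cm = px_per_cm),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("Arena: centre (%.3f, %.3f), radius %.3f, cliff angle %.4f rad, scale %s\n",
              x$center[1], x$center[2], x$radius, x$cliff_angle,
              if (is.null(x$px_per_cm)) "unset" else format(x$px_per_cm)))
  invisible(x)
}

#' Fit the arena circle by iterative grid search
#'
#' Estimates the circular enclosure's centre and radius from positional data
#' by maximising the proportion of points lying inside a candidate circle.
#' For any fixed centre, the smallest circle covering a fraction `coverage`
#' of the points has radius equal to that quantile of the point-to-centre
#' distances, so the search walks a coarse-to-fine grid of centres and keeps
#' the centre whose coverage radius is smallest. Refinement halts when centre
#' and radius move by less than `tol` between passes.
#'
#' @param x,y Point coordinates (or `x` a 2-column matrix/data frame).
#' @param coverage Fraction of points the circle must contain (default 0.995,
#'   robust to sporadic tracking glitches outside the wall).
#' @param grid0 Initial grid spacing for the centre search (default 1).
#' @param tol Convergence tolerance for centre and radius (default 0.05).
#' @return An [arena_geometry()] with the fitted centre and radius
#'   (`cliff_angle = 0`, set later by [standardize_track()]).
#' @export
fit_circle <- function(x, y = NULL, coverage = 0.995, grid0 = 1, tol = 0.05) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 50L)
    stop("need at least 50 points to fit the arena circle")
  if (sd(x) < 1e-8 || sd(y) < 1e-8 || abs(cor(x, y)) > 0.999)
    stop("degenerate point cloud (collinear or clustered); cannot fit a circle")
  cx <- median(x); cy <- median(y)
  span <- max(diff(range(x)), diff(range(y)))
  h <- max(grid0, span / 20)
  radius_at <- function(cx, cy)
    as.numeric(quantile(sqrt((x - cx)^2 + (y - cy)^2), coverage, names = FALSE))
  r <- radius_at(cx, cy)
  repeat {
    gx <- cx + h * (-4:4)
    gy <- cy + h * (-4:4)
    cand <- expand.grid(cx = gx, cy = gy)
    rr <- mapply(radius_at, cand$cx, cand$cy)
    i <- which.min(rr)
    moved <- sqrt((cand$cx[i] - cx)^2 + (cand$cy[i] - cy)^2)
    dr <- abs(rr[i] - r)
    cx <- cand$cx[i]; cy <- cand$cy[i]; r <- rr[i]
    if (h <= tol && moved <= tol && dr <= tol) break
    h <- max(h / 3, tol / 2)
  }
  arena_geometry(center = c(cx, cy), radius = r)
}

#' Standardise a track to the cliff-aligned coordinate frame
#'
#' Translates coordinates so the arena centre maps to the origin, scales
#' pixels to centimetres, and rotates by minus the cliff angle so the cliff
#' boundary lies on `x = 0`. The shallow (table) side is oriented to `x < 0`
#' using a reference point known to lie on the shallow side; if the
#' transformed reference lands at `x > 0` the frame is rotated by a further
#' half turn (an orientation-preserving flip of the two sides).
#'
#' @param track A `raw_track` (or data frame with `x`, `y`).
#' @param cliff_p1,cliff_p2 Two distinct points on the cliff boundary, in the
#'   same source frame as `track`.
#' @param geometry An [arena_geometry()] fitted on the same session.
#' @param shallow_ref A point on the shallow side (source frame). Default
#'   `NULL` keeps the orientation implied by the rotation alone.
#' @param arena_radius_cm Physical arena radius used to derive the scale when
#'   `geometry$px_per_cm` is `NULL` (default 30 cm).
#' @return A `standard_track`: data frame with `time`, `x`, `y` (cm; plus
#'   `frame` and `likelihood` if present) and attribute `geometry`, the
#'   standardised [arena_geometry()] (centre at the origin, radius in cm,
#'   recorded cliff angle).
#' @export
standardize_track <- function(track, cliff_p1, cliff_p2, geometry,
                              shallow_ref = NULL, arena_radius_cm = 30) {
  if (isTRUE(all.equal(as.numeric(cliff_p1), as.numeric(cliff_p2))))
    stop("cliff points are coincident; cannot define the cliff line")
  s <- geometry$px_per_cm %||% (geometry$radius / arena_radius_cm)
  v <- as.numeric(cliff_p2) - as.numeric(cliff_p1)
  # counter-clockwise angle from the vertical axis to the cliff line,
  # reduced to (-pi/2, pi/2] (a line has no direction)
  theta <- atan2(-v[1], v[2])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  rot <- function(p, ang) {
    cbind(cos(ang) * p[, 1] - sin(ang) * p[, 2],
          sin(ang) * p[, 1] + cos(ang) * p[, 2])
  }
  xy <- cbind(track$x - geometry$center[1], track$y - geometry$center[2]) / s
  xy <- rot(xy, -theta)
  flipped <- FALSE
  if (!is.null(shallow_ref)) {
    ref <- rot(matrix((as.numeric(shallow_ref) - geometry$center) / s, 1), -theta)
    if (ref[1, 1] > 0) { xy <- -xy; flipped <- TRUE }
  }
  out <- data.frame(time = track$time %||% seq_len(nrow(track)) - 1,
                    x = xy[, 1], y = xy[, 2])
  if (!is.null(track$frame)) out$frame <- track$frame
  if (!is.null(track$likelihood)) out$likelihood <- track$likelihood
  geom_std <- arena_geometry(center = c(0, 0), radius = geometry$radius / s,
                             cliff_angle = theta, px_per_cm = 1)
  geom_std$flipped <- flipped
  structure(out, geometry = geom_std, fps = attr(track, "fps"),
            class = c("standard_track", "data.frame"))
}

#' Spatial distances within the standardised arena
#'
#' For standardised coordinates: the cliff distance is the absolute distance
#' to the cliff line `x = 0` (the same on both sides), the centre distance is
#' the Euclidean distance to the origin, and the edge distance is the
#' remaining distance to the circular wall, so `d_center + d_edge = r`
#' exactly. `theta_edge` is the direction tangent to the wall at the nearest
#' boundary point: the counter-clockwise tangent by default, or whichever of
#' the two tangents lies within a quarter turn of `heading` when supplied.
#'
#' @param x,y Standardised coordinates (vectorised).
#' @param geometry Standardised [arena_geometry()].
#' @param heading Optional movement heading(s), radians.
#' @param tol Out-of-arena tolerance in cm (default 1); points farther out are
#'   clamped to the wall with a warning.
#' @return A data frame with `d_cliff`, `d_edge`, `d_center`, `theta_edge`.
#' @export
arena_distances <- function(x, y, geometry, heading = NULL, tol = 1) {
  r <- geometry$radius
  d_center <- sqrt(x^2 + y^2)
  out_far <- d_center > r + tol
  if (any(out_far)) {
    warning(sprintf("%d point(s) lie more than %g cm outside the arena; clamped to the wall",
                    sum(out_far), tol))
    sc <- r / d_center[out_far]
    x[out_far] <- x[out_far] * sc
    y[out_far] <- y[out_far] * sc
    d_center[out_far] <- r
  }
  d_center <- pmin(d_center, r)
  psi <- atan2(y, x)
  tangent <- .wrap_angle(psi + pi / 2)  # counter-clockwise tangent
  if (!is.null(heading)) {
    alt <- .wrap_angle(psi - pi / 2)
    use_alt <- !is.na(heading) & abs(.wrap_angle(tangent - heading)) > pi / 2
    tangent[use_alt] <- alt[use_alt]
  }
  data.frame(d_cliff = abs(x), d_edge = r - d_center, d_center = d_center,
             theta_edge = tangent)
}

#' Write / read an arena geometry JSON sidecar
#'
#' @param geometry An [arena_geometry()].
#' @param path File path for the JSON sidecar.
#' @return `path` (write) or an [arena_geometry()] (read).
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- arena_geometry(center = g$center, radius = g$radius,
                         cliff_angle = g$cliff_angle,
                         px_per_cm = g$px_per_cm)
  geom$flipped <- isTRUE(g$flipped)
  geom
}
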