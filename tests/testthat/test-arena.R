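test_that("circle fit recovers exact circles and noisy disks", {
  set.seed(11)
  ang <- runif(500, 0, 2 * pi)
  g <- fit_circle(5 + 30 * cos(ang), -2 + 30 * sin(ang))
  expect_lt(abs(g$center[1] - 5), 0.1)
  expect_lt(abs(g$center[2] + 2), 0.1)
  expect_lt(abs(g$radius - 30), 0.1)

  # uniform disk + noise: compare against the algebraic least-squares fit
  rr <- 30 * sqrt(runif(5000)); aa <- runif(5000, 0, 2 * pi)
  x <- rr * cos(aa) + rnorm(5000, 0, 0.2)
  y <- rr * sin(aa) + rnorm(5000, 0, 0.2)
  g2 <- fit_circle(x, y)
  expect_lt(abs(g2$radius - 30), 0.5)
  # boundary points: Kasa fit as oracle on the outer shell
  shell <- sqrt(x^2 + y^2) > 28
  k <- kasa_circle(x[shell], y[shell])
  expect_lt(sqrt(sum((g2$center - k[1:2])^2)), 1.5)

  expect_error(fit_circle(seq_len(100), 2 * seq_len(100) + 1), "degenerate")
  expect_error(fit_circle(x[1:10], y[1:10]), "at least 50")
})

test_that("circle fit is rotation/translation equivariant", {
  set.seed(12)
  ang <- runif(400, 0, 2 * pi)
  rr <- 30 * sqrt(runif(400))
  x <- rr * cos(ang); y <- rr * sin(ang)
  g0 <- fit_circle(x, y)
  phi <- 0.7; shift <- c(12, -8)
  x2 <- cos(phi) * x - sin(phi) * y + shift[1]
  y2 <- sin(phi) * x + cos(phi) * y + shift[2]
  g1 <- fit_circle(x2, y2)
  expect_lt(abs(g1$radius - g0$radius), 0.11)
  c0 <- c(cos(phi) * g0$center[1] - sin(phi) * g0$center[2] + shift[1],
          sin(phi) * g0$center[1] + cos(phi) * g0$center[2] + shift[2])
  expect_lt(sqrt(sum((g1$center - c0)^2)), 0.3)
})

test_that("standardisation aligns the cliff line with x = 0", {
  geom <- arena_geometry(center = c(0, 0), radius = 30, px_per_cm = 1)
  tr <- data.frame(time = 0:2, x = c(1, 2, 3), y = c(0, 1, -1))
  # vertical cliff points, centre at origin: identity transform
  std <- standardize_track(tr, c(0, -30), c(0, 30), geom)
  expect_equal(std$x, tr$x, tolerance = 1e-12)
  expect_equal(std$y, tr$y, tolerance = 1e-12)
  # horizontal cliff points: quarter-turn, former y-axis becomes the cliff line
  std2 <- standardize_track(tr, c(-30, 0), c(30, 0), geom)
  expect_equal(attr(std2, "geometry")$cliff_angle, pi / 2)
  expect_equal(std2$x, tr$y, tolerance = 1e-12)

  expect_error(standardize_track(tr, c(1, 1), c(1, 1), geom), "coincident")
})

test_that("standardisation round-trips a rotated session and is an isometry", {
  set.seed(13)
  n <- 200
  x <- runif(n, -25, 25); y <- runif(n, -25, 25)
  phi <- runif(1, -1.2, 1.2)
  cen <- c(140, -60); s <- 4.2   # pixels: centre offset and scale
  X <- s * (cos(phi) * x - sin(phi) * y) + cen[1]
  Y <- s * (sin(phi) * x + cos(phi) * y) + cen[2]
  geom <- arena_geometry(center = cen, radius = 30 * s)
  p1 <- c(s * (cos(phi) * 0 - sin(phi) * -30) + cen[1],
          s * (sin(phi) * 0 + cos(phi) * -30) + cen[2])
  p2 <- c(s * (cos(phi) * 0 - sin(phi) * 30) + cen[1],
          s * (sin(phi) * 0 + cos(phi) * 30) + cen[2])
  ref <- c(s * (cos(phi) * -20) + cen[1], s * (sin(phi) * -20) + cen[2])
  std <- standardize_track(data.frame(time = seq_len(n), x = X, y = Y),
                           p1, p2, geom, shallow_ref = ref)
  expect_equal(std$x, x, tolerance = 1e-6)
  expect_equal(std$y, y, tolerance = 1e-6)
  # isometry: pairwise distances preserved
  i <- sample(n, 50); j <- sample(n, 50)
  d_std <- sqrt((std$x[i] - std$x[j])^2 + (std$y[i] - std$y[j])^2)
  d_orig <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  expect_equal(d_std, d_orig, tolerance = 1e-9)
})

test_that("shallow-side orientation follows the reference point", {
  geom <- arena_geometry(center = c(0, 0), radius = 30, px_per_cm = 1)
  tr <- data.frame(time = 0:1, x = c(10, -5), y = c(0, 3))
  std <- standardize_track(tr, c(0, -30), c(0, 30), geom, shallow_ref = c(15, 0))
  # reference on the positive side: frame rotated half a turn
  expect_equal(std$x, -tr$x, tolerance = 1e-12)
  expect_equal(std$y, -tr$y, tolerance = 1e-12)
})

test_that("arena distances satisfy the geometric identities", {
  geom <- arena_geometry()
  d <- arena_distances(-10, 0, geom)
  expect_equal(d$d_cliff, 10)
  expect_equal(d$d_center, 10)
  expect_equal(d$d_edge, 20)
  d0 <- arena_distances(0, 0, geom)
  expect_equal(unlist(d0[c("d_cliff", "d_center", "d_edge")]),
               c(d_cliff = 0, d_center = 0, d_edge = 30))
  d2 <- arena_distances(15, 15, geom)
  expect_equal(d2$d_center, 21.2132, tolerance = 1e-4)
  expect_equal(d2$d_edge, 8.7868, tolerance = 1e-4)
  expect_equal(d2$d_cliff, 15)

  # identity d_center + d_edge = r for random in-arena points
  set.seed(14)
  x <- runif(200, -20, 20); y <- runif(200, -20, 20)
  dd <- arena_distances(x, y, geom)
  expect_equal(dd$d_center + dd$d_edge, rep(30, 200), tolerance = 1e-12)
  expect_true(all(dd$d_cliff >= 0 & dd$d_cliff <= 30))

  # far-out points are clamped with a warning
  expect_warning(dc <- arena_distances(33, 0, geom), "clamped")
  expect_equal(dc$d_edge, 0)
})

test_that("edge tangent respects the supplied heading", {
  geom <- arena_geometry()
  # at (30, 0): tangents are +pi/2 (ccw) and -pi/2
  d <- arena_distances(30, 0, geom)
  expect_equal(d$theta_edge, pi / 2)
  d2 <- arena_distances(30, 0, geom, heading = -1.4)
  expect_equal(d2$theta_edge, -pi / 2)
})

test_that("geometry JSON sidecar round-trips", {
  g <- arena_geometry(center = c(3.2, -1.5), radius = 28.7, cliff_angle = 0.21,
                      px_per_cm = 4.5)
  f <- tempfile(fileext = ".json")
  write_geometry(g, f)
  g2 <- read_geometry(f)
  expect_equal(g2$center, g$center)
  expect_equal(g2$radius, g$radius)
  expect_equal(g2$cliff_angle, g$cliff_angle)
  expect_equal(g2$px_per_cm, g$px_per_cm)
})
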