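test_that("ground-plane estimation recovers exact, tilted, and contaminated floors", {
  pl0 <- estimate_ground_plane(point_cloud(matrix(rnorm(30), 10, 3)), "fixed_z0")
  expect_equal(pl0$normal, c(0, 0, 1))
  expect_equal(pl0$d, 0)

  set.seed(3)
  floor_xy <- cbind(runif(400, -2, 2), runif(400, -2, 2))
  flat <- point_cloud(cbind(floor_xy, 0))
  pf <- estimate_ground_plane(flat, "robust_fit")
  expect_equal(pf$normal, c(0, 0, 1), tolerance = 1e-6)
  expect_lt(abs(pf$d), 1e-6)

  # floor tilted 5 degrees about Y: recovered normal within 0.5 degrees
  ang <- 5 * pi / 180
  tilt <- transform_rotate(ang, "y")
  tilted <- apply_transform(flat, tilt)
  pt <- estimate_ground_plane(tilted, "robust_fit")
  n_true <- c(sin(ang), 0, cos(ang))
  expect_lt(acos(min(1, sum(pt$normal * n_true))) * 180 / pi, 0.5)

  # 20% outliers above the floor do not move the consensus plane
  outliers <- cbind(runif(100, -2, 2), runif(100, -2, 2), runif(100, 0.05, 1))
  dirty <- point_cloud(rbind(unclass(flat), outliers))
  pd <- estimate_ground_plane(dirty, "robust_fit", inlier_tol = 0.005)
  expect_equal(pd$normal, pf$normal, tolerance = 1e-3)
  expect_lt(abs(pd$d - pf$d), 1e-3)

  # collinear points cannot define a plane
  line <- point_cloud(cbind(1:10, 0, 0))
  expect_error(estimate_ground_plane(line, "robust_fit"), "collinear")
})

test_that("height_above_ground is the perpendicular distance in cm", {
  expect_equal(height_above_ground(c(0, 0, 1.431), plane(c(0, 0, 1), 0)), 143.1)
  expect_equal(height_above_ground(c(2, -1, 0), plane(c(0, 0, 1), 0)), 0)

  # tilted plane: matches brute-force minimum distance to a dense plane grid
  pl <- plane(c(0.3, -0.2, 0.93), -0.41)
  p <- c(0.7, 0.4, 1.2)
  g <- as.matrix(expand.grid(u = seq(-2, 2, length.out = 1500),
                             v = seq(-2, 2, length.out = 1500)))
  b1 <- c(-pl$normal[3], 0, pl$normal[1]); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(pl$normal[2] * b1[3] - pl$normal[3] * b1[2],
          pl$normal[3] * b1[1] - pl$normal[1] * b1[3],
          pl$normal[1] * b1[2] - pl$normal[2] * b1[1])
  origin <- -pl$d * pl$normal
  grid_pts <- sweep(g %*% rbind(b1, b2), 2L, origin, "+")
  brute <- min(sqrt(rowSums(sweep(grid_pts, 2L, p)^2))) * 100
  expect_lt(abs(height_above_ground(p, pl) - brute), 1e-3)
})

test_that("landmark_distance is the symmetric Euclidean distance in cm", {
  expect_equal(landmark_distance(c(0, -0.26, 0), c(0, 0.26, 0)), 52)
  expect_equal(landmark_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(11)
  for (k in 1:20) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    expect_equal(landmark_distance(p1, p2), sqrt(sum((p1 - p2)^2)) * 100)
    expect_identical(landmark_distance(p1, p2), landmark_distance(p2, p1))
  }
})

test_that("cross-section girth matches analytic circle, square, and ellipse sections", {
  # dense cylinder, r = 0.5
  set.seed(5)
  th <- runif(5000, 0, 2 * pi)
  cyl <- point_cloud(cbind(runif(5000, -1, 1), 0.5 * cos(th), 1 + 0.5 * sin(th)))
  expect_lt(abs(cross_section_girth(cyl, 0) - 100 * pi) / (100 * pi), 0.01)

  # four points forming a 1 m square: perimeter exactly 400 cm
  sq <- point_cloud(cbind(0, c(-0.5, 0.5, 0.5, -0.5), c(0, 0, 1, 1)))
  expect_equal(cross_section_girth(sq, 0, 0.001), 400)

  # elliptical section vs numeric arc-length oracle (and the Ramanujan form)
  a <- 0.35; b <- 0.30
  th <- runif(6000, 0, 2 * pi)
  ell <- point_cloud(cbind(runif(6000, -0.5, 0.5), a * cos(th), 1 + b * sin(th)))
  g <- cross_section_girth(ell, 0)
  oracle <- ellipse_perimeter_numeric(a, b) * 100
  expect_lt(abs(g - oracle) / oracle, 0.01)
  expect_lt(abs(ellipse_perimeter(a, b) * 100 - oracle) / oracle, 1e-6)

  # degenerate slabs fail loudly
  expect_error(cross_section_girth(cyl, 50), "point")
  expect_error(cross_section_girth(point_cloud(cbind(0, 1:5, 1)), 0), "collinear")
})

test_that("hull perimeter agrees with the brute-force hull oracle and is monotone", {
  set.seed(21)
  for (k in 1:15) {
    n <- sample(10:50, 1)
    y <- runif(n); z <- runif(n)
    cl <- point_cloud(cbind(0, y, z))
    expect_equal(cross_section_girth(cl, 0, 0.001),
                 brute_hull_perimeter(y, z) * 100, tolerance = 1e-10)
  }

  # adding interior points never changes the perimeter; exterior points never
  # decrease it
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  ring <- cbind(0, cos(th), sin(th))
  base <- cross_section_girth(point_cloud(ring), 0, 0.001)
  inside <- rbind(ring, cbind(0, runif(30, -0.4, 0.4), runif(30, -0.4, 0.4)))
  expect_equal(cross_section_girth(point_cloud(inside), 0, 0.001), base)
  outside <- rbind(ring, c(0, 1.5, 0))
  expect_gt(cross_section_girth(point_cloud(outside), 0, 0.001), base)
})

test_that("landmark detection finds the generator's landmarks and honors ties", {
  sp <- animal_shape_params(noise_sd = 0, points_per_view = 30000)
  cl <- generate_animal_cloud(sp, poses = identity_pose(), seed = 2)
  fused <- fuse_views(cl$views, cl$transforms)
  lm <- detect_landmarks(fused)
  expect_lt(landmark_distance(lm$withers, cl$landmarks$withers), 2)
  expect_lt(landmark_distance(lm$sacrum, cl$landmarks$sacrum), 2)
  expect_gt(lm$shoulder_posterior_left[2], 0)
  expect_lt(lm$shoulder_posterior_right[2], 0)

  # mirrored in Y: left/right swap, width identical
  mirrored <- point_cloud(unclass(fused) %*% diag(c(1, -1, 1)))
  lm2 <- detect_landmarks(mirrored)
  expect_equal(lm2$shoulder_posterior_left[2], -lm$shoulder_posterior_right[2],
               tolerance = 1e-12)
  expect_equal(landmark_distance(lm2$shoulder_posterior_left, lm2$shoulder_posterior_right),
               landmark_distance(lm$shoulder_posterior_left, lm$shoulder_posterior_right))

  # deterministic tie-break: two equal-height candidates -> lowest index wins
  flatpts <- rbind(c(0, 0, 0), c(1, 0, 0),                 # x extent
                   c(0.30, 0.1, 1.4), c(0.31, -0.1, 1.4),  # equal-height withers
                   c(0.8, 0, 1.2))
  lm3 <- detect_landmarks(point_cloud(flatpts), slab_halfwidth = 0.001)
  expect_equal(lm3$withers, flatpts[3, ], ignore_attr = TRUE)

  expect_error(detect_landmarks(point_cloud(matrix(c(0, 0, 0), 1, 3))), "extent")
})

test_that("measure_animal composes its components exactly and scales with the cloud", {
  sp <- animal_shape_params(points_per_view = 8000)
  cl <- generate_animal_cloud(sp, seed = 9)
  fused <- fuse_views(cl$views, cl$transforms)
  m <- measure_animal(fused, landmarks = cl$landmarks, plane = "fixed_z0")

  pl <- plane(c(0, 0, 1), 0)
  expect_identical(m$withers_height_cm, height_above_ground(cl$landmarks$withers, pl))
  expect_identical(m$hip_height_cm, height_above_ground(cl$landmarks$sacrum, pl))
  expect_identical(m$chest_width_cm,
                   landmark_distance(cl$landmarks$shoulder_posterior_left,
                                     cl$landmarks$shoulder_posterior_right))
  expect_identical(m$chest_girth_cm,
                   cross_section_girth(fused, cl$landmarks$shoulder_posterior_left[1]))

  # uniform scaling by 2 doubles every measurement
  doubled <- point_cloud(unclass(fused) * 2)
  lm2 <- landmark_set(cl$landmarks$withers * 2, cl$landmarks$sacrum * 2,
                      cl$landmarks$shoulder_posterior_left * 2,
                      cl$landmarks$shoulder_posterior_right * 2)
  m2 <- measure_animal(doubled, landmarks = lm2, plane = "fixed_z0",
                       slab_halfwidth = 0.02)
  expect_equal(m2$withers_height_cm, 2 * m$withers_height_cm)
  expect_equal(m2$hip_height_cm, 2 * m$hip_height_cm)
  expect_equal(m2$chest_width_cm, 2 * m$chest_width_cm)
  expect_equal(m2$chest_girth_cm, 2 * m$chest_girth_cm, tolerance = 1e-12)

  # rotation about Z together with the matching axis bookkeeping is neutral:
  # heights against the (unchanged) floor are invariant
  rot <- transform_rotate(0.4, "z")
  fr <- apply_transform(fused, rot)
  wr <- apply_transform(point_cloud(matrix(cl$landmarks$withers, 1, 3)), rot)
  expect_equal(height_above_ground(wr[1, ], pl), m$withers_height_cm,
               tolerance = 1e-9)
})

test_that("measurement errors are annotated with the failing component", {
  sq <- point_cloud(cbind(c(0, 1, 0.3, 0.8), 0, c(0, 0, 1.4, 1.2)))
  expect_error(measure_animal(sq, landmarks = landmark_set(
    c(0.3, 0, 1.4), c(0.8, 0, 1.2), c(50, 0.2, 1), c(50, -0.2, 1))),
    "chest girth")
})
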