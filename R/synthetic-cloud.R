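# Synthetic multi-view animal clouds with analytic ground-truth measurements.
#
# Body model: the torso is an elliptical cylinder along world X whose vertical
# upper semi-axis is modulated by two smooth (Gaussian-profile) dorsal ridges,
# the withers and the sacrum; cross-sections are therefore two half-ellipses
# sharing the lateral semi-axis, so every target measurement has a closed
# form. Ends taper elliptically to rounded caps; four leg cylinders set the
# height above the ground plane z = 0. World X is the anterior-posterior axis
# (head at low x), Y lateral (left = +Y), Z up.

WITHERS_XFRAC <- 0.30   # withers ridge center, fraction of body length
SACRUM_XFRAC  <- 0.82   # sacrum ridge center
RIDGE_SD_FRAC <- 0.05   # Gaussian ridge sd, fraction of body length
TAPER_FRAC    <- 0.08   # elliptical end-cap length, fraction of body length

#' Ramanujan's second approximation to the ellipse perimeter
#'
#' `P = pi (a + b) (1 + 3h / (10 + sqrt(4 - 3h)))` with
#' `h = ((a - b)/(a + b))^2`. The relative error is below 1e-9 for the mild
#' eccentricities of a cattle chest section, so it serves as the analytic
#' ground truth for the generated surfaces.
#'
#' @param a,b semi-axes (same units).
#' @return perimeter in the same units.
#' @export
ellipse_perimeter <- function(a, b) {
  if (any(c(a, b) < 0)) stop("semi-axes must be nonnegative")
  h <- ifelse(a + b == 0, 0, ((a - b) / (a + b))^2)
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Parameters of the synthetic animal surface
#'
#' Defines the generating surface and computes the four ground-truth
#' measurements analytically from it (they are properties of the surface, not
#' of any sampled cloud). The cross-section at the withers is the pair of
#' half-ellipses with lateral semi-axis `chest_radius_y`, lower vertical
#' semi-axis `chest_radius_z` and upper vertical semi-axis
#' `chest_radius_z * (1 + withers_ridge)`, so
#' `chest_girth_true = (P(ry, rz_up) + P(ry, rz)) / 2` with `P` the
#' Ramanujan perimeter.
#'
#' @param body_length torso length along x, meters.
#' @param chest_radius_y lateral semi-axis of the chest section, meters.
#' @param chest_radius_z lower vertical semi-axis, meters.
#' @param leg_length ground clearance of the mid-torso belly line, meters.
#' @param withers_ridge,sacrum_ridge relative elevation of the upper vertical
#'   semi-axis at the withers and sacrum (dimensionless, may be 0).
#' @param noise_sd per-coordinate Gaussian sensor noise, meters.
#' @param points_per_view surface samples emitted per camera view.
#' @return an object of class `animal_shape_params` including the four
#'   `*_true` measurements (cm).
#' @export
animal_shape_params <- function(body_length = 2.3, chest_radius_y = 0.261,
                                chest_radius_z = 0.42, leg_length = 0.57,
                                withers_ridge = 0.05, sacrum_ridge = 0.13,
                                noise_sd = 0.005, points_per_view = 20000) {
  if (any(c(body_length, chest_radius_y, chest_radius_z, leg_length) <= 0))
    stop("all lengths must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (points_per_view < 1) stop("points_per_view must be at least 1")
  if (withers_ridge < -0.9 || sacrum_ridge < -0.9)
    stop("ridge elevations must keep the upper semi-axis positive")
  p <- list(body_length = body_length, chest_radius_y = chest_radius_y,
            chest_radius_z = chest_radius_z, leg_length = leg_length,
            withers_ridge = withers_ridge, sacrum_ridge = sacrum_ridge,
            noise_sd = noise_sd, points_per_view = as.integer(points_per_view))
  z_center <- leg_length + chest_radius_z
  rz_up_w <- chest_radius_z * ridge_scale(WITHERS_XFRAC * body_length, p)
  rz_up_s <- chest_radius_z * ridge_scale(SACRUM_XFRAC * body_length, p)
  p$withers_height_true <- (z_center + rz_up_w) * 100
  p$hip_height_true <- (z_center + rz_up_s) * 100
  p$chest_width_true <- 2 * chest_radius_y * 100
  p$chest_girth_true <- (ellipse_perimeter(chest_radius_y, rz_up_w) +
                         ellipse_perimeter(chest_radius_y, chest_radius_z)) / 2 * 100
  class(p) <- "animal_shape_params"
  p
}

# dorsal ridge modulation of the upper vertical semi-axis at position x
ridge_scale <- function(x, p) {
  L <- p$body_length
  s <- RIDGE_SD_FRAC * L
  1 + p$withers_ridge * exp(-(x - WITHERS_XFRAC * L)^2 / (2 * s^2)) +
      p$sacrum_ridge  * exp(-(x - SACRUM_XFRAC  * L)^2 / (2 * s^2))
}

# elliptical end-cap taper factor in [0, 1]
taper_scale <- function(x, L) {
  e <- TAPER_FRAC * L
  s <- rep(1, length(x))
  lo <- x < e
  hi <- x > L - e
  s[lo] <- sqrt(pmax(0, 1 - ((e - x[lo]) / e)^2))
  s[hi] <- sqrt(pmax(0, 1 - ((x[hi] - (L - e)) / e)^2))
  s
}

#' Calibrate shape parameters to target measurements
#'
#' Inverts the analytic surface model: given target withers height, hip
#' height, chest width, and chest girth (cm), returns the
#' [animal_shape_params()] whose ground truths equal them. The withers ridge
#' elevation is fixed (default 5%) and the chest semi-axes are solved by a
#' 1-D root find on the girth equation; leg length and the sacrum ridge then
#' follow from the two heights.
#'
#' @param withers_height_cm,hip_height_cm,chest_width_cm,chest_girth_cm
#'   target measurements in cm.
#' @param body_length torso length, meters; default scales with stature.
#' @param withers_ridge relative withers elevation (dimensionless).
#' @param ... further arguments (noise_sd, points_per_view) passed to
#'   [animal_shape_params()].
#' @return an [animal_shape_params()] whose `*_true` fields equal the targets
#'   (to root-finding tolerance).
#' @export
shape_params_for_measurements <- function(withers_height_cm, hip_height_cm,
                                          chest_width_cm, chest_girth_cm,
                                          body_length = NULL,
                                          withers_ridge = 0.05, ...) {
  if (is.null(body_length)) body_length <- 1.6 * withers_height_cm / 100
  ry <- chest_width_cm / 200
  k <- 1 + withers_ridge
  girth_m <- chest_girth_cm / 100
  f <- function(rz) (ellipse_perimeter(ry, k * rz) + ellipse_perimeter(ry, rz)) / 2 - girth_m
  lo <- 1e-4; hi <- 2
  if (f(lo) > 0 || f(hi) < 0)
    stop("target girth is not attainable for this chest width")
  rz <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  leg <- withers_height_cm / 100 - rz - k * rz
  if (leg <= 0.05)
    stop("target withers height leaves no ground clearance for this girth")
  rz_up_s <- hip_height_cm / 100 - leg - rz
  sacrum_ridge <- rz_up_s / rz - 1
  if (sacrum_ridge < -0.9)
    stop("target hip height is inconsistent with the withers height and girth")
  animal_shape_params(body_length = body_length, chest_radius_y = ry,
                      chest_radius_z = rz, leg_length = leg,
                      withers_ridge = withers_ridge,
                      sacrum_ridge = sacrum_ridge, ...)
}

# Sample n points on the animal surface (world frame, noiseless).
sample_animal_surface <- function(p, n) {
  L <- p$body_length
  z_center <- p$leg_length + p$chest_radius_z
  n_torso <- ceiling(0.84 * n)
  n_leg <- ceiling(0.04 * n)
  x <- stats::runif(n_torso, 0, L)
  th <- stats::runif(n_torso, 0, 2 * pi)
  tp <- taper_scale(x, L)
  ry <- p$chest_radius_y * tp
  rz_lo <- p$chest_radius_z * tp
  rz_up <- rz_lo * ridge_scale(x, p)
  sn <- sin(th)
  y <- ry * cos(th)
  z <- z_center + ifelse(sn >= 0, rz_up, rz_lo) * sn
  torso <- cbind(x, y, z)
  legs <- list()
  leg_r <- 0.35 * p$chest_radius_y
  for (lx in c(0.18, 0.82) * L) for (ly in c(-0.5, 0.5) * p$chest_radius_y) {
    a <- stats::runif(n_leg, 0, 2 * pi)
    h <- stats::runif(n_leg, 0, p$leg_length + 0.5 * p$chest_radius_z)
    legs[[length(legs) + 1L]] <- cbind(lx + leg_r * cos(a), ly + leg_r * sin(a), h)
  }
  rbind(torso, do.call(rbind, legs))
}

#' Default camera poses for a three-view rig
#'
#' Camera-to-world rigid transforms for cameras left of, right of, and above
#' the animal walkway, at the working distances of a typical depth-camera
#' installation (side cameras ~2 m out, top camera ~3 m up).
#'
#' @param body_length torso length in meters, used to center the rig.
#' @return named list of three [rigid_transform()]s (`left`, `right`, `top`).
#' @export
default_view_poses <- function(body_length = 2.3) {
  cx <- body_length / 2
  list(
    left = compose_transforms(transform_translate(c(cx, 2, 1)),
                              transform_rotate(pi / 2, "x")),
    right = compose_transforms(transform_translate(c(cx, -2, 1)),
                               transform_rotate(-pi / 2, "x")),
    top = compose_transforms(transform_translate(c(cx, 0, 3)),
                             transform_rotate(pi, "x"))
  )
}

# which world-frame points are visible from a given side; margin lets the
# half-spaces overlap so the whole surface is covered by >= 1 view
view_keep <- function(pts, side, z_center, margin = 0.05) {
  switch(side,
    left = pts[, 2] >= -margin,
    right = pts[, 2] <= margin,
    top = pts[, 3] >= z_center - margin,
    all = rep(TRUE, nrow(pts)),
    stop(sprintf("unknown view side '%s'", side)))
}

#' Generate a multi-view synthetic animal cloud
#'
#' Samples the analytic animal surface, culls each view to the half-space
#' visible from its side (left / right / top), adds per-coordinate Gaussian
#' sensor noise, and expresses each view in its own camera frame so that
#' fusing the views with the returned true transforms reconstructs the
#' world-frame animal. Landmarks and ground-truth measurements are computed
#' analytically from the parameters, never from the sampled points.
#'
#' @param params an [animal_shape_params()].
#' @param poses named list of camera-to-world [rigid_transform()]s whose
#'   names are a subset of `left`, `right`, `top`; default
#'   [default_view_poses()]. Use `identity_pose()` for a single world-frame
#'   view.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return list with `views` (list of camera-frame [point_cloud()]s),
#'   `transforms` (the true camera-to-world transforms), `landmarks` (a
#'   world-frame [landmark_set()]), and `truth` (a [body_measurements()]).
#' @export
generate_animal_cloud <- function(params, poses = default_view_poses(params$body_length),
                                  seed = 1L) {
  if (!inherits(params, "animal_shape_params"))
    stop("`params` must be an animal_shape_params object")
  if (length(poses) < 1L) stop("at least one camera pose is required")
  if (is.null(names(poses)) || !all(names(poses) %in% c("left", "right", "top", "all")))
    stop("poses must be named with sides among 'left', 'right', 'top', 'all'")
  for (tp in poses) if (!inherits(tp, "rigid_transform"))
    stop("each pose must be a rigid_transform (degenerate matrices are rejected)")
  set.seed(seed)
  z_center <- params$leg_length + params$chest_radius_z
  n <- params$points_per_view
  views <- vector("list", length(poses))
  names(views) <- names(poses)
  for (v in names(poses)) {
    pts <- matrix(numeric(0), 0, 3)
    # rejection-sample until the view holds exactly n visible points
    while (nrow(pts) < n) {
      cand <- sample_animal_surface(params, 2L * n)
      pts <- rbind(pts, cand[view_keep(cand, v, z_center), , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    if (params$noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(3L * n, 0, params$noise_sd), n, 3L)
    views[[v]] <- apply_transform(point_cloud(pts, view = v),
                                  invert_transform(poses[[v]]))
  }
  L <- params$body_length
  x_w <- WITHERS_XFRAC * L
  x_s <- SACRUM_XFRAC * L
  lms <- landmark_set(
    withers = c(x_w, 0, params$withers_height_true / 100),
    sacrum = c(x_s, 0, params$hip_height_true / 100),
    shoulder_posterior_left = c(x_w, params$chest_radius_y, z_center),
    shoulder_posterior_right = c(x_w, -params$chest_radius_y, z_center))
  truth <- body_measurements(
    withers_height_cm = params$withers_height_true,
    hip_height_cm = params$hip_height_true,
    chest_width_cm = params$chest_width_true,
    chest_girth_cm = params$chest_girth_true)
  list(views = views, transforms = poses[names(views)],
       landmarks = lms, truth = truth)
}

#' Identity camera pose
#'
#' Convenience single-view pose: the camera frame equals the world frame and
#' the whole surface is visible (pseudo-side `"all"`).
#'
#' @return named list with one identity [rigid_transform()] (`all`).
#' @export
identity_pose <- function() list(all = rigid_transform(diag(4)))
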