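# Body measurements on a fused world-frame cloud: ground plane, landmark
# heuristics, landmark distances, and plane-slice convex-hull girth.

#' Construct a plane
#'
#' A plane is stored as a unit normal `n` and offset `d` with
#' `plane = {x : n . x + d = 0}`.
#'
#' @param normal length-3 normal vector (normalized internally).
#' @param d scalar offset (for the already-normalized normal).
#' @return an object of class `plane`.
#' @export
plane <- function(normal, d) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || !all(is.finite(normal)) || !is.finite(d))
    stop("a plane needs a finite 3-vector normal and scalar offset")
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be nonzero")
  structure(list(normal = normal / nn, d = d / nn), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane: n = (%.4f, %.4f, %.4f), d = %.4f>\n",
              x$normal[1], x$normal[2], x$normal[3], x$d))
  invisible(x)
}

#' Estimate the ground plane of a scene
#'
#' Either trusts the world-frame convention that the floor is z = 0
#' (`method = "fixed_z0"`, the default: the calibrated rig expresses clouds in
#' a frame whose origin sits on the floor) or fits a consensus plane to the
#' lowest part of the cloud by random sample consensus (`method =
#' "robust_fit"`). The fitted normal is always oriented upward (positive z
#' component).
#'
#' @param cloud a [point_cloud()].
#' @param method `"fixed_z0"` or `"robust_fit"`.
#' @param inlier_tol inlier distance tolerance in meters for the consensus
#'   fit.
#' @param lowest_frac fraction of lowest-z points used as floor candidates.
#' @param iterations number of random minimal samples.
#' @param seed RNG seed for the candidate sampling (fixed so the fit is
#'   deterministic).
#' @return a [plane()].
#' @export
estimate_ground_plane <- function(cloud, method = c("fixed_z0", "robust_fit"),
                                  inlier_tol = 0.01, lowest_frac = 0.2,
                                  iterations = 200, seed = 1L) {
  method <- match.arg(method)
  if (method == "fixed_z0") return(plane(c(0, 0, 1), 0))
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 3L) stop("robust_fit needs at least 3 points")
  zcut <- stats::quantile(cloud[, 3], lowest_frac, names = FALSE)
  cand <- unclass(cloud)[cloud[, 3] <= zcut, , drop = FALSE]
  if (nrow(cand) < 3L) cand <- unclass(cloud)
  set.seed(seed)
  best_inliers <- integer(0)
  for (i in seq_len(iterations)) {
    tri <- cand[sample.int(nrow(cand), 3L), , drop = FALSE]
    nrm <- crossprod_3d(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nl <- sqrt(sum(nrm^2))
    if (nl < 1e-12) next   # collinear sample
    nrm <- nrm / nl
    d <- -sum(nrm * tri[1, ])
    dist <- abs(cand %*% nrm + d)
    inl <- which(dist <= inlier_tol)
    if (length(inl) > length(best_inliers)) best_inliers <- inl
  }
  if (length(best_inliers) < 3L)
    stop("ground plane consensus failed: candidate floor points are collinear")
  fit_plane_lsq(cand[best_inliers, , drop = FALSE])
}

crossprod_3d <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# total-least-squares plane through a point set, upward-oriented normal
fit_plane_lsq <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("cannot fit a plane: points are collinear")
  nrm <- sv$v[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  if (nrm[3] == 0) stop("fitted ground plane is vertical; not a floor")
  plane(nrm, -sum(nrm * ctr))
}

#' Construct a landmark set
#'
#' Named anatomical points on a cloud, in the world frame (meters): the
#' withers (highest point of the shoulder ridge), the sacrum (highest point
#' of the rump), and the posterior corners of the left and right shoulder
#' blades. "Left" is the positive-Y side of the body midline.
#'
#' @param withers,sacrum,shoulder_posterior_left,shoulder_posterior_right
#'   length-3 numeric points in meters.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(withers, sacrum, shoulder_posterior_left,
                         shoulder_posterior_right) {
  lm <- list(withers = as.numeric(withers), sacrum = as.numeric(sacrum),
             shoulder_posterior_left = as.numeric(shoulder_posterior_left),
             shoulder_posterior_right = as.numeric(shoulder_posterior_right))
  for (nm in names(lm))
    if (length(lm[[nm]]) != 3L || !all(is.finite(lm[[nm]])))
      stop(sprintf("landmark '%s' must be a finite 3-vector", nm))
  structure(lm, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> [m]\n")
  for (nm in names(x))
    cat(sprintf("  %-26s (%.3f, %.3f, %.3f)\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Heuristic landmark detection
#'
#' Locates the four measurement landmarks on a fused cloud whose body axis is
#' world X (anterior at low x): the withers is the highest point within the
#' anterior window of the x extent, the sacrum the highest point within the
#' posterior window, and the shoulder-blade posterior corners the extreme +Y
#' and -Y points inside a vertical slab through the withers x position. Ties
#' are broken deterministically by the lowest point index.
#'
#' @param cloud a [point_cloud()], world frame, body axis along X.
#' @param anterior,posterior fractions of the x extent searched for the
#'   withers and sacrum respectively.
#' @param slab_halfwidth half-width in meters of the shoulder slab.
#' @return a [landmark_set()].
#' @export
detect_landmarks <- function(cloud, anterior = c(0.2, 0.45),
                             posterior = c(0.7, 0.95),
                             slab_halfwidth = 0.01) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0L) stop("cannot detect landmarks on an empty cloud")
  xr <- range(cloud[, 1])
  if (diff(xr) <= 0) stop("cloud spans no x extent; body axis must be X")
  frac <- (cloud[, 1] - xr[1]) / diff(xr)
  highest_in <- function(win, what) {
    sel <- which(frac >= win[1] & frac <= win[2])
    if (length(sel) == 0L)
      stop(sprintf("no points in the %s window [%.2f, %.2f] of the x extent",
                   what, win[1], win[2]))
    sel[which.max(cloud[sel, 3])]   # which.max takes the first (lowest index) on ties
  }
  iw <- highest_in(anterior, "anterior (withers)")
  is <- highest_in(posterior, "posterior (sacrum)")
  x_w <- cloud[iw, 1]
  slab <- which(abs(cloud[, 1] - x_w) <= slab_halfwidth)
  if (length(slab) == 0L) stop("empty shoulder slab at the withers x position")
  il <- slab[which.max(cloud[slab, 2])]
  ir <- slab[which.min(cloud[slab, 2])]
  landmark_set(withers = cloud[iw, ], sacrum = cloud[is, ],
               shoulder_posterior_left = cloud[il, ],
               shoulder_posterior_right = cloud[ir, ])
}

#' Height of a point above a plane, in centimeters
#'
#' The Euclidean (perpendicular) distance from the landmark to the ground
#' plane: `|n . p + d| * 100`.
#'
#' @param p length-3 point in meters.
#' @param plane a [plane()].
#' @return nonnegative height in cm.
#' @export
height_above_ground <- function(p, plane) {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) stop("`p` must be a finite 3-vector")
  abs(sum(plane$normal * p) + plane$d) * 100
}

#' Euclidean distance between two landmarks, in centimeters
#'
#' @param p1,p2 length-3 points in meters.
#' @return distance in cm; symmetric in its arguments.
#' @export
landmark_distance <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 3L || length(p2) != 3L || !all(is.finite(c(p1, p2))))
    stop("landmarks must be finite 3-vectors")
  sqrt(sum((p1 - p2)^2)) * 100
}

# Andrew monotone-chain convex hull of 2-D points; returns indices of hull
# vertices in counter-clockwise order, strictly convex (collinear boundary
# points dropped — the perimeter is unaffected).
convex_hull_2d <- function(y, z) {
  n <- length(y)
  ord <- order(y, z)
  cross <- function(o, a, b)
    (y[a] - y[o]) * (z[b] - z[o]) - (z[a] - z[o]) * (y[b] - y[o])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2L &&
             cross(h[length(h) - 1L], h[length(h)], i) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(ord)
  upper <- build(rev(ord))
  c(lower[-length(lower)], upper[-length(upper)])
}

#' Girth of a vertical cross-section, in centimeters
#'
#' Implements the plane-slice girth: points within a thin slab
#' `|x - x0| <= slab_halfwidth` are projected onto the (y, z) plane, the 2-D
#' convex hull of the projection is built, and the closed hull perimeter is
#' returned in cm. The convex hull under-measures concave sections by
#' construction; this is the intended definition.
#'
#' @param cloud a [point_cloud()], world frame, body axis along X.
#' @param x0 slab center along x, meters.
#' @param slab_halfwidth slab half-width in meters (default 1 cm: much larger
#'   than the point spacing of a fused depth-camera cloud, much smaller than
#'   the girth curvature scale).
#' @return girth in cm.
#' @export
cross_section_girth <- function(cloud, x0, slab_halfwidth = 0.01) {
  cloud <- as_point_cloud(cloud)
  sel <- which(abs(cloud[, 1] - x0) <= slab_halfwidth)
  if (length(sel) < 3L)
    stop(sprintf("girth slab at x = %.3f m (halfwidth %.3f m) holds %d point(s); need >= 3",
                 x0, slab_halfwidth, length(sel)))
  y <- cloud[sel, 2]; z <- cloud[sel, 3]
  h <- convex_hull_2d(y, z)
  if (length(h) < 3L)
    stop(sprintf("girth slab at x = %.3f m is degenerate: all %d points are collinear",
                 x0, length(sel)))
  yy <- c(y[h], y[h[1]]); zz <- c(z[h], z[h[1]])
  sum(sqrt(diff(yy)^2 + diff(zz)^2)) * 100
}

#' Construct a body-measurement record
#'
#' The four linear traits in centimeters plus an optional live weight in kg
#' (a pass-through datum, never computed from the cloud).
#'
#' @param withers_height_cm,hip_height_cm,chest_width_cm,chest_girth_cm
#'   measurements in cm, all positive.
#' @param live_weight_kg optional live weight, kg.
#' @return an object of class `body_measurements`.
#' @export
body_measurements <- function(withers_height_cm, hip_height_cm,
                              chest_width_cm, chest_girth_cm,
                              live_weight_kg = NA_real_) {
  vals <- c(withers_height_cm = withers_height_cm,
            hip_height_cm = hip_height_cm,
            chest_width_cm = chest_width_cm,
            chest_girth_cm = chest_girth_cm)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all four body measurements must be positive and finite")
  structure(list(withers_height_cm = withers_height_cm,
                 hip_height_cm = hip_height_cm,
                 chest_width_cm = chest_width_cm,
                 chest_girth_cm = chest_girth_cm,
                 live_weight_kg = live_weight_kg),
            class = "body_measurements")
}

#' @export
print.body_measurements <- function(x, ...) {
  cat("<body_measurements>\n")
  cat(sprintf("  withers height: %8.2f cm\n", x$withers_height_cm))
  cat(sprintf("  hip height:     %8.2f cm\n", x$hip_height_cm))
  cat(sprintf("  chest width:    %8.2f cm\n", x$chest_width_cm))
  cat(sprintf("  chest girth:    %8.2f cm\n", x$chest_girth_cm))
  if (is.finite(x$live_weight_kg))
    cat(sprintf("  live weight:    %8.2f kg (pass-through)\n", x$live_weight_kg))
  invisible(x)
}

#' @export
as.data.frame.body_measurements <- function(x, ...) {
  data.frame(withers_height_cm = x$withers_height_cm,
             hip_height_cm = x$hip_height_cm,
             chest_width_cm = x$chest_width_cm,
             chest_girth_cm = x$chest_girth_cm,
             live_weight_kg = x$live_weight_kg)
}

#' Measure one animal from a fused cloud
#'
#' Composes the component operations: withers and hip heights are the
#' perpendicular distances from the withers and sacrum landmarks to the
#' ground plane; chest width is the full 3-D Euclidean distance between the
#' paired shoulder-blade posterior corners; chest girth is the convex-hull
#' perimeter of the vertical cross-section at the shoulder-corner x position.
#' The result equals the direct component calls bit-for-bit.
#'
#' @param cloud fused world-frame [point_cloud()], body axis along X, ground
#'   at z = 0 by convention.
#' @param landmarks a [landmark_set()], or `"auto"` to run
#'   [detect_landmarks()].
#' @param plane a [plane()], `"fixed_z0"` (default) or `"robust_fit"` to run
#'   [estimate_ground_plane()] with that method.
#' @param slab_halfwidth girth slab half-width in meters.
#' @return a [body_measurements()].
#' @export
measure_animal <- function(cloud, landmarks = "auto", plane = "fixed_z0",
                           slab_halfwidth = 0.01) {
  cloud <- as_point_cloud(cloud)
  if (identical(landmarks, "auto")) {
    landmarks <- tryCatch(detect_landmarks(cloud, slab_halfwidth = slab_halfwidth),
                          error = function(e) stop("landmark detection: ", conditionMessage(e)))
  }
  if (!inherits(landmarks, "landmark_set")) stop("`landmarks` must be a landmark_set or \"auto\"")
  if (is.character(plane)) {
    plane <- estimate_ground_plane(cloud, method = plane)
  }
  if (!inherits(plane, "plane")) stop("`plane` must be a plane, \"fixed_z0\" or \"robust_fit\"")
  wrap <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", what, conditionMessage(e)), call. = FALSE))
  }
  wh <- wrap("withers height", height_above_ground(landmarks$withers, plane))
  hh <- wrap("hip height", height_above_ground(landmarks$sacrum, plane))
  cw <- wrap("chest width",
             landmark_distance(landmarks$shoulder_posterior_left,
                               landmarks$shoulder_posterior_right))
  x_girth <- mean(c(landmarks$shoulder_posterior_left[1],
                    landmarks$shoulder_posterior_right[1]))
  cg <- wrap("chest girth", cross_section_girth(cloud, x_girth, slab_halfwidth))
  body_measurements(withers_height_cm = wh, hip_height_cm = hh,
                    chest_width_cm = cw, chest_girth_cm = cg)
}
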