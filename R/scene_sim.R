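#' Pinhole camera model
#'
#' Intrinsics `(fx, fy, cx, cy)` in pixels and extrinsics mapping world mm to
#' camera coordinates as `X_cam = rotation %*% X_world + translation`, camera
#' x right, y down, z forward.
#'
#' @param fx,fy focal lengths in pixels (> 0); @param cx,cy principal point.
#' @param rotation 3x3 orthonormal world-to-camera rotation.
#' @param translation length-3 translation in mm.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, rotation, translation) {
  if (fx <= 0 || fy <= 0) stop("camera_model: focal lengths must be positive")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("camera_model: rotation is not orthonormal")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 rotation = rotation, translation = as.numeric(translation)),
            class = "camera_model")
}

#' Camera looking at a target point
#'
#' Convenience constructor: places the camera at `position`, aims the optical
#' axis at `target`, and levels it against `up`.
#'
#' @param position,target length-3 world points (mm).
#' @param up world up direction (default +z).
#' @inheritParams camera_model
#' @return a [camera_model()].
#' @export
camera_lookat <- function(position, target, up = c(0, 0, 1),
                          fx = 720, fy = 720, cx = 319.5, cy = 239.5) {
  f <- target - position
  f <- f / sqrt(sum(f^2))
  xc <- c(f[2] * up[3] - f[3] * up[2],
          f[3] * up[1] - f[1] * up[3],
          f[1] * up[2] - f[2] * up[1])
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-12) stop("camera_lookat: view direction parallel to up")
  xc <- xc / nx
  yc <- c(f[2] * xc[3] - f[3] * xc[2],
          f[3] * xc[1] - f[1] * xc[3],
          f[1] * xc[2] - f[2] * xc[1])
  R <- rbind(xc, yc, f)
  dimnames(R) <- NULL
  camera_model(fx, fy, cx, cy, R, -as.numeric(R %*% position))
}

camera_K <- function(cam) {
  matrix(c(cam$fx, 0, cam$cx,
           0, cam$fy, cam$cy,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' 3x4 projection matrix of a camera
#' @param cam a [camera_model()].
#' @return 3x4 matrix `K [R | t]`.
#' @export
camera_matrix <- function(cam) {
  camera_K(cam) %*% cbind(cam$rotation, cam$translation)
}

#' Camera centre in world coordinates
#' @param cam a [camera_model()].
#' @return length-3 vector (mm).
#' @export
camera_center <- function(cam) as.numeric(-t(cam$rotation) %*% cam$translation)

#' Project a world point
#'
#' Standard pinhole projection. Points behind the camera (non-positive
#' depth) are flagged via attribute `"behind"`.
#'
#' @param cam a [camera_model()]; @param X length-3 world point (mm).
#' @return a `plane_point` (pixels).
#' @export
project_point <- function(cam, X) {
  Xc <- as.numeric(cam$rotation %*% X + cam$translation)
  if (sqrt(sum(Xc^2)) < 1e-12)
    stop("project_point: point at the camera centre")
  v <- as.numeric(camera_K(cam) %*% Xc)
  p <- structure(normalize_h(v), class = "plane_point")
  attr(p, "behind") <- Xc[3] <= 0
  p
}

#' Project a world direction (vanishing point)
#'
#' The image of the ideal point of a family of world lines with direction
#' `d`: `K R d`. Directions parallel to the image plane map to ideal image
#' points.
#'
#' @param cam a [camera_model()]; @param d length-3 direction.
#' @return a `plane_point`, possibly ideal.
#' @export
project_direction <- function(cam, d) {
  v <- as.numeric(camera_K(cam) %*% cam$rotation %*% d)
  if (abs(v[3]) <= 1e-12 * max(abs(v))) v[3] <- 0
  structure(normalize_h(v), class = "plane_point")
}

#' Signed distance from the camera centre to a world plane
#'
#' The camera-geometry oracle for the interplanar operations: the distance
#' from the camera centre to the plane through `p0` with unit normal `n`.
#'
#' @param cam a [camera_model()]; @param p0 point on the plane (mm);
#' @param n plane normal (normalized internally).
#' @return signed distance in mm along `n`.
#' @export
camera_plane_distance <- function(cam, p0, n) {
  n <- n / sqrt(sum(n^2))
  sum((camera_center(cam) - p0) * n)
}

#' Resting height of the egg axis above the groove apex
#'
#' The V-groove carrier holds the egg by tangency of its maximal
#' cross-section circle (radius `b_e`) to the two groove walls, each at angle
#' `alpha` from the vertical bisector plane; the circle centre then sits at
#' `h = b_e / sin(alpha)` above the apex line. At `alpha = pi/2` (flat floor
#' limit) this is just `b_e`.
#'
#' @param b_e semi-minor axis of the egg in mm (> 0).
#' @param alpha groove half-angle in radians, in `(0, pi/2]`.
#' @return height in mm.
#' @export
resting_height <- function(b_e, alpha) {
  if (!is.numeric(b_e) || b_e <= 0) stop("resting_height: b_e must be positive")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > pi / 2 + 1e-12)
    stop("resting_height: alpha must lie in (0, pi/2]")
  b_e / sin(alpha)
}

#' Prolate-spheroid egg model
#'
#' The egg is modelled as an ellipsoid of revolution about its major axis:
#' semi-major `a_e`, semi-minor `b_e` (both equatorial radii equal). Ground
#' truth axis lengths are `2 a_e` and `2 b_e`.
#'
#' @param a_e,b_e semi-axes in mm, `a_e > b_e > 0`.
#' @param center world centre (mm); @param axis unit direction of the major
#'   axis.
#' @return object of class `egg_ellipsoid`.
#' @export
egg_ellipsoid <- function(a_e, b_e, center = c(0, 0, 0), axis = c(1, 0, 0)) {
  if (!(a_e > b_e && b_e > 0))
    stop("egg_ellipsoid: need a_e > b_e > 0")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(a_e = a_e, b_e = b_e, center = as.numeric(center),
                 axis = axis),
            class = "egg_ellipsoid")
}

# orthonormal frame with first column = major axis
egg_frame <- function(egg) {
  u <- egg$axis
  h <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- c(u[2] * h[3] - u[3] * h[2],
         u[3] * h[1] - u[1] * h[3],
         u[1] * h[2] - u[2] * h[1])
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(u, v, w, deparse.level = 0)
}

#' 4x4 quadric of the egg ellipsoid
#'
#' Symmetric homogeneous matrix `Q` with `X^T Q X < 0` inside the ellipsoid.
#'
#' @param egg an [egg_ellipsoid()].
#' @return 4x4 symmetric matrix.
#' @export
ellipsoid_quadric <- function(egg) {
  M <- egg_frame(egg)
  A <- M %*% diag(1 / c(egg$a_e^2, egg$b_e^2, egg$b_e^2)) %*% t(M)
  c0 <- egg$center
  Q <- rbind(cbind(A, -A %*% c0),
             c(-as.numeric(t(c0) %*% A), as.numeric(t(c0) %*% A %*% c0) - 1))
  (Q + t(Q)) / 2
}

#' Exact image silhouette of the egg
#'
#' Projects the ellipsoid's dual quadric through the camera
#' (`C* = P Q* P^T`) and inverts to obtain the silhouette conic — the exact
#' outline a perfect segmentation of the egg would produce. Normalized so
#' interior points give a negative quadratic form.
#'
#' @param egg an [egg_ellipsoid()]; @param cam a [camera_model()].
#' @return 3x3 symmetric conic matrix.
#' @export
silhouette_conic <- function(egg, cam) {
  Q <- ellipsoid_quadric(egg)
  cc <- c(camera_center(cam), 1)
  if (as.numeric(t(cc) %*% Q %*% cc) <= 0)
    stop("silhouette_conic: camera centre inside the ellipsoid")
  Qs <- solve(Q)
  P <- camera_matrix(cam)
  Cs <- P %*% Qs %*% t(P)
  Cmat <- solve(Cs)
  Cmat <- (Cmat + t(Cmat)) / 2
  Cmat <- Cmat / max(abs(Cmat))
  # fix the sign so the projected centre is interior (negative form)
  pc <- unclass(project_point(cam, egg$center))
  if (as.numeric(t(pc) %*% Cmat %*% pc) > 0) Cmat <- -Cmat
  Cmat
}

#' Quadratic form of a conic at image points
#'
#' Negative inside, zero on, positive outside (for conics normalized as by
#' [silhouette_conic()]).
#'
#' @param conic 3x3 symmetric matrix; @param x,y pixel coordinate vectors.
#' @return numeric vector of form values.
#' @export
conic_value <- function(conic, x, y) {
  conic[1, 1] * x^2 + 2 * conic[1, 2] * x * y + conic[2, 2] * y^2 +
    2 * conic[1, 3] * x + 2 * conic[2, 3] * y + conic[3, 3]
}

#' Extreme points of an ellipse conic along a direction
#'
#' Closed form: the two tangent lines with normal parallel to `direction`
#' satisfy `l^T C* l = 0` in the dual conic `C* = C^{-1}`; their tangency
#' points `x = C* l` are the minimizer (`p1`) and maximizer (`p2`) of the
#' projection onto `direction`.
#'
#' @param conic 3x3 symmetric real-ellipse conic.
#' @param direction length-2 numeric.
#' @param axis_tag tag for the returned [axis_endpoints()].
#' @return an [axis_endpoints()].
#' @export
conic_extreme_points <- function(conic, direction, axis_tag = "major") {
  d <- direction / sqrt(sum(direction^2))
  Cs <- solve(conic)
  Cs <- (Cs + t(Cs)) / 2
  A <- Cs[3, 3]
  B <- 2 * (d[1] * Cs[1, 3] + d[2] * Cs[2, 3])
  Cc <- d[1]^2 * Cs[1, 1] + 2 * d[1] * d[2] * Cs[1, 2] + d[2]^2 * Cs[2, 2]
  disc <- B^2 - 4 * A * Cc
  if (abs(A) < 1e-14 || disc <= 0)
    stop("conic_extreme_points: degenerate conic (no real tangent pair)")
  cs <- (-B + c(1, -1) * sqrt(disc)) / (2 * A)
  pts <- lapply(cs, function(cc) {
    v <- as.numeric(Cs %*% c(d[1], d[2], cc))
    if (abs(v[3]) <= 1e-12 * max(abs(v)))
      stop("conic_extreme_points: degenerate conic (ideal tangency point)")
    plane_point(v[1] / v[3], v[2] / v[3])
  })
  pr <- vapply(pts, function(p) sum(euclid(p) * d), numeric(1))
  o <- order(pr)
  axis_endpoints(pts[[o[1]]], pts[[o[2]]], axis_tag)
}

#' V-groove egg carrier
#'
#' The carrier whose triangular walls are tangent to the egg's maximal
#' cross-section circle; its apex line runs along world x at height
#' `apex_height`, forcing the egg's major axis horizontal and parallel to a
#' known vertical plane.
#'
#' @param alpha groove half-angle (radians, from the vertical bisector plane
#'   to each wall), in `(0, pi/2)`.
#' @param length,width,height overall dimensions in mm.
#' @param apex_height height of the apex line above the ground (mm).
#' @return object of class `carrier_groove`.
#' @export
carrier_groove <- function(alpha = pi / 3, length = 75, width = 64,
                           height = 34, apex_height = 5) {
  if (alpha <= 0 || alpha >= pi / 2)
    stop("carrier_groove: alpha must lie in (0, pi/2)")
  if (length <= 0 || width <= 0 || height <= 0)
    stop("carrier_groove: dimensions must be positive")
  structure(list(alpha = alpha, length = length, width = width,
                 height = height, apex_height = apex_height),
            class = "carrier_groove")
}

#' Cross-parallel reference card
#'
#' A square card in the frontal plane carrying `n_strokes` parallel strokes
#' in each of the two in-plane directions (horizontal and vertical); the
#' strokes supply the two vanishing points and one stroke of known length
#' serves as the reference segment.
#'
#' @param x0,z0 lower-left corner in frontal-plane coordinates (mm).
#' @param size card side (mm); @param n_strokes strokes per direction;
#' @param spacing stroke spacing (mm); @param stroke_len stroke length (mm);
#' @param halfwidth painted stroke half-width (mm).
#' @return object of class `reference_card`.
#' @export
reference_card <- function(x0, z0 = 0, size = 60, n_strokes = 4,
                           spacing = 10, stroke_len = 50, halfwidth = 0.5) {
  structure(list(x0 = x0, z0 = z0, size = size, n_strokes = n_strokes,
                 spacing = spacing, stroke_len = stroke_len,
                 halfwidth = halfwidth),
            class = "reference_card")
}

# stroke segments of a card in frontal-plane (x, z) coordinates, grouped by
# direction: "u" (horizontal) and "w" (vertical)
card_strokes <- function(card) {
  xs <- card$x0 + 5 + c(0, card$stroke_len)
  zs <- card$z0 + card$spacing * seq_len(card$n_strokes)
  u <- lapply(zs, function(z) rbind(c(xs[1], z), c(xs[2], z)))
  xv <- card$x0 + card$spacing * seq_len(card$n_strokes)
  zv <- card$z0 + 5 + c(0, card$stroke_len)
  w <- lapply(xv, function(x) rbind(c(x, zv[1]), c(x, zv[2])))
  list(u = u, w = w)
}

#' Default acquisition camera
#'
#' 640x480 camera with 720 px focal length (a short-focal machine-vision
#' lens on a small CCD), standing ~230 mm from the carrier with a slight yaw
#' and downward tilt so the in-plane vanishing points are finite.
#'
#' @param aim fixed aim point (mm): the nominal egg position in the carrier.
#'   The rig is static — the camera does not re-aim for each egg.
#' @return a [camera_model()].
#' @export
default_camera <- function(aim = c(0, 0, 29.25)) {
  camera_lookat(position = c(40, -225, 75), target = aim)
}

#' Synthetic single-view scene
#'
#' Assembles camera, egg, carrier and the two reference cards, and computes
#' exact ground truth for every image-side quantity the measurement pipeline
#' estimates: projected axis endpoints, silhouette-conic endpoints, reference
#' endpoints, stroke segments, vanishing points and vanishing line. The egg
#' centre is placed on the frontal plane (y = 0) at the carrier resting
#' height; the cards lie in the same plane.
#'
#' @param a_e,b_e egg semi-axes (mm); @param carrier a [carrier_groove()];
#' @param camera a [camera_model()] or `NULL` for [default_camera()];
#' @param card_left,card_right [reference_card()]s;
#' @param ref_stroke index of the stroke used as the reference segment.
#' @return object of class `synthetic_scene` with a `truth` record.
#' @export
make_scene <- function(a_e = 27, b_e = 21,
                       carrier = carrier_groove(),
                       camera = NULL,
                       card_left = reference_card(x0 = -95),
                       card_right = reference_card(x0 = 33),
                       ref_stroke = 2) {
  h <- carrier$apex_height + resting_height(b_e, carrier$alpha)
  center <- c(0, 0, h)
  if (is.null(camera)) camera <- default_camera()
  egg <- egg_ellipsoid(a_e, b_e, center = center, axis = c(1, 0, 0))
  u <- c(1, 0, 0)   # major-axis direction, in the frontal plane
  w <- c(0, 0, 1)   # minor-axis (vertical) direction, in the frontal plane
  vp_u <- project_direction(camera, u)
  vp_w <- project_direction(camera, w)
  vline <- build_vanishing_line(vp_u, vp_w)
  on_plane <- function(x, z) c(x, 0, z)
  proj_seg <- function(P1, P2, tag) {
    axis_endpoints(project_point(camera, P1), project_point(camera, P2), tag)
  }
  # true projected egg-axis endpoints
  ab_major <- proj_seg(center - a_e * u, center + a_e * u, "major")
  ab_minor <- proj_seg(center - b_e * w, center + b_e * w, "minor")
  # silhouette endpoints (what a mask-based pipeline actually sees)
  conic <- silhouette_conic(egg, camera)
  dir_major <- euclid(ab_major$p2) - euclid(ab_major$p1)
  dir_minor <- euclid(ab_minor$p2) - euclid(ab_minor$p1)
  sil_major <- conic_extreme_points(conic, dir_major, "major")
  sil_minor <- conic_extreme_points(conic, dir_minor, "minor")
  # reference segments: one horizontal stroke (left card) for the major axis,
  # one vertical stroke (right card) for the minor axis
  stl <- card_strokes(card_left)
  str <- card_strokes(card_right)
  ref_major_w <- stl$u[[ref_stroke]]
  ref_minor_w <- str$w[[ref_stroke]]
  cd_major <- proj_seg(on_plane(ref_major_w[1, 1], ref_major_w[1, 2]),
                       on_plane(ref_major_w[2, 1], ref_major_w[2, 2]),
                       "reference")
  cd_minor <- proj_seg(on_plane(ref_minor_w[1, 1], ref_minor_w[1, 2]),
                       on_plane(ref_minor_w[2, 1], ref_minor_w[2, 2]),
                       "reference")
  seg_of <- function(s) line_segment(project_point(camera, on_plane(s[1, 1], s[1, 2])),
                                     project_point(camera, on_plane(s[2, 1], s[2, 2])))
  segments <- list(
    left = list(u = lapply(stl$u, seg_of), w = lapply(stl$w, seg_of)),
    right = list(u = lapply(str$u, seg_of), w = lapply(str$w, seg_of)))
  structure(list(
    camera = camera, egg = egg, carrier = carrier,
    cards = list(left = card_left, right = card_right),
    ref_length_mm = abs(ref_major_w[2, 1] - ref_major_w[1, 1]),
    truth = list(
      major_mm = 2 * a_e, minor_mm = 2 * b_e,
      ab_major = ab_major, ab_minor = ab_minor,
      sil_major = sil_major, sil_minor = sil_minor,
      cd_major = cd_major, cd_minor = cd_minor,
      conic = conic, vp_u = vp_u, vp_w = vp_w, vline = vline,
      segments = segments)),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> egg %g x %g mm; reference %g mm\n",
              2 * x$egg$a_e, 2 * x$egg$b_e, x$ref_length_mm))
  invisible(x)
}

jitter_pt <- function(p, sd) {
  xy <- euclid(p) + stats::rnorm(2, 0, sd)
  plane_point(xy[1], xy[2])
}

#' Measurement scenes from a synthetic scene
#'
#' Builds the major- and minor-axis [measurement_scene()]s from the scene's
#' ground truth, optionally replacing the exact projected axis endpoints by
#' the silhouette-conic endpoints (the mask-view of the egg) and adding
#' Gaussian pixel noise to all endpoints.
#'
#' @param scene a [make_scene()] result.
#' @param noise_px endpoint noise standard deviation in pixels (0 = exact).
#' @param endpoints `"silhouette"` (default) or `"projected"`.
#' @param vline vanishing line to use (default: the true one).
#' @param snap_to_axis constrain the endpoints by the measured direction's
#'   vanishing point via [snap_endpoints_to_vp()] (default `TRUE`): the
#'   carrier fixes the egg-axis directions, so their image lines are known to
#'   pass through the card vanishing points.
#' @return list with elements `major` and `minor`.
#' @export
measurement_scenes_from_truth <- function(scene, noise_px = 0,
                                          endpoints = c("silhouette", "projected"),
                                          vline = scene$truth$vline,
                                          snap_to_axis = TRUE) {
  endpoints <- match.arg(endpoints)
  tr <- scene$truth
  ab_maj <- if (endpoints == "silhouette") tr$sil_major else tr$ab_major
  ab_min <- if (endpoints == "silhouette") tr$sil_minor else tr$ab_minor
  mk <- function(ab, cd, vp) {
    pts <- list(ab$p1, ab$p2, cd$p1, cd$p2)
    if (noise_px > 0) pts <- lapply(pts, jitter_pt, sd = noise_px)
    if (snap_to_axis) {
      s1 <- snap_endpoints_to_vp(pts[[1]], pts[[2]], vp)
      s2 <- snap_endpoints_to_vp(pts[[3]], pts[[4]], vp)
      pts <- list(s1$p, s1$q, s2$p, s2$q)
    }
    measurement_scene(pts[[1]], pts[[2]], pts[[3]], pts[[4]],
                      vline, scene$ref_length_mm)
  }
  list(major = mk(ab_maj, tr$cd_major, tr$vp_u),
       minor = mk(ab_min, tr$cd_minor, tr$vp_w))
}

#' Synthetic pencil of segments through a known vanishing point
#'
#' Generates `n` image segments whose support lines pass exactly through
#' `vp`, with midpoints spread over the frame, then jitters the endpoints —
#' the controlled input for vanishing-point recovery experiments.
#'
#' @param vp a finite `plane_point` (the true vanishing point).
#' @param n number of segments; @param noise_px endpoint jitter sd (pixels);
#' @param seed integer seed; @param width,height frame size;
#' @param length segment length in pixels.
#' @return list of [line_segment()]s.
#' @export
simulate_segment_pencil <- function(vp, n = 8, noise_px = 0, seed = 1,
                                    width = 640, height = 480, length = 150) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  v <- euclid(vp)
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    mid <- c(stats::runif(1, 0.15 * width, 0.85 * width),
             stats::runif(1, 0.15 * height, 0.85 * height))
    d <- v - mid
    d <- d / sqrt(sum(d^2))
    a <- mid - d * length / 2 + stats::rnorm(2, 0, noise_px)
    b <- mid + d * length / 2 + stats::rnorm(2, 0, noise_px)
    segs[[i]] <- line_segment(plane_point(a[1], a[2]), plane_point(b[1], b[2]))
  }
  segs
}

#' Generate a seeded batch of synthetic scenes
#'
#' Egg sizes are drawn from independent normals for the major and minor axis
#' (defaults matching a retail-egg sample: major ~ N(54, 1.9), minor ~
#' N(42, 0.8) mm); each scene is posed in the default carrier/camera
#' geometry and paired with ready-to-measure [measurement_scene()]s carrying
#' optional endpoint noise.
#'
#' @param n number of scenes (>= 1).
#' @param size_distribution named numeric: `mean_major`, `sd_major`,
#'   `mean_minor`, `sd_minor` in mm.
#' @param noise_px endpoint jitter sd in pixels.
#' @param seed integer seed; the batch is reproducible given it.
#' @param endpoints endpoint source, see [measurement_scenes_from_truth()].
#' @return object of class `scene_batch`: list with `scenes`, `inputs`
#'   (measurement scene pairs) and `truth` (data frame of true axis lengths).
#' @export
generate_batch <- function(n,
                           size_distribution = c(mean_major = 54, sd_major = 1.9,
                                                 mean_minor = 42, sd_minor = 0.8),
                           noise_px = 0, seed = 1,
                           endpoints = "silhouette") {
  if (n < 1) stop("generate_batch: n must be at least 1")
  sd_ <- size_distribution
  need <- c("mean_major", "sd_major", "mean_minor", "sd_minor")
  if (!all(need %in% names(sd_)))
    stop("generate_batch: size_distribution must name ",
         paste(need, collapse = ", "))
  if (sd_["mean_major"] <= 0 || sd_["mean_minor"] <= 0 ||
      sd_["sd_major"] < 0 || sd_["sd_minor"] < 0 ||
      sd_["mean_major"] <= sd_["mean_minor"])
    stop("generate_batch: invalid size distribution parameters")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  scenes <- vector("list", n)
  inputs <- vector("list", n)
  truth <- data.frame(sample_id = seq_len(n), major_mm = NA_real_,
                      minor_mm = NA_real_)
  for (i in seq_len(n)) {
    repeat {
      maj <- stats::rnorm(1, sd_["mean_major"], sd_["sd_major"])
      mnr <- stats::rnorm(1, sd_["mean_minor"], sd_["sd_minor"])
      if (maj > mnr && mnr > 0) break
    }
    sc <- make_scene(a_e = maj / 2, b_e = mnr / 2)
    scenes[[i]] <- sc
    inputs[[i]] <- measurement_scenes_from_truth(sc, noise_px = noise_px,
                                                 endpoints = endpoints)
    truth$major_mm[i] <- maj
    truth$minor_mm[i] <- mnr
  }
  structure(list(scenes = scenes, inputs = inputs, truth = truth,
                 noise_px = noise_px, seed = seed, endpoints = endpoints),
            class = "scene_batch")
}

#' @export
print.scene_batch <- function(x, ...) {
  cat(sprintf("<scene_batch> %d scenes, endpoint noise %.2f px, seed %d\n",
              nrow(x$truth), x$noise_px, x$seed))
  invisible(x)
}

#' Measure every scene of a batch
#'
#' Runs [measure_egg()] on each scene's measurement inputs and binds the
#' results with the ground truth. By default the reference endpoints are
#' first averaged across the batch images with
#' [average_reference_endpoints()] — the cards are static across
#' acquisitions, so averaging their noisy image coordinates before measuring
#' (the multi-image reference rule) suppresses reference noise that the
#' length-transfer construction would otherwise amplify.
#'
#' @param batch a [generate_batch()] result.
#' @param average_reference average the reference endpoints over all scenes
#'   before measuring (default `TRUE`).
#' @return data frame: sample_id, measured/true major and minor axes (mm).
#' @export
measure_batch <- function(batch, average_reference = TRUE) {
  inputs <- batch$inputs
  if (average_reference && length(inputs) > 1) {
    for (ax in c("major", "minor")) {
      eps <- lapply(inputs, function(sc)
        axis_endpoints(sc[[ax]]$ref_c, sc[[ax]]$ref_d, "reference"))
      avg <- average_reference_endpoints(eps)
      inputs <- lapply(inputs, function(sc) {
        sc[[ax]] <- measurement_scene(sc[[ax]]$egg_a, sc[[ax]]$egg_b,
                                      avg$p1, avg$p2, sc[[ax]]$vline,
                                      sc[[ax]]$ref_length_mm)
        sc
      })
    }
  }
  res <- lapply(inputs, function(sc) measure_egg(sc$major, sc$minor))
  data.frame(sample_id = batch$truth$sample_id,
             major_measured_mm = vapply(res, `[[`, numeric(1), "Z_major_mm"),
             major_true_mm = batch$truth$major_mm,
             minor_measured_mm = vapply(res, `[[`, numeric(1), "Z_minor_mm"),
             minor_true_mm = batch$truth$minor_mm)
}

#' Write the batch manifest as CSV
#'
#' @param batch a [generate_batch()] result; @param path output path.
#' @return the manifest data frame, invisibly.
#' @export
write_batch_manifest <- function(batch, path) {
  df <- batch$truth
  df$noise_px <- batch$noise_px
  df$seed <- batch$seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Serialize a scene (camera, egg, carrier, cards, truth) to JSON
#'
#' @param scene a [make_scene()] result; @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  ep <- function(e) list(p1 = euclid(e$p1), p2 = euclid(e$p2), tag = e$axis_tag)
  obj <- list(
    camera = list(fx = scene$camera$fx, fy = scene$camera$fy,
                  cx = scene$camera$cx, cy = scene$camera$cy,
                  rotation = scene$camera$rotation,
                  translation = scene$camera$translation),
    egg = list(a_e = scene$egg$a_e, b_e = scene$egg$b_e,
               center = scene$egg$center, axis = scene$egg$axis),
    carrier = unclass(scene$carrier),
    cards = lapply(scene$cards, unclass),
    ref_length_mm = scene$ref_length_mm,
    truth = list(major_mm = scene$truth$major_mm,
                 minor_mm = scene$truth$minor_mm,
                 ab_major = ep(scene$truth$ab_major),
                 ab_minor = ep(scene$truth$ab_minor),
                 cd_major = ep(scene$truth$cd_major),
                 cd_minor = ep(scene$truth$cd_minor),
                 vp_u = unclass(scene$truth$vp_u),
                 vp_w = unclass(scene$truth$vp_w),
                 vline = unclass(scene$truth$vline)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a synthetic scene to rasters
#'
#' Per-pixel classification at pixel centres: egg pixels by the silhouette
#' conic interior test, reference pixels by back-projecting the pixel onto
#' the frontal plane (exact plane homography) and testing the card
#' rectangles. Also paints the card strokes into per-card binary line-pattern
#' masks (for stroke re-extraction) and into an RGB image in near-palette
#' colours (for the classical segmenter).
#'
#' @param scene a [make_scene()] result.
#' @param width,height raster size in pixels.
#' @return list with `mask` (a [label_mask()]), `rgb` (h x w x 3 array in
#'   `[0, 1]`), `line_masks` (list `left`, `right` of logical matrices),
#'   `segments` (exact stroke segments) and `truth`.
#' @export
render_scene <- function(scene, width = 640, height = 480) {
  P <- camera_matrix(scene$camera)
  H <- P[, c(1, 3, 4)]                 # frontal plane (x, z) -> image
  Hinv <- solve(H)
  xs <- rep(seq_len(width) - 1, each = height)
  ys <- rep(seq_len(height) - 1, times = width)
  # egg: conic interior
  egg_in <- conic_value(scene$truth$conic, xs, ys) <= 0
  if (!any(egg_in)) stop("render_scene: egg silhouette outside the frame")
  # back-project to frontal plane
  W <- Hinv %*% rbind(xs, ys, 1)
  px <- W[1, ] / W[3, ]
  pz <- W[2, ] / W[3, ]
  card_in <- rep(FALSE, length(xs))
  stroke_in <- list(left = rep(FALSE, length(xs)),
                    right = rep(FALSE, length(xs)))
  for (side in c("left", "right")) {
    cd <- scene$cards[[side]]
    inside <- px >= cd$x0 & px <= cd$x0 + cd$size &
              pz >= cd$z0 & pz <= cd$z0 + cd$size
    card_in <- card_in | inside
    st <- card_strokes(cd)
    hit <- rep(FALSE, length(xs))
    for (s in c(st$u, st$w)) {
      # flat-ended rectangular stroke: within halfwidth of the segment line
      # and between the endpoints (printed strokes have square ends)
      d <- s[2, ] - s[1, ]
      L <- sqrt(sum(d^2))
      dn <- d / L
      t <- (px - s[1, 1]) * dn[1] + (pz - s[1, 2]) * dn[2]
      perp <- abs((px - s[1, 1]) * (-dn[2]) + (pz - s[1, 2]) * dn[1])
      hit <- hit | (t >= 0 & t <= L & perp <= cd$halfwidth)
    }
    stroke_in[[side]] <- hit & inside
  }
  cls <- rep("background", length(xs))
  cls[card_in] <- "reference"
  cls[egg_in] <- "egg"
  clm <- matrix(cls, nrow = height)
  mask <- label_mask(clm)
  # RGB: near-palette colours, strokes dark on the cards
  rgb <- array(0, dim = c(height, width, 3))
  col_of <- list(background = c(230, 40, 30), egg = c(245, 240, 30),
                 reference = c(250, 250, 250))
  base <- matrix(0, nrow = length(xs), ncol = 3)
  for (cl in names(col_of)) {
    sel <- cls == cl
    base[sel, ] <- matrix(col_of[[cl]], nrow = sum(sel), ncol = 3, byrow = TRUE)
  }
  stroke_any <- stroke_in$left | stroke_in$right
  base[stroke_any, ] <- matrix(c(30, 30, 30), nrow = sum(stroke_any),
                               ncol = 3, byrow = TRUE)
  for (ch in 1:3) rgb[, , ch] <- matrix(base[, ch], nrow = height) / 255
  list(mask = mask, rgb = rgb,
       line_masks = lapply(stroke_in, function(v) matrix(v, nrow = height)),
       segments = scene$truth$segments,
       truth = scene$truth)
}
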