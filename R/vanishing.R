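#' Line segment in the image
#'
#' @param p_start,p_end distinct finite `plane_point`s (pixels).
#' @return an object of class `line_segment`.
#' @export
line_segment <- function(p_start, p_end) {
  if (is_ideal(p_start) || is_ideal(p_end))
    stop("line_segment: endpoints must be finite")
  if (same_projective(p_start, p_end, tol = 1e-12))
    stop("line_segment: endpoints coincide")
  structure(list(p_start = p_start, p_end = p_end), class = "line_segment")
}

seg_support_line <- function(s) join(s$p_start, s$p_end)

seg_midpoint <- function(s) {
  m <- (euclid(s$p_start) + euclid(s$p_end)) / 2
  plane_point(m[1], m[2])
}

seg_direction <- function(s) {
  d <- euclid(s$p_end) - euclid(s$p_start)
  d / sqrt(sum(d^2))
}

# perpendicular distance from finite point (x, y) to line l (normalized form)
point_line_dist <- function(xy, l) {
  abs(l[1] * xy[1] + l[2] * xy[2] + l[3]) / sqrt(l[1]^2 + l[2]^2)
}

# residual of one segment w.r.t. a vanishing-point hypothesis: RMS of the
# perpendicular distances of the two endpoints to the line joining the
# candidate and the segment midpoint
seg_vp_residual <- function(s, vp) {
  mid <- seg_midpoint(s)
  if (same_projective(vp, mid, tol = 1e-12)) return(0)
  l <- unclass(join(vp, mid))
  sqrt((point_line_dist(euclid(s$p_start), l)^2 +
        point_line_dist(euclid(s$p_end), l)^2) / 2)
}

#' Vanishing point from a pencil of image segments (MLESAC-style)
#'
#' Robustly estimates the common intersection of the support lines of a set
#' of image segments — the vanishing point of a family of world-parallel
#' lines. Hypotheses are the meets of two sampled support lines; each is
#' scored by a truncated-quadratic (MLESAC) cost where a segment's residual
#' is the RMS perpendicular distance of its endpoints to the line joining the
#' candidate and the segment midpoint. The best hypothesis is refined by
#' Nelder-Mead minimization of the robust cost. If all support lines are
#' mutually parallel within tolerance the common ideal point is returned.
#'
#' @param segments list of [line_segment()]s (at least 2).
#' @param max_iters number of sampling iterations (default 500).
#' @param noise_scale expected endpoint noise in pixels; the quadratic cost is
#'   truncated at `(3 * noise_scale)^2` and inliers are flagged below that
#'   residual.
#' @param seed integer seed making the estimate deterministic.
#' @return list with `vp` (a `plane_point`), `inliers` (logical vector), and
#'   `inlier_fraction`.
#' @export
estimate_vanishing_point <- function(segments, max_iters = 500,
                                     noise_scale = 1, seed = 1) {
  n <- length(segments)
  if (n < 2) stop("estimate_vanishing_point: need at least 2 segments")
  dirs <- t(vapply(segments, seg_direction, numeric(2)))
  # parallel pencil: every direction parallel to the first within tolerance
  crossmag <- abs(dirs[, 1] * dirs[1, 2] - dirs[, 2] * dirs[1, 1])
  if (all(crossmag <= 1e-9)) {
    vp <- plane_point(dirs[1, 1], dirs[1, 2], 0)
    return(list(vp = vp, inliers = rep(TRUE, n), inlier_fraction = 1))
  }
  lines <- lapply(segments, seg_support_line)
  thr2 <- (3 * noise_scale)^2
  score_of <- function(vp) {
    r2 <- vapply(segments, function(s) seg_vp_residual(s, vp)^2, numeric(1))
    sum(pmin(r2, thr2))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  best_score <- Inf
  for (it in seq_len(max_iters)) {
    ij <- sample.int(n, 2)
    li <- lines[[ij[1]]]; lj <- lines[[ij[2]]]
    if (same_projective(li, lj, tol = 1e-12)) next
    cand <- meet(li, lj)
    sc <- score_of(cand)
    if (sc < best_score) {
      best_score <- sc
      best <- cand
    }
  }
  if (is.null(best)) stop("estimate_vanishing_point: no valid hypothesis found")
  # refine finite candidates when residuals are not already negligible
  if (!is_ideal(best) && best_score > n * 1e-16) {
    xy0 <- euclid(best)
    opt <- stats::optim(xy0,
                        function(xy) score_of(plane_point(xy[1], xy[2])),
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-12))
    if (opt$value <= best_score) best <- plane_point(opt$par[1], opt$par[2])
  }
  res <- vapply(segments, function(s) seg_vp_residual(s, best), numeric(1))
  inl <- res < 3 * noise_scale
  list(vp = best, inliers = inl, inlier_fraction = mean(inl))
}

#' Vanishing line through two vanishing points
#'
#' The vanishing line of a world plane is the join of the vanishing points of
#' any two distinct directions within that plane. Two ideal vanishing points
#' (fronto-parallel camera) yield the ideal line.
#'
#' @param vp_left,vp_right distinct `plane_point`s.
#' @return a `plane_line` incident with both.
#' @export
build_vanishing_line <- function(vp_left, vp_right) {
  if (same_projective(vp_left, vp_right, tol = 1e-12))
    stop("build_vanishing_line: vanishing points coincide")
  join(vp_left, vp_right)
}

#' Vanishing geometry of a reference plane
#'
#' Bundles the two card-derived vanishing points, the vanishing line joining
#' them, and the MLESAC inlier fractions.
#'
#' @param vp_left,vp_right `plane_point`s; @param inlier_fraction_left,inlier_fraction_right
#'   proportions in `[0, 1]`.
#' @return an object of class `vanishing_geometry`.
#' @export
vanishing_geometry <- function(vp_left, vp_right,
                               inlier_fraction_left = 1,
                               inlier_fraction_right = 1) {
  vl <- build_vanishing_line(vp_left, vp_right)
  structure(list(vp_left = vp_left, vp_right = vp_right, vline = vl,
                 inlier_fraction_left = inlier_fraction_left,
                 inlier_fraction_right = inlier_fraction_right),
            class = "vanishing_geometry")
}

#' @export
print.vanishing_geometry <- function(x, ...) {
  cat("<vanishing_geometry>\n")
  cat("  vp_left : "); print(x$vp_left)
  cat("  vp_right: "); print(x$vp_right)
  cat("  vline   : "); print(x$vline)
  cat(sprintf("  inlier fractions: %.2f / %.2f\n",
              x$inlier_fraction_left, x$inlier_fraction_right))
  invisible(x)
}

#' Write / read vanishing geometry as JSON
#'
#' @param vg a `vanishing_geometry`; @param path file path.
#' @return `read_vanishing_geometry` returns a `vanishing_geometry`.
#' @export
write_vanishing_geometry <- function(vg, path) {
  jsonlite::write_json(
    list(vp_left = unclass(vg$vp_left), vp_right = unclass(vg$vp_right),
         vline = unclass(vg$vline),
         inliers = list(left = vg$inlier_fraction_left,
                        right = vg$inlier_fraction_right)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vanishing_geometry
#' @export
read_vanishing_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vanishing_geometry(
    plane_point(j$vp_left[1], j$vp_left[2], j$vp_left[3]),
    plane_point(j$vp_right[1], j$vp_right[2], j$vp_right[3]),
    j$inliers$left, j$inliers$right)
}

#' Extract straight strokes from a binary line-pattern mask
#'
#' Recovers the painted strokes of a cross-parallel reference card as image
#' segments: a seeded sequential RANSAC repeatedly fits a dominant line to
#' the remaining foreground pixels, accepts it when enough pixels lie within
#' `band` of it, emits the segment spanned by those pixels, and removes them.
#' Crossing stroke families are handled because shared pixels are consumed
#' only once.
#'
#' @param mask logical or 0/1 matrix (rows = y, columns = x).
#' @param min_length minimum accepted stroke length in pixels.
#' @param band inlier distance to the fitted line in pixels (default 1.5).
#' @param seed integer seed (extraction is deterministic given it).
#' @return list of [line_segment()]s.
#' @export
card_segments_from_mask <- function(mask, min_length = 20, band = 1.5,
                                    seed = 1) {
  m <- mask
  if (is.logical(m)) m <- m * 1L
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("card_segments_from_mask: empty mask (no foreground)")
  # 0-based pixel-centre coordinates: x = col - 1, y = row - 1
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  segs <- list()
  min_pix <- max(min_length, 5)
  while (nrow(pts) >= min_pix) {
    best_inl <- NULL
    best_n <- 0
    for (it in seq_len(300)) {
      ij <- sample.int(nrow(pts), 2)
      p <- pts[ij[1], ]; q <- pts[ij[2], ]
      d <- q - p
      nd <- sqrt(sum(d^2))
      if (nd < min_length / 2) next  # favour long spans
      nrm <- c(-d[2], d[1]) / nd
      r <- abs((pts[, 1] - p[1]) * nrm[1] + (pts[, 2] - p[2]) * nrm[2])
      inl <- r <= band
      if (sum(inl) > best_n) {
        best_n <- sum(inl)
        best_inl <- inl
      }
    }
    if (best_n < min_pix) break
    # iterate total-least-squares refits so the line settles on the stroke
    # axis even when the sampled hypothesis was slightly tilted
    inl <- best_inl
    for (ref_it in 1:3) {
      sub <- pts[inl, , drop = FALSE]
      ctr <- colMeans(sub)
      sv <- svd(sweep(sub, 2, ctr))
      u <- sv$v[, 1]
      nrm <- c(-u[2], u[1])
      r <- abs((pts[, 1] - ctr[1]) * nrm[1] + (pts[, 2] - ctr[2]) * nrm[2])
      inl_new <- r <= band
      if (sum(inl_new) < min_pix) break
      if (identical(inl_new, inl)) { inl <- inl_new; break }
      inl <- inl_new
    }
    sub <- pts[inl, , drop = FALSE]
    ctr <- colMeans(sub)
    sv <- svd(sweep(sub, 2, ctr))
    u <- sv$v[, 1]
    # subpixel endpoints: centroids of the 1-px end slabs
    t <- (sub[, 1] - ctr[1]) * u[1] + (sub[, 2] - ctr[2]) * u[2]
    a <- colMeans(sub[t <= min(t) + 1, , drop = FALSE])
    b <- colMeans(sub[t >= max(t) - 1, , drop = FALSE])
    len <- sqrt(sum((b - a)^2))
    if (len >= min_length) {
      segs[[length(segs) + 1]] <-
        line_segment(plane_point(a[1], a[2]), plane_point(b[1], b[2]))
    }
    # remove everything near the accepted line, not just the scoring band,
    # so thick strokes do not leave slivers that re-fit as duplicates
    p0 <- ctr
    nrm <- c(-u[2], u[1])
    r_all <- abs((pts[, 1] - p0[1]) * nrm[1] + (pts[, 2] - p0[2]) * nrm[2])
    pts <- pts[r_all > band + 1.5, , drop = FALSE]
  }
  if (length(segs) == 0)
    stop("card_segments_from_mask: no stroke of the requested length found")
  segs
}

# homogeneous matrix of the clockwise 90-degree frame rotation for an image
# of height H (0-based pixel centres): (x, y) -> (H - 1 - y, x)
rot90_matrix <- function(image_height) {
  matrix(c(0, -1, image_height - 1,
           1,  0, 0,
           0,  0, 1), nrow = 3, byrow = TRUE)
}

#' Map a point between the original and the 90-degree-rotated frame
#'
#' The original image of height `H` pixels is rotated clockwise by 90
#' degrees, so column x becomes the new row and row y counts from the new
#' right edge: `(x, y) -> (H - 1 - y, x)` at 0-based pixel centres. Ideal
#' points transform by rotating their direction. `inverse = TRUE` maps back;
#' the round trip is the identity.
#'
#' @param p a `plane_point` (finite or ideal).
#' @param image_height height of the *original* image in pixels.
#' @param inverse map from the rotated frame back to the original.
#' @return a `plane_point` in the other frame.
#' @export
rotate_frame_90 <- function(p, image_height, inverse = FALSE) {
  M <- rot90_matrix(image_height)
  if (inverse) M <- solve(M)
  v <- as.numeric(M %*% unclass(p))
  structure(normalize_h(v), class = "plane_point")
}

#' Rotate a line between the original and rotated frames
#'
#' Lines transform by the inverse transpose of the point map, so incidence is
#' preserved.
#'
#' @param l a `plane_line`; @inheritParams rotate_frame_90
#' @return a `plane_line` in the other frame.
#' @export
rotate_frame_90_line <- function(l, image_height, inverse = FALSE) {
  M <- rot90_matrix(image_height)
  if (inverse) M <- solve(M)
  v <- as.numeric(t(solve(M)) %*% unclass(l))
  structure(normalize_h(v), class = "plane_line")
}

#' Rotate a raster clockwise by 90 degrees
#'
#' Companion of [rotate_frame_90()] for matrices (masks): the rotated raster
#' has `r[x', y'] = m[y, x]` under the same coordinate convention.
#'
#' @param m a matrix (rows = y, columns = x).
#' @return the rotated matrix (dimensions swapped).
#' @export
rotate_raster_90 <- function(m) {
  t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
}
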