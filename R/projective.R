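#' Homogeneous plane point
#'
#' Constructs a point of the projective plane from homogeneous coordinates
#' `(h1, h2, h3)`. Finite image points have `h3 != 0` and Euclidean pixel
#' coordinates `(h1/h3, h2/h3)`; `h3 = 0` encodes an ideal point (a
#' direction, e.g. a vanishing point of lines parallel to the image plane).
#' Image coordinates are 0-based, x right, y down, sampled at pixel centres.
#'
#' @param h1,h2,h3 homogeneous coordinates; not all zero. `h3` defaults to 1
#'   so `plane_point(x, y)` builds the finite pixel point `(x, y)`.
#' @return an object of class `plane_point` (a length-3 numeric vector).
#' @export
#' @examples
#' plane_point(3, 4)          # finite point (3, 4)
#' plane_point(1, 0, 0)       # ideal point in the +x direction
plane_point <- function(h1, h2, h3 = 1) {
  v <- c(as.numeric(h1), as.numeric(h2), as.numeric(h3))
  if (!all(is.finite(v))) stop("plane_point: coordinates must be finite numbers")
  if (all(v == 0)) stop("plane_point: all three homogeneous coordinates are zero")
  structure(v, class = "plane_point")
}

#' Homogeneous plane line
#'
#' A line `l1*x + l2*y + l3 = 0` of the projective plane. The ideal line
#' (line at infinity) is any multiple of `(0, 0, 1)`.
#'
#' @param l1,l2,l3 line coefficients; not all zero.
#' @return an object of class `plane_line` (a length-3 numeric vector).
#' @export
plane_line <- function(l1, l2, l3) {
  v <- c(as.numeric(l1), as.numeric(l2), as.numeric(l3))
  if (!all(is.finite(v))) stop("plane_line: coefficients must be finite numbers")
  if (all(v == 0)) stop("plane_line: all three coefficients are zero")
  structure(v, class = "plane_line")
}

# rescale so the largest-magnitude coordinate is 1 (keeps join/meet chains
# away from overflow/underflow; sign of the leading coordinate preserved)
normalize_h <- function(v) {
  m <- max(abs(v))
  out <- v / m
  out
}

#' @export
print.plane_point <- function(x, ...) {
  if (is_ideal(x)) {
    cat(sprintf("<plane_point> ideal, direction (%g, %g)\n", x[1], x[2]))
  } else {
    cat(sprintf("<plane_point> (%g, %g)\n", x[1] / x[3], x[2] / x[3]))
  }
  invisible(x)
}

#' @export
print.plane_line <- function(x, ...) {
  cat(sprintf("<plane_line> %g x + %g y + %g = 0\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Test for an ideal point (point at infinity)
#'
#' @param p a `plane_point`.
#' @param tol relative tolerance on `h3` against the largest coordinate.
#' @return `TRUE` if the point is at infinity.
#' @export
is_ideal <- function(p, tol = 1e-12) {
  abs(p[3]) <= tol * max(abs(p))
}

#' Projective equality up to scale
#'
#' Two homogeneous triples represent the same point (or line) iff they are
#' proportional; compared via the norm of their cross product after
#' normalization.
#'
#' @param p,q two `plane_point`s or two `plane_line`s.
#' @param tol tolerance on the residual.
#' @return logical.
#' @export
same_projective <- function(p, q, tol = 1e-9) {
  a <- normalize_h(unclass(p))
  b <- normalize_h(unclass(q))
  sqrt(sum(cross3(a, b)^2)) <= tol
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Line through two points
#'
#' The join of two distinct plane points, computed as their homogeneous cross
#' product; by projective duality the same computation implements [meet()].
#'
#' @param p,q distinct `plane_point`s.
#' @return the `plane_line` incident with both.
#' @export
#' @examples
#' join(plane_point(0, 0), plane_point(1, 0))  # the x-axis: y = 0
join <- function(p, q) {
  l <- cross3(normalize_h(unclass(p)), normalize_h(unclass(q)))
  if (max(abs(l)) <= 1e-12) stop("join: points coincide (degenerate input)")
  structure(normalize_h(l), class = "plane_line")
}

#' Intersection of two lines
#'
#' The meet of two distinct plane lines. Parallel (distinct) lines meet in an
#' ideal point — the shared direction.
#'
#' @param m,n distinct `plane_line`s.
#' @return the `plane_point` incident with both.
#' @export
meet <- function(m, n) {
  p <- cross3(normalize_h(unclass(m)), normalize_h(unclass(n)))
  if (max(abs(p)) <= 1e-12) stop("meet: lines coincide (degenerate input)")
  structure(normalize_h(p), class = "plane_point")
}

#' Signed incidence residual of a point and a line
#'
#' `|p . l|` after normalizing both to unit leading magnitude; zero iff the
#' point lies on the line.
#'
#' @param p a `plane_point`; @param l a `plane_line`.
#' @return nonnegative scalar.
#' @export
incidence_residual <- function(p, l) {
  abs(sum(normalize_h(unclass(p)) * normalize_h(unclass(l))))
}

euclid <- function(p) {
  if (is_ideal(p)) stop("euclid: ideal point has no Euclidean coordinates")
  c(p[1] / p[3], p[2] / p[3])
}

#' Euclidean pixel distance between two finite points
#'
#' @param p,q finite `plane_point`s.
#' @return nonnegative distance in pixels.
#' @export
#' @examples
#' pt_distance(plane_point(0, 0), plane_point(3, 4))  # 5
pt_distance <- function(p, q) {
  if (is_ideal(p) || is_ideal(q))
    stop("pt_distance: ideal-point input; use the ratio-limit form instead")
  sqrt(sum((euclid(p) - euclid(q))^2))
}

# Signed 1-D parameters of collinear points along the line through the first
# two finite ones; orientation induced by (first -> second). Ideal points get
# parameter NA (handled as limits by callers). Collinearity is enforced.
line_params <- function(pts, tol = 1e-6) {
  fin <- !vapply(pts, is_ideal, logical(1))
  if (sum(fin) < 2) stop("line_params: need at least two finite points")
  idx <- which(fin)
  p0 <- euclid(pts[[idx[1]]])
  p1 <- euclid(pts[[idx[2]]])
  u <- p1 - p0
  nu <- sqrt(sum(u^2))
  if (nu <= 1e-12) stop("line_params: first two finite points coincide")
  u <- u / nu
  l <- join(pts[[idx[1]]], pts[[idx[2]]])
  t <- rep(NA_real_, length(pts))
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    if (incidence_residual(p, l) > tol)
      stop("cross_ratio: points are not collinear within tolerance")
    if (fin[i]) t[i] <- sum((euclid(p) - p0) * u)
  }
  t
}

#' Cross-ratio of four collinear points
#'
#' Computes `CR(p1, p2; p3, p4) = [d(p1,p3) * d(p2,p4)] / [d(p2,p3) * d(p1,p4)]`
#' with signed distances along the common line (orientation induced by the
#' first two finite points). An ideal point contributes one numerator and one
#' denominator factor whose ratio tends to 1, so it is handled exactly by
#' that limit. The value is invariant under any projective map of the line —
#' the property that makes single-view length transfer possible.
#'
#' @param p1,p2,p3,p4 pairwise-distinct collinear `plane_point`s.
#' @param tol collinearity tolerance on the normalized incidence residual.
#' @return scalar cross-ratio.
#' @export
#' @examples
#' # points at parameters 0, 1, 2, 3 on a line: (2*2)/(1*3) = 4/3
#' pts <- lapply(0:3, function(t) plane_point(t, 0))
#' cross_ratio(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
cross_ratio <- function(p1, p2, p3, p4, tol = 1e-6) {
  pts <- list(p1, p2, p3, p4)
  for (i in 1:3) for (j in (i + 1):4) {
    if (same_projective(pts[[i]], pts[[j]], tol = 1e-12))
      stop("cross_ratio: coincident points (degenerate input)")
  }
  t <- line_params(pts, tol = tol)
  num <- 1
  den <- 1
  # factors d(p1,p3), d(p2,p4) over d(p2,p3), d(p1,p4); an ideal point makes
  # its numerator/denominator pair cancel to 1
  f13 <- signed_d(t, 1, 3); f24 <- signed_d(t, 2, 4)
  f23 <- signed_d(t, 2, 3); f14 <- signed_d(t, 1, 4)
  if (is.na(t[4])) { f24 <- 1; f14 <- 1 }
  if (is.na(t[3])) { f13 <- 1; f23 <- 1 }
  if (is.na(t[1])) { f13 <- 1; f14 <- 1 }
  if (is.na(t[2])) { f24 <- 1; f23 <- 1 }
  (f13 * f24) / (f23 * f14)
}

signed_d <- function(t, i, j) t[j] - t[i]

#' Distance ratio with an ideal-point limit
#'
#' Returns `d(g, f) / d(g, a)` for finite `g`, and exactly 1 when `g` is
#' ideal — the limit used when the measured direction's vanishing point lies
#' at infinity (fronto-parallel camera).
#'
#' @param g a `plane_point`, possibly ideal, collinear with `f` and `a`.
#' @param f,a finite `plane_point`s.
#' @return scalar ratio (signed along the common line).
#' @export
ratio_with_possible_ideal <- function(g, f, a) {
  if (is_ideal(g)) return(1)
  if (same_projective(g, a, tol = 1e-12))
    stop("ratio_with_possible_ideal: g coincides with a (degenerate input)")
  t <- line_params(list(g, f, a))
  (t[2] - t[1]) / (t[3] - t[1])
}
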