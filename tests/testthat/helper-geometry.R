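# shared generators for geometry property tests

rand_finite_point <- function(lim = 500) {
  plane_point(runif(1, -lim, lim), runif(1, -lim, lim))
}

# random well-conditioned 3x3 projective map
rand_projective_map <- function() {
  repeat {
    M <- matrix(rnorm(9), 3, 3)
    if (abs(det(M)) > 0.1) return(M)
  }
}

apply_map <- function(M, p) {
  v <- as.numeric(M %*% unclass(p))
  structure(ovometry:::normalize_h(v), class = "plane_point")
}

# four distinct collinear points at given (or random) parameters on a random line
rand_collinear <- function(t = NULL) {
  if (is.null(t)) {
    repeat {
      t <- sort(rnorm(4, sd = 5))
      if (min(diff(t)) > 0.3) break
    }
  }
  p0 <- c(runif(1, -100, 100), runif(1, -100, 100))
  d <- rnorm(2); d <- d / sqrt(sum(d^2))
  lapply(t, function(ti) plane_point(p0[1] + ti * d[1], p0[2] + ti * d[2]))
}

# random nondegenerate measurement configuration: a world plane seen by a
# random camera, a measured segment AB and a parallel reference CD in that
# plane, with exact projections and the true vanishing line
rand_parallel_scene <- function() {
  repeat {
    pos <- c(runif(1, -150, 150), runif(1, -400, -200), runif(1, 30, 200))
    cam <- camera_lookat(pos, c(runif(1, -20, 20), 0, runif(1, 10, 50)))
    theta <- runif(1, 0, 2 * pi)
    u3 <- c(cos(theta), 0, sin(theta))          # in-plane direction of AB, CD
    w3 <- c(-sin(theta), 0, cos(theta))
    L <- runif(1, 30, 70)
    R <- runif(1, 20, 60)
    A0 <- c(runif(1, -30, 30), 0, runif(1, 10, 60))
    C0 <- A0 + runif(1, 20, 60) * w3 + runif(1, -20, 20) * u3
    A <- A0 - L / 2 * u3; B <- A0 + L / 2 * u3
    C <- C0 - R / 2 * u3; D <- C0 + R / 2 * u3
    pts <- lapply(list(A, B, C, D), function(X) project_point(cam, X))
    if (any(vapply(pts, function(p) isTRUE(attr(p, "behind")), logical(1)))) next
    vl <- tryCatch(build_vanishing_line(project_direction(cam, u3),
                                        project_direction(cam, w3)),
                   error = function(e) NULL)
    if (is.null(vl)) next
    sc <- tryCatch(
      measurement_scene(pts[[1]], pts[[2]], pts[[3]], pts[[4]], vl, R),
      error = function(e) NULL)
    if (is.null(sc)) next
    return(list(scene = sc, true_length = L, camera = cam, u = u3, w = w3,
                A = A, B = B, C = C, D = D))
  }
}

# one default scene and its rendering, computed once per test run
scene_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$scene)) {
      env$scene <- make_scene()
      env$render <- render_scene(env$scene)
    }
    list(scene = env$scene, render = env$render)
  }
})
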