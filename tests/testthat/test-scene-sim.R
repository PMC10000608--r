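test_that("pinhole projection obeys similar triangles and preserves cross-ratios", {
  cam <- camera_model(720, 720, 319.5, 239.5, diag(3), c(0, 0, 0))
  # optical axis maps to the principal point
  expect_equal(euclid(project_point(cam, c(0, 0, 300))), c(319.5, 239.5))
  # lateral offset x at depth d maps to fx * x / d
  p <- project_point(cam, c(10, 0, 200))
  expect_equal(euclid(p)[1] - 319.5, 720 * 10 / 200)
  expect_true(attr(project_point(cam, c(0, 0, -50)), "behind"))
  expect_error(project_point(cam, c(0, 0, 0)), "centre")

  # collinear world points project collinearly with the same cross-ratio
  set.seed(9)
  for (i in 1:100) {
    cam2 <- camera_lookat(c(runif(1, -100, 100), -runif(1, 150, 350),
                            runif(1, 20, 150)), c(0, 0, 25))
    P0 <- c(runif(1, -30, 30), runif(1, -20, 20), runif(1, 0, 50))
    dd <- rnorm(3); dd <- dd / sqrt(sum(dd^2))
    t4 <- sort(rnorm(4, sd = 20))
    world <- lapply(t4, function(t) P0 + t * dd)
    imgs <- lapply(world, function(X) project_point(cam2, X))
    cr_img <- tryCatch(
      cross_ratio(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]], tol = 1e-4),
      error = function(e) NULL)
    if (is.null(cr_img)) next
    cr_world <- ((t4[3] - t4[1]) * (t4[4] - t4[2])) /
      ((t4[3] - t4[2]) * (t4[4] - t4[1]))
    expect_lt(abs(cr_img - cr_world) / abs(cr_world), 1e-9)
  }
})

test_that("resting height realizes wall tangency of the cross-section circle", {
  expect_equal(resting_height(21, pi / 2), 21)
  expect_equal(resting_height(21, pi / 6), 42)
  expect_error(resting_height(21, 2), "alpha")
  expect_error(resting_height(-1, 1), "b_e")
  set.seed(10)
  for (i in 1:100) {
    b <- runif(1, 10, 30); a <- runif(1, 0.2, 1.5)
    h <- resting_height(b, a)
    # wall plane through the apex line with normal (0, cos a, +/- sin a)
    for (s in c(-1, 1)) {
      n <- c(0, cos(a), s * sin(a))
      expect_lt(abs(abs(sum(c(0, 0, h) * n)) - b), 1e-9)
    }
  }
})

test_that("the silhouette conic is the exact ellipsoid outline", {
  # spheroid on the optical axis: circle centred at the principal point
  cam <- camera_model(700, 700, 320, 240, diag(3), c(0, 0, 0))
  egg <- egg_ellipsoid(25, 20, center = c(0, 0, 300), axis = c(0, 0, 1))
  conic <- silhouette_conic(egg, cam)
  ep_x <- conic_extreme_points(conic, c(1, 0))
  ep_y <- conic_extreme_points(conic, c(0, 1))
  cx <- (euclid(ep_x$p1) + euclid(ep_x$p2)) / 2
  expect_equal(cx, c(320, 240), tolerance = 1e-6)
  expect_equal(pt_distance(ep_x$p1, ep_x$p2), pt_distance(ep_y$p1, ep_y$p2),
               tolerance = 1e-9)

  # every projected surface point satisfies the interior inequality
  sc <- make_scene()
  conic2 <- sc$truth$conic
  set.seed(11)
  M <- ovometry:::egg_frame(sc$egg)
  ax <- c(sc$egg$a_e, sc$egg$b_e, sc$egg$b_e)
  u <- matrix(rnorm(3 * 10000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  worst <- -Inf
  for (i in seq_len(nrow(u))) {
    X <- sc$egg$center + as.numeric(M %*% (ax * u[i, ]))
    p <- unclass(project_point(sc$camera, X))
    worst <- max(worst, as.numeric(t(p) %*% conic2 %*% p))
  }
  expect_lt(worst, 1e-6)

  inside_cam <- camera_model(700, 700, 320, 240, diag(3), c(0, 0, -300))
  expect_error(silhouette_conic(egg, inside_cam), "inside")
})

test_that("conic extreme points solve the tangency condition in closed form", {
  circ <- diag(c(1, 1, -1))            # unit circle
  ep <- conic_extreme_points(circ, c(1, 0))
  expect_equal(euclid(ep$p1), c(-1, 0), tolerance = 1e-9)
  expect_equal(euclid(ep$p2), c(1, 0), tolerance = 1e-9)
  ell <- diag(c(1 / 9, 1 / 4, -1))     # semi-axes (3, 2)
  ep2 <- conic_extreme_points(ell, c(0, 1))
  expect_equal(euclid(ep2$p2), c(0, 2), tolerance = 1e-9)

  # random ellipse: matches a dense boundary-sampling argmax
  set.seed(12)
  for (i in 1:20) {
    ctr <- rnorm(2, sd = 50); ab <- sort(runif(2, 5, 40)); th <- runif(1, 0, pi)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    S <- Rm %*% diag(1 / ab^2) %*% t(Rm)
    conic <- rbind(cbind(S, -S %*% ctr),
                   c(-t(ctr) %*% S, t(ctr) %*% S %*% ctr - 1))
    d <- rnorm(2); d <- d / sqrt(sum(d^2))
    ep <- conic_extreme_points(conic, d)
    phi <- seq(0, 2 * pi, length.out = 2e5)
    bound <- t(ctr + Rm %*% rbind(ab[1] * cos(phi), ab[2] * sin(phi)))
    best <- bound[which.max(bound %*% d), ]
    expect_lt(sqrt(sum((euclid(ep$p2) - best)^2)), 1e-3)
    expect_lt(abs(sum(euclid(ep$p2) * d) - max(bound %*% d)), 1e-6)
  }
})

test_that("silhouette chord is biased above the projected axis and shrinks with distance", {
  rel_bias <- vapply(c(1, 2, 4), function(k) {
    cam <- camera_lookat(c(40 * k, -225 * k, 75 * k), c(0, 0, 29.25),
                         fx = 720 * k, fy = 720 * k)
    sc <- make_scene(camera = cam)
    chord <- pt_distance(sc$truth$sil_major$p1, sc$truth$sil_major$p2)
    proj <- pt_distance(sc$truth$ab_major$p1, sc$truth$ab_major$p2)
    expect_gte(chord, proj)
    (chord - proj) / proj
  }, numeric(1))
  expect_true(all(diff(rel_bias) < 0))
})

test_that("rendered scenes are self-consistent with their ground truth", {
  sr <- scene_cache()
  mask <- sr$render$mask
  tab <- table(factor(mask$classes, levels = rownames(label_palette())))
  expect_equal(sum(tab), 640 * 480)
  expect_true(all(tab > 0))
  # true vanishing line is incident with every projected u-family line
  tr <- sr$scene$truth
  for (s in c(tr$segments$left$u, tr$segments$right$u)) {
    g <- meet(seg_support_line(s), tr$vline)
    expect_true(same_projective(g, tr$vp_u, tol = 1e-6))
  }
  # framing error when the egg leaves the frame
  cam_off <- camera_lookat(c(500, -225, 75), c(500, 0, 30))
  expect_error(render_scene(make_scene(camera = cam_off)), "frame")
})

test_that("batches are reproducible and match their size distribution", {
  b1 <- generate_batch(15, noise_px = 0.3, seed = 5)
  b2 <- generate_batch(15, noise_px = 0.3, seed = 5)
  expect_identical(b1$truth, b2$truth)
  expect_identical(euclid(b1$inputs[[3]]$major$egg_a),
                   euclid(b2$inputs[[3]]$major$egg_a))

  b0 <- generate_batch(10, size_distribution = c(mean_major = 54, sd_major = 0,
                                                 mean_minor = 42, sd_minor = 0),
                       seed = 1)
  expect_true(all(b0$truth$major_mm == 54) && all(b0$truth$minor_mm == 42))

  big <- generate_batch(400, seed = 2)
  se <- 1.9 / sqrt(400)
  expect_lt(abs(mean(big$truth$major_mm) - 54), 3 * se)
  expect_error(generate_batch(0), "at least 1")
  expect_error(generate_batch(5, size_distribution = c(mean_major = 40,
                                                       sd_major = 1,
                                                       mean_minor = 42,
                                                       sd_minor = 1)),
               "invalid")
})

test_that("scene and batch serializers write readable files", {
  sc <- make_scene()
  jp <- tempfile(fileext = ".json")
  write_scene_json(sc, jp)
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$truth$major_mm, 54)
  expect_equal(j$egg$b_e, 21)
  b <- generate_batch(3, seed = 1)
  cp <- tempfile(fileext = ".csv")
  write_batch_manifest(b, cp)
  df <- utils::read.csv(cp)
  expect_equal(nrow(df), 3)
  expect_true(all(c("major_mm", "minor_mm", "seed") %in% names(df)))
})
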