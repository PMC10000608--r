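affine_scene <- function() {
  measurement_scene(plane_point(0, 0), plane_point(0, 100),
                    plane_point(40, 60), plane_point(40, 100),
                    plane_line(0, 0, 1), 40)
}

test_that("transfer construction reproduces the affine parallel transport", {
  efg <- transfer_projection_point(affine_scene())
  expect_true(is_ideal(efg$e))     # bd is horizontal, vline ideal
  expect_equal(euclid(efg$f), c(0, 60))
  expect_true(is_ideal(efg$g))
  expect_equal(as.numeric(measure_axis(affine_scene())), 100)
})

test_that("f equals the projection of the world transfer point", {
  set.seed(6)
  for (i in 1:20) {
    rs <- rand_parallel_scene()
    efg <- transfer_projection_point(rs$scene)
    # world F = C + (B - D): the fourth vertex of the parallelogram BDCF
    Fw <- rs$C + rs$B - rs$D
    f_true <- project_point(rs$camera, Fw)
    expect_lt(pt_distance(efg$f, f_true), 1e-6)
  }
})

test_that("degenerate configurations raise geometry errors", {
  # b, d and the vanishing line concurrent: bd *is* the vanishing line
  vl <- join(plane_point(0, 50), plane_point(100, 50))
  expect_error(
    transfer_projection_point(measurement_scene(
      plane_point(10, 0), plane_point(0, 50), plane_point(40, 20),
      plane_point(100, 50), vl, 40)),
    "vanishing line")
  expect_error(measure_egg(affine_scene(), NULL), "minor")
})

test_that("axis measurement is projectively exact and scale equivariant", {
  set.seed(7)
  for (i in 1:60) {
    rs <- rand_parallel_scene()
    z <- as.numeric(measure_axis(rs$scene))
    expect_lt(abs(z - rs$true_length) / rs$true_length, 1e-9)
    # scaling R scales Z exactly
    sc2 <- rs$scene
    sc2$ref_length_mm <- sc2$ref_length_mm * 2.5
    expect_equal(as.numeric(measure_axis(sc2)), z * 2.5)
  }
})

test_that("measurement converges to the pixel-ratio limit as the camera recedes", {
  zs <- vapply(c(1, 4, 16, 64), function(k) {
    cam <- camera_lookat(c(40, -225 * k, 75), c(0, 0, 29.25),
                         fx = 720 * k, fy = 720 * k)
    sc <- make_scene(camera = cam)
    ms <- measurement_scenes_from_truth(sc, endpoints = "projected")
    # simple ratio: egg pixel length / reference pixel length * R
    ab <- sc$truth$ab_major; cd <- sc$truth$cd_major
    ratio <- pt_distance(ab$p1, ab$p2) / pt_distance(cd$p1, cd$p2) *
      sc$ref_length_mm
    abs(as.numeric(measure_axis(ms$major)) - ratio)
  }, numeric(1))
  expect_true(all(diff(zs) < 0))
  expect_lt(zs[4], 5e-3)
})

interplanar_fixture <- function(seed = 1) {
  set.seed(seed)
  cam <- camera_lookat(c(runif(1, -100, 100), runif(1, -350, -200),
                         runif(1, 60, 180)),
                       c(0, 0, 20))
  vline <- build_vanishing_line(project_direction(cam, c(1, 0, 0)),
                                project_direction(cam, c(0, 1, 0)))
  v <- project_direction(cam, c(0, 0, 1))
  list(cam = cam, vline = vline, v = v)
}

test_that("reference-plane camera distance matches the camera oracle", {
  for (seed in 1:10) {
    fx <- interplanar_fixture(seed)
    Zr <- runif(1, 15, 40)
    base <- c(runif(1, -40, 40), runif(1, -30, 30), 0)
    r1 <- project_point(fx$cam, base)
    r2 <- project_point(fx$cam, base + c(0, 0, Zr))
    cr <- meet(join(r1, r2), fx$vline)
    Zcr <- interplanar_Zcr(r1, r2, fx$v, cr, Zr)
    truth <- camera_plane_distance(fx$cam, base, c(0, 0, 1))
    expect_lt(abs(Zcr - truth) / truth, 1e-6)
    # linear in Zr with fixed image geometry
    expect_equal(interplanar_Zcr(r1, r2, fx$v, cr, Zr / 2) * 2, Zcr,
                 tolerance = 1e-9)
  }
})

test_that("plane separation and camera height solve the cross-ratio chain", {
  for (seed in 1:10) {
    fx <- interplanar_fixture(seed)
    z0 <- runif(1, 5, 15)        # measured base plane height
    Ztrue <- runif(1, 10, 40)    # separation to the second plane
    base <- c(runif(1, -40, 40), runif(1, -30, 30), z0)
    x <- project_point(fx$cam, base)
    xp <- project_point(fx$cam, base + c(0, 0, Ztrue))
    cpt <- meet(join(x, xp), fx$vline)
    Zc_true <- camera_plane_distance(fx$cam, base, c(0, 0, 1))
    Z <- interplanar_Z(x, xp, cpt, fx$v, Zc_true)
    expect_lt(abs(Z - Ztrue) / Ztrue, 1e-6)
    # swapping the planes leaves the magnitude unchanged
    Zc_swap <- Zc_true - Ztrue
    Zs <- interplanar_Z(xp, x, cpt, fx$v, Zc_swap)
    expect_lt(abs(abs(Zs) - Ztrue) / Ztrue, 1e-6)
    # coincident points: zero separation by convention
    expect_identical(interplanar_Z(x, x, cpt, fx$v, Zc_true), 0)
  }
})

test_that("camera height over the measured plane follows from the reference", {
  for (seed in 1:10) {
    fx <- interplanar_fixture(seed)
    zr <- 0; z0 <- runif(1, 5, 25)
    pos <- c(runif(1, -40, 40), runif(1, -30, 30), 0)
    s1 <- project_point(fx$cam, c(pos[1], pos[2], zr))
    s2 <- project_point(fx$cam, c(pos[1], pos[2], z0))
    cs <- meet(join(s1, s2), fx$vline)
    Zcr <- camera_plane_distance(fx$cam, c(0, 0, zr), c(0, 0, 1))
    Zc <- interplanar_Zc(Zcr, s1, s2, cs, fx$v)
    truth <- camera_plane_distance(fx$cam, c(0, 0, z0), c(0, 0, 1))
    expect_lt(abs(Zc - truth) / truth, 1e-6)
    # coincident planes: Zc reduces to Zcr
    expect_identical(interplanar_Zc(Zcr, s1, s1, cs, fx$v), Zcr)
  }
})

test_that("an ideal vanishing point reduces the bracket to similar triangles", {
  # v ideal: the v-distance factors cancel and
  # Zr / Zcr = d(r1, r2) / d(r1, cr) along the common line
  v <- plane_point(400, -150, 0)   # ideal point of the line direction
  r1 <- plane_point(100, 400)
  cr <- plane_point(500, 250)
  lam <- 0.4                         # r2 at 40% of the way to cr
  r2 <- plane_point(100 + lam * 400, 400 - lam * 150)
  Zr <- 30
  Zcr <- interplanar_Zcr(r1, r2, v, cr, Zr)
  expect_equal(Zcr, Zr / lam, tolerance = 1e-9)
})

test_that("both egg axes are measured with audit points recorded", {
  sc <- make_scene()
  ms <- measurement_scenes_from_truth(sc, endpoints = "projected")
  m <- measure_egg(ms$major, ms$minor)
  expect_s3_class(m, "egg_measurement")
  expect_lt(abs(m$Z_major_mm - sc$truth$major_mm) / sc$truth$major_mm, 1e-6)
  expect_lt(abs(m$Z_minor_mm - sc$truth$minor_mm) / sc$truth$minor_mm, 1e-6)
  expect_named(m$points$major, c("e", "f", "g"))
  df <- write_measurements_csv(list(m), tempfile(fileext = ".csv"))
  expect_equal(nrow(df), 1)
  expect_equal(df$Z_major_mm, m$Z_major_mm)
})

test_that("endpoint snapping removes lateral noise and keeps exact data", {
  sc <- make_scene()
  tr <- sc$truth
  s <- snap_endpoints_to_vp(tr$ab_major$p1, tr$ab_major$p2, tr$vp_u)
  expect_lt(pt_distance(s$p, tr$ab_major$p1), 1e-9)
  expect_lt(pt_distance(s$q, tr$ab_major$p2), 1e-9)
  # noisy endpoints land back on the line through the vanishing point
  set.seed(8)
  a <- euclid(tr$ab_major$p1) + rnorm(2, 0, 1)
  b <- euclid(tr$ab_major$p2) + rnorm(2, 0, 1)
  s2 <- snap_endpoints_to_vp(plane_point(a[1], a[2]), plane_point(b[1], b[2]),
                             tr$vp_u)
  l <- join(tr$vp_u, s2$p)
  expect_lt(incidence_residual(s2$q, l), 1e-9)
})
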