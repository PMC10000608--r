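#' One single-view measurement problem
#'
#' Bundles the image endpoints of the measured segment (egg axis) `ab`, the
#' image endpoints of a world-parallel reference segment `cd` of known length
#' `R` (mm), and the vanishing line of a world plane parallel to both
#' segments. This is all the image-side information the cross-ratio length
#' transfer needs.
#'
#' @param egg_a,egg_b finite `plane_point`s: image of the measured segment.
#' @param ref_c,ref_d finite `plane_point`s: image of the reference segment
#'   (`c` and `d` correspond to the same world side as `a` and `b`:
#'   the construction joins `b` with `d`).
#' @param vline a `plane_line`: vanishing line of the reference plane.
#' @param ref_length_mm positive reference length R in mm.
#' @return an object of class `measurement_scene`.
#' @export
measurement_scene <- function(egg_a, egg_b, ref_c, ref_d, vline,
                              ref_length_mm) {
  for (p in list(egg_a, egg_b, ref_c, ref_d))
    if (is_ideal(p)) stop("measurement_scene: endpoints must be finite")
  if (same_projective(egg_a, egg_b, tol = 1e-12))
    stop("measurement_scene: egg endpoints coincide")
  if (same_projective(ref_c, ref_d, tol = 1e-12))
    stop("measurement_scene: reference endpoints coincide")
  if (!is.numeric(ref_length_mm) || length(ref_length_mm) != 1 ||
      !is.finite(ref_length_mm) || ref_length_mm <= 0)
    stop("measurement_scene: ref_length_mm must be a positive scalar")
  structure(list(egg_a = egg_a, egg_b = egg_b, ref_c = ref_c, ref_d = ref_d,
                 vline = vline, ref_length_mm = ref_length_mm),
            class = "measurement_scene")
}

#' Transfer the reference length onto the measured line
#'
#' The image-side construction of the parallel-segment transfer: `bd` meets
#' the vanishing line at `e`; `ec` meets `ab` at the projection point `f`
#' (the image of the world point on line AB at reference distance from B);
#' `g` is the vanishing point of the measured direction, `ab` meet the
#' vanishing line. `g` is ideal exactly when the measured direction is
#' parallel to the image plane.
#'
#' @param scene a [measurement_scene()].
#' @return list with `plane_point`s `e`, `f`, `g`.
#' @export
transfer_projection_point <- function(scene) {
  bd <- join(scene$egg_b, scene$ref_d)
  if (same_projective(bd, scene$vline, tol = 1e-12))
    stop("transfer_projection_point: line bd coincides with the vanishing line (intersection e undefined)")
  e <- meet(bd, scene$vline)
  ab <- join(scene$egg_a, scene$egg_b)
  if (same_projective(e, scene$ref_c, tol = 1e-12))
    stop("transfer_projection_point: e coincides with c (line ec undefined)")
  ec <- join(e, scene$ref_c)
  if (same_projective(ec, ab, tol = 1e-12))
    stop("transfer_projection_point: line ec coincides with ab (projection point f undefined)")
  f <- meet(ec, ab)
  if (same_projective(ab, scene$vline, tol = 1e-12))
    stop("transfer_projection_point: ab coincides with the vanishing line (vanishing point g undefined)")
  g <- meet(ab, scene$vline)
  list(e = e, f = f, g = g)
}

#' Measure one axis length by cross-ratio length transfer
#'
#' Recovers the world length Z of the imaged segment `ab` from a
#' world-parallel reference of known length R: after transferring the
#' reference onto line `ab` ([transfer_projection_point()]),
#' `Z = R * [d(b,a) * d(g,f)] / [d(b,f) * d(g,a)]` with signed distances
#' along `ab`; the `g`-dependent factor is computed through
#' [ratio_with_possible_ideal()] and is exactly 1 when `g` is ideal.
#'
#' @param scene a [measurement_scene()].
#' @return length Z in mm, with the audit points `e`, `f`, `g` attached as
#'   attribute `"points"`.
#' @export
#' @examples
#' # affine limit: vanishing line ideal, reference 40 mm maps 40 px,
#' # egg spans 100 px on a parallel line -> 100 mm
#' sc <- measurement_scene(plane_point(0, 0), plane_point(0, 100),
#'                         plane_point(40, 60), plane_point(40, 100),
#'                         plane_line(0, 0, 1), 40)
#' measure_axis(sc)
measure_axis <- function(scene) {
  efg <- transfer_projection_point(scene)
  f <- efg$f
  g <- efg$g
  a <- scene$egg_a
  b <- scene$egg_b
  if (is_ideal(f))
    stop("measure_axis: projection point f is ideal (degenerate configuration)")
  if (same_projective(f, b, tol = 1e-12))
    stop("measure_axis: reference projects to zero length on the measured line (f = b)")
  t <- line_params(list(b, a, f))
  d_ba <- t[2] - t[1]
  d_bf <- t[3] - t[1]
  gfac <- ratio_with_possible_ideal(g, f, a)  # d(g,f)/d(g,a), 1 when g ideal
  Z <- scene$ref_length_mm * (d_ba / d_bf) * gfac
  Z <- abs(Z)
  attr(Z, "points") <- efg
  Z
}

# signed parameters of four collinear points, permitting ideal entries
interp_params <- function(pts, tol = 1e-6) line_params(pts, tol = tol)

#' Camera distance to the reference plane from a known in-plane separation
#'
#' Given the images `r1`, `r2` of two world points a known distance `Zr`
#' apart along the reference direction (with `r1` on the reference-card base
#' plane), the vanishing point `v` of that direction and the intersection
#' `cr` of line `r1 r2` with the vanishing line, the cross-ratio yields
#' `Zr / Zcr = 1 - [d(r1,v) * d(r2,cr)] / [d(r2,v) * d(r1,cr)]` where `Zcr`
#' is the distance from the camera to the base plane. Signed distances along
#' the common line; `v` ideal reduces to the affine ratio.
#'
#' @param r1,r2 finite collinear `plane_point`s.
#' @param v_pt vanishing point of the direction (may be ideal).
#' @param cr_pt intersection of line `r1 r2` with the vanishing line.
#' @param Zr known separation in mm (> 0).
#' @return `Zcr` in mm.
#' @export
interplanar_Zcr <- function(r1, r2, v_pt, cr_pt, Zr) {
  if (!is.numeric(Zr) || Zr <= 0) stop("interplanar_Zcr: Zr must be positive")
  t <- interp_params(list(r1, r2, v_pt, cr_pt))
  if (is.na(t[4]) || is.na(t[1]) || is.na(t[2]))
    stop("interplanar_Zcr: r1, r2 and cr must be finite")
  if (is.na(t[3])) {
    tau <- (t[4] - t[2]) / (t[4] - t[1])          # v ideal: factors cancel
  } else {
    tau <- ((t[3] - t[1]) * (t[4] - t[2])) / ((t[3] - t[2]) * (t[4] - t[1]))
  }
  bracket <- 1 - tau
  if (bracket <= 1e-9 || bracket > 1 + 1e-6)
    stop("interplanar_Zcr: inconsistent configuration (Zr/Zcr ratio outside (0, 1])")
  Zr / bracket
}

#' Separation of two parallel planes from the camera distance to one of them
#'
#' Given the images `x`, `x'` of a world point on the base plane and its
#' parallel projection on the second plane, the vanishing point `v` of the
#' normal direction, the intersection `c` of line `x x'` with the vanishing
#' line, and the camera-to-base-plane distance `Zc`, the cross-ratio
#' identity `Zc / (Zc - Z) = [d(x,c) * d(x',v)] / [d(x',c) * d(x,v)]`
#' (the world point under `c` sits at camera height) solves for the signed
#' separation `Z = Zc * (1 - 1/rho)`, positive toward the camera.
#'
#' @param x_img,xprime_img finite collinear `plane_point`s.
#' @param c_pt intersection with the vanishing line; @param v_pt vanishing
#'   point of the normal direction (may be ideal).
#' @param Zc camera-to-base-plane distance in mm (> 0).
#' @return signed separation `Z` in mm (callers take `abs()` for a length).
#' @export
interplanar_Z <- function(x_img, xprime_img, c_pt, v_pt, Zc) {
  if (!is.numeric(Zc) || Zc <= 0) stop("interplanar_Z: Zc must be positive")
  if (same_projective(x_img, xprime_img, tol = 1e-12)) return(0)
  t <- interp_params(list(x_img, xprime_img, c_pt, v_pt))
  if (is.na(t[1]) || is.na(t[2]) || is.na(t[3]))
    stop("interplanar_Z: x, x' and c must be finite")
  if (is.na(t[4])) {
    rho <- (t[3] - t[1]) / (t[3] - t[2])          # v ideal: factors cancel
  } else {
    rho <- ((t[3] - t[1]) * (t[4] - t[2])) / ((t[3] - t[2]) * (t[4] - t[1]))
  }
  if (abs(rho) < 1e-9)
    stop("interplanar_Z: inconsistent configuration (separation unbounded)")
  if (abs(rho - 1) < 1e-12)
    stop("interplanar_Z: distinct points force a ratio of 1 (inconsistent configuration)")
  Zc * (1 - 1 / rho)
}

#' Camera distance to the measured plane from the reference-plane distance
#'
#' Given `Zcr` (camera to the reference-card base plane), the images `s1`
#' (point on that base plane) and `s2` (point on the measured object's base
#' plane) on one world line along the normal direction, `cs` the
#' intersection of that line's image with the vanishing line and `v` the
#' normal direction's vanishing point, the cross-ratio gives
#' `Zc = Zcr * [d(s2,cs) * d(s1,v)] / [d(s1,cs) * d(s2,v)]` (signed
#' distances; the grouping is the one consistent with the pinhole-camera
#' identity `CR(s2, s1; cs, v) = Zc / Zcr`).
#'
#' @param Zcr camera-to-reference-plane distance in mm (> 0).
#' @param s1,s2 finite collinear `plane_point`s; @param cs_pt intersection
#'   with the vanishing line; @param v_pt vanishing point (may be ideal).
#' @return `Zc` in mm.
#' @export
interplanar_Zc <- function(Zcr, s1, s2, cs_pt, v_pt) {
  if (!is.numeric(Zcr) || Zcr <= 0) stop("interplanar_Zc: Zcr must be positive")
  if (same_projective(s1, s2, tol = 1e-12)) return(Zcr)  # coincident planes
  t <- interp_params(list(s2, s1, cs_pt, v_pt))
  if (is.na(t[1]) || is.na(t[2]) || is.na(t[3]))
    stop("interplanar_Zc: s1, s2 and cs must be finite")
  if (is.na(t[4])) {
    rho <- (t[3] - t[1]) / (t[3] - t[2])
  } else {
    rho <- ((t[3] - t[1]) * (t[4] - t[2])) / ((t[3] - t[2]) * (t[4] - t[1]))
  }
  if (!is.finite(rho) || rho <= 0)
    stop("interplanar_Zc: degenerate distances")
  Zcr * rho
}

#' Measure both egg axes
#'
#' Applies [measure_axis()] to a major-axis scene and a minor-axis scene (the
#' latter built in the 90-degree-rotated frame geometry where the minor
#' direction's vanishing point is estimated) and returns both lengths with
#' the intermediate transfer points for audit.
#'
#' @param scene_major,scene_minor [measurement_scene()]s for the two axes.
#' @return object of class `egg_measurement`: list with `Z_major_mm`,
#'   `Z_minor_mm`, and `points` (the `e`, `f`, `g` triples per axis).
#' @export
measure_egg <- function(scene_major, scene_minor) {
  if (missing(scene_minor) || is.null(scene_minor))
    stop("measure_egg: minor-axis scene is missing")
  if (missing(scene_major) || is.null(scene_major))
    stop("measure_egg: major-axis scene is missing")
  zmaj <- tryCatch(measure_axis(scene_major),
                   error = function(e) stop("measure_egg [major axis]: ",
                                            conditionMessage(e)))
  zmin <- tryCatch(measure_axis(scene_minor),
                   error = function(e) stop("measure_egg [minor axis]: ",
                                            conditionMessage(e)))
  structure(list(Z_major_mm = as.numeric(zmaj), Z_minor_mm = as.numeric(zmin),
                 points = list(major = attr(zmaj, "points"),
                               minor = attr(zmin, "points"))),
            class = "egg_measurement")
}

#' @export
print.egg_measurement <- function(x, ...) {
  cat("<egg_measurement>\n")
  cat(sprintf("  major axis: %.3f mm\n", x$Z_major_mm))
  cat(sprintf("  minor axis: %.3f mm\n", x$Z_minor_mm))
  invisible(x)
}

#' Write egg measurements to CSV
#'
#' One row per sample: the two axis lengths and the Euclidean coordinates of
#' the audit points `e`, `f`, `g` for each axis (NA for ideal points).
#'
#' @param measurements list of `egg_measurement`s; @param path output CSV;
#' @param sample_ids optional ids (defaults to 1..n).
#' @return the data frame written, invisibly.
#' @export
write_measurements_csv <- function(measurements, path,
                                   sample_ids = seq_along(measurements)) {
  coord <- function(p, i) if (is_ideal(p)) NA_real_ else euclid(p)[i]
  rows <- lapply(seq_along(measurements), function(k) {
    m <- measurements[[k]]
    out <- list(sample_id = sample_ids[k],
                Z_major_mm = m$Z_major_mm, Z_minor_mm = m$Z_minor_mm)
    for (ax in c("major", "minor")) {
      for (nm in c("e", "f", "g")) {
        p <- m$points[[ax]][[nm]]
        out[[paste0(ax, "_", nm, "_x")]] <- coord(p, 1)
        out[[paste0(ax, "_", nm, "_y")]] <- coord(p, 2)
      }
    }
    as.data.frame(out)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Constrain segment endpoints by a known vanishing point
#'
#' When the world direction of an imaged segment is known (an egg axis held
#' by the carrier, a card stroke), its image line must pass through that
#' direction's vanishing point. This projects noisy endpoints onto the
#' least-squares line through the vanishing point, removing the lateral
#' component of endpoint noise — the component the length-transfer
#' construction amplifies most. Exact endpoints are left unchanged.
#'
#' @param p,q finite `plane_point`s (the noisy endpoints).
#' @param vp the direction's vanishing point (finite or ideal).
#' @return list with the two projected `plane_point`s.
#' @export
snap_endpoints_to_vp <- function(p, q, vp) {
  a <- euclid(p); b <- euclid(q)
  if (is_ideal(vp)) {
    u <- unclass(vp)[1:2]
    u <- u / sqrt(sum(u^2))
    n <- c(-u[2], u[1])
    off <- mean(c(sum(a * n), sum(b * n)))
    proj <- function(x) x + (off - sum(x * n)) * n
  } else {
    v0 <- euclid(vp)
    X <- rbind(a - v0, b - v0)
    u <- svd(X)$v[, 1]
    proj <- function(x) v0 + sum((x - v0) * u) * u
  }
  a2 <- proj(a); b2 <- proj(b)
  list(p = plane_point(a2[1], a2[2]), q = plane_point(b2[1], b2[2]))
}
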