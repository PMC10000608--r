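#' Measure an egg from rendered/segmented rasters
#'
#' The assembled single-view pipeline for one image:
#' \enumerate{
#'   \item segment (or accept) a 3-class label mask;
#'   \item re-extract the card strokes from the per-card line-pattern masks;
#'   \item estimate the horizontal-direction vanishing point from the
#'     horizontal stroke family, and the vertical-direction vanishing point
#'     from the vertical family *in the 90-degree-rotated frame* (mapped back
#'     afterwards), then join them into the vanishing line;
#'   \item take the egg endpoints as the support points of the egg region
#'     along the direction from the image centre toward each vanishing
#'     point, and the reference endpoints from an extracted full stroke of
#'     known length;
#'   \item run the cross-ratio length transfer for both axes.
#' }
#'
#' @param mask a [label_mask()] (the segmentation of the image).
#' @param line_masks list with logical matrices `left` and `right`: the
#'   binary stroke patterns of the two cards (e.g. from [render_scene()], or
#'   thresholded card crops of a photograph).
#' @param ref_length_mm the known stroke length R in mm.
#' @param noise_scale expected endpoint noise (pixels) for the MLESAC score.
#' @param seed seed for the stroke extraction and MLESAC sampling.
#' @param min_stroke_px minimum accepted stroke length in pixels.
#' @return an [measure_egg()] result with the estimated
#'   `vanishing_geometry` attached as attribute `"vanishing"`.
#' @export
measure_from_rasters <- function(mask, line_masks, ref_length_mm,
                                 noise_scale = 1, seed = 1,
                                 min_stroke_px = 40) {
  H <- mask$height
  ctr <- c((mask$width - 1) / 2, (H - 1) / 2)
  segs_left <- card_segments_from_mask(line_masks$left, min_length = min_stroke_px,
                                       seed = seed)
  segs_right <- card_segments_from_mask(line_masks$right, min_length = min_stroke_px,
                                        seed = seed)
  horiz <- function(s) { d <- seg_direction(s); abs(d[1]) > abs(d[2]) }
  seg_u <- Filter(horiz, c(segs_left, segs_right))
  seg_w <- Filter(Negate(horiz), c(segs_left, segs_right))
  if (length(seg_u) < 2 || length(seg_w) < 2)
    stop("measure_from_rasters: need at least 2 strokes per direction")
  est_u <- estimate_vanishing_point(seg_u, noise_scale = noise_scale, seed = seed)
  # vertical family: estimate in the rotated frame where it is horizontal
  seg_w_rot <- lapply(seg_w, function(s)
    line_segment(rotate_frame_90(s$p_start, H), rotate_frame_90(s$p_end, H)))
  est_w_rot <- estimate_vanishing_point(seg_w_rot, noise_scale = noise_scale,
                                        seed = seed)
  vp_u <- est_u$vp
  vp_w <- rotate_frame_90(est_w_rot$vp, H, inverse = TRUE)
  vg <- vanishing_geometry(vp_u, vp_w, est_u$inlier_fraction,
                           est_w_rot$inlier_fraction)
  dir_toward <- function(vp) {
    if (is_ideal(vp)) unclass(vp)[1:2] else euclid(vp) - ctr
  }
  egg_major <- region_moment_ellipse_points(mask, "egg", dir_toward(vp_u), "major")
  egg_minor <- region_moment_ellipse_points(mask, "egg", dir_toward(vp_w), "minor")
  # every full-length stroke of a family images the same known length, so
  # measure against several and average (the multi-reference analogue of
  # averaging the reference coordinates over images); strokes whose support
  # line lies close to the egg-axis line give an ill-conditioned transfer, so
  # only the better-offset half of the family is used
  axis_over_refs <- function(ab, fam, dirv) {
    lens <- vapply(fam, function(s) pt_distance(s$p_start, s$p_end), numeric(1))
    cand <- fam[lens >= 0.85 * max(lens)]
    mid <- (euclid(ab$p1) + euclid(ab$p2)) / 2
    off <- vapply(cand, function(s) {
      l <- normalize_h(unclass(seg_support_line(s)))
      point_line_dist(mid, l)
    }, numeric(1))
    keep <- order(off, decreasing = TRUE)[seq_len(max(2, ceiling(length(cand) / 2)))]
    zs <- vapply(cand[keep], function(s) {
      cd <- pick_reference_segment(list(s), dirv)
      as.numeric(measure_axis(measurement_scene(ab$p1, ab$p2, cd$p1, cd$p2,
                                                vg$vline, ref_length_mm)))
    }, numeric(1))
    mean(zs)
  }
  out <- structure(
    list(Z_major_mm = axis_over_refs(egg_major, seg_u, dir_toward(vp_u)),
         Z_minor_mm = axis_over_refs(egg_minor, seg_w, dir_toward(vp_w)),
         points = NULL),
    class = "egg_measurement")
  attr(out, "vanishing") <- vg
  out
}

# choose the reference stroke among extracted segments of one family: the
# longest one (most reliably spanning a full stroke); endpoints ordered by
# projection onto the measured direction so they pair with the egg endpoints
pick_reference_segment <- function(segs, direction) {
  lens <- vapply(segs, function(s) pt_distance(s$p_start, s$p_end), numeric(1))
  s <- segs[[which.max(lens)]]
  d <- direction / sqrt(sum(direction^2))
  pa <- sum(euclid(s$p_start) * d)
  pb <- sum(euclid(s$p_end) * d)
  if (pa <= pb) axis_endpoints(s$p_start, s$p_end, "reference")
  else axis_endpoints(s$p_end, s$p_start, "reference")
}
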