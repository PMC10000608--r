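#' The 3-class label palette
#'
#' Class-to-RGB mapping used by all mask I/O: background (255, 0, 0),
#' egg (250, 250, 0), reference (255, 255, 255).
#'
#' @return named 3x3 integer matrix (rows = classes, columns = R, G, B).
#' @export
label_palette <- function() {
  m <- rbind(background = c(255L, 0L, 0L),
             egg        = c(250L, 250L, 0L),
             reference  = c(255L, 255L, 255L))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Label mask container
#'
#' A raster of class labels over `{background, egg, reference}` stored as a
#' character-level factor matrix (rows = y, columns = x).
#'
#' @param classes matrix of class names (or integer indices 1..3 into the
#'   palette rows).
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(classes) {
  pal <- label_palette()
  if (is.numeric(classes)) {
    cl <- matrix(rownames(pal)[classes], nrow = nrow(classes))
  } else {
    cl <- classes
  }
  bad <- !(cl %in% rownames(pal))
  if (any(bad)) stop("label_mask: unknown class label(s): ",
                     paste(unique(cl[bad]), collapse = ", "))
  structure(list(classes = cl, width = ncol(cl), height = nrow(cl),
                 palette = pal),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$classes, levels = rownames(x$palette)))
  cat(sprintf("<label_mask> %d x %d px;", x$width, x$height))
  cat(sprintf(" %s=%d", names(tab), as.integer(tab)), "\n")
  invisible(x)
}

#' Read a label mask from a palette-encoded PNG
#'
#' Every pixel's RGB must match a palette entry exactly, or within
#' `tolerance` per channel (useful for lossy-compressed masks re-saved as
#' PNG).
#'
#' @param path PNG file path.
#' @param tolerance per-channel absolute tolerance in 0..255 (default 0).
#' @return a [label_mask()].
#' @export
read_label_mask <- function(path, tolerance = 0) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  rgb255 <- round(img[, , 1:3, drop = FALSE] * 255)
  pal <- label_palette()
  h <- dim(rgb255)[1]; w <- dim(rgb255)[2]
  # distance of every pixel to every palette entry (max over channels)
  dist <- array(0, dim = c(h, w, nrow(pal)))
  for (k in seq_len(nrow(pal))) {
    dist[, , k] <- pmax(abs(rgb255[, , 1] - pal[k, 1]),
                        abs(rgb255[, , 2] - pal[k, 2]),
                        abs(rgb255[, , 3] - pal[k, 3]))
  }
  best <- apply(dist, c(1, 2), which.min)
  bestd <- apply(dist, c(1, 2), min)
  if (any(bestd > tolerance)) {
    bad <- which(bestd > tolerance, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "read_label_mask: pixel (%d, %d) has RGB (%d, %d, %d) not in the palette",
      bad[2] - 1, bad[1] - 1,
      rgb255[bad[1], bad[2], 1], rgb255[bad[1], bad[2], 2],
      rgb255[bad[1], bad[2], 3]))
  }
  label_mask(matrix(rownames(pal)[best], nrow = h))
}

#' Write a label mask as a palette-encoded PNG
#'
#' Lossless round trip with [read_label_mask()].
#'
#' @param mask a [label_mask()]; @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  pal <- mask$palette / 255
  idx <- match(mask$classes, rownames(mask$palette))
  h <- mask$height; w <- mask$width
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[idx, ch], nrow = h)
  png::writePNG(img, path)
  invisible(path)
}

#' Binary raster of one class
#'
#' @param mask a [label_mask()]; @param cls class name.
#' @return logical matrix.
#' @export
class_raster <- function(mask, cls) {
  if (!cls %in% rownames(mask$palette))
    stop("class_raster: unknown class ", cls)
  mask$classes == cls
}

#' Default thresholds for the classical segmentation fallback
#'
#' Per-class inclusive RGB ranges (0..255) tuned to the synthetic palette
#' rendering; override any entry for real photographs.
#'
#' @return nested list `segmentation:` style configuration.
#' @export
default_segmentation_config <- function() {
  list(segmentation = list(
    egg       = list(min = c(200, 200, 0),   max = c(255, 255, 120)),
    reference = list(min = c(230, 230, 230), max = c(255, 255, 255)),
    morphology_radius = 2
  ))
}

#' Classical colour-threshold segmentation
#'
#' A deterministic fallback segmenter: per-class RGB-range thresholding,
#' morphological opening then closing (EBImage disc kernel), and retention of
#' the largest connected component per foreground class; remaining pixels are
#' background. Intended for controlled scenes (the synthetic renderer, flat
#' studio backgrounds), not as a general segmenter.
#'
#' @param rgb_image numeric array `h x w x 3` in `[0, 1]` or 0..255.
#' @param config list as [default_segmentation_config()].
#' @return a [label_mask()].
#' @export
segment_classical <- function(rgb_image, config = default_segmentation_config()) {
  img <- rgb_image
  if (max(img) <= 1) img <- img * 255
  seg <- config$segmentation
  rad <- seg$morphology_radius %||% 2
  h <- dim(img)[1]; w <- dim(img)[2]
  cl <- matrix("background", nrow = h, ncol = w)
  kern <- EBImage::makeBrush(2 * rad + 1, shape = "disc")
  for (cls in c("reference", "egg")) {   # egg painted last: wins overlaps
    rg <- seg[[cls]]
    if (is.null(rg)) next
    bin <- img[, , 1] >= rg$min[1] & img[, , 1] <= rg$max[1] &
           img[, , 2] >= rg$min[2] & img[, , 2] <= rg$max[2] &
           img[, , 3] >= rg$min[3] & img[, , 3] <= rg$max[3]
    if (!any(bin)) next
    m <- EBImage::closing(EBImage::opening(bin * 1, kern), kern)
    lab <- EBImage::bwlabel(m)
    if (max(lab) == 0) next
    if (cls == "reference") {
      # cards come in pairs: keep every component at least half the largest
      sizes <- tabulate(as.integer(lab[lab > 0]))
      keep <- which(sizes >= max(sizes) / 2)
      cl[matrix(as.integer(lab) %in% keep, nrow = h)] <- cls
    } else {
      sizes <- tabulate(as.integer(lab[lab > 0]))
      cl[lab == which.max(sizes)] <- cls
    }
  }
  if (!any(cl == "egg"))
    stop("segment_classical: no egg-class pixels found (empty segmentation)")
  label_mask(cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Axis endpoints
#'
#' A pair of pixel points tagged by the axis they delimit.
#'
#' @param p1,p2 distinct finite `plane_point`s.
#' @param axis_tag one of `"major"`, `"minor"`, `"reference"`.
#' @return object of class `axis_endpoints`.
#' @export
axis_endpoints <- function(p1, p2, axis_tag = c("major", "minor", "reference")) {
  axis_tag <- match.arg(axis_tag)
  if (same_projective(p1, p2, tol = 1e-12))
    stop("axis_endpoints: endpoints coincide")
  structure(list(p1 = p1, p2 = p2, axis_tag = axis_tag),
            class = "axis_endpoints")
}

#' @export
print.axis_endpoints <- function(x, ...) {
  a <- euclid(x$p1); b <- euclid(x$p2)
  cat(sprintf("<axis_endpoints> %s: (%g, %g) -- (%g, %g)\n",
              x$axis_tag, a[1], a[2], b[1], b[2]))
  invisible(x)
}

#' Support points of a class region along a direction
#'
#' Returns the two pixels (at pixel centres, 0-based) of the class region
#' whose projections onto `direction` are minimal (`p1`) and maximal (`p2`);
#' ties broken by smaller row then smaller column. These are the image
#' endpoints `a`, `b` (egg) and `c`, `d` (reference) fed to the measurement
#' construction.
#'
#' @param mask a [label_mask()]; @param cls class name;
#' @param direction length-2 numeric (need not be unit).
#' @param axis_tag tag for the returned [axis_endpoints()].
#' @return an [axis_endpoints()].
#' @export
region_extreme_points <- function(mask, cls, direction,
                                  axis_tag = "reference") {
  sel <- which(class_raster(mask, cls), arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop("region_extreme_points: class '", cls, "' region is empty")
  if (nrow(sel) == 1)
    stop("region_extreme_points: single-pixel region (endpoints coincide)")
  x <- sel[, 2] - 1; y <- sel[, 1] - 1
  d <- direction / sqrt(sum(direction^2))
  proj <- x * d[1] + y * d[2]
  pick <- function(idx) {
    # tie-break: smaller row, then smaller column
    cand <- idx[order(sel[idx, 1], sel[idx, 2])][1]
    plane_point(x[cand], y[cand])
  }
  eps <- 1e-9
  lo <- pick(which(proj <= min(proj) + eps))
  hi <- pick(which(proj >= max(proj) - eps))
  if (same_projective(lo, hi, tol = 1e-12))
    stop("region_extreme_points: degenerate region (support points coincide)")
  axis_endpoints(lo, hi, axis_tag)
}

#' Average reference endpoints across images
#'
#' Coordinate-wise arithmetic mean of the `p1`s and `p2`s of several endpoint
#' sets of the same axis tag — the multi-image averaging rule that damps
#' reference-segmentation noise before measurement.
#'
#' @param endpoint_sets nonempty list of [axis_endpoints()] sharing a tag.
#' @return an [axis_endpoints()].
#' @export
average_reference_endpoints <- function(endpoint_sets) {
  if (length(endpoint_sets) < 1)
    stop("average_reference_endpoints: need at least one endpoint set")
  tags <- vapply(endpoint_sets, function(e) e$axis_tag, character(1))
  if (length(unique(tags)) != 1)
    stop("average_reference_endpoints: mixed axis tags: ",
         paste(unique(tags), collapse = ", "))
  p1 <- rowMeans(vapply(endpoint_sets, function(e) euclid(e$p1), numeric(2)))
  p2 <- rowMeans(vapply(endpoint_sets, function(e) euclid(e$p2), numeric(2)))
  axis_endpoints(plane_point(p1[1], p1[2]), plane_point(p2[1], p2[2]),
                 tags[1])
}

#' Read / write axis endpoints as JSON
#'
#' @param ep an [axis_endpoints()]; @param path file path.
#' @return `read_axis_endpoints` returns an [axis_endpoints()].
#' @export
write_axis_endpoints <- function(ep, path) {
  jsonlite::write_json(list(p1 = euclid(ep$p1), p2 = euclid(ep$p2),
                            axis_tag = ep$axis_tag),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_axis_endpoints
#' @export
read_axis_endpoints <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  axis_endpoints(plane_point(j$p1[1], j$p1[2]),
                 plane_point(j$p2[1], j$p2[2]), j$axis_tag)
}

#' Read segmentation / card configuration from YAML
#'
#' Reads the `segmentation:` (per-class RGB ranges, morphology radius) and
#' `cards:` (per-card rectangular regions of interest) sections used by
#' [segment_classical()] and the measurement pipeline; missing entries fall
#' back to [default_segmentation_config()].
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
read_segmentation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_segmentation_config()
  if (is.null(cfg$segmentation)) cfg$segmentation <- def$segmentation
  for (nm in names(def$segmentation)) {
    if (is.null(cfg$segmentation[[nm]]))
      cfg$segmentation[[nm]] <- def$segmentation[[nm]]
  }
  cfg
}

#' Subpixel support points of a class region along a direction
#'
#' Like [region_extreme_points()], but instead of single extreme pixels each
#' endpoint is the centroid of all region pixels whose projection onto
#' `direction` lies within `slab` pixels of the extreme projection. For a
#' smooth convex outline (an egg silhouette, a printed stroke) the end slab
#' is symmetric about the true tangency point, so the centroid estimates it
#' to subpixel accuracy where a single extreme pixel can sit several pixels
#' off laterally on a flat tip.
#'
#' @inheritParams region_extreme_points
#' @param slab slab depth in pixels (default 1).
#' @return an [axis_endpoints()].
#' @export
region_support_centroid <- function(mask, cls, direction,
                                    axis_tag = "reference", slab = 1) {
  sel <- which(class_raster(mask, cls), arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop("region_support_centroid: class '", cls, "' region is empty")
  if (nrow(sel) == 1)
    stop("region_support_centroid: single-pixel region (endpoints coincide)")
  x <- sel[, 2] - 1; y <- sel[, 1] - 1
  d <- direction / sqrt(sum(direction^2))
  proj <- x * d[1] + y * d[2]
  lo_sel <- proj <= min(proj) + slab
  hi_sel <- proj >= max(proj) - slab
  lo <- plane_point(mean(x[lo_sel]), mean(y[lo_sel]))
  hi <- plane_point(mean(x[hi_sel]), mean(y[hi_sel]))
  if (same_projective(lo, hi, tol = 1e-12))
    stop("region_support_centroid: degenerate region (support points coincide)")
  axis_endpoints(lo, hi, axis_tag)
}

#' Moment-ellipse endpoints of a smooth convex region
#'
#' Fits the area-moment ellipse of the class region (the ellipse with the
#' same centroid and second moments as the filled region: semi-axis
#' matrix `M = 4 * cov`) and returns its two support points along
#' `direction`, `c +/- M d / sqrt(d' M d)`. For an elliptical silhouette this
#' uses every region pixel, so the endpoints are far more stable than single
#' extreme pixels; for markedly non-elliptical regions use
#' [region_extreme_points()] or [region_support_centroid()] instead.
#'
#' @inheritParams region_extreme_points
#' @return an [axis_endpoints()] (`p1` minimal, `p2` maximal projection).
#' @export
region_moment_ellipse_points <- function(mask, cls, direction,
                                         axis_tag = "major") {
  sel <- which(class_raster(mask, cls), arr.ind = TRUE)
  if (nrow(sel) < 3)
    stop("region_moment_ellipse_points: class '", cls,
         "' region too small for moment fitting")
  x <- sel[, 2] - 1; y <- sel[, 1] - 1
  ctr <- c(mean(x), mean(y))
  # pixel-area correction: each pixel is a unit square, variance 1/12
  S <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x) + diag(2) / 12
  M <- 4 * S
  d <- direction / sqrt(sum(direction^2))
  q <- sqrt(sum(d * (M %*% d)))
  off <- as.numeric(M %*% d) / q
  axis_endpoints(plane_point(ctr[1] - off[1], ctr[2] - off[2]),
                 plane_point(ctr[1] + off[1], ctr[2] + off[2]), axis_tag)
}
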