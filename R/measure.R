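#' Classify fungal structures by area
#'
#' Structures with area below 95 um^2 are discarded as debris; dispersed
#' morphologies are any structure with area >= 95 and < 500 um^2; pellets are
#' any structure with area >= 500 um^2. Both boundaries are inclusive on the
#' lower side.
#'
#' @param area area(s) in um^2, >= 0.
#' @param min_area lower inclusive bound for dispersed structures (um^2).
#' @param pellet_area lower inclusive bound for pellets (um^2).
#' @return character vector: `"discarded"`, `"dispersed"` or `"pellet"`.
#' @examples
#' classify_object(c(94.9, 95, 499.9, 500))
#' @export
classify_object <- function(area, min_area = 95, pellet_area = 500) {
  if (any(!is.na(area) & area < 0)) stop("`area` must be >= 0")
  if (min_area >= pellet_area)
    stop("`min_area` must be smaller than `pellet_area`")
  out <- ifelse(area >= pellet_area, "pellet",
                ifelse(area >= min_area, "dispersed", "discarded"))
  out[is.na(area)] <- NA_character_
  out
}

#' Morphology number of a fungal structure
#'
#' Dimensionless shape statistic
#' \deqn{MN = \frac{2 \sqrt{Area} \cdot Solidity}
#'                 {\sqrt{\pi} \cdot Feret \cdot AspectRatio}}
#' equal to 1 for a perfect circle and approaching 0 for a one-dimensional
#' line. For geometrically consistent inputs (Feret the true diameter of a
#' region with the given area) the isodiametric inequality bounds
#' \eqn{2\sqrt{Area}/(\sqrt{\pi} Feret) \le 1}, so MN lies in (0, 1].
#'
#' @param area area in um^2 (> 0).
#' @param solidity area / convex hull area, in (0, 1].
#' @param feret_max maximum caliper (Feret) diameter in um (> 0).
#' @param aspect_ratio maximum / minimum caliper diameter (>= 1).
#' @return morphology number(s); `NA` inputs give `NA`.
#' @examples
#' morphology_number(pi, 1, 2, 1)                 # circle: exactly 1
#' morphology_number(2 * pi, 1, 4, 2)             # 2:1 ellipse: sqrt(2)/4
#' @export
morphology_number <- function(area, solidity, feret_max, aspect_ratio) {
  chk <- function(bad, msg) if (any(bad, na.rm = TRUE)) stop(msg)
  chk(area <= 0, "`area` must be > 0")
  chk(solidity <= 0 | solidity > 1, "`solidity` must be in (0, 1]")
  chk(feret_max <= 0, "`feret_max` must be > 0")
  chk(aspect_ratio < 1, "`aspect_ratio` must be >= 1")
  2 * sqrt(area) * solidity / (sqrt(pi) * feret_max * aspect_ratio)
}

# Exposure masks: for each of the four 4-neighbour directions, object pixels
# whose neighbour in that direction belongs to a different label (or lies
# outside the image). The midpoints of these exposed edges form the
# "mid-crack" boundary contour, which is unbiased to half-pixel digitization:
# a digitized axis-aligned rectangle measures its true width exactly and a
# digitized disk its true diameter to well under a pixel.
exposure_masks <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  obj <- core > 0L
  list(up = obj & core != pad[1:nr, 2:(nc + 1L)],
       down = obj & core != pad[3:(nr + 2L), 2:(nc + 1L)],
       left = obj & core != pad[2:(nr + 1L), 1:nc],
       right = obj & core != pad[2:(nr + 1L), 3:(nc + 2L)])
}

# Mid-crack boundary points (um) for pixels given as an (i, j) index matrix
# with per-direction exposure flags.
midcrack_points <- function(ij, exp_flags, s) {
  x <- (ij[, 2] - 0.5) * s
  y <- (ij[, 1] - 0.5) * s
  rbind(cbind(x[exp_flags$up], y[exp_flags$up] - 0.5 * s),
        cbind(x[exp_flags$down], y[exp_flags$down] + 0.5 * s),
        cbind(x[exp_flags$left] - 0.5 * s, y[exp_flags$left]),
        cbind(x[exp_flags$right] + 0.5 * s, y[exp_flags$right]))
}

# Sub-pixel boundary refinement: circular moving average of the mid-crack
# contour ordered by angle around the centroid. Averaging cancels the
# +/- half-pixel staircase oscillation (zero-mean), leaving caliper and hull
# estimates accurate to ~0.1 px for smooth shapes. Angle ordering is only
# valid for star-shaped objects, so smoothing is skipped (raw contour used)
# whenever consecutive ordered points are not close neighbours, or the
# contour is too short for the window.
smooth_contour <- function(points, centroid, pixel_scale) {
  n <- nrow(points)
  w <- min(9L, 2L * (n %/% 80L) + 1L)
  if (w < 3L) return(points)
  ang <- atan2(points[, 2] - centroid[2], points[, 1] - centroid[1])
  ord <- order(ang)
  p <- points[ord, , drop = FALSE]
  gaps <- sqrt(diff(c(p[, 1], p[1, 1]))^2 + diff(c(p[, 2], p[1, 2]))^2)
  if (max(gaps) > 3 * pixel_scale) return(points)
  half <- (w - 1L) %/% 2L
  idx <- c((n - half + 1L):n, 1L:n, 1L:half)
  xs <- stats::filter(p[idx, 1], rep(1 / w, w), sides = 2)
  ys <- stats::filter(p[idx, 2], rep(1 / w, w), sides = 2)
  cbind(xs[(half + 1L):(half + n)], ys[(half + 1L):(half + n)])
}

measure_one <- function(ij, boundary, pixel_scale, min_area, pellet_area) {
  s <- pixel_scale
  npix <- nrow(ij)
  area <- npix * s^2
  centroid_x <- mean((ij[, 2] - 0.5) * s)
  centroid_y <- mean((ij[, 1] - 0.5) * s)
  if (npix == 1L) {
    # degenerate: minimum caliper is 0 by convention, MN undefined
    return(data.frame(npix = npix, area = area,
                      feret_max = s, feret_min = 0,
                      aspect_ratio = NA_real_, solidity = 1,
                      morphology_number = NA_real_,
                      size_class = classify_object(area, min_area, pellet_area),
                      centroid_x = centroid_x, centroid_y = centroid_y,
                      degenerate = TRUE))
  }
  # Calipers are estimated on the sub-pixel smoothed contour (which cancels
  # the outward staircase bias of the raw crack boundary), with the maximum
  # Feret clamped to within half a pixel of the raw-contour value so that
  # agreement with the brute-force pairwise-distance oracle over the raw
  # boundary points is guaranteed by construction. Solidity uses the
  # smoothed hull for the same reason.
  fer_raw <- feret_calipers(boundary)
  sm <- smooth_contour(boundary, c(centroid_x, centroid_y), s)
  fer <- feret_calipers(sm)
  fer$max <- max(fer$max, fer_raw$max - 0.45 * s)
  if (fer$min <= 0) fer <- fer_raw # smoothing collapsed a thin object
  hull_pix <- if (nrow(fer$hull) >= 3L) count_hull_pixels(fer$hull, s)
              else npix
  solidity <- min(1, npix / max(hull_pix, npix))
  aspect <- fer$max / fer$min
  # measured MN is capped at 1: sub-pixel digitization can push the raw
  # formula marginally above the theoretical circle limit
  mn <- min(1, morphology_number(area, solidity, fer$max, aspect))
  data.frame(npix = npix, area = area,
             feret_max = fer$max, feret_min = fer$min,
             aspect_ratio = aspect, solidity = solidity,
             morphology_number = mn,
             size_class = classify_object(area, min_area, pellet_area),
             centroid_x = centroid_x, centroid_y = centroid_y,
             degenerate = FALSE)
}

#' Measure Euclidean parameters of segmented objects
#'
#' For each labelled object computes: area (pixel count times
#' `pixel_scale^2`), maximum and minimum Feret (caliper) diameters from the
#' convex hull of its mid-crack boundary contour (midpoints of exposed pixel
#' edges, which removes the half-pixel dilation bias), aspect ratio
#' (max / min Feret), solidity (pixel count / pixel count of the rasterized
#' convex hull), the morphology number, a size class (pellet / dispersed /
#' discarded) and the centroid. Single-pixel objects are flagged degenerate:
#' their minimum Feret is 0 and their morphology number undefined, and they
#' are excluded from summaries but retained in the table.
#'
#' @param seg a `pellet_segmentation` from [segment_objects()].
#' @param min_area,pellet_area size-class bounds in um^2, see
#'   [classify_object()].
#' @return data frame with one row per object: `label`, `npix`, `area`,
#'   `feret_max`, `feret_min`, `aspect_ratio`, `solidity`,
#'   `morphology_number`, `size_class`, `centroid_x`, `centroid_y`,
#'   `touches_border`, `degenerate`.
#' @export
measure_objects <- function(seg, min_area = 95, pellet_area = 500) {
  stopifnot(inherits(seg, "pellet_segmentation"))
  empty <- data.frame(label = integer(0), npix = integer(0), area = numeric(0),
                      feret_max = numeric(0), feret_min = numeric(0),
                      aspect_ratio = numeric(0), solidity = numeric(0),
                      morphology_number = numeric(0),
                      size_class = character(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), touches_border = logical(0),
                      degenerate = logical(0))
  if (seg$n_objects == 0L) return(empty)
  lab <- seg$labels
  em <- exposure_masks(lab)
  fg <- which(lab > 0L)
  ij_all <- arrayInd(fg, dim(lab))
  labs <- lab[fg]
  expf <- lapply(em, function(m) m[fg])
  rows <- lapply(seq_len(seg$n_objects), function(k) {
    sel <- labs == k
    ij <- ij_all[sel, , drop = FALSE]
    flags <- lapply(expf, function(v) v[sel])
    measure_one(ij, midcrack_points(ij, flags, seg$pixel_scale),
                seg$pixel_scale, min_area, pellet_area)
  })
  out <- do.call(rbind, rows)
  out <- cbind(label = seq_len(seg$n_objects), out)
  out$touches_border <- seg$touches_border
  rownames(out) <- NULL
  out
}

#' Measure a single object mask
#'
#' Convenience wrapper around the per-object measurement for one logical
#' mask; the mask must be non-empty and form a single 8-connected component.
#'
#' @param mask logical matrix, `TRUE` = object.
#' @param pixel_scale micrometers per pixel.
#' @inheritParams measure_objects
#' @return one-row data frame as in [measure_objects()] (without `label` /
#'   `touches_border`).
#' @examples
#' m <- matrix(FALSE, 30, 50); m[6:25, 6:45] <- TRUE  # 20 x 40 px rectangle
#' measure_object(m, pixel_scale = 1)[, c("area", "feret_max", "feret_min")]
#' @export
measure_object <- function(mask, pixel_scale, min_area = 95,
                           pellet_area = 500) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be logical")
  if (!any(mask)) stop("`mask` is empty")
  lab <- .cc_label(mask, 8L)
  if (max(lab) > 1L) stop("`mask` must be a single connected component")
  em <- exposure_masks(lab)
  fg <- which(mask)
  ij <- arrayInd(fg, dim(mask))
  flags <- lapply(em, function(m) m[fg])
  measure_one(ij, midcrack_points(ij, flags, pixel_scale),
              pixel_scale, min_area, pellet_area)
}

#' Segment and measure one image in a single call
#'
#' @param image numeric matrix or a `pellet_image` fixture (whose
#'   `pixel_scale` is then used by default).
#' @param pixel_scale micrometers per pixel; taken from the fixture if omitted.
#' @param ... passed to [segment_objects()].
#' @inheritParams measure_objects
#' @return list with `segmentation` and `objects` (the measurement table).
#' @export
measure_image <- function(image, pixel_scale = NULL, min_area = 95,
                          pellet_area = 500, ...) {
  if (inherits(image, "pellet_image")) {
    pixel_scale <- pixel_scale %||% image$pixel_scale
    image <- image$image
  }
  if (is.null(pixel_scale)) stop("`pixel_scale` is required")
  seg <- segment_objects(image, pixel_scale, ...)
  list(segmentation = seg,
       objects = measure_objects(seg, min_area, pellet_area))
}

#' Summarize morphology of one culture condition
#'
#' Per-condition statistics of the morphology number and the maximum pellet
#' diameter, computed over pellets only (size class `"pellet"`, non-degenerate
#' objects); dispersed and discarded structures are counted separately.
#'
#' @param objects measurement table from [measure_objects()], all from one
#'   strain/inducer condition (possibly pooled over replicate images).
#' @param condition optional named list/vector (e.g. strain, dox) echoed into
#'   the summary row.
#' @return one-row data frame: pellet/dispersed/discarded counts, `n` (number
#'   of pellets contributing to statistics), mean/median/quartiles of MN and
#'   of diameter; statistics are `NA` when `n` is 0.
#' @export
summarize_condition <- function(objects, condition = NULL) {
  pel <- objects[objects$size_class %in% "pellet" & !objects$degenerate, ,
                 drop = FALSE]
  qs <- function(x, p) if (nrow(pel)) unname(quantile(x, p)) else NA_real_
  st <- function(f, x) if (nrow(pel)) f(x) else NA_real_
  out <- data.frame(
    n = nrow(pel),
    n_pellet = sum(objects$size_class %in% "pellet"),
    n_dispersed = sum(objects$size_class %in% "dispersed"),
    n_discarded = sum(objects$size_class %in% "discarded"),
    mn_mean = st(mean, pel$morphology_number),
    mn_median = st(median, pel$morphology_number),
    mn_q1 = qs(pel$morphology_number, 0.25),
    mn_q3 = qs(pel$morphology_number, 0.75),
    diameter_mean = st(mean, pel$feret_max),
    diameter_median = st(median, pel$feret_max),
    diameter_q1 = qs(pel$feret_max, 0.25),
    diameter_q3 = qs(pel$feret_max, 0.75))
  if (!is.null(condition))
    out <- cbind(as.data.frame(as.list(condition)), out)
  out
}
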