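#' Automatic intensity threshold by between-class variance maximization
#'
#' Otsu's method on the 256-bin histogram of an 8-bit image. Foreground is
#' defined as pixels with intensity strictly greater than the returned value.
#'
#' @param image numeric or integer matrix with values in 0..255.
#' @return scalar threshold in 0..254.
#' @export
otsu_threshold <- function(image) {
  v <- as.integer(round(image))
  v[v < 0L] <- 0L; v[v > 255L] <- 255L
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  n <- sum(h)
  if (n == 0L) stop("empty image")
  lev <- 0:255
  w1 <- cumsum(h)
  mu1 <- cumsum(h * lev)
  mu_t <- mu1[256]
  w2 <- n - w1
  ok <- w1 > 0 & w2 > 0
  between <- rep(-Inf, 256)
  between[ok] <- (mu_t * w1[ok] - n * mu1[ok])^2 / (w1[ok] * w2[ok])
  lev[which.max(between)]
}

#' Segment bright objects from a grayscale culture image
#'
#' Thresholds the image (automatic Otsu threshold by default, or a fixed
#' intensity), labels 8-connected components of supra-threshold pixels, fills
#' interior holes (pellets are treated as solid bodies), and optionally
#' removes components touching the image border, whose truncated calipers
#' would bias diameter statistics. Surviving labels are dense from 1 in
#' raster-scan order.
#'
#' @param image single-channel numeric/integer matrix, 0..255.
#' @param pixel_scale micrometers per pixel (> 0).
#' @param threshold `NULL` for automatic (Otsu) or a fixed intensity;
#'   foreground is `image > threshold`.
#' @param exclude_border drop components touching the image border
#'   (default `TRUE`).
#' @param fill_holes fill enclosed background holes before labeling
#'   (default `TRUE`).
#' @param connectivity 8 (default) or 4.
#' @return object of class `pellet_segmentation`: list with `labels` (integer
#'   matrix, 0 = background), `n_objects`, `threshold` used, `pixel_scale`,
#'   `n_border_excluded`, and `border_labels_touching` (logical per kept
#'   object, all `FALSE` when `exclude_border`). An image with no
#'   supra-threshold pixels yields 0 objects with a warning.
#' @examples
#' img <- generate_pellet_image(list(shape_spec(c(150, 150), 60)),
#'                              pixel_scale = 2, seed = 1)
#' seg <- segment_objects(img$image, pixel_scale = 2)
#' seg$n_objects
#' @export
segment_objects <- function(image, pixel_scale, threshold = NULL,
                            exclude_border = TRUE, fill_holes = TRUE,
                            connectivity = 8L) {
  if (!is.matrix(image)) stop("`image` must be a single-channel matrix")
  stopifnot_scalar_num(pixel_scale, "pixel_scale", positive = TRUE)
  thr <- if (is.null(threshold)) otsu_threshold(image) else threshold
  mask <- image > thr
  if (!any(mask)) {
    warning("no supra-threshold pixels; returning empty segmentation")
    return(structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                          n_objects = 0L, threshold = thr,
                          pixel_scale = pixel_scale, n_border_excluded = 0L,
                          touches_border = logical(0)),
                     class = "pellet_segmentation"))
  }
  if (fill_holes) mask <- .fill_holes(mask)
  lab <- .cc_label(mask, as.integer(connectivity))
  n <- max(lab)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  touches <- seq_len(n) %in% border
  if (exclude_border && any(touches)) {
    remap <- integer(n)
    keep <- which(!touches)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    n_excluded <- sum(touches)
    n <- length(keep)
    touches <- rep(FALSE, n)
  } else {
    n_excluded <- 0L
  }
  structure(list(labels = lab, n_objects = as.integer(n), threshold = thr,
                 pixel_scale = pixel_scale,
                 n_border_excluded = as.integer(n_excluded),
                 touches_border = touches),
            class = "pellet_segmentation")
}

#' @export
print.pellet_segmentation <- function(x, ...) {
  cat(sprintf(
    "<pellet_segmentation> %d object(s), threshold %s, %d border-excluded\n",
    x$n_objects, format(x$threshold), x$n_border_excluded))
  invisible(x)
}
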