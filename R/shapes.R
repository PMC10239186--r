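#' Specify a synthetic pellet-like shape
#'
#' Describes one star-shaped object to render into a synthetic micrograph. The
#' base outline is an ellipse of area `pi * equivalent_radius^2` with axis
#' ratio `elongation`; its boundary radius is modulated by a fixed-frequency
#' cosine of relative amplitude `roughness` with `n_lobes` lobes, plus a small
#' seeded smooth jitter, giving controllable solidity degradation.
#'
#' @param center numeric length-2, object center in micrometers (image frame:
#'   x rightwards, y downwards, origin at the top-left image corner).
#' @param equivalent_radius radius (um) of the circle with the same area as
#'   the unperturbed ellipse; must be > 0.
#' @param elongation axis ratio (>= 1) of the base ellipse.
#' @param roughness relative amplitude of the radial boundary perturbation,
#'   in `[0, 0.9]`. 0 renders an exact ellipse.
#' @param n_lobes integer >= 0, perturbation frequency (lobes around the
#'   boundary). Ignored when `roughness` is 0.
#' @return object of class `shape_spec`.
#' @examples
#' shape_spec(c(500, 500), equivalent_radius = 120, elongation = 2,
#'            roughness = 0.2, n_lobes = 7)
#' @export
shape_spec <- function(center, equivalent_radius, elongation = 1,
                       roughness = 0, n_lobes = 0L) {
  if (length(center) != 2L || !all(is.finite(center)))
    stop("`center` must be two finite coordinates (um)")
  stopifnot_scalar_num(equivalent_radius, "equivalent_radius", positive = TRUE)
  stopifnot_scalar_num(elongation, "elongation")
  if (elongation < 1) stop("`elongation` must be >= 1")
  stopifnot_scalar_num(roughness, "roughness")
  if (roughness < 0 || roughness > 0.9) stop("`roughness` must be in [0, 0.9]")
  if (n_lobes < 0) stop("`n_lobes` must be >= 0")
  structure(list(center = as.numeric(center),
                 equivalent_radius = equivalent_radius,
                 elongation = elongation,
                 roughness = roughness,
                 n_lobes = as.integer(n_lobes)),
            class = "shape_spec")
}

# Analytic boundary radius r(theta) for a spec plus drawn perturbation
# parameters (phase, jitter harmonics). Works vectorized over theta.
shape_radius <- function(spec, theta, pert) {
  a <- spec$equivalent_radius * sqrt(spec$elongation)
  b <- spec$equivalent_radius / sqrt(spec$elongation)
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (spec$roughness <= 0) return(r_ell)
  mod <- spec$roughness * cos(spec$n_lobes * theta + pert$phase)
  if (length(pert$jit_amp)) {
    for (k in seq_along(pert$jit_amp))
      mod <- mod + pert$jit_amp[k] * cos(k * theta + pert$jit_phase[k])
  }
  r_ell * pmax(1 + mod, 0.05)
}

# Draw the seeded perturbation parameters for one shape (consumes RNG).
draw_perturbation <- function(spec, jitter_frac = 0.15) {
  if (spec$roughness <= 0)
    return(list(phase = 0, jit_amp = numeric(0), jit_phase = numeric(0)))
  list(phase = runif(1, 0, 2 * pi),
       jit_amp = rnorm(3, 0, spec$roughness * jitter_frac / sqrt(3)),
       jit_phase = runif(3, 0, 2 * pi))
}

#' Render synthetic pellet shapes into a grayscale image with ground truth
#'
#' Rasterizes a list of [shape_spec()] objects onto a black (intensity 0)
#' background, emulating stereomicroscope images of submerged fungal cultures
#' lit from above: bright solid objects on a dark field. Foreground pixels get
#' intensity `fg_mean` plus seeded Gaussian grain, clipped to stay strictly
#' above `threshold`. Alongside the image, an analytic truth table is returned
#' with each shape's polygon, area (closed form `pi * r^2 * ` for ellipses,
#' shoelace otherwise) and caliper diameters, so segmentation and measurement
#' can be validated against known geometry.
#'
#' Rendering is deterministic for a fixed `seed`. Shapes must fit in the frame
#' and must not overlap; placement is validated with each shape's bounding
#' circle (maximum boundary radius), and violations name the offending shapes.
#'
#' @param specs list of [shape_spec()] objects.
#' @param pixel_scale micrometers per pixel (> 0).
#' @param width_px,height_px frame size in pixels; defaults fit all shapes
#'   with a 5-pixel margin.
#' @param seed integer seed controlling boundary jitter and intensity grain.
#' @param fg_mean,fg_sd foreground intensity mean and grain s.d. (8-bit).
#' @param threshold stated intensity threshold; every object pixel is strictly
#'   brighter than this, every background pixel is 0.
#' @param n_vertices vertices per truth polygon.
#' @return object of class `pellet_image`: list with `image` (integer matrix,
#'   rows = y), `pixel_scale`, `threshold`, `truth` (data frame: id, center,
#'   shape parameters, `area_um2`, `feret_max_um`, `feret_min_um`, `convex`)
#'   and `polygons` (list of vertex matrices in um).
#' @examples
#' img <- generate_pellet_image(list(shape_spec(c(200, 200), 80)),
#'                              pixel_scale = 2, seed = 1)
#' img$truth$area_um2 # pi * 80^2
#' @export
generate_pellet_image <- function(specs, pixel_scale, width_px = NULL,
                                  height_px = NULL, seed = NULL,
                                  fg_mean = 200, fg_sd = 12, threshold = 70,
                                  n_vertices = 720L) {
  if (inherits(specs, "shape_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "shape_spec")))
    stop("`specs` must be a list of shape_spec objects")
  stopifnot_scalar_num(pixel_scale, "pixel_scale", positive = TRUE)
  with_seed(seed, {
    perts <- lapply(specs, draw_perturbation)
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    polys <- vector("list", length(specs))
    rmax <- numeric(length(specs))
    for (s in seq_along(specs)) {
      r <- shape_radius(specs[[s]], theta, perts[[s]])
      rmax[s] <- max(r) * 1.001
      polys[[s]] <- cbind(x = specs[[s]]$center[1] + r * cos(theta),
                          y = specs[[s]]$center[2] + r * sin(theta))
    }
    cx <- vapply(specs, function(s) s$center[1], numeric(1))
    cy <- vapply(specs, function(s) s$center[2], numeric(1))
    # bounding-circle overlap check
    if (length(specs) > 1L) {
      for (a in seq_len(length(specs) - 1L)) for (b in (a + 1L):length(specs)) {
        d <- sqrt((cx[a] - cx[b])^2 + (cy[a] - cy[b])^2)
        if (d <= rmax[a] + rmax[b])
          stop(sprintf("shapes %d and %d overlap (bounding circles intersect)",
                       a, b))
      }
    }
    margin <- 5 * pixel_scale
    if (is.null(width_px))
      width_px <- ceiling((max(cx + rmax) + margin) / pixel_scale)
    if (is.null(height_px))
      height_px <- ceiling((max(cy + rmax) + margin) / pixel_scale)
    if (any(cx - rmax < 0) || any(cy - rmax < 0) ||
        any(cx + rmax > width_px * pixel_scale) ||
        any(cy + rmax > height_px * pixel_scale)) {
      bad <- which(cx - rmax < 0 | cy - rmax < 0 |
                     cx + rmax > width_px * pixel_scale |
                     cy + rmax > height_px * pixel_scale)
      stop(sprintf("shape(s) %s do not fit inside the %dx%d px frame",
                   paste(bad, collapse = ", "), width_px, height_px))
    }
    img <- matrix(0L, nrow = height_px, ncol = width_px)
    floor_int <- threshold + 10
    for (s in seq_along(specs)) {
      sp <- specs[[s]]
      j_lo <- max(1L, floor((cx[s] - rmax[s]) / pixel_scale))
      j_hi <- min(width_px, ceiling((cx[s] + rmax[s]) / pixel_scale))
      i_lo <- max(1L, floor((cy[s] - rmax[s]) / pixel_scale))
      i_hi <- min(height_px, ceiling((cy[s] + rmax[s]) / pixel_scale))
      jj <- j_lo:j_hi; ii <- i_lo:i_hi
      xc <- (jj - 0.5) * pixel_scale - cx[s]
      yc <- (ii - 0.5) * pixel_scale - cy[s]
      dx <- matrix(xc, nrow = length(ii), ncol = length(jj), byrow = TRUE)
      dy <- matrix(yc, nrow = length(ii), ncol = length(jj))
      rr <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      inside <- rr <= shape_radius(sp, th, perts[[s]])
      n_in <- sum(inside)
      val <- pmin(255, pmax(floor_int, round(fg_mean + rnorm(n_in, 0, fg_sd))))
      block <- img[ii, jj, drop = FALSE]
      block[inside] <- as.integer(val)
      img[ii, jj] <- block
    }
    truth <- data.frame(
      id = seq_along(specs),
      center_x = cx, center_y = cy,
      equivalent_radius = vapply(specs, `[[`, numeric(1), "equivalent_radius"),
      elongation = vapply(specs, `[[`, numeric(1), "elongation"),
      roughness = vapply(specs, `[[`, numeric(1), "roughness"),
      n_lobes = vapply(specs, `[[`, integer(1), "n_lobes"))
    truth$area_um2 <- vapply(seq_along(specs), function(s) {
      if (specs[[s]]$roughness <= 0) pi * specs[[s]]$equivalent_radius^2
      else polygon_area(polys[[s]])
    }, numeric(1))
    fer <- lapply(polys, feret_calipers)
    truth$feret_max_um <- vapply(fer, `[[`, numeric(1), "max")
    truth$feret_min_um <- vapply(fer, `[[`, numeric(1), "min")
    truth$convex <- truth$roughness <= 0
    structure(list(image = img, pixel_scale = pixel_scale,
                   threshold = threshold, truth = truth, polygons = polys),
              class = "pellet_image")
  })
}

#' @export
print.pellet_image <- function(x, ...) {
  cat(sprintf("<pellet_image> %d x %d px @ %.3g um/px, %d shape(s)\n",
              ncol(x$image), nrow(x$image), x$pixel_scale, nrow(x$truth)))
  invisible(x)
}
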