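# Programmatic fixtures shared across test files.

# Logical disk mask: pixel centers within radius r (pixels) of (cx, cy).
disk_mask <- function(nr, nc, cy, cx, r) {
  xc <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
  yc <- matrix(seq_len(nr) - 0.5, nr, nc)
  (xc - cx)^2 + (yc - cy)^2 <= r^2
}

# Intensity image (0 background, 200 foreground) from a logical mask.
mask_to_image <- function(mask, fg = 200L) {
  img <- matrix(0L, nrow(mask), ncol(mask))
  img[mask] <- fg
  img
}

# A batch of random seeded shape specs placed on a non-overlapping grid,
# returned together with the rendered fixture.
random_shape_fixture <- function(n_shapes, seed, pixel_scale = 1,
                                 radius_range = c(20, 45),
                                 roughness_range = c(0, 0.4)) {
  set.seed(seed)
  per_row <- ceiling(sqrt(n_shapes))
  pitch <- 2.6 * max(radius_range) * 2
  specs <- lapply(seq_len(n_shapes) - 1L, function(k) {
    shape_spec(c((k %% per_row + 0.5) * pitch,
                 (k %/% per_row + 0.5) * pitch) + runif(2),
               equivalent_radius = runif(1, radius_range[1], radius_range[2]),
               elongation = runif(1, 1, 1.8),
               roughness = runif(1, roughness_range[1], roughness_range[2]),
               n_lobes = sample(5:9, 1))
  })
  generate_pellet_image(specs, pixel_scale, seed = seed + 1000L)
}

# True model with four strong effects (per-condition signal s.d. 1 each)
# and moderate noise (condition-level noise s.d. 1): the stated world for
# the selection-recovery criterion.
strong_four_model <- function() {
  base <- default_baselines()
  vars4 <- c("radial_growth_rate", "gc_heat_42C", "gc_congo_red",
             "pellet_diameter")
  cf <- sapply(vars4, function(v) sqrt(3) / (0.3 * base[[v]])) *
    c(1, 1, -1, -1)
  true_model(coefficients = cf, noise_sd = sqrt(3), intercept = 5)
}
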