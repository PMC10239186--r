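test_that("morphology_number matches closed forms and is linear in solidity", {
  expect_identical(morphology_number(pi, 1, 2, 1), 1)
  expect_equal(morphology_number(2 * pi, 1, 4, 2), sqrt(2) / 4)
  mn1 <- morphology_number(1200, 0.8, 60, 1.3)
  expect_equal(morphology_number(1200, 0.4, 60, 1.3), mn1 / 2)
  expect_error(morphology_number(100, 1, 0, 1), "feret_max")
  expect_error(morphology_number(100, 1.2, 10, 1), "solidity")
  expect_error(morphology_number(100, 1, 10, 0.9), "aspect_ratio")
})

test_that("size classes honour the 95/500 um^2 thresholds inclusively", {
  expect_equal(classify_object(c(94.9, 95, 499.9, 500, 10000)),
               c("discarded", "dispersed", "dispersed", "pellet", "pellet"))
  expect_error(classify_object(-1), ">= 0")
  expect_error(classify_object(100, min_area = 500, pellet_area = 95),
               "smaller")
})

test_that("a rasterized circle measures close to its closed form", {
  for (r in c(30, 50)) {
    img <- generate_pellet_image(list(shape_spec(c(2.6 * r, 2.6 * r), r)),
                                 pixel_scale = 1, seed = r)
    o <- measure_image(img)$objects
    expect_equal(o$area, pi * r^2, tolerance = 0.02)
    expect_equal(o$feret_max, 2 * r, tolerance = 0.02)
    expect_gt(o$solidity, 0.98)
    expect_equal(o$aspect_ratio, 1, tolerance = 0.02)
    expect_gte(o$morphology_number, 0.97)
    expect_equal(o$centroid_x, 2.6 * r, tolerance = 1)
  }
})

test_that("an axis-aligned rectangle has exact area, min Feret and solidity", {
  m <- matrix(FALSE, 30, 50)
  m[6:25, 6:45] <- TRUE # 40 x 20 px
  o <- measure_object(m, pixel_scale = 1)
  expect_identical(o$area, 800)
  expect_equal(o$feret_min, 20)
  expect_identical(o$solidity, 1)
  expect_equal(o$feret_max, sqrt(40^2 + 20^2), tolerance = 0.025)
  # physical units scale with pixel_scale
  o2 <- measure_object(m, pixel_scale = 2.5)
  expect_identical(o2$area, 800 * 2.5^2)
  expect_equal(o2$feret_min, 50)
})

test_that("single-pixel objects are degenerate with undefined MN", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  o <- measure_object(m, pixel_scale = 1)
  expect_true(o$degenerate)
  expect_identical(o$feret_min, 0)
  expect_true(is.na(o$morphology_number))
  expect_error(measure_object(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("measured feret_max agrees with the brute-force boundary oracle", {
  img <- random_shape_fixture(9, seed = 21)
  seg <- segment_objects(img$image, 1, exclude_border = FALSE)
  obj <- measure_objects(seg)
  expect_equal(nrow(obj), 9L)
  for (k in obj$label) {
    oracle <- feret_brute_force(mask_boundary_points(seg$labels == k, 1))
    expect_lt(abs(obj$feret_max[obj$label == k] - oracle), 0.5)
  }
})

test_that("measured MN and solidity lie in (0, 1] for varied shapes", {
  img <- random_shape_fixture(9, seed = 33, roughness_range = c(0, 0.5))
  obj <- measure_image(img, exclude_border = FALSE)$objects
  good <- !obj$degenerate
  expect_true(all(obj$morphology_number[good] > 0 &
                    obj$morphology_number[good] <= 1))
  expect_true(all(obj$solidity > 0 & obj$solidity <= 1))
  expect_true(all(obj$aspect_ratio[good] >= 1))
  expect_true(all(obj$feret_max >= obj$feret_min))
})

test_that("increasing roughness never increases mean solidity", {
  mean_sol <- sapply(c(0, 0.15, 0.3, 0.45), function(rough) {
    sols <- sapply(1:20, function(k) {
      img <- generate_pellet_image(
        list(shape_spec(c(160.3, 160.7), 50, roughness = rough, n_lobes = 8)),
        pixel_scale = 1, seed = k)
      measure_image(img)$objects$solidity
    })
    mean(sols)
  })
  expect_true(all(diff(mean_sol) <= 0))
})

test_that("object areas conserve the supra-threshold pixel count", {
  img <- random_shape_fixture(6, seed = 13)
  seg <- segment_objects(img$image, 1, exclude_border = FALSE)
  obj <- measure_objects(seg)
  expect_identical(sum(obj$npix), sum(img$image > seg$threshold))
  expect_equal(sum(obj$area), sum(img$image > seg$threshold) * 1^2)
})

test_that("condition summaries pool pellets only", {
  # three pellets with known MN
  obj <- data.frame(size_class = rep("pellet", 3), degenerate = FALSE,
                    morphology_number = c(0.2, 0.4, 0.6),
                    feret_max = c(100, 120, 140))
  s <- summarize_condition(obj, condition = list(strain = "TK1", dox = 0.2))
  expect_equal(s$mn_mean, 0.4)
  expect_equal(s$mn_median, 0.4)
  expect_equal(s$n, 3L)
  expect_equal(s$strain, "TK1")

  # mixture: dispersed and discarded excluded from the MN statistics
  obj5 <- data.frame(
    size_class = c("pellet", "pellet", "dispersed", "dispersed", "discarded"),
    degenerate = FALSE,
    morphology_number = c(0.5, 0.7, 0.9, 0.95, NA),
    feret_max = c(200, 240, 20, 18, 4))
  s5 <- summarize_condition(obj5)
  expect_equal(s5$mn_mean, 0.6) # hand-computed over the two pellets
  expect_equal(s5$diameter_mean, 220)
  expect_equal(s5$n_dispersed, 2L)
  expect_equal(s5$n_discarded, 1L)

  # empty input
  s0 <- summarize_condition(obj5[0, ])
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$mn_mean))
})
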