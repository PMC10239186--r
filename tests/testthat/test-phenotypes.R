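test_that("radial growth rate is the two-day radius increment", {
  expect_equal(radial_growth_rate(15, 35), 10)
  expect_equal(radial_growth_rate(10, 12), 1)
  expect_equal(radial_growth_rate(8, 8), 0)
  expect_error(radial_growth_rate(12, 10), "shrinking")
  expect_error(radial_growth_rate(-1, 5), ">= 0")
})

test_that("growth coefficient evaluates the ratio of ratios", {
  expect_equal(growth_coefficient(6, 8, 9, 12), 1)
  expect_equal(growth_coefficient(4, 8, 10, 10), 0.5)
  # identity: mutant == progenitor in both media
  expect_equal(growth_coefficient(5, 5, 11, 11), 1)
  expect_error(growth_coefficient(0, 8, 10, 10), "mutant_stress")
})

test_that("growth coefficient is scale invariant and 1 for the progenitor", {
  set.seed(2)
  for (k in 1:20) {
    r <- runif(4, 0.5, 12)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(growth_coefficient(r[1], r[2], r[3], r[4]),
                 growth_coefficient(c_scale * r[1], c_scale * r[2],
                                    c_scale * r[3], c_scale * r[4]))
    expect_equal(growth_coefficient(r[1], r[1], r[3], r[3]), 1)
  }
})

test_that("hyphal growth unit and protein normalization are exact ratios", {
  expect_equal(hyphal_growth_unit(300, 6), 50)
  expect_equal(hyphal_growth_unit(123.4, 1), 123.4)
  expect_equal(hyphal_growth_unit(200, 8), hyphal_growth_unit(200, 4) / 2)
  expect_error(hyphal_growth_unit(100, 0), "tips")

  expect_equal(normalize_protein(6, 2), 3)
  expect_equal(normalize_protein(0, 5), 0)
  expect_error(normalize_protein(3, 0), "dry_biomass")

  expect_equal(biomass_percent_of_control(1, 1), 100)
  expect_equal(biomass_percent_of_control(0.5, 1), 50)
  expect_equal(biomass_percent_of_control(1.2, 1), 120)
  expect_error(biomass_percent_of_control(1, 0), "control_biomass")
})

test_that("control comparisons implement the pooled Student's t-test", {
  # identical constant groups: p = 1 by continuity
  same <- compare_to_control(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "")

  # near-constant separated groups diverge
  jit <- c(1, 1 + 1e-9, 1 - 1e-9)
  far <- compare_to_control(jit, c(2, 2 + 1e-9, 2 - 1e-9))
  expect_lt(far$p_value, 0.001)
  expect_identical(far$stars, "***")
  expect_equal(far$direction, -1)

  # matches the closed-form pooled t oracle on random inputs,
  # and is symmetric under group exchange
  set.seed(6)
  for (k in 1:25) {
    x <- rnorm(sample(3:8, 1), 5, 1)
    y <- rnorm(sample(3:8, 1), 5.5, 1.5)
    expect_equal(compare_to_control(x, y)$p_value, pooled_t_p(x, y),
                 tolerance = 1e-12)
    expect_equal(compare_to_control(x, y)$p_value,
                 compare_to_control(y, x)$p_value)
  }
  expect_error(compare_to_control(1, c(1, 2)), "replicates")
})

test_that("stars follow the 0.05/0.01/0.001 thresholds", {
  expect_identical(mycophenom:::p_stars(c(0.2, 0.049, 0.009, 0.0009)),
                   c("", "*", "**", "***"))
})

test_that("per-condition comparisons cover every mutant condition", {
  sim <- simulate_phenotypes(seed = 10)
  long <- sim$long[sim$long$variable %in%
                     c("radial_growth_rate", "pellet_diameter"), ]
  cmp <- compare_all_to_control(long, control = "MA70.15")
  expect_equal(nrow(cmp), 6 * 4 * 2) # 6 mutants x 4 dox x 2 variables
  expect_false("MA70.15" %in% cmp$strain)
  expect_true(all(cmp$stars[cmp$p_value >= 0.05] == ""))
})

test_that("long-to-wide collapses replicates by their mean", {
  long <- data.frame(strain = rep(c("A", "B"), each = 4),
                     dox = 0,
                     variable = rep(c("v1", "v2"), 4),
                     replicate = rep(1:2, each = 2),
                     value = c(1, 10, 3, 20, 5, 30, 7, 40))
  wide <- phenotypes_to_wide(long)
  expect_equal(wide$v1[wide$strain == "A"], 2)
  expect_equal(wide$v2[wide$strain == "B"], 35)
  expect_error(phenotypes_to_wide(long[, -1]), "columns")
})
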