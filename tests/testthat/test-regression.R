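test_that("design-matrix assembly drops incomplete conditions with a log", {
  sim <- simulate_phenotypes(seed = 2)
  wide <- sim$wide
  wide$pellet_diameter[5] <- NA
  expect_message(
    dm <- assemble_design_matrix(wide, sim$design$variables),
    "dropped 1 condition")
  expect_equal(nrow(dm$X), 27L)
  expect_equal(nrow(dm$dropped), 1L)
  expect_error(assemble_design_matrix(wide, character(0)), "non-empty")
  expect_error(assemble_design_matrix(wide, "radial_growth_rate",
                                      response = "nope"), "absent")
})

test_that("fit_ols recovers an exact line and rejects rank deficiency", {
  x <- c(1, 2, 4, 7, 11, 16)
  wide <- data.frame(strain = "s", dox = 0, x = x,
                     protein_mg_per_g = 3 + 2 * x)
  fit <- suppressWarnings(fit_ols(assemble_design_matrix(wide, "x")))
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  # a constant column is collinear with the intercept
  wide$flat <- 5
  expect_error(fit_ols(assemble_design_matrix(wide, c("x", "flat"))),
               "rank deficient.*flat")
  # too few observations
  expect_error(fit_ols(assemble_design_matrix(wide[1:3, ], c("x", "flat"))),
               "observations")
})

test_that("fit_ols equals the normal-equations oracle on random instances", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(6:10, 1)
    k <- sample(1:3, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("v", 1:k)))
    y <- rnorm(n, 1 + X %*% rnorm(k), 0.5)
    wide <- data.frame(X, protein_mg_per_g = y)
    fit <- fit_ols(assemble_design_matrix(wide, colnames(X)))
    oracle <- ols_normal_equations(X, y)
    expect_equal(unname(fit$coefficients), as.numeric(oracle$coefficients),
                 tolerance = 1e-10)
    expect_equal(fit$intercept, as.numeric(oracle$intercept),
                 tolerance = 1e-10)
    expect_equal(unname(fit$p_values), as.numeric(oracle$p_values),
                 tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("backward elimination keeps signal and discards noise", {
  set.seed(9)
  n <- 28
  x1 <- runif(n, 0, 10)
  x2 <- rnorm(n) # pure noise
  wide <- data.frame(x1 = x1, x2 = x2,
                     protein_mg_per_g = 2 * x1 + rnorm(n, 0, 0.8))
  dm <- assemble_design_matrix(wide, c("x1", "x2"))
  fit <- backward_eliminate(dm)
  expect_setequal(names(fit$coefficients), "x1")
  # the retained model equals the refit on the surviving subset
  refit <- fit_ols(dm, "x1")
  expect_equal(fit$coefficients, refit$coefficients)
  expect_equal(fit$r_squared, refit$r_squared)
  # and beats the x2-only submodel, enumerated directly
  expect_gt(fit$r_squared, fit_ols(dm, "x2")$r_squared)
})

test_that("pure-noise designs collapse to (near) intercept-only models", {
  set.seed(31)
  sizes <- sapply(1:20, function(k) {
    wide <- data.frame(matrix(rnorm(28 * 4), 28, 4,
                              dimnames = list(NULL, paste0("v", 1:4))),
                       protein_mg_per_g = rnorm(28))
    dm <- assemble_design_matrix(wide, paste0("v", 1:4))
    fit <- suppressWarnings(backward_eliminate(dm))
    length(fit$coefficients)
  })
  expect_lte(mean(sizes), 1)
  expect_equal(sort(unique(sizes))[1], 0L)
})

test_that("a noiseless exact fit is always retained with p ~ 0", {
  x <- seq(1, 28)
  wide <- data.frame(x = x, protein_mg_per_g = 1.5 + 0.3 * x)
  fit <- suppressWarnings(backward_eliminate(assemble_design_matrix(wide, "x")))
  expect_equal(names(fit$coefficients), "x")
  expect_lt(fit$p_values[["x"]], 1e-12)
})

test_that("elimination trace is monotone and final p-values significant", {
  for (seed in c(3, 17, 42)) {
    sim <- simulate_phenotypes(seed = seed)
    dm <- assemble_design_matrix(sim$wide, sim$design$variables)
    fit <- suppressWarnings(backward_eliminate(dm))
    tr <- fit$elimination_trace
    expect_equal(tr$round[1], 1L)
    expect_equal(tr$threshold[1], 0.15)
    if (nrow(tr) > 1) expect_true(all(tr$threshold[-1] == 0.05))
    # retained-set sizes decrease monotonically
    expect_true(all(diff(tr$n_retained) <= 0))
    if (length(fit$p_values)) expect_true(all(fit$p_values <= 0.05))
  }
})

test_that("coefficient estimates are unbiased across many simulations", {
  m <- true_model()
  vars4 <- names(m$coefficients)
  n_seeds <- 500
  est <- matrix(NA_real_, n_seeds, length(vars4),
                dimnames = list(NULL, vars4))
  for (i in seq_len(n_seeds)) {
    sim <- simulate_phenotypes(model = m, seed = 5000 + i)
    fit <- fit_ols(assemble_design_matrix(sim$wide, sim$design$variables))
    est[i, ] <- fit$coefficients[vars4]
  }
  mean_err <- colMeans(est) - m$coefficients
  se_mean <- apply(est, 2, sd) / sqrt(n_seeds)
  # 4 simultaneous mean-zero checks: Bonferroni-calibrated bound (2.5 se per
  # coordinate ~ 5% joint false-alarm rate); a raw 2-se bound per coordinate
  # would flag unbiased estimators ~19% of the time by construction
  expect_true(all(abs(mean_err) < 2.5 * se_mean + 1e-8))
})

test_that("titre predictions follow the linear rule exactly", {
  model <- structure(list(intercept = 1, coefficients = c(x = 0.5),
                          p_values = c(x = 0.01)), class = "titre_model")
  expect_equal(predict_protein(model, "x", -10, control_value = 10,
                               baseline_prediction = 2.0), 1.5)
  expect_equal(predict_protein(model, "x", 0, 10, 2.0), 2.0)
  # symmetry of +/- changes about the baseline
  up <- predict_protein(model, "x", 10, 10, 2.0)
  dn <- predict_protein(model, "x", -10, 10, 2.0)
  expect_equal((up + dn) / 2, 2.0)
  # linearity in percent change and control value
  expect_equal(predict_protein(model, "x", -30, 10, 2.0) - 2.0,
               3 * (predict_protein(model, "x", -10, 10, 2.0) - 2.0))
  expect_equal(predict_protein(model, "x", -10, 20, 2.0) - 2.0,
               2 * (predict_protein(model, "x", -10, 10, 2.0) - 2.0))
  expect_error(predict_protein(model, "z", -10, 1, 1), "not retained")
  expect_error(predict_protein(model, "x", -150, 1, 1), "percent_change")

  expect_equal(relative_prediction(2.83, 2.83), 100)
  expect_error(relative_prediction(1, 0), "baseline")
})

test_that("scenario tables reproduce the baseline row and percent scale", {
  model <- structure(list(intercept = 0.5, coefficients = c(a = 2, b = -1),
                          p_values = c(a = 0.01, b = 0.02)),
                     class = "titre_model")
  tab <- predict_scenarios(model, c(a = 1, b = 0.5))
  base <- 0.5 + 2 * 1 - 1 * 0.5
  expect_equal(tab$predicted_mg_per_g[tab$variable == "(baseline)"], base)
  expect_equal(tab$percent_of_control[1], 100)
  a10 <- tab[tab$variable == "a" & tab$percent_change == -10, ]
  expect_equal(a10$predicted_mg_per_g, base + 2 * (-0.1) * 1)
  expect_error(predict_scenarios(model, c(a = 1)), "missing")
})

test_that("observed-vs-predicted R^2 separates signal from permutation null", {
  m <- true_model(noise_sd = 0)
  sim <- simulate_phenotypes(model = m, seed = 12)
  dm <- assemble_design_matrix(sim$wide, sim$design$variables)
  fit <- suppressWarnings(fit_ols(dm))
  expect_equal(observed_vs_predicted(fit, dm)$r_squared, 1, tolerance = 1e-9)

  # refit on permuted responses: concordance collapses
  set.seed(8)
  r2s <- sapply(1:20, function(k) {
    dmp <- dm
    dmp$y <- sample(dm$y)
    pfit <- suppressWarnings(backward_eliminate(dmp))
    observed_vs_predicted(pfit, dmp)$r_squared
  })
  expect_lt(median(r2s), 0.2)
})

test_that("recovery experiment reports retention of true effects", {
  rec <- recovery_experiment(model = strong_four_model(), n_seeds = 20,
                             seed = 7)
  true_vars <- names(strong_four_model()$coefficients)
  expect_true(all(rec$retention[true_vars] >= 0.8))
  expect_true(all(rec$retention[setdiff(names(rec$retention),
                                        true_vars)] <= 0.5))
  expect_error(recovery_experiment(model = true_model(
    coefficients = c(radial_growth_rate = 0)), n_seeds = 2), "nonzero")
})
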