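#' Assemble the regression design matrix from a wide phenotype table
#'
#' One observation per strain x inducer condition: the response is the
#' condition-mean protein titre and the predictors are the condition-mean
#' independent variables. Conditions missing any requested value are dropped
#' and logged. The total independent-variable value count (rows x columns) is
#' recorded; for the full default study (28 conditions x 11 variables) this
#' is 308.
#'
#' @param wide wide-format data frame, one row per condition, containing
#'   `response` and all `variables` columns (e.g. `simulate_phenotypes()$wide`
#'   or [phenotypes_to_wide()] output).
#' @param variables character vector of predictor column names (non-empty).
#' @param response response column name (default `"protein_mg_per_g"`).
#' @return object of class `design_matrix`: list with `y`, `X` (matrix),
#'   `observations` (strain/dox key data frame), `variable_names`,
#'   `response`, `n_values` (rows x columns of `X`) and `dropped` (keys of
#'   dropped conditions).
#' @export
assemble_design_matrix <- function(wide, variables,
                                   response = "protein_mg_per_g") {
  if (!length(variables)) stop("`variables` must be non-empty")
  if (!response %in% names(wide))
    stop("response column `", response, "` absent from table")
  missing_vars <- setdiff(variables, names(wide))
  if (length(missing_vars))
    stop("variable column(s) absent: ", paste(missing_vars, collapse = ", "))
  keys <- intersect(c("strain", "dox"), names(wide))
  complete <- stats::complete.cases(wide[, c(response, variables)])
  dropped <- wide[!complete, keys, drop = FALSE]
  if (nrow(dropped))
    message(sprintf("dropped %d condition(s) with missing values", nrow(dropped)))
  kept <- wide[complete, , drop = FALSE]
  X <- as.matrix(kept[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  structure(list(y = as.numeric(kept[[response]]), X = X,
                 observations = kept[, keys, drop = FALSE],
                 variable_names = variables, response = response,
                 n_values = nrow(X) * ncol(X), dropped = dropped),
            class = "design_matrix")
}

#' Ordinary least squares fit of a titre model
#'
#' Fits `y ~ X` with an always-included intercept, returning coefficients,
#' two-sided p-values from the t-distribution on `n - k - 1` degrees of
#' freedom, and R^2 — the standard spreadsheet-regression output. The design
#' must have more observations than parameters and full column rank;
#' rank-deficient fits raise an error naming the collinear columns.
#'
#' @param dm a [assemble_design_matrix()] result, optionally restricted via
#'   `variables`.
#' @param variables subset of predictors to fit (default all).
#' @return object of class `titre_model`: `intercept`, `coefficients` (named),
#'   `p_values` (named, excluding the intercept), `r_squared`, `sigma`, `df`,
#'   `fitted`, `residuals`, `n`, `variable_names`, `elimination_trace`
#'   (`NULL` for a plain fit).
#' @export
fit_ols <- function(dm, variables = dm$variable_names) {
  stopifnot(inherits(dm, "design_matrix"))
  X <- dm$X[, variables, drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1L)
    stop(sprintf("need more observations (%d) than parameters (%d)", n, k + 1L))
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(Xi))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  dat <- if (k > 0L) data.frame(X, check.names = FALSE)
         else data.frame(row.names = seq_len(n))
  dat$.response <- dm$y
  form <- if (k > 0L)
    stats::as.formula(paste(".response ~",
                            paste0("`", variables, "`", collapse = " + ")))
  else stats::as.formula(".response ~ 1")
  fit <- lm(form, data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients
  rownames(cf) <- gsub("`", "", rownames(cf))
  est <- cf[, "Estimate"]
  pv <- cf[, "Pr(>|t|)"]
  structure(list(
    intercept = unname(est["(Intercept)"]),
    coefficients = est[setdiff(names(est), "(Intercept)")],
    p_values = pv[setdiff(names(pv), "(Intercept)")],
    r_squared = if (k > 0L) sm$r.squared else 0,
    sigma = sm$sigma,
    df = fit$df.residual,
    fitted = unname(fit$fitted.values),
    residuals = unname(fit$residuals),
    n = n,
    variable_names = variables,
    elimination_trace = NULL), class = "titre_model")
}

#' Two-stage backward elimination of titre predictors
#'
#' Implements the screening procedure used with spreadsheet OLS: fit the full
#' model and remove, simultaneously, every variable whose p-value exceeds
#' `p_first` (0.15); then refit repeatedly, removing the single variable with
#' the largest p-value while it exceeds `p_subsequent` (0.05). Ties on the
#' largest p-value are broken by variable-list order. Terminates when every
#' retained variable has p <= `p_subsequent` or no variables remain (then an
#' intercept-only model is returned with a warning). The elimination trace
#' records each round's removals and threshold.
#'
#' @param dm a `design_matrix`.
#' @param p_first round-1 removal threshold (default 0.15).
#' @param p_subsequent threshold for all later rounds (default 0.05).
#' @return a `titre_model` whose `elimination_trace` is a data frame with
#'   columns `round`, `removed` (comma-separated), `threshold`,
#'   `n_retained`.
#' @examples
#' sim <- simulate_phenotypes(seed = 42)
#' dm <- assemble_design_matrix(sim$wide, sim$design$variables)
#' m <- backward_eliminate(dm)
#' m$coefficients
#' @export
backward_eliminate <- function(dm, p_first = 0.15, p_subsequent = 0.05) {
  stopifnot(inherits(dm, "design_matrix"))
  vars <- dm$variable_names
  trace <- data.frame(round = integer(0), removed = character(0),
                      threshold = numeric(0), n_retained = integer(0))
  fit <- fit_ols(dm, vars)
  # p-values can be NaN on an exactly-interpolating fit (zero residual
  # variance); treat them as perfectly significant
  pv <- fit$p_values
  pv[is.na(pv)] <- 0
  drop1st <- names(pv)[pv > p_first]
  vars <- setdiff(vars, drop1st)
  trace <- rbind(trace, data.frame(
    round = 1L, removed = paste(drop1st, collapse = ","),
    threshold = p_first, n_retained = length(vars)))
  round_i <- 1L
  repeat {
    round_i <- round_i + 1L
    if (!length(vars)) break
    fit <- fit_ols(dm, vars)
    pv <- fit$p_values
    pv[is.na(pv)] <- 0
    worst <- which.max(pv) # first index wins ties (list order)
    if (pv[worst] <= p_subsequent) break
    removed <- names(pv)[worst]
    vars <- setdiff(vars, removed)
    trace <- rbind(trace, data.frame(
      round = round_i, removed = removed, threshold = p_subsequent,
      n_retained = length(vars)))
  }
  if (!length(vars)) {
    warning("all variables eliminated; returning intercept-only model")
    fit <- fit_ols(dm, character(0))
  }
  fit$elimination_trace <- trace
  fit
}

#' @export
print.titre_model <- function(x, ...) {
  cat(sprintf("<titre_model> n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  if (length(x$coefficients)) {
    for (v in names(x$coefficients))
      cat(sprintf("  %-22s %10.4g   p = %.3g\n", v, x$coefficients[[v]],
                  x$p_values[[v]]))
  } else cat("  (intercept only)\n")
  if (!is.null(x$elimination_trace))
    cat(sprintf("  eliminated over %d round(s)\n",
                max(x$elimination_trace$round)))
  invisible(x)
}

#' Predict a protein titre under a hypothetical strain-parameter change
#'
#' Applies the fitted linear rule: a `percent_change` shift in one retained
#' variable away from its control value moves the predicted titre by
#' `coefficient * (percent_change / 100) * control_value` relative to the
#' baseline (zero-change) prediction. Exactly linear in both
#' `percent_change` and `control_value`.
#'
#' @param model a `titre_model`.
#' @param variable name of a retained model variable.
#' @param percent_change percent change(s), negative = reduction; magnitudes
#'   above 100% are rejected.
#' @param control_value the control strain's value of the variable, in its
#'   units.
#' @param baseline_prediction predicted titre at zero change, mg/g.
#' @return predicted titre(s), mg/g.
#' @examples
#' m <- structure(list(coefficients = c(x = 0.5)), class = "titre_model")
#' predict_protein(m, "x", -10, control_value = 10, baseline_prediction = 2)
#' @export
predict_protein <- function(model, variable, percent_change, control_value,
                            baseline_prediction) {
  if (!variable %in% names(model$coefficients))
    stop("variable `", variable, "` is not retained in the model")
  if (any(abs(percent_change) > 100))
    stop("`percent_change` must lie in [-100, 100]")
  stopifnot_scalar_num(control_value, "control_value")
  baseline_prediction +
    model$coefficients[[variable]] * (percent_change / 100) * control_value
}

#' Predicted titre as a percent of the control prediction
#'
#' @param predicted predicted titre(s), mg/g.
#' @param baseline the zero-change (control) prediction, mg/g, > 0.
#' @return percent of control.
#' @examples
#' relative_prediction(1.97, 2.83) # ~69.6
#' @export
relative_prediction <- function(predicted, baseline) {
  if (any(baseline <= 0)) stop("`baseline` must be > 0")
  100 * predicted / baseline
}

#' Baseline (control) titre prediction from a fitted model
#'
#' Evaluates the model at the control strain's variable values.
#'
#' @param model a `titre_model`.
#' @param control_values named numeric vector covering every retained
#'   variable.
#' @return predicted titre, mg/g.
#' @export
baseline_prediction <- function(model, control_values) {
  vars <- names(model$coefficients)
  miss <- setdiff(vars, names(control_values))
  if (length(miss))
    stop("control value(s) missing for: ", paste(miss, collapse = ", "))
  model$intercept + sum(model$coefficients * control_values[vars])
}

#' Prediction table for hypothetical strain changes
#'
#' Builds the scenario grid for the retained variables: for each variable and
#' each percent change, the predicted titre and its percent of the control
#' prediction.
#'
#' @param model a `titre_model`.
#' @param control_values named control-strain values covering the retained
#'   variables.
#' @param changes percent changes (default -10, -20, -30).
#' @return data frame with columns `variable`, `percent_change`,
#'   `predicted_mg_per_g`, `percent_of_control`.
#' @export
predict_scenarios <- function(model, control_values,
                              changes = c(-10, -20, -30)) {
  base <- baseline_prediction(model, control_values)
  rows <- lapply(names(model$coefficients), function(v) {
    pred <- predict_protein(model, v, changes, control_values[[v]], base)
    data.frame(variable = v, percent_change = changes,
               predicted_mg_per_g = pred,
               percent_of_control = relative_prediction(pred, base))
  })
  out <- rbind(data.frame(variable = "(baseline)", percent_change = 0,
                          predicted_mg_per_g = base,
                          percent_of_control = 100),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Observed versus predicted titres
#'
#' Predicts each observation's titre from the retained variables and reports
#' the squared Pearson correlation between observed and predicted values (the
#' concordance R^2 of an observed-vs-predicted scatter).
#'
#' @param model a `titre_model` fitted on variables present in `dm`.
#' @param dm the `design_matrix` to predict for.
#' @return list with `predicted` (per observation), `observed` and
#'   `r_squared`.
#' @export
observed_vs_predicted <- function(model, dm) {
  stopifnot(inherits(dm, "design_matrix"))
  vars <- names(model$coefficients)
  miss <- setdiff(vars, colnames(dm$X))
  if (length(miss))
    stop("model variable(s) absent from matrix: ", paste(miss, collapse = ", "))
  pred <- as.numeric(model$intercept +
                       dm$X[, vars, drop = FALSE] %*% model$coefficients)
  r2 <- if (length(vars) == 0L || sd(pred) == 0 || sd(dm$y) == 0) 0
  else cor(dm$y, pred)^2
  list(predicted = pred, observed = dm$y, r_squared = r2)
}

#' Selection-recovery experiment for the elimination procedure
#'
#' Repeatedly simulates a dataset from a known true model, runs the two-stage
#' backward elimination, and tabulates which variables are retained: the
#' acceptance surface for the variable-selection behaviour (retention
#' frequency of true effects, distribution and mode of retained-set size).
#'
#' @param design a [study_design()].
#' @param model a [true_model()] with at least one nonzero coefficient.
#' @param n_seeds number of simulated datasets.
#' @param seed base seed; dataset `i` uses `seed + i`.
#' @param p_first,p_subsequent elimination thresholds.
#' @param spread,replicate_cv forwarded to [simulate_phenotypes()].
#' @return list with `retention` (named retention frequency per variable),
#'   `size_distribution` (table over retained-set sizes), `modal_size`,
#'   `n_seeds`.
#' @export
recovery_experiment <- function(design = study_design(),
                                model = true_model(), n_seeds = 100,
                                seed = 1, p_first = 0.15,
                                p_subsequent = 0.05, spread = 0.3,
                                replicate_cv = 0.05) {
  if (!any(model$coefficients != 0))
    stop("`model` must have at least one nonzero coefficient")
  vars <- design$variables
  counts <- structure(numeric(length(vars)), names = vars)
  sizes <- integer(n_seeds)
  for (i in seq_len(n_seeds)) {
    sim <- simulate_phenotypes(design, model, seed = seed + i,
                               spread = spread, replicate_cv = replicate_cv)
    dm <- assemble_design_matrix(sim$wide, vars)
    fit <- suppressWarnings(backward_eliminate(dm, p_first, p_subsequent))
    kept <- names(fit$coefficients)
    counts[kept] <- counts[kept] + 1
    sizes[i] <- length(kept)
  }
  size_tab <- table(sizes)
  list(retention = counts / n_seeds,
       size_distribution = size_tab,
       modal_size = as.integer(names(size_tab)[which.max(size_tab)]),
       n_seeds = n_seeds)
}
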