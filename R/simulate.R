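#' Default independent-variable names
#'
#' The `"results"` variant is the 11-variable enumeration used for the
#' condition-level regression (radial growth rate, six stress growth
#' coefficients, hyphal length, pellet diameter, aspect ratio and solidity):
#' 11 variables over a 7 strain x 4 inducer-level design give the 308
#' independent values of the full study. The `"methods"` variant additionally
#' carries hyphal tip number and biomass dry weight.
#'
#' @param variant `"results"` (11 variables, default) or `"methods"` (13).
#' @param stresses character vector of stress names used to build the
#'   growth-coefficient variable names (`gc_<stress>`).
#' @return character vector of variable names.
#' @export
phenotype_variables <- function(variant = c("results", "methods"),
                                stresses = default_stresses()) {
  variant <- match.arg(variant)
  v <- c("radial_growth_rate", paste0("gc_", stresses),
         "hyphal_length", "pellet_diameter", "pellet_aspect_ratio",
         "pellet_solidity")
  if (variant == "methods") v <- c(v, "hyphal_tips", "biomass_dry_weight")
  v
}

default_stresses <- function() {
  c("congo_red", "heat_42C", "h2o2", "sds", "ph_3.5", "starch")
}

#' Describe a strain-by-inducer phenomics study design
#'
#' Defaults mirror a conditional-expression screen in *Aspergillus niger*:
#' six Tet-on morphogene mutants plus their progenitor control MA70.15,
#' doxycycline at 0, 0.2, 2 and 20 ug/ml (null, minor, moderate and
#' over-expression), triplicate submerged cultures, and six abiotic stresses
#' probed on solid medium.
#'
#' @param strains mutant strain identifiers (control excluded).
#' @param control control (progenitor) strain identifier; appears exactly
#'   once in the design.
#' @param dox_levels inducer concentrations, ug/ml, strictly increasing.
#' @param n_replicates biological replicates per strain x dox condition.
#' @param stresses names of the plate stress conditions.
#' @param variables independent-variable names; see [phenotype_variables()].
#' @return object of class `study_design`.
#' @examples
#' d <- study_design()
#' length(d$strains) * length(d$dox_levels) * length(d$variables) # 308
#' @export
study_design <- function(strains = c("TK26.2", "TK28.5", "TK38.5",
                                     "TK39.1", "TK51.1", "TK53.1"),
                         control = "MA70.15",
                         dox_levels = c(0, 0.2, 2, 20),
                         n_replicates = 3L,
                         stresses = default_stresses(),
                         variables = phenotype_variables("results", stresses)) {
  if (control %in% strains)
    stop("`control` must not be listed among `strains`")
  if (anyDuplicated(c(strains, control)))
    stop("strain identifiers must be unique")
  if (length(dox_levels) < 1L || any(diff(dox_levels) <= 0))
    stop("`dox_levels` must be strictly increasing")
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  structure(list(strains = c(strains, control), control = control,
                 dox_levels = dox_levels,
                 n_replicates = as.integer(n_replicates),
                 stresses = stresses, variables = variables),
            class = "study_design")
}

#' Ground-truth linear model for protein titres
#'
#' The generative counterpart of a fitted titre model: secreted protein
#' (mg per g dry biomass) is a linear function of the independent variables
#' plus Gaussian noise. Default nonzero coefficients carry the fitted effect
#' directions and magnitudes of the four retained factors — radial growth
#' rate (+0.6592 per mm/day), fitness under heat stress (+10.6824 per
#' growth-coefficient unit), fitness under cell-wall stress (-13.4059) and
#' pellet diameter (-0.0020 per um) — all other variables have true effect 0.
#' Default baselines are the control-strain operating point (growth
#' ~10 mm/day, heat growth coefficient ~1.1, cell-wall growth coefficient
#' ~0.8, pellet diameter ~2000 um); the intercept is solved so the control
#' titre equals `control_protein`.
#'
#' @param coefficients named numeric vector of true effects (response units
#'   per variable unit); names must be a subset of the design variables.
#' @param baselines named numeric vector of control-strain values, one per
#'   design variable.
#' @param noise_sd replicate-level Gaussian noise s.d., mg/g (>= 0). The
#'   default 4.3 puts the condition-level (triplicate-mean) true-model R^2
#'   near 0.6 under the default +/-30% variable spread.
#' @param intercept mg/g; if `NULL`, solved so that the control condition's
#'   expected titre equals `control_protein`.
#' @param control_protein expected control titre, mg/g (used only when
#'   `intercept` is `NULL`).
#' @return object of class `true_model`.
#' @export
true_model <- function(coefficients = c(radial_growth_rate = 0.6592,
                                        gc_heat_42C = 10.6824,
                                        gc_congo_red = -13.4059,
                                        pellet_diameter = -0.0020),
                       baselines = default_baselines(),
                       noise_sd = 4.3,
                       intercept = NULL,
                       control_protein = 2.83) {
  if (is.null(names(coefficients)) && length(coefficients))
    stop("`coefficients` must be named by variable")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!all(names(coefficients) %in% names(baselines)))
    stop("every coefficient needs a baseline: missing ",
         paste(setdiff(names(coefficients), names(baselines)), collapse = ", "))
  if (is.null(intercept)) {
    intercept <- control_protein -
      sum(coefficients * baselines[names(coefficients)])
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 noise_sd = noise_sd, baselines = baselines),
            class = "true_model")
}

#' @rdname true_model
#' @export
default_baselines <- function() {
  c(radial_growth_rate = 10,      # mm/day
    gc_congo_red = 0.8,           # cell-wall stress growth coefficient
    gc_heat_42C = 1.1,            # heat stress growth coefficient
    gc_h2o2 = 1, gc_sds = 1, `gc_ph_3.5` = 1, gc_starch = 1,
    hyphal_length = 250,          # um after 18 h germination
    pellet_diameter = 2000,       # um
    pellet_aspect_ratio = 1.2,
    pellet_solidity = 0.9,
    hyphal_tips = 5,              # tips per hypha
    biomass_dry_weight = 1.5)     # g
}

#' Simulate a strain-by-inducer phenotype and titre dataset
#'
#' Draws one dataset with the structure of the study design: for every
#' strain x dox condition each independent variable takes a condition-level
#' value — the stated baseline for the control strain, or the baseline times
#' `1 + U(-spread, spread)` for mutants — and each replicate observes it with
#' multiplicative noise `1 + N(0, replicate_cv)`. Replicate protein titres
#' follow the true linear model evaluated on the replicate's variable values
#' plus `N(0, noise_sd)` noise, so with `noise_sd = 0` the titres satisfy the
#' model equation exactly and condition means preserve it by linearity.
#'
#' @param design a [study_design()].
#' @param model a [true_model()]; all coefficient names must be design
#'   variables.
#' @param seed integer seed; identical seeds reproduce the dataset exactly.
#' @param spread half-width of the mutant condition-level multiplicative
#'   deviation from baseline (default 0.3, i.e. +/-30%).
#' @param replicate_cv replicate-level coefficient of variation of the
#'   variable measurements.
#' @return object of class `phenom_sim`: list with `long` (one row per
#'   strain x dox x variable x replicate, plus `protein_mg_per_g` rows),
#'   `wide` (one row per condition: replicate-mean variables and titre),
#'   `truth` (condition-level true values and expected titre), `design`,
#'   `model`.
#' @examples
#' sim <- simulate_phenotypes(seed = 1)
#' dim(sim$wide) # 28 conditions
#' @export
simulate_phenotypes <- function(design = study_design(),
                                model = true_model(),
                                seed = NULL, spread = 0.3,
                                replicate_cv = 0.05) {
  stopifnot(inherits(design, "study_design"), inherits(model, "true_model"))
  miss <- setdiff(names(model$coefficients), design$variables)
  if (length(miss))
    stop("true-model variables not in design: ", paste(miss, collapse = ", "))
  need <- setdiff(design$variables, names(model$baselines))
  if (length(need))
    stop("baseline missing for variable(s): ", paste(need, collapse = ", "))
  vars <- design$variables
  beta <- structure(numeric(length(vars)), names = vars)
  beta[names(model$coefficients)] <- model$coefficients
  conds <- expand.grid(strain = design$strains, dox = design$dox_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nrep <- design$n_replicates
  with_seed(seed, {
    truth <- conds
    for (v in vars) {
      base <- model$baselines[[v]]
      dev <- ifelse(conds$strain == design$control, 0,
                    runif(nrow(conds), -spread, spread))
      truth[[v]] <- base * (1 + dev)
    }
    truth$protein_true <- as.numeric(model$intercept +
      as.matrix(truth[vars]) %*% beta)
    long <- NULL
    wide <- conds
    for (v in vars) wide[[v]] <- NA_real_
    wide$protein_mg_per_g <- NA_real_
    rep_rows <- vector("list", nrow(conds))
    for (r in seq_len(nrow(conds))) {
      x_rep <- matrix(rep(as.numeric(truth[r, vars]), each = nrep),
                      nrow = nrep)
      if (replicate_cv > 0)
        x_rep <- x_rep * (1 + matrix(rnorm(nrep * length(vars), 0,
                                           replicate_cv), nrow = nrep))
      prot <- model$intercept + x_rep %*% beta +
        (if (model$noise_sd > 0) rnorm(nrep, 0, model$noise_sd) else 0)
      wide[r, vars] <- colMeans(x_rep)
      wide$protein_mg_per_g[r] <- mean(prot)
      rep_rows[[r]] <- data.frame(
        strain = conds$strain[r], dox = conds$dox[r],
        replicate = rep(seq_len(nrep), times = length(vars) + 1L),
        medium = rep(c(variable_medium(vars), "MM"), each = nrep),
        variable = rep(c(vars, "protein_mg_per_g"), each = nrep),
        value = c(as.numeric(x_rep), as.numeric(prot)),
        units = rep(c(variable_units(vars), "mg/g"), each = nrep))
    }
    long <- do.call(rbind, rep_rows)
    structure(list(long = long, wide = wide, truth = truth,
                   design = design, model = model),
              class = "phenom_sim")
  })
}

variable_medium <- function(vars) {
  ifelse(startsWith(vars, "gc_"), sub("^gc_", "", vars), "MM")
}

variable_units <- function(vars) {
  u <- c(radial_growth_rate = "mm/day", hyphal_length = "um",
         pellet_diameter = "um", pellet_aspect_ratio = "",
         pellet_solidity = "", hyphal_tips = "count",
         biomass_dry_weight = "g")
  out <- unname(u[vars])
  out[startsWith(vars, "gc_")] <- ""
  out[is.na(out)] <- ""
  out
}

#' @export
print.phenom_sim <- function(x, ...) {
  cat(sprintf(
    "<phenom_sim> %d strains x %d dox levels, %d replicates, %d variables\n",
    length(x$design$strains), length(x$design$dox_levels),
    x$design$n_replicates, length(x$design$variables)))
  invisible(x)
}
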