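#' Configuration for the end-to-end phenomics pipeline
#'
#' Bundles and validates every tunable of the analysis chain. Defaults equal
#' the study's printed settings: dox grid 0/0.2/2/20 ug/ml, size-class
#' thresholds 95 and 500 um^2, growth timepoints 72/120 h (built into
#' [radial_growth_rate()]), elimination thresholds 0.15 then 0.05.
#'
#' @param out_dir output directory (created if needed at run time).
#' @param seed integer master seed; recorded in the run manifest and all
#'   provenance output.
#' @param pixel_scale um per pixel for simulated/measured images. The default
#'   20 um/px puts millimetre-scale pellets at convenient raster sizes.
#' @param min_area,pellet_area size-class thresholds, um^2 (`min_area <
#'   pellet_area`).
#' @param control control strain identifier.
#' @param p_first,p_subsequent backward-elimination thresholds.
#' @param exclude_border drop border-touching objects when measuring.
#' @param image_px simulated image side length, pixels.
#' @param pellets_per_image pellets rendered per condition image.
#' @param changes percent changes for the prediction table.
#' @param simulate if `TRUE` (default) the pipeline generates its own inputs;
#'   if `FALSE`, `phenotype_table` must point to a long-format CSV.
#' @param phenotype_table path to a long-format phenotype CSV (only when
#'   `simulate = FALSE`).
#' @param spread,replicate_cv,noise_sd forwarded to the generators.
#' @param image_format `"P5"` (binary PGM) or `"P2"` (ASCII PGM).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, pixel_scale = 20,
                            min_area = 95, pellet_area = 500,
                            control = "MA70.15",
                            p_first = 0.15, p_subsequent = 0.05,
                            exclude_border = TRUE, image_px = 640L,
                            pellets_per_image = 4L,
                            changes = c(-10, -20, -30),
                            simulate = TRUE, phenotype_table = NULL,
                            spread = 0.3, replicate_cv = 0.05,
                            noise_sd = 4.3, image_format = "P5") {
  stopifnot_scalar_num(seed, "seed")
  stopifnot_scalar_num(pixel_scale, "pixel_scale", positive = TRUE)
  stopifnot_scalar_num(min_area, "min_area", positive = TRUE)
  stopifnot_scalar_num(pellet_area, "pellet_area", positive = TRUE)
  if (min_area >= pellet_area)
    stop("`min_area` must be smaller than `pellet_area`")
  for (p in c(p_first, p_subsequent))
    if (p <= 0 || p >= 1) stop("elimination thresholds must be in (0, 1)")
  if (!simulate && is.null(phenotype_table))
    stop("`phenotype_table` is required when `simulate = FALSE`")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 pixel_scale = pixel_scale, min_area = min_area,
                 pellet_area = pellet_area, control = control,
                 p_first = p_first, p_subsequent = p_subsequent,
                 exclude_border = exclude_border,
                 image_px = as.integer(image_px),
                 pellets_per_image = as.integer(pellets_per_image),
                 changes = changes, simulate = simulate,
                 phenotype_table = phenotype_table, spread = spread,
                 replicate_cv = replicate_cv, noise_sd = noise_sd,
                 image_format = image_format),
            class = "pipeline_config")
}

# Shape specs for one condition image, from condition-level pellet truth.
# Pellets sit on a jittered 2x2-quadrant grid so bounding circles never
# intersect; roughness is a monotone map from the solidity target.
condition_shapes <- function(diameter, aspect_ratio, solidity, n_pellets,
                             frame_um) {
  q <- frame_um / 4
  centers <- rbind(c(q, q), c(3 * q, q), c(q, 3 * q), c(3 * q, 3 * q))
  n_pellets <- min(n_pellets, 4L)
  sol <- min(0.98, max(0.6, solidity))
  rough <- min(0.8, 2.5 * (1 - sol))
  elong <- min(3, max(1, aspect_ratio))
  lapply(seq_len(n_pellets), function(k) {
    r_eq <- (diameter / 2) * runif(1, 0.9, 1.1) / sqrt(elong) /
      (1 + rough) # keep the bounding radius near diameter / 2
    shape_spec(centers[k, ], equivalent_radius = max(r_eq, 60),
               elongation = elong, roughness = rough,
               n_lobes = if (rough > 0) 8L else 0L)
  })
}

#' Run the full phenomics pipeline
#'
#' Executes simulate (optional) -> measure -> phenotypes -> regress ->
#' predict, writing per-stage CSV/PGM/JSON outputs and a run manifest (config
#' echo, seed, package version, per-stage row counts) into
#' `config$out_dir`. With `simulate = TRUE` the phenotype table is drawn from
#' the true model, one image per strain x dox condition is rendered from the
#' condition's pellet geometry, and the measured pellet diameter / aspect
#' ratio / solidity replace the simulated columns before regression, closing
#' the loop between the imaging and modelling branches. Runs are
#' deterministic for a fixed seed. Any stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @param design a [study_design()].
#' @param model a [true_model()] (its `noise_sd` is overridden by
#'   `config$noise_sd`).
#' @return invisible list with the key in-memory results: `sim`, `objects`,
#'   `summaries`, `wide`, `fit`, `ovp`, `predictions`, `manifest`.
#' @export
run_pipeline <- function(config, design = study_design(),
                         model = true_model(noise_sd = config$noise_sd)) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(config$out_dir, "images")
  path <- function(...) file.path(config$out_dir, ...)

  # -- phenotypes -----------------------------------------------------------
  if (config$simulate) {
    sim <- stage("simulate-phenotypes",
                 simulate_phenotypes(design, model, seed = config$seed,
                                     spread = config$spread,
                                     replicate_cv = config$replicate_cv))
    wide <- sim$wide
    write.csv(sim$long, path("phenotypes_long.csv"), row.names = FALSE)
  } else {
    sim <- NULL
    long <- stage("phenotypes",
                  read.csv(config$phenotype_table, stringsAsFactors = FALSE))
    wide <- stage("phenotypes", phenotypes_to_wide(long))
  }

  # -- images + measurement -------------------------------------------------
  objects <- NULL; summaries <- NULL; n_images <- 0L; n_border <- 0L
  if (config$simulate) {
    dir.create(img_dir, showWarnings = FALSE)
    frame_um <- config$image_px * config$pixel_scale
    obj_list <- list(); sum_list <- list()
    for (r in seq_len(nrow(wide))) {
      res <- stage("simulate-images", with_seed(config$seed + 1000L + r, {
        shapes <- condition_shapes(wide$pellet_diameter[r],
                                   wide$pellet_aspect_ratio[r],
                                   wide$pellet_solidity[r],
                                   config$pellets_per_image, frame_um)
        generate_pellet_image(shapes, config$pixel_scale,
                              width_px = config$image_px,
                              height_px = config$image_px,
                              seed = config$seed + 2000L + r)
      }))
      fname <- sprintf("%s_dox%s.pgm", wide$strain[r],
                       gsub("[.]", "p", format(wide$dox[r])))
      write_pgm(res$image, file.path(img_dir, fname),
                format = config$image_format)
      meas <- stage("measure",
                    measure_image(res, min_area = config$min_area,
                                  pellet_area = config$pellet_area,
                                  exclude_border = config$exclude_border))
      obs <- meas$objects
      if (nrow(obs)) {
        obs <- cbind(strain = wide$strain[r], dox = wide$dox[r],
                     image = fname, obs)
      }
      obj_list[[r]] <- obs
      sum_list[[r]] <- summarize_condition(meas$objects,
                                           condition = list(strain = wide$strain[r],
                                                            dox = wide$dox[r]))
      n_images <- n_images + 1L
      n_border <- n_border + meas$segmentation$n_border_excluded
      # measured macromorphology replaces the simulated columns
      pel <- meas$objects[meas$objects$size_class == "pellet" &
                            !meas$objects$degenerate, , drop = FALSE]
      if (nrow(pel)) {
        wide$pellet_diameter[r] <- mean(pel$feret_max)
        wide$pellet_aspect_ratio[r] <- mean(pel$aspect_ratio)
        wide$pellet_solidity[r] <- mean(pel$solidity)
      }
    }
    objects <- do.call(rbind, obj_list)
    summaries <- do.call(rbind, sum_list)
    write.csv(objects, path("objects.csv"), row.names = FALSE)
    write.csv(summaries, path("morphology_summary.csv"), row.names = FALSE)
  }
  write.csv(wide, path("phenotypes_wide.csv"), row.names = FALSE)

  # -- regression -----------------------------------------------------------
  vars <- intersect(design$variables, names(wide))
  dm <- stage("regress", assemble_design_matrix(wide, vars))
  fit <- stage("regress",
               backward_eliminate(dm, config$p_first, config$p_subsequent))
  ovp <- stage("regress", observed_vs_predicted(fit, dm))
  model_report <- list(
    intercept = fit$intercept,
    coefficients = as.list(fit$coefficients),
    p_values = as.list(fit$p_values),
    r_squared = fit$r_squared,
    observed_vs_predicted_r_squared = ovp$r_squared,
    n_observations = fit$n,
    n_independent_values = dm$n_values,
    elimination_trace = fit$elimination_trace,
    seed = config$seed)
  jsonlite::write_json(model_report, path("model.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write.csv(cbind(dm$observations, observed = ovp$observed,
                  predicted = ovp$predicted),
            path("observed_vs_predicted.csv"), row.names = FALSE)

  # -- prediction -----------------------------------------------------------
  predictions <- NULL
  if (length(fit$coefficients)) {
    ctrl <- wide[wide$strain == config$control, vars, drop = FALSE]
    if (!nrow(ctrl)) stop("pipeline stage 'predict' failed: control strain `",
                          config$control, "` absent from table")
    control_values <- colMeans(ctrl)
    predictions <- stage("predict",
                         predict_scenarios(fit, control_values,
                                           config$changes))
    write.csv(predictions, path("predictions.csv"), row.names = FALSE)
  }

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package = "mycophenom",
    version = as.character(packageVersion("mycophenom")),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      conditions = nrow(wide),
      images = n_images,
      objects_measured = if (is.null(objects)) 0L else nrow(objects),
      pellets = if (is.null(objects)) 0L else
        sum(objects$size_class == "pellet"),
      dispersed = if (is.null(objects)) 0L else
        sum(objects$size_class == "dispersed"),
      discarded = if (is.null(objects)) 0L else
        sum(objects$size_class == "discarded"),
      border_excluded = n_border,
      regression_rows = fit$n,
      independent_values = dm$n_values,
      retained_variables = length(fit$coefficients)),
    retained = names(fit$coefficients),
    r_squared = fit$r_squared)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sim = sim, objects = objects, summaries = summaries,
                 wide = wide, fit = fit, ovp = ovp,
                 predictions = predictions, manifest = manifest))
}
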