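#' Radial growth rate of a colony between 72 and 120 h
#'
#' Colony radii measured at 72 h and 120 h span 2 days, so the rate is
#' `(radius_120h - radius_72h) / 2` mm/day. A colony that shrinks indicates a
#' measurement fault and raises an error.
#'
#' @param radius_72h,radius_120h colony radii in mm, `radius_120h >=
#'   radius_72h >= 0`. Vectorized.
#' @return growth rate(s) in mm/day.
#' @examples
#' radial_growth_rate(15, 35) # 10 mm/day
#' @export
radial_growth_rate <- function(radius_72h, radius_120h) {
  if (any(radius_72h < 0)) stop("radii must be >= 0")
  if (any(radius_120h < radius_72h))
    stop("`radius_120h` < `radius_72h`: shrinking colony, measurement fault")
  (radius_120h - radius_72h) / 2
}

#' Stress growth coefficient
#'
#' Ratio-of-ratios fitness statistic: the mutant-to-progenitor ratio of
#' radial growth rates under stress, divided by the same ratio on standard
#' minimal medium (MM). Values above 1 mean the mutant's growth penalty under
#' stress is milder than the progenitor's; below 1, harsher. The progenitor
#' scored against itself is exactly 1, and the statistic is invariant to
#' rescaling all four rates.
#'
#' @param mutant_stress,progenitor_stress radial growth rates (mm/day) on
#'   stress medium, > 0.
#' @param mutant_mm,progenitor_mm radial growth rates (mm/day) on MM, > 0.
#' @return dimensionless growth coefficient(s).
#' @examples
#' growth_coefficient(6, 8, 9, 12)   # 1
#' growth_coefficient(4, 8, 10, 10)  # 0.5
#' @export
growth_coefficient <- function(mutant_stress, progenitor_stress,
                               mutant_mm, progenitor_mm) {
  args <- list(mutant_stress = mutant_stress,
               progenitor_stress = progenitor_stress,
               mutant_mm = mutant_mm, progenitor_mm = progenitor_mm)
  for (nm in names(args))
    if (any(args[[nm]] <= 0))
      stop(sprintf("`%s` must be > 0; for a strain that failed to grow the coefficient is undefined and should be recorded as missing", nm))
  (mutant_stress / progenitor_stress) / (mutant_mm / progenitor_mm)
}

#' Hyphal growth unit
#'
#' Total hyphal length divided by the number of tips; a proxy for branching
#' frequency (small values indicate hyperbranching).
#'
#' @param length total hyphal length, um (> 0).
#' @param tips number of tips (>= 1).
#' @return hyphal growth unit, um per tip.
#' @examples
#' hyphal_growth_unit(300, 6) # 50
#' @export
hyphal_growth_unit <- function(length, tips) {
  if (any(length <= 0)) stop("`length` must be > 0")
  if (any(tips < 1)) stop("`tips` must be >= 1")
  length / tips
}

#' Biomass-normalized secreted protein titre
#'
#' @param total_protein total secreted protein in the culture supernatant, mg.
#' @param dry_biomass fungal dry weight, g (> 0).
#' @return titre in mg protein per g dry biomass.
#' @export
normalize_protein <- function(total_protein, dry_biomass) {
  if (any(total_protein < 0)) stop("`total_protein` must be >= 0")
  if (any(dry_biomass <= 0)) stop("`dry_biomass` must be > 0")
  total_protein / dry_biomass
}

#' Biomass as a percent of the control strain
#'
#' @param mutant_biomass,control_biomass dry weights, g; control must be > 0.
#' @return percent of control.
#' @export
biomass_percent_of_control <- function(mutant_biomass, control_biomass) {
  if (any(control_biomass <= 0)) stop("`control_biomass` must be > 0")
  100 * mutant_biomass / control_biomass
}

#' Compare mutant replicates against the control strain
#'
#' Two-sided two-sample Student's t-test with equal-variance pooling, with
#' significance stars at 0.05 (*), 0.01 (**) and 0.001 (***). When both
#' groups are constant the test statistic is defined by continuity: p = 1 for
#' equal means, p = 0 otherwise.
#'
#' @param mutant_values,control_values numeric replicate vectors, length
#'   >= 2 each.
#' @return one-row data frame: `p_value`, `stars`, `direction` (sign of
#'   mutant mean minus control mean), `mean_mutant`, `mean_control`.
#' @examples
#' compare_to_control(c(5.1, 5.3, 5.0), c(3.0, 3.2, 3.1))
#' @export
compare_to_control <- function(mutant_values, control_values) {
  if (length(mutant_values) < 2L || length(control_values) < 2L)
    stop("need >= 2 replicates per group")
  mm <- mean(mutant_values); mc <- mean(control_values)
  pooled_var <- (sum((mutant_values - mm)^2) +
                   sum((control_values - mc)^2)) /
    (length(mutant_values) + length(control_values) - 2L)
  if (pooled_var == 0) {
    p <- if (mm == mc) 1 else 0
  } else {
    p <- t.test(mutant_values, control_values, var.equal = TRUE)$p.value
  }
  data.frame(p_value = p, stars = p_stars(p),
             direction = sign(mm - mc),
             mean_mutant = mm, mean_control = mc)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare every mutant condition against the control
#'
#' Applies [compare_to_control()] per strain x dox x variable, pairing each
#' mutant's replicates with the control strain's replicates at the same dox
#' concentration — the comparison behind per-condition significance stars on
#' phenotype boxplots.
#'
#' @param long long-format table with columns `strain`, `dox`, `variable`,
#'   `replicate`, `value` (e.g. `simulate_phenotypes(...)$long`).
#' @param control control strain identifier.
#' @return data frame with one row per mutant strain x dox x variable.
#' @export
compare_all_to_control <- function(long, control = "MA70.15") {
  need <- c("strain", "dox", "variable", "value")
  if (!all(need %in% names(long)))
    stop("`long` must have columns ", paste(need, collapse = ", "))
  if (!control %in% long$strain)
    stop("control strain ", control, " not present")
  combos <- unique(long[long$strain != control, c("strain", "dox", "variable")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    sel <- combos[k, ]
    mut <- long$value[long$strain == sel$strain & long$dox == sel$dox &
                        long$variable == sel$variable]
    ctl <- long$value[long$strain == control & long$dox == sel$dox &
                        long$variable == sel$variable]
    cbind(sel, compare_to_control(mut, ctl), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse a long phenotype table to a condition-by-variable wide table
#'
#' Averages replicates per strain x dox x variable; the regression operates
#' on these condition-level means.
#'
#' @param long long-format table with columns `strain`, `dox`, `variable`,
#'   `value`.
#' @return wide data frame, one row per strain x dox condition.
#' @export
phenotypes_to_wide <- function(long) {
  need <- c("strain", "dox", "variable", "value")
  if (!all(need %in% names(long)))
    stop("`long` must have columns ", paste(need, collapse = ", "))
  agg <- stats::aggregate(value ~ strain + dox + variable, data = long,
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = c("strain", "dox"),
                         timevar = "variable", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$dox, wide$strain), , drop = FALSE]
}
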