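# Scenario engine: define baseline and the three feed-improvement
# scenarios, run the herd, land and forest stages on a landscape, and
# aggregate combined agriculture + forest emissions, milk output,
# mitigation deltas and emission intensities.

#' Define a feeding scenario
#'
#' The scenario set: `baseline`; `FoCo` (forage quality + concentrates,
#' medium intensification: 25% of baseline DM replaced, 3 kg/day
#' concentrate); `FeCo` (feed conservation/maize silage + concentrates,
#' medium); `FoFeCo` (all three, high intensification: 50% replacement,
#' 6 kg/day). FeCo and FoFeCo (which grow maize silage) run at maize
#' yield-gap levels Ya/Yw50/Yw80; FoCo has no silage, so only Ya applies.
#'
#' @param name one of `"baseline"`, `"FoCo"`, `"FeCo"`, `"FoFeCo"`.
#' @param yield_level one of `"Ya"`, `"Yw50"`, `"Yw80"`.
#' @return a `scenario_spec` list with derived fields `intensification`,
#'   `replacement_fraction` and `concentrate_kg_day`.
#' @export
scenario_spec <- function(name = c("baseline", "FoCo", "FeCo", "FoFeCo"),
                          yield_level = c("Ya", "Yw50", "Yw80")) {
  name <- match.arg(name)
  yield_level <- match.arg(yield_level)
  if (name %in% c("baseline", "FoCo") && yield_level != "Ya")
    stop(name, " has no maize silage; only yield level Ya applies")
  high <- name == "FoFeCo"
  structure(list(
    name = name, yield_level = yield_level,
    intensification = if (name == "baseline") "none"
      else if (high) "high" else "medium",
    replacement_fraction = if (name == "baseline") 0
      else if (high) 0.50 else 0.25,
    concentrate_kg_day = if (name == "baseline") 0
      else if (high) 6 else 3), class = "scenario_spec")
}

#' Bundle the fixed inputs of a scenario run
#'
#' @param diet_table from [load_diet_table()].
#' @param feeds from [load_feed_table()].
#' @param factors from [load_emission_factors()].
#' @param yield_cfg a [yield_gap_config()].
#' @param cow a [cow_params()].
#' @param calibrate_milk if `TRUE`, the diet table's milk column overrides
#'   the herd surrogate (exact downstream accounting).
#' @return a `scenario_fixtures` list.
#' @export
scenario_fixtures <- function(diet_table = load_diet_table(),
                              feeds = load_feed_table(),
                              factors = load_emission_factors(),
                              yield_cfg = yield_gap_config(),
                              cow = cow_params(),
                              calibrate_milk = TRUE) {
  structure(list(diet_table = diet_table, feeds = feeds,
                 factors = factors, yield_cfg = yield_cfg, cow = cow,
                 calibrate_milk = calibrate_milk),
            class = "scenario_fixtures")
}

#' @keywords internal
lps_productive_heads <- function(landscape, factors) {
  dens <- landscape$cattle_density$values
  km2 <- (landscape$cattle_density$cellsize / 1000)^2
  zone <- landscape$lps_class$values
  labels <- landscape$lps_labels
  frac <- ef_mean(factors$productive_cow_fraction) %||% 0.6
  heads <- vapply(seq_along(labels), function(k)
    sum(dens[zone == k], na.rm = TRUE) * km2, numeric(1))
  stats::setNames(heads * frac, labels)
}

#' @keywords internal
scenario_demand_layer <- function(spec, landscape, fixtures) {
  dens <- landscape$cattle_density
  zone <- landscape$lps_class$values
  labels <- landscape$lps_labels
  frac <- ef_mean(fixtures$factors$productive_cow_fraction) %||% 0.6
  total <- matrix(0, nrow(dens$values), ncol(dens$values))
  for (k in seq_along(labels)) {
    lps <- labels[k]
    diet <- get_diet(fixtures$diet_table, lps, spec$name, spec$yield_level)
    my <- maize_yield_at(spec$yield_level, lps, fixtures$yield_cfg)
    dk <- with_values(dens, dens$values * (zone == k) * frac)
    dem <- feed_land_demand(dk, diet, fixtures$feeds, my)
    total <- total + ifelse(is.na(dem$values), 0, dem$values)
  }
  total[is.na(dens$values)] <- NA_real_
  with_values(dens, total, rel_sd = NULL, units = "ha")
}

#' Run one scenario on a landscape
#'
#' Stages: (1) forest attribution (dairy-attributed loss and C change);
#' (2) per-LPS herd model — milk (surrogate or calibrated to the diet
#' table) and Tier-2 per-head emissions, upscaled by productive-cow
#' numbers derived from the cattle-density layer; (3) spatial land budget
#' — cropland demand for cultivated feeds vs grazing land, deficit
#' polygons, 5-km buffer and the retained forest loss inside; (4) LUC
#' emissions on newly converted grazing land (relative to the baseline
#' diet's land use) and concentrate-production emissions; (5) combined
#' totals and intensities. The baseline scenario retains the full
#' attributed forest loss (no deficit filtering) and has zero LUC by
#' construction.
#'
#' @param spec a [scenario_spec()].
#' @param landscape a `landscape`.
#' @param fixtures a [scenario_fixtures()].
#' @param attribution optional precomputed [attribute_forest_loss()]
#'   result (cached across scenarios for speed and identical forests).
#' @param buffer_radius metres (default 5,000).
#' @return a `scenario_result`.
#' @export
run_scenario <- function(spec, landscape, fixtures = scenario_fixtures(),
                         attribution = NULL, buffer_radius = 5000) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  if (is.null(attribution))
    attribution <- attribute_forest_loss(landscape)
  factors <- fixtures$factors
  labels <- landscape$lps_labels
  heads <- lps_productive_heads(landscape, factors)
  calib <- if (fixtures$calibrate_milk) fixtures$diet_table else NULL

  per_lps <- lapply(labels, function(lps) {
    diet <- get_diet(fixtures$diet_table, lps, spec$name, spec$yield_level)
    milk <- lifetime_milk(diet, fixtures$feeds, fixtures$cow,
                          calibration = calib)
    nreq <- fertilizer_n_requirement(spec$yield_level, lps,
                                     fixtures$yield_cfg)
    silage_ha_head <- diet$intake[["maize_silage"]] / 1000 /
      maize_yield_at(spec$yield_level, lps, fixtures$yield_cfg)
    breakdown <- cow_emissions(diet, fixtures$feeds, factors,
                               cow = fixtures$cow, milk = milk,
                               n_fertilizer_per_head =
                                 nreq$fertilizer_n * silage_ha_head)
    list(lps = lps, milk = milk, breakdown = breakdown,
         conc_kg = diet$intake[["concentrate"]])
  })
  names(per_lps) <- labels

  # study-area herd aggregates (Mg CO2eq yr-1, kg FPCM yr-1)
  milk_total <- sum(vapply(labels, function(l)
    per_lps[[l]]$milk * heads[l], numeric(1)))
  cat_names <- names(per_lps[[1]]$breakdown)
  ag_categories <- stats::setNames(numeric(length(cat_names)), cat_names)
  for (l in labels)
    ag_categories <- ag_categories +
      unclass(per_lps[[l]]$breakdown) * heads[l] / 1000
  conc_tonnes <- sum(vapply(labels, function(l)
    per_lps[[l]]$conc_kg * heads[l], numeric(1))) / 1000
  ag_categories[["concentrate_co2e"]] <-
    conc_tonnes * 1000 * ef_mean(factors$concentrate_ef) / 1000

  # spatial land budget
  demand <- scenario_demand_layer(spec, landscape, fixtures)
  base_demand <- if (spec$name == "baseline") demand else
    scenario_demand_layer(scenario_spec("baseline"), landscape, fixtures)
  avail <- landscape$grazing_land
  def <- land_deficit(demand, avail)
  buffered <- buffer_deficit(def$polygons, buffer_radius)
  conv <- pmin(demand$values, avail$values)
  conv_base <- pmin(base_demand$values, avail$values)
  luc_area <- sum(pmax(conv - conv_base, 0), na.rm = TRUE)
  luc <- luc_emissions(luc_area, factors$luc_ef_grass_to_crop,
                       ef_sd = (factors$luc_ef_grass_to_crop$max -
                                  factors$luc_ef_grass_to_crop$min) / 4,
                       amortisation_years =
                         factors$luc_amortisation_years %||% 20)
  ag_categories[["luc_co2"]] <- luc$emissions
  ag_total <- sum(ag_categories)

  # forest feedback: baseline keeps the whole attributed loss
  if (spec$name == "baseline") {
    forest <- list(retained = attribution$total_loss_co2eq, mitigated = 0,
                   baseline_total = attribution$total_loss_co2eq)
  } else {
    forest <- scenario_forest_loss(attribution$c_loss_cattle, buffered)
  }
  gain_total <- attribution$total_loss_co2eq +
    attribution$total_change_co2eq   # gain = change + loss
  forest_net <- forest$retained - gain_total   # >0: forest is a source

  structure(list(
    spec = spec, milk = milk_total,
    milk_per_lps = stats::setNames(
      vapply(labels, function(l) per_lps[[l]]$milk, numeric(1)), labels),
    heads = heads,
    emissions = ag_categories, ag_total = ag_total,
    concentrate_tonnes = conc_tonnes,
    luc_area_ha = luc_area,
    deficit = def, buffered = buffered,
    deficit_area_ha = sum(def$deficit_mask$values, na.rm = TRUE) *
      pixel_area_ha(def$deficit_mask),
    forest = forest, forest_net = forest_net,
    combined_total = ag_total + forest_net,
    intensity = emission_intensity(ag_total * 1000, milk_total),
    intensity_with_forest = emission_intensity(
      (ag_total + forest_net) * 1000, milk_total)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s / %s\n", x$spec$name,
              x$spec$yield_level))
  cat(sprintf("  milk: %.3g kg FPCM yr-1   ag emissions: %.4g Mg CO2eq yr-1\n",
              x$milk, x$ag_total))
  cat(sprintf("  intensity: %.2f (%.2f incl. forest) kg CO2eq / kg FPCM\n",
              x$intensity, x$intensity_with_forest))
  cat(sprintf("  deficit: %.0f ha   LUC: %.0f ha   retained forest loss: %.1f Mg CO2eq yr-1\n",
              x$deficit_area_ha, x$luc_area_ha, x$forest$retained))
  invisible(x)
}

#' Population-weighted aggregation of per-LPS results
#'
#' @param milk_per_lps named kg FPCM head⁻¹ yr⁻¹.
#' @param intensity_per_lps named kg CO2eq per kg FPCM.
#' @param heads named productive cows per LPS.
#' @return list: `milk_total` and the production-weighted mean
#'   `intensity`.
#' @export
aggregate_study_area <- function(milk_per_lps, intensity_per_lps, heads) {
  if (any(heads < 0)) stop("populations must be non-negative")
  milk <- milk_per_lps * heads
  list(milk_total = sum(milk),
       intensity = sum(intensity_per_lps * milk) / sum(milk))
}

#' Mitigation comparison across scenarios
#'
#' Compares each scenario against the baseline: percentage changes in
#' milk, agricultural emissions and emission intensity (all with the
#' baseline as denominator; intensity also as the milk-weighted mean of
#' per-LPS deltas), forest mitigation, and the combined
#' agriculture-plus-forest total.
#'
#' @param results list of `scenario_result`s including one baseline.
#' @return a `mitigation_report` data.frame.
#' @export
mitigation_report <- function(results) {
  names(results) <- vapply(results, function(r)
    paste0(r$spec$name, "-", r$spec$yield_level), character(1))
  base <- Filter(function(r) r$spec$name == "baseline", results)
  if (!length(base)) stop("no baseline result present")
  b <- base[[1]]
  rows <- lapply(results, function(r) {
    data.frame(
      scenario = r$spec$name, yield_level = r$spec$yield_level,
      milk_increase_pct = (r$milk - b$milk) / b$milk * 100,
      d_ag_emissions_pct = (r$ag_total - b$ag_total) / b$ag_total * 100,
      d_intensity_pct = (r$intensity - b$intensity) / b$intensity * 100,
      d_intensity_with_forest_pct =
        (r$intensity_with_forest - b$intensity_with_forest) /
          b$intensity_with_forest * 100,
      forest_mitigated_co2eq = r$forest$baseline_total -
        r$forest$retained,
      d_combined_pct = (r$combined_total - b$combined_total) /
        abs(b$combined_total) * 100,
      intensity = r$intensity,
      intensity_with_forest = r$intensity_with_forest)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mitigation_report", "data.frame")
  out
}

#' @export
print.mitigation_report <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, 1))
  cat("<mitigation_report> (% changes vs baseline)\n")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a mitigation report as CSV
#' @param x a `mitigation_report`.
#' @param path output path.
#' @export
write_mitigation_report <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
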