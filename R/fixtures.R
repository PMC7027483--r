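# Loaders for the packaged reference tables: per-LPS scenario diets and
# milk yields, cow populations, concentrate ingredient composition and
# national crop yields, feed quality attributes, and emission-factor
# ranges. Users can point each loader at their own file with the same
# columns.

#' @keywords internal
pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "dairyshed")
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}

#' Load the per-LPS diet and milk-yield table
#'
#' One row per LPS x scenario x maize yield level with annual dry-matter
#' intake by feed type (kg DM head⁻¹ yr⁻¹), the fat-and-protein-corrected
#' milk yield, the milk increase over baseline (%) and the reference
#' emission intensity. The milk-yield column doubles as the calibration
#' fixture for the herd surrogate.
#'
#' @param path CSV path; default: the packaged table.
#' @return data.frame.
#' @export
load_diet_table <- function(path = pkg_extdata("diets.csv")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("lps", "scenario", "yield_level", "dmi", "pasture", "napier",
              "maize_stover", "maize_silage", "concentrate", "milk_fpcm")
  if (!all(needed %in% names(d)))
    stop("diet table must have columns: ", paste(needed, collapse = ", "))
  comp <- d$pasture + d$napier + d$maize_stover + d$maize_silage +
    d$concentrate
  if (any(abs(comp - d$dmi) > 0.01 * pmax(d$dmi, 1)))
    warning("DMI differs from the sum of feed components by more than 1% ",
            "in some rows (rounding in the source table)")
  d
}

#' Extract one diet from the diet table
#'
#' @param diet_table from [load_diet_table()].
#' @param lps,scenario,yield_level row selector. Yield level only affects
#'   crop yields, not the ration, so a missing yield level falls back to
#'   the scenario's first row.
#' @return a `diet` list: `intake` (named kg DM head⁻¹ yr⁻¹ per feed),
#'   `lps`, `scenario`, `yield_level`, `milk_fixture` (kg FPCM head⁻¹
#'   yr⁻¹).
#' @export
get_diet <- function(diet_table, lps, scenario, yield_level = "Ya") {
  rows <- diet_table[diet_table$lps == lps &
                       diet_table$scenario == scenario, , drop = FALSE]
  if (!nrow(rows))
    stop("no diet row for LPS ", lps, ", scenario ", scenario)
  r <- rows[rows$yield_level == yield_level, , drop = FALSE]
  if (!nrow(r)) r <- rows[1, , drop = FALSE]
  structure(list(
    intake = c(pasture = r$pasture, napier = r$napier,
               maize_stover = r$maize_stover,
               maize_silage = r$maize_silage,
               concentrate = r$concentrate),
    lps = lps, scenario = scenario, yield_level = yield_level,
    milk_fixture = r$milk_fpcm), class = "diet")
}

#' @export
print.diet <- function(x, ...) {
  cat(sprintf("<diet> %s / %s / %s  (total DMI %.0f kg head-1 yr-1)\n",
              x$lps, x$scenario, x$yield_level, sum(x$intake)))
  print(round(x$intake))
  invisible(x)
}

#' Load the feed quality table
#'
#' Per feed: dry-matter digestibility, crude protein (fraction of DM),
#' gross energy density (MJ per kg DM), crop yield for cultivated feeds
#' (t DM ha⁻¹) and flags for concentrates and cultivated (land-demanding)
#' feeds.
#'
#' @param path CSV path; default: the packaged table.
#' @return data.frame keyed by `name`.
#' @export
load_feed_table <- function(path = pkg_extdata("feeds.csv")) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(f$dm_digestibility < 0 | f$dm_digestibility > 1) ||
      any(f$crude_protein < 0 | f$crude_protein > 1))
    stop("digestibility and crude protein must lie in [0, 1]")
  cult <- f$cultivated == 1 & !is.na(f$crop_yield_t_ha)
  if (any(f$crop_yield_t_ha[cult] <= 0))
    stop("cultivated feeds must have positive crop yields")
  f
}

#' Load cow populations per livestock production system
#'
#' Dairy-cow population, productive-cow count and the baseline concentrate
#' tonnage per LPS. The baseline tonnage column is a reported fixture (it
#' is not derivable from the baseline per-head concentrate intakes);
#' scenario tonnages are always computed from populations.
#'
#' @param path CSV path; default: the packaged table.
#' @return data.frame.
#' @export
load_cow_populations <- function(path = pkg_extdata("cow_populations.csv")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load concentrate ingredient composition and national crop yields
#'
#' @param path CSV path; default: the packaged table.
#' @return data.frame: ingredient, composition_fraction (sums to 1),
#'   yield_t_ha, national_area_ha.
#' @export
load_concentrate_ingredients <- function(
    path = pkg_extdata("concentrate_ingredients.csv")) {
  ing <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (abs(sum(ing$composition_fraction) - 1) > 1e-8)
    stop("ingredient composition fractions must sum to 1")
  if (any(ing$yield_t_ha <= 0)) stop("ingredient yields must be positive")
  ing
}

#' Load emission factors and model constants
#'
#' Factors with `(min, mean, max)` ranges participate in the uncertainty
#' analysis; scalars are fixed constants. Ranges must satisfy
#' `min <= mean <= max` and fractional factors must lie in \[0, 1\].
#'
#' @param path YAML path; default: the packaged file.
#' @return a named list; ranged entries are lists with `min`, `mean`,
#'   `max`.
#' @export
load_emission_factors <- function(
    path = pkg_extdata("emission_factors.yaml")) {
  ef <- yaml::read_yaml(path)
  ranged <- Filter(function(x) is.list(x) && all(c("min", "mean", "max")
                                                 %in% names(x)), ef)
  for (nm in names(ranged)) {
    r <- ranged[[nm]]
    if (!(r$min <= r$mean && r$mean <= r$max))
      stop("emission factor ", nm, " violates min <= mean <= max")
  }
  for (split in ef$manure_split) {
    if (abs(sum(unlist(split)) - 1) > 1e-8)
      stop("manure system split must sum to 1")
  }
  ef
}

#' Mean value of a (possibly ranged) emission factor
#'
#' Ranged factors are lists with `min`/`mean`/`max`; scalars pass
#' through. Useful when writing model closures for [lhs_uncertainty()].
#'
#' @param x a ranged factor or scalar.
#' @return the mean (or the scalar itself).
#' @export
ef_mean <- function(x) if (is.list(x)) x$mean else x
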