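# Attribution of forest carbon loss to dairy-cattle grazing.
#
# Chain: restrict net forest C loss to natural forest, exclude burnt
# pixels (they drop out of both loss and area, rather than being zeroed),
# subtract nonrenewable fuelwood biomass (clamped at zero: negative
# grazing-attributed loss is physically meaningless), scale by the
# county-level dairy proportion, and propagate variance analytically:
#
#   var(loss_cattle) = var(net loss) + var(NRB) - 2 cov(net loss, NRB)
#
# Internal rasters stay in kg C ha^-1 yr^-1; CO2eq conversion (44/12)
# happens only in reporting helpers.

#' Natural-forest mask
#'
#' Restricts a forest mask to natural forest by removing plantations.
#'
#' @param forest_mask,plantation_mask co-registered `grid_layer`s with
#'   0/1 values.
#' @return a `grid_layer` equal to `forest AND NOT plantation`.
#' @export
natural_forest_mask <- function(forest_mask, plantation_mask) {
  check_same_grid(forest_mask, plantation_mask)
  v <- (forest_mask$values == 1) & !(plantation_mask$values == 1)
  with_values(forest_mask, v * 1, rel_sd = NULL, units = "mask")
}

#' Exclude burnt pixels from a carbon-loss layer
#'
#' Fire-driven loss can be neither attributed to cattle nor mitigated by
#' feeding, so burnt pixels are set to nodata — excluded from the loss
#' field *and* from any area denominator — not zeroed.
#'
#' @param c_loss a `grid_layer`.
#' @param burn_mask co-registered 0/1 `grid_layer`.
#' @return `c_loss` with burnt pixels as `NA`.
#' @export
exclude_burned <- function(c_loss, burn_mask) {
  check_same_grid(c_loss, burn_mask)
  v <- c_loss$values
  burned <- burn_mask$values == 1
  v[burned] <- NA_real_
  rs <- c_loss$rel_sd
  if (!is.null(rs)) rs[burned] <- NA_real_
  with_values(c_loss, v, rel_sd = rs)
}

#' Variance of the fuelwood-corrected loss
#'
#' Analytic error propagation for a difference of two correlated inputs:
#' `var_loss + var_nrb - 2 * cov`, floored at zero against round-off.
#' Vectorised.
#'
#' @param var_loss,var_nrb variances (>= 0).
#' @param cov covariance; must satisfy `|cov| <= sqrt(var_loss * var_nrb)`.
#' @return the propagated variance.
#' @export
propagate_variance <- function(var_loss, var_nrb, cov = 0) {
  ok <- !is.na(var_loss) & !is.na(var_nrb)
  if (any(var_loss[ok] < 0) || any(var_nrb[ok] < 0))
    stop("variances must be non-negative")
  cv <- rep_len(cov, length(var_loss))
  bound <- sqrt(var_loss * var_nrb)
  if (any(abs(cv[ok]) > bound[ok] * (1 + 1e-12)))
    stop("covariance violates the Cauchy-Schwarz bound")
  pmax(var_loss + var_nrb - 2 * cv, 0)
}

#' Subtract nonrenewable fuelwood biomass from net forest carbon loss
#'
#' Per-pixel `max(net_c_loss - nrb, 0)`; the residual is the loss pool
#' attributable to cattle grazing. The variance field is populated via
#' [propagate_variance()] using the relative SDs carried by the inputs and
#' an assumed input correlation `cor_inputs` (default 0; how the original
#' covariance was estimated is not published, so it is exposed as a
#' parameter).
#'
#' @param net_c_loss,nrb co-registered `grid_layer`s (kg C ha⁻¹ yr⁻¹),
#'   both already restricted to natural forest.
#' @param cor_inputs correlation between the two inputs used to form the
#'   covariance term, in \[-1, 1\].
#' @return list: `layer` (clamped difference, with rel_sd) and
#'   `variance` (`grid_layer` of per-pixel variances).
#' @export
subtract_fuelwood <- function(net_c_loss, nrb, cor_inputs = 0) {
  check_same_grid(net_c_loss, nrb)
  if (any(nrb$values < 0, na.rm = TRUE))
    stop("NRB input must be non-negative")
  if (abs(cor_inputs) > 1) stop("cor_inputs must lie in [-1, 1]")
  v <- pmax(net_c_loss$values - nrb$values, 0)
  sd_l <- abs(net_c_loss$values) *
    (net_c_loss$rel_sd %||% matrix(0, nrow(v), ncol(v)))
  sd_n <- abs(nrb$values) *
    (nrb$rel_sd %||% matrix(0, nrow(v), ncol(v)))
  var_v <- propagate_variance(sd_l^2, sd_n^2, cor_inputs * sd_l * sd_n)
  rs <- sqrt(var_v) / ifelse(v > 0, v, NA_real_)
  rs[v == 0] <- 0
  list(layer = with_values(net_c_loss, v, rel_sd = rs),
       variance = with_values(net_c_loss, var_v, rel_sd = NULL,
                              units = "(kg C ha-1 yr-1)^2"))
}

#' Scale attributed loss by county dairy proportions
#'
#' Multiplies each pixel by the dairy-cattle proportion of the county zone
#' it falls in, converting cattle-attributed loss to dairy-attributed loss.
#' Variance scales by the square of the proportion.
#'
#' @param c_loss_cattle a `grid_layer`.
#' @param county_zone co-registered `grid_layer` of county ids.
#' @param counties data.frame with `county_id` and `dairy_proportion`
#'   columns.
#' @return the scaled `grid_layer`.
#' @export
scale_by_dairy_proportion <- function(c_loss_cattle, county_zone, counties) {
  check_same_grid(c_loss_cattle, county_zone)
  if (any(counties$dairy_proportion < 0 | counties$dairy_proportion > 1))
    stop("dairy proportions must lie in [0, 1]")
  prop <- counties$dairy_proportion[
    match(county_zone$values, counties$county_id)]
  prop <- matrix(prop, nrow(c_loss_cattle$values))
  valid <- !is.na(c_loss_cattle$values)
  if (any(valid & is.na(prop))) {
    bad <- which(valid & is.na(prop), arr.ind = TRUE)
    stop("pixels not covered by any county, e.g. (row, col): ",
         paste(apply(utils::head(bad, 5), 1, paste, collapse = ","),
               collapse = "; "))
  }
  with_values(c_loss_cattle, c_loss_cattle$values * prop)
}

#' Forest carbon change under grazing
#'
#' Net forest C gain minus the grazing-attributed loss; negative values
#' indicate net loss.
#'
#' @param c_gain,c_loss_cattle co-registered `grid_layer`s.
#' @return a `grid_layer` (kg C ha⁻¹ yr⁻¹). Pixels valid in either input
#'   are kept, with the missing side treated as 0.
#' @export
forest_c_change <- function(c_gain, c_loss_cattle) {
  check_same_grid(c_gain, c_loss_cattle)
  g <- c_gain$values; l <- c_loss_cattle$values
  both_na <- is.na(g) & is.na(l)
  g[is.na(g)] <- 0; l[is.na(l)] <- 0
  v <- g - l
  v[both_na] <- NA_real_
  with_values(c_gain, v, rel_sd = NULL)
}

#' Run the full forest-attribution chain on a landscape
#'
#' Applies, in order: natural-forest masking, fire exclusion, fuelwood
#' subtraction (with variance propagation) and dairy-proportion scaling,
#' then derives the forest C change layer. If the inputs are cumulative
#' over an observation period rather than annual rates, set `period_years`
#' to annualise them first.
#'
#' @param landscape a `landscape` bundle from [generate_landscape()] (or a
#'   compatible list of layers).
#' @param cor_inputs correlation between net loss and NRB for the
#'   covariance term (default 0).
#' @param period_years divide input carbon layers by this period length to
#'   annualise; default 1 (already annual rates).
#' @return an `attribution_result`: `c_loss_cattle`, `c_change_cattle`,
#'   `var_c_loss_cattle` layers plus summary totals (Mg CO2eq yr⁻¹).
#' @export
attribute_forest_loss <- function(landscape, cor_inputs = 0,
                                  period_years = 1) {
  annualise <- function(l) {
    if (period_years == 1) return(l)
    with_values(l, l$values / period_years)
  }
  nat <- natural_forest_mask(landscape$forest_mask,
                             landscape$plantation_mask)
  mask_to <- function(l, m) {
    v <- l$values; v[m$values != 1] <- NA_real_
    rs <- l$rel_sd; if (!is.null(rs)) rs[m$values != 1] <- NA_real_
    with_values(l, v, rel_sd = rs)
  }
  loss <- mask_to(annualise(landscape$net_c_loss), nat)
  loss <- exclude_burned(loss, landscape$burn_mask)
  nrb <- mask_to(annualise(landscape$nrb), nat)
  nrb <- exclude_burned(nrb, landscape$burn_mask)
  sub <- subtract_fuelwood(loss, nrb, cor_inputs = cor_inputs)
  dairy <- scale_by_dairy_proportion(sub$layer, landscape$county_zone,
                                     landscape$counties)
  prop <- landscape$counties$dairy_proportion[
    match(landscape$county_zone$values, landscape$counties$county_id)]
  var_dairy <- with_values(sub$variance,
                           sub$variance$values *
                             matrix(prop, nrow(sub$variance$values))^2)
  gain <- mask_to(annualise(landscape$net_c_gain), nat)
  change <- forest_c_change(gain, dairy)
  structure(list(
    c_loss_cattle = dairy,
    c_change_cattle = change,
    var_c_loss_cattle = var_dairy,
    natural_forest = nat,
    total_loss_co2eq = study_total(dairy, as_co2eq = TRUE),
    total_change_co2eq = study_total(change, as_co2eq = TRUE),
    total_sd_co2eq = c_to_co2eq_mg(
      sqrt(sum(var_dairy$values, na.rm = TRUE)) *
        pixel_area_ha(dairy))),
    class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result>\n")
  cat(sprintf("  dairy-attributed forest C loss: %.1f Mg CO2eq yr-1 (SD %.1f)\n",
              x$total_loss_co2eq, x$total_sd_co2eq))
  cat(sprintf("  forest C change under grazing:  %.1f Mg CO2eq yr-1\n",
              x$total_change_co2eq))
  invisible(x)
}

#' Write the attribution summary as CSV
#' @param x an `attribution_result`.
#' @param path output path.
#' @export
write_attribution_summary <- function(x, path) {
  utils::write.csv(data.frame(
    quantity = c("total_loss_co2eq", "total_change_co2eq", "total_sd_co2eq"),
    value = c(x$total_loss_co2eq, x$total_change_co2eq, x$total_sd_co2eq),
    units = "Mg CO2eq yr-1"), path, row.names = FALSE)
  invisible(path)
}
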