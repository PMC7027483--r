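# Spatial land budget: per-pixel cropland demand for cultivated feeds,
# land-deficit polygons (8-connected components of deficit pixels),
# metric buffering, the feedback of buffered deficits on forest carbon
# loss, land-use-change emissions, and the (aspatial) concentrate demand
# and land footprint chain.

# ---- maize yield-gap levels ------------------------------------------------

#' Maize yield-gap configuration
#'
#' Actual yield (Ya) and the water-limited yield potential (Yw) of fodder
#' maize, with levels Yw50/Yw80 realising 50% and 80% of Yw. Yields vary
#' by agro-ecological zone via per-LPS multipliers (arid systems below,
#' humid above the reference). The N requirement to move from Ya to a
#' target yield converts crop N uptake to applied N through source-specific
#' nitrogen use efficiencies (fertilizer 33%, manure 20%).
#'
#' @param ya_yield actual maize (whole-plant silage) yield, t DM ha⁻¹.
#' @param yw_yield water-limited yield potential, t DM ha⁻¹.
#' @param lps_multiplier named per-LPS yield multipliers.
#' @param n_uptake_per_t crop N uptake per tonne of additional DM,
#'   kg N t⁻¹.
#' @param fertilizer_share share of the additional uptake supplied by
#'   synthetic fertilizer (remainder from manure).
#' @param nue_fertilizer,nue_manure nitrogen use efficiencies.
#' @return a `yield_gap_config` list.
#' @export
yield_gap_config <- function(ya_yield = 1.766, yw_yield = 6.4,
                             lps_multiplier = c(MRA = 0.8, MRH = 1.1,
                                                MRT = 1.0, MIA = 0.8,
                                                MIH = 1.1, MIT = 1.0),
                             n_uptake_per_t = 22,
                             fertilizer_share = 0.5,
                             nue_fertilizer = 0.33, nue_manure = 0.20) {
  if (ya_yield <= 0 || yw_yield <= 0) stop("yields must be positive")
  if (ya_yield > 0.5 * yw_yield)
    warning("actual yield exceeds Yw50; yield-gap levels will not be ",
            "monotone")
  structure(as.list(environment()), class = "yield_gap_config")
}

#' Maize yield at a yield-gap level
#'
#' @param level one of `"Ya"`, `"Yw50"`, `"Yw80"`.
#' @param lps LPS label(s) (vectorised).
#' @param cfg a [yield_gap_config()].
#' @return t DM ha⁻¹, same length as `lps`.
#' @export
maize_yield_at <- function(level, lps, cfg = yield_gap_config()) {
  base <- switch(level,
                 Ya = cfg$ya_yield,
                 Yw50 = 0.5 * cfg$yw_yield,
                 Yw80 = 0.8 * cfg$yw_yield,
                 stop("unknown yield level: ", level))
  mult <- cfg$lps_multiplier[lps]
  if (anyNA(mult)) stop("unknown LPS label(s): ",
                        paste(lps[is.na(mult)], collapse = ", "))
  unname(base * mult)
}

#' Fertilizer N requirement to reach a yield-gap level
#'
#' Additional crop N uptake (uptake-per-tonne times the yield increment
#' over Ya) is split between fertilizer and manure sources and divided by
#' the source nitrogen use efficiency to give applied N. Non-decreasing
#' in the yield level.
#'
#' @inheritParams maize_yield_at
#' @return list per ha of maize: `n_uptake`, `fertilizer_n`, `manure_n`
#'   (kg N ha⁻¹ applied).
#' @export
fertilizer_n_requirement <- function(level, lps, cfg = yield_gap_config()) {
  y <- maize_yield_at(level, lps, cfg)
  ya <- maize_yield_at("Ya", lps, cfg)
  uptake <- pmax(y - ya, 0) * cfg$n_uptake_per_t
  list(n_uptake = uptake,
       fertilizer_n = uptake * cfg$fertilizer_share / cfg$nue_fertilizer,
       manure_n = uptake * (1 - cfg$fertilizer_share) / cfg$nue_manure)
}

# ---- spatial demand and deficits -------------------------------------------

#' Per-pixel cropland demand for cultivated feeds
#'
#' For each pixel: heads (density times pixel area) times the per-head
#' annual intake of each cultivated feed, divided by that feed's yield.
#' Maize-silage yield is supplied per pixel (scalar or matrix) so
#' yield-gap levels and LPS zones can vary spatially; other cultivated
#' feeds use the yield in the feed table.
#'
#' @param cattle_density `grid_layer`, head km⁻².
#' @param diet a `diet` (or any named intake vector wrapped in a list with
#'   `$intake`).
#' @param feeds feed table.
#' @param maize_yield t DM ha⁻¹: scalar or matrix matching the grid.
#' @return demand `grid_layer` in ha per pixel.
#' @export
feed_land_demand <- function(cattle_density, diet, feeds, maize_yield) {
  v <- cattle_density$values
  heads <- v * (cattle_density$cellsize / 1000)^2   # head per pixel
  demand <- matrix(0, nrow(v), ncol(v))
  for (feed in names(diet$intake)) {
    kg <- diet$intake[[feed]]
    if (kg <= 0) next
    row <- feeds[feeds$name == feed, , drop = FALSE]
    if (!nrow(row) || row$cultivated != 1) next
    yld <- if (feed == "maize_silage") maize_yield else row$crop_yield_t_ha
    if (any(yld <= 0, na.rm = TRUE) || anyNA(yld))
      stop("non-positive or missing yield for cultivated feed ", feed)
    demand <- demand + heads * (kg / 1000) / yld
  }
  demand[is.na(v)] <- NA_real_
  with_values(cattle_density, demand, rel_sd = NULL, units = "ha")
}

#' Label land-deficit pixels and build deficit polygons
#'
#' A pixel is in deficit where cropland demand exceeds the grazing land
#' available for conversion. Deficit pixels are grouped into 8-connected
#' components; each component is one (multipart) polygon of 1-km² pixel
#' squares.
#'
#' @param demand,available co-registered `grid_layer`s, ha per pixel.
#' @return list: `deficit_mask` (`grid_layer`, 0/1), `polygons` (a
#'   `deficit_polygons` object).
#' @export
land_deficit <- function(demand, available) {
  check_same_grid(demand, available)
  d <- demand$values; a <- available$values
  mask <- !is.na(d) & !is.na(a) & d > a
  comp <- label_components(mask)
  polys <- structure(list(
    labels = comp, n = max(comp, 0),
    xll = demand$xll, yll = demand$yll,
    cellsize = demand$cellsize, crs = demand$crs, radius = 0),
    class = "deficit_polygons")
  list(deficit_mask = with_values(demand, mask * 1, rel_sd = NULL,
                                  units = "mask"),
       polygons = polys)
}

#' 8-connected component labelling of a boolean matrix
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      ni <- i + offs$di; nj <- j + offs$dj
      ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
      q <- (nj[ok] - 1L) * nr + ni[ok]
      q <- q[mask[q] & lab[q] == 0L]
      lab[q] <- cur
      stack <- c(stack, q)
    }
  }
  lab
}

#' @export
print.deficit_polygons <- function(x, ...) {
  cat(sprintf("<deficit_polygons> %d component(s), %d pixel(s), buffer %g m\n",
              x$n, sum(x$labels > 0), x$radius))
  invisible(x)
}

#' Buffer deficit polygons by a metric radius
#'
#' Euclidean (Minkowski-sum) buffer of the union of deficit pixel squares,
#' represented exactly: a point lies in the buffered polygons iff its
#' distance to the nearest deficit square is at most the radius. Requires
#' projected coordinates in metres.
#'
#' @param polygons a `deficit_polygons` object.
#' @param radius buffer radius in metres (default 5,000 m — the
#'   empirically determined farm-neighbourhood radius).
#' @return a `deficit_polygons` with the buffer radius set.
#' @export
buffer_deficit <- function(polygons, radius = 5000) {
  if (grepl("deg|4326|longlat|geographic", polygons$crs, ignore.case = TRUE))
    stop("buffering requires projected coordinates in metres, not a ",
         "geographic (degree) CRS")
  if (radius < 0) stop("radius must be non-negative")
  polygons$radius <- polygons$radius + radius
  polygons
}

#' Point-in-(buffered)-polygons test
#'
#' Exact: distance from each point to the nearest deficit pixel square,
#' compared with the buffer radius.
#'
#' @param polygons a `deficit_polygons`.
#' @param x,y point coordinates (metres, same CRS as the grid).
#' @return logical vector.
#' @export
polygons_contain <- function(polygons, x, y) {
  idx <- which(polygons$labels > 0)
  if (!length(idx)) return(rep(FALSE, length(x)))
  nr <- nrow(polygons$labels); cs <- polygons$cellsize
  i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
  cx <- polygons$xll + (j - 0.5) * cs
  cy <- polygons$yll + (nr - i + 0.5) * cs
  r <- polygons$radius
  out <- logical(length(x))
  for (k in seq_along(x)) {
    dx <- pmax(abs(x[k] - cx) - cs / 2, 0)
    dy <- pmax(abs(y[k] - cy) - cs / 2, 0)
    out[k] <- any(dx * dx + dy * dy <= r * r + 1e-9)
  }
  out
}

#' Area of (buffered) deficit polygons
#'
#' Unbuffered polygons have exact area (pixel count times pixel area);
#' buffered areas are computed by deterministic fine-grid quadrature over
#' the bounding box (resolution `radius/100`, or the cell size if finer).
#'
#' @param polygons a `deficit_polygons`.
#' @return area in m².
#' @export
polygons_area <- function(polygons) {
  npix <- sum(polygons$labels > 0)
  cs <- polygons$cellsize
  if (npix == 0) return(0)
  if (polygons$radius == 0) return(npix * cs^2)
  idx <- which(polygons$labels > 0)
  nr <- nrow(polygons$labels)
  i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
  cx <- polygons$xll + (j - 0.5) * cs
  cy <- polygons$yll + (nr - i + 0.5) * cs
  r <- polygons$radius
  res <- min(cs, r / 100)
  gx <- seq(min(cx) - cs / 2 - r - res, max(cx) + cs / 2 + r + res, by = res)
  gy <- seq(min(cy) - cs / 2 - r - res, max(cy) + cs / 2 + r + res, by = res)
  inside <- 0
  for (yk in gy) {
    dx2 <- outer(gx, cx, function(px, qx) pmax(abs(px - qx) - cs / 2, 0)^2)
    dy2 <- matrix(pmax(abs(yk - cy) - cs / 2, 0)^2,
                  nrow = length(gx), ncol = length(cx), byrow = TRUE)
    inside <- inside + sum(rowSums(dx2 + dy2 <= r * r) > 0)
  }
  inside * res^2
}

#' Forest carbon loss retained and mitigated under a scenario
#'
#' Grazing-attributed forest C loss pixels whose centres intersect the
#' buffered land-deficit polygons remain as losses (land shortage keeps
#' cattle grazing in adjacent forest); the rest of the baseline loss is
#' mitigated. Totals in Mg CO2eq yr⁻¹.
#'
#' @param c_loss_cattle attributed-loss `grid_layer` (kg C ha⁻¹ yr⁻¹).
#' @param buffered a `deficit_polygons` (typically buffered 5 km).
#' @return list `retained`, `mitigated`, `baseline_total` (Mg CO2eq
#'   yr⁻¹) and the retained-pixel mask.
#' @export
scenario_forest_loss <- function(c_loss_cattle, buffered) {
  v <- c_loss_cattle$values
  total <- study_total(c_loss_cattle, as_co2eq = TRUE)
  if (buffered$n == 0) {
    retained_mask <- matrix(FALSE, nrow(v), ncol(v))
  } else {
    if (nrow(buffered$labels) != nrow(v) ||
        ncol(buffered$labels) != ncol(v))
      stop("loss layer and deficit polygons are not co-registered")
    r_cells <- buffered$radius / c_loss_cattle$cellsize
    retained_mask <- dilate_mask(buffered$labels > 0, r_cells)
  }
  keep <- retained_mask & !is.na(v)
  retained <- c_to_co2eq_mg(sum(v[keep]) * pixel_area_ha(c_loss_cattle))
  list(retained = retained, mitigated = total - retained,
       baseline_total = total, retained_mask = retained_mask)
}

#' Land-use-change emissions from converted area
#'
#' @param converted_area ha of grazing land converted to cropland.
#' @param luc_ef emission factor, Mg CO2eq ha⁻¹ — scalar or a ranged
#'   list with `mean` (and optionally an `sd` attribute via `ef_sd`).
#' @param ef_sd optional SD of the emission factor (Mg CO2eq ha⁻¹).
#' @param amortisation_years spread the one-time stock change over this
#'   many years (1 = report the full stock change).
#' @return list `emissions`, `sd` (Mg CO2eq, per year if amortised).
#' @export
luc_emissions <- function(converted_area, luc_ef, ef_sd = 0,
                          amortisation_years = 1) {
  if (any(converted_area < 0)) stop("area must be non-negative")
  ef <- ef_mean(luc_ef)
  list(emissions = converted_area * ef / amortisation_years,
       sd = converted_area * ef_sd / amortisation_years)
}

# ---- concentrate chain ------------------------------------------------------

#' Concentrate demand from cow populations
#'
#' Tonnes of concentrate per LPS: productive cows times the annual
#' per-head amount (450 kg at medium, 900 kg at high intensification).
#' Internal math in double precision; rounding to integer tonnes happens
#' only at report time.
#'
#' @param populations data.frame from [load_cow_populations()].
#' @param annual_kg kg concentrate head⁻¹ yr⁻¹.
#' @return data.frame `lps`, `tonnes` plus a `"Total"` row.
#' @export
concentrate_demand <- function(populations, annual_kg) {
  if (any(populations$productive_dairy_cows < 0))
    stop("cow counts must be non-negative")
  t_lps <- populations$productive_dairy_cows * annual_kg / 1000
  data.frame(lps = c(populations$lps, "Total"),
             tonnes = c(t_lps, sum(t_lps)))
}

#' Concentrate land footprint
#'
#' Splits a total concentrate tonnage into ingredients by composition,
#' converts tonnages to areas with national crop yields, and subtracts the
#' area already allocated to the baseline tonnage, so the footprint is the
#' *additional* land that scenario demand would claim.
#'
#' @param total_tonnes scenario concentrate demand, t.
#' @param ingredients data.frame from [load_concentrate_ingredients()].
#' @param baseline_tonnes baseline concentrate demand, t.
#' @return a `concentrate_footprint` data.frame: per-ingredient tonnes,
#'   baseline area, scenario (additional) area, plus a `"Total"` row;
#'   unrounded, with a print method that rounds.
#' @export
concentrate_footprint <- function(total_tonnes, ingredients,
                                  baseline_tonnes) {
  if (abs(sum(ingredients$composition_fraction) - 1) > 1e-8)
    stop("composition fractions must sum to 1")
  fr <- ingredients$composition_fraction
  yld <- ingredients$yield_t_ha
  t_ing <- fr * total_tonnes
  base_t <- fr * baseline_tonnes
  base_ha <- base_t / yld
  scen_ha <- t_ing / yld - base_ha
  out <- data.frame(
    ingredient = c(ingredients$ingredient, "Total"),
    baseline_tonnes = c(base_t, sum(base_t)),
    baseline_ha = c(base_ha, sum(base_ha)),
    scenario_tonnes = c(t_ing, sum(t_ing)),
    scenario_ha = c(scen_ha, sum(scen_ha)))
  class(out) <- c("concentrate_footprint", "data.frame")
  out
}

#' @export
print.concentrate_footprint <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round)
  cat("<concentrate_footprint> (tonnes and ha, rounded)\n")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Worst-case deforestation emissions of the concentrate footprint
#'
#' If the additional land for concentrate ingredients were cleared from
#' secondary forest, emissions are area times the forest-to-cropland
#' emission factor. Reported in Mt CO2eq with the SD scaled from the
#' factor's SD.
#'
#' @param footprint_ha additional area, ha.
#' @param ef emission factor, Mg CO2eq ha⁻¹ (default 112.7).
#' @param ef_sd SD of the factor (default 3.9).
#' @return list `emissions_mt`, `sd_mt`.
#' @export
worst_case_deforestation <- function(footprint_ha, ef = 112.7,
                                     ef_sd = 3.9) {
  list(emissions_mt = footprint_ha * ef / 1e6,
       sd_mt = footprint_ha * ef_sd / 1e6)
}

#' Write deficit polygons as GeoJSON
#'
#' Each 8-connected component becomes one MultiPolygon of its pixel
#' squares (unbuffered outline).
#'
#' @param polygons a `deficit_polygons`.
#' @param path output path.
#' @export
write_deficit_geojson <- function(polygons, path) {
  nr <- nrow(polygons$labels); cs <- polygons$cellsize
  feats <- lapply(seq_len(polygons$n), function(k) {
    idx <- which(polygons$labels == k)
    i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
    x0 <- polygons$xll + (j - 1) * cs
    y0 <- polygons$yll + (nr - i) * cs
    rings <- lapply(seq_along(idx), function(q) {
      x <- x0[q]; y <- y0[q]
      list(list(c(x, y), c(x + cs, y), c(x + cs, y + cs),
                c(x, y + cs), c(x, y)))
    })
    list(type = "Feature",
         properties = list(component = k, n_pixels = length(idx),
                           buffer_m = polygons$radius),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
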