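# Synthetic landscape generator: co-registered 1-km rasters, county zones
# and a farm survey with the statistical structure the downstream analysis
# assumes, so every stage is testable without remote-sensing downloads.

#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate the structure of the study region's data stack: a 1-km²
#' pixel grid over a dairy shed with montane forest blocks, net forest
#' carbon loss/gain with reported relative SDs, nonrenewable fuelwood
#' biomass (NRB) below net loss on average, dairy-cattle density elevated
#' near forest edges, grazing land on agricultural pixels, six livestock
#' production system (LPS) zones and county zones carrying dairy-cattle
#' proportions.
#'
#' @param grid_rows,grid_cols grid dimensions (pixels).
#' @param pixel_area pixel area in ha (100 ha = 1 km²).
#' @param forest_fraction fraction of pixels that are forest, in \[0,1\].
#' @param plantation_fraction_of_forest fraction of forest pixels that are
#'   plantations (excluded from natural forest), in \[0,1\].
#' @param burn_fraction_of_forest fraction of forest pixels burnt during the
#'   observation period, in \[0,1\].
#' @param mean_net_c_loss,mean_net_c_gain mean annual net forest C loss /
#'   gain, kg C ha⁻¹ yr⁻¹.
#' @param mean_nrb mean annual nonrenewable fuelwood biomass extraction,
#'   kg C ha⁻¹ yr⁻¹ (should not exceed `mean_net_c_loss`).
#' @param relative_sd_loss,relative_sd_nrb relative standard deviations
#'   attached to the loss and NRB layers (unitless).
#' @param cattle_density_range dairy-cattle density range, head km⁻².
#' @param grazing_land_range grazing land per agricultural pixel, ha.
#' @param edge_band_km width of the forest-edge band in which cattle density
#'   is boosted, km.
#' @param edge_density_boost multiplicative density boost inside the band.
#' @param grazing_edge_scarcity in \[0,1\): fractional reduction of grazing
#'   land near forest edges, so land deficits cluster at forest margins (the
#'   spatial pattern the analysis assumes; exposed as a parameter because it
#'   is a property of the landscape, not a published quantity).
#' @param n_counties number of county zones (Voronoi partition).
#' @param dairy_proportion_range range of county-level dairy proportions.
#' @param lps_classes labels of the six LPS classes.
#' @param autocorr_range_cells correlation length of the low-pass-filtered
#'   noise driving all continuous fields, in pixels.
#' @param seed integer master seed; all substreams derive from it.
#' @return a validated `landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 60, grid_cols = 60,
                             pixel_area = 100,
                             forest_fraction = 0.25,
                             plantation_fraction_of_forest = 0.10,
                             burn_fraction_of_forest = 0.05,
                             mean_net_c_loss = 2000,
                             mean_net_c_gain = 500,
                             mean_nrb = 600,
                             relative_sd_loss = 0.3,
                             relative_sd_nrb = 0.4,
                             cattle_density_range = c(5, 120),
                             grazing_land_range = c(20, 80),
                             edge_band_km = 5,
                             edge_density_boost = 1.8,
                             grazing_edge_scarcity = 0.5,
                             n_counties = 8,
                             dairy_proportion_range = c(0.3, 0.9),
                             lps_classes = c("MRA", "MRH", "MRT",
                                             "MIA", "MIH", "MIT"),
                             autocorr_range_cells = 3,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (grid_rows < 1 || grid_cols < 1)
    stop("grid dimensions must be positive")
  fr <- c(forest_fraction, plantation_fraction_of_forest,
          burn_fraction_of_forest, grazing_edge_scarcity)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]")
  if (pixel_area <= 0) stop("pixel_area must be positive")
  if (any(dairy_proportion_range < 0 | dairy_proportion_range > 1))
    stop("dairy_proportion_range must lie in [0, 1]")
  if (mean_net_c_loss < 0 || mean_nrb < 0)
    stop("mean rates must be non-negative")
  if (length(lps_classes) < 1) stop("need at least one LPS class")
  class(cfg) <- "landscape_config"
  cfg
}

#' Generate a synthetic landscape bundle
#'
#' Produces co-registered `grid_layer` rasters: net forest C loss and gain
#' (with relative SDs), boolean forest / plantation / burn masks
#' (plantation and burn are subsets of forest), NRB, dairy-cattle density,
#' grazing-land area, an LPS class raster and a county zone raster with a
#' per-county `dairy_proportion` table. Deterministic given
#' `config$seed`; continuous fields are spatially autocorrelated
#' (low-pass-filtered noise) so downstream deficit polygons are coherent.
#'
#' @param config a [landscape_config()].
#' @return a `landscape` list of layers plus `counties` (data.frame:
#'   county_id, seed_x, seed_y, dairy_proportion) and the config.
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "landscape_config"))
    config <- do.call(landscape_config, config)
  nr <- config$grid_rows; nc <- config$grid_cols
  cs <- sqrt(config$pixel_area * 1e4)   # cellsize m from pixel area ha
  mk <- function(v, rel_sd = NULL, units = "")
    grid_layer(v, rel_sd = rel_sd, units = units, cellsize = cs)

  # forest mask: threshold a smooth field -> contiguous patches
  set.seed(child_seed(config$seed, "forest"))
  f_field <- smooth_noise(nr, nc, config$autocorr_range_cells * 2)
  forest <- matrix(FALSE, nr, nc)
  if (config$forest_fraction > 0) {
    thr <- stats::quantile(f_field, 1 - config$forest_fraction)
    forest <- f_field >= thr
  }

  # plantations and burns: smooth-field subsets of forest
  set.seed(child_seed(config$seed, "plantation"))
  p_field <- smooth_noise(nr, nc, config$autocorr_range_cells)
  plantation <- matrix(FALSE, nr, nc)
  if (any(forest) && config$plantation_fraction_of_forest > 0) {
    thr <- stats::quantile(p_field[forest],
                           1 - config$plantation_fraction_of_forest)
    plantation <- forest & p_field >= thr
  }
  set.seed(child_seed(config$seed, "burn"))
  b_field <- smooth_noise(nr, nc, config$autocorr_range_cells)
  burn <- matrix(FALSE, nr, nc)
  if (any(forest) && config$burn_fraction_of_forest > 0) {
    thr <- stats::quantile(b_field[forest],
                           1 - config$burn_fraction_of_forest)
    burn <- forest & b_field >= thr
  }

  # carbon fields: lognormal-like positive, spatially autocorrelated,
  # scaled to the configured means over forest; nodata outside forest
  pos_field <- function(name, mean_val, rel_sd) {
    set.seed(child_seed(config$seed, name))
    z <- smooth_noise(nr, nc, config$autocorr_range_cells)
    v <- exp(z * rel_sd)                 # positive, CV ~ rel_sd
    v <- v / mean(v) * mean_val
    v[!forest] <- NA_real_
    rs <- matrix(rel_sd, nr, nc); rs[!forest] <- NA_real_
    mk(v, rel_sd = rs, units = "kg C ha-1 yr-1")
  }
  net_c_loss <- pos_field("loss", config$mean_net_c_loss,
                          config$relative_sd_loss)
  net_c_gain <- pos_field("gain", config$mean_net_c_gain,
                          config$relative_sd_loss)
  # NRB tied below the loss field on average: a damped copy of loss plus
  # its own noise, rescaled to mean_nrb (so subtraction is mostly >= 0)
  set.seed(child_seed(config$seed, "nrb"))
  z <- smooth_noise(nr, nc, config$autocorr_range_cells)
  nrb_v <- exp(z * config$relative_sd_nrb)
  base <- net_c_loss$values
  if (config$mean_net_c_loss > 0 && any(forest)) {
    shape <- base / mean(base[forest])
    nrb_v <- nrb_v * shape
    nrb_v <- nrb_v / mean(nrb_v[forest]) * config$mean_nrb
  } else {
    nrb_v <- nrb_v * 0
  }
  if (config$mean_net_c_loss > 0)
    nrb_v <- pmin(nrb_v, base * (config$mean_nrb /
                                   max(config$mean_net_c_loss, 1e-12)) * 2)
  nrb_v[!forest] <- NA_real_
  nrb_rs <- matrix(config$relative_sd_nrb, nr, nc)
  nrb_rs[!forest] <- NA_real_
  nrb <- mk(nrb_v, rel_sd = nrb_rs, units = "kg C ha-1 yr-1")

  # distance (in cells) to nearest forest pixel, for the edge band
  band_cells <- config$edge_band_km * 1000 / cs
  near_forest <- dilate_mask(forest, band_cells, cs) & !forest

  set.seed(child_seed(config$seed, "cattle"))
  z <- smooth_noise(nr, nc, config$autocorr_range_cells)
  u <- stats::pnorm(z)
  dens <- config$cattle_density_range[1] +
    u * diff(config$cattle_density_range)
  dens[near_forest] <- pmin(dens[near_forest] * config$edge_density_boost,
                            config$cattle_density_range[2] *
                              config$edge_density_boost)
  dens[forest] <- 0
  cattle <- mk(dens, units = "head km-2")

  set.seed(child_seed(config$seed, "grazing"))
  z <- smooth_noise(nr, nc, config$autocorr_range_cells)
  u <- stats::pnorm(z)
  gl <- config$grazing_land_range[1] + u * diff(config$grazing_land_range)
  gl[near_forest] <- gl[near_forest] * (1 - config$grazing_edge_scarcity)
  gl <- pmin(gl, config$pixel_area)     # cannot exceed the pixel itself
  gl[forest] <- 0
  grazing <- mk(gl, units = "ha")

  # LPS zones: Voronoi partition of as many seeds as classes
  set.seed(child_seed(config$seed, "lps"))
  lps_zone <- voronoi_zones(nr, nc, length(config$lps_classes))
  lps <- mk(matrix(as.numeric(lps_zone), nr, nc), units = "lps id")

  # counties: Voronoi partition + dairy proportions
  set.seed(child_seed(config$seed, "county"))
  cz <- voronoi_zones(nr, nc, config$n_counties)
  seeds <- attr(cz, "seeds")
  county <- mk(matrix(as.numeric(cz), nr, nc), units = "county id")
  dp <- stats::runif(config$n_counties,
                     config$dairy_proportion_range[1],
                     config$dairy_proportion_range[2])
  counties <- data.frame(
    county_id = seq_len(config$n_counties),
    seed_x = seeds[, 2] * cs - cs / 2,
    seed_y = (nr - seeds[, 1] + 0.5) * cs,
    dairy_proportion = dp)

  structure(list(
    net_c_loss = net_c_loss, net_c_gain = net_c_gain,
    forest_mask = mk(forest * 1), plantation_mask = mk(plantation * 1),
    burn_mask = mk(burn * 1), nrb = nrb,
    cattle_density = cattle, grazing_land = grazing,
    lps_class = lps, lps_labels = config$lps_classes,
    county_zone = county, counties = counties,
    config = config), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<landscape> %d x %d pixels (1 px = %g ha), seed %d\n",
              cfg$grid_rows, cfg$grid_cols, cfg$pixel_area, cfg$seed))
  cat(sprintf("  forest: %d px  plantation: %d  burnt: %d  counties: %d\n",
              sum(x$forest_mask$values == 1),
              sum(x$plantation_mask$values == 1),
              sum(x$burn_mask$values == 1), nrow(x$counties)))
  invisible(x)
}

#' Read a landscape configuration from YAML
#'
#' Top-level keys map one-to-one onto [landscape_config()] arguments.
#'
#' @param path YAML file path.
#' @return a validated `landscape_config`.
#' @export
landscape_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(landscape_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(landscape_config, cfg)
}

#' Write county zones as GeoJSON
#'
#' One MultiPolygon feature per county (its pixel squares) carrying the
#' `dairy_proportion` property.
#'
#' @param landscape a `landscape`.
#' @param path output path.
#' @export
write_counties_geojson <- function(landscape, path) {
  cz <- landscape$county_zone
  nr <- nrow(cz$values); cs <- cz$cellsize
  feats <- lapply(seq_len(nrow(landscape$counties)), function(k) {
    idx <- which(cz$values == k)
    i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
    x0 <- cz$xll + (j - 1) * cs
    y0 <- cz$yll + (nr - i) * cs
    rings <- lapply(seq_along(idx), function(q) {
      x <- x0[q]; y <- y0[q]
      list(list(c(x, y), c(x + cs, y), c(x + cs, y + cs),
                c(x, y + cs), c(x, y)))
    })
    list(type = "Feature",
         properties = list(
           county_id = landscape$counties$county_id[k],
           dairy_proportion = landscape$counties$dairy_proportion[k]),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Raster Voronoi partition: assign each pixel to its nearest seed
#' @keywords internal
voronoi_zones <- function(nr, nc, n_zones) {
  sr <- stats::runif(n_zones, 0.5, nr + 0.5)
  sc <- stats::runif(n_zones, 0.5, nc + 0.5)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best <- matrix(1L, nr, nc)
  bestd <- (rows - sr[1])^2 + (cols - sc[1])^2
  if (n_zones > 1) for (k in 2:n_zones) {
    d <- (rows - sr[k])^2 + (cols - sc[k])^2
    upd <- d < bestd
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  attr(best, "seeds") <- cbind(sr, sc)
  best
}

#' Binary dilation of a mask by a metric radius
#'
#' A pixel is in the dilated mask iff its centre lies within `radius_cells`
#' cell-widths of the *square* of any TRUE pixel (exact point-to-square
#' distance), i.e. the mask's Minkowski sum with a disc, sampled at pixel
#' centres.
#' @keywords internal
dilate_mask <- function(mask, radius_cells, cellsize = 1) {
  if (!any(mask) || radius_cells <= 0) return(mask)
  r <- radius_cells
  k <- ceiling(r + 0.5)
  offs <- expand.grid(di = -k:k, dj = -k:k)
  d <- sqrt(pmax(abs(offs$di) - 0.5, 0)^2 + pmax(abs(offs$dj) - 0.5, 0)^2)
  offs <- offs[d <= r, , drop = FALSE]
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(offs))) {
    di <- offs$di[i]; dj <- offs$dj[i]
    sr <- max(1, 1 - di):min(nr, nr - di)
    sc <- max(1, 1 - dj):min(nc, nc - dj)
    out[sr + di, sc + dj] <- out[sr + di, sc + dj] | mask[sr, sc]
  }
  out
}
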