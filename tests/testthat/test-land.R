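# Land budget: yield-gap levels, spatial demand/deficit/buffer chain and
# the concentrate demand + land-footprint arithmetic.

test_that("yield-gap levels are monotone and N requirement inverts NUE", {
  cfg <- yield_gap_config()
  for (lps in names(cfg$lps_multiplier)) {
    y <- sapply(c("Ya", "Yw50", "Yw80"), maize_yield_at, lps = lps,
                cfg = cfg)
    expect_true(all(diff(y) > 0), label = lps)
    n <- sapply(c("Ya", "Yw50", "Yw80"), function(l)
      fertilizer_n_requirement(l, lps, cfg)$fertilizer_n)
    expect_true(all(diff(n) >= 0), label = lps)
  }
  expect_error(maize_yield_at("Yw99", "MRA", cfg), "unknown yield level")
  expect_error(maize_yield_at("Ya", "XXX", cfg), "unknown LPS")
  # Ya needs no additional N
  expect_equal(fertilizer_n_requirement("Ya", "MRT", cfg)$fertilizer_n, 0)
  # inverse-NUE arithmetic: 35.7 kg N uptake at 33% NUE -> 108.2 applied
  cfg2 <- yield_gap_config(ya_yield = 1, yw_yield = 2 * (1 + 35.7 / 22),
                           lps_multiplier = c(MRT = 1),
                           fertilizer_share = 1)
  req <- fertilizer_n_requirement("Yw50", "MRT", cfg2)
  expect_equal(req$n_uptake, 35.7, tolerance = 1e-9)
  expect_equal(round(req$fertilizer_n, 1), 108.2)
  # NUE of 1 means applied N equals uptake
  cfg3 <- yield_gap_config(nue_fertilizer = 1, fertilizer_share = 1)
  r3 <- fertilizer_n_requirement("Yw80", "MRT", cfg3)
  expect_equal(r3$fertilizer_n, r3$n_uptake)
})

test_that("feed land demand follows heads x intake / yield", {
  feeds <- load_feed_table()
  d <- structure(list(intake = c(maize_silage = 883)), class = "diet")
  dens0 <- grid_layer(matrix(0, 2, 2), cellsize = 1000)
  expect_true(all(feed_land_demand(dens0, d, feeds, 1.766)$values == 0))
  dens <- grid_layer(matrix(10, 1, 1), cellsize = 1000)  # 10 head/pixel
  out <- feed_land_demand(dens, d, feeds, 1.766)
  expect_equal(out$values[1, 1], 5.0)   # 10 * 0.883 t / 1.766 t/ha
  out2 <- feed_land_demand(dens, d, feeds, 2 * 1.766)
  expect_equal(out2$values[1, 1], 2.5)  # doubling yield halves demand
  expect_error(feed_land_demand(dens, d, feeds, 0), "yield")
  # non-cultivated feeds claim no land
  d2 <- structure(list(intake = c(pasture = 5000)), class = "diet")
  expect_true(all(feed_land_demand(dens, d2, feeds, 1.766)$values == 0))
})

test_that("deficit labelling uses 8-connectivity and exact areas", {
  avail <- grid_layer(matrix(1, 4, 4), cellsize = 1000)
  nodef <- land_deficit(grid_layer(matrix(0, 4, 4), cellsize = 1000),
                        avail)
  expect_equal(nodef$polygons$n, 0)
  expect_equal(polygons_area(nodef$polygons), 0)

  one <- matrix(0, 4, 4); one[2, 2] <- 2
  d1 <- land_deficit(grid_layer(one, cellsize = 1000), avail)
  expect_equal(d1$polygons$n, 1)
  expect_equal(polygons_area(d1$polygons), 1e6)   # one 1-km^2 square

  diag2 <- matrix(0, 4, 4); diag2[1, 1] <- 2; diag2[2, 2] <- 2
  d2 <- land_deficit(grid_layer(diag2, cellsize = 1000), avail)
  expect_equal(d2$polygons$n, 1)   # diagonal neighbours join

  apart <- matrix(0, 4, 4); apart[1, 1] <- 2; apart[4, 4] <- 2
  d3 <- land_deficit(grid_layer(apart, cellsize = 1000), avail)
  expect_equal(d3$polygons$n, 2)
})

test_that("buffering grows area per the Minkowski closed form", {
  avail <- grid_layer(matrix(1, 3, 3), cellsize = 1000)
  one <- matrix(0, 3, 3); one[2, 2] <- 2
  d <- land_deficit(grid_layer(one, cellsize = 1000), avail)
  b0 <- buffer_deficit(d$polygons, 0)
  expect_equal(polygons_area(b0), 1e6)   # zero buffer is the identity
  b5 <- buffer_deficit(d$polygons, 5000)
  # 1 km^2 square + 4 sides x (1 x 5) + pi 5^2, in km^2
  expect_equal(polygons_area(b5) / 1e6, 1 + 4 * 5 + pi * 25,
               tolerance = 0.002)
  geo <- d$polygons; geo$crs <- "EPSG:4326 (degrees)"
  expect_error(buffer_deficit(geo, 5000), "projected")
  # containment is an exact distance test
  expect_true(polygons_contain(b5, 1500 + 5000, 1500))
  expect_false(polygons_contain(b5, 2000 + 5001, 1500))
})

test_that("retained forest loss is the buffered-deficit intersection", {
  loss <- grid_layer(matrix(1:9, 3, 3), cellsize = 1000)
  avail <- grid_layer(matrix(10, 3, 3), cellsize = 1000)
  none <- land_deficit(grid_layer(matrix(0, 3, 3), cellsize = 1000),
                       avail)$polygons
  out <- scenario_forest_loss(loss, none)
  expect_equal(out$retained, 0)
  expect_equal(out$mitigated, out$baseline_total)

  all_def <- land_deficit(grid_layer(matrix(20, 3, 3), cellsize = 1000),
                          avail)$polygons
  out2 <- scenario_forest_loss(loss, buffer_deficit(all_def, 0))
  expect_equal(out2$mitigated, 0)

  # one deficit pixel, zero buffer: retained = that pixel only (hand sum)
  one <- matrix(0, 3, 3); one[2, 2] <- 20
  p1 <- land_deficit(grid_layer(one, cellsize = 1000), avail)$polygons
  out3 <- scenario_forest_loss(loss, p1)
  expect_equal(out3$retained, 5 * 100 * (44 / 12) / 1000)
})

test_that("LUC emissions reproduce the worst-case deforestation numbers", {
  expect_equal(luc_emissions(0, 112.7)$emissions, 0)
  e1 <- luc_emissions(1045921, 112.7, ef_sd = 3.9)
  expect_equal(round(e1$emissions / 1e6), 118)
  expect_lt(abs(e1$emissions / 1e6 - 118), 4)
  e2 <- luc_emissions(501800, 112.7, ef_sd = 3.9)
  expect_equal(round(e2$emissions / 1e6), 57)
  expect_lt(abs(e2$emissions / 1e6 - 57), 2)
  w <- worst_case_deforestation(501800)
  expect_equal(w$emissions_mt, 501800 * 112.7 / 1e6)
  expect_equal(w$sd_mt, 501800 * 3.9 / 1e6)
})

test_that("concentrate demand reproduces the population arithmetic", {
  pops <- load_cow_populations()
  med <- concentrate_demand(pops, 450)
  expect_equal(round(med$tonnes[med$lps == "MRA"]), 66484)
  expect_equal(round(med$tonnes[med$lps == "MRT"]), 659702)
  expect_equal(round(med$tonnes[med$lps == "Total"]), 807863)
  high <- concentrate_demand(pops, 900)
  expect_equal(round(high$tonnes[high$lps == "Total"]), 1615726)
})

test_that("concentrate footprint matches the reference land-use table", {
  ing <- load_concentrate_ingredients()
  fp <- concentrate_footprint(807863, ing, baseline_tonnes = 62834)
  row <- function(tb, nm, col) tb[[col]][tb$ingredient == nm]
  expect_equal(round(row(fp, "rice_bran", "scenario_ha")), 75059)
  expect_equal(round(row(fp, "wheat_grain", "baseline_ha")), 8790)
  expect_equal(round(row(fp, "maize", "scenario_ha")), 132341)
  expect_equal(round(row(fp, "Total", "scenario_ha")), 501800)
  expect_equal(round(row(fp, "Total", "baseline_ha")), 42321)
  # conservation: ingredient tonnes and areas sum to the totals
  body <- fp[fp$ingredient != "Total", ]
  expect_equal(sum(body$scenario_tonnes), row(fp, "Total",
                                              "scenario_tonnes"))
  expect_equal(sum(body$scenario_ha), row(fp, "Total", "scenario_ha"))
  fp_hi <- concentrate_footprint(1615726, ing, baseline_tonnes = 62834)
  expect_equal(round(row(fp_hi, "Total", "scenario_ha")), 1045921)
  bad <- ing; bad$composition_fraction[1] <- 0.5
  expect_error(concentrate_footprint(1000, bad, 100), "sum to 1")
})
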