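# Per-kernel checks against independently coded single-expression oracles,
# plus the diet-level examples from the reference intake table.

make_diet <- function(intake, lps = "MRA", scenario = "baseline") {
  structure(list(intake = intake, lps = lps, scenario = scenario,
                 yield_level = "Ya", milk_fixture = NA), class = "diet")
}

test_that("annual concentrate is daily ration times feeding days", {
  expect_equal(annual_concentrate(3, 150), 450)
  expect_equal(annual_concentrate(6, 150), 900)
  expect_equal(annual_concentrate(0, 150), 0)
  expect_error(annual_concentrate(3, 400), "365")
  expect_error(annual_concentrate(-1, 150), "non-negative")
})

test_that("gross energy intake is the intake-weighted energy sum", {
  feeds <- load_feed_table()
  expect_equal(gross_energy_intake(make_diet(c(pasture = 0)), feeds), 0)
  expect_equal(gross_energy_intake(make_diet(c(pasture = 1000)), feeds),
               18450)
  # baseline total DMI at a uniform energy density, by hand
  expect_equal(gross_energy_intake(make_diet(c(pasture = 3565)), feeds),
               3565 * 18.45)
  expect_error(gross_energy_intake(make_diet(c(lucerne = 10)), feeds),
               "lucerne")
})

test_that("enteric methane follows the Tier-2 closed form", {
  expect_equal(enteric_ch4(0, 0.065), 0)
  expect_equal(enteric_ch4(5565, 0.1), 10)   # 5565 * 0.1 / 55.65
  expect_equal(enteric_ch4(65774.25, 0.065), 65774.25 * 0.065 / 55.65)
  expect_equal(round(enteric_ch4(65774.25, 0.065), 1), 76.8)
  expect_error(enteric_ch4(-1, 0.065), "non-negative")
  expect_error(enteric_ch4(100, 0.2), "0.12")
})

test_that("manure methane responds to the system split", {
  expect_equal(manure_ch4(0, 0.24, c(heap = 0.01), c(heap = 1)), 0)
  expect_equal(manure_ch4(1000, 0.24, c(heap = 0.01), c(heap = 1)),
               1000 * 0.24 * 0.67 * 0.01)
  expect_equal(round(manure_ch4(1000, 0.24, c(heap = 0.01),
                                c(heap = 1)), 2), 1.61)
  mcf <- c(pasture = 0.01, heap = 0.04)
  lo <- manure_ch4(1000, 0.24, mcf, c(pasture = 0.9, heap = 0.1))
  hi <- manure_ch4(1000, 0.24, mcf, c(pasture = 0.4, heap = 0.6))
  expect_gt(hi, lo)   # shifting manure to heaps raises CH4
  expect_error(manure_ch4(1, 0.24, mcf, c(pasture = 0.5, heap = 0.4)),
               "sum to 1")
})

test_that("nitrogen flows balance and scale linearly in protein", {
  feeds <- load_feed_table()
  z <- n_flows(make_diet(c(pasture = 0)), feeds, 0)
  expect_equal(unlist(z), c(n_intake = 0, n_milk = 0, n_retained = 0,
                            n_excreted = 0))
  f1 <- n_flows(make_diet(c(pasture = 1000)), feeds, 500)
  feeds2 <- feeds
  feeds2$crude_protein <- feeds2$crude_protein * 2
  f2 <- n_flows(make_diet(c(pasture = 1000)), feeds2, 500)
  expect_equal(f2$n_intake, 2 * f1$n_intake)
  # independently coded closed form at reference-table magnitudes
  cp <- 0.10; dmi <- 3565; milk <- 1729; ret <- 0.02
  oracle <- dmi * cp / 6.25 * (1 - ret) - milk * 0.0033 * 10 / 6.38
  feeds3 <- feeds; feeds3$crude_protein[feeds3$name == "pasture"] <- cp
  got <- n_flows(make_diet(c(pasture = dmi)), feeds3, milk,
                 milk_protein_pct = 3.3, retention_frac = ret)
  expect_equal(got$n_excreted, oracle, tolerance = 1e-12)
  expect_error(n_flows(make_diet(c(pasture = 10)), feeds, 5000),
               "inconsistent")
})

test_that("N2O pathways match the direct-emission closed form", {
  factors <- load_emission_factors()
  z <- n2o_emissions(0, 0, factors)
  expect_true(all(unlist(z) == 0))
  f0 <- factors
  for (nm in c("ef1", "ef3_heap", "ef3_pasture", "ef4", "ef5"))
    f0[[nm]] <- list(min = 0, mean = 0, max = 0)
  expect_true(all(unlist(n2o_emissions(100, 50, f0)) == 0))
  # 100 kg N through a single 0.01 factor at GWP 298
  f1 <- factors
  f1$ef3_heap <- list(min = 0.01, mean = 0.01, max = 0.01)
  out <- n2o_emissions(100, 0, f1, system_split = c(pasture = 0, heap = 1))
  expect_equal(out$manure_direct, 100 * 0.01 * (44 / 28) * 298,
               tolerance = 1e-12)
  expect_equal(round(out$manure_direct, 1), 468.3)
})

test_that("Tier-2 kernels match independent oracles on random draws", {
  set.seed(42)
  for (i in 1:100) {
    ge <- runif(1, 0, 1e5); ym <- runif(1, 0.01, 0.12)
    expect_equal(enteric_ch4(ge, ym), ge * ym / 55.65,
                 tolerance = 1e-9)
    vs <- runif(1, 0, 3000); b0 <- runif(1, 0.1, 0.3)
    m1 <- runif(1, 0, 0.1); m2 <- runif(1, 0, 0.1); s <- runif(1)
    expect_equal(
      manure_ch4(vs, b0, c(a = m1, b = m2), c(a = s, b = 1 - s)),
      vs * b0 * 0.67 * (s * m1 + (1 - s) * m2), tolerance = 1e-9)
    dig <- runif(1, 0.4, 0.8)
    expect_equal(vs_excretion(ge, dig, ash = 0.08, urinary = 0.04),
                 (ge * (1 - dig) + 0.04 * ge) * 0.92 / 18.45,
                 tolerance = 1e-9)
  }
})

test_that("milk model is monotone and obeys the calibration fixture", {
  feeds <- load_feed_table()
  cow <- cow_params()
  # maintenance-only diet yields no milk, with a warning
  tiny <- make_diet(c(pasture = 400))
  expect_warning(m0 <- lifetime_milk(tiny, feeds, cow), "maintenance")
  expect_equal(m0, 0)
  # improving digestibility at fixed DMI never decreases milk
  d <- make_diet(c(pasture = 4000))
  base <- lifetime_milk(d, feeds, cow)
  feeds_hi <- feeds
  feeds_hi$dm_digestibility[feeds_hi$name == "pasture"] <- 0.70
  expect_gte(lifetime_milk(d, feeds_hi, cow), base)
  # calibration table overrides the surrogate exactly
  diets <- load_diet_table()
  dd <- get_diet(diets, "MRA", "FeCo", "Ya")
  expect_equal(lifetime_milk(dd, feeds, cow, calibration = diets), 2489)
})

test_that("emission intensity is a guarded scale-invariant ratio", {
  expect_equal(emission_intensity(100, 50), 2)
  expect_equal(emission_intensity(200, 100), 2)
  expect_error(emission_intensity(100, 0), "positive")
  # fixture consistency: back-computed emissions over fixture milk
  expect_equal(emission_intensity(2.38 * 2489, 2489), 2.38)
})

test_that("CH4-derived categories scale exactly with the CH4 GWP", {
  feeds <- load_feed_table()
  factors <- load_emission_factors()
  diets <- load_diet_table()
  d <- get_diet(diets, "MRT", "baseline")
  e1 <- cow_emissions(d, feeds, factors, milk = 1932)
  f2 <- factors; f2$gwp_ch4 <- factors$gwp_ch4 * 2
  e2 <- cow_emissions(d, feeds, f2, milk = 1932)
  expect_equal(e2[["enteric_ch4"]], 2 * e1[["enteric_ch4"]])
  expect_equal(e2[["manure_ch4"]], 2 * e1[["manure_ch4"]])
  expect_equal(e2[["soil_n2o_direct"]], e1[["soil_n2o_direct"]])
  # additivity: categories are non-negative and total is their sum
  expect_true(all(unclass(e1) >= 0))
  expect_equal(sum(e1), sum(unclass(e1)))
})

test_that("higher-digestibility forage cuts enteric CH4 per kg milk", {
  feeds <- load_feed_table()
  factors <- load_emission_factors()
  base <- make_diet(c(pasture = 4000))
  impr <- make_diet(c(napier = 4000))   # equal DMI/energy, better feed
  mb <- lifetime_milk(base, feeds)
  mi <- lifetime_milk(impr, feeds)
  eb <- enteric_ch4(gross_energy_intake(base, feeds), 0.065) / mb
  ei <- enteric_ch4(gross_energy_intake(impr, feeds), 0.065) / mi
  expect_lt(ei, eb)
})
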