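# Farm-forest statistics: neighbourhood zonal means, Spearman structure,
# rank tests and the compact letter display.

test_that("neighbourhood means recover uniform and hand-computed values", {
  v <- matrix(5, 6, 6)
  l <- grid_layer(v, cellsize = 1000)
  farms <- data.frame(farm_id = 1:2, x = c(3000, 500), y = c(3000, 500))
  st <- neighbourhood_stats(farms, list(loss = l), radius = 2500)
  expect_equal(st$loss, c(5, 5))

  # 3x3 toy, farm at the centre, radius covering the + neighbourhood
  v2 <- matrix(1:9, 3, 3)
  l2 <- grid_layer(v2, cellsize = 1000)
  farm <- data.frame(farm_id = 1, x = 1500, y = 1500)
  st2 <- neighbourhood_stats(farm, list(loss = l2), radius = 1100)
  # centre (5) + 4 rook neighbours (2, 4, 6, 8): mean 5
  expect_equal(st2$loss, mean(c(5, 2, 4, 6, 8)))
  expect_equal(st2$n_forest_pixels, 5)

  # farm with no valid pixel in reach is flagged
  v3 <- matrix(NA_real_, 3, 3)
  st3 <- neighbourhood_stats(farm, list(loss = grid_layer(v3,
                                                          cellsize = 1000)),
                             radius = 1100)
  expect_equal(st3$n_forest_pixels, 0)
  expect_true(is.na(st3$loss))
  expect_error(neighbourhood_stats(farm, list(loss = l2), radius = 0),
               "positive")
})

test_that("survey generation validates inputs and type structure", {
  cfg <- landscape_config(seed = 21)
  expect_error(generate_farm_survey(cfg, n_farms = 10), ">= 30")
  expect_error(generate_farm_survey(cfg, effect_sizes = c(n_cattle = 1.2)),
               "< 1")
  expect_error(generate_farm_survey(cfg, effect_sizes = c(bogus = 0.2)),
               "unknown indicator")
  s <- generate_farm_survey(cfg, n_farms = 216)
  expect_true(all(s$n_improved_cattle <= s$n_cattle))
  expect_true(all(s$area_fodder >= 0 & s$farm_size >= 0))
  expect_setequal(unique(s$farm_type), c("small", "large", "intensified"))
  agg <- tapply(s$milk_yield, s$farm_type, mean)
  expect_gt(agg[["intensified"]], max(agg[c("small", "large")]))
  fod <- tapply(s$fodder_fraction_diet, s$farm_type, mean)
  expect_gt(fod[["intensified"]], max(fod[c("small", "large")]))
})

test_that("null effect sizes yield near-zero correlations (Monte Carlo)", {
  hits <- 0L
  n_rep <- 200
  for (k in seq_len(n_rep)) {
    cfg <- landscape_config(seed = 1000 + k)
    s <- generate_farm_survey(cfg, n_farms = 216,
                              effect_sizes = c(n_cattle = 0))
    r <- suppressWarnings(stats::cor(s$n_cattle, s$c_loss_neigh,
                                     method = "spearman"))
    if (abs(r) < 0.15) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("target Spearman correlations are recovered within tolerance", {
  targets <- c(n_cattle = 0.15, n_improved_cattle = -0.37)
  recov <- sapply(1:20, function(k) {
    s <- generate_farm_survey(landscape_config(seed = 500 + k),
                              n_farms = 216, effect_sizes = targets)
    c(stats::cor(s$n_cattle, s$c_loss_neigh, method = "spearman"),
      stats::cor(s$n_improved_cattle, s$c_loss_neigh,
                 method = "spearman"))
  })
  expect_lt(abs(mean(recov[1, ]) - 0.15), 0.1)
  expect_lt(abs(mean(recov[2, ]) - (-0.37)), 0.1)
})

test_that("indicator correlations report rho, p, flags and degeneracies", {
  cfg <- landscape_config(seed = 33)
  s <- generate_farm_survey(cfg, n_farms = 216)
  st <- data.frame(farm_id = s$farm_id, n_forest_pixels = 1,
                   c_loss_cattle = s$c_loss_neigh)
  out <- indicator_correlations(s, st, indicators = c("n_cattle",
                                                      "milk_yield"))
  expect_equal(nrow(out$correlations), 2)
  expect_true(all(c("rho", "p", "n") %in% names(out$correlations)))
  # indicator identical to the layer statistic: rho = 1
  s2 <- s; s2$milk_yield <- s2$c_loss_neigh
  out2 <- indicator_correlations(s2, st, indicators = "milk_yield")
  expect_equal(out2$correlations$rho, 1)
  # rho is invariant under strictly monotone transforms
  s3 <- s; s3$milk_yield <- exp(s3$milk_yield / 1000)
  r_raw <- indicator_correlations(s, st,
                                  indicators = "milk_yield")$correlations$rho
  r_tr <- indicator_correlations(s3, st,
                                 indicators = "milk_yield")$correlations$rho
  expect_equal(r_raw, r_tr)
  # constant column: undefined, reported as missing
  s4 <- s; s4$milk_yield <- 1
  out4 <- indicator_correlations(s4, st, indicators = "milk_yield")
  expect_true(is.na(out4$correlations$rho))
  # collinearity flagging
  s5 <- s; s5$milk_yield <- s5$n_cattle * 2
  out5 <- indicator_correlations(s5, st,
                                 indicators = c("n_cattle", "milk_yield"))
  expect_equal(nrow(out5$collinear), 1)
})

test_that("pairwise Wilcoxon tests separate shifted groups", {
  set.seed(99)
  # identical distributions: high adjusted p, one letter group
  base <- data.frame(
    farm_id = 1:60, farm_type = rep(c("small", "large", "intensified"),
                                    each = 20))
  st <- data.frame(farm_id = 1:60, n_forest_pixels = 1,
                   loss = rnorm(60))
  out <- farm_type_tests(base, st)
  expect_true(all(out$loss$pairs$p_adj > 0.05))
  expect_equal(length(unique(out$loss$letters)), 1)

  # two types shifted by 3 pooled SDs: significant in >= 95% of runs
  sig <- replicate(40, {
    st2 <- data.frame(farm_id = 1:60, n_forest_pixels = 1,
                      loss = c(rnorm(20), rnorm(20), rnorm(20) + 3))
    o <- farm_type_tests(base, st2)
    p <- o$loss$pairs
    max(p$p_adj[p$type_a == "intensified" | p$type_b == "intensified"])
  })
  expect_gte(mean(sig < 0.01), 0.95)

  # three groups, one distinct: letters {a, a, b}
  st3 <- data.frame(farm_id = 1:60, n_forest_pixels = 1,
                    loss = c(rnorm(20), rnorm(20), rnorm(20) + 5))
  o3 <- farm_type_tests(base, st3)
  lt <- o3$loss$letters
  expect_equal(unname(lt[c("small", "large")]), c("a", "a"))
  expect_equal(unname(lt[["intensified"]]), "b")

  # small groups are excluded with a warning
  tiny <- base; tiny$farm_type[1:18] <- "small"
  tiny$farm_type[19:20] <- "rare"
  expect_warning(farm_type_tests(tiny, st), "rare")
})

test_that("survey couples to the landscape through real exposure values", {
  L <- small_landscape()
  att <- attribute_forest_loss(L)
  cfg <- L$config
  probe <- generate_farm_survey(cfg, n_farms = 216, landscape = L)
  st <- neighbourhood_stats(probe,
                            list(c_loss_cattle = att$c_loss_cattle),
                            radius = 5000)
  keep <- st$n_forest_pixels > 0
  expect_gte(sum(keep), 30)
  s <- generate_farm_survey(cfg, n_farms = sum(keep),
                            effect_sizes = c(n_improved_cattle = -0.37),
                            exposure = st$c_loss_cattle[keep])
  r <- stats::cor(s$n_improved_cattle, s$c_loss_neigh,
                  method = "spearman")
  expect_lt(r, 0)   # sign respected against real neighbourhood stats
  expect_equal(s$c_loss_neigh, st$c_loss_cattle[keep])
})
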