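test_that("generator honours size, determinism and dendritic constraints", {
  expect_error(generator_config(n_reaches = 0, seed = 1), "config error")
  expect_error(generator_config(n_reaches = 10), "seed is required")

  one <- generate_dendritic_network(generator_config(n_reaches = 1, seed = 1))
  expect_equal(nrow(one$reaches), 1L)
  expect_equal(nrow(one$edges), 0L)
  expect_equal(one$reaches$strahler_order, 1L)

  cfg <- generator_config(n_reaches = 120, seed = 9)
  a <- generate_dendritic_network(cfg)
  b <- generate_dendritic_network(cfg)
  expect_identical(a$reaches, b$reaches)
  expect_identical(a$edges, b$edges)

  dend <- generate_dendritic_network(
    generator_config(n_reaches = 150, divergence_rate = 0, split_rate = 0,
                     seed = 5))
  expect_true(all(table(dend$edges$from) <= 1))
  expect_equal(nrow(dend$reaches), 150L)
})

test_that("noise-free scaling laws are monotone along dendritic paths", {
  cfg <- generator_config(n_reaches = 150, divergence_rate = 0, split_rate = 0,
                          discharge_law = c(c = 0.01, b = 0.9, sd = 0),
                          seed = 11)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  q <- setNames(net$reaches$mean_annual_q, net$reaches$comid)
  s <- setNames(net$reaches$slope, net$reaches$comid)
  from <- as.character(net$edges$from); to <- as.character(net$edges$to)
  expect_true(all(q[to] > q[from]))       # discharge grows downstream
  expect_true(all(s[to] <= s[from]))      # slope never increases downstream
})

test_that("log-log regression over generated reaches recovers the discharge exponent", {
  cfg <- generator_config(n_reaches = 500,
                          discharge_law = c(c = 0.01, b = 0.9, sd = 0.1),
                          seed = 17)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  fit <- lm(log(mean_annual_q) ~ log(ws_area_km2), data = net$reaches)
  expect_lt(abs(coef(fit)[2] - 0.9), 0.05)
})

test_that("gage panels carry separable clusters and controlled missingness", {
  cfg <- generator_config(n_reaches = 400, seed = 23)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)

  p0 <- generate_gage_panel(net, n_sites = 100, k_clusters = 3,
                            separation = 6, missing_frac = 0, seed = 1)
  expect_false(anyNA(p0$sites[p0$feature_cols]))

  pm <- generate_gage_panel(net, n_sites = 100, k_clusters = 3,
                            separation = 6, missing_frac = 0.05, seed = 1)
  frac <- mean(is.na(as.matrix(pm$sites[pm$feature_cols])))
  expect_equal(frac, 0.05, tolerance = 0.01)

  expect_error(generate_gage_panel(net, n_sites = 10, k_clusters = 1, seed = 1),
               "config error")
  # pairwise centre distances equal the requested separation: Ward at the
  # true k recovers the labels almost perfectly
  p <- generate_gage_panel(net, n_sites = 300, k_clusters = 4,
                           separation = 6, seed = 2)
  w <- cluster_ward(as.matrix(p$sites[p$feature_cols]), 4)
  expect_gte(mclust::adjustedRandIndex(w$labels$k4, p$sites$true_label), 0.9)
  # separation 0 removes all label signal
  pz <- generate_gage_panel(net, n_sites = 300, k_clusters = 4,
                            separation = 0, seed = 2)
  wz <- cluster_ward(as.matrix(pz$sites[pz$feature_cols]), 4)
  expect_lt(abs(mclust::adjustedRandIndex(wz$labels$k4, pz$sites$true_label)),
            0.05)
})

test_that("temperature sites pass screening at the enumerated rate", {
  cfg <- generator_config(n_reaches = 300, seed = 29)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  n <- 6000
  p <- generate_temperature_sites(net, n_sites = n, noise_sd = 1, seed = 31)
  kept <- nrow(screen_reference_sites(p)$sites) / n
  p_exp <- expected_kept_fraction()
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(kept - p_exp), 4 * se)

  # forcing maximal disturbance empties the reference set
  p$sites$disturbance <- "very high"
  expect_equal(nrow(screen_reference_sites(p)$sites), 0L)
})

test_that("valley-input mixture components map to their confinement classes", {
  cfg <- generator_config(n_reaches = 400, seed = 37)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  vi <- generate_valley_inputs(net, seed = 41)
  expect_identical(generate_valley_inputs(net, seed = 41), vi)  # seeded
  cls <- classify_confinement(vi)
  dry <- vi$inundated_fraction < 1
  expect_true(all(cls[dry & vi$true_component == 1] == "unconfined"))
  expect_true(all(cls[dry & vi$true_component == 2] == "moderately confined"))
  expect_true(all(cls[dry & vi$true_component == 3] == "confined"))
  expect_setequal(unique(cls),
                  c("unconfined", "moderately confined", "confined",
                    "unclassified"))
})

test_that("synthetic DEM tiles reproduce closed-form valley widths", {
  # canyon walls above flood height: valley bottom is the channel itself
  can <- make_dem_tile("canyon", wall_height = 100, cell_size = 1)
  vb <- delineate_valley_bottom(can, flood_height = 5)
  expect_equal(vb$vb_width_m, 1)
  # V-valley: half-width h / s within one cell, at three resolutions
  h <- 5; s <- 0.5
  for (cs in c(1, 0.5, 0.25)) {
    dem <- make_dem_tile("vshape", nrow = round(60 / cs) + 1, ncol = 21,
                         cell_size = cs, side_slope = s)
    vb <- delineate_valley_bottom(dem, flood_height = h)
    half <- (vb$vb_width_m - cs) / 2
    expect_lt(abs(half - h / s), cs + 1e-9)
  }
})
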