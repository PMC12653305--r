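test_that("config validation rejects bad worlds", {
  expect_error(simulation_config(baseline_ndvi = 1.2))
  expect_error(simulation_config(cloud_fraction = 1.5))
  expect_error(simulation_config(
    disturbance_events = list(list(year = 1999, fraction = 0.4, drop = 0.3))),
    "year")
  expect_error(simulation_config(
    disturbance_events = list(list(year = 2022, fraction = 0.4, drop = -1))),
    "drop")
  expect_error(simulation_config(
    disturbance_events = list(list(year = 2022, fraction = 0.4, drop = 1.9))),
    "below -1")
  expect_error(simulation_config(
    disturbance_events = list(list(year = 2022, drop = 0.3,
                                   footprint = matrix(TRUE, 3, 3)))),
    "footprint")
})

test_that("identical seed gives bit-identical scenes, plots and climate", {
  cfg <- simulation_config(grid_rows = 12, grid_cols = 12, scenes_per_year = 3,
                           seed = 42)
  a <- simulate_forest(cfg)
  b <- simulate_forest(cfg)
  expect_identical(a$scenes, b$scenes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$plots, b$plots)
  expect_identical(a$climate, b$climate)
})

test_that("stream splitting isolates the climate from the scene draw", {
  cfg <- simulation_config(grid_rows = 8, grid_cols = 8, seed = 7)
  direct <- simulate_climate(cfg)
  set.seed(12345)  # perturb global RNG state
  invisible(simulate_scenes(cfg))
  expect_identical(simulate_climate(cfg), direct)
})

test_that("noise-free cloud-free scenes equal the true baseline field exactly", {
  cfg <- simulation_config(grid_rows = 10, grid_cols = 10, scenes_per_year = 2,
                           cloud_fraction = 0, noise_sd = 0,
                           disturbance_events = list(), seed = 3)
  sim <- simulate_scenes(cfg)
  for (y in names(sim$scenes)) for (s in sim$scenes[[y]]) {
    nd <- (s$nir - s$red) / (s$nir + s$red)
    expect_equal(nd, sim$truth$true_ndvi[, , y], tolerance = 1e-12)
    expect_equal(s$cloud_pct, 0)
    expect_true(all(s$qa_bits == 0L) && all(s$scene_class == 4L))
  }
})

test_that("reflectance pairs invert the index with the band sum fixed at 0.5", {
  cfg <- simulation_config(grid_rows = 6, grid_cols = 6, scenes_per_year = 2,
                           seed = 11)
  sim <- simulate_scenes(cfg)
  s <- sim$scenes[[1]][[1]]
  expect_equal(s$red + s$nir, matrix(0.5, 6, 6), tolerance = 1e-12)
})

test_that("an injected event depresses true NDVI by exactly its drop", {
  cfg <- simulation_config(
    grid_rows = 20, grid_cols = 20, noise_sd = 0,
    disturbance_events = list(list(year = 2022, fraction = 0.4, drop = 0.3)),
    seed = 5)
  sim <- simulate_scenes(cfg)
  fp <- sim$truth$footprints[["2022"]]
  expect_equal(sum(fp), round(0.4 * 400))
  base <- sim$truth$pixel_base
  eff <- sim$truth$year_effect[["2022"]]
  expect_equal(sim$truth$true_ndvi[, , "2022"][fp], (base + eff - 0.3)[fp],
               tolerance = 1e-12)
  expect_equal(mean(sim$truth$true_ndvi[, , "2022"][fp]),
               mean(base[fp]) + eff - 0.3, tolerance = 1e-12)
  # undisturbed years and pixels untouched
  expect_equal(sim$truth$true_ndvi[, , "2021"], base + sim$truth$year_effect[["2021"]],
               tolerance = 1e-12)
})

test_that("scene metadata cloud_pct equals the realized contaminated fraction", {
  cfg <- simulation_config(grid_rows = 16, grid_cols = 16, scenes_per_year = 4,
                           cloud_fraction = 0.3, seed = 9)
  sim <- simulate_scenes(cfg)
  for (s in sim$scenes[[1]]) {
    contaminated <- s$qa_bits != 0L | s$scene_class %in% c(3L, 8L, 9L)
    expect_equal(s$cloud_pct, 100 * mean(contaminated))
  }
})

test_that("realized cloudy fraction concentrates around cloud_fraction", {
  p <- 0.2
  cfg <- simulation_config(grid_rows = 96, grid_cols = 96, scenes_per_year = 6,
                           cloud_fraction = p, cloud_block = 4, seed = 21,
                           n_plots_level1 = 5, n_plots_level2 = 2)
  sim <- simulate_scenes(cfg)
  n_blocks <- (96 / 4)^2
  se <- sqrt(p * (1 - p) / n_blocks)
  fracs <- vapply(sim$scenes[[1]], function(s) s$cloud_pct / 100, 0)
  expect_true(all(abs(fracs - p) <= 3 * se))
})

test_that("plot defoliation follows the stated linear response", {
  cfg0 <- simulation_config(grid_rows = 10, grid_cols = 10, noise_sd = 0,
                            defoliation_gain = 0, defoliation_base = 5,
                            disturbance_events = list(), seed = 2)
  sim0 <- simulate_scenes(cfg0)
  rec0 <- simulate_plots(cfg0, sim0$truth)
  expect_true(all(rec0$defoliation_pct == 5))
  expect_true(all(rec0$defoliation_category == "None"))

  cfg1 <- simulation_config(
    grid_rows = 10, grid_cols = 10, noise_sd = 0,
    defoliation_gain = 100, defoliation_base = 5,
    disturbance_events = list(list(year = 2022, fraction = 1, drop = 0.3)),
    seed = 2)
  sim1 <- simulate_scenes(cfg1)
  rec1 <- simulate_plots(cfg1, sim1$truth)
  hit <- rec1$year == 2022
  expect_true(all(rec1$defoliation_pct[hit] == 35))        # 5 + 100 * 0.3
  expect_true(all(rec1$defoliation_category[hit] == "Medium"))
  expect_true(all(rec1$defoliation_pct[!hit] == 5))
})

test_that("the network has the configured tier sizes each year", {
  cfg <- simulation_config(grid_rows = 30, grid_cols = 30, seed = 4)
  sim <- simulate_scenes(cfg)
  rec <- simulate_plots(cfg, sim$truth)
  per_year <- table(rec$level, rec$year)
  expect_true(all(per_year["I", ] == 78))
  expect_true(all(per_year["II", ] == 7))
  expect_true(all(rec$row >= 1 & rec$row <= 30 & rec$col >= 1 & rec$col <= 30))
})

test_that("decoupled noise-free climate repeats the same climatology", {
  cfg <- simulation_config(drought_coupling = FALSE, climate_noise_sd = 0,
                           seed = 6)
  cl <- simulate_climate(cfg)
  byy <- split(cl[cl$site_id == cl$site_id[1], c("tmean_c", "precip_mm")],
               cl$year[cl$site_id == cl$site_id[1]])
  for (k in seq_along(byy)[-1]) expect_equal(byy[[k]], byy[[1]],
                                             ignore_attr = TRUE)
})

test_that("halving drought precipitation doubles TPF, noise-free", {
  cfg <- simulation_config(climate_noise_sd = 0, drought_temp_delta = 0,
                           drought_precip_factor = 0.5, seed = 8)
  tt <- tpf(simulate_climate(cfg), site = "L2-001")
  ctrl <- tt$tpf[tt$year == 2021]
  expect_equal(tt$tpf[tt$year == 2022], 2 * ctrl, tolerance = 1e-12)
})
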