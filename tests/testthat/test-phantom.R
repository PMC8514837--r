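# Synthetic phantom generation: construction, ground truth, determinism.

test_that("a noiseless single-layer slab is bone inside, air outside", {
  sp <- phantom_spec("slab", dim_mm = c(6, 6, 20),
                     layers = list(list(thickness = 10, hu = 1500)))
  ph <- generate_slab(sp)
  v <- ph$volume
  expect_equal(ph$truth$thickness, 10)
  zc <- (seq_len(dim(v)[3]) - 1) * v$spacing[3]
  in_slab <- zc > ph$truth$z_bottom & zc < ph$truth$z_top
  expect_true(all(v$data[, , in_slab] == 1500))
  expect_true(all(v$data[, , !in_slab] == -1000))
})

test_that("layer interfaces land on voxel boundaries, truth records them", {
  sp <- phantom_spec("layered_slab")
  ph <- generate_slab(sp)
  dz <- ph$volume$spacing[3]
  # interfaces at half-voxel offsets from the center grid
  expect_true(all(abs((ph$truth$interfaces / dz) %% 1 - 0.5) < 1e-9))
  expect_equal(ph$truth$layer_thickness, c(2, 6, 2))
  expect_equal(ph$truth$thickness, 10)
  # analytic profile reproduces the layer structure
  expect_equal(ph$truth$profile_fun(c(0.1, 1.9)), c(1500, 1500))
  expect_equal(ph$truth$profile_fun(c(2.1, 7.9)), c(300, 300))
  expect_equal(ph$truth$profile_fun(c(8.1, 9.9)), c(1500, 1500))
  expect_equal(ph$truth$profile_fun(10.5), -1000)
})

test_that("analytic layered-slab indices equal the brute-force oracles", {
  ph <- generate_slab(phantom_spec("layered_slab"))
  depths <- seq(0, 10, by = 0.15)
  samples <- ph$truth$profile_fun(depths)
  expect_equal(unname(ph$truth$sisi["sisi_4"]),
               oracle_sisi(samples, 0.15, 10, 4))
  expect_equal(unname(ph$truth$sisi["sisi_5"]),
               oracle_sisi(samples, 0.15, 10, 5))
  # 2 mm cortex: 14 dense samples of the 27 within 4 mm
  expect_equal(unname(ph$truth$sisi["sisi_4"]), 100 * 14 / 27)
  expect_equal(ph$truth$codi,
               oracle_codi(samples, 0.15, 10, 1.32), tolerance = 1e-12)
  expect_equal(ph$truth$cortical_hu, oracle_cortical(samples, 0.15))
})

test_that("air cells occupy the requested volume fraction of their layer", {
  sp <- phantom_spec("layered_slab", dim_mm = c(30, 30, 16),
                     layers = list(list(thickness = 2, hu = 1500),
                                   list(thickness = 8, hu = 300),
                                   list(thickness = 2, hu = 1500)),
                     air_cell_params = list(radius = 1, fraction = 0.3),
                     seed = 7)
  ph <- generate_slab(sp)
  v <- ph$volume
  zc <- (seq_len(dim(v)[3]) - 1) * v$spacing[3]
  inter <- ph$truth$interfaces
  trab <- zc < inter[2] & zc > inter[3]
  frac <- mean(v$data[, , trab] < 0)  # air cells at -800 HU in 300 HU bone
  expect_lt(abs(frac - 0.3), 0.05)
})

test_that("identical spec and seed give identical volumes", {
  sp <- phantom_spec("layered_slab", air_cell_params = list(fraction = 0.2),
                     noise_sd = 10, seed = 42)
  v1 <- generate_slab(sp)$volume$data
  v2 <- generate_slab(sp)$volume$data
  expect_identical(v1, v2)
  v3 <- generate_slab(phantom_spec("layered_slab",
                                   air_cell_params = list(fraction = 0.2),
                                   noise_sd = 10, seed = 43))$volume$data
  expect_false(identical(v1, v3))
})

test_that("oversized layers are rejected", {
  expect_error(generate_slab(phantom_spec("slab", dim_mm = c(5, 5, 8),
                                          layers = list(list(thickness = 10,
                                                             hu = 1500)))),
               "thicker than the volume")
  expect_error(phantom_spec("slab", layers = list(list(thickness = -1,
                                                       hu = 1500))),
               "positive")
  expect_error(phantom_spec("slab", air_cell_params = list(fraction = 1.2)),
               "fraction")
})

test_that("the calibration phantom recovers its generating line", {
  # noiseless: measured insert means are exact, so the fit is exact
  ph <- generate_calibration(phantom_spec("calibration"), slope = 1.32,
                             intercept = 0)
  expect_equal(nrow(ph$insert_table), 6)
  expect_equal(ph$insert_table$density_mg_ha_cm3,
               c(0, 100, 200, 400, 600, 800))
  m <- fit_calibration(ph$insert_table)
  expect_equal(m$slope, 1.32, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-9)

  # identity slope: insert means equal the densities
  ph1 <- generate_calibration(phantom_spec("calibration"), slope = 1,
                              intercept = 0)
  expect_equal(ph1$insert_table$mean_hu, ph1$insert_table$density_mg_ha_cm3,
               tolerance = 1e-12)
})

test_that("5 HU noise leaves the fitted slope within 0.01 of truth", {
  ph <- generate_calibration(phantom_spec("calibration", noise_sd = 5,
                                          seed = 9))
  expect_gt(min(ph$insert_table$n_voxels), 1e3)
  m <- fit_calibration(ph$insert_table)
  expect_lt(abs(m$slope - 1.32), 0.01)
})

test_that("the full pipeline recovers noiseless slab ground truth", {
  # thickness within half a voxel diagonal and cortical HU within 1% at
  # every interior grid point, through segment -> mesh -> probe
  sp <- phantom_spec("slab", dim_mm = c(14, 14, 18),
                     layers = list(list(thickness = 8, hu = 1400)))
  ph <- generate_slab(sp)
  lab <- remove_islands(label_bone(ph$volume), 300)
  mesh <- build_mesh(lab, smoothing_mm = 4)
  fr <- slab_frame(ph, grid_window = c(-3, 3, -3, 3))
  g <- make_grid(fr$frame, nx = 3, ny = 3, spacing = 3, corner = c(-3, -3))
  tab <- probe_table(ph$volume, mesh, g)
  expect_true(all(tab$status == "ok"))
  tol <- sqrt(sum(ph$volume$spacing^2)) / 2
  expect_true(all(abs(tab$d_tb_mm - ph$truth$d_tb) <= tol))
  expect_true(all(abs(tab$cortical_hu - 1400) / 1400 <= 0.01))
})
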