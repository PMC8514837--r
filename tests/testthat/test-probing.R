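# Probe projection, trajectory sampling, thickness and cortical density.

test_that("probes on a flat slab travel along the slab normal", {
  vol <- make_slab_volume(thickness = 6, hu = 1500, lateral = c(8, 8))
  mesh <- build_mesh(label_bone(vol), smoothing_mm = 0)
  fr <- downward_frame(origin = c(4, 4, 20))
  pr <- project_probe(c(0, 0), mesh, fr)
  expect_equal(pr$status, "ok")
  expect_lt(max(abs(pr$direction - (-fr$z_axis))), 1e-6)
  expect_lt(max(abs(pr$direction - c(0, 0, -1))), 1e-6)

  # beyond the mesh extent the probe misses
  miss <- project_probe(c(300, 0), mesh, fr)
  expect_equal(miss$status, "no_intersection")
})

test_that("a tilted surface yields the analytically rotated normal", {
  # analytic box rotated 30 degrees about y: project_probe must return the
  # rotated plane normal (inward) of the first face hit
  box <- box_mesh(c(-30, -30, -10), c(30, 30, 0))
  R <- rotation_about(c(0, 1, 0), 30 * pi / 180)
  tilted <- rotate_mesh(box, R)
  fr <- downward_frame(origin = c(0, 0, 40))
  pr <- project_probe(c(0, 0), tilted, fr)
  expect_equal(pr$status, "ok")
  expected <- as.numeric(R %*% c(0, 0, -1))  # inward normal of the top face
  expect_lt(max(abs(pr$direction - expected)), 1e-3)
})

test_that("sampling a uniform slab returns the slab value everywhere", {
  vol <- make_slab_volume(thickness = 10, hu = 1500, lateral = c(6, 6),
                          air_above = 4, air_below = 4)
  # sample downward from just below the top surface, inside the slab
  s <- sample_profile(vol, c(3, 3, 13), c(0, 0, -1), d_max = 8)
  expect_true(all(abs(s - 1500) < 1e-9))
})

test_that("an 18 mm trajectory at 0.15 mm spacing has 121 samples", {
  vol <- make_slab_volume(thickness = 20, hu = 1500, lateral = c(5, 5),
                          air_above = 2, air_below = 2)
  s <- sample_profile(vol, c(2.5, 2.5, 21), c(0, 0, -1),
                      delta_d = 0.15, d_max = 18)
  expect_length(s, floor(18 / 0.15) + 1)
  expect_length(s, 121)
})

test_that("sampling resolves a two-layer interface at its analytic depth", {
  # 1500 HU above z = 12, 300 HU below; fine 0.05 mm z spacing so samples
  # at 1.95 and 2.10 mm depth straddle the boundary cleanly
  nz <- 400
  zc <- (seq_len(nz) - 1L) * 0.05
  col <- ifelse(zc > 17.975, -1000, ifelse(zc > 12, 1500, 300))
  vol <- ct_volume(array(rep(col, each = 16), dim = c(4, 4, nz)),
                   spacing = c(1, 1, 0.05))
  entry <- c(2, 2, 14)  # boundary at depth 2 mm below the entry
  s <- sample_profile(vol, entry, c(0, 0, -1), delta_d = 0.15, d_max = 6)
  depths <- (seq_along(s) - 1) * 0.15
  expect_equal(s[depths == 1.95], 1500, tolerance = 1e-6)
  expect_equal(s[depths == 2.10], 300, tolerance = 1e-6)
})

test_that("sample depths increase strictly and never pass d_max", {
  vol <- make_slab_volume(thickness = 10, hu = 1500)
  set.seed(51)
  for (dm in c(1, 4.5, 9)) {
    s <- sample_profile(vol, c(6, 6, 12), c(0, 0, -1), delta_d = 0.15,
                        d_max = dm)
    expect_lte((length(s) - 1) * 0.15, dm + 1e-9)
    expect_length(s, floor(dm / 0.15) + 1)
  }
  expect_error(sample_profile(vol, c(6, 6, 100), c(0, 0, -1)), "outside")
})

test_that("slab thickness is recovered and capped at 18 mm", {
  for (t in c(2, 4, 6, 8, 10, 15)) {
    vol <- make_slab_volume(thickness = t, hu = 1500, lateral = c(8, 8))
    mesh <- build_mesh(label_bone(vol), smoothing_mm = 0)
    fr <- downward_frame(origin = c(4, 4, t + 10))
    pr <- project_probe(c(0, 0), mesh, fr)
    th <- thickness(mesh, pr$entry_point, pr$direction)
    expect_lt(abs(th$d_tb - t), sqrt(sum(c(0.2, 0.2, 0.2)^2)) / 2)
  }
  # 25 mm slab: clamped exactly to the cap
  vol <- make_slab_volume(thickness = 25, hu = 1500, lateral = c(8, 8))
  mesh <- build_mesh(label_bone(vol), smoothing_mm = 0)
  fr <- downward_frame(origin = c(4, 4, 35))
  pr <- project_probe(c(0, 0), mesh, fr)
  th <- thickness(mesh, pr$entry_point, pr$direction)
  expect_identical(th$d_tb, 18)
})

test_that("oblique trajectories see the path length, then the cap", {
  # analytic 10 mm slab; at 60 degrees incidence the path is 20 mm -> cap
  slab <- box_mesh(c(-40, -40, -10), c(40, 40, 0))
  entry <- c(0, 0, 0)
  dir60 <- c(sin(60 * pi / 180), 0, -cos(60 * pi / 180))
  th <- thickness(slab, entry, dir60)
  expect_identical(th$d_tb, 18)
  # at 45 degrees the path 10 / cos(45) fits under the cap
  dir45 <- c(sin(pi / 4), 0, -cos(pi / 4))
  expect_equal(thickness(slab, entry, dir45)$d_tb, 10 / cos(pi / 4),
               tolerance = 1e-9)
  # a ray exiting sideways meets the far wall beyond the cap: clamped
  th_side <- thickness(slab, c(0, 0, -5), c(1, 0, 0))
  expect_identical(th_side$d_tb, 18)
  expect_true(th_side$opposite_found)
  # an open surface with nothing behind it: capped with a warning
  open_face <- bone_mesh(rbind(c(-5, -5, 0), c(5, -5, 0), c(5, 5, 0),
                               c(-5, 5, 0)),
                         rbind(c(1, 3, 2), c(1, 4, 3)))
  expect_warning(th_open <- thickness(open_face, c(0, 0, 0), c(0, 0, -1)),
                 "no opposite")
  expect_identical(th_open$d_tb, 18)
  expect_false(th_open$opposite_found)
})

test_that("internal cavity walls do not shorten the thickness", {
  # outer slab plus an internal box: farthest hit within the cap wins
  outer <- box_mesh(c(-20, -20, -12), c(20, 20, 0))
  inner <- box_mesh(c(-5, -5, -8), c(5, 5, -3))
  merged <- bone_mesh(rbind(outer$vertices, inner$vertices),
                      rbind(outer$faces, inner$faces + 8L))
  th <- thickness(merged, c(0, 0, 0), c(0, 0, -1))
  expect_equal(th$d_tb, 12, tolerance = 1e-9)
})

test_that("cortical density follows the onset-plus-window rule", {
  expect_equal(cortical_density(rep(1200, 40), 0.15)$cortical_hu, 1200)
  prof <- c(500, 500, rep(1100, 60))
  got <- cortical_density(prof, 0.15)
  expect_equal(got$cortical_hu, 1100)
  expect_equal(got$onset_index, 3)

  # ramp crossing 1000: mean of the 11 samples in the 1.5 mm window
  ramp <- seq(400, 2000, by = 25)
  got <- cortical_density(ramp, 0.15)
  expect_equal(got$cortical_hu, oracle_cortical(ramp, 0.15))
  onset <- which(ramp >= 1000)[1]
  expect_equal(got$cortical_hu, mean(ramp[onset:(onset + 10)]))

  # no sample reaches the onset: no cortex
  expect_equal(cortical_density(rep(800, 50), 0.15)$status, "no_cortex")
  expect_true(is.na(cortical_density(rep(800, 50), 0.15)$cortical_hu))
})

test_that("cortical density equals the brute-force oracle on random profiles", {
  set.seed(52)
  for (q in 1:1000) {
    prof <- random_profile()
    got <- cortical_density(prof$samples, prof$delta_d)
    ref <- oracle_cortical(prof$samples, prof$delta_d)
    if (is.na(ref)) expect_equal(got$status, "no_cortex")
    else expect_identical(got$cortical_hu, ref)
  }
})

test_that("uniform-cortex phantoms recover density within 1 percent", {
  for (rho in c(1000, 1200, 1500)) {
    vol <- make_slab_volume(thickness = 8, hu = rho, lateral = c(8, 8))
    mesh <- build_mesh(label_bone(vol), smoothing_mm = 0)
    fr <- downward_frame(origin = c(4, 4, 16))
    prof <- probe_profile(c(0, 0), vol, mesh, fr)
    expect_lt(abs(prof$cortical_hu - rho) / rho, 0.01)
  }
})

test_that("probe profiles satisfy their structural invariants", {
  vol <- make_slab_volume(thickness = 10, hu = 1500, lateral = c(8, 8))
  mesh <- build_mesh(label_bone(vol), smoothing_mm = 0)
  fr <- downward_frame(origin = c(4, 4, 18))
  prof <- probe_profile(c(0, 0), vol, mesh, fr)
  expect_true(prof$d_tb >= 0 && prof$d_tb <= 18)
  expect_length(prof$samples, floor(min(prof$d_tb, 18) / prof$delta_d) + 1)
  expect_equal(sqrt(sum(prof$direction^2)), 1, tolerance = 1e-9)
})
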