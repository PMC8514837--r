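# Threshold labeling, island removal, isosurface meshing.

test_that("label_bone thresholds inclusively at the boundary", {
  vol <- make_slab_volume(thickness = 4, hu = 1500, lateral = c(4, 4))
  lab <- label_bone(vol)
  expect_identical(lab$mask, vol$data >= 620)
  expect_true(any(lab$mask))

  # a volume uniformly just below the threshold labels nothing
  v619 <- ct_volume(array(619, dim = c(5, 5, 5)), spacing = c(1, 1, 1))
  expect_false(any(label_bone(v619)$mask))
  expect_true(all(label_bone(ct_volume(array(620, dim = c(5, 5, 5)),
                                       spacing = c(1, 1, 1)))$mask))

  # internal air cells stay out of the mask
  vc <- make_slab_volume(thickness = 6, hu = 1500, lateral = c(6, 6))
  vc$data[15, 15, 25] <- -800
  labc <- label_bone(vc)
  expect_identical(labc$mask, vc$data >= 620)
  expect_false(labc$mask[15, 15, 25])
})

test_that("remove_islands keeps >=300-voxel components, drops smaller", {
  mk <- function(len) {
    m <- array(FALSE, dim = c(310, 3, 3))
    m[seq_len(len), 2, 2] <- TRUE
    lab <- structure(list(mask = m, threshold_hu = 620,
                          min_island_voxels = NA, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), axes = diag(3)),
                     class = "bone_label")
    lab
  }
  expect_false(any(remove_islands(mk(299), 300)$mask))
  expect_equal(sum(remove_islands(mk(300), 300)$mask), 300)
})

test_that("island removal matches a flood-fill oracle on slab plus specks", {
  set.seed(31)
  m <- array(FALSE, dim = c(30, 30, 20))
  m[, , 3:8] <- TRUE                        # large slab, 5400 voxels
  m[2:4, 2:4, 12:16] <- TRUE                # 45-voxel speck
  m[20:22, 20:22, 14:18] <- TRUE            # 45-voxel speck
  m[10:12, 25:27, 12:14] <- TRUE            # 27-voxel speck
  lab <- structure(list(mask = m, threshold_hu = 620,
                        min_island_voxels = NA, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), axes = diag(3)),
                   class = "bone_label")
  ref <- oracle_components(m)
  sizes <- tabulate(ref[ref > 0])
  expect_identical(sort(sizes), sort(c(5400L, 45L, 45L, 27L)))
  filt <- remove_islands(lab, 300)
  expect_identical(filt$mask, array(ref %in% which(sizes >= 300) & ref > 0,
                                    dim = dim(m)))
  expect_equal(sum(filt$mask), 5400)

  # component labeling itself agrees with the oracle
  got <- label_components(m)
  expect_equal(max(got), max(ref))
  relabel <- got
  for (l in seq_len(max(ref)))
    expect_length(unique(relabel[ref == l]), 1L)

  # idempotence and empty-mask identity
  expect_identical(remove_islands(filt, 300)$mask, filt$mask)
  empty <- lab; empty$mask[] <- FALSE
  expect_identical(remove_islands(empty, 300)$mask, empty$mask)

  # every retained component is large enough, by re-labeling
  lab2 <- label_components(filt$mask)
  if (max(lab2) > 0)
    expect_true(all(tabulate(lab2[lab2 > 0]) >= 300))
})

test_that("cuboid masks mesh to a matching bounding box with unit normals", {
  vol <- ct_volume(array(-1000, dim = c(20, 22, 24)), spacing = c(1, 1, 1))
  vol$data[5:15, 6:17, 7:19] <- 1500
  lab <- label_bone(vol)
  mesh <- build_mesh(lab, smoothing_mm = 0)
  bb <- rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
  # mask voxel-center extents (0-based): [4,14] x [5,16] x [6,18]
  expect_lt(max(abs(bb[1, ] - (c(4, 5, 6) - 0.5))), 1)
  expect_lt(max(abs(bb[2, ] - (c(14, 16, 18) + 0.5))), 1)
  expect_lt(max(abs(sqrt(rowSums(mesh$normals^2)) - 1)), 1e-9)
  # all vertices inside the volume's physical bounding box
  pb <- physical_bbox(vol)
  expect_true(all(mesh$vertices >= rep(pb[1, ] - 1e-9, each = nrow(mesh$vertices))))
  expect_true(all(mesh$vertices <= rep(pb[2, ] + 1e-9, each = nrow(mesh$vertices))))
})

test_that("slab meshes have two opposing faces and outward normals", {
  vol <- make_slab_volume(thickness = 6, hu = 1500, lateral = c(10, 10))
  mesh <- build_mesh(label_bone(vol), smoothing_mm = 0)
  z <- (mesh$vertices[mesh$faces[, 1], 3] + mesh$vertices[mesh$faces[, 2], 3] +
          mesh$vertices[mesh$faces[, 3], 3]) / 3
  zr <- range(mesh$vertices[, 3])
  top <- z > zr[2] - 1e-6
  bottom <- z < zr[1] + 1e-6
  mt <- colMeans(mesh$normals[top, , drop = FALSE])
  mb <- colMeans(mesh$normals[bottom, , drop = FALSE])
  expect_lt(sum(mt * mb) / sqrt(sum(mt^2) * sum(mb^2)), -0.99)
  expect_gt(mt[3], 0.99)   # outward: +z on the top face
  expect_lt(mb[3], -0.99)
})

test_that("zero smoothing is a no-op on the raw isosurface", {
  vol <- make_slab_volume(thickness = 4, hu = 1500, lateral = c(5, 5))
  lab <- label_bone(vol)
  raw <- extract_isosurface(lab)
  mesh <- build_mesh(lab, smoothing_mm = 0)
  expect_identical(mesh$vertices, raw$vertices)
  smoothed <- build_mesh(lab, smoothing_mm = 2)
  expect_gt(max(abs(smoothed$vertices - raw$vertices)), 0)
})

test_that("a smoothed sphere mask meshes to within 5% of its surface area", {
  spc <- 0.5
  r <- 10 * spc  # radius of 10 voxels
  d <- c(27, 27, 27)
  cc <- (d - 1) / 2
  ijk <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  mask <- array(colSums((t(ijk) - cc)^2) * spc^2 <= r^2, dim = d)
  vol <- ct_volume(array(ifelse(mask, 1500, -1000), dim = d),
                   spacing = rep(spc, 3))
  mesh <- build_mesh(label_bone(vol), smoothing_mm = 4)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * r^2) - 1), 0.05)
})

test_that("empty labels cannot be meshed", {
  vol <- ct_volume(array(-1000, dim = c(5, 5, 5)), spacing = c(1, 1, 1))
  expect_error(build_mesh(label_bone(vol)), "empty")
})

test_that("meshes export as PLY and STL, labels as NIfTI", {
  vol <- make_slab_volume(thickness = 3, hu = 1500, lateral = c(3, 3),
                          spacing = c(0.5, 0.5, 0.5))
  lab <- label_bone(vol)
  mesh <- build_mesh(lab, smoothing_mm = 0)
  ply <- tempfile(fileext = ".ply")
  stl <- tempfile(fileext = ".stl")
  write_mesh(mesh, ply)
  write_mesh(mesh, stl)
  expect_identical(readLines(ply, n = 1), "ply")
  expect_match(readLines(stl, n = 1), "^solid")
  expect_equal(length(grep("^facet", readLines(stl))), nrow(mesh$faces))
  nii <- tempfile(fileext = ".nii")
  write_label_nifti(lab, nii)
  back <- read_volume(nii)
  expect_identical(back$data > 0.5, lab$mask)
})
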