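test_that("NIfTI volumes round-trip through write/load", {
  # identity case: 10^3 zeros at 1 mm isotropic
  vol <- label_volume(array(0L, c(10, 10, 10)))
  p <- withr::local_tempfile(fileext = ".nii")
  write_volume(vol, p)
  back <- load_volume(p)
  expect_equal(back$spacing, c(1, 1, 1))
  expect_equal(back$data, vol$data, ignore_attr = TRUE)
  expect_equal(back$affine, vol$affine)

  # anisotropic header survives, spacing derived from affine column norms
  an <- label_volume(array(rep(c(0L, 3L), 32), c(4, 4, 4)),
                     spacing = c(1, 1, 2))
  pgz <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(an, pgz)
  back2 <- load_volume(pgz)
  expect_equal(back2$spacing, c(1, 1, 2))
  expect_equal(back2$data, an$data, ignore_attr = TRUE)
  expect_equal(back2$affine, an$affine)

  # non-integer data go through float64 unchanged
  fv <- label_volume(array(runif(27), c(3, 3, 3)))
  p3 <- withr::local_tempfile(fileext = ".nii")
  write_volume(fv, p3)
  expect_equal(load_volume(p3)$data, fv$data, ignore_attr = TRUE)

  expect_error(load_volume(file.path(tempdir(), "nope.nii")), "cannot read")
})

test_that("binarize thresholds one label and preserves metadata", {
  a <- array(0L, c(4, 4, 4))
  a[1, 1, 1] <- 5L; a[2, 2, 2] <- 7L; a[3, 3, 3] <- 5L
  vol <- label_volume(a, spacing = c(1, 1, 2))
  m5 <- binarize(vol, 5)
  expect_equal(sum(m5$data), 2)
  expect_equal(which(m5$data == 1), which(a == 5))
  expect_equal(m5$affine, vol$affine)
  expect_warning(m0 <- binarize(vol, 99), "not present")
  expect_equal(sum(m0$data), 0)
  # idempotence
  expect_equal(binarize(binarize(vol, 5), 1)$data, m5$data)
})

test_that("voxel/world conversions follow the affine and invert exactly", {
  vol <- label_volume(array(0L, c(10, 10, 10)))
  expect_equal(voxel_to_world(vol, c(3, 4, 5)), c(3, 4, 5))
  vol2 <- label_volume(array(0L, c(10, 10, 10)), spacing = c(2, 2, 2))
  expect_equal(voxel_to_world(vol2, c(1, 1, 1)), c(2, 2, 2))
  # a sheared affine still round-trips
  aff <- rbind(c(1, 0.3, 0, -5), c(0, 1.2, 0, 7), c(0, 0, 2, 1), c(0, 0, 0, 1))
  vol3 <- label_volume(array(0L, c(8, 8, 8)), affine = aff)
  ijk <- matrix(runif(30, 0, 7), ncol = 3)
  expect_equal(world_to_voxel(vol3, voxel_to_world(vol3, ijk)), ijk,
               tolerance = 1e-9)
})

test_that("mesh_summary counts the octahedron and its variants correctly", {
  oct <- octahedron()
  s <- mesh_summary(oct)
  expect_equal(s$n_vertices, 6)
  expect_equal(s$n_edges, 12)
  expect_equal(s$n_faces, 8)
  expect_equal(s$euler_characteristic, 2)
  expect_equal(s$n_components, 1)
  expect_true(s$is_closed)
  expect_gt(s$enclosed_volume, 0)  # outward orientation => positive volume
  expect_equal(s$enclosed_volume, 4 / 3)  # 8 tetrahedra of volume 1/6

  open <- tri_mesh(oct$vertices, oct$faces[-1, , drop = FALSE])
  expect_false(mesh_summary(open)$is_closed)

  two <- tri_mesh(rbind(oct$vertices, sweep(oct$vertices, 2, c(10, 0, 0), `+`)),
                  rbind(oct$faces, oct$faces + 6L))
  s2 <- mesh_summary(two)
  expect_equal(s2$n_components, 2)
  expect_equal(s2$euler_characteristic, 4)
})

test_that("tri_mesh validates faces and clean_mesh repairs degeneracies", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 1, 2))), "repeated")
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "out of range")
  # a zero-area (collinear) face and an unreferenced vertex get removed
  v2 <- rbind(v, c(2, 0, 0), c(5, 5, 5))
  f2 <- rbind(c(1, 2, 3), c(1, 2, 4))  # face 2 is collinear
  cm <- clean_mesh(tri_mesh(v2, f2))
  expect_equal(nrow(cm$faces), 1)
  expect_equal(nrow(cm$vertices), 3)
  expect_true(all(shapefilt:::.face_areas(cm) > 0))
})

test_that("mesh files round-trip in VTK, PLY (ascii/binary) and OFF", {
  m <- icosphere(7, subdiv = 1)
  for (ext in c("vtk", "off", "ply")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, p)
    back <- read_mesh(p)
    expect_equal(back$faces, m$faces, label = ext)
    expect_lt(max(abs(back$vertices - m$vertices)), 1e-6)
  }
  pb <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, pb, binary = TRUE)
  backb <- read_mesh(pb)
  expect_equal(backb$faces, m$faces)
  expect_lt(max(abs(backb$vertices - m$vertices)), 1e-5)  # float32 storage
})

test_that("marching-cubes volume tracks the voxel count of large masks", {
  # solid sphere with K >= 1000 foreground voxels: enclosed volume within
  # 30% of K mm^3 (the 0.5 iso-level adds about half a voxel outwards)
  for (r in c(7, 10)) {
    mask <- ellipsoid_mask(c(r, r, r), grid = rep(2L * r + 9L, 3))
    k <- sum(mask$data)
    expect_gt(k, 1000)
    vol <- mesh_summary(marching_cubes_extract(mask))$enclosed_volume
    expect_lt(abs(vol - k) / k, 0.3)
  }
})
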