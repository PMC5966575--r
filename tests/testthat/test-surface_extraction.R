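test_that("marching tetrahedra produce closed, correctly sized surfaces", {
  # a single foreground voxel
  b <- array(0L, c(7, 7, 7)); b[4, 4, 4] <- 1L
  s1 <- mesh_summary(marching_cubes_extract(label_volume(b)))
  expect_true(s1$is_closed)
  expect_equal(s1$euler_characteristic, 2)
  expect_equal(s1$n_components, 1)
  expect_gt(s1$enclosed_volume, 0)
  expect_lt(s1$enclosed_volume, 1)

  # solid 10-voxel cube: the 0.5 level sits half a voxel outside the
  # outermost foreground centers, giving ~986 mm^3 (independent
  # marching-cubes oracle); strictly between the center cube 9^3 and the
  # outer envelope 10^3
  sc <- mesh_summary(marching_cubes_extract(cube_mask(10, 16)))
  expect_true(sc$is_closed)
  expect_equal(sc$euler_characteristic, 2)
  expect_gt(sc$enclosed_volume, 729)
  expect_lt(sc$enclosed_volume, 1000)
  expect_lt(abs(sc$enclosed_volume - 986) / 986, 0.1)

  expect_error(marching_cubes_extract(label_volume(array(0L, c(5, 5, 5)))),
               "empty mask")
})

test_that("a solid torus keeps its genus (chi = 0)", {
  g <- expand.grid(i = 0:39, j = 0:39, k = 0:19)
  x <- g$i - 19.5; y <- g$j - 19.5; z <- g$k - 9.5
  inside <- (sqrt(x^2 + y^2) - 8)^2 + z^2 <= 9  # ring 8, tube 3
  tor <- label_volume(array(as.integer(inside), c(40, 40, 20)))
  st <- mesh_summary(marching_cubes_extract(tor))
  expect_true(st$is_closed)
  expect_equal(st$euler_characteristic, 0)
})

test_that("extraction is translation-equivariant and volume-monotone", {
  base <- ellipsoid_mask(c(8, 6, 5), grid = c(40L, 40L, 40L))
  m0 <- marching_cubes_extract(base)
  shift <- c(2L, 3L, 1L)
  a2 <- array(0L, dim(base$data))
  a2[(1 + shift[1]):40, (1 + shift[2]):40, (1 + shift[3]):40] <-
    base$data[1:(40 - shift[1]), 1:(40 - shift[2]), 1:(40 - shift[3])]
  m1 <- marching_cubes_extract(label_volume(a2, affine = base$affine))
  expect_equal(m1$vertices, sweep(m0$vertices, 2, shift * base$spacing, `+`),
               tolerance = 1e-12)

  # nested masks give monotone non-decreasing enclosed volumes
  vols <- vapply(c(5, 6.5, 8), function(r) {
    mesh_summary(marching_cubes_extract(
      ellipsoid_mask(c(r, r, r), grid = c(28L, 28L, 28L))))$enclosed_volume
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("keep_largest_component drops satellite surface components", {
  a <- array(0L, c(24, 24, 24))
  a[4:14, 4:14, 4:14] <- 1L     # big blob
  a[19:21, 19:21, 19:21] <- 1L  # small blob
  vol <- label_volume(a)
  kept <- marching_cubes_extract(vol, extraction_config())
  expect_equal(mesh_summary(kept)$n_components, 1)
  all_of_them <- marching_cubes_extract(
    vol, extraction_config(keep_largest_component = FALSE))
  expect_equal(mesh_summary(all_of_them)$n_components, 2)
})

test_that("the template route is accurate, well-shaped and smoother", {
  mask <- make_phantom(phantom_spec("ellipsoid"))  # radii 12, 8, 6 mm
  tpl <- default_template(mask)
  s <- mesh_summary(tpl)
  expect_true(s$is_closed)
  expect_equal(s$euler_characteristic, 2)
  expect_lt(abs(s$enclosed_volume - 4 / 3 * pi * 576) / (4 / 3 * pi * 576),
            0.05)

  # smoother than the marching-cubes surface at a matched vertex count
  mc <- marching_cubes_extract(mask)
  mc_matched <- remesh_isotropic(mc, 1.8)
  expect_lt(abs(nrow(mc_matched$vertices) - nrow(tpl$vertices)) /
              nrow(tpl$vertices), 0.25)
  expect_lt(gl_surface(tpl), gl_surface(mc_matched))
  expect_lt(gl_surface(tpl), gl_surface(mc))

  # sphere: bounded edge-length spread after remeshing
  sph <- ellipsoid_mask(c(10, 10, 10), grid = c(34L, 34L, 34L))
  tps <- default_template(sph, edge = 2)
  e <- shapefilt:::.mesh_edges(tps)
  len <- sqrt(rowSums((tps$vertices[e[, 1], ] - tps$vertices[e[, 2], ])^2))
  expect_lte(max(len) / min(len), 3)

  # multi-component input is an error on the template route
  a <- array(0L, c(24, 24, 24))
  a[4:10, 4:10, 4:10] <- 1L; a[16:21, 16:21, 16:21] <- 1L
  expect_error(delaunay_template_mesh(label_volume(a)), "single connected")
})

test_that("select_template picks the area-typical, smooth, closed candidate", {
  spheres <- lapply(c(5, 10, 15), icosphere, subdiv = 2)
  # mean area corresponds to radius sqrt((25+100+225)/3) ~ 10.8: pick r = 10
  expect_equal(select_template(spheres), 2)
  # identical candidates: first index by tie-break
  expect_equal(select_template(list(spheres[[1]], spheres[[1]])), 1)
  # non-closed candidates are excluded no matter their area
  open_big <- tri_mesh(spheres[[2]]$vertices,
                       spheres[[2]]$faces[-1, , drop = FALSE])
  expect_equal(select_template(list(open_big, spheres[[3]])), 2)
  expect_error(select_template(list(open_big, open_big)), "no valid template")
})
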