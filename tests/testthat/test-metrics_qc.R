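test_that("DSC matches brute-force voxel counting", {
  a <- array(0L, c(6, 6, 6)); a[2:3, 2:3, 2:3] <- 1L
  b <- array(0L, c(6, 6, 6)); b[3:4, 2:3, 2:3] <- 1L  # shifted 1 voxel in x
  A <- label_volume(a); B <- label_volume(b)
  expect_equal(dsc(A, A), 1)
  expect_equal(dsc(A, B), 2 * 4 / 16)  # overlap 4 of 8+8
  expect_equal(dsc(A, B), dsc(B, A))
  disj <- label_volume(array(0L, c(6, 6, 6)))
  disj$data[6, 6, 6] <- 1L
  expect_equal(dsc(A, disj), 0)
  expect_warning(expect_equal(
    dsc(label_volume(array(0L, c(3, 3, 3))),
        label_volume(array(0L, c(3, 3, 3)))), 1), "empty")
  expect_error(dsc(A, label_volume(array(0L, c(5, 5, 5)))), "same grid")
})

test_that("AVD is the volume difference over the mean volume", {
  mk <- function(n) {
    a <- array(0L, c(6, 6, 6)); a[seq_len(n)] <- 1L
    label_volume(a)
  }
  expect_equal(avd(mk(8), mk(8)), 0)
  expect_equal(avd(mk(8), mk(12)), 4 / 10)
  expect_equal(avd(mk(8), mk(12)), avd(mk(12), mk(8)))
  expect_equal(avd(mk(0), mk(5)), 2)  # the maximum of the range
  expect_warning(expect_equal(avd(mk(0), mk(0)), 0), "empty")
  # voxel volume cancels but must come from the same grid
  an <- label_volume(array(c(rep(1L, 8), rep(0L, 56)), c(4, 4, 4)),
                     spacing = c(1, 1, 2))
  bn <- label_volume(array(c(rep(1L, 12), rep(0L, 52)), c(4, 4, 4)),
                     spacing = c(1, 1, 2))
  expect_equal(avd(an, bn), 0.4)
})

test_that("PCC behaves like the product-moment correlation", {
  expect_equal(pcc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pcc(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(pcc(1:3, 1:4), "equal length")
  set.seed(10)
  x <- rnorm(50)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(50)
  expect_gt(pcc(x, y), 0.6)
  expect_lt(pcc(x, y), 0.95)
})

test_that("the Geometric Laplacian matches hand evaluations", {
  # vertex at the inverse-distance-weighted centroid of a regular hexagon
  hexv <- t(vapply(0:5, function(k)
    c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  m <- tri_mesh(rbind(c(0, 0, 0), hexv),
                cbind(1, 2:7, c(3:7, 2)))
  expect_equal(gl_vertex(m, 1), c(0, 0, 0), tolerance = 1e-12)

  # octahedron apex: four equidistant equatorial neighbors average to the
  # origin, so GL is the apex position itself
  oct <- octahedron(1)
  expect_equal(gl_vertex(oct, 5), c(0, 0, 1), tolerance = 1e-12)
  # each of the six symmetric vertices contributes norm 1
  expect_equal(gl_surface(oct), 6)

  # homogeneity under uniform scaling
  s <- 3.7
  expect_equal(gl_vertex(tri_mesh(oct$vertices * s, oct$faces), 5),
               s * gl_vertex(oct, 5))
  expect_equal(gl_surface(tri_mesh(oct$vertices * s, oct$faces)), 6 * s)

  # rigid-motion invariance
  sph <- icosphere(6, subdiv = 2)
  R <- rotation_z(33)
  moved <- tri_mesh(sweep(sph$vertices %*% t(R), 2, c(4, -7, 2), `+`),
                    sph$faces)
  expect_equal(gl_surface(moved), gl_surface(sph), tolerance = 1e-9)

  # roughness ordering: jittered sphere vs smooth sphere, equal vertices
  set.seed(2)
  noisy <- tri_mesh(sph$vertices +
                      matrix(rnorm(length(sph$vertices), sd = 0.15), ncol = 3),
                    sph$faces)
  expect_gt(gl_surface(noisy), gl_surface(sph))

  # degenerate edges are a hard error
  v <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  bad <- tri_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_error(gl_surface(bad), "degenerate")
})

test_that("IQR outlier analysis follows the stated quantile convention", {
  x <- c(1, 2, 3, 4, 100)
  # linear interpolation of order statistics: Q1 = 2, Q3 = 4
  rep1 <- outlier_analysis(x, rule = "as_printed")
  expect_equal(rep1$q1, 2)
  expect_equal(rep1$q3, 4)
  expect_equal(c(rep1$lower, rep1$upper), c(-1, 5))
  expect_equal(rep1$outlier_indices, 5L)
  rep2 <- outlier_analysis(x, rule = "tukey")
  expect_equal(c(rep2$lower, rep2$upper), c(-1, 7))
  expect_equal(rep2$outlier_indices, 5L)
  # constant samples flag nothing under either rule
  expect_length(outlier_analysis(rep(4, 6))$outlier_indices, 0)
  expect_length(outlier_analysis(rep(4, 6), "tukey")$outlier_indices, 0)
  expect_error(outlier_analysis(c(1, 2, 3)), "at least 4")
})

test_that("the Welch t-test matches the textbook formula", {
  x <- c(1, 2, 3)
  expect_equal(two_sample_t(x, x), list(t = 0, p = 1))
  expect_equal(two_sample_t(c(2, 2), c(2, 2)), list(t = 0, p = 1))

  set.seed(11)
  a <- rnorm(50, 0); b <- rnorm(50, 5)
  expect_lt(two_sample_t(a, b)$p, 1e-10)

  # hand-worked 3 + 3 case against the Welch formula written from scratch
  u <- c(1.1, 2.3, 2.9); v <- c(3.4, 4.1, 5.2)
  res <- two_sample_t(u, v)
  se2 <- var(u) / 3 + var(v) / 3
  tman <- (mean(u) - mean(v)) / sqrt(se2)
  df <- se2^2 / ((var(u) / 3)^2 / 2 + (var(v) / 3)^2 / 2)
  pman <- 2 * pt(-abs(tman), df)
  expect_equal(res$t, tman, tolerance = 1e-9)
  expect_equal(res$p, pman, tolerance = 1e-9)
})

test_that("CAP scores and subgroup thresholds are as defined", {
  r <- cap_score(40, 42)
  expect_equal(r$cap, 40 * 8.34)
  expect_equal(r$group, "mid-HD")
  expect_equal(cap_score(50, 33.66)$cap, 0)
  expect_equal(cap_score(50, 33.66)$group, "low-HD")
  # both subgroup boundaries are inclusive to mid-HD
  expect_equal(cap_score(290 / (42 - 33.66), 42)$group, "mid-HD")
  expect_equal(cap_score(368 / (42 - 33.66), 42)$group, "mid-HD")
  expect_equal(cap_score(80, 42)$group, "high-HD")  # CAP 667.2
  expect_equal(cap_score(20, 42)$group, "low-HD")   # CAP 166.8
})
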