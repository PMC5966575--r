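test_that("soft assignment matches the Gaussian formula and its limits", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  # vanishing temperature: identity permutation on well-separated points
  sa <- soft_assignment(pts, pts, temperature = 1e-3)
  expect_equal(sa$assignment, diag(3), tolerance = 1e-12)
  expect_equal(sa$score, 0, tolerance = 1e-12)
  # infinite-temperature limit: uniform rows
  sa2 <- soft_assignment(pts, pts, temperature = 1e9)
  expect_equal(sa2$assignment, matrix(1 / 3, 3, 3), tolerance = 1e-6)
  expect_equal(rowSums(sa2$assignment), rep(1, 3), tolerance = 1e-9)

  # direct evaluation of the formula on hand-set coordinates
  src <- rbind(c(0, 0, 0), c(1, 2, 3), c(5, 5, 5))
  dst <- rbind(c(1, 0, 0), c(0, 2, 2), c(4, 4, 6))
  temp <- 7.5
  sa3 <- soft_assignment(src, dst, temp)
  d2 <- outer(seq_len(3), seq_len(3),
              Vectorize(function(i, j) sum((src[i, ] - dst[j, ])^2)))
  w <- exp(-d2 / temp)
  expect_equal(sa3$assignment, w / rowSums(w), tolerance = 1e-12)
  expect_equal(sa3$score, sum(sa3$assignment * d2), tolerance = 1e-12)
})

test_that("weighted Procrustes recovers exact transforms and rejects
           degenerate geometry", {
  set.seed(3)
  src <- matrix(rnorm(30, sd = 5), ncol = 3)
  R <- rotation_z(20)
  t <- c(3, -2, 5)
  dst <- sweep(src %*% t(R), 2, t, `+`)
  tr <- weighted_procrustes(src, dst, diag(nrow(src)))
  expect_lt(max(abs(tr$rotation - R)), 1e-9)
  expect_lt(max(abs(tr$translation - t)), 1e-9)

  id <- weighted_procrustes(src, src, diag(nrow(src)))
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)

  line <- cbind(1:6, 2 * (1:6), -1 * (1:6))
  expect_error(weighted_procrustes(line, line, diag(6)), "degenerate")
})

test_that("rigid_align recovers known motions of a surface", {
  tpl <- icosphere(8, subdiv = 2)
  tpl <- tri_mesh(tpl$vertices %*% diag(c(1, 0.8, 0.6)), tpl$faces)

  # identity case
  tr0 <- rigid_align(tpl, tpl)
  expect_lt(max(abs(tr0$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tr0$translation)), 1e-6)

  # noiseless 25-degree rotation + shift: vertex RMS below 0.1 mm
  R <- rotation_z(25)
  tgt <- tri_mesh(sweep(tpl$vertices %*% t(R), 2, c(3, -2, 5), `+`), tpl$faces)
  tr <- rigid_align(tpl, tgt)
  moved <- apply_rigid(tpl$vertices, tr)
  expect_lt(sqrt(mean(rowSums((moved - tgt$vertices)^2))), 0.1)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
  # accepted scores are non-increasing
  expect_true(all(diff(attr(tr, "score_trace")) <= 1e-9))

  # 0.5 mm iid vertex jitter on a known 15-degree rotation: angle error < 2
  set.seed(99)
  R15 <- rotation_z(15)
  tgt2 <- tri_mesh(sweep(tpl$vertices %*% t(R15), 2, c(1, 2, -1), `+`) +
                     matrix(rnorm(length(tpl$vertices), sd = 0.5), ncol = 3),
                   tpl$faces)
  tr2 <- rigid_align(tpl, tgt2)
  err <- rotation_angle_deg(t(R15) %*% tr2$rotation)
  expect_lt(err, 2)
})

test_that("rigid_align is equivariant under a pre-applied rigid motion", {
  tpl <- icosphere(8, subdiv = 2)
  tpl <- tri_mesh(tpl$vertices %*% diag(c(1, 0.75, 0.55)), tpl$faces)
  R <- rotation_z(25)
  tgt <- tri_mesh(sweep(tpl$vertices %*% t(R), 2, c(4, 0, -3), `+`), tpl$faces)
  set.seed(4)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- 0.4
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  g <- rigid_transform(diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K,
                       c(2, -1, 3))
  pre <- apply_rigid(tpl, g)
  tr_direct <- rigid_align(tpl, tgt)
  tr_pre <- rigid_align(pre, tgt)
  # rigid_align(g(template), target) composed with g matches the direct fit
  recompose <- shapefilt:::.compose_rigid(g, tr_pre)
  a <- apply_rigid(tpl$vertices, recompose)
  b <- apply_rigid(tpl$vertices, tr_direct)
  expect_lt(sqrt(mean(rowSums((a - b)^2))), 0.1)
})
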