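test_that("current representation matches hand computations", {
  oct <- octahedron(3)
  cur <- to_current(oct)
  # closed surface: area-weighted normals sum to zero
  expect_lt(max(abs(colSums(cur$normals))),
            1e-12 * mesh_summary(oct)$total_area)

  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  ct <- to_current(tri)
  expect_equal(drop(ct$centers), c(1 / 3, 1 / 3, 0))
  expect_equal(drop(ct$normals), c(0, 0, 0.5))

  # homogeneity: scaling by s scales centers by s and normals by s^2
  s <- 2.5
  scaled <- to_current(tri_mesh(oct$vertices * s, oct$faces))
  expect_equal(scaled$centers, cur$centers * s)
  expect_equal(scaled$normals, cur$normals * s^2)
})

test_that("squared currents distance matches a brute-force double sum", {
  oct <- octahedron(3)
  expect_lt(abs(current_distance2(to_current(oct), to_current(oct), 2)), 1e-9)

  t1 <- to_current(tri_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                            rbind(1:3)))
  t2 <- to_current(tri_mesh(rbind(c(1, 1, 1), c(2, 1, 2), c(1, 3, 1)),
                            rbind(1:3)))
  sw <- 1.7
  ip <- function(A, B) {
    acc <- 0
    for (f in seq_len(nrow(A$centers)))
      for (g in seq_len(nrow(B$centers)))
        acc <- acc + exp(-sum((A$centers[f, ] - B$centers[g, ])^2) / sw^2) *
          sum(A$normals[f, ] * B$normals[g, ])
    acc
  }
  expect_equal(current_distance2(t1, t2, sw),
               ip(t1, t1) - 2 * ip(t1, t2) + ip(t2, t2), tolerance = 1e-12)

  # sigma_W -> infinity on closed meshes: both currents integrate to zero
  ico <- icosahedron(4)
  shifted <- tri_mesh(sweep(ico$vertices, 2, c(2, 1, -1), `+`), ico$faces)
  expect_lt(abs(current_distance2(to_current(ico), to_current(shifted), 1e6)),
            1e-6)
})

test_that("the particle flow obeys its closed-form special cases", {
  kern <- kernel_params(2, 1, 0.1)
  # zero momenta: identity
  p0 <- deformation_path(array(0, c(5, 4, 3)),
                         matrix(rnorm(12), ncol = 3), kern)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(flow_points(pts, p0), pts)

  # one control point with constant momentum (1,0,0): the point rides the
  # kernel center (k = 1 at zero distance), moving 1 mm in x
  T <- 20
  mom <- array(0, c(T, 1, 3)); mom[, 1, 1] <- 1
  p1 <- deformation_path(mom, matrix(c(0, 0, 0), 1), kern)
  out <- flow_points(matrix(c(0, 0, 0), 1), p1)
  expect_equal(drop(out), c(1, 0, 0), tolerance = 1e-9)

  # far-field query barely moves
  far <- flow_points(matrix(c(50, 0, 0), 1), p1)
  expect_lt(abs(far[1] - 50), 1e-9)
  expect_equal(far[2:3], c(0, 0))
})

test_that("lddmm_energy matches an independent re-implementation", {
  kern <- kernel_params(3, 2, 0.2)
  tpl <- icosahedron(5)
  tgt <- tri_mesh(tpl$vertices * 1.2, tpl$faces)
  Tn <- 4
  n <- nrow(tpl$vertices)

  # zero momenta, template = target: both terms vanish
  z <- deformation_path(array(0, c(Tn, n, 3)), tpl$vertices, kern)
  e0 <- lddmm_energy(z, tpl, to_current(tpl))
  expect_equal(e0$reg, 0)
  expect_lt(abs(e0$data), 1e-9)

  # zero momenta, different target: data equals the plain currents distance
  e1 <- lddmm_energy(z, tpl, to_current(tgt))
  expect_equal(e1$data,
               current_distance2(to_current(tpl), to_current(tgt),
                                 kern$sigma_W), tolerance = 1e-9)

  # random small path vs a from-scratch R evaluation of both sums
  set.seed(5)
  mom <- array(rnorm(Tn * n * 3, sd = 0.2), c(Tn, n, 3))
  path <- deformation_path(mom, tpl$vertices, kern)
  e <- lddmm_energy(path, tpl, to_current(tgt))
  h <- 1 / Tn
  q <- tpl$vertices
  reg <- 0
  for (t in seq_len(Tn)) {
    a <- matrix(mom[t, , ], ncol = 3)
    K <- exp(-as.matrix(stats::dist(q))^2 / kern$sigma_V^2)
    diag(K) <- 1
    reg <- reg + h * sum(K * (a %*% t(a)))
    q <- q + h * K %*% a
  }
  expect_equal(e$reg, reg, tolerance = 1e-9)
  expect_equal(e$data,
               current_distance2(to_current(tri_mesh(q, tpl$faces)),
                                 to_current(tgt), kern$sigma_W),
               tolerance = 1e-9)
  expect_equal(e$total, kern$gamma * e$reg + e$data, tolerance = 1e-12)
})

test_that("the analytic momentum gradient agrees with finite differences", {
  kern <- kernel_params(4, 3, 0.1)
  tpl <- icosahedron(5)
  tgt_cur <- to_current(tri_mesh(tpl$vertices %*% diag(c(1.3, 1, 0.8)),
                                 tpl$faces))
  tt <- shapefilt:::.cur_ip_grad(tgt_cur$centers, tgt_cur$normals,
                                 tgt_cur$centers, tgt_cur$normals,
                                 kern$sigma_W, FALSE)$ip
  ttc <- structure(tt, target = tgt_cur)
  Tn <- 3
  set.seed(7)
  mom <- array(rnorm(Tn * 12 * 3, sd = 0.3), c(Tn, 12, 3))
  eg <- shapefilt:::.lddmm_energy_grad(mom, tpl$faces, tpl$vertices, kern, ttc)
  h <- 1e-5
  idx <- sample(length(mom), 25)
  fd <- vapply(idx, function(i) {
    mp <- mom; mp[i] <- mp[i] + h
    mm <- mom; mm[i] <- mm[i] - h
    (shapefilt:::.lddmm_energy_grad(mp, tpl$faces, tpl$vertices, kern, ttc)$total -
     shapefilt:::.lddmm_energy_grad(mm, tpl$faces, tpl$vertices, kern, ttc)$total) /
      (2 * h)
  }, numeric(1))
  rel <- abs(fd - eg$grad[idx]) / pmax(abs(fd), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("lddmm_match is a fixed point at the target and preserves
           topology", {
  tpl <- icosphere(8, subdiv = 2)
  fit0 <- lddmm_match(tpl, tpl, kernel_params(4, 3, 0.1), timesteps = 5)
  expect_lt(max(abs(fit0$path$momenta)), 1e-3)
  expect_lt(max(abs(fit0$deformed$vertices - tpl$vertices)), 1e-3)

  # sphere -> flattened sphere: face list identical, chi preserved, energy
  # trace non-increasing, no orientation flips
  tgt <- tri_mesh(tpl$vertices %*% diag(c(1.15, 1, 0.85)), tpl$faces)
  fit <- lddmm_match(tpl, tgt, kernel_params(4, 3, 0.1), timesteps = 5,
                     opt = lddmm_control(max_iter = 40, rel_tol = 1e-6))
  expect_identical(fit$deformed$faces, tpl$faces)
  expect_equal(mesh_summary(fit$deformed)$euler_characteristic, 2)
  expect_true(all(diff(fit$energy_trace) <= 1e-9))
  n0 <- shapefilt:::.face_normal_vectors(tpl)
  n1 <- shapefilt:::.face_normal_vectors(fit$deformed)
  expect_true(all(rowSums(n0 * n1) > 0))
  expect_true(all(shapefilt:::.face_areas(fit$deformed) > 0))
  expect_lt(fit$energy$data,
            current_distance2(to_current(tpl), to_current(tgt), 3))
})
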