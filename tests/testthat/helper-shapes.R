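# Fixture meshes and masks built in code.

# regular octahedron with apexes on the axes at distance r, CCW outward
octahedron <- function(r = 1) {
  v <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
             c(0, 0, r), c(0, 0, -r))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  tri_mesh(v, f)
}

# regular icosahedron scaled to circumradius r
icosahedron <- function(r = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  tri_mesh(v / sqrt(1 + t^2) * r, f)
}

# icosphere: subdivided icosahedron projected to radius r (smooth sphere mesh)
icosphere <- function(r = 1, subdiv = 2) {
  m <- icosahedron(r)
  for (s in seq_len(subdiv)) {
    v <- m$vertices; f <- m$faces
    n <- nrow(v)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ek <- key(e[, 1], e[, 2])
    uk <- !duplicated(ek)
    mids <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    mid_id <- stats::setNames(seq_len(sum(uk)) + n, ek[uk])
    newf <- lapply(seq_len(nrow(f)), function(i) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- mid_id[[key(a, b)]]; bc <- mid_id[[key(b, c)]]
      ca <- mid_id[[key(c, a)]]
      rbind(c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    })
    v <- rbind(v, mids)
    v <- v / sqrt(rowSums(v^2)) * r
    m <- tri_mesh(v, do.call(rbind, newf))
  }
  m
}

# binary ellipsoid mask, grid centered
ellipsoid_mask <- function(radii, grid = c(48L, 48L, 48L), spacing = c(1, 1, 1)) {
  make_phantom(phantom_spec("ellipsoid", list(radii = radii),
                            grid_shape = grid, spacing = spacing))
}

# cube mask of side `s` voxels inside an n^3 grid
cube_mask <- function(s = 10, n = 16) {
  a <- array(0L, c(n, n, n))
  lo <- (n - s) %/% 2 + 1
  a[lo:(lo + s - 1), lo:(lo + s - 1), lo:(lo + s - 1)] <- 1L
  label_volume(a)
}

# the default smooth ellipsoid template used across pipeline tests
default_template <- function(mask = make_phantom(phantom_spec("ellipsoid")),
                             edge = 1.8) {
  delaunay_template_mesh(mask, extraction_config(gaussian_sigma_mm = 1.5,
                                                 target_edge_length_mm = edge,
                                                 keep_largest_component = FALSE))
}

# fast optimizer settings for pipeline tests (scaled-down iteration budget)
fast_cfg <- function(...) {
  pipeline_config(opt = lddmm_control(max_iter = 50L, rel_tol = 1e-5),
                  max_target_faces = 2000L, ...)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

rotation_angle_deg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}
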