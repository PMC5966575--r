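#' Triangle mesh in world millimetres
#'
#' Vertices are an N x 3 real matrix (mm); faces are an M x 3 matrix of
#' 1-based vertex indices, counter-clockwise when viewed from outside.
#' No per-vertex attributes are stored: normals and areas are recomputed on
#' demand, since deformation invalidates any cache.
#'
#' @param vertices N x 3 numeric matrix, world mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices; no face may
#'   repeat a vertex.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be N x 3")
  if (ncol(faces) != 3L) stop("`faces` must be M x 3")
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("faces with repeated vertices are not allowed")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

# undirected unique edges as an E x 2 matrix (sorted pairs, 1-based)
.mesh_edges <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(matrix(integer(), 0, 2))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- (e[, 1] - 1) * as.double(nrow(mesh$vertices)) + e[, 2]
  e[!duplicated(key), , drop = FALSE]
}

# count of incident faces per undirected edge (names are edge keys)
.edge_face_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) - 1
  key <- key * as.double(nrow(mesh$vertices)) + pmax(e[, 1], e[, 2])
  table(key)
}

# area-weighted face normals, M x 3 (norm = face area; outward for CCW faces)
.face_normal_vectors <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

.face_areas <- function(mesh) sqrt(rowSums(.face_normal_vectors(mesh)^2))

# signed volume by the divergence theorem (positive for outward orientation)
.signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Combinatorial and geometric summary of a mesh
#'
#' Edges are counted as undirected unique vertex pairs, so the Euler
#' characteristic V - E + F is well defined even for non-manifold debug
#' meshes.  A mesh is closed iff every edge is shared by exactly two faces.
#' The enclosed volume is the signed divergence-theorem sum, positive for
#' outward-oriented closed surfaces.
#'
#' @param mesh a [tri_mesh()].
#' @return A list of class `mesh_summary` with `n_vertices`, `n_edges`,
#'   `n_faces`, `euler_characteristic`, `n_components`, `is_closed`,
#'   `total_area` (mm^2) and `enclosed_volume` (mm^3).
#' @examples
#' oct <- tri_mesh(rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
#'                       c(0,0,1), c(0,0,-1)),
#'                 rbind(c(1,3,5), c(3,2,5), c(2,4,5), c(4,1,5),
#'                       c(3,1,6), c(2,3,6), c(4,2,6), c(1,4,6)))
#' mesh_summary(oct)$euler_characteristic  # 2
#' @export
mesh_summary <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  ne <- nrow(.mesh_edges(mesh))
  counts <- .edge_face_counts(mesh)
  closed <- nf > 0 && all(counts == 2)
  lab <- .vertex_components(nv, mesh$faces - 1L)
  structure(list(
    n_vertices = nv, n_edges = ne, n_faces = nf,
    euler_characteristic = nv - ne + nf,
    n_components = attr(lab, "n_components"),
    is_closed = closed,
    total_area = sum(.face_areas(mesh)),
    enclosed_volume = .signed_volume(mesh)
  ), class = "mesh_summary")
}

#' @export
print.mesh_summary <- function(x, ...) {
  cat("<mesh_summary> V=", x$n_vertices, " E=", x$n_edges, " F=", x$n_faces,
      " chi=", x$euler_characteristic, " components=", x$n_components,
      if (x$is_closed) " closed" else " open",
      "\n  area=", signif(x$total_area, 6), " mm^2, volume=",
      signif(x$enclosed_volume, 6), " mm^3\n", sep = "")
  invisible(x)
}

#' Remove degenerate faces and unreferenced vertices
#'
#' Drops faces with (numerically) zero area, merges exactly duplicated
#' vertices, and removes vertices referenced by no face.  After cleanup all
#' face areas are strictly positive.
#'
#' @param mesh a [tri_mesh()].
#' @param area_tol faces with area below this (mm^2) are removed.
#' @return A cleaned [tri_mesh()].
#' @export
clean_mesh <- function(mesh, area_tol = 1e-12) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  # merge exact duplicate vertices
  key <- paste(v[, 1], v[, 2], v[, 3])
  first <- match(key, key)
  if (any(first != seq_len(nrow(v)))) {
    f <- matrix(first[f], ncol = 3)
  }
  # drop degenerate faces
  if (nrow(f) > 0) {
    bad <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    f <- f[!bad, , drop = FALSE]
    if (nrow(f) > 0) {
      tmp <- tri_mesh(v, f)
      f <- f[.face_areas(tmp) > area_tol, , drop = FALSE]
    }
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  tri_mesh(v[used, , drop = FALSE], matrix(remap[f], ncol = 3))
}

# keep only the faces of the component with the most faces
.largest_component <- function(mesh) {
  lab <- .vertex_components(nrow(mesh$vertices), mesh$faces - 1L)
  if (attr(lab, "n_components") <= 1L) return(mesh)
  face_lab <- lab[mesh$faces[, 1]]
  best <- as.integer(names(which.max(table(face_lab))))
  clean_mesh(tri_mesh(mesh$vertices,
                      mesh$faces[face_lab == best, , drop = FALSE]))
}
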