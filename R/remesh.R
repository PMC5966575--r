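# Incremental isotropic remeshing (split / collapse / flip / tangential
# relax), the classic surface-mesh improvement loop.  Operates on closed
# triangle meshes; an optional `project` callback snaps relaxed vertices
# back onto an implicit surface so smoothing does not shrink the shape.

# adjacency list (neighbor ids per vertex) from an edge matrix
.adjacency <- function(edges, n) {
  fac <- factor(c(edges[, 1], edges[, 2]), levels = seq_len(n))
  split(c(edges[, 2], edges[, 1]), fac)
}

.edge_key <- function(e, n) (pmin(e[, 1], e[, 2]) - 1) * as.double(n) +
  pmax(e[, 1], e[, 2])

# split every edge longer than `thresh`; returns list(V, F)
.remesh_split <- function(V, F, thresh) {
  n <- nrow(V)
  E <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- .edge_key(E, n)
  ukey <- !duplicated(key)
  Eu <- E[ukey, , drop = FALSE]
  len <- sqrt(rowSums((V[Eu[, 1], , drop = FALSE] -
                       V[Eu[, 2], , drop = FALSE])^2))
  long <- len > thresh
  if (!any(long)) return(list(V = V, F = F))
  mids <- (V[Eu[long, 1], , drop = FALSE] + V[Eu[long, 2], , drop = FALSE]) / 2
  mid_id <- seq_len(sum(long)) + n
  lut <- new.env(hash = TRUE, parent = emptyenv())
  lk <- key[ukey][long]
  for (i in seq_along(lk)) assign(as.character(lk[i]), mid_id[i], envir = lut)
  getmid <- function(a, b) {
    k <- as.character((min(a, b) - 1) * n + max(a, b))
    if (exists(k, envir = lut, inherits = FALSE)) get(k, envir = lut) else NA_integer_
  }
  newF <- vector("list", nrow(F))
  for (f in seq_len(nrow(F))) {
    a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
    mab <- getmid(a, b); mbc <- getmid(b, c); mca <- getmid(c, a)
    ns <- sum(!is.na(c(mab, mbc, mca)))
    newF[[f]] <- if (ns == 0) {
      rbind(c(a, b, c))
    } else if (ns == 3) {
      rbind(c(a, mab, mca), c(b, mbc, mab), c(c, mca, mbc), c(mab, mbc, mca))
    } else if (ns == 1) {
      if (!is.na(mab)) rbind(c(a, mab, c), c(mab, b, c))
      else if (!is.na(mbc)) rbind(c(a, b, mbc), c(a, mbc, c))
      else rbind(c(a, b, mca), c(mca, b, c))
    } else { # two split edges
      if (is.na(mca)) rbind(c(a, mab, c), c(mab, b, mbc), c(mab, mbc, c))
      else if (is.na(mab)) rbind(c(a, b, mbc), c(a, mbc, mca), c(mca, mbc, c))
      else rbind(c(a, mab, mca), c(mab, b, c), c(mab, c, mca))
    }
  }
  list(V = rbind(V, mids), F = do.call(rbind, newF))
}

# collapse every edge shorter than `thresh` (greedy, link-condition guarded)
.remesh_collapse <- function(V, F, thresh) {
  n <- nrow(V)
  E <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- .edge_key(E, n)
  Eu <- E[!duplicated(key), , drop = FALSE]
  len <- sqrt(rowSums((V[Eu[, 1], , drop = FALSE] -
                       V[Eu[, 2], , drop = FALSE])^2))
  short <- which(len < thresh)
  if (length(short) == 0) return(list(V = V, F = F))
  short <- short[order(len[short])]
  adj <- .adjacency(Eu, n)
  touched <- logical(n)
  map <- seq_len(n)
  for (s in short) {
    a <- Eu[s, 1]; b <- Eu[s, 2]
    if (touched[a] || touched[b]) next
    common <- intersect(adj[[a]], adj[[b]])
    if (length(common) != 2) next  # collapsing would pinch the surface
    V[a, ] <- (V[a, ] + V[b, ]) / 2
    map[b] <- a
    touched[c(a, b, adj[[a]], adj[[b]])] <- TRUE
  }
  F <- matrix(map[F], ncol = 3)
  bad <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3]
  F <- F[!bad, , drop = FALSE]
  fkey <- paste(pmin(F[, 1], pmin(F[, 2], F[, 3])),
                F[, 1] + F[, 2] + F[, 3],
                pmax(F[, 1], pmax(F[, 2], F[, 3])))
  F <- F[!duplicated(fkey), , drop = FALSE]
  list(V = V, F = F)
}

# one pass of valence-equalizing edge flips on a closed manifold mesh
.remesh_flip <- function(V, F) {
  n <- nrow(V)
  E <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- .edge_key(E, n)
  face_of <- rep(seq_len(nrow(F)), 3)
  ord <- order(key)
  key_s <- key[ord]; face_s <- face_of[ord]
  grp_start <- which(!duplicated(key_s))
  deg <- tabulate(c(E[!duplicated(key), 1], E[!duplicated(key), 2]), n)
  ekeys <- new.env(hash = TRUE, parent = emptyenv())
  for (k in unique(key_s)) assign(as.character(k), TRUE, envir = ekeys)
  face_used <- logical(nrow(F))
  has_dir <- function(f, a, b) {
    x <- F[f, 1]; y <- F[f, 2]; z <- F[f, 3]
    (x == a && y == b) || (y == a && z == b) || (z == a && x == b)
  }
  for (gi in seq_along(grp_start)) {
    i0 <- grp_start[gi]
    i1 <- if (gi < length(grp_start)) grp_start[gi + 1] - 1 else length(key_s)
    if (i1 - i0 != 1) next  # not a 2-manifold edge
    f1 <- face_s[i0]; f2 <- face_s[i1]
    if (face_used[f1] || face_used[f2]) next
    k <- key_s[i0]
    a <- as.integer((k - 1) %/% n) + 1L
    b <- as.integer(k - (a - 1) * as.double(n))
    if (!has_dir(f1, a, b)) { tmp <- f1; f1 <- f2; f2 <- tmp }
    if (!has_dir(f1, a, b) || !has_dir(f2, b, a)) next
    cc <- setdiff(F[f1, ], c(a, b))
    dd <- setdiff(F[f2, ], c(a, b))
    if (length(cc) != 1 || length(dd) != 1 || cc == dd) next
    ck <- as.character((min(cc, dd) - 1) * n + max(cc, dd))
    if (exists(ck, envir = ekeys, inherits = FALSE)) next  # edge exists
    dv <- function(d) (d - 6)^2
    cur <- dv(deg[a]) + dv(deg[b]) + dv(deg[cc]) + dv(deg[dd])
    new <- dv(deg[a] - 1) + dv(deg[b] - 1) + dv(deg[cc] + 1) + dv(deg[dd] + 1)
    if (new >= cur) next
    F[f1, ] <- c(a, dd, cc)
    F[f2, ] <- c(b, cc, dd)
    deg[a] <- deg[a] - 1L; deg[b] <- deg[b] - 1L
    deg[cc] <- deg[cc] + 1L; deg[dd] <- deg[dd] + 1L
    assign(ck, TRUE, envir = ekeys)
    face_used[c(f1, f2)] <- TRUE
  }
  list(V = V, F = F)
}

# area-weighted vertex normals
.vertex_normals <- function(V, F) {
  fn <- {
    e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  }
  vn <- matrix(0, nrow(V), 3)
  for (a in 1:3) {
    acc <- rowsum(fn, F[, a])
    vn[as.integer(rownames(acc)), ] <- vn[as.integer(rownames(acc)), ] + acc
  }
  nn <- sqrt(rowSums(vn^2))
  vn / pmax(nn, 1e-12)
}

#' Isotropic incremental remeshing
#'
#' Alternates long-edge splits, short-edge collapses, valence-equalizing
#' flips and tangential Laplacian relaxation, the standard incremental
#' remeshing loop.  With a `project` callback the relaxed vertices are
#' snapped back onto an implicit surface each iteration.
#'
#' @param mesh a closed [tri_mesh()].
#' @param target_edge_length desired edge length, in the mesh's coordinate
#'   units.
#' @param iterations number of remeshing sweeps.
#' @param project optional function mapping an N x 3 matrix of points to
#'   their projections on the underlying surface; when `NULL`, relaxation
#'   is restricted to the local tangent plane.
#' @param lambda relaxation step in (0, 1].
#' @return The remeshed [tri_mesh()].
#' @export
remesh_isotropic <- function(mesh, target_edge_length, iterations = 6,
                             project = NULL, lambda = 0.6) {
  stopifnot(inherits(mesh, "tri_mesh"), target_edge_length > 0)
  V <- mesh$vertices
  F <- mesh$faces
  L <- target_edge_length
  for (it in seq_len(iterations)) {
    s <- .remesh_split(V, F, 4 / 3 * L);    V <- s$V; F <- s$F
    # the collapse pass only removes an independent edge set; iterate it
    # until the short edges are gone
    for (sub in 1:12) {
      nv0 <- nrow(V)
      s <- .remesh_collapse(V, F, 4 / 5 * L); V <- s$V; F <- s$F
      cm <- clean_mesh(tri_mesh(V, F));       V <- cm$vertices; F <- cm$faces
      if (nrow(V) == nv0) break
    }
    s <- .remesh_flip(V, F);                V <- s$V; F <- s$F
    # tangential relaxation
    E <- .mesh_edges(tri_mesh(V, F))
    adj <- .adjacency(E, nrow(V))
    deg <- pmax(lengths(adj), 1L)
    avg <- matrix(0, nrow(V), 3)
    acc1 <- rowsum(V[E[, 2], , drop = FALSE], E[, 1])
    avg[as.integer(rownames(acc1)), ] <- avg[as.integer(rownames(acc1)), ] + acc1
    acc2 <- rowsum(V[E[, 1], , drop = FALSE], E[, 2])
    avg[as.integer(rownames(acc2)), ] <- avg[as.integer(rownames(acc2)), ] + acc2
    avg <- avg / deg
    disp <- lambda * (avg - V)
    if (is.null(project)) {
      vn <- .vertex_normals(V, F)
      disp <- disp - vn * rowSums(disp * vn)
      V <- V + disp
    } else {
      V <- project(V + disp)
    }
  }
  clean_mesh(tri_mesh(V, F))
}
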