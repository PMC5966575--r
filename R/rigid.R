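#' Rigid (rotation + translation) transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (!identical(dim(rotation), c(3L, 3L)))
    stop("`rotation` must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("`rotation` is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("`rotation` must be a proper rotation (det = +1, no reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat("<rigid_transform> rotation ", signif(ang, 4), " deg, translation (",
      paste(signif(x$translation, 4), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x an N x 3 matrix of points or a [tri_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed points/mesh (`R x + t`).
#' @export
apply_rigid <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "tri_mesh")) {
    return(tri_mesh(apply_rigid(x$vertices, transform), x$faces))
  }
  sweep(x %*% t(transform$rotation), 2, transform$translation, `+`)
}

# composition: (g2 %then% g1)(x) = g1(g2(x))
.compose_rigid <- function(first, second) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Gaussian soft assignment between two point sets
#'
#' Row-stochastic correspondence weights
#' `assignment[i, j] = exp(-||src_i - dst_j||^2 / temperature)` normalized
#' over `j`, with the weighted-distance score
#' `sum_ij assignment[i, j] ||src_i - dst_j||^2`.
#'
#' @param src_pts P x 3 matrix (mm), P >= 3.
#' @param dst_pts Q x 3 matrix (mm), Q >= 3.
#' @param temperature positive annealing temperature, mm^2.
#' @return A list of class `soft_assign_state` with `assignment` (P x Q),
#'   `temperature` and `score`.
#' @export
soft_assignment <- function(src_pts, dst_pts, temperature) {
  src_pts <- as.matrix(src_pts); dst_pts <- as.matrix(dst_pts)
  stopifnot(nrow(src_pts) >= 3, nrow(dst_pts) >= 3, temperature > 0)
  d2 <- outer(rowSums(src_pts^2), rep(1, nrow(dst_pts))) +
    outer(rep(1, nrow(src_pts)), rowSums(dst_pts^2)) -
    2 * src_pts %*% t(dst_pts)
  d2 <- pmax(d2, 0)
  # subtract the row minimum before exponentiating (overflow-safe)
  logw <- -d2 / temperature
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  a <- w / rowSums(w)
  structure(list(assignment = a, temperature = temperature,
                 score = sum(a * d2)),
            class = "soft_assign_state")
}

#' Weighted Procrustes solve for the optimal rigid transform
#'
#' Closed-form minimizer of
#' `sum_ij assignment[i, j] ||R src_i + t - dst_j||^2` via the SVD of the
#' weighted cross-covariance, with the determinant correction that excludes
#' reflections.
#'
#' @param src_pts P x 3 matrix.
#' @param dst_pts Q x 3 matrix.
#' @param assignment P x Q row-stochastic weight matrix.
#' @return A [rigid_transform()].
#' @export
weighted_procrustes <- function(src_pts, dst_pts, assignment) {
  src_pts <- as.matrix(src_pts); dst_pts <- as.matrix(dst_pts)
  if (max(abs(rowSums(assignment) - 1)) > 1e-6)
    stop("`assignment` must be row-stochastic")
  # with unit row sums the problem reduces to matching src_i to the
  # per-row barycenters m_i = sum_j a_ij dst_j
  m <- assignment %*% dst_pts
  cs <- colMeans(src_pts)
  cm <- colMeans(m)
  H <- crossprod(sweep(src_pts, 2, cs), sweep(m, 2, cm))
  sv <- svd(H)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-12)
    stop("degenerate (rank < 2) cross-covariance; ",
         "cannot recover a unique alignment")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cm - as.numeric(R %*% cs))
}

#' Annealing schedule for rigid alignment
#'
#' @param t0 initial temperature (mm^2); `NULL` = mean squared
#'   nearest-neighbor distance after initialization.
#' @param cooling geometric cooling factor in (0, 1).
#' @param t_min final temperature (mm^2).
#' @param max_iter iteration cap.
#' @param max_points vertex subsample cap per mesh (uniform random, seeded).
#' @param seed subsampling seed.
#' @return A list of class `rigid_schedule`.
#' @export
rigid_schedule <- function(t0 = NULL, cooling = 0.93, t_min = 0.25,
                           max_iter = 200L, max_points = 2000L, seed = 1L) {
  stopifnot(cooling > 0, cooling < 1, t_min > 0)
  structure(list(t0 = t0, cooling = cooling, t_min = t_min,
                 max_iter = as.integer(max_iter),
                 max_points = as.integer(max_points),
                 seed = as.integer(seed)),
            class = "rigid_schedule")
}

.subsample_rows <- function(x, k, seed) {
  if (nrow(x) <= k) return(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x[sort(sample.int(nrow(x), k)), , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# mean squared nearest-neighbor distance from src to dst (block-wise)
.mean_sq_nn <- function(src, dst) {
  nn <- numeric(nrow(src))
  bs <- 512L
  for (i0 in seq(1, nrow(src), by = bs)) {
    i1 <- min(i0 + bs - 1, nrow(src))
    blk <- src[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rep(1, nrow(dst))) +
      outer(rep(1, i1 - i0 + 1), rowSums(dst^2)) - 2 * blk %*% t(dst)
    nn[i0:i1] <- pmax(apply(d2, 1, min), 0)
  }
  mean(nn)
}

#' Rigidly align a template surface to a target surface
#'
#' Correspondence-free rigid registration of the two vertex sets:
#' alternating Gaussian [soft_assignment()] and [weighted_procrustes()]
#' solves under a geometric annealing schedule, initialized by centroid
#' matching plus principal-axes alignment (axis signs disambiguated by the
#' soft-assign score).  Improving transforms only are accepted, so the
#' recorded score trace is non-increasing.  No scaling component is
#' estimated.
#'
#' @param template,target [tri_mesh()] objects (or N x 3 point matrices).
#' @param schedule a [rigid_schedule()].
#' @return A [rigid_transform()] taking the template into the target frame,
#'   with attributes `score_trace` and `converged`.
#' @export
rigid_align <- function(template, target, schedule = rigid_schedule()) {
  stopifnot(inherits(schedule, "rigid_schedule"))
  src <- if (inherits(template, "tri_mesh")) template$vertices else as.matrix(template)
  dst <- if (inherits(target, "tri_mesh")) target$vertices else as.matrix(target)
  if (nrow(src) < 3 || nrow(dst) < 3) stop("need at least 3 points per surface")
  src <- .subsample_rows(src, schedule$max_points, schedule$seed)
  dst <- .subsample_rows(dst, schedule$max_points, schedule$seed + 1L)

  # --- initialization: centroids + principal axes, signs by score ---------
  cs <- colMeans(src); cd <- colMeans(dst)
  es <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  ed <- eigen(stats::cov(dst), symmetric = TRUE)$vectors
  t0 <- schedule$t0
  cands <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    R <- ed %*% diag(c(s1, s2, s1 * s2 * sign(det(ed %*% t(es))))) %*% t(es)
    if (det(R) < 0) next
    cand <- rigid_transform(R, cd - as.numeric(R %*% cs))
    moved <- apply_rigid(src, cand)
    tt <- if (is.null(t0)) .mean_sq_nn(moved, dst) else t0
    sc <- soft_assignment(moved, dst, max(tt, schedule$t_min))$score
    cands[[length(cands) + 1]] <- list(transform = cand, score = sc,
                                       angle = sum(diag(R)))
  }
  # near-symmetric shapes make several axis-sign branches score-equivalent;
  # break those ties toward the smallest rotation (largest trace)
  scores <- vapply(cands, `[[`, numeric(1), "score")
  tol <- max(1e-9, 1e-3 * abs(min(scores)))
  tied <- which(scores <= min(scores) + tol)
  best <- cands[[tied[which.max(vapply(cands[tied], `[[`, numeric(1),
                                       "angle"))]]]
  transform <- best$transform
  temp <- if (is.null(t0)) {
    .mean_sq_nn(apply_rigid(src, transform), dst)
  } else t0
  temp <- max(temp, schedule$t_min)

  trace <- numeric(0)
  score <- Inf
  converged <- FALSE
  for (it in seq_len(schedule$max_iter)) {
    moved <- apply_rigid(src, transform)
    sa <- soft_assignment(moved, dst, temp)
    cand <- tryCatch(weighted_procrustes(src, dst, sa$assignment),
                     error = function(e) NULL)
    if (!is.null(cand)) {
      sc <- soft_assignment(apply_rigid(src, cand), dst, temp)$score
      if (sc <= score + 1e-9) {  # accept improving transforms only
        transform <- cand
        score <- min(score, sc)
      }
    }
    trace <- c(trace, score)
    if (temp <= schedule$t_min) { converged <- TRUE; break }
    temp <- max(temp * schedule$cooling, schedule$t_min)
  }
  if (!converged)
    warning("rigid_align: annealing did not reach t_min within max_iter; ",
            "returning best transform so far")
  attr(transform, "score_trace") <- trace
  attr(transform, "converged") <- converged
  transform
}
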