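## Geometry primitives: area-weighted vertex normals, rigid Kabsch alignment,
## generalized Procrustes analysis (rotation + translation only -- size is
## deliberately retained so growth stays in the shape model), and the 3D
## thin-plate spline (biharmonic kernel phi(r) = r) used for landmark-driven
## dense correspondence.

#' Area-weighted outward vertex normals
#'
#' Face normals weighted by triangle area are accumulated per vertex and
#' normalized; global outward orientation is enforced by requiring normals to
#' point away from the centroid on average.
#'
#' @param vertices n x 3 matrix.
#' @param triangles m x 3 index matrix.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # |fn| = 2 * area
  n <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, triangles[, k])
    at <- as.integer(rownames(acc))
    n[at, ] <- n[at, ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  ctr <- colMeans(vertices)
  if (sum(rowSums(n * (vertices - rep(ctr, each = nrow(vertices))))) < 0) n <- -n
  n
}

#' Rigid Kabsch alignment of two point sets
#'
#' Finds the rotation `R` (proper, det +1 -- reflections are never used) and
#' translation `t` minimizing `||X R' + t - Y||`.
#'
#' @param X,Y k x 3 matrices of corresponding points.
#' @return List with `R` (3 x 3), `t` (length 3) and `apply(points)`.
#' @export
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- cy - as.vector(R %*% cx)
  list(R = R, t = t_,
       apply = function(P) P %*% t(R) + rep(t_, each = nrow(P)))
}

#' Generalized Procrustes alignment (rigid, no scaling)
#'
#' Iteratively superimposes landmark configurations onto an evolving mean by
#' rotation and translation only, until the mean moves by less than `tol`
#' (RMS) or `max_iter` iterations. The returned mean configuration is
#' centered at the origin. Scaling is deliberately excluded so that size
#' (facial growth) survives into downstream shape models.
#'
#' @param landmark_sets List of k x 3 matrices (k equal, >= 2 sets).
#' @param tol Convergence tolerance on the mean (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @return List: `aligned` (list of k x 3), `mean` (k x 3),
#'   `transforms` (list of `R`, `t` per set), `iterations`.
#' @export
procrustes_align <- function(landmark_sets, tol = 1e-8, max_iter = 100) {
  if (length(landmark_sets) < 2L) stop("need at least 2 landmark sets")
  k <- nrow(landmark_sets[[1]])
  if (any(vapply(landmark_sets, nrow, integer(1)) != k))
    stop("all landmark sets must have the same number of points")
  for (i in seq_along(landmark_sets)) {
    sv <- svd(scale(landmark_sets[[i]], scale = FALSE))$d
    if (sv[2] < 1e-9 * max(sv[1], 1))
      stop("degenerate landmark configuration (collinear) in set ", i)
  }
  mn <- scale(landmark_sets[[1]], scale = FALSE)
  attr(mn, "scaled:center") <- NULL
  iter <- 0L
  transforms <- vector("list", length(landmark_sets))
  aligned <- landmark_sets
  repeat {
    iter <- iter + 1L
    for (i in seq_along(landmark_sets)) {
      tf <- kabsch(landmark_sets[[i]], mn)
      transforms[[i]] <- tf
      aligned[[i]] <- tf$apply(landmark_sets[[i]])
    }
    new_mn <- Reduce(`+`, aligned) / length(aligned)
    new_mn <- sweep(new_mn, 2, colMeans(new_mn))
    delta <- sqrt(mean((new_mn - mn)^2))
    mn <- new_mn
    if (delta < tol || iter >= max_iter) break
  }
  list(aligned = aligned, mean = mn, transforms = transforms, iterations = iter)
}

#' Fit a 3D thin-plate spline warp
#'
#' Interpolating warp through landmark pairs with the biharmonic kernel
#' `phi(r) = r` plus an affine part; at `lambda = 0` each source landmark
#' maps exactly onto its target, and affine (hence rigid) maps are reproduced
#' exactly. `lambda > 0` relaxes interpolation toward smoothness.
#'
#' @param src,dst k x 3 matrices of paired landmarks.
#' @param lambda Regularization (>= 0); default scales with the source
#'   bounding-box diagonal.
#' @return A `tps_warp` object; apply with [tps_apply()].
#' @export
tps_fit <- function(src, dst, lambda = NULL) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  k <- nrow(src)
  if (nrow(dst) != k) stop("source and target landmark counts differ")
  D <- as.matrix(stats::dist(src))
  close_ <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(close_))
    stop("coincident landmarks make the TPS system singular: rows ",
         close_[1, 1], " and ", close_[1, 2])
  if (is.null(lambda)) {
    diag_len <- sqrt(sum((apply(src, 2, max) - apply(src, 2, min))^2))
    lambda <- 1e-3 * diag_len
  }
  if (lambda < 0) stop("lambda must be >= 0")
  P <- cbind(1, src)
  A <- rbind(cbind(D + diag(lambda, k), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  coefs <- solve(A, rhs)
  structure(list(src = src, w = coefs[seq_len(k), , drop = FALSE],
                 a = coefs[k + 1:4, , drop = FALSE], lambda = lambda),
            class = "tps_warp")
}

#' Apply a thin-plate spline warp to points
#'
#' @param warp A [tps_fit()] result.
#' @param points n x 3 matrix.
#' @return Warped n x 3 matrix.
#' @export
tps_apply <- function(warp, points) {
  points <- as.matrix(points)
  U <- cross_dist(points, warp$src)
  cbind(1, points) %*% warp$a + U %*% warp$w
}

cross_dist <- function(A, B) {
  # pairwise Euclidean distances, nrow(A) x nrow(B)
  aa <- rowSums(A^2); bb <- rowSums(B^2)
  d2 <- outer(aa, bb, `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Warp a base mesh onto target landmarks
#'
#' Convenience wrapper: fits the TPS from `base_landmarks` to
#' `target_landmarks` and applies it to all base vertices.
#'
#' @param base_vertices n x 3 base mesh vertices.
#' @param base_landmarks,target_landmarks k x 3 paired landmark matrices.
#' @param lambda TPS regularization (see [tps_fit()]).
#' @return Warped n x 3 vertex matrix.
#' @export
tps_warp <- function(base_vertices, base_landmarks, target_landmarks,
                     lambda = NULL) {
  tps_apply(tps_fit(base_landmarks, target_landmarks, lambda), base_vertices)
}
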