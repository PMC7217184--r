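## The dense surface model: PCA of corresponded point coordinates.
## Fitting returns a classed object with print/summary/predict/plot methods;
## modes are unit 3N-vectors ordered by decreasing variance, retained count is
## the smallest k whose cumulative variance fraction reaches the target.

#' Fit a dense surface model
#'
#' Principal-component analysis of the mean-centered, flattened corresponded
#' point matrices (singular value decomposition of the n x 3N data matrix;
#' variance divisor n - 1). Modes are ordered by decreasing variance and the
#' sign of each mode is fixed so its largest-magnitude coefficient is
#' positive, making stored models reproducible. The retained mode count is
#' the smallest k whose cumulative variance fraction reaches
#' `variance_target` (default 0.99).
#'
#' @param faces A `corresponded_cohort` from [correspond_cohort()], or a list
#'   of N x 3 point matrices (all equal N).
#' @param variance_target Fraction of total shape variance the retained modes
#'   must cover (default 0.99).
#' @param meta Optional data frame of subject metadata (taken from the
#'   corresponded cohort when available).
#' @return A `dsm` object with elements `mean_points` (N x 3), `modes`
#'   (3N x m orthonormal columns), `variances` (mm^2, non-increasing),
#'   `variance_fractions`, `retained`, `scores` (training n x m), `meta`,
#'   `triangles`.
#' @export
#' @examples
#' pts <- lapply(1:5, function(i) matrix(rnorm(30), 10, 3))
#' m <- dsm(pts, variance_target = 0.99)
#' m
dsm <- function(faces, variance_target = 0.99, meta = NULL) {
  extra <- list()
  if (inherits(faces, "corresponded_cohort")) {
    if (is.null(meta)) meta <- faces$meta
    extra <- faces[c("triangles", "landmark_index", "regions")]
    faces <- faces$points
  }
  n <- length(faces)
  if (n < 2L) stop("need at least 2 faces to fit a dense surface model")
  N <- nrow(faces[[1]])
  if (any(vapply(faces, nrow, integer(1)) != N))
    stop("all faces must have the same point count")
  X <- t(vapply(faces, function(f) as.vector(f), numeric(3L * N)))
  if (any(!is.finite(X))) stop("non-finite coordinates in input faces")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  m <- min(n - 1L, length(sv$d))
  variances <- (sv$d^2 / (n - 1))[seq_len(m)]
  pos <- variances > max(variances[1], .Machine$double.eps) * 1e-12
  variances <- variances[pos]
  modes <- sv$v[, seq_len(m), drop = FALSE][, pos, drop = FALSE]
  # sign convention: largest-magnitude coefficient of each mode positive
  for (j in seq_len(ncol(modes))) {
    i_max <- which.max(abs(modes[, j]))
    if (modes[i_max, j] < 0) modes[, j] <- -modes[, j]
  }
  fractions <- variances / sum(variances)
  retained <- which(cumsum(fractions) >= variance_target - 1e-12)[1]
  if (is.na(retained)) retained <- length(fractions)
  scores <- Xc %*% modes
  obj <- structure(list(mean_points = matrix(mu, N, 3),
                        modes = modes, variances = variances,
                        variance_fractions = fractions, retained = retained,
                        variance_target = variance_target,
                        scores = scores, meta = meta, n_points = N,
                        n_train = n,
                        triangles = extra$triangles,
                        landmark_index = extra$landmark_index,
                        regions = extra$regions),
                   class = "dsm")
  obj
}

#' @rdname dsm
#' @param ... Passed on to [dsm()].
#' @export
build_dsm <- function(faces, variance_target = 0.99, ...) {
  dsm(faces, variance_target = variance_target, ...)
}

#' @export
print.dsm <- function(x, ...) {
  cat("Dense surface model\n")
  cat(sprintf("  %d training faces x %d surface points\n", x$n_train, x$n_points))
  cat(sprintf("  %d modes; %d retained covering %.2f%% of shape variance (target %.0f%%)\n",
              length(x$variances), x$retained,
              100 * sum(x$variance_fractions[seq_len(x$retained)]),
              100 * x$variance_target))
  invisible(x)
}

#' @export
summary.dsm <- function(object, n_modes = 10, ...) {
  k <- min(n_modes, length(object$variances))
  tab <- data.frame(mode = seq_len(k),
                    sd_mm = sqrt(object$variances[seq_len(k)]),
                    var_fraction = object$variance_fractions[seq_len(k)],
                    cum_fraction = cumsum(object$variance_fractions)[seq_len(k)])
  out <- list(table = tab, retained = object$retained,
              cum_retained = sum(object$variance_fractions[seq_len(object$retained)]),
              n_train = object$n_train, n_points = object$n_points)
  class(out) <- "summary.dsm"
  out
}

#' @export
print.summary.dsm <- function(x, ...) {
  cat(sprintf("Dense surface model: %d faces, %d points, %d retained modes (%.2f%% variance)\n",
              x$n_train, x$n_points, x$retained, 100 * x$cum_retained))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.dsm <- function(x, ...) {
  k <- length(x$variance_fractions)
  graphics::plot(seq_len(k), 100 * cumsum(x$variance_fractions), type = "b",
                 pch = 19, cex = 0.6, xlab = "mode",
                 ylab = "cumulative variance (%)",
                 main = "DSM mode variance coverage", ...)
  graphics::abline(h = 100 * x$variance_target, lty = 2)
  graphics::abline(v = x$retained, lty = 3)
  invisible(x)
}

#' Project faces into DSM mode-score space
#'
#' Scores are the inner products of the centered, flattened face with the
#' retained modes.
#'
#' @param object A [dsm()] model.
#' @param newdata An N x 3 point matrix, a list of them, or a
#'   `corresponded_cohort`.
#' @param n_modes Number of leading modes (default: retained count).
#' @param ... Unused.
#' @return Score matrix (faces x modes), or a vector for a single face.
#' @export
predict.dsm <- function(object, newdata, n_modes = object$retained, ...) {
  if (inherits(newdata, "corresponded_cohort")) newdata <- newdata$points
  single <- is.matrix(newdata)
  if (single) newdata <- list(newdata)
  n_modes <- min(n_modes, ncol(object$modes))
  mu <- as.vector(object$mean_points)
  S <- t(vapply(newdata, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != object$n_points || ncol(f) != 3L)
      stop("face dimension mismatch: expected ", object$n_points, " x 3 points")
    as.vector((as.vector(f) - mu) %*% object$modes[, seq_len(n_modes), drop = FALSE])
  }, numeric(n_modes)))
  if (n_modes == 1L) S <- matrix(as.vector(S), ncol = 1L)
  colnames(S) <- paste0("PC", seq_len(n_modes))
  if (single) S[1, ] else S
}

#' @rdname predict.dsm
#' @param model A [dsm()] model.
#' @param face An N x 3 point matrix.
#' @export
project_face <- function(model, face, n_modes = model$retained) {
  predict(model, face, n_modes = n_modes)
}

#' Reconstruct a surface from mode scores
#'
#' `mean + sum(scores_i * mode_i)`, reshaped to N x 3.
#'
#' @param model A [dsm()] model.
#' @param scores Numeric vector, length at most the retained mode count.
#' @return N x 3 point matrix.
#' @export
reconstruct <- function(model, scores) {
  scores <- as.numeric(scores)
  if (length(scores) > model$retained)
    stop("score vector longer than retained mode count (",
         model$retained, ")")
  v <- as.vector(model$mean_points)
  if (length(scores))
    v <- v + as.vector(model$modes[, seq_along(scores), drop = FALSE] %*% scores)
  matrix(v, model$n_points, 3)
}

#' Pointwise mean surface of a set of faces
#'
#' @param faces List of N x 3 matrices, or a `corresponded_cohort`.
#' @param subset Optional index/logical vector selecting faces.
#' @return N x 3 matrix.
#' @export
group_mean <- function(faces, subset = NULL) {
  if (inherits(faces, "corresponded_cohort")) faces <- faces$points
  if (!is.null(subset)) faces <- faces[subset]
  if (length(faces) == 0L) stop("empty subset: no faces to average")
  Reduce(`+`, faces) / length(faces)
}

#' Linear morph between two corresponded surfaces
#'
#' @param surface_a,surface_b N x 3 matrices.
#' @param t Interpolation parameter in `[0, 1]`; 0 gives `surface_a`.
#' @return N x 3 matrix `(1 - t) * a + t * b`.
#' @export
morph <- function(surface_a, surface_b, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1)
    stop("t must be a single number in [0, 1]")
  if (!all(dim(surface_a) == dim(surface_b)))
    stop("surfaces must have identical dimensions")
  (1 - t) * surface_a + t * surface_b
}
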