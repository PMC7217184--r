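## Dense correspondence: GPA on the sparse landmarks (rigid only), TPS warp of
## the base mesh onto each subject's aligned landmarks, then closest-point
## projection onto the subject's surface. Every corresponded face has exactly
## the base vertex count, indexed by base vertex, in a common frame anchored
## to the base landmarks.

#' Project points onto a triangulated surface
#'
#' Each query point is replaced by its closest point on the target surface
#' (exact point-to-triangle distance, grid accelerated). Points farther than
#' `max_distance` from the surface keep their input position and are flagged
#' in the miss mask.
#'
#' @param points n x 3 query points.
#' @param target A [landmarked_mesh()] (or any list with `vertices`,
#'   `triangles`).
#' @param max_distance Miss threshold, mm (default 10).
#' @return List: `points` (n x 3), `distance` (n), `miss` (logical n).
#' @export
project_to_surface <- function(points, target, max_distance = 10) {
  points <- as.matrix(points)
  res <- .closest_points_cpp(points, target$vertices, target$triangles)
  miss <- res$distance > max_distance
  out <- res$points
  out[miss, ] <- points[miss, , drop = FALSE]
  list(points = out, distance = res$distance, miss = miss)
}

#' Induce dense correspondence across a cohort
#'
#' Runs the landmark-driven dense-correspondence pipeline with no manual
#' interaction: (1) generalized Procrustes alignment of all 22-point landmark
#' sets (rotation + translation only; size is retained); (2) the GPA mean is
#' rigidly anchored onto the base-mesh landmarks, fixing a common frame
#' independent of any input pose; (3) per subject, the base mesh is
#' thin-plate-spline warped onto the subject's aligned landmarks and the
#' warped vertices are projected onto the subject's surface.
#'
#' @param subjects List of [landmarked_mesh()] with full landmark sets, or a
#'   `cohort` from [generate_cohort()], or a manifest CSV path.
#' @param base Base mesh: a landmarked mesh (default: a [make_template()]
#'   when `subjects` is a synthetic cohort, else the first subject).
#' @param lambda TPS regularization (default `1e-3 *` landmark bbox diagonal).
#' @param max_distance Projection miss threshold, mm.
#' @return A `corresponded_cohort`: `points` (list of N x 3 matrices),
#'   `triangles` (base topology), `meta` (data frame), `alignment` (per
#'   subject `R`, `t` mapping input to common frame), `miss_fraction`.
#' @export
correspond_cohort <- function(subjects, base = NULL, lambda = NULL,
                              max_distance = 10) {
  if (is.character(subjects)) subjects <- read_cohort(subjects)
  if (inherits(subjects, "cohort")) {
    if (is.null(base)) base <- subjects$template
    subjects <- subjects$subjects
  } else if (is.list(subjects) && !is.null(subjects$subjects)) {
    subjects <- subjects$subjects
  }
  if (is.null(base)) base <- subjects[[1]]
  if (is.null(base$landmarks)) stop("base mesh must carry landmarks")

  schema <- landmark_schema()
  bad <- vapply(subjects, function(s) is.null(s$landmarks), logical(1))
  if (any(bad))
    stop("subjects missing landmarks: ",
         paste(names(subjects)[bad] %||% which(bad), collapse = ", "))

  lm_sets <- lapply(subjects, function(s) s$landmarks[schema, , drop = FALSE])
  gpa <- procrustes_align(lm_sets)
  # anchor the common frame to the base landmarks
  anchor <- kabsch(gpa$mean, base$landmarks[schema, , drop = FALSE])

  n_base <- nrow(base$vertices)
  points <- vector("list", length(subjects))
  alignment <- vector("list", length(subjects))
  miss_fraction <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    tf <- gpa$transforms[[i]]
    R <- anchor$R %*% tf$R
    t_ <- as.vector(anchor$R %*% tf$t) + anchor$t
    lm_i <- lm_sets[[i]] %*% t(R) + rep(t_, each = length(schema))
    mesh_i <- subjects[[i]]$vertices %*% t(R) + rep(t_, each = nrow(subjects[[i]]$vertices))
    warped <- tps_warp(base$vertices, base$landmarks[schema, , drop = FALSE],
                       lm_i, lambda = lambda)
    prj <- project_to_surface(warped,
                              list(vertices = mesh_i,
                                   triangles = subjects[[i]]$triangles),
                              max_distance = max_distance)
    points[[i]] <- prj$points
    alignment[[i]] <- list(R = R, t = t_)
    miss_fraction[i] <- mean(prj$miss)
  }
  meta <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$meta$subject_id %||% NA_character_,
               sex = s$meta$sex %||% NA_character_,
               age = s$meta$age %||% NA_real_,
               group = s$meta$group %||% NA_character_,
               stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  structure(list(points = points, triangles = base$triangles, meta = meta,
                 alignment = alignment, miss_fraction = miss_fraction,
                 base_landmarks = base$landmarks[schema, , drop = FALSE],
                 landmark_index = base$landmark_index,
                 regions = base$regions, n_points = n_base),
            class = "corresponded_cohort")
}

#' @export
print.corresponded_cohort <- function(x, ...) {
  cat("Corresponded cohort:", length(x$points), "faces x", x$n_points,
      "points\n")
  cat(sprintf("  mean miss fraction %.4f (max %.4f)\n",
              mean(x$miss_fraction), max(x$miss_fraction)))
  invisible(x)
}

#' Per-subject landmarks in the common corresponded frame
#'
#' @param cc A `corresponded_cohort` built with a base carrying
#'   `landmark_index` (e.g. the synthetic template).
#' @param i Subject index.
#' @return 22 x 3 landmark matrix (corresponded points at the landmark
#'   vertices).
#' @export
corresponded_landmarks <- function(cc, i) {
  if (is.null(cc$landmark_index))
    stop("base mesh had no landmark_index; landmarks unavailable")
  lm <- cc$points[[i]][cc$landmark_index, , drop = FALSE]
  rownames(lm) <- names(cc$landmark_index)
  lm
}
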