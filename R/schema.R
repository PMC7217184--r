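#' Canonical facial landmark schema
#'
#' The fixed, ordered set of 22 anatomical landmark names used throughout the
#' package. The composition follows standard facial anthropometry and is chosen
#' so that the measurement set (nose width, nose length, philtrum length,
#' mouth width, face height) is always computable: glabella, nasion,
#' endocanthion L/R, exocanthion L/R, palpebrale superius/inferius L/R,
#' pronasale, subnasale, alare L/R, labiale superius/inferius, crista
#' philtri L/R, chelion L/R, pogonion, gnathion. `_l` denotes the subject's
#' left side (+x), `_r` the right (-x).
#'
#' @return Character vector of 22 landmark names, in canonical order.
#' @export
#' @examples
#' landmark_schema()
landmark_schema <- function() {
  c("glabella", "nasion",
    "endocanthion_l", "endocanthion_r",
    "exocanthion_l", "exocanthion_r",
    "palpebrale_superius_l", "palpebrale_superius_r",
    "palpebrale_inferius_l", "palpebrale_inferius_r",
    "pronasale", "subnasale",
    "alare_l", "alare_r",
    "labiale_superius", "labiale_inferius",
    "crista_philtri_l", "crista_philtri_r",
    "chelion_l", "chelion_r",
    "pogonion", "gnathion")
}

#' Subject metadata record
#'
#' @param subject_id Character identifier.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years; must be positive.
#' @param group Non-empty group label, e.g. `"control"` or `"CS"`.
#' @return A `subject_meta` list.
#' @export
subject_meta <- function(subject_id, sex, age, group) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0)
    stop("age must be a positive finite number (years)")
  if (!is.character(group) || length(group) != 1L || !nzchar(group))
    stop("group must be a non-empty string")
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 age = as.numeric(age), group = group),
            class = "subject_meta")
}

#' Construct a landmarked mesh
#'
#' Bundles a triangular surface mesh with its (optional) named landmark set
#' and subject metadata, validating the package invariants: triangle indices
#' in range, exactly the 22 schema landmarks with no duplicates, and every
#' landmark inside the mesh bounding box inflated by 10%.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param triangles Integer m x 3 matrix of 1-based vertex indices.
#' @param landmarks Optional 22 x 3 matrix with rownames from
#'   [landmark_schema()], or `NULL`.
#' @param meta Optional [subject_meta()] record.
#' @return A `landmarked_mesh` object.
#' @export
landmarked_mesh <- function(vertices, triangles, landmarks = NULL, meta = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(vertices) == 0L || nrow(triangles) == 0L)
    stop("empty mesh: zero vertices or zero triangles")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle indices out of vertex range")
  if (!is.null(landmarks)) landmarks <- validate_landmarks(landmarks, vertices)
  structure(list(vertices = vertices, triangles = triangles,
                 landmarks = landmarks, meta = meta),
            class = "landmarked_mesh")
}

validate_landmarks <- function(landmarks, vertices = NULL) {
  landmarks <- as.matrix(landmarks)
  storage.mode(landmarks) <- "double"
  schema <- landmark_schema()
  nm <- rownames(landmarks)
  if (is.null(nm)) stop("landmarks must have rownames from the landmark schema")
  if (anyDuplicated(nm)) stop("duplicate landmark names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  missing <- setdiff(schema, nm)
  extra <- setdiff(nm, schema)
  if (length(missing) || length(extra))
    stop("landmark schema mismatch; missing: [",
         paste(missing, collapse = ", "), "]; extra: [",
         paste(extra, collapse = ", "), "]")
  landmarks <- landmarks[schema, , drop = FALSE]
  if (any(!is.finite(landmarks))) stop("non-finite landmark coordinates")
  if (!is.null(vertices)) {
    lo <- apply(vertices, 2, min); hi <- apply(vertices, 2, max)
    pad <- 0.1 * (hi - lo)
    lo <- lo - pad; hi <- hi + pad
    inside <- landmarks >= rep(lo, each = nrow(landmarks)) &
      landmarks <= rep(hi, each = nrow(landmarks))
    if (!all(inside)) {
      bad <- schema[rowSums(!inside) > 0]
      stop("landmarks outside inflated mesh bounding box: ",
           paste(bad, collapse = ", "))
    }
  }
  landmarks
}

#' @export
print.landmarked_mesh <- function(x, ...) {
  cat("Landmarked mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles,",
      if (is.null(x$landmarks)) "no landmarks" else
        paste(nrow(x$landmarks), "landmarks"), "\n")
  if (!is.null(x$meta))
    cat(sprintf("  subject %s (%s, %.1f y, group %s)\n", x$meta$subject_id,
                x$meta$sex, x$meta$age, x$meta$group))
  invisible(x)
}
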