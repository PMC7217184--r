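## Face signatures: per-point displacements of a corresponded face from the
## mean of age/sex-matched controls, normalized by the per-point control SD.
## The scalar signature weight (dysmorphism score) sums the squared normalized
## axial components over all points; the surface-normal component feeds the
## red-green-blue heat maps.

#' Build an age/sex-matched control reference
#'
#' Selects the `k` controls of the required sex nearest in age to the target
#' (expanded to include ties at the cut and at least a `min_window` year
#' window), and computes the pointwise mean surface and per-point,
#' per-component sample SD, floor-clamped at `sd_floor`. The per-point SD of
#' displacements along the reference surface normal is computed from the same
#' controls.
#'
#' @param cc A `corresponded_cohort` (controls are rows with
#'   `group == control_label`).
#' @param sex `"male"` or `"female"`.
#' @param age Target age, years.
#' @param k Number of nearest-in-age controls to match (default 25).
#' @param min_window Minimum age half-window, years (default 2).
#' @param sd_floor SD clamp, mm (default 0.05).
#' @param control_label Group label identifying controls.
#' @return A `matched_reference`: `ref_mean` (N x 3), `ref_sd` (N x 3),
#'   `ref_sd_normal` (N), `normals` (N x 3), `control_ids`, `age_window`.
#' @export
matched_reference <- function(cc, sex, age, k = 25, min_window = 2,
                              sd_floor = 0.05, control_label = "control") {
  sex <- match.arg(sex, c("male", "female"))
  sel <- which(cc$meta$group == control_label & cc$meta$sex == sex)
  if (length(sel) < 5L)
    stop("insufficient controls: need >= 5 of sex ", sex, ", have ",
         length(sel))
  d_age <- abs(cc$meta$age[sel] - age)
  cutoff <- max(sort(d_age)[min(k, length(sel))], min_window)
  sel <- sel[d_age <= cutoff + 1e-12]
  faces <- cc$points[sel]
  n <- length(faces)
  ref_mean <- Reduce(`+`, faces) / n
  sq <- Reduce(`+`, lapply(faces, function(f) (f - ref_mean)^2))
  ref_sd <- pmax(sqrt(sq / (n - 1)), sd_floor)
  normals <- vertex_normals(ref_mean, cc$triangles)
  nd <- vapply(faces, function(f) rowSums((f - ref_mean) * normals),
               numeric(nrow(ref_mean)))
  ref_sd_normal <- pmax(apply(nd, 1, stats::sd), sd_floor)
  structure(list(ref_mean = ref_mean, ref_sd = ref_sd,
                 ref_sd_normal = ref_sd_normal, normals = normals,
                 control_ids = cc$meta$subject_id[sel],
                 sex = sex, age = age, k = k,
                 age_window = cutoff, sd_floor = sd_floor),
            class = "matched_reference")
}

#' @export
print.matched_reference <- function(x, ...) {
  cat(sprintf("Matched control reference: %d %s controls within %.1f y of age %.1f\n",
              length(x$control_ids), x$sex, x$age_window, x$age))
  invisible(x)
}

#' Compute a face signature against a matched reference
#'
#' Raw per-point displacement is `face - ref_mean`; the normal component is
#' its projection onto the reference mean's outward unit vertex normal, and
#' the axial components are the x/y/z projections. Each component is
#' normalized by the matching control SD. The scalar weight is
#' `sqrt(sum over points of the squared normalized x, y, z components)` --
#' a rough scalar estimate of facial dysmorphism.
#'
#' @param face N x 3 corresponded point matrix.
#' @param reference A [matched_reference()].
#' @return A `face_signature`: `raw` (N x 3, mm), `normalized` (N x 3, SD
#'   units), `normal_raw` (N, mm), `normal` (N, SD units), `weight`.
#' @export
signature <- function(face, reference) {
  face <- as.matrix(face)
  if (!all(dim(face) == dim(reference$ref_mean)))
    stop("face dimension mismatch with reference (",
         nrow(reference$ref_mean), " x 3 expected)")
  raw <- face - reference$ref_mean
  normalized <- raw / reference$ref_sd
  normal_raw <- rowSums(raw * reference$normals)
  normal <- normal_raw / reference$ref_sd_normal
  structure(list(raw = raw, normalized = normalized,
                 normal_raw = normal_raw, normal = normal,
                 weight = sqrt(sum(normalized^2))),
            class = "face_signature")
}

#' @export
print.face_signature <- function(x, ...) {
  cat(sprintf("Face signature: %d points, weight %.2f (SD units)\n",
              nrow(x$raw), x$weight))
  invisible(x)
}

#' Scalar signature weight
#'
#' Square root of the sum of squared normalized axial (x, y, z) displacement
#' components over all corresponded points. Zero iff all raw displacements
#' are zero; scaling all raw displacements by `c > 0` scales the weight by
#' exactly `c`.
#'
#' @param sig A [signature()], or an N x 3 matrix of normalized components.
#' @return Non-negative scalar.
#' @export
signature_weight <- function(sig) {
  m <- if (inherits(sig, "face_signature")) sig$normalized else as.matrix(sig)
  sqrt(sum(m^2))
}

#' Heat-map colors for a signature channel
#'
#' Maps a signature component to red-green-blue per-vertex colors: 0 is pure
#' green (coincidence with the matched mean), `-scale` and below pure red
#' (inward/contraction), `+scale` and above pure blue (outward/expansion),
#' with linear interpolation between. The default scale saturates at +/- 2 SD.
#'
#' @param sig A [signature()].
#' @param channel `"normal"` (default), `"x"`, `"y"` or `"z"`.
#' @param scale Saturation point in SD units (> 0; default 2).
#' @return N x 3 RGB matrix with entries in `[0, 1]`.
#' @export
heatmap_colors <- function(sig, channel = c("normal", "x", "y", "z"),
                           scale = 2) {
  channel <- match.arg(channel)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  v <- switch(channel,
              normal = sig$normal,
              x = sig$normalized[, 1],
              y = sig$normalized[, 2],
              z = sig$normalized[, 3])
  t_ <- pmin(abs(v) / scale, 1)
  cols <- cbind(ifelse(v < 0, t_, 0), 1 - t_, ifelse(v > 0, t_, 0))
  colnames(cols) <- c("red", "green", "blue")
  cols
}

#' Signature weights for a whole cohort
#'
#' Convenience driver: builds a matched reference for every subject (each
#' against the control cohort, holding the subject itself out when it is a
#' control) and returns the per-subject signature weight alongside the
#' metadata.
#'
#' @param cc A `corresponded_cohort`.
#' @inheritParams matched_reference
#' @return Data frame: subject_id, sex, age, group, weight, n_matched.
#' @export
cohort_signature_weights <- function(cc, k = 25, min_window = 2,
                                     sd_floor = 0.05,
                                     control_label = "control") {
  res <- lapply(seq_along(cc$points), function(i) {
    cc_i <- cc
    if (cc$meta$group[i] == control_label) {
      keep <- setdiff(seq_along(cc$points), i)
      cc_i <- cc
      cc_i$points <- cc$points[keep]
      cc_i$meta <- cc$meta[keep, , drop = FALSE]
    }
    ref <- matched_reference(cc_i, cc$meta$sex[i], cc$meta$age[i], k = k,
                             min_window = min_window, sd_floor = sd_floor,
                             control_label = control_label)
    sig <- signature(cc$points[[i]], ref)
    data.frame(weight = sig$weight, n_matched = length(ref$control_ids))
  })
  cbind(cc$meta, do.call(rbind, res))
}
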