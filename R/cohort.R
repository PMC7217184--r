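## Synthetic face cohorts: deterministic generator emulating a dysmorphology
## study -- localized group displacement fields with sex-specific magnitudes
## and optional age ramp, an isotropic linear growth model, smooth individual
## shape variation, sensor-like vertex noise and arbitrary rigid pose.

#' Define a localized displacement effect field
#'
#' A Gaussian bump displacement applied to the template: every vertex is
#' displaced by `amplitude * exp(-d^2 / (2 radius^2))` along `direction`,
#' where `d` is the distance to the anchor (a landmark or the centroid of a
#' region mask).
#'
#' @param label Effect name (appears in ground-truth exports).
#' @param region Region-mask name from the template (anchor = mask centroid),
#'   or `NULL` if `landmark` is given.
#' @param landmark Landmark name used as anchor, or `NULL`.
#' @param direction `"normal"` (outward surface normal at each vertex) or a
#'   length-3 vector, normalized internally.
#' @param amplitude Peak displacement, mm (finite, may be negative).
#' @param radius Gaussian radius, mm (> 0).
#' @param sex_mult Named multipliers `c(male = , female = )`.
#' @param age_ramp_a0 If non-`NULL`, amplitude is scaled by
#'   `min(1, age / age_ramp_a0)` so the feature develops with age.
#' @return An `effect_field` list.
#' @export
effect_field <- function(label, region = NULL, landmark = NULL,
                         direction = "normal", amplitude, radius,
                         sex_mult = c(male = 1, female = 1),
                         age_ramp_a0 = NULL) {
  if (is.null(region) == is.null(landmark))
    stop("give exactly one of region or landmark as anchor")
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (is.numeric(direction)) {
    if (length(direction) != 3L) stop("direction must be 'normal' or length 3")
    direction <- direction / sqrt(sum(direction^2))
  } else if (!identical(direction, "normal"))
    stop("direction must be 'normal' or a length-3 vector")
  structure(list(label = label, region = region, landmark = landmark,
                 direction = direction, amplitude = amplitude, radius = radius,
                 sex_mult = sex_mult, age_ramp_a0 = age_ramp_a0),
            class = "effect_field")
}

# per-vertex displacement (n x 3, mm) of one field on the template,
# for a given sex and age
effect_displacement <- function(field, template, sex = "male", age = Inf,
                                normals = NULL) {
  v <- template$vertices
  anchor <- if (!is.null(field$landmark)) {
    template$landmarks[field$landmark, ]
  } else {
    colMeans(v[template$regions[[field$region]], , drop = FALSE])
  }
  a <- field$amplitude * unname(field$sex_mult[[sex]])
  if (!is.null(field$age_ramp_a0)) a <- a * min(1, age / field$age_ramp_a0)
  d2 <- rowSums((v - rep(anchor, each = nrow(v)))^2)
  w <- a * exp(-d2 / (2 * field$radius^2))
  if (identical(field$direction, "normal")) {
    if (is.null(normals)) normals <- vertex_normals(v, template$triangles)
    normals * w
  } else {
    outer(w, field$direction)
  }
}

#' Default syndrome effect fields
#'
#' The stock displacement field set emulating the facial gestalt studied
#' here: a wider nose (lateral alar displacement), a longer, more prominent
#' nose tip, a longer philtrum, fuller lips and a more prominent chin, each
#' more pronounced in males than females.
#'
#' @param amplitude Overall scale of the field amplitudes, mm (default 1.5).
#' @return List of [effect_field()]s.
#' @export
syndrome_effect_fields <- function(amplitude = 1.5) {
  sm <- c(male = 1.2, female = 0.8)
  list(
    effect_field("nose_width_l", landmark = "alare_l",
                 direction = c(1, 0, 0), amplitude = amplitude, radius = 8,
                 sex_mult = sm),
    effect_field("nose_width_r", landmark = "alare_r",
                 direction = c(-1, 0, 0), amplitude = amplitude, radius = 8,
                 sex_mult = sm),
    effect_field("nose_tip", landmark = "pronasale",
                 direction = "normal", amplitude = amplitude, radius = 10,
                 sex_mult = sm),
    effect_field("philtrum_length", landmark = "labiale_superius",
                 direction = c(0, -1, 0), amplitude = amplitude, radius = 8,
                 sex_mult = sm),
    effect_field("lip_fullness", region = "lips",
                 direction = "normal", amplitude = amplitude, radius = 10,
                 sex_mult = sm),
    effect_field("chin", landmark = "pogonion",
                 direction = "normal", amplitude = amplitude, radius = 9,
                 sex_mult = sm))
}

#' Cohort generator configuration
#'
#' @param groups Named list; each element a list with `n`, `sex_ratio`
#'   (fraction male), `age_range` `c(lo, hi)` years (optionally overridden
#'   per sex via `age_range_male` / `age_range_female`), `effects` (list of
#'   [effect_field()]s), and `growth` `c(s0, s1)` for the isotropic scale
#'   `s(age) = s0 + s1 * age`.
#' @param n_modes Number of smooth random individual-variation modes.
#' @param mode_sd Per-mode loading SD, mm.
#' @param noise_sd Sensor-like iid vertex noise SD, mm.
#' @param pose_rot_max Max rigid pose rotation, degrees.
#' @param pose_trans_max Max rigid pose translation, mm.
#' @param resolution Template vertex-count target.
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(groups, n_modes = 5, mode_sd = 1.5, noise_sd = 0.2,
                          pose_rot_max = 10, pose_trans_max = 20,
                          resolution = 5000, seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (!is.numeric(gr$n) || gr$n < 0) stop("group ", g, ": n must be >= 0")
    if (is.null(gr$sex_ratio)) groups[[g]]$sex_ratio <- 0.5
    if (is.null(gr$age_range)) groups[[g]]$age_range <- c(2, 22)
    if (is.null(gr$effects)) groups[[g]]$effects <- list()
    if (is.null(gr$growth)) groups[[g]]$growth <- c(0.80, 0.012)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(groups = groups, n_modes = n_modes, mode_sd = mode_sd,
                 noise_sd = noise_sd, pose_rot_max = pose_rot_max,
                 pose_trans_max = pose_trans_max, resolution = resolution,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Study-like default configuration
#'
#' Mirrors the study's cohort structure at a configurable scale: a control
#' group spanning ages 2-22 of both sexes and a syndrome group (`"CS"`) with
#' the [syndrome_effect_fields()] displacement set and a faster growth model
#' (`s0` and `s1` both larger than controls, emulating macrosomia).
#'
#' @param n_control,n_cs Group sizes (default 40 controls, 20 patients).
#' @param effect_amplitude Scale of the syndrome fields, mm.
#' @param ... Passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
study_config <- function(n_control = 40, n_cs = 20, effect_amplitude = 1.5,
                         ...) {
  cohort_config(groups = list(
    control = list(n = n_control, sex_ratio = 0.5, age_range = c(2, 22),
                   effects = list(), growth = c(0.80, 0.012)),
    CS = list(n = n_cs, sex_ratio = 0.5, age_range = c(2.7, 22),
              effects = syndrome_effect_fields(effect_amplitude),
              growth = c(0.82, 0.015))), ...)
}

random_rotation <- function(max_deg) {
  if (max_deg <= 0) return(diag(3))
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# smooth random displacement field: Gaussian bump at a random surface anchor
# with random direction and radius; unit peak amplitude
random_mode_field <- function(template) {
  v <- template$vertices
  anchor <- v[sample.int(nrow(v), 1L), ]
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  radius <- stats::runif(1, 15, 35)
  d2 <- rowSums((v - rep(anchor, each = nrow(v)))^2)
  outer(exp(-d2 / (2 * radius^2)), dir)
}

#' Sample one synthetic subject
#'
#' Applies, in order: group effect fields (sex/age modulated), individual
#' variation mode loadings, iid vertex noise, the isotropic growth scale
#' `s(age)`, and a random rigid pose. Landmarks are template vertices and are
#' transported through the same deformation. Uses the current RNG state;
#' deterministic given it.
#'
#' @param template A [make_template()] surface.
#' @param meta A [subject_meta()].
#' @param config A [cohort_config()] (group of `meta` must exist in it).
#' @param modes Optional list of precomputed individual-variation fields
#'   (n x 3 each); generated by [generate_cohort()].
#' @return A [landmarked_mesh()] with `loadings` and `true_displacement`
#'   attributes (ground truth).
#' @export
sample_subject <- function(template, meta, config, modes = list()) {
  gr <- config$groups[[meta$group]]
  if (is.null(gr)) stop("unknown group in config: ", meta$group)
  v <- template$vertices
  nrm <- vertex_normals(v, template$triangles)
  disp <- matrix(0, nrow(v), 3)
  for (f in gr$effects)
    disp <- disp + effect_displacement(f, template, meta$sex, meta$age, nrm)
  true_disp <- disp
  loadings <- numeric(0)
  if (length(modes)) {
    loadings <- stats::rnorm(length(modes), 0, config$mode_sd)
    for (j in seq_along(modes)) disp <- disp + loadings[j] * modes[[j]]
  }
  if (config$noise_sd > 0)
    disp <- disp + matrix(stats::rnorm(3 * nrow(v), 0, config$noise_sd),
                          nrow(v), 3)
  s <- gr$growth[1] + gr$growth[2] * meta$age
  pts <- s * (v + disp)
  R <- random_rotation(config$pose_rot_max)
  tr <- stats::runif(3, -config$pose_trans_max, config$pose_trans_max)
  pts <- pts %*% t(R) + rep(tr, each = nrow(pts))
  lm <- pts[template$landmark_index, , drop = FALSE]
  rownames(lm) <- landmark_schema()
  out <- landmarked_mesh(pts, template$triangles, landmarks = lm, meta = meta)
  out$loadings <- loadings
  out$true_displacement <- true_disp
  out
}

#' Generate a synthetic cohort
#'
#' Deterministically generates all subjects of a configuration. With
#' `dir = NULL` the cohort is returned in memory; otherwise each subject's
#' surface (PLY) and landmarks (CSV) are written along with a manifest CSV
#' and a ground-truth JSON sidecar (injected per-group displacement fields
#' and per-subject mode loadings).
#'
#' @param config A [cohort_config()].
#' @param dir Output directory or `NULL` (in-memory).
#' @param template Optional pre-built template (else built at
#'   `config$resolution`).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return A `cohort` list: `template`, `subjects` (list of
#'   [landmarked_mesh()]), `manifest` (data frame), `ground_truth`.
#' @export
generate_cohort <- function(config, dir = NULL, template = NULL,
                            overwrite = FALSE) {
  if (!is.null(dir) && dir.exists(dir) && length(dir(dir)) && !overwrite)
    stop("output directory not empty (use overwrite = TRUE): ", dir)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (is.null(template)) template <- make_template(config$resolution)
  modes <- lapply(seq_len(config$n_modes), function(i) random_mode_field(template))
  nrm <- vertex_normals(template$vertices, template$triangles)

  subjects <- list(); rows <- list(); gt_load <- list()
  for (g in names(config$groups)) {
    gr <- config$groups[[g]]
    if (gr$n == 0) next
    n_male <- round(gr$n * gr$sex_ratio)
    sexes <- c(rep("male", n_male), rep("female", gr$n - n_male))
    ages <- vapply(seq_len(gr$n), function(i) {
      rng <- gr[[paste0("age_range_", sexes[i])]] %||% gr$age_range
      stats::runif(1, rng[1], rng[2])
    }, numeric(1))
    for (i in seq_len(gr$n)) {
      id <- sprintf("%s_%03d", g, i)
      meta <- subject_meta(id, sexes[i], ages[i], g)
      subj <- sample_subject(template, meta, config, modes)
      subjects[[id]] <- subj
      gt_load[[id]] <- subj$loadings
      rows[[id]] <- data.frame(subject_id = id, sex = meta$sex,
                               age = meta$age, group = g,
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL

  # ground truth: per-group mean injected field at reference sex/age
  gt_fields <- lapply(names(config$groups), function(g) {
    gr <- config$groups[[g]]
    if (!length(gr$effects)) return(NULL)
    male <- Reduce(`+`, lapply(gr$effects, effect_displacement,
                               template = template, sex = "male", age = Inf,
                               normals = nrm))
    female <- Reduce(`+`, lapply(gr$effects, effect_displacement,
                                 template = template, sex = "female",
                                 age = Inf, normals = nrm))
    list(male = male, female = female)
  })
  names(gt_fields) <- names(config$groups)
  ground_truth <- list(fields = gt_fields, loadings = gt_load,
                       modes = modes, growth = lapply(config$groups, `[[`, "growth"))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$mesh_path <- file.path(dir, paste0(manifest$subject_id, ".ply"))
    manifest$landmarks_path <- file.path(dir, paste0(manifest$subject_id,
                                                     "_landmarks.csv"))
    for (i in seq_len(nrow(manifest))) {
      s <- subjects[[manifest$subject_id[i]]]
      write_mesh(s, manifest$mesh_path[i])
      write_landmarks(s$landmarks, manifest$landmarks_path[i])
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    gt_json <- list(
      loadings = gt_load,
      growth = ground_truth$growth,
      fields = lapply(gt_fields, function(f)
        if (is.null(f)) NULL else lapply(f, function(m) round(m, 6))))
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(template = template, subjects = subjects, manifest = manifest,
                 ground_truth = ground_truth, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$manifest), "subjects\n")
  print(table(group = x$manifest$group, sex = x$manifest$sex))
  invisible(x)
}

#' Read a cohort manifest and its files
#'
#' Loads the meshes and landmark tables referenced by a manifest CSV
#' (columns: subject_id, sex, age, group, mesh_path, landmarks_path) into an
#' in-memory cohort. Fails before reading anything if a referenced file is
#' missing.
#'
#' @param path Manifest CSV path.
#' @return List of [landmarked_mesh()] plus the manifest data frame.
#' @export
read_cohort <- function(path) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "group", "mesh_path", "landmarks_path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  manifest$mesh_path <- resolve(manifest$mesh_path)
  manifest$landmarks_path <- resolve(manifest$landmarks_path)
  missing <- !file.exists(manifest$mesh_path) | !file.exists(manifest$landmarks_path)
  if (any(missing))
    stop("missing files for subjects: ",
         paste(manifest$subject_id[missing], collapse = ", "))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- read_mesh(manifest$mesh_path[i])
    m$landmarks <- validate_landmarks(read_landmarks(manifest$landmarks_path[i]),
                                      m$vertices)
    m$meta <- subject_meta(manifest$subject_id[i], manifest$sex[i],
                           manifest$age[i], manifest$group[i])
    m
  })
  names(subjects) <- manifest$subject_id
  list(subjects = subjects, manifest = manifest)
}
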