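## Landmark anthropometry: the measured facial distances and the group
## comparison statistics (pooled-variance Student's t with Bonferroni
## threshold).

MEASUREMENT_PAIRS <- list(
  nose_width = c("alare_l", "alare_r"),
  nose_length = c("nasion", "pronasale"),
  philtrum_length = c("subnasale", "labiale_superius"),
  mouth_width = c("chelion_l", "chelion_r"),
  face_height = c("nasion", "gnathion"))

#' Landmark-based facial measurements
#'
#' Euclidean distances (mm) between named landmark pairs: nose width
#' (alare L-R), nose length (nasion-pronasale), philtrum length
#' (subnasale-labiale superius), mouth width (chelion L-R) and face height
#' (nasion-gnathion). Rigid-transform invariant by construction. The
#' nose-length pair is a convention (nasion-pronasale); pass `pairs` to
#' override any definition.
#'
#' @param landmarks 22 x 3 matrix with schema rownames.
#' @param pairs Named list of landmark-name pairs (default the set above).
#' @return Named numeric vector of distances (mm).
#' @export
#' @examples
#' tpl <- make_template(800)
#' measure_face(tpl$landmarks)
measure_face <- function(landmarks, pairs = MEASUREMENT_PAIRS) {
  landmarks <- validate_landmarks(landmarks)
  vapply(pairs, function(p) {
    sqrt(sum((landmarks[p[1], ] - landmarks[p[2], ])^2))
  }, numeric(1))
}

#' Measurements for every subject of a cohort
#'
#' @param subjects List of [landmarked_mesh()], a `cohort`, or a
#'   `corresponded_cohort` (landmarks read off the corresponded points).
#' @param pairs Passed to [measure_face()].
#' @return Tidy data frame: subject_id, sex, age, group, measurement, value.
#' @export
cohort_measurements <- function(subjects, pairs = MEASUREMENT_PAIRS) {
  if (inherits(subjects, "corresponded_cohort")) {
    meta <- subjects$meta
    lms <- lapply(seq_along(subjects$points), function(i)
      corresponded_landmarks(subjects, i))
  } else {
    if (inherits(subjects, "cohort")) subjects <- subjects$subjects
    meta <- do.call(rbind, lapply(subjects, function(s)
      as.data.frame(s$meta[c("subject_id", "sex", "age", "group")],
                    stringsAsFactors = FALSE)))
    lms <- lapply(subjects, `[[`, "landmarks")
  }
  out <- do.call(rbind, lapply(seq_along(lms), function(i) {
    v <- measure_face(lms[[i]], pairs)
    data.frame(meta[i, c("subject_id", "sex", "age", "group")],
               measurement = names(v), value = unname(v),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' Divides the p-value cut-off by the number of tests run.
#'
#' @param alpha Family-wise cut-off in (0, 1) (e.g. 0.05).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 4)  # 0.0125
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Unpaired Student's t comparison of two groups
#'
#' Classic pooled-variance two-tailed Student's t-test (Welch's correction
#' available via `welch = TRUE`), with the significance flag evaluated
#' against a Bonferroni-style threshold. Degenerate zero-variance inputs are
#' resolved explicitly: equal means give p = 1, unequal means p = 0 (with a
#' warning).
#'
#' @param values_a,values_b Numeric vectors (each n >= 2).
#' @param threshold Significance threshold (default
#'   `bonferroni_threshold(0.05, 4)` = 0.0125).
#' @param measurement Optional label carried into the result.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return A `group_comparison`: means, SDs, ns, `t`, `df`, `p`,
#'   `significant`.
#' @export
compare_groups <- function(values_a, values_b,
                           threshold = bonferroni_threshold(0.05, 4),
                           measurement = NA_character_, welch = FALSE) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2")
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b)) {
      t_ <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p set to 0")
      t_ <- Inf * sign(mean(values_a) - mean(values_b)); p <- 0
    }
    df <- length(values_a) + length(values_b) - 2
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = !welch)
    t_ <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(list(measurement = measurement,
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 sd_a = stats::sd(values_a), sd_b = stats::sd(values_b),
                 n_a = length(values_a), n_b = length(values_b),
                 t = t_, df = df, p = p, threshold = threshold,
                 significant = p < threshold, welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.2f +/- %.2f (n=%d) vs %.2f +/- %.2f (n=%d)\n",
              if (is.na(x$measurement)) "Group comparison" else x$measurement,
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  %st = %.3f, df = %.1f, p = %.4g (%ssignificant at %.4g)\n",
              if (x$welch) "Welch " else "", x$t, x$df, x$p,
              if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}

#' Compare all measurements between two groups
#'
#' Runs [compare_groups()] per measurement on a tidy measurement table, with
#' the Bonferroni threshold computed from the number of measurements tested.
#'
#' @param measurements Output of [cohort_measurements()].
#' @param group_a,group_b Group labels to compare.
#' @param alpha Family-wise cut-off before correction (default 0.05).
#' @param sex Optionally restrict to one sex.
#' @return Data frame with one row per measurement (means, t, p,
#'   significant) plus the threshold used as an attribute.
#' @export
compare_measurements <- function(measurements, group_a, group_b, alpha = 0.05,
                                 sex = NULL) {
  if (!is.null(sex)) measurements <- measurements[measurements$sex == sex, ]
  ms <- unique(measurements$measurement)
  thr <- bonferroni_threshold(alpha, length(ms))
  rows <- lapply(ms, function(m) {
    a <- measurements$value[measurements$measurement == m &
                              measurements$group == group_a]
    b <- measurements$value[measurements$measurement == m &
                              measurements$group == group_b]
    cmp <- compare_groups(a, b, threshold = thr, measurement = m)
    data.frame(measurement = m, mean_a = cmp$mean_a, mean_b = cmp$mean_b,
               sd_a = cmp$sd_a, sd_b = cmp$sd_b, n_a = cmp$n_a, n_b = cmp$n_b,
               t = cmp$t, p = cmp$p, significant = cmp$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
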