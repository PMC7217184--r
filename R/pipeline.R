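## End-to-end orchestration: validate config, run correspond -> DSM ->
## signatures -> measurements/stats -> classification -> growth, writing every
## artifact with a config snapshot and a per-stage log into one run directory.

#' Assemble a pipeline run configuration
#'
#' @param manifest Path to a cohort manifest CSV, or an in-memory `cohort`.
#' @param out_dir Output run directory.
#' @param base `"template"` (synthetic template at `resolution`) or
#'   `"first_control"`.
#' @param lambda,max_distance Correspondence parameters.
#' @param variance_target DSM variance target.
#' @param k,min_window,sd_floor Matched-reference parameters.
#' @param heatmap_scale Heat-map saturation, SD units.
#' @param folds,seed Discrimination fold scheme and master seed.
#' @param control_label Group label identifying controls.
#' @param resolution Template resolution when `base = "template"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(manifest, out_dir, base = "template", lambda = NULL,
                       max_distance = 10, variance_target = 0.99, k = 25,
                       min_window = 2, sd_floor = 0.05, heatmap_scale = 2,
                       folds = "auto", seed = 1, control_label = "control",
                       resolution = 5000) {
  if (!inherits(manifest, "cohort") && !file.exists(manifest))
    stop("manifest not found: ", manifest)
  base <- match.arg(base, c("template", "first_control"))
  stopifnot(variance_target > 0, variance_target <= 1, max_distance > 0,
            k >= 1, sd_floor > 0, heatmap_scale > 0,
            folds %in% c("auto", "loo") || folds >= 2)
  structure(list(manifest = manifest, out_dir = out_dir, base = base,
                 lambda = lambda, max_distance = max_distance,
                 variance_target = variance_target, k = k,
                 min_window = min_window, sd_floor = sd_floor,
                 heatmap_scale = heatmap_scale, folds = folds,
                 seed = as.integer(seed), control_label = control_label,
                 resolution = resolution),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on a cohort and writes, under
#' `config$out_dir`: the config snapshot (`config.yaml`), a per-stage log,
#' the model summary (`model.json`), per-subject signature weights and
#' measurements (tidy CSV), measurement comparison tables, classification
#' results (JSON) and growth regression comparisons (JSON), plus group-mean
#' heat-map meshes (PLY). Deterministic stages are bit-identical under
#' rerun with the same config.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S"), msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  snap <- config
  snap$manifest <- if (inherits(config$manifest, "cohort"))
    "<in-memory cohort>" else config$manifest
  yaml::write_yaml(unclass(snap), file.path(config$out_dir, "config.yaml"))

  # -- load & validate ------------------------------------------------------
  cohort <- if (inherits(config$manifest, "cohort")) config$manifest
  else read_cohort(config$manifest)
  subjects <- cohort$subjects
  manifest <- cohort$manifest
  say("loaded cohort: %d subjects, groups: %s", length(subjects),
      paste(names(table(manifest$group)), collapse = ", "))

  base <- if (config$base == "template") {
    if (inherits(cohort, "cohort")) cohort$template
    else make_template(config$resolution)
  } else {
    ctrl <- which(manifest$group == config$control_label)
    if (!length(ctrl)) stop("no control subject available as base mesh")
    subjects[[ctrl[1]]]
  }

  # -- correspondence -------------------------------------------------------
  cc <- correspond_cohort(subjects, base = base, lambda = config$lambda,
                          max_distance = config$max_distance)
  say("correspondence: %d faces x %d points, mean miss fraction %.4f",
      length(cc$points), cc$n_points, mean(cc$miss_fraction))

  # -- dense surface model --------------------------------------------------
  model <- dsm(cc, variance_target = config$variance_target)
  say("DSM: %d modes, %d retained (%.2f%% variance)",
      length(model$variances), model$retained,
      100 * sum(model$variance_fractions[seq_len(model$retained)]))
  jsonlite::write_json(list(
    n_train = model$n_train, n_points = model$n_points,
    retained = model$retained,
    variance_fractions = model$variance_fractions,
    cum_retained = sum(model$variance_fractions[seq_len(model$retained)]),
    miss_fraction = cc$miss_fraction),
    file.path(config$out_dir, "model.json"), auto_unbox = TRUE, digits = NA)

  # -- signatures + heat maps -----------------------------------------------
  weights <- cohort_signature_weights(cc, k = config$k,
                                      min_window = config$min_window,
                                      sd_floor = config$sd_floor,
                                      control_label = config$control_label)
  utils::write.csv(weights, file.path(config$out_dir, "signature_weights.csv"),
                   row.names = FALSE, quote = FALSE)
  say("signatures: weights for %d subjects", nrow(weights))
  groups <- setdiff(unique(cc$meta$group), config$control_label)
  for (g in groups) {
    for (sx in intersect(c("male", "female"),
                         cc$meta$sex[cc$meta$group == g])) {
      sel <- cc$meta$group == g & cc$meta$sex == sx
      if (sum(sel) < 1) next
      gm <- group_mean(cc$points[sel])
      ref <- try(matched_reference(cc, sx, mean(cc$meta$age[sel]),
                                   k = config$k, min_window = config$min_window,
                                   sd_floor = config$sd_floor,
                                   control_label = config$control_label),
                 silent = TRUE)
      if (inherits(ref, "try-error")) next
      sig <- signature(gm, ref)
      write_heatmap_mesh(
        file.path(config$out_dir, sprintf("heatmap_%s_%s.ply", g, sx)),
        gm, cc$triangles,
        heatmap_colors(sig, "normal", scale = config$heatmap_scale))
    }
  }

  # -- measurements + group stats ------------------------------------------
  meas <- cohort_measurements(cc)
  utils::write.csv(meas, file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE, quote = FALSE)
  cmp_tabs <- list()
  for (g in groups) {
    for (sx in c("male", "female")) {
      sub <- meas[meas$group %in% c(config$control_label, g), ]
      if (length(unique(sub$group[sub$sex == sx])) == 2L &&
          min(table(sub$group[sub$sex == sx])) >= 2 * length(unique(sub$measurement))) {
        tab <- compare_measurements(sub, g, config$control_label, sex = sx)
        tab$group <- g; tab$sex <- sx
        cmp_tabs[[paste(g, sx)]] <- tab
      }
    }
  }
  if (length(cmp_tabs))
    utils::write.csv(do.call(rbind, cmp_tabs),
                     file.path(config$out_dir, "measurement_comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
  say("measurements: %d values, %d comparison tables", nrow(meas),
      length(cmp_tabs))

  # -- classification -------------------------------------------------------
  disc <- NULL
  if (length(groups) >= 1L && min(table(cc$meta$group)) >= 2L) {
    disc <- discriminate(cc, folds = config$folds, seed = config$seed,
                         variance_target = config$variance_target)
    jsonlite::write_json(list(
      scheme = disc$scheme,
      accuracy = lapply(disc$classifiers, function(r)
        list(accuracy = r$accuracy, macro_accuracy = r$macro_accuracy,
             confusion = as.data.frame(r$confusion)))),
      file.path(config$out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
    say("classification (%s): closest-mean accuracy %.3f", disc$scheme,
        disc$classifiers$closest_mean$accuracy)
  }

  # -- growth ---------------------------------------------------------------
  growth <- list()
  for (g in groups) {
    if (sum(cc$meta$group == g) >= 3L &&
        sum(cc$meta$group == config$control_label) >= 3L) {
      pc1 <- pc1_growth_comparison(cc, config$control_label, g, model = model)
      wsub <- weights[weights$group %in% c(config$control_label, g), ]
      dt <- dysmorphism_trend(wsub$weight, wsub$age, wsub$group)
      growth[[g]] <- list(
        pc1 = list(groups = pc1$groups, slope_test = pc1$slope_test,
                   intercept_test = pc1$intercept_test, decision = pc1$decision),
        weight = list(groups = dt$groups, slope_test = dt$slope_test,
                      intercept_test = dt$intercept_test,
                      decision = dt$decision,
                      mean_weight_p = dt$weight_test$p))
      say("growth vs %s: PC1 %s", g, pc1$decision)
    }
  }
  if (length(growth))
    jsonlite::write_json(growth, file.path(config$out_dir, "growth.json"),
                         auto_unbox = TRUE, digits = NA)

  say("pipeline complete: %s", config$out_dir)
  invisible(config$out_dir)
}
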