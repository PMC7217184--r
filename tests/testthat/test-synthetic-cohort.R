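test_that("template meets its contract: size, landmarks, symmetry, regions", {
  tpl <- make_template(5000)
  expect_gte(nrow(tpl$vertices), 4000)
  expect_lte(nrow(tpl$vertices), 6000)
  expect_identical(rownames(tpl$landmarks), landmark_schema())
  # landmarks are template vertices
  expect_equal(tpl$vertices[tpl$landmark_index, ], unname(tpl$landmarks),
               ignore_attr = TRUE)

  # bilateral symmetry: the mirrored vertex set equals the vertex set
  small <- fix_template(800)
  v <- small$vertices
  mirrored <- cbind(-v[, 1], v[, 2], v[, 3])
  ord <- function(m) m[order(round(m[, 1], 6), round(m[, 2], 6)), ]
  expect_lt(max(abs(ord(mirrored) - ord(v))), 1e-6)

  # nose width equals the documented template constant up to grid snapping
  d <- sqrt(sum((small$landmarks["alare_l", ] - small$landmarks["alare_r", ])^2))
  expect_lt(abs(d - 30), small$grid$du)

  # regions non-empty; philtrum/lips/chin pairwise disjoint
  expect_true(all(lengths(small$regions) > 0))
  expect_length(intersect(small$regions$philtrum, small$regions$lips), 0)
  expect_length(intersect(small$regions$lips, small$regions$chin), 0)

  expect_error(make_template(100), "resolution")
})

test_that("a subject with all variation switched off is the template", {
  tpl <- fix_template(800)
  cfg <- cohort_config(groups = list(
    g = list(n = 1, effects = list(), growth = c(1, 0))),
    n_modes = 0, noise_sd = 0, pose_rot_max = 0, pose_trans_max = 0,
    resolution = 800, seed = 1)
  s <- sample_subject(tpl, subject_meta("s1", "male", 10, "g"), cfg)
  expect_equal(s$vertices, tpl$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(s$landmarks), unname(tpl$landmarks), tolerance = 1e-12)
  expect_error(sample_subject(tpl, subject_meta("s1", "male", 10, "nope"), cfg),
               "unknown group")
})

test_that("a single outward effect displaces vertices by the bump formula", {
  tpl <- fix_template(800)
  fld <- effect_field("bump", region = "nose", direction = "normal",
                      amplitude = 2, radius = 8)
  cfg <- cohort_config(groups = list(
    g = list(n = 1, effects = list(fld), growth = c(1, 0))),
    n_modes = 0, noise_sd = 0, pose_rot_max = 0, pose_trans_max = 0,
    resolution = 800, seed = 1)
  s <- sample_subject(tpl, subject_meta("s1", "male", 10, "g"), cfg)
  disp <- s$vertices - tpl$vertices
  # independent evaluation of the Gaussian bump at every vertex
  anchor <- colMeans(tpl$vertices[tpl$regions$nose, ])
  d <- sqrt(rowSums((tpl$vertices - rep(anchor, each = nrow(tpl$vertices)))^2))
  expected_mag <- 2 * exp(-d^2 / (2 * 8^2))
  expect_equal(sqrt(rowSums(disp^2)), expected_mag, tolerance = 1e-8)
  # outward: displacement is along the outward normal where it is material
  nrm <- vertex_normals(tpl$vertices, tpl$triangles)
  big <- expected_mag > 0.5
  expect_true(all(rowSums(disp[big, ] * nrm[big, ]) > 0))
})

test_that("cohort generation is deterministic and honors the configuration", {
  cfg <- study_config(n_control = 8, n_cs = 6, resolution = 700, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$subjects[[3]]$vertices, b$subjects[[3]]$vertices)

  # files on disk: manifest + per-subject mesh/landmarks + ground truth
  dir <- withr::local_tempdir()
  generate_cohort(cfg, dir = file.path(dir, "run"))
  man <- read.csv(file.path(dir, "run", "manifest.csv"))
  expect_equal(nrow(man), 14L)
  expect_true(all(file.exists(man$mesh_path)))
  expect_true(file.exists(file.path(dir, "run", "ground_truth.json")))
  expect_error(generate_cohort(cfg, dir = file.path(dir, "run")),
               "not empty")

  # n = 0 removes the group from the manifest
  cfg0 <- study_config(n_control = 5, n_cs = 0, resolution = 700, seed = 9)
  m0 <- generate_cohort(cfg0)$manifest
  expect_false("CS" %in% m0$group)
})

test_that("a study-sized configuration yields the configured cohort layout", {
  cfg <- cohort_config(groups = list(
    control = list(n = 145, age_range = c(2, 22)),
    CS = list(n = 20, sex_ratio = 0.5,
              age_range_male = c(2.7, 16.2), age_range_female = c(3.1, 22.0),
              effects = syndrome_effect_fields())),
    resolution = 700, seed = 4)
  coh <- generate_cohort(cfg, template = fix_template(700))
  man <- coh$manifest
  expect_equal(sum(man$group == "control"), 145L)
  expect_equal(sum(man$group == "CS" & man$sex == "male"), 10L)
  expect_equal(sum(man$group == "CS" & man$sex == "female"), 10L)
  cs_m <- man[man$group == "CS" & man$sex == "male", ]
  cs_f <- man[man$group == "CS" & man$sex == "female", ]
  expect_true(all(cs_m$age >= 2.7 & cs_m$age <= 16.2))
  expect_true(all(cs_f$age >= 3.1 & cs_f$age <= 22.0))
})

test_that("growth slope s1 is recovered from inter-landmark distances", {
  cfg <- cohort_config(groups = list(
    g = list(n = 60, age_range = c(2, 22), growth = c(0.80, 0.012))),
    noise_sd = 0.2, resolution = 700, seed = 7)
  coh <- generate_cohort(cfg, template = fix_template(700))
  tpl <- coh$template
  d0 <- mean(dist(tpl$landmarks))  # template mean inter-landmark distance
  md <- vapply(coh$subjects, function(s) mean(dist(s$landmarks)), numeric(1))
  ages <- coh$manifest$age
  s1_hat <- unname(coef(lm(md ~ ages))[2]) / d0
  expect_lt(abs(s1_hat - 0.012) / 0.012, 0.10)
})

test_that("cohort manifests round-trip through disk", {
  cfg <- study_config(n_control = 6, n_cs = 4, resolution = 700, seed = 5)
  dir <- file.path(withr::local_tempdir(), "coh")
  mem <- generate_cohort(cfg, dir = dir)
  back <- read_cohort(file.path(dir, "manifest.csv"))
  expect_equal(length(back$subjects), 10L)
  s_mem <- mem$subjects[[2]]; s_dsk <- back$subjects[[2]]
  expect_lt(max(abs(s_mem$vertices - s_dsk$vertices)), 1e-6)
  expect_lt(max(abs(s_mem$landmarks - s_dsk$landmarks)), 1e-6)
  expect_equal(s_dsk$meta$group, s_mem$meta$group)

  # a missing mesh file is reported by subject before any load
  man <- read.csv(file.path(dir, "manifest.csv"))
  file.remove(man$mesh_path[3])
  expect_error(read_cohort(file.path(dir, "manifest.csv")),
               man$subject_id[3])
})
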