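# build a minimal corresponded cohort by hand around a template surface
toy_cc <- function(ages, sexes = NULL, groups = NULL, jitter = 0,
                   res = 800, seed = 21) {
  tpl <- fix_template(res)
  n <- length(ages)
  sexes <- sexes %||% rep("male", n)
  groups <- groups %||% rep("control", n)
  set.seed(seed)
  pts <- lapply(seq_len(n), function(i)
    tpl$vertices + if (jitter > 0)
      matrix(rnorm(3 * nrow(tpl$vertices), 0, jitter),
             nrow(tpl$vertices), 3) else 0)
  structure(list(points = pts, triangles = tpl$triangles,
                 meta = data.frame(subject_id = paste0("s", seq_len(n)),
                                   sex = sexes, age = ages, group = groups,
                                   stringsAsFactors = FALSE),
                 n_points = nrow(tpl$vertices),
                 landmark_index = tpl$landmark_index,
                 regions = tpl$regions),
            class = "corresponded_cohort")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("matched reference selects k nearest-in-age controls of one sex", {
  cc <- toy_cc(ages = c(3, 4, 5, 6, 20), jitter = 0.5)
  ref <- matched_reference(cc, "male", age = 5, k = 3, min_window = 0.5)
  expect_setequal(ref$control_ids, c("s2", "s3", "s4"))  # ages 4, 5, 6

  # k beyond the cohort uses every control of that sex
  ref_all <- matched_reference(cc, "male", age = 5, k = 50)
  expect_length(ref_all$control_ids, 5L)

  # fewer than 5 controls of the requested sex is an error
  expect_error(matched_reference(cc, "female", age = 5), "insufficient")

  # identical control surfaces: mean is the surface, SD clamps to the floor
  cc0 <- toy_cc(ages = c(6, 7, 8, 9, 10), jitter = 0)
  ref0 <- matched_reference(cc0, "male", age = 8, sd_floor = 0.05)
  expect_equal(ref0$ref_mean, cc0$points[[1]])
  expect_true(all(ref0$ref_sd == 0.05))
  expect_true(all(ref0$ref_sd_normal == 0.05))
})

test_that("the minimum age window widens the matched set when ties demand it", {
  cc <- toy_cc(ages = c(8, 8.5, 9.1, 9.2, 9.4, 12), jitter = 0.3)
  # k = 2 would take {9.1, 9.2}; the 2-year window must also catch 8.5, 9.4, 8
  ref <- matched_reference(cc, "male", age = 9, k = 2, min_window = 2)
  expect_setequal(ref$control_ids, c("s1", "s2", "s3", "s4", "s5"))
})

test_that("signatures vanish at the reference and follow the sign convention", {
  cc <- toy_cc(ages = 5:12, jitter = 0.4)
  ref <- matched_reference(cc, "male", age = 8, k = 8)
  sig0 <- signature(ref$ref_mean, ref)
  expect_true(all(sig0$raw == 0))
  expect_true(all(sig0$normal == 0))
  expect_equal(sig0$weight, 0)

  # +1 SD outward along every reference normal: normal component is +1
  face <- ref$ref_mean + ref$ref_sd_normal * ref$normals
  sig1 <- signature(face, ref)
  expect_equal(sig1$normal, rep(1, nrow(ref$ref_mean)), tolerance = 1e-9)
  expect_true(all(sig1$normal_raw > 0))  # outward is positive

  expect_error(signature(ref$ref_mean[1:5, ], ref), "dimension")
})

test_that("signature weight equals the brute-force accumulation oracle", {
  set.seed(33)
  for (rep in 1:100) {
    N <- sample(5:40, 1)
    norm_comp <- matrix(rnorm(3 * N, 0, 2), N, 3)
    w <- signature_weight(norm_comp)
    acc <- 0
    for (i in seq_len(N)) for (j in 1:3) acc <- acc + norm_comp[i, j]^2
    expect_equal(w, sqrt(acc), tolerance = 1e-10)
  }
  # single point displaced (3, 4, 0) in SD units: weight 5
  m <- matrix(0, 10, 3); m[4, ] <- c(3, 4, 0)
  expect_equal(signature_weight(m), 5)
})

test_that("weight scales exactly linearly with raw displacement", {
  cc <- toy_cc(ages = 5:12, jitter = 0.4)
  ref <- matched_reference(cc, "male", age = 8, k = 8)
  set.seed(4)
  delta <- matrix(rnorm(3 * nrow(ref$ref_mean), 0, 0.5),
                  nrow(ref$ref_mean), 3)
  w1 <- signature(ref$ref_mean + delta, ref)$weight
  w3 <- signature(ref$ref_mean + 3 * delta, ref)$weight
  expect_equal(w3, 3 * w1, tolerance = 1e-9)
})

test_that("heat-map colors: green at zero, saturating red/blue at the scale", {
  mk_sig <- function(v) structure(list(normal = v,
                                       normalized = cbind(v, v, v)),
                                  class = "face_signature")
  v <- c(0, -2, 2, -7, 7, 1, -1)
  cols <- heatmap_colors(mk_sig(v), "normal", scale = 2)
  expect_equal(cols[1, ], c(red = 0, green = 1, blue = 0))
  expect_equal(cols[2, ], c(red = 1, green = 0, blue = 0))
  expect_equal(cols[3, ], c(red = 0, green = 0, blue = 1))
  # beyond the scale saturates to the same extreme hue
  expect_equal(cols[4, ], cols[2, ])
  expect_equal(cols[5, ], cols[3, ])
  # linear in between
  expect_equal(cols[6, ], c(red = 0, green = 0.5, blue = 0.5))
  expect_equal(cols[7, ], c(red = 0.5, green = 0.5, blue = 0))
  expect_error(heatmap_colors(mk_sig(v), "normal", scale = 0), "scale")
  # axial channels read the requested column
  cx <- heatmap_colors(mk_sig(v), "x", scale = 2)
  expect_equal(cx, cols)
})

test_that("cohort signature weights separate patients from held-out controls", {
  cfg <- cohort_config(groups = list(
    control = list(n = 24, age_range = c(4, 20)),
    CS = list(n = 10, age_range = c(4, 20),
              effects = syndrome_effect_fields(1.5))),
    resolution = 700, seed = 17)
  cc <- correspond_cohort(generate_cohort(cfg, template = fix_template(700)))
  w <- cohort_signature_weights(cc, k = 12)
  expect_equal(nrow(w), 34L)
  expect_true(all(w$weight > 0))
  # patients (effect >= 1 mm) carry more dysmorphism than held-out controls
  expect_gt(mean(w$weight[w$group == "CS"]),
            mean(w$weight[w$group == "control"]))
})
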