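test_that("GPA removes rigid pose differences without scaling", {
  lm <- asym_landmarks()
  lm2 <- lm %*% t(rotmat(30)) + rep(c(5, 0, 0), each = nrow(lm))
  res <- procrustes_align(list(lm, lm2))
  expect_lt(sqrt(mean((res$aligned[[1]] - res$aligned[[2]])^2)), 1e-6)
  # no scaling: centroid size is preserved
  csize <- function(m) sqrt(sum(scale(m, scale = FALSE)^2))
  expect_equal(csize(res$aligned[[1]]), csize(lm), tolerance = 1e-9)

  # duplicated set: mean is the centered set
  res2 <- procrustes_align(list(lm, lm, lm))
  expect_equal(res2$mean, scale(lm, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_lt(max(abs(colMeans(res2$mean))), 1e-9)

  # reflections are not matched: a mirrored set stays distant
  lm_mirror <- lm; lm_mirror[, 1] <- -lm_mirror[, 1]
  res3 <- procrustes_align(list(lm, lm_mirror))
  expect_gt(sqrt(mean((res3$aligned[[1]] - res3$aligned[[2]])^2)), 1)

  # collinear configurations are rejected
  line <- cbind(1:22, 2 * (1:22), -1 * (1:22))
  expect_error(procrustes_align(list(line, line)), "collinear")
})

test_that("rigid alignment residual agrees with the vegan Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(11)
  X <- asym_landmarks()
  Y <- X + matrix(rnorm(length(X), 0, 2), nrow(X))
  tf <- kabsch(X, Y)
  rss_ours <- sum((tf$apply(X) - Y)^2)
  # vegan solves the same rigid superimposition of X onto Y;
  # with scale = FALSE and symmetric = FALSE it is the pairwise oracle
  vp <- vegan::procrustes(Y, X, scale = FALSE, symmetric = FALSE)
  expect_equal(rss_ours, sum(residuals(vp)^2), tolerance = 1e-8)
})

test_that("TPS warp interpolates, reproduces rigid maps, rejects coincident landmarks", {
  tpl <- fix_template(800)
  blm <- tpl$landmarks
  # identity: target = base landmarks
  w <- tps_warp(tpl$vertices, blm, blm, lambda = 0)
  expect_lt(max(abs(w - tpl$vertices)), 1e-6)

  # affine reproduction: rigid target moves all vertices rigidly
  R <- rotmat(20, c(0.1, 1, 0.3)); tr <- c(4, -7, 11)
  tlm <- blm %*% t(R) + rep(tr, each = nrow(blm))
  w2 <- tps_warp(tpl$vertices, blm, tlm)  # default lambda
  expected <- tpl$vertices %*% t(R) + rep(tr, each = nrow(tpl$vertices))
  expect_lt(max(abs(w2 - expected)), 1e-4)

  # lambda = 0 maps each base landmark exactly onto its target
  set.seed(3)
  tlm2 <- blm + matrix(rnorm(length(blm), 0, 3), nrow(blm))
  fit <- tps_fit(blm, tlm2, lambda = 0)
  expect_lt(max(abs(tps_apply(fit, blm) - tlm2)), 1e-6)

  bad <- blm; bad[2, ] <- bad[1, ]
  expect_error(tps_fit(bad, tlm2), "coincident")
  expect_error(tps_fit(blm, tlm2, lambda = -1), "lambda")
})

test_that("closest-point projection is exact point-to-triangle geometry", {
  # one large triangle in the z = 0 plane
  tri_mesh <- list(vertices = rbind(c(-10, -10, 0), c(10, -10, 0), c(0, 10, 0)),
                   triangles = rbind(c(1L, 2L, 3L)))
  # a point on the triangle stays put
  p_on <- rbind(c(0, 0, 0))
  r1 <- project_to_surface(p_on, tri_mesh)
  expect_equal(r1$points, p_on, tolerance = 1e-12)
  expect_false(any(r1$miss))
  # height h above the interior projects to the foot at distance h
  r2 <- project_to_surface(rbind(c(1, 2, 5)), tri_mesh)
  expect_equal(r2$points[1, ], c(1, 2, 0))
  expect_equal(r2$distance[1], 5)
  # beyond max_distance: kept and flagged
  far <- rbind(c(0, 0, 50))
  r3 <- project_to_surface(far, tri_mesh, max_distance = 10)
  expect_equal(r3$points, far)
  expect_true(r3$miss[1])
  # closest point to a query beyond an edge lands on the edge/vertex
  r4 <- project_to_surface(rbind(c(20, -10, 0)), tri_mesh)
  expect_equal(r4$points[1, ], c(10, -10, 0))
})

test_that("projection matches a brute-force all-triangle scan on a face patch", {
  tpl <- fix_template(800)
  set.seed(8)
  q <- tpl$vertices[sample(nrow(tpl$vertices), 30), ] +
    matrix(rnorm(90, 0, 3), 30, 3)
  res <- project_to_surface(q, tpl, max_distance = Inf)
  # independent oracle: exhaustive point-to-triangle minimization in R
  tri_pts <- function(t) tpl$vertices[tpl$triangles[t, ], ]
  closest_tri <- function(p, a, b, c_) {
    # minimize |a + s(b-a) + t(c-a) - p| over the triangle (active-set on
    # the barycentric constraints via fine sampling + local refinement)
    E <- cbind(b - a, c_ - a)
    st <- tryCatch(solve(crossprod(E), crossprod(E, p - a)),
                   error = function(e) c(0, 0))
    s <- st[1]; t_ <- st[2]
    cand <- rbind(c(s, t_), c(0, 0), c(1, 0), c(0, 1))
    gr <- as.matrix(expand.grid(s = seq(0, 1, length.out = 41),
                                t = seq(0, 1, length.out = 41)))
    gr <- gr[rowSums(gr) <= 1, ]
    cand <- rbind(cand, gr)
    cand <- cand[cand[, 1] >= 0 & cand[, 2] >= 0 & rowSums(cand) <= 1, ,
                 drop = FALSE]
    pts <- matrix(a, nrow(cand), 3, byrow = TRUE) + cand %*% t(E)
    min(sqrt(rowSums((pts - matrix(p, nrow(cand), 3, byrow = TRUE))^2)))
  }
  for (i in seq_len(10)) {
    d_brute <- min(vapply(seq_len(nrow(tpl$triangles)), function(t) {
      v <- tri_pts(t)
      closest_tri(q[i, ], v[1, ], v[2, ], v[3, ])
    }, numeric(1)))
    expect_lt(abs(res$distance[i] - d_brute), 0.05)
    expect_lte(res$distance[i], d_brute + 1e-9)
  }
})

test_that("corresponding a cohort of base copies reproduces the base", {
  tpl <- fix_template(800)
  mk <- function(id) {
    m <- landmarked_mesh(tpl$vertices, tpl$triangles, tpl$landmarks,
                         subject_meta(id, "male", 10, "control"))
    m
  }
  cc <- correspond_cohort(list(a = mk("a"), b = mk("b"), c = mk("c")),
                          base = tpl)
  for (i in 1:3) expect_lt(max(abs(cc$points[[i]] - tpl$vertices)), 1e-6)
  expect_equal(cc$miss_fraction, rep(0, 3))

  # rigidly transformed copies come back to the base frame
  subs <- list(a = mk("a"), b = rigid_copy(mk("b")),
               c = rigid_copy(mk("c"), deg = -40, trans = c(-20, 8, 3)))
  cc2 <- correspond_cohort(subs, base = tpl)
  for (i in 1:3)
    expect_lt(sqrt(mean((cc2$points[[i]] - tpl$vertices)^2)), 1e-3)
  # rotations are proper
  for (al in cc2$alignment) {
    expect_equal(crossprod(al$R), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(det(al$R), 1, tolerance = 1e-9)
  }
})

test_that("corresponded cohorts have fixed topology and low miss fractions", {
  cc <- fix_study_cc()
  expect_equal(length(cc$points), 36L)
  expect_true(all(vapply(cc$points, nrow, integer(1)) == cc$n_points))
  expect_true(all(vapply(cc$points, function(p) all(is.finite(p)), logical(1))))
  expect_lt(mean(cc$miss_fraction), 0.01)

  # a subject without landmarks aborts before processing
  coh <- generate_cohort(study_config(n_control = 3, n_cs = 2,
                                      resolution = 700, seed = 13))
  coh$subjects[[2]]$landmarks <- NULL
  expect_error(correspond_cohort(coh$subjects, base = coh$template),
               "missing landmarks")
})
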