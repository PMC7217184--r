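# Shared fixtures, lazily built and cached for the whole test session.
# Templates at reduced resolution keep the suite fast; the full-scale
# configuration is exercised once in the acceptance tests.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fix_template <- function(res = 800) {
  cached(paste0("tpl_", res), make_template(res))
}

# two groups identical except for the injected syndrome effect fields;
# narrow age band so the group contrast is the effect itself
two_group_config <- function(amplitude, seed, n = 20, res = 700,
                             age_range = c(9, 11), noise_sd = 0.2) {
  cohort_config(groups = list(
    A = list(n = n, effects = list(), age_range = age_range),
    B = list(n = n, effects = syndrome_effect_fields(amplitude),
             age_range = age_range)),
    resolution = res, noise_sd = noise_sd, seed = seed)
}

# small study-like corresponded cohort reused across test files
fix_study_cc <- function() {
  cached("study_cc", {
    coh <- generate_cohort(study_config(n_control = 24, n_cs = 12,
                                        resolution = 800, seed = 2))
    correspond_cohort(coh)
  })
}

# a deliberately asymmetric landmark configuration (not collinear, not
# mirror-symmetric) for Procrustes tests
asym_landmarks <- function() {
  set.seed(42)
  k <- 22
  m <- cbind(runif(k, -40, 40), runif(k, -60, 60), runif(k, 0, 50))
  m[1, ] <- c(35, 10, 5)  # break any accidental symmetry
  m
}

rotmat <- function(deg, axis = c(0, 1, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rigid_copy <- function(mesh, deg = 25, axis = c(0.2, 1, 0.4),
                       trans = c(12, -5, 30)) {
  R <- rotmat(deg, axis)
  out <- mesh
  out$vertices <- mesh$vertices %*% t(R) + rep(trans, each = nrow(mesh$vertices))
  if (!is.null(mesh$landmarks)) {
    out$landmarks <- mesh$landmarks %*% t(R) +
      rep(trans, each = nrow(mesh$landmarks))
  }
  out
}
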