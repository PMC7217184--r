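## Synthetic face template: a smooth height-field surface over an elliptical
## domain (half-ellipsoid dome) with Gaussian feature bumps (nose ridge and
## tip, alae, lips, chin, brow ridges), exactly bilaterally symmetric about
## x = 0. Coordinates are mm: +x subject-left, +y up, +z out of the face.

TEMPLATE_HALF_WIDTH <- 70   # mm, semi-axis in x
TEMPLATE_HALF_HEIGHT <- 95  # mm, semi-axis in y
TEMPLATE_DEPTH <- 55        # mm, dome depth in z
TEMPLATE_NOSE_WIDTH <- 30   # mm, nominal alare_l - alare_r separation

# nominal (x, y) landmark positions on the template, mm; left = +x
template_landmark_targets <- function() {
  m <- rbind(
    glabella = c(0, 38), nasion = c(0, 30),
    endocanthion_l = c(12, 26), endocanthion_r = c(-12, 26),
    exocanthion_l = c(32, 25), exocanthion_r = c(-32, 25),
    palpebrale_superius_l = c(22, 29), palpebrale_superius_r = c(-22, 29),
    palpebrale_inferius_l = c(22, 22), palpebrale_inferius_r = c(-22, 22),
    pronasale = c(0, -2), subnasale = c(0, -12),
    alare_l = c(TEMPLATE_NOSE_WIDTH / 2, -6),
    alare_r = c(-TEMPLATE_NOSE_WIDTH / 2, -6),
    labiale_superius = c(0, -24), labiale_inferius = c(0, -38),
    crista_philtri_l = c(5, -23), crista_philtri_r = c(-5, -23),
    chelion_l = c(24, -31), chelion_r = c(-24, -31),
    pogonion = c(0, -55), gnathion = c(0, -68))
  colnames(m) <- c("x", "y")
  m[landmark_schema(), , drop = FALSE]
}

gauss2 <- function(x, y, x0, y0, sx, sy, a) {
  a * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2)))
}

# facial relief added to the dome; symmetric in x by construction
template_relief <- function(x, y) {
  gauss2(x, y, 0, 10, 6.5, 17, 14) +                       # nasal ridge
    gauss2(x, y, 0, -3, 7, 6, 7) +                         # nasal tip
    gauss2(x, y, 15, -6, 5, 5, 4) +                        # ala L
    gauss2(x, y, -15, -6, 5, 5, 4) +                       # ala R
    gauss2(x, y, 0, -30, 16, 7.5, 6) +                     # lips
    gauss2(x, y, 0, -57, 10, 9, 7) +                       # chin boss
    gauss2(x, y, 22, 36, 12, 5, 4) +                       # brow L
    gauss2(x, y, -22, 36, 12, 5, 4) -                      # brow R
    gauss2(x, y, 22, 25, 9, 5, 3) -                        # orbit L
    gauss2(x, y, -22, 25, 9, 5, 3)                         # orbit R
}

template_height <- function(x, y) {
  r2 <- pmin(1, (x / TEMPLATE_HALF_WIDTH)^2 + (y / TEMPLATE_HALF_HEIGHT)^2)
  TEMPLATE_DEPTH * sqrt(1 - r2) + template_relief(x, y)
}

# region predicates on (x, y); philtrum/lips/chin are pairwise disjoint
template_region_defs <- list(
  nose     = function(x, y) abs(x) <= 19 & y >= -13 & y <= 28,
  philtrum = function(x, y) abs(x) <= 7 & y >= -24 & y < -13,
  lips     = function(x, y) abs(x) <= 26 & y >= -38 & y < -24,
  chin     = function(x, y) abs(x) <= 20 & y >= -70 & y < -44,
  brow     = function(x, y) abs(x) >= 8 & abs(x) <= 34 & y >= 31 & y <= 42,
  cheeks   = function(x, y) abs(x) >= 26 & abs(x) <= 60 & y >= -30 & y <= 15,
  forehead = function(x, y) y >= 45)

#' Build the synthetic face template
#'
#' Constructs a smooth, bilaterally symmetric face-like surface (elliptical
#' dome plus Gaussian feature relief for nose, alae, lips, chin and brow),
#' places all 22 schema landmarks on template vertices, and attaches named
#' region masks (nose, philtrum, lips, chin, brow, cheeks, forehead).
#'
#' @param resolution Target vertex count (>= 500); the realized count is
#'   within 20% of the target.
#' @return A `face_template`: a [landmarked_mesh()] with additional elements
#'   `landmark_index` (named vertex indices), `regions` (named integer
#'   vectors of vertex indices) and `grid` spacing info.
#' @export
#' @examples
#' tpl <- make_template(1000)
#' tpl
make_template <- function(resolution = 5000) {
  if (!is.numeric(resolution) || resolution < 500)
    stop("resolution too small to place landmarks (need >= 500)")
  # grid sized so that ~pi/4 of the rectangle falls inside the ellipse;
  # odd column count keeps an exact x = 0 column for symmetry
  nu <- ceiling(sqrt(resolution / (pi / 4) *
                       TEMPLATE_HALF_WIDTH / TEMPLATE_HALF_HEIGHT))
  if (nu %% 2L == 0L) nu <- nu + 1L
  nv <- ceiling(nu * TEMPLATE_HALF_HEIGHT / TEMPLATE_HALF_WIDTH)
  us <- seq(-1, 1, length.out = nu)
  vs <- seq(-1, 1, length.out = nv)
  gx <- outer(us * TEMPLATE_HALF_WIDTH, rep(1, nv))
  gy <- outer(rep(1, nu), vs * TEMPLATE_HALF_HEIGHT)
  inside <- outer(us^2, vs^2, `+`) <= 1 + 1e-12
  vid <- matrix(0L, nu, nv)
  vid[inside] <- seq_len(sum(inside))
  x <- gx[inside]; y <- gy[inside]
  z <- template_height(x, y)
  verts <- cbind(x = x, y = y, z = z)

  tris <- list()
  for (j in seq_len(nv - 1L)) {
    for (i in seq_len(nu - 1L)) {
      a <- vid[i, j]; b <- vid[i + 1L, j]
      c_ <- vid[i + 1L, j + 1L]; d <- vid[i, j + 1L]
      corners <- c(a, b, c_, d)
      k <- sum(corners > 0L)
      if (k == 4L) {
        tris[[length(tris) + 1L]] <- c(a, b, c_)
        tris[[length(tris) + 1L]] <- c(a, c_, d)
      } else if (k == 3L) {
        tris[[length(tris) + 1L]] <- corners[corners > 0L]
      }
    }
  }
  tri <- do.call(rbind, tris)

  # landmark vertices: nearest grid node to each nominal position; right-side
  # landmarks use the mirrored node of their left partner so pairs are exact
  targets <- template_landmark_targets()
  schema <- landmark_schema()
  lidx <- integer(length(schema)); names(lidx) <- schema
  iu_mirror <- function(iu) nu + 1L - iu
  node_of <- function(tx, ty) {
    iu <- which.min(abs(us * TEMPLATE_HALF_WIDTH - tx))
    iv <- which.min(abs(vs * TEMPLATE_HALF_HEIGHT - ty))
    c(iu, iv)
  }
  for (nm in schema) {
    if (endsWith(nm, "_r")) next
    n_ <- node_of(targets[nm, 1], targets[nm, 2])
    if (vid[n_[1], n_[2]] == 0L) stop("landmark node outside template: ", nm)
    lidx[nm] <- vid[n_[1], n_[2]]
    if (endsWith(nm, "_l")) {
      rm_ <- sub("_l$", "_r", nm)
      lidx[rm_] <- vid[iu_mirror(n_[1]), n_[2]]
    }
  }
  if (anyDuplicated(lidx)) stop("template resolution too coarse: landmark ",
                                "nodes collide; increase resolution")

  regions <- lapply(template_region_defs, function(f) which(f(x, y)))
  if (any(vapply(regions, length, integer(1)) == 0L))
    stop("empty template region mask; increase resolution")

  lm <- verts[lidx, , drop = FALSE]
  rownames(lm) <- schema
  tpl <- landmarked_mesh(verts, tri, landmarks = lm)
  tpl$landmark_index <- lidx
  tpl$regions <- regions
  tpl$grid <- list(nu = nu, nv = nv,
                   du = 2 * TEMPLATE_HALF_WIDTH / (nu - 1),
                   dv = 2 * TEMPLATE_HALF_HEIGHT / (nv - 1))
  class(tpl) <- c("face_template", class(tpl))
  tpl
}

#' @export
print.face_template <- function(x, ...) {
  cat("Synthetic face template:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles, 22 landmarks,",
      length(x$regions), "region masks\n")
  invisible(x)
}
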