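## Surface mesh, landmark and heat-map file I/O.
## OBJ and PLY (ASCII + binary little-endian) are parsed here directly; binary
## PLY vertex coordinates are written as doubles so round-trips hold to 1e-6 mm.

PLY_TYPE_SIZE <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_prop <- function(raw, offsets, type) {
  size <- PLY_TYPE_SIZE[[type]]
  idx <- as.vector(outer(0:(size - 1L), offsets, `+`)) + 1L
  bytes <- raw[idx]
  what <- switch(type,
                 float = , float32 = , double = , float64 = "double",
                 "integer")
  sz <- if (what == "double") size else size
  signed <- !type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")
  out <- readBin(bytes, what = what, n = length(offsets), size = sz,
                 signed = if (what == "integer" && size < 4L) signed else TRUE,
                 endian = "little")
  as.numeric(out)
}

fan_split <- function(poly) {
  # split a polygon (1-based vertex indices, cyclic order) into triangles by
  # a fan rooted at the lowest-index vertex, preserving winding
  k <- length(poly)
  if (k < 3L) stop("face with fewer than 3 vertices")
  r <- which.min(poly)
  poly <- c(poly[r:k], poly[seq_len(r - 1L)])
  if (k == 3L) return(matrix(poly, 1L, 3L))
  t(vapply(2:(k - 1L), function(i) c(poly[1L], poly[i], poly[i + 1L]),
           integer(3)))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before element")
      if (tok[2] == "list")
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE,
                                                count_type = tok[3],
                                                item_type = tok[4])
      else
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt %||% "<missing>")
  if (!all(c("vertex", "face") %in% names(elements)))
    stop("PLY must contain vertex and face elements")

  out <- list()
  if (fmt == "ascii") {
    lines <- readLines(con)
    lines <- lines[nzchar(trimws(lines))]
    pos <- 0L
    for (el in names(elements)) {
      e <- elements[[el]]
      if (e$n == 0L) { out[[el]] <- NULL; next }
      block <- lines[(pos + 1L):(pos + e$n)]
      pos <- pos + e$n
      toks <- strsplit(trimws(block), "\\s+")
      if (el == "vertex") {
        vals <- matrix(as.numeric(unlist(toks)), nrow = e$n, byrow = TRUE)
        colnames(vals) <- names(e$props)
        out$vertex <- vals
      } else if (el == "face") {
        out$face <- lapply(toks, function(x) as.integer(x[-1]) + 1L)
      }
    }
  } else {
    payload <- readBin(con, "raw", n = file.size(path))
    off <- 0L
    for (el in names(elements)) {
      e <- elements[[el]]
      if (any(vapply(e$props, function(p) isTRUE(p$list), logical(1)))) {
        # list element (faces): detect homogeneous polygon size, else loop
        p <- e$props[[1]]
        csz <- PLY_TYPE_SIZE[[p$count_type]]; isz <- PLY_TYPE_SIZE[[p$item_type]]
        first_n <- ply_read_prop(payload, off, p$count_type)
        rec <- csz + first_n * isz
        faces <- vector("list", e$n)
        if (off + e$n * rec <= length(payload) &&
            all(ply_read_prop(payload, off + (0:(e$n - 1L)) * rec,
                              p$count_type) == first_n)) {
          starts <- off + (0:(e$n - 1L)) * rec + csz
          idx <- as.vector(outer((0:(first_n - 1L)) * isz, starts, `+`))
          vals <- ply_read_prop(payload, idx, p$item_type)
          faces <- lapply(seq_len(e$n), function(i)
            as.integer(vals[((i - 1L) * first_n + 1L):(i * first_n)]) + 1L)
          off <- off + e$n * rec
        } else {
          for (i in seq_len(e$n)) {
            cnt <- as.integer(ply_read_prop(payload, off, p$count_type))
            faces[[i]] <- as.integer(
              ply_read_prop(payload, off + csz + (0:(cnt - 1L)) * isz,
                            p$item_type)) + 1L
            off <- off + csz + cnt * isz
          }
        }
        out[[el]] <- faces
      } else {
        sizes <- vapply(e$props, function(p) PLY_TYPE_SIZE[[p$type]], integer(1))
        rec <- sum(sizes)
        starts <- off + (0:(e$n - 1L)) * rec
        vals <- matrix(0, e$n, length(sizes), dimnames = list(NULL, names(sizes)))
        po <- 0L
        for (j in seq_along(sizes)) {
          vals[, j] <- ply_read_prop(payload, starts + po, e$props[[j]]$type)
          po <- po + sizes[j]
        }
        off <- off + e$n * rec
        out[[el]] <- vals
      }
    }
  }
  out
}

#' Read a triangular surface mesh
#'
#' Reads an OBJ or PLY (ASCII or binary little-endian) surface. Polygonal
#' faces with more than three vertices are triangulated deterministically by a
#' fan split rooted at the lowest vertex index. Per-vertex RGB colors in a PLY
#' are returned (rescaled to `[0, 1]`) in the `colors` element.
#'
#' @param path Path to a `.obj` or `.ply` file.
#' @return A [landmarked_mesh()] without landmarks (and with `colors` if the
#'   file stores per-vertex color).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    lines <- readLines(path, warn = FALSE)
    vlines <- lines[startsWith(lines, "v ")]
    flines <- lines[startsWith(lines, "f ")]
    if (length(vlines) == 0L || length(flines) == 0L)
      stop("empty mesh: zero vertices or zero triangles in ", path)
    vt <- strsplit(trimws(sub("^v", "", vlines)), "\\s+")
    verts <- matrix(as.numeric(unlist(lapply(vt, `[`, 1:3))),
                    ncol = 3, byrow = TRUE)
    polys <- lapply(strsplit(trimws(sub("^f", "", flines)), "\\s+"),
                    function(x) as.integer(sub("/.*$", "", x)))
    if (any(unlist(polys) < 0L)) stop("negative OBJ indices not supported")
    tri <- do.call(rbind, lapply(polys, fan_split))
    mesh <- landmarked_mesh(verts, tri)
  } else if (ext == "ply") {
    p <- read_ply(path)
    vcols <- colnames(p$vertex)
    if (!all(c("x", "y", "z") %in% vcols)) stop("PLY lacks x/y/z properties")
    verts <- p$vertex[, c("x", "y", "z"), drop = FALSE]
    if (length(p$face) == 0L) stop("empty mesh: zero triangles in ", path)
    tri <- do.call(rbind, lapply(p$face, fan_split))
    mesh <- landmarked_mesh(verts, tri)
    if (all(c("red", "green", "blue") %in% vcols))
      mesh$colors <- p$vertex[, c("red", "green", "blue"), drop = FALSE] / 255
  } else stop("unsupported mesh format: .", ext, " (expected .obj or .ply)")
  mesh
}

#' Write a triangular surface mesh
#'
#' @param mesh A [landmarked_mesh()] (landmarks are not written; see
#'   [write_landmarks()]).
#' @param path Output `.obj` or `.ply` path; format follows the extension.
#' @param binary For PLY, write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; tr <- mesh$triangles
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  } else if (ext == "ply") {
    write_ply(path, v, tr, colors = NULL, binary = binary)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

write_ply <- function(path, vertices, triangles, colors = NULL, binary = TRUE) {
  n <- nrow(vertices); m <- nrow(triangles)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", n),
           "property double x", "property double y", "property double z",
           if (!is.null(colors)) c("property uchar red", "property uchar green",
                                   "property uchar blue"),
           paste("element face", m),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    if (is.null(colors)) {
      writeBin(as.vector(t(vertices)), con, size = 8, endian = "little")
    } else {
      cb <- as.integer(round(pmin(pmax(colors, 0), 1) * 255))
      for (i in seq_len(n)) {
        writeBin(vertices[i, ], con, size = 8, endian = "little")
        writeBin(as.raw(cb[i + n * (0:2)]), con)
      }
    }
    for (i in seq_len(m)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(triangles[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    if (is.null(colors)) {
      writeLines(sprintf("%.12g %.12g %.12g",
                         vertices[, 1], vertices[, 2], vertices[, 3]), con)
    } else {
      cb <- round(pmin(pmax(colors, 0), 1) * 255)
      writeLines(sprintf("%.12g %.12g %.12g %d %d %d",
                         vertices[, 1], vertices[, 2], vertices[, 3],
                         cb[, 1], cb[, 2], cb[, 3]), con)
    }
    writeLines(sprintf("3 %d %d %d", triangles[, 1] - 1L,
                       triangles[, 2] - 1L, triangles[, 3] - 1L), con)
  }
  invisible(path)
}

#' Write a per-vertex colored heat-map mesh
#'
#' Writes a PLY surface with 8-bit per-vertex colors (as produced by
#' [heatmap_colors()]); re-reading with [read_mesh()] recovers the colors
#' within the 1/255 quantization.
#'
#' @param path Output `.ply` path.
#' @param vertices n x 3 point matrix (mm).
#' @param triangles m x 3 triangle index matrix.
#' @param colors n x 3 RGB matrix with entries in `[0, 1]`.
#' @param binary Write binary little-endian PLY (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_heatmap_mesh <- function(path, vertices, triangles, colors, binary = TRUE) {
  colors <- as.matrix(colors)
  if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
    stop("colors must be one RGB triple per vertex (",
         nrow(vertices), " expected, got ", nrow(colors), ")")
  if (any(colors < 0) || any(colors > 1)) stop("colors must lie in [0, 1]")
  write_ply(path, as.matrix(vertices), as.matrix(triangles), colors, binary)
}

#' Read a landmark table
#'
#' Reads a `name,x,y,z` CSV and returns the landmarks in canonical schema
#' order regardless of row order in the file.
#'
#' @param path CSV path.
#' @param schema Ordered landmark name vector (default [landmark_schema()]).
#' @return A 22 x 3 matrix with schema rownames.
#' @export
read_landmarks <- function(path, schema = landmark_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(df)))
    stop("landmark file must have columns name,x,y,z: ", path)
  missing <- setdiff(schema, df$name)
  extra <- setdiff(df$name, schema)
  if (length(missing) || length(extra))
    stop("landmark schema mismatch in ", path, "; missing: [",
         paste(missing, collapse = ", "), "]; extra: [",
         paste(extra, collapse = ", "), "]")
  m <- as.matrix(df[match(schema, df$name), c("x", "y", "z")])
  rownames(m) <- schema
  m
}

#' Write a landmark table
#'
#' @param landmarks 22 x 3 matrix with schema rownames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_landmarks(landmarks)
  df <- data.frame(name = rownames(landmarks),
                   x = landmarks[, 1], y = landmarks[, 2], z = landmarks[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
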