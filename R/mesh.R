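#' Construct a triangulated surface mesh
#'
#' Vertices are in millimetres. Degenerate (zero-area) faces are dropped at
#' construction; face indices are validated.
#'
#' @param vertices numeric n x 3 matrix, mm.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param surface_class `"skin"` or `"bone"`.
#' @param stage `"pre"`, `"post"` or `"predicted"`.
#' @param area_tol faces with area below this (mm^2) are removed.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, surface_class = c("skin", "bone"),
                         stage = c("pre", "post", "predicted"),
                         area_tol = 1e-12) {
  surface_class <- match.arg(surface_class)
  stage <- match.arg(stage)
  vertices <- as_points_matrix(vertices)
  assert_finite_matrix(vertices, "mesh vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stopf("faces must be an m x 3 index matrix")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stopf("face indices out of range [1, %d]", nrow(vertices))
  if (nrow(faces)) {
    a <- face_areas(vertices, faces)
    faces <- faces[a > area_tol, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces,
                 surface_class = surface_class, stage = stage),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s/%s: %d vertices, %d faces\n",
              x$surface_class, x$stage, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  e1 <- vertices[faces[, 2L], , drop = FALSE] - a
  e2 <- vertices[faces[, 3L], , drop = FALSE] - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  0.5 * row_norms(cr)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  cr / pmax(row_norms(cr), .Machine$double.xmin)
}

# Angle-weighted vertex normals (Thurmer & Wuthrich): robust pseudo-normals
# for the inside/outside sign of the distance map.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh)
  n <- matrix(0, nrow(v), 3L)
  corner_angle <- function(p, q, r) {
    u <- q - p; w <- r - p
    cosang <- rowSums(u * w) / pmax(row_norms(u) * row_norms(w), 1e-300)
    acos(pmin(pmax(cosang, -1), 1))
  }
  va <- v[f[, 1L], , drop = FALSE]
  vb <- v[f[, 2L], , drop = FALSE]
  vc <- v[f[, 3L], , drop = FALSE]
  ang <- cbind(corner_angle(va, vb, vc), corner_angle(vb, vc, va),
               corner_angle(vc, va, vb))
  for (k in 1:3) {
    acc <- rowsum(ang[, k] * fn, group = f[, k])
    idx <- as.integer(rownames(acc))
    n[idx, ] <- n[idx, ] + acc
  }
  n / pmax(row_norms(n), .Machine$double.xmin)
}

# TRUE when every shared edge is traversed once in each direction (consistent
# orientation, edge-manifold). Boundary edges are allowed.
is_consistently_oriented <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(he[, 1L], he[, 2L])
  if (anyDuplicated(key)) return(FALSE)   # same directed edge twice
  rkey <- paste(he[, 2L], he[, 1L])
  cnt <- table(c(key, rkey))
  all(cnt <= 2L)
}

#' Query the closest point on a triangle mesh
#'
#' Exhaustive triangle-exact search: for each query point the returned point
#' lies on the closed triangle `face`, `distance` is the Euclidean distance
#' from the query, and no point on any other triangle is strictly closer.
#' Ties are resolved to the lowest face index.
#'
#' @param query a 3-vector or n x 3 matrix of query points (mm).
#' @param mesh a `surface_mesh`.
#' @return list with `points` (n x 3), `face` (index), `distance` (mm) and
#'   `bary` (barycentric coordinates of the foot point in its face).
#' @export
closest_point_on_mesh <- function(query, mesh) {
  if (nrow(mesh$faces) == 0L) stopf("mesh has no faces")
  q <- as_points_matrix(query)
  assert_finite_matrix(q, "query points")
  .closest_points_cpp(q, mesh$vertices, mesh$faces)
}

# ---- mesh file IO ---------------------------------------------------------

#' Read a triangle mesh (OBJ, PLY or STL)
#'
#' Supports Wavefront OBJ (v/f records, polygonal faces fan-triangulated),
#' PLY (ascii and binary little-endian) and STL (ascii and binary). All
#' coordinates are taken to be millimetres.
#'
#' @param path mesh file; format from the extension.
#' @param surface_class,stage labels attached to the returned mesh.
#' @return a `surface_mesh`
#' @export
read_mesh <- function(path, surface_class = "skin", stage = "pre") {
  ext <- tolower(tools::file_ext(path))
  vf <- switch(ext,
               obj = .read_obj(path),
               ply = .read_ply(path),
               stl = .read_stl(path),
               stopf("unsupported mesh extension: '%s'", ext))
  surface_mesh(vf$vertices, vf$faces, surface_class = surface_class,
               stage = stage)
}

#' Write a triangle mesh (OBJ, PLY ascii/binary or STL ascii)
#' @param mesh a `surface_mesh`
#' @param path output file; format from the extension.
#' @param binary for PLY: write binary little-endian instead of ascii.
#' @param colors optional n x 3 integer matrix (0-255) of per-vertex RGB,
#'   written for PLY only.
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, binary = FALSE, colors = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = .write_obj(mesh, path),
         ply = .write_ply(mesh, path, binary = binary, colors = colors),
         stl = .write_stl_ascii(mesh, path),
         stopf("unsupported mesh extension: '%s'", ext))
  invisible(path)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                             function(s) as.numeric(s[1:3])))
  faces <- list()
  for (fl in flines) {
    toks <- strsplit(trimws(sub("^f", "", fl)), "\\s+")[[1L]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1L))
    for (k in seq_len(length(idx) - 2L))             # fan triangulation
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
}

.read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- character()
  repeat {
    line <- .read_line_bytes(con)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 500L) stopf("PLY header not terminated")
  }
  fmt_line <- grep("^format", header, value = TRUE)[1L]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1L]))
  # vertex property list (in order), to know how many scalars per vertex
  el_starts <- grep("^element", header)
  vprop_lines <- character(); fprop_lines <- character()
  for (i in seq_along(el_starts)) {
    from <- el_starts[i] + 1L
    to <- if (i < length(el_starts)) el_starts[i + 1L] - 1L else length(header) - 1L
    props <- grep("^property", header[from:to], value = TRUE)
    if (grepl("^element vertex", header[el_starts[i]])) vprop_lines <- props
    if (grepl("^element face", header[el_starts[i]])) fprop_lines <- props
  }
  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    v <- t(vapply(vtok, function(s) as.numeric(s[1:3]), numeric(3L)))
    ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- list()
    for (s in ftok) {
      n <- as.integer(s[1L]); idx <- as.integer(s[1L + seq_len(n)]) + 1L
      for (k in seq_len(n - 2L))
        faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
    }
    return(list(vertices = v, faces = do.call(rbind, faces)))
  }
  if (fmt != "binary_little_endian")
    stopf("unsupported PLY format '%s'", fmt)
  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L,
                 ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L, uint = 4L,
                 int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
                 double = 8L, float64 = 8L)
  vtypes <- vapply(strsplit(trimws(vprop_lines), "\\s+"), `[[`, "", 2L)
  if (any(!vtypes %in% names(type_size)))
    stopf("unsupported PLY vertex property type")
  v <- matrix(NA_real_, nv, 3L)
  for (i in seq_len(nv)) {
    vals <- numeric(length(vtypes))
    for (j in seq_along(vtypes)) {
      tp <- vtypes[j]; sz <- type_size[[tp]]
      vals[j] <- if (tp %in% c("float", "float32", "double", "float64")) {
        readBin(con, "double", 1L, size = sz, endian = "little")
      } else {
        readBin(con, "integer", 1L, size = sz, endian = "little",
                signed = !(tp %in% c("uchar", "uint8", "ushort", "uint16")))
      }
    }
    v[i, ] <- vals[1:3]
  }
  fl <- strsplit(trimws(fprop_lines[1L]), "\\s+")[[1L]]
  cnt_t <- fl[3L]; idx_t <- fl[4L]
  faces <- list()
  for (i in seq_len(nf)) {
    n <- readBin(con, "integer", 1L, size = type_size[[cnt_t]],
                 endian = "little",
                 signed = !(cnt_t %in% c("uchar", "uint8", "ushort", "uint16")))
    idx <- readBin(con, "integer", n, size = type_size[[idx_t]],
                   endian = "little") + 1L
    for (k in seq_len(n - 2L))
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

.read_line_bytes <- function(con) {
  bytes <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stopf("unexpected end of PLY header")
    if (b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  sub("\r$", "", rawToChar(bytes))
}

.write_ply <- function(mesh, path, binary = FALSE, colors = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(colors))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4L,
               endian = "little")
      if (!is.null(colors))
        writeBin(as.raw(colors[i, ]), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    if (is.null(colors)) {
      writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                         mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    } else {
      writeLines(sprintf("%.9g %.9g %.9g %d %d %d", mesh$vertices[, 1L],
                         mesh$vertices[, 2L], mesh$vertices[, 3L],
                         colors[, 1L], colors[, 2L], colors[, 3L]), con)
    }
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                       mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  }
}

.read_stl <- function(path) {
  # sniff: ascii STL starts with "solid" and contains "facet"
  head_bytes <- readBin(path, "raw", 512L)
  head_txt <- rawToChar(head_bytes[head_bytes != as.raw(0L)])
  if (grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("vertex", lines, value = TRUE)
    pts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(s) as.numeric(s[2:4])))
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80L)
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    pts <- matrix(NA_real_, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)
      pts[3L * i - 2L, ] <- vals[4:6]
      pts[3L * i - 1L, ] <- vals[7:9]
      pts[3L * i, ] <- vals[10:12]
    }
  }
  # weld exactly coincident vertices so shared edges are shared indices
  key <- paste(pts[, 1L], pts[, 2L], pts[, 3L])
  uid <- match(key, unique(key))
  v <- pts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = faces)
}

.write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  fn <- face_normals(mesh)
  writeLines("solid craniowarp", con)
  v <- mesh$vertices; f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1L], fn[i, 2L],
                       fn[i, 3L]), con)
    writeLines("    outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[f[i, k], 1L],
                         v[f[i, k], 2L], v[f[i, k], 3L]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid craniowarp", con)
}
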