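# Triangle-mesh file I/O: STL (ASCII and binary) and PLY (ASCII and
# binary little-endian, with optional per-vertex RGB colors).
#
# A mesh is a plain list: vertices (n x 3 numeric), faces (m x 3 integer,
# 1-based), optionally colors (n x 3 integer, 0..255).

#' Write a mesh to STL
#'
#' STL stores independent triangles; vertex connectivity is not preserved.
#'
#' @param mesh list with `vertices` and `faces`.
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices; F <- mesh$faces
  normals <- face_normals(V, F)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(normals[i, ]), con, size = 4, endian = "little")
      for (k in 1:3) {
        writeBin(as.numeric(V[F[i, k], ]), con, size = 4, endian = "little")
      }
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    lines <- c("solid mesh")
    for (i in seq_len(nrow(F))) {
      lines <- c(lines,
                 sprintf("  facet normal %.9g %.9g %.9g",
                         normals[i, 1], normals[i, 2], normals[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         V[F[i, 1:3], 1], V[F[i, 1:3], 2], V[F[i, 1:3], 3]),
                 "    endloop", "  endfacet")
    }
    writeLines(c(lines, "endsolid mesh"), path)
  }
  invisible(path)
}

face_normals <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Read an STL file (auto-detects ASCII vs binary)
#'
#' Coincident triangle corners are merged back into shared vertices.
#'
#' @param path STL file path.
#' @return mesh list with `vertices` and `faces`.
#' @export
read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 512)
  txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]))
    tri <- do.call(rbind, nums)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    tri <- matrix(0, nf * 3, 3)
    for (i in seq_len(nf)) {
      readBin(con, "numeric", n = 3, size = 4, endian = "little")
      for (k in 1:3) {
        tri[(i - 1) * 3 + k, ] <-
          readBin(con, "numeric", n = 3, size = 4, endian = "little")
      }
      readBin(con, "integer", n = 1, size = 2, endian = "little")
    }
  }
  key <- apply(round(tri, 6), 1, paste, collapse = ",")
  uid <- !duplicated(key)
  verts <- tri[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Write a mesh to PLY (with optional per-vertex colors)
#'
#' @param mesh list with `vertices`, `faces`, optionally `colors`
#'   (n x 3 integer, 0..255).
#' @param path output path.
#' @param binary binary little-endian (default) or ASCII.
#' @export
write_ply <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices; F <- mesh$faces
  has_col <- !is.null(mesh$colors)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0"
              else "format ascii 1.0",
              sprintf("element vertex %d", nrow(V)),
              "property float x", "property float y", "property float z",
              if (has_col) c("property uchar red", "property uchar green",
                             "property uchar blue"),
              sprintf("element face %d", nrow(F)),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    for (i in seq_len(nrow(V))) {
      writeBin(as.numeric(V[i, ]), con, size = 4, endian = "little")
      if (has_col) writeBin(as.raw(mesh$colors[i, ]), con)
    }
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    vl <- if (has_col) {
      sprintf("%.9g %.9g %.9g %d %d %d", V[, 1], V[, 2], V[, 3],
              mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3])
    } else {
      sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    }
    fl <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
    writeLines(c(header, vl, fl), path)
  }
  invisible(path)
}

#' Read a PLY file written by [write_ply()] (ASCII or binary little-endian)
#'
#' @param path PLY file path.
#' @return mesh list with `vertices`, `faces` and `colors` when present.
#' @export
read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate end_header (raw scan: the binary body may contain nul bytes)
  hit <- grepRaw("end_header\n", raw, fixed = TRUE)
  check_that(length(hit) > 0, "not a PLY file (no end_header)")
  header <- strsplit(rawToChar(raw[seq_len(hit[1] - 1)]), "\n")[[1]]
  body_off <- hit[1] + nchar("end_header\n") - 1
  fmt <- grep("^format", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)))
  has_col <- any(grepl("property uchar red", header))
  if (binary) {
    con <- rawConnection(raw[(body_off + 1):length(raw)])
    on.exit(close(con))
    V <- matrix(0, nv, 3)
    cols <- if (has_col) matrix(0L, nv, 3) else NULL
    for (i in seq_len(nv)) {
      V[i, ] <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
      if (has_col) cols[i, ] <- as.integer(readBin(con, "raw", n = 3))
    }
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      check_that(cnt == 3, "only triangle faces are supported")
      F[i, ] <- readBin(con, "integer", n = 3, size = 4,
                        endian = "little") + 1L
    }
  } else {
    lines <- strsplit(rawToChar(raw), "\n")[[1]]
    body <- lines[(length(header) + 1 + 1):length(lines)]
    body <- body[nzchar(body)]
    vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    V <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
    cols <- if (has_col) {
      t(vapply(vparts, function(p) as.integer(p[4:6]), integer(3)))
    }
    fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    F <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L, integer(3)))
  }
  out <- list(vertices = V, faces = F)
  if (has_col) out$colors <- cols
  out
}

#' Read a mesh file by extension (.stl or .ply)
#' @param path mesh file path.
#' @return mesh list.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         abort_gm(sprintf("unsupported mesh format '%s'", ext)))
}
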