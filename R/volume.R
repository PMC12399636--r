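# Multi-slice integration and 3-D thickness-surface reconstruction:
# natural-order slice sorting, merged CSV tables, distribution plots,
# triangulated surface construction over the (slice, x) grid with the
# blue-green-yellow-red thickness colormap, optional Laplacian smoothing,
# and PLY/OBJ export.

#' Order slice filenames naturally and assign slice numbers
#'
#' Numeric substrings are compared as integers (slice2 before slice10);
#' the 1-based rank becomes the slice number.
#'
#' @param filenames character vector of slice filenames.
#' @return tibble with `filename` (sorted) and `slice_number`.
#' @export
natural_sort_slices <- function(filenames) {
  check_that(length(filenames) > 0, "no filenames")
  check_that(!anyDuplicated(filenames), "duplicate filenames")
  ord <- natural_order(filenames)
  tibble::tibble(filename = filenames[ord],
                 slice_number = seq_along(filenames))
}

#' Merge per-slice measurement rows into a thickness table
#'
#' Rows are concatenated in natural slice order and tagged with the slice
#' number from that order.
#'
#' @param per_slice_rows named list (names = source filenames) of per-slice
#'   row tibbles as produced by [measure_slice()]`$rows`.
#' @return tibble of class `thickness_table` with columns `image_name`,
#'   `slice_number`, `x`, `thickness_px`, `thickness_mm`, `direction`.
#' @export
merge_tables <- function(per_slice_rows) {
  check_that(length(per_slice_rows) > 0 && !is.null(names(per_slice_rows)),
             "per_slice_rows must be a named list")
  ord <- natural_sort_slices(names(per_slice_rows))
  out <- dplyr::bind_rows(lapply(seq_len(nrow(ord)), function(i) {
    nm <- ord$filename[i]
    rows <- per_slice_rows[[nm]]
    check_that(!is.null(rows), sprintf("unknown filename tag '%s'", nm))
    dplyr::mutate(rows, image_name = nm,
                  slice_number = ord$slice_number[i],
                  .before = 1)
  }))
  out <- out[, c("image_name", "slice_number", "x", "thickness_px",
                 "thickness_mm", "direction")]
  class(out) <- c("thickness_table", class(out))
  out
}

#' Write / read a thickness table as CSV
#'
#' The CSV round-trips losslessly: `read_thickness_table(write_...)`
#' reproduces the table.
#'
#' @param table a `thickness_table`.
#' @param path CSV path.
#' @export
write_thickness_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thickness_table
#' @return the thickness table.
#' @export
read_thickness_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("thickness_table", class(out))
  out
}

#' Map thickness values to the blue-green-yellow-red gradient
#'
#' Piecewise-linear interpolation through the anchors blue (minimum),
#' green (1/3), yellow (2/3) and red (maximum) of the value range. A
#' constant input maps to the single mid-scale color. The same map is
#' used by the scatter plots and the 3-D surface.
#'
#' @param values finite numeric vector.
#' @param limits optional c(min, max) range overriding the data range.
#' @return integer matrix n x 3 of RGB colors (0..255).
#' @export
thickness_colormap <- function(values, limits = NULL) {
  check_that(length(values) > 0, "no values")
  check_that(all(is.finite(values)), "values must be finite")
  if (is.null(limits)) limits <- range(values)
  span <- limits[2] - limits[1]
  t <- if (span > 0) (values - limits[1]) / span else rep(0.5, length(values))
  anchors <- rbind(c(0, 0, 255),    # blue
                   c(0, 255, 0),    # green
                   c(255, 255, 0),  # yellow
                   c(255, 0, 0))    # red
  pos <- c(0, 1 / 3, 2 / 3, 1)
  rgb <- vapply(1:3, function(ch) {
    approx(pos, anchors[, ch], xout = clamp(t, 0, 1))$y
  }, numeric(length(t)))
  matrix(as.integer(round(rgb)), ncol = 3)
}

#' Triangulate the (slice, x) thickness grid into a 3-D surface
#'
#' One vertex per measured grid cell at
#' `(slice_number * slice_mm, x * pixel_mm, thickness_mm)`; every grid
#' quad whose four corners are present is split into two triangles along
#' the `(i, j) -> (i+1, j+1)` diagonal; quads with missing corners are
#' omitted. Vertex colors follow [thickness_colormap()].
#'
#' @param table a `thickness_table` covering a slice-by-column grid
#'   (missing cells allowed).
#' @param slice_mm physical spacing between slices (default 0.3 mm).
#' @param pixel_mm physical spacing between columns (default 0.1 mm).
#' @return object of class `thickness_surface`: list with `vertices`
#'   (n x 3), `triangles` (m x 3, 1-based), `colors` (n x 3 RGB),
#'   `thickness` (per-vertex mm), `grid` (slice/x index per vertex).
#' @export
grid_mesh <- function(table, slice_mm = 0.3, pixel_mm = 0.1) {
  slices <- sort(unique(table$slice_number))
  xs <- sort(unique(table$x))
  check_that(length(slices) >= 2 && length(xs) >= 2,
             "need at least 2 slices and 2 columns")
  M <- length(slices); N <- length(xs)
  zi <- matrix(NA_real_, M, N)
  si <- match(table$slice_number, slices)
  xi <- match(table$x, xs)
  check_that(!anyDuplicated(cbind(si, xi)),
             "duplicate (slice, x) measurements")
  zi[cbind(si, xi)] <- table$thickness_mm
  present <- !is.na(zi)
  vid <- matrix(NA_integer_, M, N)
  vid[present] <- seq_len(sum(present))
  ii <- which(present, arr.ind = TRUE)
  verts <- cbind(slices[ii[, 1]] * slice_mm, xs[ii[, 2]] * pixel_mm,
                 zi[present])
  tris <- list()
  for (i in seq_len(M - 1)) {
    for (j in seq_len(N - 1)) {
      v00 <- vid[i, j]; v10 <- vid[i + 1, j]
      v01 <- vid[i, j + 1]; v11 <- vid[i + 1, j + 1]
      if (anyNA(c(v00, v10, v01, v11))) next
      tris[[length(tris) + 1L]] <- c(v00, v11, v10)
      tris[[length(tris) + 1L]] <- c(v00, v01, v11)
    }
  }
  triangles <- if (length(tris)) do.call(rbind, tris) else
    matrix(integer(0), 0, 3)
  structure(list(vertices = verts, triangles = triangles,
                 colors = thickness_colormap(verts[, 3]),
                 thickness = verts[, 3],
                 grid = cbind(slice = ii[, 1], col = ii[, 2])),
            class = "thickness_surface")
}

#' Laplacian (umbrella) smoothing of a thickness surface
#'
#' Each iteration relaxes the z-coordinate toward the mean of the
#' edge-connected neighbours: `z <- z + lambda * (mean(z_nb) - z)`.
#' x/y stay fixed, planar surfaces are fixed points, and the z range
#' never expands. Vertex colors are recomputed from the smoothed z.
#'
#' @param surface a `thickness_surface`.
#' @param iterations number of relaxation sweeps (>= 0).
#' @param lambda_factor relaxation factor in (0, 1].
#' @return smoothed `thickness_surface`.
#' @export
laplacian_smooth <- function(surface, iterations, lambda_factor = 0.5) {
  check_that(iterations >= 0, "iterations must be >= 0")
  check_that(lambda_factor > 0 && lambda_factor <= 1,
             "lambda_factor must be in (0, 1]")
  if (iterations == 0) return(surface)
  n <- nrow(surface$vertices)
  e <- rbind(surface$triangles[, c(1, 2)], surface$triangles[, c(2, 3)],
             surface$triangles[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  z <- surface$vertices[, 3]
  deg <- tabulate(e[, 1], nbins = n)
  for (it in seq_len(iterations)) {
    sums <- rep(0, n)
    acc <- tapply(z[e[, 2]], e[, 1], sum)
    sums[as.integer(names(acc))] <- acc
    nb_mean <- ifelse(deg > 0, sums / pmax(deg, 1), z)
    z <- ifelse(deg > 0, z + lambda_factor * (nb_mean - z), z)
  }
  surface$vertices[, 3] <- z
  surface$thickness <- z
  surface$colors <- thickness_colormap(z)
  surface
}

#' Export a thickness surface to PLY or OBJ
#'
#' PLY files carry per-vertex RGB colors (binary little-endian by
#' default); OBJ writes vertex colors as extended `v x y z r g b` lines.
#'
#' @param surface a `thickness_surface`.
#' @param path output path ending in `.ply` or `.obj`.
#' @param binary binary PLY (default) or ASCII.
#' @export
export_surface <- function(surface, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  mesh <- list(vertices = surface$vertices, faces = surface$triangles,
               colors = surface$colors)
  if (ext == "ply") {
    write_ply(mesh, path, binary = binary)
  } else if (ext == "obj") {
    vl <- sprintf("v %.9g %.9g %.9g %.6g %.6g %.6g",
                  mesh$vertices[, 1], mesh$vertices[, 2],
                  mesh$vertices[, 3], mesh$colors[, 1] / 255,
                  mesh$colors[, 2] / 255, mesh$colors[, 3] / 255)
    fl <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                  mesh$faces[, 3])
    writeLines(c("# thickness surface", vl, fl), path)
  } else {
    abort_gm(sprintf("unsupported surface format '%s'", ext))
  }
  invisible(path)
}

#' Distribution plots for a thickness table
#'
#' A scatter plot of (x, slice) colored by thickness (heatmap effect,
#' same colormap as the 3-D surface) and per-slice thickness curves.
#'
#' @param table a `thickness_table`.
#' @param out_dir optional directory; when given, `scatter.png` and
#'   `curves.png` are written.
#' @param dpi raster resolution for written files.
#' @return list of ggplot objects `scatter` and `curves` (invisibly when
#'   files are written).
#' @export
plot_distribution <- function(table, out_dir = NULL, dpi = 150) {
  check_that(nrow(table) > 0, "thickness table is empty")
  cols <- thickness_colormap(table$thickness_mm)
  lims <- range(table$thickness_mm)
  anchor_cols <- grDevices::rgb(c(0, 0, 255, 255), c(0, 255, 255, 0),
                                c(255, 0, 0, 0), maxColorValue = 255)
  scatter <- ggplot2::ggplot(table,
                             ggplot2::aes(x = .data$x,
                                          y = .data$slice_number,
                                          color = .data$thickness_mm)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_gradientn(colors = anchor_cols, limits = lims,
                                   name = "GT (mm)") +
    ggplot2::labs(x = "image column (px)", y = "slice number") +
    ggplot2::theme_minimal()
  curves <- ggplot2::ggplot(table,
                            ggplot2::aes(x = .data$x,
                                         y = .data$thickness_mm,
                                         group = .data$slice_number,
                                         color = .data$slice_number)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_color_viridis_c(name = "slice") +
    ggplot2::labs(x = "image column (px)",
                  y = "gingival thickness (mm)") +
    ggplot2::theme_minimal()
  out <- list(scatter = scatter, curves = curves)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(file.path(out_dir, "scatter.png"), scatter,
                    width = 6, height = 4, dpi = dpi)
    ggplot2::ggsave(file.path(out_dir, "curves.png"), curves,
                    width = 6, height = 4, dpi = dpi)
    return(invisible(out))
  }
  out
}

#' @export
print.thickness_surface <- function(x, ...) {
  cat(sprintf("thickness surface: %d vertices, %d triangles, z in [%.3g, %.3g] mm\n",
              nrow(x$vertices), nrow(x$triangles),
              min(x$thickness), max(x$thickness)))
  invisible(x)
}
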