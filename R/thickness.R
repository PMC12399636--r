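# Gingival-thickness measurement on colorized segmentation images:
# exact color thresholding, tooth-boundary contour extraction, the
# vertical enter/exit pixel scan, 1-D Gaussian profile smoothing, and
# annotated overlays.

#' Construct a thickness profile tibble
#'
#' @param x 0-based column indices.
#' @param thickness_px per-column thickness in pixels (>= 0).
#' @param direction scan direction, `"up"` or `"down"`.
#' @param sigma Gaussian smoothing sigma already applied (pixels).
#' @param pixel_spacing physical pixel spacing in mm/px.
#' @return tibble of class `thickness_profile` with columns `x`,
#'   `thickness_px`, `thickness_mm`, `direction`; attributes `sigma` and
#'   `pixel_spacing`.
#' @export
thickness_profile <- function(x, thickness_px, direction = "down",
                              sigma = 0, pixel_spacing = 0.1) {
  check_that(length(x) == length(thickness_px),
             "x and thickness_px lengths differ")
  check_that(all(thickness_px >= 0), "thickness must be non-negative")
  check_that(direction %in% c("up", "down"), "direction must be up or down")
  out <- tibble::tibble(x = as.numeric(x),
                        thickness_px = as.numeric(thickness_px),
                        thickness_mm = as.numeric(thickness_px) *
                          pixel_spacing,
                        direction = direction)
  attr(out, "sigma") <- sigma
  attr(out, "pixel_spacing") <- pixel_spacing
  class(out) <- c("thickness_profile", class(out))
  out
}

#' Extract gingiva and tooth binary masks by exact color thresholds
#'
#' Red (gingiva): `R > 75 & G < 30 & B < 30`; green (tooth/bone):
#' `G > 75 & R < 30 & B < 30`. The rules are mutually exclusive, so the
#' masks are disjoint by construction.
#'
#' @param img numeric array H x W x 3 (R, G, B) on the 0..255 scale.
#' @return list with logical matrices `gingiva` and `tooth`.
#' @export
extract_color_masks <- function(img) {
  check_that(length(dim(img)) == 3 && dim(img)[3] == 3,
             "expected an H x W x 3 color image")
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  list(gingiva = R > 75 & G < 30 & B < 30,
       tooth = G > 75 & R < 30 & B < 30)
}

#' Extract the tooth-surface boundary contour from a tooth mask
#'
#' Morphological closing (3x3 box, 1 iteration) smooths edges and fills
#' small holes; connected components are traced and the largest-area
#' component is taken as the main tooth surface. Contour points with
#' `y = 0` (crop-edge artifacts) are discarded, duplicate x positions keep
#' the smallest y (the gingiva-facing edge under the y-down convention is
#' resolved by the scan itself), and points are sorted by x.
#'
#' @param tooth_mask logical or 0/1 matrix.
#' @param closing_size structuring element size (default 3).
#' @return tibble of class `boundary_contour` with columns `x`, `y`
#'   (0-based pixel coordinates), strictly increasing in `x`.
#' @export
tooth_boundary <- function(tooth_mask, closing_size = 3) {
  check_that(is.matrix(tooth_mask), "tooth_mask must be a matrix")
  m <- (tooth_mask > 0) + 0
  check_that(sum(m) > 0, "no tooth surface: mask is empty")
  eb <- EBImage::Image(t(m))
  if (closing_size > 1) {
    eb <- EBImage::closing(eb, EBImage::makeBrush(closing_size, "box"))
  }
  lab <- EBImage::bwlabel(eb)
  areas <- table(EBImage::imageData(lab))
  areas <- areas[names(areas) != "0"]
  check_that(length(areas) > 0, "no tooth surface: no contour after closing")
  main <- as.integer(names(areas)[which.max(areas)])
  oc <- EBImage::ocontour(lab)[[main]]   # columns: x, y (0-based)
  contour_to_boundary(oc)
}

# dedup/sort rules shared with tests: drop y == 0, per-x min y, sort by x
contour_to_boundary <- function(pts) {
  pts <- pts[pts[, 2] != 0, , drop = FALSE]
  check_that(nrow(pts) > 0, "no tooth surface: contour only at y = 0")
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  keep <- !duplicated(pts[, 1])
  out <- tibble::tibble(x = as.integer(pts[keep, 1]),
                        y = as.integer(pts[keep, 2]))
  class(out) <- c("boundary_contour", class(out))
  out
}

#' Vertical enter/exit pixel scan of gingival thickness
#'
#' For each image column, the scan starts one pixel past the boundary
#' point at that column (columns without a boundary point use the nearest
#' boundary x; ties prefer the smaller x), steps row by row in the scan
#' direction, skips non-gingiva pixels until it enters the gingival band,
#' counts consecutive gingiva pixels, and stops at the first non-gingiva
#' pixel or the image edge. Columns that never enter get thickness 0.
#'
#' @param gingiva_mask logical matrix (TRUE = gingiva).
#' @param boundary a [tooth_boundary()] contour.
#' @param direction `"down"` (default) or `"up"`.
#' @param max_skip maximum pixels to skip before entering the band
#'   (default unlimited); guards against runaway scans.
#' @param pixel_spacing mm/px for the mm column.
#' @return raw [thickness_profile()] (sigma 0) covering every column.
#' @export
scan_thickness <- function(gingiva_mask, boundary, direction = "down",
                           max_skip = Inf, pixel_spacing = 0.1) {
  check_that(direction %in% c("up", "down"),
             "direction must be 'up' or 'down'")
  check_that(nrow(boundary) > 0, "boundary is empty")
  H <- nrow(gingiva_mask); W <- ncol(gingiva_mask)
  step <- if (direction == "down") 1L else -1L
  bx <- boundary$x; by <- boundary$y
  thick <- numeric(W)
  for (col in seq_len(W) - 1L) {
    i <- match(col, bx)
    if (is.na(i)) {
      d <- abs(bx - col)
      i <- which(d == min(d))[1]   # bx sorted: first hit = smaller x
    }
    y <- by[i] + step
    skipped <- 0
    count <- 0L
    while (y >= 0 && y < H) {
      inside <- gingiva_mask[y + 1L, col + 1L]
      if (count == 0L) {
        if (inside) {
          count <- 1L
        } else {
          skipped <- skipped + 1
          if (skipped > max_skip) break
        }
      } else {
        if (inside) count <- count + 1L else break
      }
      y <- y + step
    }
    thick[col + 1L] <- count
  }
  thickness_profile(x = seq_len(W) - 1L, thickness_px = thick,
                    direction = direction, sigma = 0,
                    pixel_spacing = pixel_spacing)
}

#' Smooth a thickness profile with a 1-D Gaussian filter
#'
#' Convolution along x with a normalized Gaussian kernel (support 4
#' sigma), reflected at the profile ends; `sigma = 0` returns the profile
#' unchanged. Constants are preserved exactly and the output can never be
#' negative.
#'
#' @param profile a [thickness_profile()].
#' @param sigma Gaussian sigma in pixels (>= 0).
#' @return smoothed `thickness_profile` (same length, updated attributes).
#' @export
smooth_profile <- function(profile, sigma) {
  check_that(sigma >= 0, "sigma must be non-negative")
  if (sigma == 0) return(profile)
  v <- profile$thickness_px
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  idx <- seq_len(n)
  sm <- numeric(n)
  for (d in seq_along(k)) {
    sm <- sm + k[d] * v[reflect_index(idx + d - 1L - r, n)]
  }
  out <- thickness_profile(profile$x, pmax(sm, 0),
                           direction = profile$direction[1],
                           sigma = sigma,
                           pixel_spacing = attr(profile, "pixel_spacing"))
  out
}

#' Annotate a segmentation image with the boundary and measured thickness
#'
#' Boundary points are marked with small yellow dots; at each measured
#' column a vertical line of the measured length is drawn in light blue
#' in the scan direction. The input image is not modified.
#'
#' @param img H x W x 3 RGB array (0..255).
#' @param boundary a [tooth_boundary()] contour.
#' @param profile a [thickness_profile()].
#' @return annotated copy of the image.
#' @export
annotate_slice <- function(img, boundary, profile) {
  check_that(length(dim(img)) == 3, "img must be H x W x 3")
  W <- dim(img)[2]; H <- dim(img)[1]
  check_that(max(boundary$x) < W && max(profile$x) < W,
             "boundary/profile wider than the image")
  out <- img
  step <- if (profile$direction[1] == "down") 1L else -1L
  bmap <- setNames(boundary$y, boundary$x)
  for (i in seq_len(nrow(profile))) {
    tk <- round(profile$thickness_px[i])
    if (tk <= 0) next
    xcol <- profile$x[i]
    bxs <- as.integer(names(bmap))
    j <- which.min(abs(bxs - xcol))
    y0 <- bmap[[j]] + step
    ys <- y0 + step * (seq_len(tk) - 1L)
    ys <- ys[ys >= 0 & ys < H]
    out[ys + 1L, xcol + 1L, 1] <- 120
    out[ys + 1L, xcol + 1L, 2] <- 200
    out[ys + 1L, xcol + 1L, 3] <- 255
  }
  for (i in seq_len(nrow(boundary))) {
    y <- boundary$y[i]; x <- boundary$x[i]
    out[y + 1L, x + 1L, ] <- c(255, 255, 0)
  }
  out
}

#' Thickness measurement configuration
#'
#' @param direction `"down"`, `"up"` or `"auto"` (pick, per slice, the
#'   direction with more gingiva pixels within 10 rows of the boundary).
#' @param sigma Gaussian profile smoothing sigma (pixels).
#' @param pixel_spacing mm per pixel (default 0.1).
#' @param closing_size structuring element for boundary extraction.
#' @param max_skip scan skip limit before entering the band.
#' @return list of class `measure_config`.
#' @export
measure_config <- function(direction = "down", sigma = 2,
                           pixel_spacing = 0.1, closing_size = 3,
                           max_skip = Inf) {
  check_that(direction %in% c("up", "down", "auto"),
             "direction must be up, down or auto")
  structure(list(direction = direction, sigma = sigma,
                 pixel_spacing = pixel_spacing,
                 closing_size = closing_size, max_skip = max_skip),
            class = "measure_config")
}

auto_direction <- function(gingiva_mask, boundary, band = 10) {
  H <- nrow(gingiva_mask)
  score <- c(down = 0, up = 0)
  for (i in seq_len(nrow(boundary))) {
    x <- boundary$x[i] + 1L; y <- boundary$y[i] + 1L
    dn <- (y + 1):min(y + band, H)
    up <- max(y - band, 1):(y - 1)
    if (y < H) score["down"] <- score["down"] + sum(gingiva_mask[dn, x])
    if (y > 1) score["up"] <- score["up"] + sum(gingiva_mask[up, x])
  }
  if (score["up"] > score["down"]) "up" else "down"
}

#' Measure gingival thickness on one colorized segmentation image
#'
#' Composes [extract_color_masks()], [tooth_boundary()],
#' [scan_thickness()], [smooth_profile()] and [annotate_slice()].
#'
#' @param img H x W x 3 RGB array (0..255) using the red = gingiva,
#'   green = tooth convention.
#' @param cfg a [measure_config()].
#' @param image_name name recorded in the output rows.
#' @return list of class `slice_measurement` with `profile` (smoothed),
#'   `raw_profile`, `boundary`, `direction`, `overlay` (annotated image)
#'   and `rows` (tibble: image_name, x, thickness_px, thickness_mm,
#'   direction).
#' @export
measure_slice <- function(img, cfg = measure_config(),
                          image_name = "slice") {
  masks <- extract_color_masks(img)
  boundary <- tryCatch(
    tooth_boundary(masks$tooth, cfg$closing_size),
    error = function(e) {
      abort_gm(sprintf("slice '%s': %s", image_name, conditionMessage(e)))
    })
  dir <- cfg$direction
  if (dir == "auto") dir <- auto_direction(masks$gingiva, boundary)
  raw <- scan_thickness(masks$gingiva, boundary, dir,
                        max_skip = cfg$max_skip,
                        pixel_spacing = cfg$pixel_spacing)
  prof <- smooth_profile(raw, cfg$sigma)
  overlay <- annotate_slice(img, boundary, prof)
  rows <- tibble::tibble(image_name = image_name, x = prof$x,
                         thickness_px = prof$thickness_px,
                         thickness_mm = prof$thickness_mm,
                         direction = dir)
  structure(list(profile = prof, raw_profile = raw, boundary = boundary,
                 direction = dir, overlay = overlay, rows = rows),
            class = "slice_measurement")
}

#' Plot a thickness profile
#'
#' @param object a [thickness_profile()].
#' @param ... unused.
#' @return a ggplot of thickness (mm) against image column.
#' @export
autoplot.thickness_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x,
                                       y = .data$thickness_mm)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "image column (px)", y = "gingival thickness (mm)") +
    ggplot2::theme_minimal()
}
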