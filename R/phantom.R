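# Synthetic phantoms with analytic ground truth.
#
# A slice phantom emulates one cropped cross-sectional image of an
# edentulous ridge: a bone/tooth slab entering from the top of the crop,
# whose lower edge (the "ridge" boundary) is a per-column profile, covered
# by a gingival band of prescribed per-column thickness, over background.
# Because the analytic thickness function is known, every downstream stage
# (segmentation, boundary extraction, pixel scan, 3-D reconstruction) can
# be scored exactly.

#' Specify a single-slice phantom
#'
#' @param width,height image size in pixels (>= 32).
#' @param bone_profile function mapping column `x` (0-based) to the row of
#'   the gingiva-facing bone boundary (image coordinates, y down). The bone
#'   slab occupies rows `0..bone_profile(x)`; the crop is assumed to cut the
#'   tooth at the top edge, which is why boundary points at `y = 0` are
#'   image artifacts downstream.
#' @param thickness_fn function mapping column `x` to the gingival band
#'   thickness in pixels (>= 0). The band occupies the `round(thickness_fn(x))`
#'   rows directly below the bone boundary.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (8-bit grayscale units).
#' @param seed integer RNG seed for the noise.
#' @param intensities named vector of class base intensities before noise
#'   (8-bit scale). Defaults mimic CBCT soft/hard tissue contrast.
#' @param gap_rows optional integer vector of row offsets (1-based, counted
#'   from the first band row) turned back into background, to exercise the
#'   thickness scan's exit logic. Default none: the band is contiguous.
#' @return object of class `slice_phantom_spec`.
#' @export
slice_phantom_spec <- function(width, height, bone_profile, thickness_fn,
                               noise_sd = 5, seed = 1,
                               intensities = c(background = 30,
                                               gingiva = 90,
                                               bone = 200),
                               gap_rows = integer()) {
  check_that(is.numeric(width) && is.numeric(height) &&
               width >= 32 && height >= 32,
             "slice phantom invariant violated: width and height must be >= 32")
  check_that(is.function(bone_profile) && is.function(thickness_fn),
             "bone_profile and thickness_fn must be functions of x")
  check_that(noise_sd >= 0, "noise_sd must be non-negative")
  xs <- seq_len(width) - 1
  tvals <- vapply(xs, thickness_fn, numeric(1))
  bvals <- vapply(xs, bone_profile, numeric(1))
  check_that(all(tvals >= 0),
             "slice phantom invariant violated: thickness_fn(x) >= 0 for all x")
  check_that(all(bvals + tvals < height),
             paste("slice phantom invariant violated:",
                   "bone_profile(x) + thickness_fn(x) < height for all x"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 bone_profile = bone_profile, thickness_fn = thickness_fn,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 intensities = intensities, gap_rows = as.integer(gap_rows)),
            class = "slice_phantom_spec")
}

#' Generate a slice phantom: grayscale image, label mask, true profile
#'
#' For every column `x`, the mask contains exactly `round(thickness_fn(x))`
#' gingiva pixels (label 2) directly below the bone boundary; bone/tooth is
#' label 1, background 0. The grayscale image is the class base intensity
#' plus seeded Gaussian noise, clipped to 0..255.
#'
#' @param spec a [slice_phantom_spec()].
#' @return list with `gray` (matrix), `mask` (integer matrix) and
#'   `true_profile` (a [thickness_profile] tibble with the analytic
#'   per-column counts).
#' @export
make_slice_phantom <- function(spec) {
  check_that(inherits(spec, "slice_phantom_spec"),
             "spec must be created with slice_phantom_spec()")
  W <- spec$width; H <- spec$height
  xs <- seq_len(W) - 1
  bvals <- round(vapply(xs, spec$bone_profile, numeric(1)))
  tvals <- round(vapply(xs, spec$thickness_fn, numeric(1)))
  mask <- matrix(0L, H, W)
  for (j in seq_len(W)) {
    b <- bvals[j]
    if (b >= 0) mask[seq_len(min(b, H - 1) + 1), j] <- 1L
    tk <- tvals[j]
    if (tk > 0) {
      rows <- (b + 2):(b + 1 + tk)      # 1-based rows below the boundary
      rows <- rows[rows <= H]           # rounding can touch the last row
      if (length(spec$gap_rows)) {
        rows <- setdiff(rows, b + 1 + spec$gap_rows)
      }
      mask[rows, j] <- 2L
    }
  }
  inten <- spec$intensities
  gray <- matrix(inten[["background"]], H, W)
  gray[mask == 1L] <- inten[["bone"]]
  gray[mask == 2L] <- inten[["gingiva"]]
  if (spec$noise_sd > 0) {
    gray <- with_seed(spec$seed,
                      gray + matrix(rnorm(H * W, 0, spec$noise_sd), H, W))
  }
  gray <- clamp(gray, 0, 255)
  profile <- thickness_profile(x = xs, thickness_px = tvals,
                               direction = "down", sigma = 0,
                               pixel_spacing = 0.1)
  list(gray = gray, mask = mask, true_profile = profile)
}

#' Specify a multi-slice phantom series
#'
#' @param n_slices number of slices (>= 2).
#' @param slice_spec a [slice_phantom_spec()] template; its `thickness_fn`
#'   is replaced slice-by-slice by `thickness_field`.
#' @param thickness_field function `(k, x) -> thickness` with `k` the
#'   0-based slice index; should be continuous in both arguments so the
#'   series has a smooth mesiodistal thickness variation.
#' @param seed integer seed; slice `k` uses `seed + k`.
#' @return object of class `series_phantom_spec`.
#' @export
series_phantom_spec <- function(n_slices, slice_spec, thickness_field,
                                seed = 1) {
  check_that(n_slices >= 2,
             "series phantom invariant violated: n_slices must be >= 2")
  check_that(inherits(slice_spec, "slice_phantom_spec"),
             "slice_spec must be a slice_phantom_spec")
  check_that(is.function(thickness_field),
             "thickness_field must be a function (slice, x)")
  structure(list(n_slices = as.integer(n_slices), slice_spec = slice_spec,
                 thickness_field = thickness_field, seed = as.integer(seed)),
            class = "series_phantom_spec")
}

#' Generate a phantom slice series
#'
#' Slice `k` (0-based) is generated with `thickness_fn(x) =
#' thickness_field(k, x)` and filename `slice<k+1>.png`, so that natural
#' sorting of filenames is exercised for `n_slices >= 10`.
#'
#' @param spec a [series_phantom_spec()].
#' @param out_dir optional directory; when given, `slice<k>.png` (gray),
#'   `slice<k>_mask.png`, `slice<k>_color.png` and a ground-truth
#'   `truth.csv` (columns slice, x, thickness_px) are written.
#' @return named list (names = filenames) of slice triples as returned by
#'   [make_slice_phantom()].
#' @export
make_series_phantom <- function(spec, out_dir = NULL) {
  check_that(inherits(spec, "series_phantom_spec"),
             "spec must be created with series_phantom_spec()")
  out <- vector("list", spec$n_slices)
  names(out) <- paste0("slice", seq_len(spec$n_slices), ".png")
  for (k in seq_len(spec$n_slices) - 1L) {
    sl <- spec$slice_spec
    field <- spec$thickness_field
    sl$thickness_fn <- local({
      kk <- k
      function(x) field(kk, x)
    })
    sl$seed <- spec$seed + k
    sl <- slice_phantom_spec(sl$width, sl$height, sl$bone_profile,
                             sl$thickness_fn, sl$noise_sd, sl$seed,
                             sl$intensities, sl$gap_rows)
    out[[k + 1L]] <- make_slice_phantom(sl)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    truth <- list()
    for (k in seq_along(out)) {
      base <- sprintf("slice%d", k)
      write_gray_png(out[[k]]$gray, file.path(out_dir, paste0(base, ".png")))
      write_mask_png(out[[k]]$mask,
                     file.path(out_dir, paste0(base, "_mask.png")))
      write_color_png(colorize_labels(out[[k]]$mask),
                      file.path(out_dir, paste0(base, "_color.png")))
      truth[[k]] <- tibble::tibble(slice = k,
                                   x = out[[k]]$true_profile$x,
                                   thickness_px =
                                     out[[k]]$true_profile$thickness_px)
    }
    write.csv(do.call(rbind, truth), file.path(out_dir, "truth.csv"),
              row.names = FALSE)
  }
  out
}

#' Colorize a label mask with the red/green segmentation convention
#'
#' Gingiva (label 2) is rendered pure red, bone/tooth (label 1) pure green,
#' background black, matching the color-threshold rules used by
#' [extract_color_masks()] exactly.
#'
#' @param mask integer matrix with values in \{0, 1, 2\}.
#' @return numeric array H x W x 3 (R, G, B) on the 0..255 scale.
#' @export
colorize_labels <- function(mask) {
  check_that(is.matrix(mask), "mask must be a matrix")
  check_that(all(mask %in% 0:2),
             "mask contains labels outside {0, 1, 2}")
  img <- array(0, c(nrow(mask), ncol(mask), 3))
  img[, , 1][mask == 2L] <- 255  # red channel: gingiva
  img[, , 2][mask == 1L] <- 255  # green channel: bone/tooth
  img
}

#' Generate a labelled phantom dataset for segmentation training
#'
#' Each slice draws its own ridge level, ridge undulation phase and
#' gingival-band amplitude, so the dataset spans the anatomically
#' plausible range: band thickness 2.5-18 px (0.25-1.8 mm at 0.1 mm/px,
#' straddling the 1 mm thin/thick-gingiva threshold), bone boundary at
#' 25-45% of the image height, additive intensity noise sd 6. Images are
#' preprocessed to `[0, 1]` at the requested resolution.
#'
#' @param n number of slices.
#' @param size image side in pixels (default 128).
#' @param seed dataset seed.
#' @return list with `images` (preprocessed matrices) and `masks`
#'   (integer label matrices).
#' @export
make_phantom_dataset <- function(n, size = 128, seed = 1) {
  with_seed(seed, {
    imgs <- vector("list", n)
    msks <- vector("list", n)
    for (i in seq_len(n)) {
      amp <- runif(1, 6, 18)
      phase <- runif(1, 0, 2 * pi)
      level <- runif(1, 0.25, 0.45)
      spec <- slice_phantom_spec(
        size, size,
        bone_profile = local({
          b <- level; p <- phase; s <- size
          function(x) s * b + 10 * sin(2 * pi * x / s + p)
        }),
        thickness_fn = local({
          a <- amp; p <- phase; s <- size
          function(x) a * (0.7 + 0.3 * cos(2 * pi * x / s + p))
        }),
        noise_sd = 6, seed = seed * 1000L + i)
      ph <- make_slice_phantom(spec)
      imgs[[i]] <- preprocess_slice(ph$gray, input_size = size)
      msks[[i]] <- ph$mask
    }
    list(images = imgs, masks = msks)
  })
}

# ---- mesh phantoms ----------------------------------------------------------

#' Construct a proper rigid transform
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation length-3 numeric vector.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  check_that(all(dim(rotation) == c(3, 3)), "rotation must be 3 x 3")
  check_that(max(abs(crossprod(rotation) - diag(3))) < 1e-9,
             "rotation must be orthogonal (R'R = I within 1e-9)")
  check_that(abs(det(rotation) - 1) < 1e-9,
             "rotation must be proper (det(R) = +1 within 1e-9)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation matrix about a coordinate axis or arbitrary unit axis
#'
#' @param angle rotation angle in radians.
#' @param axis `"x"`, `"y"`, `"z"` or a length-3 vector.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(angle, axis = "z") {
  if (is.character(axis)) {
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   abort_gm("axis must be x, y, z or a 3-vector"))
  }
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix of points.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, points) {
  points <- rbind(points)
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' Build a feature-rich dental-arch surface mesh
#'
#' A height-field surface over a horseshoe-shaped ridge with tooth-like
#' bumps, used as the base geometry for registration phantoms. Tooth cusps
#' and ridge edges give the orthographic depth maps the corner-like
#' features the keypoint detector needs.
#'
#' @param n_teeth number of tooth bumps along the arch.
#' @param grid grid resolution per side (vertex count is `grid^2`).
#' @param seed seed for the small random surface detail.
#' @return mesh: list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
make_arch_mesh <- function(n_teeth = 6, grid = 40, seed = 1) {
  u <- seq(-1, 1, length.out = grid)
  v <- seq(-1, 1, length.out = grid)
  pts <- expand.grid(x = u, y = v)
  r <- sqrt(pts$x^2 + pts$y^2)
  # ridge: annulus of radius ~0.65, height falls off away from it
  z <- 5.0 * exp(-((r - 0.65) / 0.2)^2)
  # tooth bumps along the front half of the arch
  cusp_angles <- seq(-pi * 0.75, pi * 0.75, length.out = n_teeth)
  for (a in cusp_angles) {
    cx <- 0.65 * cos(a); cy <- 0.65 * sin(a)
    d2 <- (pts$x - cx)^2 + (pts$y - cy)^2
    z <- z + 4.5 * exp(-d2 / (2 * 0.07^2))
  }
  detail <- with_seed(seed, {
    n_bump <- 30
    bx <- runif(n_bump, -0.9, 0.9); by <- runif(n_bump, -0.9, 0.9)
    bh <- runif(n_bump, -0.8, 1.1); bs <- runif(n_bump, 0.04, 0.09)
    d <- 0
    for (i in seq_len(n_bump)) {
      d <- d + bh[i] * exp(-((pts$x - bx[i])^2 + (pts$y - by[i])^2) /
                             (2 * bs[i]^2))
    }
    d
  })
  z <- z + detail * exp(-((r - 0.65) / 0.35)^2)
  verts <- unname(cbind(pts$x * 10, pts$y * 10, as.numeric(z)))
  faces <- matrix(0L, 2 * (grid - 1)^2, 3)
  f <- 1L
  for (i in seq_len(grid - 1)) {
    for (j in seq_len(grid - 1)) {
      v00 <- (j - 1L) * grid + i
      v10 <- v00 + 1L
      v01 <- v00 + grid
      v11 <- v01 + 1L
      faces[f, ] <- c(v00, v10, v11); f <- f + 1L
      faces[f, ] <- c(v00, v11, v01); f <- f + 1L
    }
  }
  list(vertices = verts, faces = faces)
}

#' Specify a registration phantom pair
#'
#' @param base_mesh triangle mesh (list with `vertices`, `faces`), at least
#'   4 non-coplanar vertices.
#' @param true_transform a [rigid_transform()] mapping source to target
#'   coordinates.
#' @param surface_noise_sd per-vertex Gaussian noise (length units) applied
#'   to the target, emulating the independent surface error of a second
#'   imaging modality.
#' @param seed integer seed for the vertex noise.
#' @return object of class `mesh_pair_spec`.
#' @export
mesh_pair_spec <- function(base_mesh, true_transform,
                           surface_noise_sd = 0, seed = 1) {
  check_that(is.list(base_mesh) && !is.null(base_mesh$vertices),
             "base_mesh must be a list with a vertices matrix")
  V <- base_mesh$vertices
  check_that(nrow(V) >= 4, "base_mesh must have at least 4 vertices")
  centered <- sweep(V, 2, colMeans(V))
  check_that(min(svd(centered)$d) > 1e-8,
             "base_mesh vertices are degenerate (coplanar)")
  check_that(inherits(true_transform, "rigid_transform"),
             "true_transform must be a rigid_transform")
  structure(list(base_mesh = base_mesh, true_transform = true_transform,
                 surface_noise_sd = surface_noise_sd,
                 seed = as.integer(seed)),
            class = "mesh_pair_spec")
}

#' Generate a source/target mesh pair related by a known rigid motion
#'
#' @param spec a [mesh_pair_spec()].
#' @return list with `source` (the base mesh), `target` (transformed +
#'   noisy copy) and `true_transform` for recovery scoring.
#' @export
make_registration_pair <- function(spec) {
  check_that(inherits(spec, "mesh_pair_spec"),
             "spec must be created with mesh_pair_spec()")
  V <- spec$base_mesh$vertices
  Vt <- apply_transform(spec$true_transform, V)
  if (spec$surface_noise_sd > 0) {
    Vt <- Vt + with_seed(spec$seed,
                         matrix(rnorm(length(Vt), 0, spec$surface_noise_sd),
                                nrow(Vt), 3))
  }
  list(source = spec$base_mesh,
       target = list(vertices = Vt, faces = spec$base_mesh$faces),
       true_transform = spec$true_transform)
}
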