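# Shared fixture builders used across the test files. Everything is
# generated in code; no stored data.

const_slice_spec <- function(width = 64, height = 64, thickness = 5,
                             noise_sd = 0, seed = 1, ...) {
  slice_phantom_spec(width, height,
                     bone_profile = function(x) 20,
                     thickness_fn = function(x) thickness,
                     noise_sd = noise_sd, seed = seed, ...)
}

# direct mask construction for scan tests: boundary row `b` (0-based),
# per-column gingiva runs given as a list of row vectors (0-based)
build_gingiva_mask <- function(H, W, rows_by_col) {
  m <- matrix(FALSE, H, W)
  for (x in seq_along(rows_by_col)) {
    rws <- rows_by_col[[x]]
    if (length(rws)) m[rws + 1L, x] <- TRUE
  }
  m
}

simple_boundary <- function(xs, ys) {
  out <- tibble::tibble(x = as.integer(xs), y = as.integer(ys))
  class(out) <- c("boundary_contour", class(out))
  out
}

tiny_model <- function(input_size = 32, seed = 1) {
  build_segmentation_network(
    model_config(input_size = input_size, width_multiplier = 0.25,
                 aspp_rates = c(2, 4, 6)),
    seed = seed)
}

tiny_dataset <- function(n = 6, size = 32, seed = 1) {
  with_seed_local <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  with_seed_local(seed, {
    imgs <- list(); msks <- list()
    for (i in seq_len(n)) {
      spec <- slice_phantom_spec(size, size,
                                 bone_profile = function(x) size * 0.35,
                                 thickness_fn = function(x) 5,
                                 noise_sd = 4, seed = seed + i)
      ph <- make_slice_phantom(spec)
      imgs[[i]] <- ph$gray / 255
      msks[[i]] <- ph$mask
    }
    list(images = imgs, masks = msks)
  })
}

random_rigid <- function(seed, max_angle_deg = 10) {
  set.seed(seed)
  ax <- rnorm(3)
  ang <- runif(1, 3, max_angle_deg) * pi / 180
  rigid_transform(rotation_about(ang, ax), runif(3, -2, 2))
}
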