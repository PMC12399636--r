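# Slice preprocessing, geometric/photometric augmentation, and
# patient-disjoint dataset splitting.

#' Preprocess a grayscale cross-sectional slice
#'
#' Pipeline order: intensity window/clip, rescale to `[0, 1]`, adaptive
#' histogram equalization (CLAHE), bilateral edge-preserving filter,
#' resize to the square network input size.
#'
#' @param gray numeric matrix (any intensity scale).
#' @param window_low,window_high intensity window; defaults are the 1st
#'   and 99th percentiles of the image. `window_low >= window_high` is an
#'   error.
#' @param input_size output resolution (default 512).
#' @param clahe_clip,clahe_tiles CLAHE clip limit and tile grid.
#' @param bilateral_d,bilateral_sigma_color,bilateral_sigma_space
#'   bilateral filter diameter and range/spatial sigmas (range sigma on
#'   the 0..255 scale).
#' @return `input_size` x `input_size` matrix with values in `[0, 1]`.
#' @export
preprocess_slice <- function(gray, window_low = NULL, window_high = NULL,
                             input_size = 512, clahe_clip = 2,
                             clahe_tiles = 8, bilateral_d = 5,
                             bilateral_sigma_color = 25,
                             bilateral_sigma_space = 5) {
  check_that(is.matrix(gray) && length(gray) > 0, "image is empty")
  auto <- is.null(window_low) || is.null(window_high)
  if (is.null(window_low)) window_low <- quantile(gray, 0.01, names = FALSE)
  if (is.null(window_high)) window_high <- quantile(gray, 0.99, names = FALSE)
  if (!auto) {
    check_that(window_low < window_high, "window_low must be < window_high")
  }
  x <- clamp(gray, window_low, window_high)
  rng <- window_high - window_low
  if (rng <= 0) {
    x <- matrix(0, nrow(gray), ncol(gray))   # degenerate constant window
  } else {
    x <- (x - window_low) / rng
  }
  if (diff(range(x)) > 0) {
    eb <- EBImage::Image(t(x))               # EBImage indexes [x, y]
    eb <- EBImage::clahe(eb, nx = clahe_tiles, ny = clahe_tiles,
                         limit = clahe_clip)
    x <- clamp(t(EBImage::imageData(eb)), 0, 1)
    x <- .cpp_bilateral(x * 255, as.integer(bilateral_d),
                        bilateral_sigma_color, bilateral_sigma_space) / 255
  }
  if (nrow(x) != input_size || ncol(x) != input_size) {
    eb <- EBImage::resize(EBImage::Image(t(x)), w = input_size,
                          h = input_size)
    x <- t(EBImage::imageData(eb))
  }
  clamp(x, 0, 1)
}

#' Randomly augment an image/mask pair
#'
#' Applies one identical geometric transform to image and mask (rotation
#' uniform in +/-15 degrees about the center, horizontal flip with
#' probability 0.5) and a photometric brightness/contrast jitter (factors
#' uniform in `[0.9, 1.1]`) to the image only. The mask is resampled with
#' nearest-neighbour interpolation so labels stay in \{0, 1, 2\}. Random
#' draws come from the current RNG state; pass `params` to fix them.
#'
#' @param image matrix in `[0, 1]`.
#' @param mask integer matrix of the same size.
#' @param params optional list(angle_deg, flip, brightness, contrast)
#'   overriding the random draws.
#' @return list with `image`, `mask` and the `params` used.
#' @export
augment_sample <- function(image, mask, params = NULL) {
  check_that(all(dim(image) == dim(mask)),
             "image and mask sizes differ")
  if (is.null(params)) {
    params <- list(angle_deg = runif(1, -15, 15),
                   flip = runif(1) < 0.5,
                   brightness = runif(1, 0.9, 1.1),
                   contrast = runif(1, 0.9, 1.1))
  }
  H <- nrow(image); W <- ncol(image)
  th <- params$angle_deg * pi / 180
  # output pixel -> source pixel: rotate about the image center, then
  # optionally mirror columns
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fm <- if (params$flip) matrix(c(-1, 0, 0, 1), 2, 2) else diag(2)
  M <- R %*% Fm
  tvec <- c(cx, cy) - M %*% c(cx, cy)
  A <- cbind(M, tvec)
  img2 <- .cpp_warp_affine(image, A, FALSE, 0)
  msk2 <- .cpp_warp_affine(mask + 0, A, TRUE, 0)
  storage.mode(msk2) <- "integer"
  img2 <- (img2 - 0.5) * params$contrast + 0.5
  img2 <- img2 * params$brightness
  list(image = clamp(img2, 0, 1), mask = msk2, params = params)
}

#' Patient-disjoint train/validation/test split
#'
#' Patients (not samples) are shuffled and partitioned so that the patient
#' counts match the ratios up to rounding (largest-remainder rule); no
#' patient contributes samples to more than one split.
#'
#' @param samples data frame with at least a `patient_id` column.
#' @param ratios length-3 ratios summing to 1 (default 7:1:2).
#' @param seed shuffle seed.
#' @return named list of tibbles `train`, `val`, `test`.
#' @export
split_by_patient <- function(samples, ratios = c(0.7, 0.1, 0.2), seed = 1) {
  check_that(!is.null(samples$patient_id),
             "samples must carry a patient_id column")
  check_that(abs(sum(ratios) - 1) < 1e-9, "ratios must sum to 1")
  pats <- unique(samples$patient_id)
  check_that(length(pats) >= 3, "need at least as many patients as splits")
  pats <- with_seed(seed, sample(pats))
  n <- length(pats)
  base <- floor(n * ratios)
  rem <- n * ratios - base
  extra <- n - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  cuts <- cumsum(base)
  groups <- list(train = pats[seq_len(cuts[1])],
                 val = pats[(cuts[1] + 1):cuts[2]],
                 test = pats[(cuts[2] + 1):cuts[3]])
  samples <- tibble::as_tibble(samples)
  lapply(groups, function(g) samples[samples$patient_id %in% g, ])
}
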