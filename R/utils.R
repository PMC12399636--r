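# Shared helpers: argument validation, seeded RNG scoping, natural-order
# filename sorting, and PNG I/O conventions used across the package.
#
# Image conventions (used everywhere):
#   * grayscale image: numeric matrix [row = y (down), col = x (right)],
#     values on the 8-bit scale 0..255 unless stated otherwise;
#   * label mask: integer matrix, same indexing, values 0 (background),
#     1 (bone/tooth), 2 (gingiva);
#   * color image: numeric array H x W x 3, channels R, G, B, 0..255.
# Pixel coordinates reported to users are 0-based (x = column index,
# y = row index, y increasing downward).

abort_gm <- function(msg, class = "gingimap_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_that <- function(ok, msg, class = "gingimap_invalid") {
  if (!isTRUE(ok)) abort_gm(msg, class = class)
  invisible(TRUE)
}

#' Evaluate an expression under a local, restorable RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Natural-order key for a filename
#' @noRd
natural_key <- function(x) {
  parts <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))[[1]]
  nums <- suppressWarnings(as.numeric(parts))
  ifelse(is.na(nums),
         parts,
         formatC(nums, width = 20, flag = "0", format = "d"))
}

natural_order <- function(filenames) {
  keys <- vapply(filenames, function(f) {
    paste(natural_key(f), collapse = "\x01")
  }, character(1))
  order(keys)
}

# ---- PNG I/O ----------------------------------------------------------------

#' Read a grayscale PNG as a 0..255 matrix
#'
#' @param path path to an 8- or 16-bit PNG.
#' @return numeric matrix (rows = y, cols = x), values scaled to 0..255.
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}

#' Write a grayscale 0..255 matrix as an 8-bit PNG
#'
#' @param img numeric matrix on the 0..255 scale.
#' @param path output path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmax(pmin(img / 255, 1), 0), path)
  invisible(path)
}

#' Read a label-mask PNG (integer class values)
#'
#' Masks are stored as 8-bit grayscale PNGs whose raw pixel values are the
#' class labels (0 background, 1 bone/tooth, 2 gingiva).
#'
#' @param path path to the mask PNG.
#' @return integer matrix of class labels.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a label mask as an 8-bit PNG
#'
#' @param mask integer matrix of class labels (small non-negative values).
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a color PNG as an H x W x 3 RGB array on the 0..255 scale
#' @param path path to a color PNG.
#' @return numeric array H x W x 3 (R, G, B).
#' @export
read_color_png <- function(path) {
  img <- png::readPNG(path)
  check_that(length(dim(img)) == 3 && dim(img)[3] >= 3,
             "expected a color PNG with at least 3 channels")
  img[, , 1:3] * 255
}

#' Write an H x W x 3 RGB array (0..255) as a PNG
#' @param img numeric array H x W x 3.
#' @param path output path.
#' @export
write_color_png <- function(img, path) {
  png::writePNG(pmax(pmin(img / 255, 1), 0), path)
  invisible(path)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# reflect arbitrary (possibly far out-of-range) indices into 1..n
reflect_index <- function(j, n) {
  if (n == 1) return(rep(1L, length(j)))
  m <- 2L * n - 2L
  j <- (j - 1L) %% m
  ifelse(j >= n, m - j, j) + 1L
}
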