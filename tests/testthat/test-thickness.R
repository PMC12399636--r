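test_that("color thresholds follow the exact red/green rules", {
  img <- array(0, c(2, 3, 3))
  img[1, 1, ] <- c(200, 10, 10)    # red -> gingiva
  img[1, 2, ] <- c(10, 200, 10)    # green -> tooth
  img[1, 3, ] <- c(100, 100, 100)  # neither
  img[2, 1, ] <- c(76, 29, 29)     # just over the red threshold
  img[2, 2, ] <- c(75, 29, 29)     # R not > 75
  m <- extract_color_masks(img)
  expect_true(m$gingiva[1, 1]); expect_false(m$tooth[1, 1])
  expect_true(m$tooth[1, 2]); expect_false(m$gingiva[1, 2])
  expect_false(m$gingiva[1, 3] || m$tooth[1, 3])
  expect_true(m$gingiva[2, 1])
  expect_false(m$gingiva[2, 2])
  expect_false(any(m$gingiva & m$tooth))
  expect_error(extract_color_masks(matrix(0, 3, 3)), "3")
})

test_that("boundary dedup rules: drop y = 0, keep min y, sort by x", {
  pts <- rbind(c(2, 5), c(2, 3), c(4, 7))
  out <- gingimap:::contour_to_boundary(pts)
  expect_equal(out$x, c(2L, 4L))
  expect_equal(out$y, c(3L, 7L))
  pts2 <- rbind(c(3, 0), c(3, 4), c(1, 2))
  out2 <- gingimap:::contour_to_boundary(pts2)
  expect_false(any(out2$x == 3 & out2$y == 0))
  expect_equal(out2$y[out2$x == 3], 4L)
})

test_that("tooth_boundary extracts the top edge of a solid rectangle", {
  mask <- matrix(FALSE, 30, 40)
  mask[11:21, 6:16] <- TRUE        # rows 10..20, cols 5..15 (0-based)
  b <- tooth_boundary(mask)
  inner <- b[b$x %in% 6:14, ]
  expect_true(all(inner$y == 10))
  expect_equal(range(b$x), c(5, 15))
  expect_error(tooth_boundary(matrix(FALSE, 5, 5)), "no tooth surface")
})

test_that("vertical scan implements the enter/exit logic", {
  # boundary y = 2 at x in 0..2; gingiva: x0 rows 3-4, x1 rows 3-5, x2 none
  g <- build_gingiva_mask(10, 3, list(c(3, 4), c(3, 4, 5), integer()))
  b <- simple_boundary(0:2, c(2, 2, 2))
  prof <- scan_thickness(g, b, "down")
  expect_equal(prof$thickness_px, c(2, 3, 0))
  # gap: counting stops at the first exit
  g2 <- build_gingiva_mask(12, 1, list(c(3, 4, 5, 8)))
  prof2 <- scan_thickness(g2, simple_boundary(0, 2), "down")
  expect_equal(prof2$thickness_px, 3)
  # run to the image edge
  g3 <- build_gingiva_mask(10, 1, list(3:9))
  prof3 <- scan_thickness(g3, simple_boundary(0, 2), "down")
  expect_equal(prof3$thickness_px, 7)
  # columns without a boundary point borrow the nearest x
  g4 <- build_gingiva_mask(10, 4, list(c(3, 4), c(3, 4), c(3, 4), c(3, 4)))
  prof4 <- scan_thickness(g4, simple_boundary(c(0, 3), c(2, 2)), "down")
  expect_equal(prof4$thickness_px, rep(2, 4))
  expect_error(scan_thickness(g4, simple_boundary(integer(), integer())),
               "empty")
})

test_that("upward scans mirror downward scans", {
  set.seed(5)
  for (rep in 1:5) {
    H <- 40; W <- 20
    b_rows <- sample(15:20, W, TRUE)
    runs <- lapply(seq_len(W), function(i) {
      n <- sample(0:8, 1)
      if (n == 0) integer() else b_rows[i] + seq_len(n)
    })
    g <- build_gingiva_mask(H, W, runs)
    bd <- simple_boundary(seq_len(W) - 1L, b_rows)
    down <- scan_thickness(g, bd, "down")
    gm <- g[H:1, ]                      # vertical mirror
    bdm <- simple_boundary(bd$x, H - 1L - bd$y)
    up <- scan_thickness(gm, bdm, "up")
    expect_equal(up$thickness_px, down$thickness_px)
  }
})

test_that("Gaussian profile smoothing preserves constants and mass", {
  p <- thickness_profile(0:3, rep(5, 4))
  expect_equal(smooth_profile(p, 2)$thickness_px, rep(5, 4))
  expect_identical(smooth_profile(p, 0), p)
  imp <- thickness_profile(0:20, c(rep(0, 10), 10, rep(0, 10)))
  sm <- smooth_profile(imp, 1)
  expect_equal(sum(sm$thickness_px), 10, tolerance = 1e-6)
  expect_true(all(sm$thickness_px >= 0))
  expect_equal(nrow(sm), 21)
  expect_error(smooth_profile(p, -1), "sigma")
})

test_that("measure_slice equals the phantom oracle on noise-free slices", {
  spec <- slice_phantom_spec(96, 96,
                             bone_profile = function(x) 30 + 6 * cos(x / 7),
                             thickness_fn = function(x)
                               8 + 4 * sin(2 * pi * x / 96),
                             noise_sd = 0)
  ph <- make_slice_phantom(spec)
  m <- measure_slice(colorize_labels(ph$mask), measure_config(sigma = 0))
  expect_equal(m$rows$thickness_px, ph$true_profile$thickness_px)
  expect_equal(m$rows$thickness_mm, ph$true_profile$thickness_px * 0.1)
  expect_error(measure_slice(array(0, c(32, 32, 3))), "no tooth surface")
})

test_that("auto direction picks the side holding the gingiva", {
  spec <- const_slice_spec(thickness = 6)
  ph <- make_slice_phantom(spec)
  img <- colorize_labels(ph$mask)
  m <- measure_slice(img, measure_config(direction = "auto", sigma = 0))
  expect_equal(m$direction, "down")
  flipped <- img[nrow(img):1, , ]
  m2 <- measure_slice(flipped, measure_config(direction = "auto", sigma = 0))
  expect_equal(m2$direction, "up")
  expect_equal(m2$rows$thickness_px, m$rows$thickness_px)
})

test_that("overlays mark boundaries in yellow and leave the source intact", {
  spec <- const_slice_spec(thickness = 4)
  ph <- make_slice_phantom(spec)
  img <- colorize_labels(ph$mask)
  before <- img
  m <- measure_slice(img, measure_config(sigma = 0))
  expect_identical(img, before)
  expect_equal(dim(m$overlay), dim(img))
  b1 <- m$boundary[1, ]
  expect_equal(m$overlay[b1$y + 1, b1$x + 1, ], c(255, 255, 0))
  # zero-thickness columns draw no measurement line
  spec0 <- slice_phantom_spec(64, 64, function(x) 20,
                              function(x) ifelse(x < 32, 0, 5), noise_sd = 0)
  ph0 <- make_slice_phantom(spec0)
  m0 <- measure_slice(colorize_labels(ph0$mask), measure_config(sigma = 0))
  col10 <- m0$overlay[, 11, ]   # x = 10: boundary dot only, no blue line
  blue <- which(col10[, 1] == 120 & col10[, 3] == 255)
  expect_length(blue, 0)
})
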