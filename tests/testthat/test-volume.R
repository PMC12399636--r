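test_that("natural sorting compares embedded numbers as integers", {
  out <- natural_sort_slices(c("slice10.png", "slice2.png", "slice1.png"))
  expect_equal(out$filename, c("slice1.png", "slice2.png", "slice10.png"))
  expect_equal(out$slice_number, 1:3)
  one <- natural_sort_slices("only.png")
  expect_equal(one$slice_number, 1)
  sorted <- c("a1.png", "a2.png", "a3.png")
  expect_equal(natural_sort_slices(sorted)$filename, sorted)
  expect_error(natural_sort_slices(c("a.png", "a.png")), "duplicate")
})

test_that("merged tables concatenate rows in natural slice order", {
  mk_rows <- function(nm, n = 4, t0 = 1) {
    tibble::tibble(image_name = nm, x = 0:(n - 1),
                   thickness_px = t0 + 0:(n - 1),
                   thickness_mm = (t0 + 0:(n - 1)) * 0.1,
                   direction = "down")
  }
  rows <- list("slice10.png" = mk_rows("slice10.png"),
               "slice2.png" = mk_rows("slice2.png"),
               "slice1.png" = mk_rows("slice1.png"))
  tab <- merge_tables(rows)
  expect_equal(nrow(tab), 12)
  expect_equal(unique(tab$image_name),
               c("slice1.png", "slice2.png", "slice10.png"))
  expect_equal(tab$slice_number[tab$image_name == "slice10.png"],
               rep(3L, 4))
  # ten slices: slice10 carries slice_number 10
  rows10 <- setNames(lapply(sprintf("slice%d.png", 1:10), mk_rows),
                     sprintf("slice%d.png", 1:10))
  tab10 <- merge_tables(rows10)
  expect_equal(unique(tab10$slice_number[tab10$image_name == "slice10.png"]),
               10L)
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_thickness_table(tab, f)
  back <- read_thickness_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("grid meshes have M*N vertices and 2(M-1)(N-1) triangles", {
  mk_tab <- function(M, N) {
    tab <- tibble::tibble(image_name = "s",
                          slice_number = rep(seq_len(M), each = N),
                          x = rep(seq_len(N) - 1, M),
                          thickness_px = seq_len(M * N),
                          thickness_mm = seq_len(M * N) * 0.1,
                          direction = "down")
    class(tab) <- c("thickness_table", class(tab))
    tab
  }
  for (M in 2:6) {
    for (N in 2:6) {
      s <- grid_mesh(mk_tab(M, N))
      expect_equal(nrow(s$vertices), M * N)
      expect_equal(nrow(s$triangles), 2 * (M - 1) * (N - 1))
    }
  }
  # one missing cell in a 2x2 grid: 3 vertices, no complete quad
  t22 <- mk_tab(2, 2)[-4, ]
  s22 <- grid_mesh(t22)
  expect_equal(nrow(s22$vertices), 3)
  expect_equal(nrow(s22$triangles), 0)
  expect_error(grid_mesh(mk_tab(1, 5)), "2 slices")
})

test_that("grid meshes scale axes physically and color by thickness", {
  tab <- tibble::tibble(image_name = "s",
                        slice_number = rep(1:2, each = 2),
                        x = rep(c(0, 10), 2),
                        thickness_px = c(1, 2, 3, 4),
                        thickness_mm = c(0.1, 0.2, 0.3, 0.4),
                        direction = "down")
  class(tab) <- c("thickness_table", class(tab))
  s <- grid_mesh(tab, slice_mm = 0.3, pixel_mm = 0.1)
  expect_equal(sort(unique(s$vertices[, 1])), c(0.3, 0.6))
  expect_equal(sort(unique(s$vertices[, 2])), c(0, 1))
  expect_equal(s$colors[which.min(s$thickness), ], c(0L, 0L, 255L))
  expect_equal(s$colors[which.max(s$thickness), ], c(255L, 0L, 0L))
})

test_that("Laplacian smoothing relaxes spikes and fixes planes", {
  tab <- tibble::tibble(image_name = "s",
                        slice_number = rep(1:3, each = 3),
                        x = rep(0:2, 3),
                        thickness_px = rep(1, 9),
                        thickness_mm = rep(1, 9),
                        direction = "down")
  class(tab) <- c("thickness_table", class(tab))
  flat <- grid_mesh(tab)
  expect_equal(laplacian_smooth(flat, 5)$vertices, flat$vertices)
  spike <- flat
  spike$vertices[5, 3] <- 2           # center vertex of the 3x3 grid
  spike$thickness[5] <- 2
  out <- laplacian_smooth(spike, 1, lambda_factor = 1)
  # center moves exactly to the mean of its edge neighbours (all at 1)
  expect_equal(out$vertices[5, 3], 1)
  expect_identical(laplacian_smooth(spike, 0), spike)
  # z range never expands
  set.seed(3)
  spike$vertices[, 3] <- runif(9)
  rng0 <- range(spike$vertices[, 3])
  sm <- laplacian_smooth(spike, 10, 0.8)
  expect_gte(min(sm$vertices[, 3]), rng0[1])
  expect_lte(max(sm$vertices[, 3]), rng0[2])
  expect_error(laplacian_smooth(flat, 1, 1.5), "lambda")
})

test_that("the thickness colormap runs blue-green-yellow-red monotonically", {
  v <- seq(0, 1, length.out = 101)
  cm <- thickness_colormap(v)
  expect_equal(cm[1, ], c(0L, 0L, 255L))
  expect_equal(cm[101, ], c(255L, 0L, 0L))
  third <- thickness_colormap(c(0, 1 / 3, 1))[2, ]
  expect_equal(third, c(0L, 255L, 0L))
  # hue order blue -> green -> yellow -> red is monotone in thickness
  hues <- grDevices::rgb2hsv(t(cm))[1, ]
  expect_true(all(diff(hues) <= 1e-9))
  const <- thickness_colormap(rep(2, 5))
  expect_equal(nrow(unique(const)), 1)
  expect_equal(const[1, ], thickness_colormap(c(0, 0.5, 1))[2, ])
  expect_error(thickness_colormap(numeric(0)), "values")
  expect_error(thickness_colormap(c(1, NA)), "finite")
})

test_that("surface export round-trips through PLY and OBJ", {
  tab <- tibble::tibble(image_name = "s",
                        slice_number = rep(1:3, each = 4),
                        x = rep(0:3, 3),
                        thickness_px = 1:12,
                        thickness_mm = (1:12) * 0.1,
                        direction = "down")
  class(tab) <- c("thickness_table", class(tab))
  surf <- grid_mesh(tab)
  f <- tempfile(fileext = ".ply")
  export_surface(surf, f)
  back <- read_ply(f)
  expect_equal(nrow(back$vertices), 12)
  expect_equal(nrow(back$faces), nrow(surf$triangles))
  expect_identical(back$colors, surf$colors)
  expect_equal(back$vertices, unname(surf$vertices), tolerance = 1e-6)
  fa <- tempfile(fileext = ".ply")
  export_surface(surf, fa, binary = FALSE)
  backa <- read_ply(fa)
  expect_identical(backa$colors, surf$colors)
  fo <- tempfile(fileext = ".obj")
  export_surface(surf, fo)
  obj <- readLines(fo)
  expect_equal(sum(startsWith(obj, "v ")), 12)
  expect_equal(sum(startsWith(obj, "f ")), nrow(surf$triangles))
  expect_error(export_surface(surf, tempfile(fileext = ".xyz")),
               "unsupported")
})

test_that("distribution plots are written as non-empty PNGs", {
  tab <- tibble::tibble(image_name = rep(c("s1", "s2"), each = 16),
                        slice_number = rep(1:2, each = 16),
                        x = rep(0:15, 2),
                        thickness_px = runif(32, 2, 10),
                        thickness_mm = runif(32, 0.2, 1),
                        direction = "down")
  class(tab) <- c("thickness_table", class(tab))
  d <- tempfile()
  plot_distribution(tab, out_dir = d)
  for (f in file.path(d, c("scatter.png", "curves.png"))) {
    expect_true(file.exists(f))
    expect_gt(file.size(f), 1000)
  }
  expect_error(plot_distribution(tab[0, ]), "empty")
})
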