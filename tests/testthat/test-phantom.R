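test_that("noise-free phantom masks contain exactly round(t(x)) gingiva pixels per column", {
  spec <- slice_phantom_spec(64, 64,
                             bone_profile = function(x) 20 + 5 * sin(x / 9),
                             thickness_fn = function(x) 3 + 0.1 * x,
                             noise_sd = 0)
  ph <- make_slice_phantom(spec)
  counts <- colSums(ph$mask == 2L)
  expect_equal(counts, round(3 + 0.1 * (0:63)), ignore_attr = TRUE)
  # the hand-evaluated column: x = 40 -> 3 + 4.0 = 7 pixels
  expect_identical(sum(ph$mask[, 41] == 2L), 7L)
  # band sits directly below the boundary row
  b <- round(20 + 5 * sin(40 / 9))
  expect_true(all(ph$mask[b + 1 + seq_len(7), 41] == 2L))
  expect_identical(ph$mask[b + 1, 41], 1L)
})

test_that("constant and zero-thickness bands behave as specified", {
  ph <- make_slice_phantom(const_slice_spec(thickness = 5))
  expect_true(all(colSums(ph$mask == 2L) == 5L))
  spec <- slice_phantom_spec(64, 64,
                             bone_profile = function(x) 20,
                             thickness_fn = function(x) ifelse(x < 10, 0, 6),
                             noise_sd = 0)
  ph2 <- make_slice_phantom(spec)
  expect_true(all(colSums(ph2$mask[, 1:10] == 2L) == 0L))
  expect_true(all(colSums(ph2$mask[, 11:64] == 2L) == 6L))
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- const_slice_spec(noise_sd = 7, seed = 42)
  a <- make_slice_phantom(spec)
  b <- make_slice_phantom(spec)
  expect_identical(a$gray, b$gray)
  expect_identical(a$mask, b$mask)
  c <- make_slice_phantom(const_slice_spec(noise_sd = 7, seed = 43))
  expect_false(identical(a$gray, c$gray))
})

test_that("invalid slice specs name the violated invariant", {
  expect_error(slice_phantom_spec(16, 64, function(x) 10, function(x) 3),
               "width and height")
  expect_error(slice_phantom_spec(64, 64, function(x) 10,
                                  function(x) -1),
               "thickness_fn")
  expect_error(slice_phantom_spec(64, 64, function(x) 60,
                                  function(x) 10),
               "bone_profile")
})

test_that("series phantoms follow the thickness field and naming contract", {
  base <- const_slice_spec()
  spec <- series_phantom_spec(3, base, function(k, x) 4)
  out <- make_series_phantom(spec)
  expect_named(out, c("slice1.png", "slice2.png", "slice3.png"))
  for (s in out) expect_true(all(colSums(s$mask == 2L) == 4L))
  # field depends on the 0-based slice index
  spec2 <- series_phantom_spec(4, base, function(k, x) k + 1)
  out2 <- make_series_phantom(spec2)
  expect_true(all(colSums(out2[[3]]$mask == 2L) == 3L))
  spec12 <- series_phantom_spec(12, base, function(k, x) 4)
  nm <- names(make_series_phantom(spec12))
  expect_true(all(c("slice2.png", "slice10.png") %in% nm))
  expect_error(series_phantom_spec(1, base, function(k, x) 4), "n_slices")
})

test_that("colorize_labels matches the red/green convention and round-trips", {
  mask <- matrix(0L, 8, 8)
  expect_equal(colorize_labels(mask), array(0, c(8, 8, 3)))
  mask[3, 4] <- 2L
  img <- colorize_labels(mask)
  expect_equal(img[3, 4, ], c(255, 0, 0))
  mask[5, 6] <- 1L
  img <- colorize_labels(mask)
  expect_equal(img[5, 6, ], c(0, 255, 0))
  em <- extract_color_masks(img)
  rt <- matrix(0L, 8, 8)
  rt[em$tooth] <- 1L
  rt[em$gingiva] <- 2L
  expect_identical(rt, mask)
  expect_error(colorize_labels(matrix(3L, 2, 2)), "labels")
})

test_that("registration pairs apply the stated rigid motion", {
  mesh <- make_arch_mesh(grid = 8)
  idp <- make_registration_pair(mesh_pair_spec(mesh, rigid_transform()))
  expect_equal(idp$target$vertices, mesh$vertices)
  tp <- make_registration_pair(
    mesh_pair_spec(mesh, rigid_transform(diag(3), c(5, 0, 0))))
  expect_equal(tp$target$vertices[1, ], mesh$vertices[1, ] + c(5, 0, 0))
  # hand rotation arithmetic: 10 degrees about z on (1, 0, 0)
  R <- rotation_about(10 * pi / 180, "z")
  expect_equal(as.numeric(R %*% c(1, 0, 0)),
               c(cos(10 * pi / 180), sin(10 * pi / 180), 0),
               tolerance = 1e-12)
  # degenerate mesh rejected
  flat <- list(vertices = cbind(runif(10), runif(10), 0),
               faces = cbind(1:8, 2:9, 3:10))
  expect_error(mesh_pair_spec(flat, rigid_transform()), "degenerate")
})

test_that("noisy registration targets are seeded and reproducible", {
  mesh <- make_arch_mesh(grid = 8)
  sp <- mesh_pair_spec(mesh, random_rigid(1), surface_noise_sd = 0.05,
                       seed = 9)
  a <- make_registration_pair(sp)
  b <- make_registration_pair(sp)
  expect_identical(a$target$vertices, b$target$vertices)
  expect_false(identical(a$target$vertices,
                         apply_transform(sp$true_transform, mesh$vertices)))
})
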