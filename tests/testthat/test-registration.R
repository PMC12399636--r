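test_that("projection views sit at the prescribed azimuths and are deterministic", {
  mesh <- make_arch_mesh(grid = 16)
  views <- render_projections(mesh, n_views = 9)
  expect_length(views, 9)
  expect_equal(vapply(views, function(v) v$angle, numeric(1)),
               (0:8) * 2 * pi / 9)
  views2 <- render_projections(mesh, n_views = 9)
  for (i in 1:9) expect_identical(views[[i]]$image, views2[[i]]$image)
  expect_error(render_projections(list(vertices = matrix(0, 0, 3),
                                       faces = matrix(0L, 0, 3))),
               "empty")
  expect_error(render_projections(mesh, n_views = 1), "n_views")
})

test_that("orthographic silhouettes span extent/pixel_scale pixels", {
  # unit cube
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  f <- rbind(c(1, 2, 4), c(1, 4, 3), c(5, 8, 6), c(5, 7, 8),
             c(1, 5, 6), c(1, 6, 2), c(3, 8, 7), c(3, 4, 8),
             c(1, 7, 5), c(1, 3, 7), c(2, 6, 8), c(2, 8, 4))
  ps <- 0.1
  view <- render_projections(list(vertices = v, faces = f), n_views = 4,
                             pixel_scale = ps)[[1]]
  cols <- which(colSums(is.finite(view$image)) > 0)
  rows <- which(rowSums(is.finite(view$image)) > 0)
  expect_equal(diff(range(cols)), 1 / ps)
  expect_equal(diff(range(rows)), 1 / ps)
})

test_that("backprojection inverts rendering within pixel_scale", {
  mesh <- make_arch_mesh(grid = 24, seed = 2)
  check_roundtrip <- function(ps) {
    view <- render_projections(mesh, n_views = 9, pixel_scale = ps)[[3]]
    kps <- detect_keypoints(view)
    kps <- kps[gingimap:::has_depth(view, kps[, 1], kps[, 2]), ,
               drop = FALSE]
    expect_gt(nrow(kps), 3)
    pts <- backproject(kps[, 1:2, drop = FALSE], view)
    # each back-projected point must lie near the mesh surface
    nn <- gingimap:::.cpp_nn_index(pts, mesh$vertices)
    median(nn$dist)
  }
  ps <- max(apply(mesh$vertices, 2, function(v) diff(range(v)))) / 256
  err1 <- check_roundtrip(ps)
  expect_lt(err1, 8 * ps)
  # undefined depth raises an error
  view <- render_projections(mesh, pixel_scale = ps)[[1]]
  empty_px <- which(!is.finite(view$image), arr.ind = TRUE)[1, ]
  expect_error(backproject(c(empty_px[2] - 1, empty_px[1] - 1), view),
               "silhouette")
})

test_that("a view matches itself with zero displacement", {
  mesh <- make_arch_mesh(grid = 32, seed = 3)
  ps <- max(apply(mesh$vertices, 2, function(v) diff(range(v)))) / 256
  view <- render_projections(mesh, pixel_scale = ps)[[1]]
  m <- detect_and_match(view, view, seed = 1)
  expect_gt(nrow(m), 10)
  expect_equal(m$xA, m$xB)
  expect_equal(m$yA, m$yB)
  model <- attr(m, "model")
  expect_equal(model$scale, 1, tolerance = 1e-6)
  expect_lt(abs(model$tx) + abs(model$ty), 1e-6)
})

test_that("a translated view is recovered as a pure shift", {
  mesh <- make_arch_mesh(grid = 32, seed = 3)
  ps <- max(apply(mesh$vertices, 2, function(v) diff(range(v)))) / 256
  view <- render_projections(mesh, pixel_scale = ps)[[1]]
  shifted <- view
  img <- view$image
  shifted$image <- cbind(matrix(NA_real_, nrow(img), 5),
                         img[, 1:(ncol(img) - 5)])
  m <- detect_and_match(view, shifted, seed = 1)
  model <- attr(m, "model")
  expect_equal(model$tx, 5, tolerance = 0.5)
  expect_equal(model$ty, 0, tolerance = 0.5)
})

test_that("matching against unrelated noise is flagged", {
  mesh <- make_arch_mesh(grid = 32, seed = 3)
  ps <- max(apply(mesh$vertices, 2, function(v) diff(range(v)))) / 256
  view <- render_projections(mesh, pixel_scale = ps)[[1]]
  noise <- view
  set.seed(4)
  noise$image <- matrix(runif(length(view$image), 0, max(view$image,
                                                         na.rm = TRUE)),
                        nrow(view$image))
  m <- suppressWarnings(detect_and_match(view, noise, seed = 1))
  expect_true(isTRUE(attr(m, "flagged")))
})

test_that("landmark stability ranks view support and spread as specified", {
  mk <- function(n_views, spread) {
    P <- matrix(rnorm(3 * n_views, sd = spread / sqrt(3)), ncol = 3)
    P <- sweep(P, 2, colMeans(P))   # exact centered spread
    structure(list(positions = sweep(P, 2, c(1, 2, 3), `+`),
                   target_positions = P, views = seq_len(n_views),
                   stability = n_views /
                     (1 + sqrt(mean(rowSums(P^2))))),
              class = "landmark_candidate")
  }
  set.seed(1)
  allviews <- mk(9, 0)
  once <- mk(1, 0)
  expect_gt(allviews$stability, once$stability)
  sel <- select_landmarks(list(once, allviews), k = 1)
  expect_identical(sel[[1]], allviews)
  tight <- mk(4, 0.1); loose <- mk(4, 0.2)
  expect_gt(tight$stability, loose$stability)
  expect_warning(select_landmarks(list(once), k = 10), "candidates")
  # k = 10 from a 55-candidate pool returns exactly 10
  pool <- replicate(55, mk(sample(1:9, 1), runif(1, 0, 1)),
                    simplify = FALSE)
  expect_length(select_landmarks(pool, 10), 10)
})

test_that("pooled candidates are capped and penalize target-side scatter", {
  set.seed(2)
  src <- matrix(rnorm(300), ncol = 3)
  dst <- src + 1
  cands <- pool_landmark_candidates(src, dst, rep(1:4, 25),
                                    cluster_radius = 0.1,
                                    max_candidates = 55)
  expect_lte(length(cands), 55)
  # same source cluster, scattered targets -> lower stability
  srcc <- matrix(rep(c(0, 0, 0), 4), ncol = 3, byrow = TRUE)
  good <- pool_landmark_candidates(srcc, srcc + 1, 1:4, 0.5)[[1]]
  bad <- pool_landmark_candidates(srcc,
                                  matrix(rnorm(12, sd = 3), ncol = 3),
                                  1:4, 0.5)[[1]]
  expect_gt(good$stability, bad$stability)
})

test_that("the closed-form rigid fit recovers exact transforms", {
  set.seed(5)
  src <- matrix(rnorm(30), ncol = 3)
  expect_equal(estimate_rigid(src, src)$rotation, diag(3),
               tolerance = 1e-12)
  tfit <- estimate_rigid(src, sweep(src, 2, c(5, 0, 0), `+`))
  expect_equal(tfit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tfit$translation, c(5, 0, 0), tolerance = 1e-9)
  R <- rotation_about(30 * pi / 180, "z")
  rfit <- estimate_rigid(src, src %*% t(R))
  ang <- acos((sum(diag(rfit$rotation %*% t(R))) - 1) / 2)
  expect_lt(ang * 180 / pi, 1e-6)
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(estimate_rigid(line, line), "collinear")
  # returned transforms are proper rotations
  for (i in 1:10) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    fit <- estimate_rigid(A, B)
    expect_lt(max(abs(crossprod(fit$rotation) - diag(3))), 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("ICP is a fixed point at the truth and recovers perturbations", {
  mesh <- make_arch_mesh(grid = 24, seed = 6)
  tr <- random_rigid(11)
  pair <- make_registration_pair(mesh_pair_spec(mesh, tr, 0))
  centers <- mesh$vertices[seq(1, nrow(mesh$vertices), by = 60), ]
  refined <- icp_refine(pair$source, pair$target, tr, centers,
                        region_radius = 3)
  trace <- attr(refined, "objective_trace")
  expect_lt(trace[length(trace)], 1e-9)
  e <- transform_error(refined, tr)
  expect_lt(e$rotation_deg, 1e-6)
  # perturbed start on a noise-free pair converges back
  pert <- rigid_transform(tr$rotation %*% rotation_about(2 * pi / 180, "y"),
                          tr$translation + c(0.1, 0, 0))
  ref2 <- icp_refine(pair$source, pair$target, pert, centers,
                     region_radius = 5)
  e2 <- transform_error(ref2, tr)
  expect_lt(e2$rotation_deg, 0.1)
  tr2 <- attr(ref2, "objective_trace")
  expect_true(all(diff(tr2) <= 1e-12))
  expect_error(icp_refine(pair$source, pair$target, tr,
                          matrix(c(1e6, 1e6, 1e6), 1), 0.1),
               "no source vertices")
})

test_that("the full registration pipeline recovers identity and mild motion", {
  mesh <- make_arch_mesh(grid = 32, seed = 7)
  res_id <- register_meshes(mesh, mesh, register_config(seed = 1))
  e <- transform_error(res_id$transform, rigid_transform())
  expect_lt(e$rotation_deg, 0.1)
  expect_lt(e$translation, 0.1 * res_id$pixel_scale)
  tr <- random_rigid(21)
  pair <- make_registration_pair(mesh_pair_spec(mesh, tr, 0.05, seed = 3))
  res <- register_meshes(pair$source, pair$target, register_config(seed = 2))
  err <- transform_error(res$transform, tr)
  expect_lt(err$rotation_deg, 1)
  expect_lt(err$translation, res$pixel_scale)
  expect_true(all(diff(res$objective_trace) <= 1e-12))
  expect_equal(res$n_landmarks, 10)
  # transform JSON round trip
  f <- tempfile(fileext = ".json")
  write_transform_json(res$transform, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(matrix(js$rotation, 3, 3, byrow = TRUE),
               res$transform$rotation, tolerance = 1e-12)
})
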