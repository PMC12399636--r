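# Feature-based rigid registration of two surface meshes (e.g. an
# intraoral-scan surface and a CBCT-derived surface of the same dentition).
#
# The 3-D feature detection problem is reduced to 2-D: both meshes are
# rendered as orthographic depth maps from a ring of azimuths (default
# step 2*pi/9), corner-like keypoints are detected on the depth maps
# (Harris detector) and described with SIFT-style gradient-orientation
# histograms, matches are screened with RANSAC under a 2-D similarity
# model, surviving matches are back-projected to 3-D, pooled into
# landmark candidates (capped at 55), ranked by geometric stability, and
# the 10 most stable landmarks seed a closed-form rigid fit that is
# refined by ICP restricted to the surface near the landmarks.

# ---- projection rendering ---------------------------------------------------

#' Render orthographic depth-map projections of a mesh
#'
#' Views are taken at azimuths `k * 2*pi/n_views` about the vertical axis
#' (z). Each view stores the geometry needed to invert a pixel back to 3-D
#' (axes, origin offsets and the per-pixel depth along the view ray).
#'
#' @param mesh list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @param n_views number of azimuths (>= 2, default 9).
#' @param pixel_scale length units per pixel; default scales the mesh's
#'   largest extent to ~128 pixels.
#' @param margin empty border in pixels around the silhouette.
#' @return list of `projection_view` objects with fields `angle`, `image`
#'   (depth matrix, NA outside the silhouette), `pixel_scale`, `e1`, `e2`,
#'   `dir`, `u0`, `w0`, `margin`.
#' @export
render_projections <- function(mesh, n_views = 9, pixel_scale = NULL,
                               margin = 4) {
  check_that(!is.null(mesh$vertices) && nrow(mesh$vertices) > 0 &&
               !is.null(mesh$faces) && nrow(mesh$faces) > 0,
             "mesh is empty")
  check_that(n_views >= 2, "n_views must be >= 2")
  V <- mesh$vertices
  if (is.null(pixel_scale)) {
    pixel_scale <- max(apply(V, 2, function(v) diff(range(v)))) / 128
  }
  lapply(seq_len(n_views) - 1L, function(k) {
    angle <- k * 2 * pi / n_views
    d <- c(cos(angle), sin(angle), 0)
    e1 <- c(-sin(angle), cos(angle), 0)
    e2 <- c(0, 0, 1)
    u <- V %*% e1
    w <- V %*% e2
    dep <- V %*% d
    u0 <- min(u); w0 <- max(w)
    Wpx <- ceiling((max(u) - u0) / pixel_scale) + 1 + 2 * margin
    Hpx <- ceiling((w0 - min(w)) / pixel_scale) + 1 + 2 * margin
    Vv <- cbind((u - u0) / pixel_scale + margin,
                (w0 - w) / pixel_scale + margin,
                dep)
    img <- .cpp_rasterize(Vv, mesh$faces - 1L, as.integer(Hpx),
                          as.integer(Wpx))
    structure(list(angle = angle, image = img, pixel_scale = pixel_scale,
                   e1 = e1, e2 = e2, dir = d, u0 = u0, w0 = w0,
                   margin = margin),
              class = "projection_view")
  })
}

#' Back-project a pixel of a projection view to 3-D
#'
#' Exact inverse of the orthographic render mapping; the depth buffer
#' supplies the coordinate along the view ray.
#'
#' @param px numeric length-2 (x = column, y = row; 0-based pixel coords)
#'   or an n x 2 matrix of pixels.
#' @param view a `projection_view`.
#' @return numeric 3-vector, or n x 3 matrix for matrix input.
#' @export
backproject <- function(px, view) {
  one <- is.null(dim(px))
  px <- rbind(px)
  xi <- round(px[, 1]); yi <- round(px[, 2])
  H <- nrow(view$image); W <- ncol(view$image)
  check_that(all(xi >= 0 & xi < W & yi >= 0 & yi < H),
             "pixel outside the view image")
  dep <- view$image[cbind(yi + 1, xi + 1)]
  check_that(all(is.finite(dep)),
             "pixel outside the silhouette (undefined depth)")
  u <- (px[, 1] - view$margin) * view$pixel_scale + view$u0
  w <- view$w0 - (px[, 2] - view$margin) * view$pixel_scale
  pts <- outer(u, view$e1) + outer(w, view$e2) + outer(dep, view$dir)
  if (one) drop(pts) else pts
}

has_depth <- function(view, x, y) {
  xi <- round(x); yi <- round(y)
  inside <- xi >= 0 & xi < ncol(view$image) & yi >= 0 & yi < nrow(view$image)
  out <- inside
  out[inside] <- is.finite(view$image[cbind(yi[inside] + 1, xi[inside] + 1)])
  out
}

# ---- keypoints and descriptors ---------------------------------------------

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with reflected edges
conv_sep <- function(img, k) {
  r <- (length(k) - 1) / 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (d in seq_along(k)) {
    out <- out + k[d] * img[reflect_index(seq_len(H) + d - 1 - r, H), ]
  }
  out2 <- matrix(0, H, W)
  for (d in seq_along(k)) {
    out2 <- out2 + k[d] * out[, reflect_index(seq_len(W) + d - 1 - r, W)]
  }
  out2
}

view_height_map <- function(view) {
  img <- view$image
  far <- max(img, na.rm = TRUE)
  h <- far - img
  h[is.na(h)] <- 0
  h / view$pixel_scale      # heights in pixel units, scale-consistent
}

local_extrema <- function(R, radius = 3, maxima = TRUE) {
  H <- nrow(R); W <- ncol(R)
  nm <- matrix(TRUE, H, W)
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      if (dy == 0 && dx == 0) next
      sh <- matrix(if (maxima) -Inf else Inf, H, W)
      ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
      vy <- ys >= 1 & ys <= H; vx <- xs >= 1 & xs <= W
      sh[vy, vx] <- R[ys[vy], xs[vx]]
      nm <- nm & if (maxima) (R >= sh) else (R <= sh)
    }
  }
  nm
}

view_gradients <- function(view, smooth = 1.5) {
  h <- conv_sep(view_height_map(view), gauss_kernel1d(smooth))
  H <- nrow(h); W <- ncol(h)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (h[, 3:W] - h[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (h[3:H, ] - h[1:(H - 2), ]) / 2
  list(h = h, gx = gx, gy = gy)
}

#' Detect keypoints on a projection view's depth map
#'
#' Combines the SIFT-style difference-of-Gaussians blob detector (extrema
#' of DoG fire on tooth cusps and surface bumps) with the Harris corner
#' detector, with non-maximum suppression. Depth maps are converted to
#' height maps (scale-normalized by pixel_scale) first.
#'
#' @param view a `projection_view`.
#' @param max_keypoints keep at most this many strongest keypoints.
#' @param dog_sigmas the two Gaussian scales of the DoG detector.
#' @param dog_quality,harris_quality relative response thresholds.
#' @param min_distance non-maximum suppression radius (pixels).
#' @param border exclusion border so descriptor support fits (pixels).
#' @return matrix with columns x, y (0-based pixel coords) and response
#'   (normalized, max 1).
#' @export
detect_keypoints <- function(view, max_keypoints = 200,
                             dog_sigmas = c(2, 3.2), dog_quality = 0.02,
                             harris_quality = 0.002, min_distance = 3,
                             border = 17) {
  h0 <- view_height_map(view)
  H <- nrow(h0); W <- ncol(h0)
  if (H <= 2 * border + 2 || W <= 2 * border + 2) {
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x", "y", "response"))))
  }
  dog <- conv_sep(h0, gauss_kernel1d(dog_sigmas[1])) -
    conv_sep(h0, gauss_kernel1d(dog_sigmas[2]))
  dmax <- max(abs(dog))
  blobs <- (local_extrema(dog, min_distance, TRUE) &
              dog > dog_quality * dmax) |
    (local_extrema(dog, min_distance, FALSE) & dog < -dog_quality * dmax)
  g <- view_gradients(view)
  k <- gauss_kernel1d(2)
  Sxx <- conv_sep(g$gx * g$gx, k)
  Syy <- conv_sep(g$gy * g$gy, k)
  Sxy <- conv_sep(g$gx * g$gy, k)
  R <- (Sxx * Syy - Sxy^2) - 0.06 * (Sxx + Syy)^2
  rmax <- max(R)
  corners <- local_extrema(R, min_distance, TRUE) & R > harris_quality * rmax
  cand <- blobs | corners
  cand[c(seq_len(border), (H - border + 1):H), ] <- FALSE
  cand[, c(seq_len(border), (W - border + 1):W)] <- FALSE
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x", "y", "response"))))
  }
  score <- pmax(abs(dog[idx]) / max(dmax, 1e-12), R[idx] / max(rmax, 1e-12))
  o <- order(score, decreasing = TRUE)
  o <- o[seq_len(min(length(o), max_keypoints))]
  cbind(x = idx[o, 2] - 1, y = idx[o, 1] - 1, response = score[o])
}

# SIFT-style descriptor: 32x32 gradient patch, 4x4 cells x 8 orientation
# bins, Gaussian-weighted, normalized, clipped at 0.2, renormalized.
# Upright (no orientation normalization): all views share pixel scale and
# the in-plane rotation between modalities is small.
describe_keypoints <- function(view, kps, half = 16) {
  g <- view_gradients(view)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ori <- atan2(g$gy, g$gx)        # [-pi, pi]
  offs <- (-half):(half - 1)
  wts <- exp(-(outer(offs + 0.5, offs + 0.5,
                     function(a, b) a^2 + b^2)) / (2 * (0.75 * half)^2))
  cell <- pmin((offs + half) %/% (half / 2), 3)   # 0..3
  cr <- matrix(cell, 2 * half, 2 * half)
  cc <- matrix(cell, 2 * half, 2 * half, byrow = TRUE)
  n <- nrow(kps)
  D <- matrix(0, n, 128)
  for (i in seq_len(n)) {
    cx <- kps[i, "x"] + 1; cy <- kps[i, "y"] + 1
    rows <- cy + offs; cols <- cx + offs
    m <- mag[rows, cols] * wts
    o <- ori[rows, cols]
    bin <- floor((o + pi) / (2 * pi) * 8) %% 8      # 0..7
    code <- (cr * 4 + cc) * 8 + bin + 1             # 1..128
    v <- vapply(split(as.vector(m), as.vector(code)), sum, numeric(1))
    d <- numeric(128)
    d[as.integer(names(v))] <- v
    nrm <- sqrt(sum(d^2))
    if (nrm > 0) d <- d / nrm
    d <- pmin(d, 0.2)
    nrm <- sqrt(sum(d^2))
    if (nrm > 0) d <- d / nrm
    D[i, ] <- d
  }
  D
}

# ---- matching with RANSAC screening ----------------------------------------

ls_similarity <- function(a, b) {
  # complex least-squares similarity q*a + t = b
  am <- mean(a); bm <- mean(b)
  den <- sum(Mod(a - am)^2)
  q <- if (den > 0) sum((b - bm) * Conj(a - am)) / den else complex(real = 1)
  t <- bm - q * am
  list(q = q, t = t)
}

#' Detect, describe and match keypoints between two projection views
#'
#' Putative matches (mutual nearest descriptor with Lowe ratio test) are
#' screened with RANSAC under a 2-D similarity model (inlier threshold
#' 2 px, 1000 iterations, seeded); only inlier correspondences are
#' returned.
#'
#' @param viewA,viewB `projection_view` objects rendered at the same
#'   `pixel_scale`.
#' @param seed RANSAC seed.
#' @param ransac_iters,ransac_thresh RANSAC iteration count and inlier
#'   threshold in pixels.
#' @param ratio Lowe ratio-test threshold (1 disables the ratio test and
#'   keeps all mutual nearest-neighbour matches).
#' @param scale_range admissible similarity scale range; projections share
#'   pixel_scale, so the true model is near scale 1.
#' @param min_inliers matches below this count are flagged unreliable.
#' @return tibble with columns `xA, yA, xB, yB` (0-based pixel coords) of
#'   inlier correspondences; attributes `model` (list with `scale`,
#'   `angle`, `tx`, `ty`), `n_putative` and `flagged`.
#' @export
detect_and_match <- function(viewA, viewB, seed = 1,
                             ransac_iters = 1000, ransac_thresh = 2,
                             ratio = 1, scale_range = c(0.8, 1.25),
                             min_inliers = 8) {
  check_that(abs(viewA$pixel_scale - viewB$pixel_scale) < 1e-12,
             "views must share pixel_scale")
  empty <- function(n_put) {
    out <- tibble::tibble(xA = numeric(0), yA = numeric(0),
                          xB = numeric(0), yB = numeric(0))
    attr(out, "model") <- NULL
    attr(out, "n_putative") <- n_put
    attr(out, "flagged") <- TRUE
    out
  }
  kA <- detect_keypoints(viewA); kB <- detect_keypoints(viewB)
  if (nrow(kA) < 2 || nrow(kB) < 2) {
    warning("too few keypoints for matching")
    return(empty(0L))
  }
  dA <- describe_keypoints(viewA, kA)
  dB <- describe_keypoints(viewB, kB)
  # cosine distances via cross-products (descriptors are unit-ish)
  S <- dA %*% t(dB)
  d2 <- pmax(2 - 2 * S, 0)       # squared Euclidean for unit vectors
  bestB <- apply(d2, 1, which.min)
  bestA <- apply(d2, 2, which.min)
  mutual <- bestA[bestB] == seq_len(nrow(kA))
  if (ratio < 1 && ncol(d2) >= 2) {
    ord2 <- apply(d2, 1, function(r) sort(r, partial = 2)[1:2])
    mutual <- mutual &
      (sqrt(ord2[1, ]) < ratio * sqrt(pmax(ord2[2, ], 1e-12)))
  }
  sel <- which(mutual)
  if (length(sel) < 4) {
    warning("fewer than 4 putative matches; returning empty correspondence set")
    return(empty(length(sel)))
  }
  a <- complex(real = kA[sel, "x"], imaginary = kA[sel, "y"])
  b <- complex(real = kB[bestB[sel], "x"], imaginary = kB[bestB[sel], "y"])
  n <- length(a)
  best_in <- logical(n); best_cnt <- -1L
  with_seed(seed, {
    for (it in seq_len(ransac_iters)) {
      ij <- sample.int(n, 2)
      da <- a[ij[2]] - a[ij[1]]
      if (Mod(da) < 1e-9) next
      q <- (b[ij[2]] - b[ij[1]]) / da
      if (Mod(q) < scale_range[1] || Mod(q) > scale_range[2]) next
      t <- b[ij[1]] - q * a[ij[1]]
      resid <- Mod(q * a + t - b)
      inl <- resid < ransac_thresh
      if (sum(inl) > best_cnt) {
        best_cnt <- sum(inl)
        best_in <- inl
      }
    }
  })
  if (best_cnt < 2) return(empty(n))
  fit <- ls_similarity(a[best_in], b[best_in])
  resid <- Mod(fit$q * a + fit$t - b)
  inl <- resid < ransac_thresh
  if (sum(inl) >= 2) {
    fit <- ls_similarity(a[inl], b[inl])
  } else {
    inl <- best_in
  }
  out <- tibble::tibble(xA = Re(a[inl]), yA = Im(a[inl]),
                        xB = Re(b[inl]), yB = Im(b[inl]))
  attr(out, "model") <- list(scale = Mod(fit$q), angle = Arg(fit$q),
                             tx = Re(fit$t), ty = Im(fit$t))
  attr(out, "n_putative") <- n
  attr(out, "flagged") <- sum(inl) < min_inliers
  out
}

# ---- landmark pooling and selection ----------------------------------------

#' Pool 3-D correspondences into landmark candidates
#'
#' Back-projected inlier correspondences from all view pairs are clustered
#' greedily by proximity of their source-side 3-D positions
#' (radius = `cluster_radius`); at most `max_candidates` clusters are kept
#' (largest first). Each candidate records the views it was detected in and
#' a geometric stability score:
#' `stability = n_views_detected / (1 + RMS spread of positions)`.
#'
#' @param src_pts,dst_pts n x 3 matrices of corresponding 3-D points.
#' @param view_ids integer view index per correspondence.
#' @param cluster_radius pooling radius (length units).
#' @param max_candidates candidate pool cap (default 55).
#' @return list of `landmark_candidate` objects.
#' @export
pool_landmark_candidates <- function(src_pts, dst_pts, view_ids,
                                     cluster_radius, max_candidates = 55) {
  n <- nrow(src_pts)
  check_that(n > 0, "no correspondences to pool")
  assigned <- integer(n)
  centers <- list()
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(centers)) {
      if (sqrt(sum((src_pts[i, ] - centers[[ci]])^2)) <= cluster_radius) {
        hit <- ci; break
      }
    }
    if (hit == 0L) {
      centers[[length(centers) + 1L]] <- src_pts[i, ]
      hit <- length(centers)
    }
    assigned[i] <- hit
  }
  sizes <- tabulate(assigned)
  keep <- order(sizes, decreasing = TRUE)
  keep <- keep[seq_len(min(length(keep), max_candidates))]
  lapply(keep, function(ci) {
    rows <- which(assigned == ci)
    P <- src_pts[rows, , drop = FALSE]
    Q <- dst_pts[rows, , drop = FALSE]
    spread_src <- sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))
    spread_dst <- sqrt(mean(rowSums(sweep(Q, 2, colMeans(Q))^2)))
    # a landmark is stable only if BOTH sides agree across views;
    # aliased matches (e.g. one tooth off) scatter on the target side
    spread <- max(spread_src, spread_dst)
    structure(list(positions = P,
                   target_positions = Q,
                   views = view_ids[rows],
                   stability = length(unique(view_ids[rows])) / (1 + spread)),
              class = "landmark_candidate")
  })
}

#' Select the k most geometrically stable landmark candidates
#'
#' @param candidates list of `landmark_candidate` objects.
#' @param k number of landmarks to keep (default 10).
#' @return the k candidates with highest stability (ties broken by lower
#'   candidate index); all candidates with a warning when fewer than k.
#' @export
select_landmarks <- function(candidates, k = 10) {
  check_that(length(candidates) >= 1, "no landmark candidates")
  if (length(candidates) < k) {
    warning(sprintf("only %d candidates available (requested %d)",
                    length(candidates), k))
    k <- length(candidates)
  }
  st <- vapply(candidates, function(cd) cd$stability, numeric(1))
  ord <- order(-st, seq_along(st))
  candidates[ord[seq_len(k)]]
}

# ---- rigid fitting ----------------------------------------------------------

#' Closed-form least-squares rigid fit (Kabsch/SVD, no scaling)
#'
#' @param src_pts,dst_pts n x 3 matrices (n >= 3, non-collinear) of
#'   corresponding points.
#' @return a [rigid_transform()] minimizing mean squared correspondence
#'   distance, with `det(R) = +1` enforced.
#' @export
estimate_rigid <- function(src_pts, dst_pts) {
  src_pts <- rbind(src_pts); dst_pts <- rbind(dst_pts)
  check_that(nrow(src_pts) >= 3 && nrow(dst_pts) == nrow(src_pts),
             "need >= 3 corresponding points")
  sc <- colMeans(src_pts); dc <- colMeans(dst_pts)
  A <- sweep(src_pts, 2, sc); B <- sweep(dst_pts, 2, dc)
  sv <- svd(t(A) %*% B)
  check_that(sv$d[2] > 1e-12 * max(sv$d[1], 1e-300),
             "degenerate (collinear) point configuration")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(R, dc - as.numeric(R %*% sc))
}

# robust rigid fit: exhaustive/random triples + consensus, final Kabsch
# refit on the inlier set; guards the landmark-based initialization
# against residual mismatches
estimate_rigid_robust <- function(src_pts, dst_pts, inlier_thresh,
                                  max_trials = 500, seed = 1) {
  n <- nrow(src_pts)
  if (n < 4) return(estimate_rigid(src_pts, dst_pts))
  triples <- utils::combn(n, 3)
  if (ncol(triples) > max_trials) {
    sel <- with_seed(seed, sample.int(ncol(triples), max_trials))
    triples <- triples[, sel, drop = FALSE]
  }
  best_in <- NULL; best_cnt <- -1L
  for (k in seq_len(ncol(triples))) {
    ij <- triples[, k]
    fit <- tryCatch(estimate_rigid(src_pts[ij, ], dst_pts[ij, ]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    resid <- sqrt(rowSums((apply_transform(fit, src_pts) - dst_pts)^2))
    cnt <- sum(resid < inlier_thresh)
    if (cnt > best_cnt) {
      best_cnt <- cnt
      best_in <- resid < inlier_thresh
    }
  }
  if (is.null(best_in) || sum(best_in) < 3) {
    return(estimate_rigid(src_pts, dst_pts))
  }
  estimate_rigid(src_pts[best_in, , drop = FALSE],
                 dst_pts[best_in, , drop = FALSE])
}

#' Refine a rigid transform by local ICP
#'
#' Point-to-point ICP restricted to source vertices within
#' `region_radius` of any landmark center; alternates nearest-neighbour
#' correspondence against the target vertices with a Kabsch refit. The
#' objective (mean nearest-neighbour distance) is recorded per iteration
#' and is non-increasing; iteration stops at relative change < `tol` or
#' `max_iter` iterations.
#'
#' @param src_mesh,dst_mesh meshes (lists with `vertices`).
#' @param init initial [rigid_transform()].
#' @param region_centers k x 3 matrix of landmark centers (source frame).
#' @param region_radius inclusion radius around each center.
#' @param max_iter,tol stopping parameters.
#' @return refined [rigid_transform()] with attribute `objective_trace`.
#' @export
icp_refine <- function(src_mesh, dst_mesh, init, region_centers,
                       region_radius, max_iter = 50, tol = 1e-6) {
  check_that(inherits(init, "rigid_transform"), "init must be a rigid_transform")
  region_centers <- rbind(region_centers)
  check_that(nrow(region_centers) > 0, "region_centers is empty")
  V <- src_mesh$vertices
  nn <- .cpp_nn_index(V, region_centers)
  P <- V[nn$dist <= region_radius, , drop = FALSE]
  check_that(nrow(P) >= 3,
             "no source vertices inside the landmark regions")
  Q_all <- dst_mesh$vertices
  cur <- init
  trace <- numeric(0)
  prev_obj <- Inf
  for (it in seq_len(max_iter)) {
    Pt <- apply_transform(cur, P)
    nn <- .cpp_nn_index(Pt, Q_all)
    obj <- mean(nn$dist)
    if (obj > prev_obj) break     # guard: never report an increase
    trace <- c(trace, obj)
    if (is.finite(prev_obj) && (prev_obj - obj) < tol * max(prev_obj, 1e-12)) {
      break
    }
    prev_obj <- obj
    cur <- estimate_rigid(P, Q_all[nn$index, , drop = FALSE])
  }
  attr(cur, "objective_trace") <- trace
  cur
}

# ---- full pipeline ----------------------------------------------------------

#' Registration configuration
#'
#' @param n_views number of projection azimuths (default 9, step 2*pi/9).
#' @param pixel_scale projection resolution (length/px); `NULL` = auto.
#' @param k_landmarks landmarks used for the initial fit (default 10).
#' @param max_candidates candidate pool cap (default 55).
#' @param cluster_radius_px landmark pooling radius in pixels (default 2).
#' @param region_radius_px ICP region radius in pixels (default 20 at the
#'   default rendering resolution of ~256 px per mesh extent, i.e. a
#'   tooth-sized neighbourhood around each landmark).
#' @param match_window each source view is matched against target views
#'   within this azimuth-index window (default 0 = same index only; with
#'   the default 9 views, neighbouring azimuths are 40 degrees apart and
#'   rarely match).
#' @param ransac_iters,ransac_thresh,seed RANSAC controls.
#' @return list of class `register_config`.
#' @export
register_config <- function(n_views = 9, pixel_scale = NULL,
                            k_landmarks = 10, max_candidates = 55,
                            cluster_radius_px = 2, region_radius_px = 20,
                            match_window = 0, ransac_iters = 1000,
                            ransac_thresh = 2, seed = 1) {
  structure(list(n_views = n_views, pixel_scale = pixel_scale,
                 k_landmarks = k_landmarks, max_candidates = max_candidates,
                 cluster_radius_px = cluster_radius_px,
                 region_radius_px = region_radius_px,
                 match_window = match_window, ransac_iters = ransac_iters,
                 ransac_thresh = ransac_thresh, seed = seed),
            class = "register_config")
}

#' Register two surface meshes (full pipeline)
#'
#' Composes [render_projections()], [detect_and_match()],
#' [backproject()], [pool_landmark_candidates()], [select_landmarks()],
#' [estimate_rigid()] and [icp_refine()] into the complete coarse-to-fine
#' registration. Returns the transform mapping `source` coordinates into
#' `target` coordinates.
#'
#' @param source,target meshes (lists with `vertices`, `faces`).
#' @param config a [register_config()].
#' @return object of class `registration_result`: list with `transform`
#'   (a [rigid_transform()]), `n_landmarks`, `n_correspondences`,
#'   `objective_trace` and `final_objective`.
#' @export
register_meshes <- function(source, target, config = register_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_gm(sprintf("registration stage '%s' failed: %s",
                       name, conditionMessage(e)))
    })
  }
  ps <- config$pixel_scale
  if (is.null(ps)) {
    # fine enough that tooth-scale features span tens of pixels
    ps <- max(apply(source$vertices, 2,
                    function(v) diff(range(v)))) / 256
  }
  viewsA <- stage("render", render_projections(source, config$n_views, ps))
  viewsB <- stage("render", render_projections(target, config$n_views, ps))
  src_pts <- NULL; dst_pts <- NULL; view_ids <- integer(0)
  nv <- config$n_views
  for (i in seq_len(nv)) {
    for (dj in -config$match_window:config$match_window) {
      j <- ((i - 1 + dj) %% nv) + 1
      corr <- stage("match", suppressWarnings(
        detect_and_match(viewsA[[i]], viewsB[[j]],
                         seed = config$seed + i * 131 + j,
                         ransac_iters = config$ransac_iters,
                         ransac_thresh = config$ransac_thresh)))
      if (nrow(corr) == 0 || isTRUE(attr(corr, "flagged"))) next
      ok <- has_depth(viewsA[[i]], corr$xA, corr$yA) &
        has_depth(viewsB[[j]], corr$xB, corr$yB)
      corr <- corr[ok, , drop = FALSE]
      if (nrow(corr) == 0) next
      pa <- stage("backproject",
                  backproject(cbind(corr$xA, corr$yA), viewsA[[i]]))
      pb <- stage("backproject",
                  backproject(cbind(corr$xB, corr$yB), viewsB[[j]]))
      src_pts <- rbind(src_pts, pa)
      dst_pts <- rbind(dst_pts, pb)
      view_ids <- c(view_ids, rep(i, nrow(corr)))
    }
  }
  check_that(!is.null(src_pts) && nrow(src_pts) >= 3,
             "registration stage 'match' failed: no usable correspondences")
  cands <- stage("pool",
                 pool_landmark_candidates(src_pts, dst_pts, view_ids,
                                          cluster_radius =
                                            config$cluster_radius_px * ps,
                                          max_candidates =
                                            config$max_candidates))
  marks <- stage("select",
                 suppressWarnings(select_landmarks(cands,
                                                   config$k_landmarks)))
  src_ctr <- t(vapply(marks, function(m) colMeans(m$positions), numeric(3)))
  dst_ctr <- t(vapply(marks, function(m) colMeans(m$target_positions),
                      numeric(3)))
  init <- stage("estimate_rigid",
                estimate_rigid_robust(src_ctr, dst_ctr,
                                      inlier_thresh = 4 * ps,
                                      seed = config$seed))
  refined <- stage("icp",
                   icp_refine(source, target, init, src_ctr,
                              region_radius = config$region_radius_px * ps))
  trace <- attr(refined, "objective_trace")
  structure(list(transform = refined,
                 n_landmarks = length(marks),
                 n_correspondences = nrow(src_pts),
                 objective_trace = trace,
                 final_objective = trace[length(trace)],
                 pixel_scale = ps),
            class = "registration_result")
}

#' Angular and translational error between two rigid transforms
#'
#' @param est,truth [rigid_transform()] objects.
#' @return list with `rotation_deg` (geodesic rotation error in degrees)
#'   and `translation` (Euclidean norm of the translation error).
#' @export
transform_error <- function(est, truth) {
  Rerr <- est$rotation %*% t(truth$rotation)
  ang <- acos(clamp((sum(diag(Rerr)) - 1) / 2, -1, 1))
  list(rotation_deg = ang * 180 / pi,
       translation = sqrt(sum((est$translation - truth$translation)^2)))
}

#' Write a rigid transform to JSON
#'
#' @param transform a [rigid_transform()].
#' @param path output JSON path (rotation as 9 floats row-major,
#'   translation as 3 floats).
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(transform$rotation)),
                            translation = transform$translation),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
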