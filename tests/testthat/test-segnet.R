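test_that("cross-entropy loss matches hand-computed values", {
  # perfect one-hot prediction
  p <- rbind(c(1, 0), c(0, 1))
  expect_lt(cross_entropy_loss(p, p), 1e-9)
  # single pixel, uniform prediction: -log 0.5
  expect_equal(cross_entropy_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0))),
               -log(0.5), tolerance = 1e-4)
  expect_equal(round(cross_entropy_loss(rbind(c(0.5, 0.5)),
                                        rbind(c(1, 0))), 4), 0.6931)
  # doubling the true-class weight doubles the loss
  l1 <- cross_entropy_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0)), c(1, 1))
  l2 <- cross_entropy_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0)), c(2, 1))
  expect_equal(l2, 2 * l1)
  expect_error(cross_entropy_loss(rbind(c(0.7, 0.7)), rbind(c(1, 0))),
               "sum to 1")
})

test_that("Dice loss matches hand-computed overlap values", {
  expect_lt(dice_loss(rbind(c(1, 0)), rbind(c(1, 0))), 1e-6)
  expect_equal(dice_loss(rbind(c(1, 0)), rbind(c(0, 1))), 1,
               tolerance = 1e-6)
  expect_equal(dice_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0))), 1 / 3,
               tolerance = 1e-4)
  expect_equal(round(dice_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0))), 4),
               0.3333)
})

test_that("composite loss is the weighted sum of its terms", {
  p <- rbind(c(0.5, 0.5), c(0.2, 0.8))
  y <- rbind(c(1, 0), c(0, 1))
  expect_equal(composite_loss(p, y, loss_config(alpha = 1, beta = 0)),
               cross_entropy_loss(p, y))
  expect_equal(composite_loss(p, y, loss_config(alpha = 0, beta = 1)),
               dice_loss(p, y))
  expect_equal(composite_loss(p, y, loss_config(alpha = 1, beta = 1)),
               cross_entropy_loss(p, y) + dice_loss(p, y))
  expect_error(loss_config(alpha = 0, beta = 0), "alpha")
})

test_that("dice and composite losses stay within their bounds", {
  set.seed(2)
  for (i in 1:50) {
    z <- matrix(rnorm(12), 4, 3)
    p <- exp(z) / rowSums(exp(z))
    y <- diag(3)[sample(1:3, 4, TRUE), ]
    expect_gte(dice_loss(p, y), 0)
    expect_lte(dice_loss(p, y), 1)
    expect_gte(composite_loss(p, y), 0)
  }
})

test_that("batch-size-adaptive learning rate evaluates and clamps correctly", {
  cfg <- training_config()
  expect_equal(adjusted_learning_rate(16, cfg), 7e-3)
  cfg2 <- training_config(lr_init = 7e-3, lr_min = 7e-5, lr_max = 7e-3)
  expect_equal(adjusted_learning_rate(8, cfg2), 3.5e-3)
  cfg3 <- training_config(lr_init = 7e-3, lr_min = 1e-3)
  expect_equal(adjusted_learning_rate(1, cfg3), 1e-3)       # lower clamp
  cfg4 <- training_config(lr_init = 7e-3, lr_max = 8e-3)
  expect_equal(adjusted_learning_rate(64, cfg4), 8e-3)      # upper clamp
  # monotone non-decreasing in batch size
  lrs <- vapply(1:64, adjusted_learning_rate, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) >= 0))
})

test_that("cosine annealing hits its endpoints and midpoint", {
  cfg <- training_config(total_epochs = 100, freeze_epochs = 10)
  base <- adjusted_learning_rate(cfg$batch_freeze, cfg)
  expect_equal(cosine_lr(0, cfg), base)
  expect_equal(cosine_lr(50, cfg, batch_size = cfg$batch_freeze),
               (base + cfg$lr_min) / 2)
  eps_end <- cosine_lr(99, cfg, batch_size = cfg$batch_freeze)
  expect_lt(eps_end, cfg$lr_min + 0.002 * base)
  expect_error(cosine_lr(100, cfg), "epoch")
  expect_error(cosine_lr(-1, cfg), "epoch")
})

test_that("network output has the input spatial shape and C channels", {
  net <- tiny_model(input_size = 32)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  out <- segnet_forward(net, x)
  expect_equal(dim(out$value), c(32, 32, 3, 2))
  # a different valid input size through the same fully-convolutional net
  x2 <- array(runif(48 * 48), c(48, 48, 1, 1))
  out2 <- segnet_forward(net, x2)
  expect_equal(dim(out2$value), c(48, 48, 3, 1))
  expect_error(model_config(input_size = 100, downsample_factor = 16),
               "divisible")
})

test_that("encoder taps and ASPP structure match the architecture contract", {
  net <- tiny_model(input_size = 32)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  fts <- segnet_forward(net, x, return_features = TRUE)
  expect_equal(dim(fts$low_level$value)[1:2], c(8, 8))    # 1/4 resolution
  expect_equal(dim(fts$deep$value)[1:2], c(2, 2))         # 1/16 resolution
  expect_equal(dim(fts$deep$value)[3], 80L)               # 320 * 0.25 scaled
  aspp_branches <- c("b1", "b2", "b3", "b4", "pool")
  expect_true(all(aspp_branches %in% names(net$aspp)))
  expect_length(aspp_branches, 5)
  expect_error(model_config(aspp_rates = c(6, 6, 12)), "increasing")
})

test_that("network gradients agree with finite differences", {
  set.seed(3)
  net <- tiny_model(input_size = 32, seed = 2)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  lab <- array(sample(0:2, 32 * 32 * 2, TRUE), c(32, 32, 2))
  lcfg <- loss_config()
  cw <- c(1.2, 0.8, 1.5)
  tp <- gingimap:::tape_new()
  out <- segnet_forward(net, x, training = TRUE, tape = tp)
  lg <- gingimap:::segnet_loss_grad(out$value, lab, lcfg, cw)
  gingimap:::tape_backward(tp, out, lg$grad)
  lossf <- function() {
    o <- segnet_forward(net, x, training = TRUE, tape = NULL)
    gingimap:::segnet_loss_grad(o$value, lab, lcfg, cw)$loss
  }
  p <- net$params[[3]]
  ga <- p$grad[1]
  expect_gt(abs(ga), 1e-8)       # a live path
  old <- p$value[1]; eps <- 1e-6
  l1 <- lossf(); p$value[1] <- old + eps; l2 <- lossf(); p$value[1] <- old
  expect_equal((l2 - l1) / eps, ga, tolerance = 1e-3)
})

test_that("probabilities from the head are a valid softmax", {
  net <- tiny_model(input_size = 32)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  out <- segnet_forward(net, x)
  pm <- gingimap:::logits_to_probs(out$value)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(max(abs(rowSums(pm) - 1)) < 1e-12)
})

test_that("staged training freezes the backbone and logs validation entries", {
  ds <- tiny_dataset(n = 8, size = 32)
  datasets <- list(train = list(images = ds$images[1:6],
                                masks = ds$masks[1:6]),
                   val = list(images = ds$images[7:8],
                              masks = ds$masks[7:8]))
  net <- tiny_model(input_size = 32, seed = 4)
  backbone_before <- lapply(Filter(function(p) p$group == "backbone",
                                   net$params), function(p) p$value)
  tcfg <- training_config(freeze_epochs = 3, total_epochs = 5,
                          eval_every = 2, batch_freeze = 4,
                          batch_unfreeze = 2, seed = 1)
  res <- train_staged(net, datasets, tcfg, loss_config(), augment = FALSE)
  backbone_mid <- lapply(Filter(function(p) p$group == "backbone",
                                res$net$params), function(p) p$value)
  # training ran past the freeze phase: backbone must have moved by the end
  expect_false(isTRUE(all.equal(backbone_before, backbone_mid)))
  expect_equal(res$history$phase, c(rep("freeze", 3), rep("unfreeze", 2)))
  expect_equal(which(!is.na(res$history$val_miou)), c(2, 4))
  expect_false(is.null(res$best$state))
})

test_that("backbone parameters are bit-identical across the freeze phase", {
  ds <- tiny_dataset(n = 4, size = 32)
  datasets <- list(train = list(images = ds$images, masks = ds$masks),
                   val = list(images = list(), masks = list()))
  net <- tiny_model(input_size = 32, seed = 5)
  before <- lapply(Filter(function(p) p$group == "backbone", net$params),
                   function(p) p$value)
  head_before <- lapply(Filter(function(p) p$group == "head", net$params),
                        function(p) p$value)
  # run exactly the 3 frozen epochs of a 3 + 1 staged schedule
  res <- train_staged(net, datasets,
                      training_config(freeze_epochs = 3, total_epochs = 4,
                                      eval_every = 100, batch_freeze = 2,
                                      batch_unfreeze = 2, seed = 1),
                      loss_config(), augment = FALSE, stop_after = 3)
  after <- lapply(Filter(function(p) p$group == "backbone",
                         res$net$params), function(p) p$value)
  head_after <- lapply(Filter(function(p) p$group == "head",
                              res$net$params), function(p) p$value)
  expect_identical(before, after)                 # backbone bit-unchanged
  expect_false(isTRUE(all.equal(head_before, head_after)))  # head trained
})

test_that("augmentation keeps labels valid and flips map columns", {
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(sample(0:2, 32 * 32, TRUE), 32, 32)
  idp <- list(angle_deg = 0, flip = FALSE, brightness = 1, contrast = 1)
  a <- augment_sample(img, mask, idp)
  expect_equal(a$image, img, tolerance = 1e-12)
  expect_identical(a$mask, mask)
  fl <- augment_sample(img, mask, modifyList(idp, list(flip = TRUE)))
  expect_identical(fl$mask, mask[, 32:1])
  set.seed(8)
  for (i in 1:100) {
    a <- augment_sample(img, mask)
    expect_true(all(a$mask %in% 0:2))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  expect_error(augment_sample(img, mask[1:16, ]), "size")
})

test_that("patient-wise splitting is disjoint and matches the 7:1:2 ratio", {
  samples10 <- tibble::tibble(id = 1:30,
                              patient_id = rep(1:10, each = 3))
  sp <- split_by_patient(samples10, seed = 3)
  counts <- vapply(sp, function(s) length(unique(s$patient_id)), numeric(1))
  expect_equal(unname(counts), c(7, 1, 2))
  expect_length(intersect(sp$train$patient_id, sp$val$patient_id), 0)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_length(intersect(sp$val$patient_id, sp$test$patient_id), 0)
  samples50 <- tibble::tibble(patient_id = rep(1:50, each = 2))
  sp50 <- split_by_patient(samples50, seed = 1)
  expect_equal(unname(vapply(sp50, function(s)
    length(unique(s$patient_id)), numeric(1))), c(35, 5, 10))
  expect_error(split_by_patient(tibble::tibble(patient_id = 1:2)),
               "patients")
})

test_that("preprocessing maps any input to [0, 1] at the target size", {
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  out <- preprocess_slice(img, input_size = 128)
  expect_equal(dim(out), c(128, 128))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  const <- matrix(42, 48, 48)
  outc <- preprocess_slice(const, input_size = 48)
  expect_equal(max(outc) - min(outc), 0)
  expect_error(preprocess_slice(img, window_low = 10, window_high = 5),
               "window")
})

test_that("save/load round-trips a network bit-exactly", {
  net <- tiny_model(input_size = 32, seed = 6)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  y1 <- segnet_forward(net, x)$value
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  net2 <- load_network(f)
  y2 <- segnet_forward(net2, x)$value
  expect_identical(y1, y2)
})
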