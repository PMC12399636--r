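# Encoder-decoder semantic segmentation network (DeepLabV3+ layout with a
# MobileNetV2 backbone), its composite cross-entropy + Dice loss, the
# batch-size-adaptive cosine learning-rate schedule and the staged
# freeze/unfreeze SGD training loop.
#
# The encoder taps two scales: a low-level feature map at 1/4 of the input
# resolution (nominally 24 channels before width scaling) and the deep
# backbone map at 1/16 (nominally 320 channels). The ASPP head has five
# parallel branches (1x1 conv, three 3x3 dilated convs at the configured
# rates, and global average pooling); the decoder upsamples the ASPP
# output, concatenates the projected low-level features, refines, and
# projects to the class scores at full input resolution.

make_divisible <- function(v, divisor = 8) {
  nv <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

#' Segmentation model configuration
#'
#' @param n_classes number of output classes C (default 3: background,
#'   bone/tooth, gingiva).
#' @param input_size square input resolution in pixels; must be divisible
#'   by `downsample_factor`.
#' @param downsample_factor encoder output stride (default 16).
#' @param aspp_rates dilation rates of the three dilated ASPP branches,
#'   strictly increasing (default 6, 12, 18).
#' @param low_level_channels nominal channel width of the 1/4-resolution
#'   encoder tap (default 24, scaled by `width_multiplier`).
#' @param backbone_channels nominal channel width of the deep encoder map
#'   (default 320, scaled by `width_multiplier`).
#' @param width_multiplier channel width multiplier for desk-scale models
#'   (default 1).
#' @param in_channels input image channels (default 1, grayscale).
#' @param aspp_channels,decoder_channels nominal ASPP / decoder widths
#'   (scaled by `width_multiplier`).
#' @param low_level_proj nominal width of the decoder's low-level
#'   projection (default 48, scaled).
#' @param aspp_separable,decoder_separable factorize the 3x3 convolutions
#'   in the ASPP branches / decoder refinement as depthwise-separable
#'   convolutions (default TRUE), consistent with the backbone's
#'   lightweight design.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_classes = 3, input_size = 512,
                         downsample_factor = 16,
                         aspp_rates = c(6, 12, 18),
                         low_level_channels = 24, backbone_channels = 320,
                         width_multiplier = 1, in_channels = 1,
                         aspp_channels = 256, decoder_channels = 256,
                         low_level_proj = 48,
                         aspp_separable = TRUE, decoder_separable = TRUE) {
  check_that(input_size %% downsample_factor == 0,
             "input_size must be divisible by downsample_factor")
  check_that(length(aspp_rates) == 3 && all(diff(aspp_rates) > 0),
             "aspp_rates must be three strictly increasing integers")
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 downsample_factor = as.integer(downsample_factor),
                 aspp_rates = as.integer(aspp_rates),
                 low_level_channels = as.integer(low_level_channels),
                 backbone_channels = as.integer(backbone_channels),
                 width_multiplier = width_multiplier,
                 in_channels = as.integer(in_channels),
                 aspp_channels = as.integer(aspp_channels),
                 decoder_channels = as.integer(decoder_channels),
                 low_level_proj = as.integer(low_level_proj),
                 aspp_separable = aspp_separable,
                 decoder_separable = decoder_separable),
            class = "model_config")
}

# ---- layer constructors -----------------------------------------------------

conv_make <- function(kh, kw, cin, cout, stride = 1, dil = 1,
                      depthwise = FALSE, group = "head") {
  pad <- ((kh - 1L) %/% 2L) * dil
  fan <- if (depthwise) kh * kw else kh * kw * cin
  wdim <- if (depthwise) c(kh, kw, cin) else c(kh, kw, cin, cout)
  w <- array(rnorm(prod(wdim), 0, sqrt(2 / fan)), wdim)
  nb <- if (depthwise) cin else cout
  list(w = make_param(w, decay = TRUE, group = group),
       b = make_param(numeric(nb), decay = FALSE, group = group),
       stride = as.integer(stride), pad = as.integer(pad),
       dil = as.integer(dil), depthwise = depthwise)
}

bn_make <- function(C, group = "head") {
  state <- new.env(parent = emptyenv())
  state$mean <- numeric(C)
  state$var <- rep(1, C)
  list(gamma = make_param(rep(1, C), decay = FALSE, group = group),
       beta = make_param(numeric(C), decay = FALSE, group = group),
       state = state)
}

cbr_make <- function(kh, cin, cout, stride = 1, dil = 1,
                     depthwise = FALSE, relu = TRUE, group = "head") {
  list(conv = conv_make(kh, kh, cin, if (depthwise) cin else cout,
                        stride, dil, depthwise, group),
       bn = bn_make(if (depthwise) cin else cout, group),
       relu = relu)
}

fwd_cbr <- function(tape, x, cb, training) {
  x <- op_conv(tape, x, cb$conv)
  op_bn(tape, x, cb$bn, training, relu6 = cb$relu)
}

inverted_residual_make <- function(cin, cout, stride, expand, dil,
                                   group = "backbone") {
  hidden <- cin * expand
  list(expand = if (expand != 1) cbr_make(1, cin, hidden, group = group),
       dw = cbr_make(3, hidden, hidden, stride = stride, dil = dil,
                     depthwise = TRUE, group = group),
       project = cbr_make(1, hidden, cout, relu = FALSE, group = group),
       use_res = stride == 1 && cin == cout)
}

fwd_block <- function(tape, x, blk, training) {
  y <- x
  if (!is.null(blk$expand)) y <- fwd_cbr(tape, y, blk$expand, training)
  y <- fwd_cbr(tape, y, blk$dw, training)
  y <- fwd_cbr(tape, y, blk$project, training)
  if (blk$use_res) y <- op_add(tape, x, y)
  y
}

collect_params <- function(x) {
  out <- list()
  rec <- function(v) {
    if (is.environment(v)) {
      out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (nm in names(v)) {
        if (nm %in% c("state")) next
        rec(v[[nm]])
      }
      if (is.null(names(v))) for (e in v) rec(e)
    }
  }
  rec(x)
  Filter(function(p) !is.null(p$value), out)
}

#' Build the segmentation network
#'
#' Constructs the MobileNetV2-style backbone (inverted residual blocks,
#' output stride = `downsample_factor`, later stages dilated), the
#' five-branch ASPP head and the decoder. Backbone weights are trained
#' from scratch; [set_backbone_frozen()] switches gradient updates for the
#' backbone on and off.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the weight initialization.
#' @return object of class `segnet` (list of layers plus the flat
#'   parameter list used by the optimizer).
#' @export
build_segmentation_network <- function(config = model_config(), seed = 1) {
  check_that(inherits(config, "model_config"), "config must be a model_config")
  wm <- config$width_multiplier
  os <- config$downsample_factor
  with_seed(seed, {
    ch_stem <- make_divisible(32 * wm)
    settings <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2),
                     c(6, 64, 4, 2), c(6, 96, 3, 1), c(6, 160, 3, 2),
                     c(6, 320, 1, 1))
    stem <- cbr_make(3, config$in_channels, ch_stem, stride = 2,
                     group = "backbone")
    cs <- 2L; dil <- 1L
    cin <- ch_stem
    groups <- list()
    low_level_group <- 2L   # output of the 24-channel stage, stride 4
    for (gi in seq_along(settings)) {
      s <- settings[[gi]]
      t <- s[1]; cout <- make_divisible(s[2] * wm); n <- s[3]; st <- s[4]
      blocks <- list()
      for (bi in seq_len(n)) {
        if (bi == 1) {
          if (cs * st > os) {
            st_eff <- 1L
            dil <- dil * st
          } else {
            st_eff <- st
            cs <- cs * st
          }
        } else {
          st_eff <- 1L
        }
        blocks[[bi]] <- inverted_residual_make(cin, cout, st_eff, t, dil)
        cin <- cout
      }
      groups[[gi]] <- blocks
    }
    ch_low <- make_divisible(24 * wm)
    ch_deep <- make_divisible(320 * wm)
    ch_aspp <- make_divisible(config$aspp_channels * wm)
    ch_dec <- make_divisible(config$decoder_channels * wm)
    ch_lowp <- make_divisible(config$low_level_proj * wm)
    aspp_branch <- function(rate) {
      if (config$aspp_separable) {
        list(dw = cbr_make(3, ch_deep, ch_deep, dil = rate,
                           depthwise = TRUE),
             pw = cbr_make(1, ch_deep, ch_aspp))
      } else {
        list(conv = cbr_make(3, ch_deep, ch_aspp, dil = rate))
      }
    }
    aspp <- list(b1 = cbr_make(1, ch_deep, ch_aspp),
                 b2 = aspp_branch(config$aspp_rates[1]),
                 b3 = aspp_branch(config$aspp_rates[2]),
                 b4 = aspp_branch(config$aspp_rates[3]),
                 pool = cbr_make(1, ch_deep, ch_aspp),
                 project = cbr_make(1, 5L * ch_aspp, ch_aspp))
    dec_in <- ch_aspp + ch_lowp
    decoder <- list(low_proj = cbr_make(1, ch_low, ch_lowp),
                    refine = if (config$decoder_separable) {
                      list(dw = cbr_make(3, dec_in, dec_in,
                                         depthwise = TRUE),
                           pw = cbr_make(1, dec_in, ch_dec))
                    } else {
                      list(conv = cbr_make(3, dec_in, ch_dec))
                    },
                    classifier = conv_make(1, 1, ch_dec, config$n_classes))
    net <- structure(list(cfg = config, stem = stem, groups = groups,
                          low_level_group = low_level_group,
                          aspp = aspp, decoder = decoder,
                          channels = list(low = ch_low, deep = ch_deep,
                                          aspp = ch_aspp, dec = ch_dec)),
                     class = "segnet")
    net$params <- collect_params(net[c("stem", "groups", "aspp", "decoder")])
    net
  })
}

fwd_sep_or_dense <- function(tape, x, br, training) {
  if (!is.null(br$conv)) return(fwd_cbr(tape, x, br$conv, training))
  x <- fwd_cbr(tape, x, br$dw, training)
  fwd_cbr(tape, x, br$pw, training)
}

#' Forward pass of the segmentation network
#'
#' @param net a `segnet` built by [build_segmentation_network()].
#' @param x input array dim(H, W, in_channels, N), values in `[0, 1]`.
#' @param training use batch statistics and record gradients when a tape
#'   is supplied.
#' @param tape autodiff tape or `NULL` for inference.
#' @param return_features also return the two encoder taps.
#' @return logits node (list with `value` dim(H, W, C, N)); with
#'   `return_features = TRUE` a list with `logits`, `low_level`, `deep`.
#' @export
segnet_forward <- function(net, x, training = FALSE, tape = NULL,
                           return_features = FALSE) {
  d <- dim(x)
  check_that(length(d) == 4, "input must be a 4-D array (H, W, C, N)")
  H <- d[1]; W <- d[2]
  node <- op_input(tape, x)
  node <- fwd_cbr(tape, node, net$stem, training)
  low <- NULL
  for (gi in seq_along(net$groups)) {
    for (blk in net$groups[[gi]]) {
      node <- fwd_block(tape, node, blk, training)
    }
    if (gi == net$low_level_group) low <- node
  }
  deep <- node
  a <- net$aspp
  dm <- dim(deep$value)
  branches <- list(fwd_cbr(tape, deep, a$b1, training),
                   fwd_sep_or_dense(tape, deep, a$b2, training),
                   fwd_sep_or_dense(tape, deep, a$b3, training),
                   fwd_sep_or_dense(tape, deep, a$b4, training),
                   op_upsample(tape,
                               fwd_cbr(tape, op_global_pool(tape, deep),
                                       a$pool, training),
                               dm[1], dm[2]))
  node <- op_concat(tape, branches)
  node <- fwd_cbr(tape, node, a$project, training)
  lowp <- fwd_cbr(tape, low, net$decoder$low_proj, training)
  ld <- dim(lowp$value)
  node <- op_upsample(tape, node, ld[1], ld[2])
  node <- op_concat(tape, list(node, lowp))
  node <- fwd_sep_or_dense(tape, node, net$decoder$refine, training)
  node <- op_conv(tape, node, net$decoder$classifier)
  logits <- op_upsample(tape, node, H, W)
  if (return_features) list(logits = logits, low_level = low, deep = deep)
  else logits
}

#' Freeze or unfreeze the backbone parameters
#'
#' Freezing stops gradient updates for every backbone parameter (stem and
#' inverted residual blocks); batch-norm running statistics continue to
#' track the data.
#'
#' @param net a `segnet`.
#' @param frozen logical.
#' @export
set_backbone_frozen <- function(net, frozen) {
  for (p in net$params) {
    if (p$group == "backbone") p$frozen <- frozen
  }
  invisible(net)
}

#' Snapshot / restore network state
#'
#' @param net a `segnet`.
#' @return list of parameter values and batch-norm statistics.
#' @export
network_state <- function(net) {
  list(params = lapply(net$params, function(p) p$value),
       bn = lapply(collect_bn_states(net), function(s)
         list(mean = s$mean, var = s$var)))
}

collect_bn_states <- function(net) {
  out <- list()
  rec <- function(v) {
    if (is.list(v)) {
      if (!is.null(v$state) && is.environment(v$state)) {
        out[[length(out) + 1L]] <<- v$state
      }
      for (e in v) if (is.list(e)) rec(e)
    }
  }
  rec(net[c("stem", "groups", "aspp", "decoder")])
  out
}

#' @rdname network_state
#' @param state a state list from [network_state()].
#' @export
network_restore <- function(net, state) {
  for (i in seq_along(net$params)) net$params[[i]]$value <- state$params[[i]]
  sts <- collect_bn_states(net)
  for (i in seq_along(sts)) {
    sts[[i]]$mean <- state$bn[[i]]$mean
    sts[[i]]$var <- state$bn[[i]]$var
  }
  invisible(net)
}

#' Save / load a trained network
#'
#' @param net a `segnet`.
#' @param path file path (.rds).
#' @export
save_network <- function(net, path) {
  saveRDS(list(cfg = net$cfg, state = network_state(net)), path)
  invisible(path)
}

#' @rdname save_network
#' @return the restored `segnet`.
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  net <- build_segmentation_network(obj$cfg, seed = 1)
  network_restore(net, obj$state)
  net
}

# ---- losses -----------------------------------------------------------------

check_loss_inputs <- function(pred_probs, labels) {
  pred_probs <- rbind(pred_probs); labels <- rbind(labels)
  check_that(all(dim(pred_probs) == dim(labels)),
             "pred_probs and labels must have the same shape")
  check_that(all(pred_probs >= -1e-9 & pred_probs <= 1 + 1e-9),
             "probabilities must lie in [0, 1]")
  check_that(max(abs(rowSums(pred_probs) - 1)) < 1e-6,
             "probability rows must sum to 1 within 1e-6")
  list(p = pred_probs, y = labels)
}

#' Pixel-wise weighted cross-entropy loss
#'
#' Mean over pixels of `-sum_c w_c * y_c * log(p_c)`, with the log argument
#' clamped at 1e-12. Per-class weights address class imbalance.
#'
#' @param pred_probs N x C matrix of predicted class probabilities (rows
#'   sum to 1).
#' @param labels N x C one-hot true labels.
#' @param class_weights length-C positive weights (default all 1).
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(pred_probs, labels, class_weights = NULL) {
  li <- check_loss_inputs(pred_probs, labels)
  C <- ncol(li$p)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  check_that(length(class_weights) == C && all(class_weights > 0),
             "class_weights must be positive and of length C")
  wmat <- matrix(class_weights, nrow(li$p), C, byrow = TRUE)
  -mean(rowSums(wmat * li$y * log(pmax(li$p, 1e-12))))
}

#' Dice loss (soft Dice overlap)
#'
#' `1 - 2*sum(p*y) / (sum(p^2) + sum(y^2))` with a smoothing epsilon of
#' 1e-6 in numerator and denominator. With `average = "micro"` (default)
#' the sums run jointly over pixels and classes; `"macro"` computes the
#' overlap per class and averages.
#'
#' @inheritParams cross_entropy_loss
#' @param average `"micro"` or `"macro"`.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_probs, labels, average = c("micro", "macro")) {
  average <- match.arg(average)
  li <- check_loss_inputs(pred_probs, labels)
  eps <- 1e-6
  one <- function(p, y) 1 - (2 * sum(p * y) + eps) / (sum(p^2) + sum(y^2) + eps)
  if (average == "micro") {
    one(li$p, li$y)
  } else {
    mean(vapply(seq_len(ncol(li$p)),
                function(c) one(li$p[, c], li$y[, c]), numeric(1)))
  }
}

#' Loss configuration for the composite segmentation loss
#'
#' @param alpha weight of the cross-entropy term (>= 0).
#' @param beta weight of the Dice term (>= 0); `alpha + beta > 0`.
#' @param class_weights per-class cross-entropy weights, or `NULL` to
#'   derive inverse-frequency weights from the training split.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(alpha = 1, beta = 1, class_weights = NULL) {
  check_that(alpha >= 0 && beta >= 0 && alpha + beta > 0,
             "alpha, beta must be >= 0 with alpha + beta > 0")
  if (!is.null(class_weights)) {
    check_that(all(class_weights > 0), "class_weights must be positive")
  }
  structure(list(alpha = alpha, beta = beta, class_weights = class_weights),
            class = "loss_config")
}

#' Composite segmentation loss: `alpha * CE + beta * Dice`
#'
#' @inheritParams cross_entropy_loss
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
composite_loss <- function(pred_probs, labels, cfg = loss_config()) {
  check_that(inherits(cfg, "loss_config"), "cfg must be a loss_config")
  cfg$alpha * cross_entropy_loss(pred_probs, labels, cfg$class_weights) +
    cfg$beta * dice_loss(pred_probs, labels)
}

# ---- learning-rate schedule -------------------------------------------------

#' Training configuration for staged SGD
#'
#' @param lr_init initial learning rate (default 7e-3).
#' @param lr_min lower learning-rate bound (default 0.01 * lr_init).
#' @param lr_max upper learning-rate bound (default lr_init).
#' @param nbs reference batch size for the adaptive rule (default 16).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 weight decay on convolution weights (default 1e-4).
#' @param freeze_epochs backbone-frozen epochs (default 50).
#' @param total_epochs total epochs (default 200).
#' @param batch_freeze,batch_unfreeze batch sizes in the two phases
#'   (defaults 8 and 4).
#' @param eval_every validation interval in epochs (default 5).
#' @param seed RNG seed for shuffling and augmentation.
#' @return object of class `training_config`.
#' @export
training_config <- function(lr_init = 7e-3, lr_min = 0.01 * lr_init,
                            lr_max = lr_init, nbs = 16, momentum = 0.9,
                            weight_decay = 1e-4, freeze_epochs = 50,
                            total_epochs = 200, batch_freeze = 8,
                            batch_unfreeze = 4, eval_every = 5, seed = 1) {
  check_that(lr_min > 0 && lr_min <= lr_max, "need 0 < lr_min <= lr_max")
  check_that(freeze_epochs < total_epochs,
             "freeze_epochs must be < total_epochs")
  check_that(batch_freeze >= 1 && batch_unfreeze >= 1,
             "batch sizes must be >= 1")
  structure(list(lr_init = lr_init, lr_min = lr_min, lr_max = lr_max,
                 nbs = nbs, momentum = momentum,
                 weight_decay = weight_decay,
                 freeze_epochs = as.integer(freeze_epochs),
                 total_epochs = as.integer(total_epochs),
                 batch_freeze = as.integer(batch_freeze),
                 batch_unfreeze = as.integer(batch_unfreeze),
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Batch-size-adaptive learning rate
#'
#' `lr = min(max(batch_size / nbs * lr_init, lr_min), lr_max)`.
#'
#' @param batch_size current batch size (>= 1).
#' @param cfg a [training_config()].
#' @return adjusted learning rate.
#' @export
adjusted_learning_rate <- function(batch_size, cfg = training_config()) {
  check_that(batch_size >= 1, "batch_size must be >= 1")
  min(max(batch_size / cfg$nbs * cfg$lr_init, cfg$lr_min), cfg$lr_max)
}

#' Cosine-annealed learning rate for a given epoch
#'
#' `lr(e) = lr_min + 0.5 * (lr_base - lr_min) * (1 + cos(pi * e / total))`
#' where `lr_base` is the batch-size-adjusted rate; a single cosine spans
#' both training phases.
#'
#' @param epoch 0-based epoch, `0 <= epoch < total_epochs`.
#' @param cfg a [training_config()].
#' @param batch_size batch size whose adjusted rate anchors the schedule;
#'   default is the phase batch size at `epoch`.
#' @return learning rate for the epoch.
#' @export
cosine_lr <- function(epoch, cfg = training_config(), batch_size = NULL) {
  check_that(epoch >= 0 && epoch < cfg$total_epochs,
             "epoch out of range [0, total_epochs)")
  if (is.null(batch_size)) {
    batch_size <- if (epoch < cfg$freeze_epochs) cfg$batch_freeze else
      cfg$batch_unfreeze
  }
  lr_base <- adjusted_learning_rate(batch_size, cfg)
  cfg$lr_min + 0.5 * (lr_base - cfg$lr_min) *
    (1 + cos(pi * epoch / cfg$total_epochs))
}

# ---- training ---------------------------------------------------------------

# row-wise softmax of a pixels x C matrix
softmax_rows <- function(zm) {
  mx <- zm[, 1]
  for (c in seq_len(ncol(zm))[-1]) mx <- pmax(mx, zm[, c])
  ez <- exp(zm - mx)
  ez / rowSums(ez)
}

# per-pixel class probabilities, pixels stacked sample-major:
# row index = h + H*(w + W*n)
logits_to_probs <- function(logits) {
  d <- dim(logits)
  C <- d[3]; N <- d[4]
  hw <- d[1] * d[2]
  pm <- matrix(0, hw * N, C)
  for (n in seq_len(N)) {
    zm <- matrix(logits[, , , n], ncol = C)
    pm[(n - 1) * hw + seq_len(hw), ] <- softmax_rows(zm)
  }
  pm
}

# composite loss value + gradient w.r.t. logits for a training batch
segnet_loss_grad <- function(logits, labels, lcfg, class_weights) {
  d <- dim(logits)
  C <- d[3]; N <- d[4]; hw <- d[1] * d[2]
  pm <- logits_to_probs(logits)
  yv <- as.integer(labels) + 1L                      # class index 1..C
  n <- length(yv)
  ii <- cbind(seq_len(n), yv)
  w <- class_weights
  ptrue <- pmax(pm[ii], 1e-12)
  ce <- -mean(w[yv] * log(ptrue))
  eps <- 1e-6
  S <- sum(pm[ii]); P2 <- sum(pm^2); Y2 <- n
  dice <- 1 - (2 * S + eps) / (P2 + Y2 + eps)
  loss <- lcfg$alpha * ce + lcfg$beta * dice
  # gradients w.r.t. probabilities: CE touches only the true class,
  # Dice has a dense term in p plus a one-hot term
  den <- P2 + Y2 + eps
  gp <- lcfg$beta * ((2 * S + eps) * 2 * pm) / den^2
  gp[ii] <- gp[ii] - lcfg$alpha * w[yv] / ptrue / n -
    lcfg$beta * 2 / den
  # chain through the softmax
  gz <- pm * (gp - rowSums(gp * pm))
  gz4 <- array(0, d)
  for (nn in seq_len(N)) {
    gz4[, , , nn] <- gz[(nn - 1) * hw + seq_len(hw), ]
  }
  list(loss = loss, ce = ce, dice = dice, grad = gz4)
}

batch_tensor <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, c(H, W, 1, length(images)))
  for (i in seq_along(images)) x[, , 1, i] <- images[[i]]
  x
}

#' Inverse-frequency class weights from training masks
#'
#' @param masks list of integer label masks.
#' @param n_classes number of classes.
#' @return length-C weights proportional to inverse pixel frequency,
#'   normalized to mean 1.
#' @export
inverse_frequency_weights <- function(masks, n_classes = 3) {
  counts <- numeric(n_classes)
  for (m in masks) {
    tb <- tabulate(as.vector(m) + 1L, nbins = n_classes)
    counts <- counts + tb
  }
  counts <- pmax(counts, 1)
  w <- sum(counts) / counts
  w / mean(w)
}

#' Staged freeze/unfreeze SGD training
#'
#' Epochs `[0, freeze_epochs)` train with the backbone frozen and batch
#' size `batch_freeze`; the remaining epochs unfreeze the backbone and use
#' `batch_unfreeze`. The optimizer is SGD with momentum and weight decay;
#' the learning rate follows a single cosine annealing schedule anchored
#' at the batch-size-adjusted base rate. Validation mIoU is computed every
#' `eval_every` epochs and the best-mIoU state is retained.
#'
#' @param net a `segnet`.
#' @param datasets list with `train` and `val`, each a list with `images`
#'   (matrices in `[0, 1]`) and `masks` (integer matrices).
#' @param tcfg a [training_config()].
#' @param lcfg a [loss_config()]; `NULL` class weights are replaced by
#'   inverse-frequency weights from the training split.
#' @param augment apply random rotation/flip/brightness-contrast
#'   augmentation to each training draw.
#' @param verbose print a line per epoch.
#' @param stop_after optionally stop after this many epochs (useful for
#'   inspecting the state mid-schedule); the schedule itself is unchanged.
#' @return list with `net` (final state), `history` (tibble: epoch, phase,
#'   lr, loss, val_miou), `best` (list: epoch, miou, state) and
#'   `class_weights`.
#' @export
train_staged <- function(net, datasets, tcfg = training_config(),
                         lcfg = loss_config(), augment = TRUE,
                         verbose = FALSE, stop_after = NULL) {
  check_that(length(datasets$train$images) > 0, "training set is empty")
  cw <- lcfg$class_weights
  if (is.null(cw)) {
    cw <- inverse_frequency_weights(datasets$train$masks, net$cfg$n_classes)
  }
  n_train <- length(datasets$train$images)
  hist <- list()
  best <- list(miou = -Inf, epoch = NA_integer_, state = NULL)
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$total_epochs) - 1L) {
      if (!is.null(stop_after) && epoch >= stop_after) break
      freeze <- epoch < tcfg$freeze_epochs
      set_backbone_frozen(net, freeze)
      bs <- if (freeze) tcfg$batch_freeze else tcfg$batch_unfreeze
      lr <- cosine_lr(epoch, tcfg, bs)
      ord <- sample.int(n_train)
      losses <- numeric(0)
      for (start in seq(1, n_train, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n_train)]
        imgs <- datasets$train$images[idx]
        msks <- datasets$train$masks[idx]
        if (augment) {
          for (k in seq_along(imgs)) {
            a <- augment_sample(imgs[[k]], msks[[k]])
            imgs[[k]] <- a$image; msks[[k]] <- a$mask
          }
        }
        x <- batch_tensor(imgs)
        lab <- array(unlist(msks), c(dim(msks[[1]]), length(msks)))
        tape <- tape_new()
        out <- segnet_forward(net, x, training = TRUE, tape = tape)
        lg <- segnet_loss_grad(out$value, lab, lcfg, cw)
        tape_backward(tape, out, lg$grad)
        sgd_step(net$params, lr, tcfg$momentum, tcfg$weight_decay)
        losses <- c(losses, lg$loss)
        rm(tape)
      }
      row <- tibble::tibble(epoch = epoch + 1L,
                            phase = if (freeze) "freeze" else "unfreeze",
                            lr = lr, loss = mean(losses),
                            val_miou = NA_real_)
      if ((epoch + 1L) %% tcfg$eval_every == 0 &&
          length(datasets$val$images) > 0) {
        ev <- evaluate_network(net, datasets$val$images,
                               datasets$val$masks, batch = bs)
        row$val_miou <- ev$miou
        if (ev$miou > best$miou) {
          best <- list(miou = ev$miou, epoch = epoch + 1L,
                       state = network_state(net))
        }
      }
      hist[[length(hist) + 1L]] <- row
      if (verbose) {
        message(sprintf("epoch %3d [%s] lr=%.5f loss=%.4f%s",
                        epoch + 1L, row$phase, lr, row$loss,
                        if (is.na(row$val_miou)) "" else
                          sprintf(" val_mIoU=%.3f", row$val_miou)))
      }
      gc(FALSE)
    }
  })
  list(net = net, history = dplyr::bind_rows(hist), best = best,
       class_weights = cw)
}

#' Evaluate a network on a labelled image set
#'
#' @param net a `segnet`.
#' @param images list of input matrices in `[0, 1]`.
#' @param masks list of integer truth masks.
#' @param batch evaluation batch size.
#' @return a metrics report (see [class_metrics()]).
#' @export
evaluate_network <- function(net, images, masks, batch = 4) {
  C <- net$cfg$n_classes
  cm <- matrix(0, C, C)
  for (start in seq(1, length(images), by = batch)) {
    idx <- start:min(start + batch - 1, length(images))
    x <- batch_tensor(images[idx])
    out <- segnet_forward(net, x, training = FALSE, tape = NULL)
    pred <- logits_to_mask(out$value)
    for (k in seq_along(idx)) {
      cm <- cm + unclass(confusion_counts(pred[, , k], masks[[idx[k]]], C))
    }
  }
  class(cm) <- "confusion_matrix"
  class_metrics(cm)
}

logits_to_mask <- function(logits) {
  d <- dim(logits)
  out <- array(0L, c(d[1], d[2], d[4]))
  for (n in seq_len(d[4])) {
    zm <- matrix(logits[, , , n], ncol = d[3])
    out[, , n] <- max.col(zm, ties.method = "first") - 1L
  }
  out
}

#' Segment a single image with a trained network
#'
#' @param net a `segnet`.
#' @param image matrix in `[0, 1]` whose size matches the network input.
#' @return integer label mask (0 background, 1 bone/tooth, 2 gingiva).
#' @export
predict_segmentation <- function(net, image) {
  x <- array(image, c(nrow(image), ncol(image), 1, 1))
  out <- segnet_forward(net, x, training = FALSE, tape = NULL)
  logits_to_mask(out$value)[, , 1]
}
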