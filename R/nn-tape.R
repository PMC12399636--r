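# Minimal reverse-mode autodiff over 4-D feature maps, backing the
# segmentation network. Feature maps are numeric arrays dim(H, W, C, N).
# A "node" is a list(value, id, needs_grad); ops push a backward closure
# onto the tape. Parameters are environments (value/grad/momentum) so
# backward can accumulate into them in place; gradient work is skipped
# entirely for subgraphs that contain no trainable parameter (this is what
# makes the backbone-frozen training phase cheap).

tape_new <- function(enabled = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$backs <- list()
  tp$parents <- list()
  tp$enabled <- enabled
  tp
}

tp_node <- function(tape, value, parents = list(), back = NULL,
                    needs_grad = FALSE) {
  if (is.null(tape) || !tape$enabled || !needs_grad) {
    return(list(value = value, id = NA_integer_, needs_grad = needs_grad))
  }
  tape$n <- tape$n + 1L
  id <- tape$n
  tape$backs[[id]] <- back
  tape$parents[[id]] <- vapply(parents, function(p) p$id, integer(1))
  list(value = value, id = id, needs_grad = TRUE)
}

tape_backward <- function(tape, seed_node, seed_grad) {
  if (is.na(seed_node$id)) return(invisible(NULL))
  grads <- vector("list", tape$n)
  grads[[seed_node$id]] <- seed_grad
  for (i in rev(seq_len(tape$n))) {
    g <- grads[[i]]
    if (is.null(g)) next
    bk <- tape$backs[[i]]
    if (is.null(bk)) next
    pg <- bk(g)
    ps <- tape$parents[[i]]
    for (j in seq_along(ps)) {
      pid <- ps[j]
      if (is.na(pid)) next
      if (is.null(pg[[j]])) next
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else
        grads[[pid]] + pg[[j]]
    }
    grads[[i]] <- NULL
  }
  invisible(NULL)
}

# ---- parameters -------------------------------------------------------------

make_param <- function(value, decay = TRUE, group = "head") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$mom <- NULL
  p$decay <- decay
  p$group <- group
  p$frozen <- FALSE
  p
}

param_accum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

param_trainable <- function(p) !p$frozen

# ---- ops --------------------------------------------------------------------

op_input <- function(tape, x) list(value = x, id = NA_integer_,
                                   needs_grad = FALSE)

op_conv <- function(tape, x, layer) {
  w <- layer$w; b <- layer$b
  y <- if (layer$depthwise) {
    .cpp_dwconv_fwd(x$value, w$value, b$value, layer$stride, layer$pad,
                    layer$dil)
  } else {
    .cpp_conv2d_fwd(x$value, w$value, b$value, layer$stride, layer$pad,
                    layer$dil)
  }
  ng <- x$needs_grad || param_trainable(w)
  if (is.null(tape) || !tape$enabled || !ng) {
    return(list(value = y, id = NA_integer_, needs_grad = FALSE))
  }
  xv <- x$value; wv <- w$value
  st <- layer$stride; pd <- layer$pad; dl <- layer$dil
  dwise <- layer$depthwise
  x_ng <- x$needs_grad
  back <- function(g) {
    r <- if (dwise) .cpp_dwconv_bwd(xv, wv, g, st, pd, dl) else
      .cpp_conv2d_bwd(xv, wv, g, st, pd, dl)
    if (param_trainable(w)) {
      param_accum(w, r$gw)
      param_accum(b, r$gb)
    }
    list(if (x_ng) r$gx else NULL)
  }
  tp_node(tape, y, list(x), back, needs_grad = TRUE)
}

# batch normalization over (H, W, N) per channel, optionally with a
# fused ReLU6 on the output
op_bn <- function(tape, x, layer, training, relu6 = FALSE) {
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  g_ <- layer$gamma; b_ <- layer$beta; stt <- layer$state
  eps <- 1e-5
  m <- H * W * N
  if (training) {
    st <- .cpp_channel_stats(xv)
    mu <- st$sum / m
    var <- pmax(st$sumsq / m - mu^2, 0)
    stt$mean <- 0.9 * stt$mean + 0.1 * mu
    stt$var <- 0.9 * stt$var + 0.1 * var * m / max(m - 1, 1)
  } else {
    mu <- stt$mean; var <- stt$var
  }
  ivar <- 1 / sqrt(var + eps)
  ng <- x$needs_grad || param_trainable(g_)
  record <- !is.null(tape) && tape$enabled && ng
  y <- .cpp_bn_fwd(xv, mu, ivar, g_$value, b_$value, relu6)
  if (!record) {
    return(list(value = y, id = NA_integer_, needs_grad = FALSE))
  }
  yv <- if (relu6) y else NULL
  x_ng <- x$needs_grad
  back <- function(g) {
    r <- .cpp_bn_bwd(xv, mu, g, g_$value, ivar, x_ng, yv)
    if (param_trainable(g_)) {
      param_accum(g_, r$dgamma)
      param_accum(b_, r$dbeta)
    }
    if (!x_ng) return(list(NULL))
    list(r$gx)
  }
  tp_node(tape, y, list(x), back, needs_grad = TRUE)
}

op_relu6 <- function(tape, x) {
  y <- .cpp_relu6_fwd(x$value)
  if (is.null(tape) || !tape$enabled || !x$needs_grad) {
    return(list(value = y, id = NA_integer_, needs_grad = x$needs_grad))
  }
  xv <- x$value
  back <- function(g) list(.cpp_relu6_bwd(xv, g))
  tp_node(tape, y, list(x), back, needs_grad = TRUE)
}

op_add <- function(tape, a, b) {
  y <- a$value + b$value
  ng <- a$needs_grad || b$needs_grad
  if (is.null(tape) || !tape$enabled || !ng) {
    return(list(value = y, id = NA_integer_, needs_grad = ng))
  }
  a_ng <- a$needs_grad; b_ng <- b$needs_grad
  back <- function(g) list(if (a_ng) g else NULL, if (b_ng) g else NULL)
  tp_node(tape, y, list(a, b), back, needs_grad = TRUE)
}

op_concat <- function(tape, nodes) {
  ds <- lapply(nodes, function(n) dim(n$value))
  H <- ds[[1]][1]; W <- ds[[1]][2]; N <- ds[[1]][4]
  Cs <- vapply(ds, function(d) d[3], numeric(1))
  y <- array(0, c(H, W, sum(Cs), N))
  off <- 0
  for (i in seq_along(nodes)) {
    y[, , off + seq_len(Cs[i]), ] <- nodes[[i]]$value
    off <- off + Cs[i]
  }
  ng <- any(vapply(nodes, function(n) n$needs_grad, logical(1)))
  if (is.null(tape) || !tape$enabled || !ng) {
    return(list(value = y, id = NA_integer_, needs_grad = ng))
  }
  needs <- vapply(nodes, function(n) n$needs_grad, logical(1))
  back <- function(g) {
    out <- vector("list", length(Cs))
    off <- 0
    for (i in seq_along(Cs)) {
      if (needs[i]) {
        out[[i]] <- g[, , off + seq_len(Cs[i]), , drop = FALSE]
      }
      off <- off + Cs[i]
    }
    out
  }
  tp_node(tape, y, nodes, back, needs_grad = TRUE)
}

op_upsample <- function(tape, x, Hout, Wout) {
  d <- dim(x$value)
  if (d[1] == Hout && d[2] == Wout) return(x)
  y <- .cpp_upsample_fwd(x$value, as.integer(Hout), as.integer(Wout))
  if (is.null(tape) || !tape$enabled || !x$needs_grad) {
    return(list(value = y, id = NA_integer_, needs_grad = x$needs_grad))
  }
  back <- function(g) list(.cpp_upsample_bwd(g, d[1], d[2]))
  tp_node(tape, y, list(x), back, needs_grad = TRUE)
}

op_global_pool <- function(tape, x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x$value, nrow = H * W)
  y <- array(colMeans(xm), c(1, 1, C, N))
  if (is.null(tape) || !tape$enabled || !x$needs_grad) {
    return(list(value = y, id = NA_integer_, needs_grad = x$needs_grad))
  }
  back <- function(g) {
    gm <- matrix(rep(as.vector(g) / (H * W), each = H * W), nrow = H * W)
    list(array(gm, d))
  }
  tp_node(tape, y, list(x), back, needs_grad = TRUE)
}

# ---- optimizer --------------------------------------------------------------

sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (p in params) {
    if (p$frozen || is.null(p$grad)) {
      p$grad <- NULL
      next
    }
    g <- p$grad
    if (p$decay && weight_decay > 0) g <- g + weight_decay * p$value
    p$mom <- if (is.null(p$mom)) g else momentum * p$mom + g
    p$value <- p$value - lr * p$mom
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
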