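# A compact convolutional-network engine: 4-d activations laid out as
# (channels, height, width, batch) arrays, im2col + BLAS matrix products for
# convolutions, explicit reverse-mode gradients per layer. 1-D audio layers
# are 2-D layers with height 1. Supported groupings: full convolutions
# (groups = 1) and depthwise (groups = channels, one filter per channel).

kaiming_normal <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

new_layer <- function(type, name, ...) {
  structure(c(list(type = type, name = name), list(...)), class = "tembo_layer")
}

layer_conv <- function(in_ch, out_ch, kh = 1, kw, sh = 1, sw = 1,
                       ph = 0, pw = NULL, groups = 1, bias = TRUE,
                       name = "conv") {
  pw <- pw %||% ((kw - 1) %/% 2)
  if (groups != 1 && !(groups == in_ch && out_ch == in_ch)) {
    abort(sprintf("layer %s: only groups=1 or depthwise (groups=in=out) convolutions are supported",
                  name), class = "tembo_validation_error")
  }
  fan_in <- (in_ch / groups) * kh * kw
  W <- if (groups == 1) {
    matrix(kaiming_normal(out_ch * in_ch * kh * kw, fan_in), nrow = out_ch)
  } else {
    matrix(kaiming_normal(out_ch * kh * kw, fan_in), nrow = out_ch)
  }
  new_layer("conv", name, W = W, b = if (bias) numeric(out_ch) else NULL,
            in_ch = in_ch, out_ch = out_ch, kh = kh, kw = kw, sh = sh,
            sw = sw, ph = ph, pw = pw, groups = groups)
}

layer_bn <- function(ch, name = "bn", eps = 1e-5, momentum = 0.1) {
  new_layer("bn", name, gamma = rep(1, ch), beta = numeric(ch),
            running_mean = numeric(ch), running_var = rep(1, ch),
            eps = eps, momentum = momentum, ch = ch)
}

layer_act <- function(kind = c("relu", "relu6", "leaky_relu"), alpha = 0.01,
                      name = kind[1]) {
  new_layer(match.arg(kind), name, alpha = alpha)
}

layer_pool <- function(kind = c("max", "avg"), kh = 1, kw, sh = kh, sw = kw,
                       name = paste0(kind[1], "pool")) {
  new_layer(paste0(match.arg(kind), "pool"), name, kh = kh, kw = kw,
            sh = sh, sw = sw)
}

layer_global_avgpool <- function(name = "gap") new_layer("gap", name)

layer_adaptive_avgpool_w <- function(out_w, name = "adaptive_avgpool") {
  new_layer("adaptive_avgpool", name, out_w = out_w)
}

layer_dropout <- function(p, name = "dropout") new_layer("dropout", name, p = p)

layer_flatten <- function(name = "flatten") new_layer("flatten", name)

layer_linear <- function(in_f, out_f, bias = TRUE, name = "linear") {
  new_layer("linear", name,
            W = matrix(kaiming_normal(out_f * in_f, in_f), nrow = out_f),
            b = if (bias) numeric(out_f) else NULL,
            in_f = in_f, out_f = out_f)
}

layer_softmax <- function(name = "softmax") new_layer("softmax", name)

layer_reshape <- function(ch, h, w, name = "reshape") {
  new_layer("reshape", name, ch = ch, h = h, w = w)
}

layer_residual <- function(body, proj = NULL, name = "residual") {
  new_layer("residual", name, body = body, proj = proj)
}

layer_parallel_concat <- function(branches, name = "fusion") {
  new_layer("parallel_concat", name, branches = branches)
}

# ---- im2col index construction -------------------------------------------

conv_out_dim <- function(n, k, s, p, name) {
  o <- (n + 2 * p - k) %/% s + 1
  if (o < 1) {
    abort(sprintf("stage %s: spatial size %d too small for kernel %d / stride %d",
                  name, n, k, s), class = "tembo_shape_error")
  }
  o
}

pad_input <- function(x, ph, pw) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  xp[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- x
  xp
}

# Gather indices for full convolution: rows ordered (c, kh, kw), columns
# ordered (oh, ow); returns matrix of linear indices into one padded sample.
im2col_idx_full <- function(C, Hp, Wp, kh, kw, sh, sw, OH, OW) {
  c_vec <- rep(seq_len(C), kh * kw)
  ki <- rep(rep(seq_len(kh), each = C), kw)
  kj <- rep(seq_len(kw), each = C * kh)
  base_row <- c_vec + (ki - 1) * C + (kj - 1) * C * Hp
  oh <- rep(seq_len(OH), OW)
  ow <- rep(seq_len(OW), each = OH)
  base_col <- (oh - 1) * sh * C + (ow - 1) * sw * C * Hp
  outer(base_row, base_col, "+")
}

# Gather indices for per-channel windows (depthwise conv / pooling): rows
# ordered (kh, kw), columns ordered (oh, ow, c).
im2col_idx_chan <- function(C, Hp, Wp, kh, kw, sh, sw, OH, OW) {
  ki <- rep(seq_len(kh), kw)
  kj <- rep(seq_len(kw), each = kh)
  base_row <- (ki - 1) * C + (kj - 1) * C * Hp
  oh <- rep(seq_len(OH), OW)
  ow <- rep(seq_len(OW), each = OH)
  inner <- (oh - 1) * sh * C + (ow - 1) * sw * C * Hp
  base_col <- rep(inner, C) + rep(seq_len(C), each = OH * OW)
  outer(base_row, base_col, "+")
}

expand_batch_idx <- function(idx, per_sample, n) {
  out <- rep(as.vector(idx), n) + rep((seq_len(n) - 1) * per_sample, each = length(idx))
  if (per_sample * n < .Machine$integer.max) as.integer(out) else out
}

# Scatter-add a (rows x cols) value matrix into a flat buffer. Within one
# kernel-offset row the target indices are distinct (different output
# positions read different input positions), so each row accumulates with a
# single vectorized update; collisions across rows are resolved by the loop.
scatter_add_rows <- function(vals, big, nrows, total_len) {
  out <- numeric(total_len)
  dim(big) <- c(nrows, length(big) %/% nrows)
  dim(vals) <- dim(big)
  for (r in seq_len(nrows)) {
    idx <- big[r, ]
    out[idx] <- out[idx] + vals[r, ]
  }
  out
}

# ---- layer forward/backward ----------------------------------------------

conv_forward <- function(layer, x) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  OH <- conv_out_dim(H, layer$kh, layer$sh, layer$ph, layer$name)
  OW <- conv_out_dim(W, layer$kw, layer$sw, layer$pw, layer$name)
  xp <- pad_input(x, layer$ph, layer$pw)
  dp <- dim(xp)
  per_sample <- prod(dp[1:3])
  if (layer$groups == 1) {
    idx <- im2col_idx_full(C, dp[2], dp[3], layer$kh, layer$kw,
                           layer$sh, layer$sw, OH, OW)
    big <- expand_batch_idx(idx, per_sample, N)
    Xcol <- xp[big]
    dim(Xcol) <- c(nrow(idx), length(big) %/% nrow(idx))
    Y <- layer$W %*% Xcol
    if (!is.null(layer$b)) Y <- Y + layer$b
    y <- array(Y, c(layer$out_ch, OH, OW, N))
    cache <- list(Xcol = Xcol, big = big, dp = dp, d = d, OH = OH, OW = OW)
  } else {
    idx <- im2col_idx_chan(C, dp[2], dp[3], layer$kh, layer$kw,
                           layer$sh, layer$sw, OH, OW)
    big <- expand_batch_idx(idx, per_sample, N)
    Xcol <- xp[big]
    dim(Xcol) <- c(nrow(idx), length(big) %/% nrow(idx))
    Wt <- t(layer$W)                         # (kh*kw) x C
    ch_idx <- rep(rep(seq_len(C), each = OH * OW), N)
    Y <- colSums(Xcol * Wt[, ch_idx, drop = FALSE])
    if (!is.null(layer$b)) Y <- Y + layer$b[ch_idx]
    y <- aperm(array(Y, c(OH, OW, C, N)), c(3, 1, 2, 4))
    cache <- list(Xcol = Xcol, big = big, dp = dp, d = d, OH = OH, OW = OW,
                  ch_idx = ch_idx)
  }
  list(y = y, cache = cache)
}

conv_backward <- function(layer, cache, dy, need_dx = TRUE) {
  d <- cache$d; dp <- cache$dp
  C <- d[1]; N <- d[4]; OH <- cache$OH; OW <- cache$OW
  if (layer$groups == 1) {
    dYm <- matrix(dy, nrow = layer$out_ch)
    dW <- tcrossprod(dYm, cache$Xcol)
    db <- if (!is.null(layer$b)) rowSums(dYm) else NULL
    dx <- NULL
    if (need_dx) {
      dXcol <- crossprod(layer$W, dYm)
      dxp <- scatter_add_rows(dXcol, cache$big, nrow(dXcol), prod(dp))
      dim(dxp) <- dp
      dx <- dxp[, layer$ph + seq_len(d[2]), layer$pw + seq_len(d[3]), , drop = FALSE]
      dim(dx) <- d
    }
  } else {
    R2 <- layer$kh * layer$kw
    dyv <- as.vector(aperm(dy, c(2, 3, 1, 4)))      # (oh, ow, c, n) order
    Z <- cache$Xcol * rep(dyv, each = R2)
    Za <- array(Z, c(R2, OH * OW, C, N))
    m <- aperm(Za, c(1, 3, 2, 4))
    dim(m) <- c(R2 * C, OH * OW * N)
    dW <- t(matrix(rowSums(m), R2, C))
    db <- NULL
    if (!is.null(layer$b)) {
      dm <- array(dyv, c(OH * OW, C, N))
      db <- apply(dm, 2, sum)
    }
    dx <- NULL
    if (need_dx) {
      Wt <- t(layer$W)
      dXcol <- Wt[, cache$ch_idx, drop = FALSE] * rep(dyv, each = R2)
      dxp <- scatter_add_rows(dXcol, cache$big, R2, prod(dp))
      dim(dxp) <- dp
      dx <- dxp[, layer$ph + seq_len(d[2]), layer$pw + seq_len(d[3]), , drop = FALSE]
      dim(dx) <- d
    }
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * invstd
  y <- layer$gamma * xhat + layer$beta
  dim(y) <- d
  upd <- NULL
  if (training) {
    upd <- list(running_mean = (1 - layer$momentum) * layer$running_mean + layer$momentum * mu,
                running_var = (1 - layer$momentum) * layer$running_var + layer$momentum * v)
  }
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                           training = training),
       state_update = upd)
}

bn_backward <- function(layer, cache, dy, need_dx = TRUE) {
  d <- cache$d
  dym <- matrix(dy, nrow = d[1])
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dx <- NULL
  if (need_dx) {
    m <- ncol(dym)
    if (cache$training) {
      dx <- (layer$gamma * cache$invstd / m) *
        (m * dym - dbeta - xhat * dgamma)
    } else {
      dx <- layer$gamma * cache$invstd * dym
    }
    dim(dx) <- d
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

pool_forward <- function(layer, x, kind) {
  d <- dim(x)
  C <- d[1]; N <- d[4]
  OH <- conv_out_dim(d[2], layer$kh, layer$sh, 0, layer$name)
  OW <- conv_out_dim(d[3], layer$kw, layer$sw, 0, layer$name)
  per_sample <- prod(d[1:3])
  idx <- im2col_idx_chan(C, d[2], d[3], layer$kh, layer$kw,
                         layer$sh, layer$sw, OH, OW)
  big <- expand_batch_idx(idx, per_sample, N)
  R2 <- layer$kh * layer$kw
  Xcol <- x[big]
  dim(Xcol) <- c(R2, length(big) %/% R2)
  if (kind == "max") {
    cur <- Xcol[1, ]
    arg <- rep(1L, ncol(Xcol))
    if (R2 > 1) {
      for (r in 2:R2) {
        better <- Xcol[r, ] > cur
        cur[better] <- Xcol[r, better]
        arg[better] <- r
      }
    }
    Y <- cur
    cache <- list(arg = arg, big = big, d = d, OH = OH, OW = OW, R2 = R2)
  } else {
    Y <- colSums(Xcol) / R2
    cache <- list(big = big, d = d, OH = OH, OW = OW, R2 = R2)
  }
  y <- aperm(array(Y, c(OH, OW, C, N)), c(3, 1, 2, 4))
  list(y = y, cache = cache)
}

pool_backward <- function(layer, cache, dy, kind) {
  d <- cache$d
  dyv <- as.vector(aperm(dy, c(2, 3, 1, 4)))
  if (kind == "max") {
    bigm <- cache$big
    dim(bigm) <- c(cache$R2, length(dyv))
    dx <- numeric(prod(d))
    for (r in seq_len(cache$R2)) {
      hit <- cache$arg == r
      idx <- bigm[r, hit]
      dx[idx] <- dx[idx] + dyv[hit]
    }
  } else {
    dx <- scatter_add_rows(rep(dyv / cache$R2, each = cache$R2), cache$big,
                           cache$R2, prod(d))
  }
  dim(dx) <- d
  list(dx = dx, grads = NULL)
}

gap_forward <- function(layer, x) {
  d <- dim(x)
  a <- x
  dim(a) <- c(d[1], d[2] * d[3], d[4])
  y <- colMeans(aperm(a, c(2, 1, 3)))   # (C, N)
  dim(y) <- c(d[1], 1, 1, d[4])
  list(y = y, cache = list(d = d))
}

gap_backward <- function(layer, cache, dy) {
  d <- cache$d
  hw <- d[2] * d[3]
  dym <- matrix(dy, nrow = d[1]) / hw   # (C, N)
  dx <- array(dym[, rep(seq_len(d[4]), each = hw), drop = FALSE], d)
  list(dx = dx, grads = NULL)
}

adaptive_avgpool_forward <- function(layer, x) {
  d <- dim(x)
  stopifnot(d[2] == 1)
  W <- d[3]; out <- layer$out_w
  e <- floor(seq_len(out) * W / out)
  s <- c(0, e[-out]) + 1
  len <- e - s + 1
  a <- x
  dim(a) <- c(d[1], W, d[4])
  y <- array(0, c(d[1], 1, out, d[4]))
  for (i in seq_len(out)) {
    seg <- a[, s[i]:e[i], , drop = FALSE]
    y[, 1, i, ] <- colMeans(aperm(seg, c(2, 1, 3)))
  }
  list(y = y, cache = list(d = d, s = s, e = e, len = len, out = out))
}

adaptive_avgpool_backward <- function(layer, cache, dy) {
  d <- cache$d
  i_of_w <- rep(seq_len(cache$out), times = cache$len)
  dya <- dy
  dim(dya) <- c(d[1], cache$out, d[4])
  dx <- dya[, i_of_w, , drop = FALSE]
  dx <- sweep(dx, 2, cache$len[i_of_w], "/")
  dim(dx) <- d
  list(dx = dx, grads = NULL)
}

act_forward <- function(layer, x) {
  y <- x
  switch(layer$type,
    relu = {
      neg <- x < 0
      y[neg] <- 0
      list(y = y, cache = list(neg = neg))
    },
    relu6 = {
      neg <- x < 0
      hi <- x > 6
      y[neg] <- 0
      y[hi] <- 6
      list(y = y, cache = list(dead = neg | hi))
    },
    leaky_relu = {
      neg <- x < 0
      y[neg] <- layer$alpha * x[neg]
      list(y = y, cache = list(neg = neg))
    }
  )
}

act_backward <- function(layer, cache, dy) {
  dx <- dy
  switch(layer$type,
    relu = dx[cache$neg] <- 0,
    relu6 = dx[cache$dead] <- 0,
    leaky_relu = dx[cache$neg] <- layer$alpha * dy[cache$neg]
  )
  list(dx = dx, grads = NULL)
}

dropout_forward <- function(layer, x, training) {
  if (!training || layer$p <= 0) {
    return(list(y = x, cache = list(mask = NULL)))
  }
  mask <- (runif(length(x)) >= layer$p) / (1 - layer$p)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, cache, dy) {
  if (is.null(cache$mask)) return(list(dx = dy, grads = NULL))
  list(dx = dy * cache$mask, grads = NULL)
}

softmax_forward <- function(x) {
  mx <- apply(x, 2, max)
  e <- exp(sweep(x, 2, mx))
  y <- sweep(e, 2, colSums(e), "/")
  list(y = y, cache = list(y = y))
}

softmax_backward <- function(cache, dy) {
  y <- cache$y
  s <- colSums(dy * y)
  list(dx = y * sweep(dy, 2, s), grads = NULL)
}

# ---- network-level forward / backward ------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = conv_forward(layer, x),
    bn = bn_forward(layer, x, training),
    relu = , relu6 = , leaky_relu = act_forward(layer, x),
    maxpool = pool_forward(layer, x, "max"),
    avgpool = pool_forward(layer, x, "avg"),
    gap = gap_forward(layer, x),
    adaptive_avgpool = adaptive_avgpool_forward(layer, x),
    dropout = dropout_forward(layer, x, training),
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[1:3]), d[4])
      list(y = y, cache = list(d = d))
    },
    reshape = {
      d <- dim(x)
      y <- x
      dim(y) <- c(layer$ch, layer$h, layer$w, d[length(d)])
      list(y = y, cache = list(d = d))
    },
    linear = {
      y <- layer$W %*% x
      if (!is.null(layer$b)) y <- y + layer$b
      list(y = y, cache = list(x = x))
    },
    softmax = softmax_forward(x),
    residual = {
      body <- nn_forward(layer$body, x, training)
      if (!is.null(layer$proj)) {
        pr <- conv_forward(layer$proj, x)
        list(y = body$y + pr$y,
             cache = list(body = body, proj = pr$cache),
             state_update = body$state_update)
      } else {
        list(y = body$y + x, cache = list(body = body),
             state_update = body$state_update)
      }
    },
    parallel_concat = {
      outs <- lapply(layer$branches, function(br) nn_forward(br, x, training))
      dims <- lapply(outs, function(o) dim(o$y))
      hw <- vapply(dims, function(d) paste(d[2], d[3]), character(1))
      if (length(unique(hw)) != 1) {
        abort(sprintf("stage %s: branch spatial sizes differ (%s)",
                      layer$name, paste(unique(hw), collapse = " vs ")),
              class = "tembo_shape_error")
      }
      chans <- vapply(dims, function(d) d[1], numeric(1))
      d1 <- dims[[1]]
      y <- array(0, c(sum(chans), d1[2], d1[3], d1[4]))
      off <- 0
      for (o in outs) {
        ci <- dim(o$y)[1]
        y[off + seq_len(ci), , , ] <- o$y
        off <- off + ci
      }
      list(y = y, cache = list(outs = outs, chans = chans),
           state_update = lapply(outs, function(o) o$state_update))
    },
    abort(sprintf("unknown layer type: %s", layer$type))
  )
}

# Forward through a layer list. Returns output, per-layer caches, and
# batch-norm running-stat updates (applied by the training loop).
nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  updates <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], x, training)
    x <- res$y
    caches[i] <- list(res$cache)
    updates[i] <- list(res$state_update)
  }
  list(y = x, caches = caches, state_update = updates)
}

layer_backward <- function(layer, cache, dy, need_dx) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dy, need_dx),
    bn = bn_backward(layer, cache, dy, need_dx),
    relu = , relu6 = , leaky_relu = act_backward(layer, cache, dy),
    maxpool = pool_backward(layer, cache, dy, "max"),
    avgpool = pool_backward(layer, cache, dy, "avg"),
    gap = gap_backward(layer, cache, dy),
    adaptive_avgpool = adaptive_avgpool_backward(layer, cache, dy),
    dropout = dropout_backward(layer, cache, dy),
    flatten = , reshape = {
      dx <- dy
      dim(dx) <- cache$d
      list(dx = dx, grads = NULL)
    },
    linear = {
      dW <- tcrossprod(dy, cache$x)
      db <- if (!is.null(layer$b)) rowSums(dy) else NULL
      dx <- if (need_dx) crossprod(layer$W, dy) else NULL
      list(dx = dx, grads = list(W = dW, b = db))
    },
    softmax = softmax_backward(cache, dy),
    residual = {
      body <- nn_backward(layer$body, cache$body$caches, dy, need_dx = TRUE)
      if (!is.null(layer$proj)) {
        pr <- conv_backward(layer$proj, cache$proj, dy, need_dx = need_dx)
        dx <- if (need_dx) body$dx + pr$dx else NULL
        list(dx = dx, grads = list(body = body$grads, proj = pr$grads))
      } else {
        list(dx = body$dx + dy, grads = list(body = body$grads))
      }
    },
    parallel_concat = {
      off <- 0
      dx <- NULL
      grads <- vector("list", length(layer$branches))
      for (k in seq_along(layer$branches)) {
        ci <- cache$chans[k]
        dyk <- dy[off + seq_len(ci), , , , drop = FALSE]
        off <- off + ci
        bk <- nn_backward(layer$branches[[k]], cache$outs[[k]]$caches, dyk,
                          need_dx = TRUE)
        grads[[k]] <- bk$grads
        dx <- if (is.null(dx)) bk$dx else dx + bk$dx
      }
      list(dx = dx, grads = list(branches = grads))
    },
    abort(sprintf("unknown layer type: %s", layer$type))
  )
}

nn_backward <- function(layers, caches, dy, need_dx = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    need <- need_dx || i > 1
    res <- layer_backward(layers[[i]], caches[[i]], dy, need)
    grads[[i]] <- res$grads
    dy <- res$dx
  }
  list(dx = dy, grads = grads)
}

# ---- parameter trees ------------------------------------------------------

layer_param_tree <- function(layer) {
  switch(layer$type,
    conv = list(W = layer$W, b = layer$b),
    bn = list(gamma = layer$gamma, beta = layer$beta),
    linear = list(W = layer$W, b = layer$b),
    residual = list(body = lapply(layer$body, layer_param_tree),
                    proj = if (!is.null(layer$proj)) layer_param_tree(layer$proj)),
    parallel_concat = list(branches = lapply(layer$branches, function(br)
      lapply(br, layer_param_tree))),
    NULL
  )
}

get_params <- function(layers) lapply(layers, layer_param_tree)

set_layer_params <- function(layer, tree) {
  switch(layer$type,
    conv = , linear = {
      layer$W <- tree$W
      if (!is.null(layer$b)) layer$b <- tree$b
    },
    bn = {
      layer$gamma <- tree$gamma
      layer$beta <- tree$beta
    },
    residual = {
      layer$body <- set_params(layer$body, tree$body)
      if (!is.null(layer$proj)) layer$proj <- set_layer_params(layer$proj, tree$proj)
    },
    parallel_concat = {
      layer$branches <- purrr::map2(layer$branches, tree$branches, set_params)
    }
  )
  layer
}

set_params <- function(layers, trees) {
  purrr::map2(layers, trees, function(l, t) {
    if (is.null(t)) l else set_layer_params(l, t)
  })
}

flatten_leaves <- function(tree) {
  if (is.null(tree)) return(list())
  if (is.numeric(tree)) return(list(tree))
  do.call(c, lapply(tree, flatten_leaves))
}

rebuild_tree <- function(skeleton, leaves, env) {
  if (is.null(skeleton)) return(NULL)
  if (is.numeric(skeleton)) {
    env$i <- env$i + 1
    out <- leaves[[env$i]]
    attributes(out) <- attributes(skeleton)
    return(out)
  }
  out <- lapply(skeleton, rebuild_tree, leaves = leaves, env = env)
  names(out) <- names(skeleton)
  out
}

# Apply BN running-stat updates recorded during a training forward pass.
apply_state_updates <- function(layers, updates) {
  for (i in seq_along(layers)) {
    u <- updates[[i]]
    if (is.null(u)) next
    type <- layers[[i]]$type
    if (type == "bn") {
      layers[[i]]$running_mean <- u$running_mean
      layers[[i]]$running_var <- u$running_var
    } else if (type == "residual") {
      layers[[i]]$body <- apply_state_updates(layers[[i]]$body, u)
    } else if (type == "parallel_concat") {
      for (k in seq_along(layers[[i]]$branches)) {
        layers[[i]]$branches[[k]] <-
          apply_state_updates(layers[[i]]$branches[[k]], u[[k]])
      }
    }
  }
  layers
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  leaves <- flatten_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  p <- flatten_leaves(params)
  g <- flatten_leaves(grads)
  stopifnot(length(p) == length(g))
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (j in seq_along(p)) {
    state$m[[j]] <- beta1 * state$m[[j]] + (1 - beta1) * g[[j]]
    state$v[[j]] <- beta2 * state$v[[j]] + (1 - beta2) * g[[j]]^2
    p[[j]] <- p[[j]] - lr * (state$m[[j]] / bc1) /
      (sqrt(state$v[[j]] / bc2) + eps)
  }
  env <- new.env()
  env$i <- 0
  new_params <- rebuild_tree(params, p, env)
  list(params = new_params, state = state)
}
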