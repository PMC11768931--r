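# Raw-waveform classifier architectures, complexity profiling (parameters,
# FLOPs, serialized size), and post-training int8 weight quantization.
# Every builder accepts a (batch, input_samples) waveform matrix and emits a
# (batch, n_classes) probability matrix whose rows sum to 1.

new_model <- function(name, layers, n_classes, input_samples, config,
                      classes = NULL) {
  if (is.null(classes)) {
    classes <- if (n_classes == 3) c("roar", "rumble", "trumpet") else
      paste0("class", seq_len(n_classes))
  }
  structure(list(name = name, layers = layers, n_classes = n_classes,
                 input_samples = input_samples, config = config,
                 classes = classes),
            class = "tembo_model")
}

#' @export
print.tembo_model <- function(x, ...) {
  cat(sprintf("<tembo_model> %s: %d-sample input -> %d classes, %s parameters\n",
              x$name, x$input_samples, x$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Waveform matrix (N x L) -> activation array for the model's input layout.
model_input_array <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_samples) {
    abort(sprintf("model %s expects %d samples per clip, got %d",
                  model$name, model$input_samples, ncol(x)),
          class = "tembo_shape_error")
  }
  array(t(x), c(1, 1, ncol(x), nrow(x)))
}

#' Predict class probabilities or labels
#'
#' @param object A `tembo_model`.
#' @param newdata Waveform matrix, clips in rows (`batch x input_samples`).
#' @param type `"prob"` for the probability matrix, `"class"` for labels.
#' @param ... Unused.
#' @return `batch x n_classes` probability matrix, or a character vector of
#'   class labels.
#' @export
predict.tembo_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  out <- nn_forward(object$layers, model_input_array(object, newdata),
                    training = FALSE)
  probs <- t(out$y)
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, ties.method = "first")]
}

# ---- ElephantCallerNet -----------------------------------------------------

#' Build the spatial/temporal feature-extraction network
#'
#' A raw-waveform classifier in the ACDNet family. A spatial
#' feature-extraction block (SFEB; strided 1-D convolutions plus max pooling)
#' runs first and extracts fine-grained frequency detail; a temporal
#' feature-extraction block (TFEB; a stack of conv + batch norm + ReLU blocks
#' with interleaved max and average pooling) consumes it. The SFEB map is
#' then adaptively average-pooled to the TFEB output length and concatenated
#' along the channel dimension (the fusion stage), followed by a conv/BN/ReLU
#' integration stage with max pooling, dropout, a hidden fully connected
#' layer, and a softmax head. All conv/linear weights use Kaiming-normal
#' initialization, matched to the ReLU activations.
#'
#' @param input_samples Waveform length the network accepts (default 96000,
#'   i.e. 6 s at 16 kHz).
#' @param n_classes Number of classes (default 3).
#' @param dropout_p Dropout probability in `[0, 1)` (default 0.2).
#' @param sfeb List of SFEB conv stages `(out_channels, kernel, stride)`.
#' @param sfeb_pool Max-pool size closing the SFEB.
#' @param tfeb_channels TFEB block output channels.
#' @param tfeb_kernel TFEB kernel size (odd, >= 3).
#' @param tfeb_pools Pool sizes after each TFEB block (max/avg alternating).
#' @param integration_channels,fc_hidden Integration conv width and hidden
#'   fully connected width.
#' @param seed Seed for weight initialization.
#' @return A `tembo_model`.
#' @export
build_elephant_caller_net <- function(input_samples = 96000, n_classes = 3,
                                      dropout_p = 0.2,
                                      sfeb = list(c(8, 9, 2), c(16, 5, 2)),
                                      sfeb_pool = 4,
                                      tfeb_channels = c(32, 64, 128, 128, 256),
                                      tfeb_kernel = 3,
                                      tfeb_pools = c(4, 4, 2, 2, 2),
                                      integration_channels = 256,
                                      fc_hidden = 768,
                                      seed = 1L) {
  check_field(dropout_p >= 0 && dropout_p < 1, "dropout_p", "must lie in [0, 1)")
  check_field(n_classes >= 2, "n_classes", "must be >= 2")
  ks <- c(vapply(sfeb, `[`, numeric(1), 2), tfeb_kernel)
  check_field(all(ks >= 3 & ks %% 2 == 1), "kernel sizes",
              "must be odd and >= 3")
  check_field(length(tfeb_pools) == length(tfeb_channels), "tfeb_pools",
              "one pool size per TFEB block")
  withr::with_seed(as.integer(seed), {
    sfeb_layers <- list()
    in_ch <- 1
    for (i in seq_along(sfeb)) {
      st <- sfeb[[i]]
      sfeb_layers <- c(sfeb_layers, list(
        layer_conv(in_ch, st[1], kh = 1, kw = st[2], sw = st[3],
                   name = sprintf("sfeb_conv%d", i)),
        layer_bn(st[1], name = sprintf("sfeb_bn%d", i)),
        layer_act("relu", name = sprintf("sfeb_relu%d", i))
      ))
      in_ch <- st[1]
    }
    sfeb_layers <- c(sfeb_layers,
                     list(layer_pool("max", kw = sfeb_pool, name = "sfeb_pool")))
    sfeb_shape <- shape_walk(sfeb_layers, c(1, 1, input_samples))$shape
    tfeb_layers <- list()
    prev <- sfeb_shape[1]
    for (i in seq_along(tfeb_channels)) {
      kind <- if (i %% 2 == 1) "max" else "avg"
      tfeb_layers <- c(tfeb_layers, list(
        layer_conv(prev, tfeb_channels[i], kw = tfeb_kernel,
                   name = sprintf("tfeb_conv%d", i)),
        layer_bn(tfeb_channels[i], name = sprintf("tfeb_bn%d", i)),
        layer_act("relu", name = sprintf("tfeb_relu%d", i)),
        layer_pool(kind, kw = tfeb_pools[i], name = sprintf("tfeb_pool%d", i))
      ))
      prev <- tfeb_channels[i]
    }
    tfeb_shape <- shape_walk(tfeb_layers, sfeb_shape)$shape
    fusion <- layer_parallel_concat(
      list(tfeb_layers,
           list(layer_adaptive_avgpool_w(tfeb_shape[3], name = "sfeb_branch_pool"))),
      name = "fusion")
    fused_ch <- tfeb_shape[1] + sfeb_shape[1]
    int_pool <- min(2, tfeb_shape[3])
    head_layers <- list(
      layer_conv(fused_ch, integration_channels, kw = 3, name = "integration_conv"),
      layer_bn(integration_channels, name = "integration_bn"),
      layer_act("relu", name = "integration_relu"),
      layer_pool("max", kw = int_pool, name = "integration_pool"),
      layer_dropout(dropout_p, name = "dropout")
    )
    head_shape <- shape_walk(head_layers,
                             c(fused_ch, 1, tfeb_shape[3]))$shape
    flat <- prod(head_shape)
    layers <- c(sfeb_layers, list(fusion), head_layers, list(
      layer_flatten(),
      layer_linear(flat, fc_hidden, name = "fc_hidden"),
      layer_act("relu", name = "fc_relu"),
      layer_linear(fc_hidden, n_classes, name = "fc_out"),
      layer_softmax()
    ))
    new_model("elephant_caller_net", layers, n_classes, input_samples,
              config = list(dropout_p = dropout_p, sfeb = sfeb,
                            tfeb_channels = tfeb_channels,
                            tfeb_kernel = tfeb_kernel,
                            tfeb_pools = tfeb_pools,
                            integration_channels = integration_channels,
                            fc_hidden = fc_hidden, seed = seed))
  })
}

# ---- MobileNetV2 -----------------------------------------------------------

# Standard width-divisor rounding used by the MobileNet family.
make_divisible <- function(v, divisor = 8) {
  new_v <- max(divisor, floor(v + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

mbv2_inverted_residual <- function(in_ch, out_ch, stride, expand, idx) {
  hidden <- as.integer(round(in_ch * expand))
  nm <- function(s) sprintf("invres%d_%s", idx, s)
  body <- list()
  if (expand != 1) {
    body <- c(body, list(
      layer_conv(in_ch, hidden, kw = 1, bias = FALSE, name = nm("expand")),
      layer_bn(hidden, name = nm("expand_bn")),
      layer_act("relu6", name = nm("expand_relu"))
    ))
  }
  body <- c(body, list(
    layer_conv(hidden, hidden, kh = 3, kw = 3, sh = stride, sw = stride,
               ph = 1, pw = 1, groups = hidden, bias = FALSE, name = nm("dw")),
    layer_bn(hidden, name = nm("dw_bn")),
    layer_act("relu6", name = nm("dw_relu")),
    layer_conv(hidden, out_ch, kw = 1, bias = FALSE, name = nm("project")),
    layer_bn(out_ch, name = nm("project_bn"))
  ))
  if (stride == 1 && in_ch == out_ch) {
    list(layer_residual(body, name = nm("res")))
  } else {
    body
  }
}

#' Build a width-1.0 MobileNetV2 over reshaped raw waveforms
#'
#' The standard MobileNetV2 inverted-residual stack (depthwise-separable
#' convolutions, ReLU6, batch norm, linear bottlenecks) with the stem
#' convolution taking `in_channels` inputs and a linear `n_classes` head.
#' Raw waveforms are reshaped to a single-channel 2-D grid before the stem
#' (default `300 x 320` for 96,000 samples); the parameter count is
#' grid-independent. With `in_channels = 1` and `n_classes = 3` the network
#' has exactly 2,227,139 trainable parameters.
#'
#' @param n_classes Number of output classes (default 3).
#' @param in_channels Stem input channels (default 1).
#' @param input_samples Waveform length (default 96000).
#' @param grid `c(height, width)` reshape grid with
#'   `prod(grid) == input_samples`; chosen automatically when `NULL`.
#' @param width_mult Width multiplier (default 1.0).
#' @param dropout_p Classifier dropout (default 0.2).
#' @param seed Seed for weight initialization.
#' @return A `tembo_model`.
#' @export
build_mobilenet_v2_raw <- function(n_classes = 3, in_channels = 1,
                                   input_samples = 96000, grid = NULL,
                                   width_mult = 1.0, dropout_p = 0.2,
                                   seed = 1L) {
  check_field(n_classes >= 2, "n_classes", "must be >= 2")
  check_field(in_channels >= 1, "in_channels", "must be >= 1")
  grid <- grid %||% choose_grid(input_samples)
  if (prod(grid) != input_samples) {
    abort(sprintf("grid %d x %d does not factor the %d-sample waveform",
                  grid[1], grid[2], input_samples), class = "tembo_shape_error")
  }
  settings <- list(  # (expand t, channels c, repeats n, stride s)
    c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
    c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1)
  )
  withr::with_seed(as.integer(seed), {
    stem_ch <- make_divisible(32 * width_mult)
    layers <- list(
      layer_reshape(1, grid[1], grid[2], name = "grid_reshape"),
      layer_conv(in_channels, stem_ch, kh = 3, kw = 3, sh = 2, sw = 2,
                 ph = 1, pw = 1, bias = FALSE, name = "stem"),
      layer_bn(stem_ch, name = "stem_bn"),
      layer_act("relu6", name = "stem_relu")
    )
    in_ch <- stem_ch
    idx <- 0
    for (s in settings) {
      out_ch <- make_divisible(s[2] * width_mult)
      for (r in seq_len(s[3])) {
        idx <- idx + 1
        stride <- if (r == 1) s[4] else 1
        layers <- c(layers, mbv2_inverted_residual(in_ch, out_ch, stride,
                                                   s[1], idx))
        in_ch <- out_ch
      }
    }
    last_ch <- make_divisible(1280 * max(1, width_mult))
    layers <- c(layers, list(
      layer_conv(in_ch, last_ch, kw = 1, bias = FALSE, name = "head_conv"),
      layer_bn(last_ch, name = "head_bn"),
      layer_act("relu6", name = "head_relu"),
      layer_global_avgpool(),
      layer_flatten(),
      layer_dropout(dropout_p, name = "head_dropout"),
      layer_linear(last_ch, n_classes, name = "classifier"),
      layer_softmax()
    ))
    new_model("mobilenet_v2", layers, n_classes, input_samples,
              config = list(in_channels = in_channels, grid = grid,
                            width_mult = width_mult, seed = seed))
  })
}

# Near-square factorization of the waveform length for the 2-D reshape.
choose_grid <- function(n) {
  if (n == 96000) return(c(300L, 320L))
  h <- floor(sqrt(n))
  while (h >= 1 && n %% h != 0) h <- h - 1
  if (h < 32) {
    abort(sprintf("cannot factor %d samples into a usable 2-D grid; supply `grid`", n),
          class = "tembo_shape_error")
  }
  c(as.integer(h), as.integer(n / h))
}

# ---- YAMNet-style 1-D depthwise-separable stack ---------------------------

#' Build a 1-D depthwise-separable convolution classifier
#'
#' A YAMNet-flavoured raw-waveform network: a strided stem convolution
#' followed by depthwise-separable blocks (depthwise conv + pointwise conv,
#' each with batch norm and ReLU), global average pooling, and a linear
#' classifier. Trained from scratch.
#'
#' @param n_classes Number of classes.
#' @param input_samples Waveform length.
#' @param channels Block output channels.
#' @param strides Per-block depthwise strides (first entry is the stem's).
#' @param kernel Depthwise/stem kernel size.
#' @param width_mult Channel width multiplier.
#' @param seed Seed for weight initialization.
#' @return A `tembo_model`.
#' @export
build_yamnet_1d <- function(n_classes = 3, input_samples = 96000,
                            channels = c(32, 64, 128, 128, 256, 256),
                            strides = c(4, 4, 4, 2, 2, 2),
                            kernel = 9, width_mult = 1.0, seed = 1L) {
  check_field(length(strides) == length(channels), "strides",
              "one stride per block")
  ch <- pmax(1L, as.integer(round(channels * width_mult)))
  pad <- (kernel - 1) %/% 2
  withr::with_seed(as.integer(seed), {
    layers <- list(
      layer_conv(1, ch[1], kw = kernel, sw = strides[1], ph = 0, pw = pad,
                 name = "stem"),
      layer_bn(ch[1], name = "stem_bn"),
      layer_act("relu", name = "stem_relu")
    )
    for (i in 2:length(ch)) {
      layers <- c(layers, list(
        layer_conv(ch[i - 1], ch[i - 1], kw = kernel, sw = strides[i], pw = pad,
                   groups = ch[i - 1], name = sprintf("dw%d", i)),
        layer_bn(ch[i - 1], name = sprintf("dw_bn%d", i)),
        layer_act("relu", name = sprintf("dw_relu%d", i)),
        layer_conv(ch[i - 1], ch[i], kw = 1, name = sprintf("pw%d", i)),
        layer_bn(ch[i], name = sprintf("pw_bn%d", i)),
        layer_act("relu", name = sprintf("pw_relu%d", i))
      ))
    }
    layers <- c(layers, list(
      layer_global_avgpool(),
      layer_flatten(),
      layer_linear(ch[length(ch)], n_classes, name = "classifier"),
      layer_softmax()
    ))
    new_model("yamnet_1d", layers, n_classes, input_samples,
              config = list(channels = ch, strides = strides, kernel = kernel,
                            width_mult = width_mult, seed = seed))
  })
}

# ---- RawNet-style residual 1-D network ------------------------------------

# One residual block: conv-BN-LeakyReLU-conv-BN with an identity skip
# (1x1 projection when the channel count changes); no activation after the
# addition, so a block with zeroed conv weights is the identity map in
# evaluation mode.
rawnet_block <- function(in_ch, out_ch, kernel, idx) {
  nm <- function(s) sprintf("resblock%d_%s", idx, s)
  body <- list(
    layer_conv(in_ch, out_ch, kw = kernel, bias = FALSE, name = nm("conv1")),
    layer_bn(out_ch, name = nm("bn1")),
    layer_act("leaky_relu", name = nm("lrelu")),
    layer_conv(out_ch, out_ch, kw = kernel, bias = FALSE, name = nm("conv2")),
    layer_bn(out_ch, name = nm("bn2"))
  )
  proj <- if (in_ch != out_ch) {
    layer_conv(in_ch, out_ch, kw = 1, bias = FALSE, name = nm("proj"))
  }
  layer_residual(body, proj = proj, name = nm("res"))
}

#' Build a residual 1-D convolution classifier
#'
#' A RawNet-flavoured network: residual blocks of two convolutions with
#' batch normalization and LeakyReLU, identity skips (1x1 projection on
#' channel change), interleaved max pooling for downsampling, global average
#' pooling and a softmax head.
#'
#' @param n_classes Number of classes.
#' @param input_samples Waveform length.
#' @param channels Residual block output channels.
#' @param pools Pool size after the stem and after each block.
#' @param kernel Convolution kernel size.
#' @param seed Seed for weight initialization.
#' @return A `tembo_model`.
#' @export
build_rawnet_residual <- function(n_classes = 3, input_samples = 96000,
                                  channels = c(64, 64, 128, 128),
                                  pools = c(4, 4, 4, 2), kernel = 3,
                                  seed = 1L) {
  check_field(length(pools) == length(channels), "pools",
              "one pool size per block")
  withr::with_seed(as.integer(seed), {
    layers <- list(
      layer_conv(1, channels[1], kw = kernel, sw = 2, name = "stem"),
      layer_bn(channels[1], name = "stem_bn"),
      layer_act("leaky_relu", name = "stem_lrelu")
    )
    prev <- channels[1]
    for (i in seq_along(channels)) {
      layers <- c(layers, list(
        rawnet_block(prev, channels[i], kernel, i),
        layer_pool("max", kw = pools[i], name = sprintf("pool%d", i))
      ))
      prev <- channels[i]
    }
    layers <- c(layers, list(
      layer_global_avgpool(),
      layer_flatten(),
      layer_linear(prev, n_classes, name = "classifier"),
      layer_softmax()
    ))
    new_model("rawnet_residual", layers, n_classes, input_samples,
              config = list(channels = channels, pools = pools,
                            kernel = kernel, seed = seed))
  })
}

# ---- small 2-D CNN for feature images -------------------------------------

#' Build a small 2-D CNN over stacked feature images
#'
#' The spectrogram-pipeline CNN baseline: conv/BN/ReLU blocks with 2-D max
#' pooling over `(n_mfcc + 12) x n_frames` feature images, global average
#' pooling and a softmax head.
#'
#' @param n_classes Number of classes.
#' @param input_shape `c(rows, frames)` of the feature image.
#' @param channels Conv block widths.
#' @param seed Seed for weight initialization.
#' @return A `tembo_model` whose `input_samples` is `prod(input_shape)`;
#'   feed it flattened feature images (row-major per clip via
#'   [flatten_feature_matrix()]).
#' @export
build_feature_cnn <- function(n_classes = 3, input_shape = c(25, 184),
                              channels = c(16, 32, 64), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    layers <- list(layer_reshape(1, input_shape[1], input_shape[2],
                                 name = "image_reshape"))
    prev <- 1
    h <- input_shape[1]
    w <- input_shape[2]
    for (i in seq_along(channels)) {
      ph <- min(2L, h)  # pooling adapts to small feature images
      pw <- min(2L, w)
      layers <- c(layers, list(
        layer_conv(prev, channels[i], kh = 3, kw = 3, ph = 1, pw = 1,
                   name = sprintf("conv%d", i)),
        layer_bn(channels[i], name = sprintf("bn%d", i)),
        layer_act("relu", name = sprintf("relu%d", i)),
        layer_pool("max", kh = ph, kw = pw, name = sprintf("pool%d", i))
      ))
      h <- h %/% ph
      w <- w %/% pw
      prev <- channels[i]
    }
    layers <- c(layers, list(
      layer_global_avgpool(),
      layer_flatten(),
      layer_linear(prev, n_classes, name = "classifier"),
      layer_softmax()
    ))
    new_model("feature_cnn", layers, n_classes,
              input_samples = prod(input_shape),
              config = list(input_shape = input_shape, channels = channels,
                            seed = seed))
  })
}

#' Flatten a feature image to the vector layout the 2-D CNN expects
#' @param image A `feature_image`.
#' @return Numeric vector of length `nrow * ncol` of the stacked matrix.
#' @export
flatten_feature_matrix <- function(image) as.vector(image$stacked)

# ---- profiling -------------------------------------------------------------

#' Count trainable parameters
#'
#' Sums the sizes of every trainable array (convolution and linear weights
#' and biases, batch-norm scale and shift).
#'
#' @param model A `tembo_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  leaves <- flatten_leaves(get_params(model$layers))
  sum(vapply(leaves, length, numeric(1)))
}

# Walk layer shapes, accumulating analytic FLOPs (1 MAC = 2 FLOPs; bias adds
# counted; BN 2/element; activations 1/element; max pool k-1 compares,
# avg pool k adds + 1 divide per output; softmax 5/class; residual add
# 1/element). Aborts with the stage name on non-positive spatial sizes.
shape_walk <- function(layers, shape) {
  flops <- 0
  for (layer in layers) {
    res <- switch(layer$type,
      conv = {
        oh <- conv_out_dim(shape[2], layer$kh, layer$sh, layer$ph, layer$name)
        ow <- conv_out_dim(shape[3], layer$kw, layer$sw, layer$pw, layer$name)
        f <- 2 * oh * ow * layer$out_ch * (layer$in_ch / layer$groups) *
          layer$kh * layer$kw
        if (!is.null(layer$b)) f <- f + oh * ow * layer$out_ch
        list(shape = c(layer$out_ch, oh, ow), flops = f)
      },
      bn = list(shape = shape, flops = 2 * prod(shape)),
      relu = , relu6 = , leaky_relu = list(shape = shape, flops = prod(shape)),
      maxpool = , avgpool = {
        oh <- conv_out_dim(shape[2], layer$kh, layer$sh, 0, layer$name)
        ow <- conv_out_dim(shape[3], layer$kw, layer$sw, 0, layer$name)
        k <- layer$kh * layer$kw
        per <- if (layer$type == "maxpool") k - 1 else k + 1
        list(shape = c(shape[1], oh, ow), flops = oh * ow * shape[1] * per)
      },
      gap = list(shape = c(shape[1], 1, 1), flops = prod(shape) + shape[1]),
      adaptive_avgpool = list(shape = c(shape[1], 1, layer$out_w),
                              flops = shape[1] * (shape[3] + layer$out_w)),
      dropout = list(shape = shape, flops = 0),
      flatten = list(shape = c(prod(shape), 1, 1), flops = 0),
      reshape = list(shape = c(layer$ch, layer$h, layer$w), flops = 0),
      linear = list(shape = c(layer$out_f, 1, 1),
                    flops = 2 * layer$in_f * layer$out_f +
                      if (!is.null(layer$b)) layer$out_f else 0),
      softmax = list(shape = shape, flops = 5 * shape[1]),
      residual = {
        body <- shape_walk(layer$body, shape)
        f <- body$flops + prod(body$shape)
        if (!is.null(layer$proj)) {
          f <- f + shape_walk(list(layer$proj), shape)$flops
        }
        list(shape = body$shape, flops = f)
      },
      parallel_concat = {
        outs <- lapply(layer$branches, shape_walk, shape = shape)
        shp <- outs[[1]]$shape
        list(shape = c(sum(vapply(outs, function(o) o$shape[1], numeric(1))),
                       shp[2], shp[3]),
             flops = sum(vapply(outs, function(o) o$flops, numeric(1))))
      },
      abort(sprintf("estimate_flops: unsupported layer type %s", layer$type))
    )
    shape <- res$shape
    flops <- flops + res$flops
  }
  list(shape = shape, flops = flops)
}

#' Analytic FLOP estimate for a forward pass
#'
#' Counting convention: one multiply-accumulate = 2 FLOPs; bias additions
#' counted; batch norm 2 FLOPs/element (folded affine); activations 1
#' FLOP/element; max pooling k-1 comparisons and average pooling k+1
#' operations per output; softmax 5 FLOPs/class; residual additions 1
#' FLOP/element. Exactly linear in batch size and additive over layers.
#' Unsupported layer kinds raise an error rather than silently undercounting.
#'
#' @param model A `tembo_model`.
#' @param batch Batch size (default 1).
#' @return A list with `flops_per_input` and `flops_per_batch`.
#' @export
estimate_flops <- function(model, batch = 1) {
  first <- model$layers[[1]]
  in_shape <- if (first$type == "reshape") {
    c(1, 1, model$input_samples)
  } else {
    c(1, 1, model$input_samples)
  }
  res <- shape_walk(model$layers, in_shape)
  list(flops_per_input = res$flops, flops_per_batch = res$flops * batch)
}

# ---- serialization & quantization -----------------------------------------

walk_weight_tensors <- function(layers, fn) {
  for (layer in layers) {
    switch(layer$type,
      conv = , linear = {
        fn(layer$W, layer$Wq, layer$w_scale)
        if (!is.null(layer$b)) fn(layer$b, NULL, NULL)
      },
      bn = {
        fn(layer$gamma, NULL, NULL); fn(layer$beta, NULL, NULL)
        fn(layer$running_mean, NULL, NULL); fn(layer$running_var, NULL, NULL)
      },
      residual = {
        walk_weight_tensors(layer$body, fn)
        if (!is.null(layer$proj)) walk_weight_tensors(list(layer$proj), fn)
      },
      parallel_concat = {
        for (br in layer$branches) walk_weight_tensors(br, fn)
      },
      NULL
    )
  }
  invisible(NULL)
}

# Serialize all weights to a connection: quantized tensors as one float32
# scale + int8 payload, everything else as float32.
serialize_model_weights <- function(model, con) {
  walk_weight_tensors(model$layers, function(w, wq, scale) {
    if (!is.null(wq)) {
      writeBin(as.numeric(scale), con, size = 4, endian = "little")
      writeBin(as.integer(wq), con, size = 1)
    } else {
      writeBin(as.numeric(w), con, size = 4, endian = "little")
    }
  })
}

#' Serialized model size in bytes
#'
#' Measures the byte length of the model's weight serialization (float32
#' tensors; int8 payload plus per-tensor scale after [quantize_int8()]).
#'
#' @param model A `tembo_model`.
#' @return Size in bytes.
#' @export
model_serialized_size <- function(model) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  serialize_model_weights(model, con)
  length(rawConnectionValue(con))
}

#' Save model weights and a description sidecar
#'
#' @param model A `tembo_model`.
#' @param path Output path for the binary weight file; a JSON sidecar with
#'   the network description is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  con <- file(path, "wb")
  serialize_model_weights(model, con)
  close(con)
  jsonlite::write_json(network_description(model), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

quantize_tree <- function(layers) {
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    if (layer$type %in% c("conv", "linear")) {
      scale <- max(abs(layer$W)) / 127
      if (scale == 0) scale <- 1
      q <- round(layer$W / scale)
      layer$Wq <- q
      layer$w_scale <- scale
      layer$W[] <- q * scale   # dequantized weights used at inference
    } else if (layer$type == "residual") {
      layer$body <- quantize_tree(layer$body)
      if (!is.null(layer$proj)) layer$proj <- quantize_tree(list(layer$proj))[[1]]
    } else if (layer$type == "parallel_concat") {
      layer$branches <- lapply(layer$branches, quantize_tree)
    }
    layers[[i]] <- layer
  }
  layers
}

#' Post-training int8 weight quantization
#'
#' Uniform symmetric per-tensor quantization of every convolution and linear
#' weight matrix to 8 bits; inference runs on the dequantized weights, so the
#' per-tensor reconstruction error is bounded by half a quantization step.
#' Biases and batch-norm parameters stay in float. The serialized size drops
#' to roughly a quarter of the float32 size.
#'
#' @param model A trained `tembo_model`.
#' @return The quantized model (class `tembo_qmodel`).
#' @export
quantize_int8 <- function(model) {
  model$layers <- quantize_tree(model$layers)
  class(model) <- c("tembo_qmodel", class(model))
  model
}

#' Architecture description with complexity profile
#'
#' @param model A `tembo_model`.
#' @return A list with `name`, `n_classes`, `input_samples`,
#'   `parameter_count`, `flops_per_input` and `serialized_size_bytes`.
#' @export
network_description <- function(model) {
  list(name = model$name, n_classes = model$n_classes,
       input_samples = model$input_samples,
       parameter_count = count_parameters(model),
       flops_per_input = estimate_flops(model)$flops_per_input,
       serialized_size_bytes = model_serialized_size(model))
}

#' @export
glance.tembo_model <- function(x, ...) {
  as_tibble(network_description(x))
}
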