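#' Generator architecture configuration
#'
#' Describes the attention U-Net generator: a 7x7 reflection-padded stem
#' convolution with `base_filters` filters, an encoder that halves the
#' spatial resolution and doubles the channel width at every level, a
#' bottleneck of residual blocks combined with a self-attention module, and
#' a decoder with skip connections from the corresponding encoder layers,
#' closed by a 3x3 convolution with tanh activation producing a single
#' intensity-normalized channel.
#'
#' @param base_filters Filters in the stem convolution (channel widths at
#'   encoder level k are `base_filters * 2^k`).
#' @param n_levels Number of down/upsampling stages; input sides must be
#'   divisible by `2^n_levels`.
#' @param n_res_blocks Residual blocks at the bottleneck.
#' @param norm Feature normalization, `"instance"` or `"batch"` (batch
#'   statistics degenerate to instance statistics at batch size one, which
#'   is how training operates here).
#' @param activation `"relu"` or `"leaky_relu"`.
#' @param attention_at_bottleneck Place a self-attention module after the
#'   residual stack.
#' @param attention_gates Apply additive attention gates to the skip
#'   connections (the Attention-UNet convention).
#' @param upsample `"nearest"` (nearest-neighbour upsampling followed by a
#'   3x3 convolution) or `"transposed"`-style behaviour emulated by the
#'   same pathway; nearest is the default because it avoids checkerboard
#'   artifacts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(base_filters = 64L, n_levels = 2L,
                             n_res_blocks = 6L, norm = c("instance", "batch"),
                             activation = c("relu", "leaky_relu"),
                             attention_at_bottleneck = TRUE,
                             attention_gates = TRUE,
                             upsample = c("nearest", "transposed")) {
  norm <- match.arg(norm)
  activation <- match.arg(activation)
  upsample <- match.arg(upsample)
  stopifnot(base_filters >= 1, n_levels >= 1, n_res_blocks >= 0)
  structure(list(base_filters = as.integer(base_filters),
                 n_levels = as.integer(n_levels),
                 n_res_blocks = as.integer(n_res_blocks),
                 norm = norm, activation = activation,
                 attention_at_bottleneck = isTRUE(attention_at_bottleneck),
                 attention_gates = isTRUE(attention_gates),
                 upsample = upsample),
            class = "generator_config")
}

#' Discriminator architecture configuration
#'
#' PatchGAN discriminator: four 4x4 stride-two convolutions with strictly
#' increasing channel widths, self-attention inserted after the listed
#' layers, and a final 4x4 stride-one convolution to a one-channel grid of
#' patch probabilities (sigmoid output).
#'
#' @param channel_widths Widths of the four stride-two convolutions.
#' @param attention_after_layers Layer indices (1-4) followed by a
#'   self-attention module.
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(channel_widths = c(64L, 128L, 256L, 512L),
                                 attention_after_layers = c(2L, 3L)) {
  channel_widths <- as.integer(channel_widths)
  attention_after_layers <- as.integer(attention_after_layers)
  if (any(diff(channel_widths) <= 0)) stop("channel_widths must be strictly increasing")
  if (length(attention_after_layers) &&
      (min(attention_after_layers) < 1L ||
       max(attention_after_layers) > length(channel_widths)))
    stop("attention_after_layers out of range")
  structure(list(channel_widths = channel_widths,
                 attention_after_layers = attention_after_layers),
            class = "discriminator_config")
}

#' Desk-scale network preset
#'
#' A small generator/discriminator pair (16 base filters, 2 levels, 2
#' residual blocks; discriminator widths 16-128) intended for CPU training
#' on 64x64 phantom slices.
#'
#' @return List with elements `generator` and `discriminator`.
#' @export
tiny_preset <- function() {
  list(generator = generator_config(base_filters = 16L, n_levels = 2L,
                                    n_res_blocks = 2L),
       discriminator = discriminator_config(channel_widths = c(16L, 32L, 64L, 128L)))
}

# ---- parameter initialisation ---------------------------------------------

init_conv <- function(kh, kw, ic, oc) {
  sd <- sqrt(2 / (kh * kw * ic))
  list(w = ad_param(array(stats::rnorm(kh * kw * ic * oc, sd = sd),
                          c(kh, kw, ic, oc))),
       b = ad_param(rep(0, oc)))
}

init_norm <- function(ch) list(g = ad_param(rep(1, ch)), bt = ad_param(rep(0, ch)))

#' Self-attention module
#'
#' Non-local attention over all spatial positions: query/key projections at
#' width `channels / 8`, a value projection at full width, row-wise softmax
#' attention, and a learned scalar gate initialized at zero so that a
#' freshly constructed module is exactly the identity.
#'
#' @param channels Feature channels; must be at least 8 so the query/key
#'   bottleneck has width >= 1.
#' @return A module list with `$params` and `$forward(x)`; `x` is an
#'   `(H, W, C)` array (or autodiff node) and the output has the same shape.
#' @export
self_attention_module <- function(channels) {
  channels <- as.integer(channels)
  if (channels < 8L) stop("self-attention requires at least 8 channels (query/key width C/8 >= 1)")
  k <- channels %/% 8L
  sd <- sqrt(1 / channels)
  params <- list(
    wq = ad_param(matrix(stats::rnorm(channels * k, sd = sd), channels, k)),
    wk = ad_param(matrix(stats::rnorm(channels * k, sd = sd), channels, k)),
    wv = ad_param(matrix(stats::rnorm(channels * channels, sd = sd), channels, channels)),
    gamma = ad_param(0)
  )
  forward <- function(x) {
    xn <- as_node(x)
    d <- dim(ad_value(xn))
    if (d[3L] != channels) stop("channel mismatch in self-attention")
    n <- d[1L] * d[2L]
    m <- ad_reshape(xn, c(n, channels))
    q <- ad_matmul(m, params$wq)
    key <- ad_matmul(m, params$wk)
    a <- ad_softmax_rows(ad_matmul(q, ad_t(key)))
    o <- ad_matmul(a, ad_matmul(m, params$wv))
    ad_add(xn, ad_scale_node(ad_reshape(o, d), params$gamma))
  }
  attention <- function(x) {
    # attention weights for inspection: rows sum to one
    m <- matrix(ad_value(as_node(x)), ncol = channels)
    q <- m %*% ad_value(params$wq)
    key <- m %*% ad_value(params$wk)
    s <- q %*% t(key)
    s <- exp(s - apply(s, 1L, max))
    s / rowSums(s)
  }
  list(channels = channels, params = params, forward = forward,
       attention = attention)
}

#' Apply a self-attention module to a feature map
#'
#' @param features `(H, W, C)` array.
#' @param module A module from [self_attention_module()]; if omitted a
#'   freshly initialized module (an exact identity) is used.
#' @return `(H, W, C)` array.
#' @export
self_attention <- function(features, module = NULL) {
  if (is.null(module)) module <- self_attention_module(dim(features)[3L])
  ad_value(module$forward(features))
}

# attention gate on a skip connection (additive gating):
# psi = sigmoid(W_psi relu(W_g g + W_x s)), skip' = skip * psi
init_attention_gate <- function(ch) {
  inter <- max(1L, ch %/% 2L)
  list(wg = init_conv(1L, 1L, ch, inter), wx = init_conv(1L, 1L, ch, inter),
       psi = init_conv(1L, 1L, inter, 1L))
}

apply_attention_gate <- function(gate, g, s) {
  a <- ad_relu(ad_add(ad_conv2d(g, gate$wg$w, gate$wg$b),
                      ad_conv2d(s, gate$wx$w, gate$wx$b)))
  psi <- ad_sigmoid(ad_conv2d(a, gate$psi$w, gate$psi$b))
  ad_mul_gate(s, psi)
}

act_fn <- function(cfg) if (cfg$activation == "relu") ad_relu else ad_leaky_relu

#' Build an attention U-Net generator
#'
#' Constructs the generator described by a [generator_config()]: 7x7
#' reflection-padded stem (64 filters by default), stride-two encoder
#' stages doubling the channel width, residual bottleneck blocks (two 3x3
#' convolutions with intermediate normalization and activation plus an
#' additive shortcut, routed through a 1x1 convolution when widths differ)
#' combined with self-attention, a decoder with (gated) skip connections,
#' and a final 3x3 convolution with tanh.
#'
#' Parameters are drawn from the R random number generator; call
#' `set.seed()` beforehand for reproducible initialization.
#'
#' @param cfg A [generator_config()].
#' @return An object of class `ct_generator` with elements `$params` (named
#'   list of parameter nodes), `$forward(x)` mapping an `(H, W, 1)` array or
#'   node to a same-shaped node, `$encoder_channels`, and `$cfg`.
#' @export
build_generator <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  b <- cfg$base_filters
  L <- cfg$n_levels
  enc_ch <- b * 2L^(0:L)

  p <- list()
  p$stem <- init_conv(7L, 7L, 1L, b)
  p$stem_n <- init_norm(b)
  for (k in seq_len(L)) {
    p[[paste0("enc", k)]] <- init_conv(3L, 3L, enc_ch[k], enc_ch[k + 1L])
    p[[paste0("enc", k, "_n")]] <- init_norm(enc_ch[k + 1L])
  }
  cb <- enc_ch[L + 1L]
  for (r in seq_len(cfg$n_res_blocks)) {
    p[[paste0("res", r, "_c1")]] <- init_conv(3L, 3L, cb, cb)
    p[[paste0("res", r, "_n1")]] <- init_norm(cb)
    p[[paste0("res", r, "_c2")]] <- init_conv(3L, 3L, cb, cb)
    p[[paste0("res", r, "_n2")]] <- init_norm(cb)
  }
  attn <- if (cfg$attention_at_bottleneck) self_attention_module(cb) else NULL
  for (k in rev(seq_len(L))) {
    oc <- enc_ch[k]
    p[[paste0("dec", k, "_up")]] <- init_conv(3L, 3L, enc_ch[k + 1L], oc)
    p[[paste0("dec", k, "_up_n")]] <- init_norm(oc)
    if (cfg$attention_gates) p[[paste0("dec", k, "_gate")]] <- init_attention_gate(oc)
    p[[paste0("dec", k, "_fuse")]] <- init_conv(3L, 3L, 2L * oc, oc)
    p[[paste0("dec", k, "_fuse_n")]] <- init_norm(oc)
  }
  p$head <- init_conv(3L, 3L, b, 1L)

  flat <- flatten_params(p)
  if (!is.null(attn)) {
    flat <- c(flat, stats::setNames(attn$params, paste0("attn.", names(attn$params))))
  }
  act <- act_fn(cfg)

  forward <- function(x) {
    xn <- as_node(x)
    d <- dim(ad_value(xn))
    if (length(d) != 3L || d[3L] != 1L) stop("generator input must be an (H, W, 1) array")
    if (d[1L] %% 2L^L != 0L || d[2L] %% 2L^L != 0L)
      stop(sprintf("input sides (%d x %d) must be divisible by 2^%d", d[1L], d[2L], L))
    h <- act(ad_instance_norm(
      ad_conv2d(xn, p$stem$w, p$stem$b, pad = 3L, pad_mode = "reflect"),
      p$stem_n$g, p$stem_n$bt))
    skips <- vector("list", L)
    skips[[1L]] <- h
    for (k in seq_len(L)) {
      h <- act(ad_instance_norm(
        ad_conv2d(h, p[[paste0("enc", k)]]$w, p[[paste0("enc", k)]]$b,
                  stride = 2L, pad = 1L),
        p[[paste0("enc", k, "_n")]]$g, p[[paste0("enc", k, "_n")]]$bt))
      if (k < L) skips[[k + 1L]] <- h
    }
    for (r in seq_len(cfg$n_res_blocks)) {
      r1 <- act(ad_instance_norm(
        ad_conv2d(h, p[[paste0("res", r, "_c1")]]$w, p[[paste0("res", r, "_c1")]]$b, pad = 1L),
        p[[paste0("res", r, "_n1")]]$g, p[[paste0("res", r, "_n1")]]$bt))
      r2 <- ad_instance_norm(
        ad_conv2d(r1, p[[paste0("res", r, "_c2")]]$w, p[[paste0("res", r, "_c2")]]$b, pad = 1L),
        p[[paste0("res", r, "_n2")]]$g, p[[paste0("res", r, "_n2")]]$bt)
      h <- ad_add(h, r2)
    }
    if (!is.null(attn)) h <- attn$forward(h)
    for (k in rev(seq_len(L))) {
      up <- act(ad_instance_norm(
        ad_conv2d(ad_upsample2(h), p[[paste0("dec", k, "_up")]]$w,
                  p[[paste0("dec", k, "_up")]]$b, pad = 1L),
        p[[paste0("dec", k, "_up_n")]]$g, p[[paste0("dec", k, "_up_n")]]$bt))
      s <- skips[[k]]
      if (cfg$attention_gates)
        s <- apply_attention_gate(p[[paste0("dec", k, "_gate")]], up, s)
      h <- act(ad_instance_norm(
        ad_conv2d(ad_concat_c(up, s), p[[paste0("dec", k, "_fuse")]]$w,
                  p[[paste0("dec", k, "_fuse")]]$b, pad = 1L),
        p[[paste0("dec", k, "_fuse_n")]]$g, p[[paste0("dec", k, "_fuse_n")]]$bt))
    }
    ad_tanh(ad_conv2d(h, p$head$w, p$head$b, pad = 1L))
  }

  structure(list(cfg = cfg, params = flat, forward = forward,
                 encoder_channels = enc_ch),
            class = "ct_generator")
}

#' Build a PatchGAN discriminator
#'
#' Four 4x4 stride-two convolutions (padding 1) with the configured channel
#' widths, leaky-ReLU activations, instance normalization from the second
#' layer on, self-attention after the configured layers, and a final 4x4
#' stride-one convolution to one channel followed by a sigmoid, producing a
#' grid of per-patch real/fake probabilities.
#'
#' @param cfg A [discriminator_config()].
#' @return Object of class `ct_discriminator` with `$params`,
#'   `$forward(x)`, `$output_shape(c(H, W))` and `$min_input`.
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "discriminator_config"))
  widths <- cfg$channel_widths
  nl <- length(widths)
  p <- list()
  ic <- 1L
  attn <- list()
  for (i in seq_len(nl)) {
    p[[paste0("conv", i)]] <- init_conv(4L, 4L, ic, widths[i])
    if (i > 1L) p[[paste0("norm", i)]] <- init_norm(widths[i])
    if (i %in% cfg$attention_after_layers)
      attn[[as.character(i)]] <- self_attention_module(widths[i])
    ic <- widths[i]
  }
  p$final <- init_conv(4L, 4L, ic, 1L)
  flat <- flatten_params(p)
  for (nm in names(attn))
    flat <- c(flat, stats::setNames(attn[[nm]]$params,
                                    paste0("attn", nm, ".", names(attn[[nm]]$params))))

  out_side <- function(s) {
    for (i in seq_len(nl)) s <- floor((s + 2L - 4L) / 2L) + 1L
    s + 2L - 4L + 1L
  }
  output_shape <- function(hw) vapply(hw, out_side, numeric(1))
  # smallest input whose output grid is >= 1x1
  min_input <- {
    s <- 1L
    repeat { if (out_side(s) >= 1L) break; s <- s + 1L }
    s
  }

  forward <- function(x) {
    xn <- as_node(x)
    d <- dim(ad_value(xn))
    if (length(d) != 3L || d[3L] != 1L) stop("discriminator input must be an (H, W, 1) array")
    if (min(output_shape(d[1:2])) < 1L)
      stop(sprintf("input %dx%d too small for the PatchGAN; minimum side is %d",
                   d[1L], d[2L], min_input))
    h <- xn
    for (i in seq_len(nl)) {
      h <- ad_conv2d(h, p[[paste0("conv", i)]]$w, p[[paste0("conv", i)]]$b,
                     stride = 2L, pad = 1L)
      if (i > 1L) h <- ad_instance_norm(h, p[[paste0("norm", i)]]$g,
                                        p[[paste0("norm", i)]]$bt)
      h <- ad_leaky_relu(h, 0.2)
      a <- attn[[as.character(i)]]
      if (!is.null(a)) h <- a$forward(h)
    }
    ad_sigmoid(ad_conv2d(h, p$final$w, p$final$b, stride = 1L, pad = 1L))
  }

  structure(list(cfg = cfg, params = flat, forward = forward,
                 output_shape = output_shape, min_input = min_input),
            class = "ct_discriminator")
}

#' Run a network forward
#'
#' @param net A `ct_generator` or `ct_discriminator`.
#' @param x Input `(H, W, 1)` array.
#' @return Output array (same shape for generators; a probability grid for
#'   discriminators).
#' @export
net_forward <- function(net, x) ad_value(net$forward(x))

#' Number of trainable parameters of a network
#' @param net A network object.
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(net) sum(vapply(net$params, function(p) length(ad_value(p)), numeric(1)))

# flatten nested conv/norm parameter lists into a single named list of nodes
flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    el <- p[[nm]]
    if (is_adnode(el)) {
      out[[nm]] <- el
    } else {
      sub <- flatten_params(el)
      names(sub) <- paste0(nm, ".", names(sub))
      out <- c(out, sub)
    }
  }
  out
}

# assign a flat list of parameter values (from a checkpoint) into a network
set_params <- function(net, values) {
  if (!setequal(names(values), names(net$params)))
    stop("checkpoint parameters do not match the network architecture")
  for (nm in names(values)) net$params[[nm]]$v <- values[[nm]]
  invisible(net)
}

get_params <- function(net) lapply(net$params, ad_value)
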