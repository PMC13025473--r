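# Reverse-mode automatic differentiation on image tensors.
#
# Tensors are plain R arrays with dim (H, W, C) (or matrices / scalars for
# attention and loss heads).  Every op returns a lightweight node; when a
# tape is active the node carries a backward closure and is recorded, so
# ad_backward() can sweep the tape in reverse.  With no tape active the ops
# evaluate eagerly at plain-forward cost, which is the inference path.

.ad <- new.env(parent = emptyenv())
.ad$active <- FALSE
.ad$tape <- NULL
.ad$n <- 0L

ad_begin <- function() {
  .ad$active <- TRUE
  .ad$tape <- vector("list", 512L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_end <- function() {
  .ad$active <- FALSE
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

is_adnode <- function(x) inherits(x, "adnode")

new_node <- function(v, bw = NULL, param = FALSE) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$bw <- bw
  n$param <- param
  class(n) <- "adnode"
  if (.ad$active && !is.null(bw)) {
    .ad$n <- .ad$n + 1L
    if (.ad$n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    .ad$tape[[.ad$n]] <- n
  }
  n
}

ad_param <- function(v) new_node(v, param = TRUE)

ad_const <- function(v) if (is_adnode(v)) new_node(v$v) else new_node(v)

as_node <- function(x) if (is_adnode(x)) x else new_node(x)

ad_value <- function(x) if (is_adnode(x)) x$v else x

acc_grad <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# Sweep the tape in reverse from `loss` (a scalar node).
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss), length(loss$v) == 1L)
  loss$g <- 1
  if (.ad$n > 0L) {
    for (i in rev(seq_len(.ad$n))) {
      nd <- .ad$tape[[i]]
      if (!is.null(nd$g)) nd$bw(nd$g)
    }
  }
  invisible(NULL)
}

taping <- function() .ad$active

# ---- primitive ops ---------------------------------------------------------

pad_mode_code <- function(pad_mode) {
  switch(pad_mode, zero = 0L, reflect = 1L, replicate = 2L,
         stop("unknown pad_mode: ", pad_mode))
}

ad_conv2d <- function(x, w, b, stride = 1L, pad = 0L, pad_mode = "zero") {
  x <- as_node(x)
  pm <- pad_mode_code(pad_mode)
  v <- cpp_conv2d(x$v, w$v, b$v, as.integer(stride), as.integer(pad), pm)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    bk <- cpp_conv2d_backward(x$v, w$v, g, as.integer(stride), as.integer(pad),
                              pm, isTRUE(w$param))
    acc_grad(x, bk$gx)
    if (isTRUE(w$param)) { acc_grad(w, bk$gw); acc_grad(b, bk$gb) }
  })
}

# separable symmetric-kernel valid correlation (SSIM Gaussian window)
ad_gauss_valid <- function(x, kernel1d) {
  x <- as_node(x)
  v <- cpp_sepconv_valid(x$v, kernel1d)
  if (!taping()) return(new_node(v))
  d <- dim(x$v)
  new_node(v, bw = function(g)
    acc_grad(x, cpp_sepconv_valid_adjoint(g, kernel1d, d[1L], d[2L])))
}

ad_upsample2 <- function(x) {
  x <- as_node(x)
  v <- cpp_upsample2(x$v)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(x, cpp_downsum2(g)))
}

ad_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x)
  fw <- cpp_inorm_forward(x$v, gamma$v, beta$v, eps)
  if (!taping()) return(new_node(fw$y))
  new_node(fw$y, bw = function(g) {
    bk <- cpp_inorm_backward(g, fw$xhat, fw$inv_sd, gamma$v)
    acc_grad(x, bk$gx)
    acc_grad(gamma, bk$dgamma); acc_grad(beta, bk$dbeta)
  })
}

ad_relu <- function(x) {
  x <- as_node(x)
  v <- pmax(x$v, 0)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(x, g * (x$v > 0)))
}

ad_leaky_relu <- function(x, slope = 0.2) {
  x <- as_node(x)
  pos <- x$v > 0
  v <- x$v * (slope + (1 - slope) * pos)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(x, g * (slope + (1 - slope) * pos)))
}

ad_tanh <- function(x) {
  x <- as_node(x)
  v <- tanh(x$v)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(x, g * (1 - v^2)))
}

ad_sigmoid <- function(x) {
  x <- as_node(x)
  v <- 1 / (1 + exp(-x$v))
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(x, g * v * (1 - v)))
}

ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  v <- a$v + b$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) { acc_grad(a, g); acc_grad(b, g) })
}

ad_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  v <- a$v - b$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) { acc_grad(a, g); acc_grad(b, -g) })
}

ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  v <- a$v * b$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) { acc_grad(a, g * b$v); acc_grad(b, g * a$v) })
}

ad_div <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  v <- a$v / b$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    acc_grad(a, g / b$v)
    acc_grad(b, -g * a$v / (b$v * b$v))
  })
}

ad_scale <- function(a, k) {
  a <- as_node(a)
  v <- a$v * k
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, g * k))
}

ad_add_const <- function(a, k) {
  a <- as_node(a)
  v <- a$v + k
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, g))
}

ad_square <- function(a) ad_mul(a, a)

# multiply a tensor by a scalar *node* (e.g. the learned attention gate)
ad_scale_node <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  v <- x$v * s$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    acc_grad(x, g * s$v)
    acc_grad(s, sum(g * x$v))
  })
}

ad_abs <- function(a) {
  a <- as_node(a)
  v <- abs(a$v)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, g * sign(a$v)))
}

ad_log <- function(a) {
  a <- as_node(a)
  v <- log(a$v)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, g / a$v))
}

ad_clamp <- function(a, lo, hi) {
  a <- as_node(a)
  v <- pmin(pmax(a$v, lo), hi)
  if (!is.null(dim(a$v))) dim(v) <- dim(a$v)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, g * (a$v >= lo & a$v <= hi)))
}

ad_mean <- function(a) {
  a <- as_node(a)
  n <- length(a$v)
  v <- sum(a$v) / n
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, 0 * a$v + g / n))
}

ad_sum <- function(a) {
  a <- as_node(a)
  v <- sum(a$v)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, 0 * a$v + g))
}

# channel-wise broadcast multiply: gate has dim (H, W, 1)
ad_mul_gate <- function(x, gate) {
  x <- as_node(x); gate <- as_node(gate)
  d <- dim(x$v)
  gv <- rep(as.vector(gate$v), d[3L])
  v <- x$v * gv
  dim(v) <- d
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    acc_grad(x, array(g * gv, d))
    gg <- rowSums(matrix(g * x$v, d[1L] * d[2L], d[3L]))
    acc_grad(gate, array(gg, c(d[1L], d[2L], 1L)))
  })
}

ad_concat_c <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  da <- dim(a$v); db <- dim(b$v)
  v <- array(c(a$v, b$v), c(da[1L], da[2L], da[3L] + db[3L]))
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    na <- length(a$v)
    acc_grad(a, array(g[seq_len(na)], da))
    acc_grad(b, array(g[na + seq_len(length(b$v))], db))
  })
}

ad_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  v <- a$v %*% b$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    acc_grad(a, g %*% t(b$v))
    acc_grad(b, crossprod(a$v, g))
  })
}

ad_t <- function(a) {
  a <- as_node(a)
  v <- t(a$v)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, t(g)))
}

ad_reshape <- function(a, d) {
  a <- as_node(a)
  v <- a$v
  dim(v) <- d
  if (!taping()) return(new_node(v))
  od <- dim(a$v)
  new_node(v, bw = function(g) { dim(g) <- od; acc_grad(a, g) })
}

ad_softmax_rows <- function(a) {
  a <- as_node(a)
  m <- a$v - apply(a$v, 1L, max)
  e <- exp(m)
  v <- e / rowSums(e)
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) acc_grad(a, v * (g - rowSums(g * v))))
}

# forward finite differences with replicate edge handling: the last
# row/column difference is zero, so gradients are DC-offset invariant.
ad_fdiff_h <- function(x) {
  x <- as_node(x)
  d <- dim(x$v)
  v <- x$v[c(2:d[1L], d[1L]), , , drop = FALSE] - x$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    gx <- array(0, d)
    gx[2:d[1L], , ] <- gx[2:d[1L], , ] + g[1:(d[1L] - 1L), , ]
    gx[1:(d[1L] - 1L), , ] <- gx[1:(d[1L] - 1L), , ] - g[1:(d[1L] - 1L), , ]
    acc_grad(x, gx)
  })
}

ad_fdiff_w <- function(x) {
  x <- as_node(x)
  d <- dim(x$v)
  v <- x$v[, c(2:d[2L], d[2L]), , drop = FALSE] - x$v
  if (!taping()) return(new_node(v))
  new_node(v, bw = function(g) {
    gx <- array(0, d)
    gx[, 2:d[2L], ] <- gx[, 2:d[2L], ] + g[, 1:(d[2L] - 1L), ]
    gx[, 1:(d[2L] - 1L), ] <- gx[, 1:(d[2L] - 1L), ] - g[, 1:(d[2L] - 1L), ]
    acc_grad(x, gx)
  })
}
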