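# Independent brute-force reference implementations used to validate the
# package's vectorized / compiled code paths.  Everything here is written as
# plain loops over pixels, deliberately sharing no code with the package.

# random (H, W, 1) image in [-1, 1]
rand_img <- function(h, w = h) {
  array(stats::runif(h * w, -1, 1), c(h, w, 1L))
}

# padded pixel lookup for the three padding conventions
oracle_pad_lookup <- function(img, i, j, mode) {
  H <- nrow(img); W <- ncol(img)
  wrap <- function(t, n) {
    if (t >= 1 && t <= n) return(t)
    if (mode == "zero") return(NA_integer_)
    if (mode == "replicate") return(min(max(t, 1), n))
    # reflect without repeating the border sample
    if (t < 1) return(2 - t)
    2 * n - t
  }
  ii <- wrap(i, H); jj <- wrap(j, W)
  if (is.na(ii) || is.na(jj)) 0 else img[ii, jj]
}

# direct convolution (cross-correlation, as in the package): x (H, W, C),
# w (KH, KW, IC, OC), bias length OC
oracle_conv2d <- function(x, w, b, stride = 1L, pad = 0L, mode = "zero") {
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
  KH <- dim(w)[1L]; KW <- dim(w)[2L]; OC <- dim(w)[4L]
  OH <- (H + 2 * pad - KH) %/% stride + 1L
  OW <- (W + 2 * pad - KW) %/% stride + 1L
  out <- array(0, c(OH, OW, OC))
  for (oc in seq_len(OC)) for (oi in seq_len(OH)) for (oj in seq_len(OW)) {
    acc <- b[oc]
    for (c in seq_len(C)) for (kh in seq_len(KH)) for (kw in seq_len(KW)) {
      i <- (oi - 1L) * stride + kh - pad
      j <- (oj - 1L) * stride + kw - pad
      acc <- acc + oracle_pad_lookup(x[, , c, drop = FALSE][, , 1L], i, j, mode) *
        w[kh, kw, c, oc]
    }
    out[oi, oj, oc] <- acc
  }
  out
}

oracle_l1 <- function(a, b) {
  s <- 0
  for (t in seq_along(a)) s <- s + abs(a[t] - b[t])
  s / length(a)
}

oracle_bce <- function(p, target) {
  s <- 0
  for (t in seq_along(p)) {
    q <- min(max(p[t], 1e-7), 1 - 1e-7)
    s <- s - (if (target == 1) log(q) else log(1 - q))
  }
  s / length(p)
}

# forward finite difference with replicated edge, one direction
oracle_fdiff <- function(img, along = c("h", "w")) {
  along <- match.arg(along)
  H <- nrow(img); W <- ncol(img)
  d <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (along == "h") d[i, j] <- img[min(i + 1L, H), j] - img[i, j]
    else d[i, j] <- img[i, min(j + 1L, W)] - img[i, j]
  }
  d
}

oracle_gd_one <- function(f, r) {
  0.5 * (oracle_l1(oracle_fdiff(f, "h"), oracle_fdiff(r, "h")) +
           oracle_l1(oracle_fdiff(f, "w"), oracle_fdiff(r, "w")))
}

# SSIM with an explicit 11x11 Gaussian window (sigma 1.5), valid region,
# computed pixel-by-pixel
oracle_ssim <- function(a, b, data_range, size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g1 <- exp(-r^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  win <- outer(g1, g1)
  H <- nrow(a); W <- ncol(a)
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  vals <- c()
  for (i in seq_len(H - size + 1L)) for (j in seq_len(W - size + 1L)) {
    pa <- a[i:(i + size - 1L), j:(j + size - 1L)]
    pb <- b[i:(i + size - 1L), j:(j + size - 1L)]
    mu_a <- sum(win * pa); mu_b <- sum(win * pb)
    va <- sum(win * pa * pa) - mu_a^2
    vb <- sum(win * pb * pb) - mu_b^2
    cab <- sum(win * pa * pb) - mu_a * mu_b
    vals <- c(vals, ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
                ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
  }
  mean(vals)
}

as2d <- function(x) if (length(dim(x)) == 3L) x[, , 1L] else x

# circular ROI statistics by explicit pixel scan
oracle_roi_stats <- function(img, center, radius) {
  vals <- c()
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    if ((i - center[1L])^2 + (j - center[2L])^2 <= radius^2)
      vals <- c(vals, img[i, j])
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

# one Adam step computed longhand
oracle_adam_step <- function(theta, g, m, v, t, lr, beta1, beta2, eps = 1e-8) {
  m2 <- beta1 * m + (1 - beta1) * g
  v2 <- beta2 * v + (1 - beta2) * g^2
  mh <- m2 / (1 - beta1^t)
  vh <- v2 / (1 - beta2^t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
}

# tiny paired slices for smoke-training tests
toy_pairs <- function(n = 2L, size = 32L, seed = 7L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- matrix(stats::rnorm(size * size, mean = 40, sd = 10), size, size)
    list(patient = sprintf("T%02d", i), ncct = base, cect = base + 50)
  })
}
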