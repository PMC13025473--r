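# The training engine differentiates every operator on a tape; these tests
# compare compiled forward passes against loop oracles and analytic
# gradients against central finite differences.

ad <- function(name) get(name, envir = asNamespace("ctsynth"))

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (t in seq_along(x)) {
    xp <- x; xp[t] <- xp[t] + eps
    xm <- x; xm[t] <- xm[t] - eps
    g[t] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("compiled convolution matches the loop oracle for all paddings", {
  set.seed(40)
  for (mode in c("zero", "reflect", "replicate")) {
    x <- array(stats::rnorm(10 * 9 * 2), c(10, 9, 2))
    w <- array(stats::rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    b <- stats::rnorm(4)
    got <- ctsynth:::ad_value(ad("ad_conv2d")(x, ad("ad_const")(w),
                                              ad("ad_const")(b),
                                              stride = 1L, pad = 1L,
                                              pad_mode = mode))
    expect_equal(got, oracle_conv2d(x, w, b, 1L, 1L, mode), tolerance = 1e-12,
                 info = mode)
  }
  # stride 2, kernel 4 (the PatchGAN geometry)
  x <- array(stats::rnorm(12 * 12), c(12, 12, 1))
  w <- array(stats::rnorm(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  b <- stats::rnorm(3)
  got <- ctsynth:::ad_value(ad("ad_conv2d")(x, ad("ad_const")(w),
                                            ad("ad_const")(b),
                                            stride = 2L, pad = 1L))
  expect_equal(got, oracle_conv2d(x, w, b, 2L, 1L, "zero"), tolerance = 1e-12)
})

test_that("convolution gradients agree with finite differences", {
  set.seed(41)
  x <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2))
  w0 <- array(stats::rnorm(3 * 3 * 2 * 3, sd = 0.5), c(3, 3, 2, 3))
  b0 <- stats::rnorm(3)
  run <- function(xv, wv, bv) {
    ad("ad_begin")()
    xn <- ad("ad_param")(xv); wn <- ad("ad_param")(wv); bn <- ad("ad_param")(bv)
    loss <- ad("ad_mean")(ad("ad_square")(
      ad("ad_conv2d")(xn, wn, bn, stride = 1L, pad = 1L, pad_mode = "reflect")))
    ad("ad_backward")(loss)
    ad("ad_end")()
    list(x = xn$g, w = wn$g, b = bn$g, v = ctsynth:::ad_value(loss))
  }
  got <- run(x, w0, b0)
  fx <- function(xv) {
    o <- oracle_conv2d(xv, w0, b0, 1L, 1L, "reflect"); mean(o^2)
  }
  fw <- function(wv) {
    o <- oracle_conv2d(x, wv, b0, 1L, 1L, "reflect"); mean(o^2)
  }
  expect_equal(got$x, num_grad(fx, x), tolerance = 1e-6)
  expect_equal(got$w, num_grad(fw, w0), tolerance = 1e-6)
})

test_that("instance norm output is standardized and its gradient checks out", {
  set.seed(42)
  x <- array(stats::rnorm(6 * 6 * 3, mean = 4, sd = 3), c(6, 6, 3))
  g <- rep(1, 3); b <- rep(0, 3)
  out <- ctsynth:::ad_value(ad("ad_instance_norm")(x, ad("ad_param")(g),
                                                   ad("ad_param")(b)))
  for (c in 1:3) {
    expect_equal(mean(out[, , c]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(as.vector(out[, , c])) * sqrt(35 / 36), 1,
                 tolerance = 1e-4)  # population sd with eps = 1e-5
  }
  run <- function(xv) {
    ad("ad_begin")()
    xn <- ad("ad_param")(xv)
    loss <- ad("ad_mean")(ad("ad_square")(
      ad("ad_instance_norm")(xn, ad("ad_param")(c(1.3, 0.7, 2)),
                             ad("ad_param")(c(0.1, -0.2, 0)))))
    ad("ad_backward")(loss)
    ad("ad_end")()
    list(g = xn$g, v = ctsynth:::ad_value(loss))
  }
  f <- function(xv) {
    o <- xv
    for (c in 1:3) {
      m <- mean(xv[, , c]); v <- mean((xv[, , c] - m)^2)
      o[, , c] <- c(1.3, 0.7, 2)[c] * (xv[, , c] - m) / sqrt(v + 1e-5) +
        c(0.1, -0.2, 0)[c]
    }
    mean(o^2)
  }
  expect_equal(run(x)$g, num_grad(f, x, eps = 1e-4), tolerance = 1e-4)
})

test_that("elementwise and reduction operators backpropagate correctly", {
  set.seed(43)
  x <- array(stats::runif(5 * 5, -0.9, 0.9), c(5, 5, 1))
  check_op <- function(op_name, f_ref, ...) {
    ad("ad_begin")()
    xn <- ad("ad_param")(x)
    loss <- ad("ad_mean")(ad("ad_square")(ad(op_name)(xn, ...)))
    ad("ad_backward")(loss)
    ad("ad_end")()
    f <- function(xv) mean(f_ref(xv)^2)
    expect_equal(xn$g, num_grad(f, x), tolerance = 1e-6, info = op_name)
  }
  check_op("ad_tanh", tanh)
  check_op("ad_sigmoid", function(z) 1 / (1 + exp(-z)))
  check_op("ad_relu", function(z) pmax(z, 0))
  check_op("ad_leaky_relu", function(z) ifelse(z > 0, z, 0.2 * z), 0.2)
  check_op("ad_fdiff_h", function(z) {
    m <- z[, , 1]; array(oracle_fdiff(m, "h"), dim(z))
  })
  check_op("ad_fdiff_w", function(z) {
    m <- z[, , 1]; array(oracle_fdiff(m, "w"), dim(z))
  })
})

test_that("upsample2 is exact nearest-neighbour and adjoint to block sums", {
  set.seed(44)
  x <- array(stats::rnorm(4 * 4 * 2), c(4, 4, 2))
  up <- ctsynth:::ad_value(ad("ad_upsample2")(x))
  expect_equal(dim(up), c(8L, 8L, 2L))
  for (i in 1:8) for (j in 1:8)
    expect_equal(up[i, j, ], x[ceiling(i / 2), ceiling(j / 2), ])
  # gradient: each input pixel collects its 2x2 block
  ad("ad_begin")()
  xn <- ad("ad_param")(x)
  loss <- ad("ad_sum")(ad("ad_mul")(ad("ad_upsample2")(xn),
                                    ad("ad_const")(up)))
  ad("ad_backward")(loss)
  ad("ad_end")()
  expect_equal(xn$g, 4 * x, tolerance = 1e-12)
})

test_that("tape isolation: gradients do not leak across ad_begin/ad_end", {
  set.seed(45)
  p <- ad("ad_param")(matrix(stats::rnorm(4), 2, 2))
  ad("ad_begin")()
  l1 <- ad("ad_sum")(ad("ad_square")(p))
  ad("ad_backward")(l1)
  ad("ad_end")()
  g1 <- p$g
  expect_equal(g1, 2 * ctsynth:::ad_value(p), tolerance = 1e-12)
  ad("ad_zero_grad")(list(p))
  expect_null(p$g)
  # a fresh tape accumulates from zero again
  ad("ad_begin")()
  l2 <- ad("ad_sum")(ad("ad_square")(p))
  ad("ad_backward")(l2)
  ad("ad_end")()
  expect_equal(p$g, g1, tolerance = 1e-12)
})

test_that("softmax rows and matmul support the attention pattern", {
  set.seed(46)
  m <- matrix(stats::rnorm(12), 4, 3)
  sm <- ctsynth:::ad_value(ad("ad_softmax_rows")(ad("ad_const")(m)))
  expect_equal(rowSums(sm), rep(1, 4), tolerance = 1e-12)
  ref <- t(apply(m, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(sm, ref, tolerance = 1e-12)
  a <- matrix(stats::rnorm(6), 2, 3); b <- matrix(stats::rnorm(12), 3, 4)
  expect_equal(ctsynth:::ad_value(ad("ad_matmul")(ad("ad_const")(a),
                                                  ad("ad_const")(b))),
               a %*% b, tolerance = 1e-12)
})
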