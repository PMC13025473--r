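# The composite CycleGAN objective.  Internal .xxx_node functions operate on
# autodiff nodes (used during training); the exported functions accept plain
# arrays and return numeric scalars.  All L1-type norms are means over
# elements, so the lambda weights are independent of image size.

PROB_EPS <- 1e-7

#' Loss weights of the composite generator objective
#'
#' The generator objective is
#' `L_G = L_adv + lambda_cyc L_cyc + lambda_id L_id + lambda_gd L_gd +
#'  L_perceptual + lambda_ssim L_ssim + lambda_vox L_vox`,
#' with the adversarial and perceptual terms carrying implicit weight 1.
#' Defaults are the published operating point: 10 for the cycle, identity,
#' gradient-difference and voxel terms, 0.5 for the SSIM term.
#'
#' @param lambda_cyc,lambda_id,lambda_gd,lambda_vox,lambda_ssim Non-negative
#'   weights.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_cyc = 10, lambda_id = 10, lambda_gd = 10,
                         lambda_vox = 10, lambda_ssim = 0.5) {
  w <- list(lambda_cyc = lambda_cyc, lambda_id = lambda_id,
            lambda_gd = lambda_gd, lambda_vox = lambda_vox,
            lambda_ssim = lambda_ssim)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

.clamp_prob <- function(p) ad_clamp(p, PROB_EPS, 1 - PROB_EPS)

.bce_node <- function(p, target) {
  if (!isTRUE(target %in% c(0, 1))) stop("BCE target must be 0 or 1")
  pc <- .clamp_prob(as_node(p))
  if (target == 1) ad_scale(ad_mean(ad_log(pc)), -1)
  else ad_scale(ad_mean(ad_log(ad_add_const(ad_scale(pc, -1), 1))), -1)
}

.l1_node <- function(a, b) ad_mean(ad_abs(ad_sub(as_node(a), as_node(b))))

.adv_node <- function(dy_on_fake, dx_on_fake)
  ad_add(.bce_node(dy_on_fake, 1), .bce_node(dx_on_fake, 1))

.cycle_node <- function(x, recon_x, y, recon_y)
  ad_add(.l1_node(recon_x, x), .l1_node(recon_y, y))

.identity_node <- function(y, g_xy_of_y, x, g_yx_of_x)
  ad_add(.l1_node(g_xy_of_y, y), .l1_node(g_yx_of_x, x))

.gd_one <- function(f, r) {
  f <- as_node(f); r <- as_node(r)
  ad_scale(ad_add(.l1_node(ad_fdiff_h(f), ad_fdiff_h(r)),
                  .l1_node(ad_fdiff_w(f), ad_fdiff_w(r))), 0.5)
}

.gd_node <- function(fake_y, y, fake_x, x)
  ad_add(.gd_one(fake_y, y), .gd_one(fake_x, x))

.vox_node <- function(fake_y, y, fake_x, x)
  ad_add(.l1_node(fake_y, y), .l1_node(fake_x, x))

.ssim_loss_node <- function(fake_y, y, fake_x, x, data_range = 2) {
  s1 <- ad_clamp(ssim_node(fake_y, y, data_range), PROB_EPS, 1)
  s2 <- ad_clamp(ssim_node(fake_x, x, data_range), PROB_EPS, 1)
  ad_add(ad_scale(ad_log(s1), -1), ad_scale(ad_log(s2), -1))
}

.perceptual_node <- function(fake_y, y, extractor) {
  ff <- extractor_features(extractor, fake_y)
  fr <- extractor_features(extractor, y)
  acc <- NULL
  for (i in seq_along(ff)) {
    term <- .l1_node(ff[[i]], fr[[i]])
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  ad_scale(acc, 1 / length(ff))
}

.check_same_shape <- function(...) {
  ds <- lapply(list(...), function(z) dim(ad_value(as_node(z))))
  if (!all(vapply(ds[-1], identical, logical(1), ds[[1]])))
    stop("image shapes must match")
  invisible(NULL)
}

as_img <- function(x) {
  x <- ad_value(x)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.null(dim(x))) stop("expected an image array")
  x
}

#' Binary cross-entropy with mean reduction
#'
#' `-[t log p + (1 - t) log(1 - p)]` averaged over all grid elements;
#' probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param p Probability grid (values strictly inside (0,1) up to clamping).
#' @param target 0 or 1.
#' @return Scalar loss.
#' @export
bce <- function(p, target) {
  if (any(!is.finite(p))) stop("non-finite probabilities")
  ad_value(.bce_node(p, target))
}

#' Adversarial generator loss
#'
#' `BCE(D_Y(G_XY(x)), 1) + BCE(D_X(G_YX(y)), 1)`: both synthetic images
#' should be classified as real by their discriminators.
#'
#' @param dy_on_fake,dx_on_fake Discriminator probability grids on the
#'   synthetic CECT and synthetic NCCT.
#' @return Scalar loss.
#' @export
adversarial_loss <- function(dy_on_fake, dx_on_fake)
  ad_value(.adv_node(dy_on_fake, dx_on_fake))

#' Cycle-consistency loss
#'
#' `||G_YX(G_XY(x)) - x||_1 + ||G_XY(G_YX(y)) - y||_1` (means over pixels);
#' forces the two generators to act as approximate inverses.
#'
#' @param x,recon_x NCCT slice and its reconstruction through both
#'   generators.
#' @param y,recon_y CECT slice and its reconstruction.
#' @return Scalar loss.
#' @export
cycle_loss <- function(x, recon_x, y, recon_y) {
  .check_same_shape(x, recon_x); .check_same_shape(y, recon_y)
  ad_value(.cycle_node(x, recon_x, y, recon_y))
}

#' Identity loss
#'
#' `||G_XY(y) - y||_1 + ||G_YX(x) - x||_1`: a generator fed an image already
#' in its target domain should leave intensities unchanged.
#'
#' @param y,g_xy_of_y CECT slice and `G_XY(y)`.
#' @param x,g_yx_of_x NCCT slice and `G_YX(x)`.
#' @return Scalar loss.
#' @export
identity_loss <- function(y, g_xy_of_y, x, g_yx_of_x) {
  .check_same_shape(y, g_xy_of_y); .check_same_shape(x, g_yx_of_x)
  ad_value(.identity_node(y, g_xy_of_y, x, g_yx_of_x))
}

#' Gradient-difference loss
#'
#' `||grad(fake_y) - grad(y)||_1 + ||grad(fake_x) - grad(x)||_1` where
#' `grad` is the forward finite difference along rows and columns with
#' replicate edge handling (the per-direction term is the mean over both
#' axes' difference images).  Invariant to adding a constant to both images.
#'
#' @param fake_y,y,fake_x,x Image arrays with sides >= 2.
#' @return Scalar loss.
#' @export
gradient_difference_loss <- function(fake_y, y, fake_x, x) {
  .check_same_shape(fake_y, y); .check_same_shape(fake_x, x)
  ad_value(.gd_node(as_img(fake_y), as_img(y), as_img(fake_x), as_img(x)))
}

#' Voxel-wise L1 loss
#'
#' `||G_XY(x) - y||_1 + ||G_YX(y) - x||_1`: direct supervision from the
#' paired same-session slices.
#'
#' @param fake_y,y,fake_x,x Image arrays.
#' @return Scalar loss.
#' @export
voxel_loss <- function(fake_y, y, fake_x, x) {
  .check_same_shape(fake_y, y); .check_same_shape(fake_x, x)
  ad_value(.vox_node(fake_y, y, fake_x, x))
}

#' Structural-similarity loss
#'
#' `-log SSIM(G_XY(x), y) - log SSIM(G_YX(y), x)`; SSIM values are clamped
#' to `(1e-7, 1]` before the logarithm, so the loss is 0 exactly when both
#' SSIM values are 1 and positive otherwise.  SSIM uses the same 11x11
#' Gaussian-window statistics as [ssim_index()], computed on the
#' normalized [-1, 1] intensity scale (`data_range = 2`).
#'
#' @param fake_y,y,fake_x,x Image arrays.
#' @param data_range Dynamic range of the inputs.
#' @return Scalar loss.
#' @export
ssim_loss <- function(fake_y, y, fake_x, x, data_range = 2) {
  .check_same_shape(fake_y, y); .check_same_shape(fake_x, x)
  ad_value(.ssim_loss_node(as_img(fake_y), as_img(y), as_img(fake_x),
                           as_img(x), data_range))
}

#' Perceptual loss
#'
#' Mean L1 distance between frozen convolutional feature maps of the
#' synthetic and real image, averaged over extractor layers.  The default
#' extractor is a deterministic frozen random convolutional stack (see
#' [feature_extractor()]), so no pretrained weights are required.
#'
#' @param fake_y,y Image arrays.
#' @param extractor A [feature_extractor()]; the package default when `NULL`.
#' @return Scalar loss.
#' @export
perceptual_loss <- function(fake_y, y, extractor = NULL) {
  .check_same_shape(fake_y, y)
  if (is.null(extractor)) extractor <- default_extractor()
  ad_value(.perceptual_node(as_img(fake_y), as_img(y), extractor))
}

#' Discriminator objective
#'
#' `0.5 * [BCE(D_Y(y), 1) + BCE(D_Y(G_XY(x)), 0) + BCE(D_X(x), 1) +
#'  BCE(D_X(G_YX(y)), 0)]`.
#'
#' @param dy_on_real,dy_on_fake,dx_on_real,dx_on_fake Probability grids.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(dy_on_real, dy_on_fake, dx_on_real, dx_on_fake) {
  ad_value(ad_scale(ad_add(
    ad_add(.bce_node(dy_on_real, 1), .bce_node(dy_on_fake, 0)),
    ad_add(.bce_node(dx_on_real, 1), .bce_node(dx_on_fake, 0))), 0.5))
}

#' Total generator objective
#'
#' Combines the seven components into
#' `L_G = adv + lambda_cyc cyc + lambda_id id + lambda_gd gd + perceptual +
#'  lambda_ssim ssim + lambda_vox vox`.
#'
#' @param parts Named list (or individual arguments via `...`) with scalar
#'   components `adv`, `cyc`, `id`, `gd`, `perceptual`, `ssim`, `vox`, all
#'   non-negative.
#' @param weights A [loss_weights()].
#' @return Object of class `loss_breakdown`: the components plus `total`.
#' @export
generator_total <- function(parts, weights = loss_weights()) {
  need <- c("adv", "cyc", "id", "gd", "perceptual", "ssim", "vox")
  if (!all(need %in% names(parts))) stop("missing loss components: ",
                                         paste(setdiff(need, names(parts)), collapse = ", "))
  parts <- lapply(parts[need], ad_value)
  if (any(unlist(parts) < 0)) stop("loss components must be non-negative")
  total <- parts$adv + weights$lambda_cyc * parts$cyc +
    weights$lambda_id * parts$id + weights$lambda_gd * parts$gd +
    parts$perceptual + weights$lambda_ssim * parts$ssim +
    weights$lambda_vox * parts$vox
  structure(c(parts, list(total = total, weights = weights)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("Generator loss breakdown\n")
  for (nm in c("adv", "cyc", "id", "gd", "perceptual", "ssim", "vox"))
    cat(sprintf("  %-10s %.6f\n", nm, x[[nm]]))
  cat(sprintf("  %-10s %.6f\n", "total", x$total))
  invisible(x)
}

# ---- frozen feature extractor ---------------------------------------------

.extractor_cache <- new.env(parent = emptyenv())

#' Frozen convolutional feature extractor for the perceptual loss
#'
#' A small fixed convolutional stack (3x3 stride-2 convolutions with ReLU)
#' whose weights are drawn once from a fixed seed and never trained.  Random
#' frozen features are a deterministic, download-free stand-in for
#' pretrained perceptual features; the extractor consumes single-channel
#' images in [-1, 1] directly.
#'
#' @param channels Channel widths of the successive layers.
#' @param seed Seed for the frozen weights.
#' @return Object of class `feature_extractor`.
#' @export
feature_extractor <- function(channels = c(8L, 16L), seed = 20240901L) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ic <- 1L
  layers <- list()
  for (i in seq_along(channels)) {
    oc <- as.integer(channels[i])
    sd <- sqrt(2 / (9 * ic))
    layers[[i]] <- list(
      w = ad_const(array(stats::rnorm(9L * ic * oc, sd = sd), c(3L, 3L, ic, oc))),
      b = ad_const(rep(0, oc)))
    ic <- oc
  }
  structure(list(layers = layers, seed = seed, channels = channels),
            class = "feature_extractor")
}

default_extractor <- function() {
  if (is.null(.extractor_cache$default))
    .extractor_cache$default <- feature_extractor()
  .extractor_cache$default
}

extractor_features <- function(extractor, x) {
  h <- as_node(x)
  out <- vector("list", length(extractor$layers))
  for (i in seq_along(extractor$layers)) {
    ly <- extractor$layers[[i]]
    h <- ad_relu(ad_conv2d(h, ly$w, ly$b, stride = 2L, pad = 1L))
    out[[i]] <- h
  }
  out
}
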