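#' Training configuration
#'
#' Optimization hyperparameters for the CycleGAN: Adam with beta1 = 0.5,
#' beta2 = 0.999 and learning rate 2e-4 (linear decay to zero after half
#' the epochs), batch size 1, paired same-session sampling by default.
#'
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param beta1,beta2 Adam moment decays.
#' @param seed Seed controlling initialization and data order.
#' @param weights A [loss_weights()].
#' @param generator A [generator_config()].
#' @param discriminator A [discriminator_config()].
#' @param lr_decay Linearly decay the learning rate to zero over the second
#'   half of training.
#' @param paired Feed anatomically matched (x, y) pairs per step; set
#'   `FALSE` for strict unpaired CycleGAN sampling (y drawn at random).
#' @param perceptual_bidirectional Also apply the perceptual term in the
#'   CECT-to-NCCT direction.
#' @param checkpoint_every Write a checkpoint every this many epochs.
#' @param checkpoint_dir Directory for scheduled checkpoints.
#' @param verbose Print per-epoch losses.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, learning_rate = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, seed = 1L, weights = loss_weights(),
                         generator = generator_config(),
                         discriminator = discriminator_config(),
                         lr_decay = TRUE, paired = TRUE,
                         perceptual_bidirectional = FALSE,
                         checkpoint_every = Inf, checkpoint_dir = NULL,
                         verbose = FALSE) {
  stopifnot(epochs >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
                 weights = weights, generator = generator,
                 discriminator = discriminator, lr_decay = lr_decay,
                 paired = paired,
                 perceptual_bidirectional = perceptual_bidirectional,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir, verbose = verbose),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(p) 0 * ad_value(p)),
       v = lapply(params, function(p) 0 * ad_value(p)), t = 0L)

adam_step <- function(params, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- params[[nm]]$g
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]]$v <- params[[nm]]$v -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  state
}

# ---- leakage guard ---------------------------------------------------------

#' Check a patient-level train/test split for leakage
#'
#' @param train_manifest,test_manifest Manifests (or plain character
#'   vectors of patient IDs).
#' @return List with `status` (`"pass"` / `"fail"`), `shared` IDs, and a
#'   `message`.
#' @export
check_split <- function(train_manifest, test_manifest) {
  ids <- function(m) if (is.character(m)) m else manifest_patients(m)
  tr <- ids(train_manifest); te <- ids(test_manifest)
  shared <- intersect(tr, te)
  status <- if (length(shared)) "fail" else "pass"
  msg <- if (length(shared))
    paste0("patient-level leakage: ", paste(shared, collapse = ", "))
  else if (!length(te)) "pass (empty test set)"
  else "pass"
  if (!length(te)) warning("test manifest lists no patients")
  list(status = status, shared = shared, message = msg,
       n_train = length(tr), n_test = length(te))
}

# ---- core fit --------------------------------------------------------------

#' Fit the CycleGAN on paired slices
#'
#' Trains both generators (G_XY: NCCT to CECT, G_YX: CECT to NCCT) and both
#' PatchGAN discriminators by alternating updates: per step the generators
#' are updated on the full composite objective (adversarial,
#' cycle-consistency, identity, gradient-difference, perceptual, SSIM and
#' voxel terms), then the discriminators on their binary cross-entropy
#' objective against detached synthetic images.  Deterministic given
#' `config$seed`.
#'
#' @param pairs List of training pairs; each element has `ncct` and `cect`
#'   HU matrices (and optionally `patient`).  Slices are normalized to
#'   `[-1, 1]` internally.
#' @param config A [train_config()].
#' @param hu_floor,hu_ceiling Normalization bounds.
#' @return Object of class `cyclegan`: the four networks, per-epoch loss
#'   `history`, `config`, and normalization bounds.  Use [predict()] or
#'   [synthesize()] for inference (only G_XY is consulted).
#' @export
fit_cyclegan <- function(pairs, config = train_config(),
                         hu_floor = -1024, hu_ceiling = 1024) {
  stopifnot(inherits(config, "train_config"), length(pairs) >= 1)
  with_seed(config$seed, {
    g_xy <- build_generator(config$generator)
    g_yx <- build_generator(config$generator)
    d_x <- build_discriminator(config$discriminator)
    d_y <- build_discriminator(config$discriminator)
    fit_cyclegan_impl(pairs, config, g_xy, g_yx, d_x, d_y,
                      hu_floor, hu_ceiling)
  })
}

fit_cyclegan_impl <- function(pairs, config, g_xy, g_yx, d_x, d_y,
                              hu_floor, hu_ceiling) {
  w <- config$weights
  extractor <- default_extractor()
  xs <- lapply(pairs, function(p) hu_normalize(p$ncct, hu_floor, hu_ceiling)$pixels)
  ys <- lapply(pairs, function(p) hu_normalize(p$cect, hu_floor, hu_ceiling)$pixels)

  params_g <- c(stats::setNames(g_xy$params, paste0("gxy.", names(g_xy$params))),
                stats::setNames(g_yx$params, paste0("gyx.", names(g_yx$params))))
  params_d <- c(stats::setNames(d_x$params, paste0("dx.", names(d_x$params))),
                stats::setNames(d_y$params, paste0("dy.", names(d_y$params))))
  st_g <- adam_init(params_g)
  st_d <- adam_init(params_d)

  comp_names <- c("adv", "cyc", "id", "gd", "perceptual", "ssim", "vox",
                  "total", "disc")
  history <- matrix(NA_real_, config$epochs, length(comp_names),
                    dimnames = list(NULL, comp_names))
  n <- length(pairs)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate
    if (config$lr_decay && epoch > config$epochs / 2)
      lr <- config$learning_rate *
        (config$epochs - epoch + 1) / (config$epochs - floor(config$epochs / 2))
    ord <- sample.int(n)
    acc <- stats::setNames(numeric(length(comp_names)), comp_names)
    for (step in seq_len(n)) {
      i <- ord[step]
      x <- xs[[i]]
      y <- if (config$paired) ys[[i]] else ys[[sample.int(n, 1L)]]

      ad_begin()
      fake_y <- g_xy$forward(x)
      fake_x <- g_yx$forward(y)
      rec_x <- g_yx$forward(fake_y)
      rec_y <- g_xy$forward(fake_x)
      adv <- .adv_node(d_y$forward(fake_y), d_x$forward(fake_x))
      cyc <- .cycle_node(x, rec_x, y, rec_y)
      idt <- if (w$lambda_id > 0)
        .identity_node(y, g_xy$forward(y), x, g_yx$forward(x))
      else new_node(0)
      gd <- .gd_node(fake_y, y, fake_x, x)
      per <- .perceptual_node(fake_y, y, extractor)
      if (config$perceptual_bidirectional)
        per <- ad_scale(ad_add(per, .perceptual_node(fake_x, x, extractor)), 0.5)
      ssm <- .ssim_loss_node(fake_y, y, fake_x, x)
      vox <- .vox_node(fake_y, y, fake_x, x)
      total <- ad_add(adv, ad_add(ad_scale(cyc, w$lambda_cyc),
               ad_add(ad_scale(idt, w$lambda_id),
               ad_add(ad_scale(gd, w$lambda_gd),
               ad_add(per,
               ad_add(ad_scale(ssm, w$lambda_ssim),
                      ad_scale(vox, w$lambda_vox)))))))
      if (!is.finite(ad_value(total)))
        stop(sprintf(
          "non-finite generator loss at epoch %d step %d (adv=%.3g cyc=%.3g id=%.3g gd=%.3g per=%.3g ssim=%.3g vox=%.3g)",
          epoch, step, ad_value(adv), ad_value(cyc), ad_value(idt),
          ad_value(gd), ad_value(per), ad_value(ssm), ad_value(vox)))
      ad_backward(total)
      ad_end()
      fy_det <- ad_value(fake_y); fx_det <- ad_value(fake_x)
      st_g <- adam_step(params_g, st_g, lr, config$beta1, config$beta2)
      ad_zero_grad(params_g)
      ad_zero_grad(params_d)   # adversarial backprop reaches D; discard

      ad_begin()
      ld <- ad_scale(ad_add(
        ad_add(.bce_node(d_y$forward(y), 1), .bce_node(d_y$forward(fy_det), 0)),
        ad_add(.bce_node(d_x$forward(x), 1), .bce_node(d_x$forward(fx_det), 0))), 0.5)
      if (!is.finite(ad_value(ld)))
        stop(sprintf("non-finite discriminator loss at epoch %d step %d", epoch, step))
      ad_backward(ld)
      ad_end()
      st_d <- adam_step(params_d, st_d, lr, config$beta1, config$beta2)
      ad_zero_grad(params_d)
      ad_zero_grad(params_g)   # symmetric isolation

      acc <- acc + c(ad_value(adv), ad_value(cyc), ad_value(idt),
                     ad_value(gd), ad_value(per), ad_value(ssm),
                     ad_value(vox), ad_value(total), ad_value(ld))
    }
    history[epoch, ] <- acc / n
    if (config$verbose)
      message(sprintf("epoch %3d  G %.4f  D %.4f  cyc %.4f  vox %.4f",
                      epoch, history[epoch, "total"], history[epoch, "disc"],
                      history[epoch, "cyc"], history[epoch, "vox"]))
    if (is.finite(config$checkpoint_every) &&
        epoch %% config$checkpoint_every == 0 &&
        !is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(make_fit(g_xy, g_yx, d_x, d_y, history[seq_len(epoch), , drop = FALSE],
                               config, hu_floor, hu_ceiling),
                      file.path(config$checkpoint_dir,
                                sprintf("epoch_%04d.ckpt", epoch)))
    }
  }
  make_fit(g_xy, g_yx, d_x, d_y, history, config, hu_floor, hu_ceiling)
}

make_fit <- function(g_xy, g_yx, d_x, d_y, history, config, hu_floor, hu_ceiling) {
  structure(list(g_xy = g_xy, g_yx = g_yx, d_x = d_x, d_y = d_y,
                 history = as.data.frame(history), config = config,
                 hu_floor = hu_floor, hu_ceiling = hu_ceiling),
            class = "cyclegan")
}

#' Fit the CycleGAN from a dataset manifest
#'
#' Loads the paired slices listed in `train_manifest`, refuses to start if
#' any patient also appears in `test_manifest` (patient-level leakage
#' guard), and fits.
#'
#' @param train_manifest A `phantom_manifest` (see [read_manifest()]).
#' @param config A [train_config()].
#' @param test_manifest Optional manifest of held-out patients.
#' @param ... Passed to [fit_cyclegan()].
#' @return A `cyclegan` fit.
#' @export
train_cyclegan <- function(train_manifest, config = train_config(),
                           test_manifest = NULL, ...) {
  if (!is.null(test_manifest)) {
    chk <- check_split(train_manifest, test_manifest)
    if (chk$status != "pass") stop("refusing to train: ", chk$message)
  }
  fit_cyclegan(load_pairs(train_manifest), config, ...)
}

#' Synthesize contrast-enhanced CT from a non-contrast volume
#'
#' Inference path: every slice is normalized to `[-1, 1]`, passed through
#' the NCCT-to-CECT generator G_XY only (the reverse generator and both
#' discriminators exist solely to optimize G_XY during training), and
#' denormalized back to HU.  Output geometry and patient ID mirror the
#' input; HU values are bounded by the normalization range (tanh head).
#'
#' @param ncct A [ct_volume()] (any `series_kind`; typically NCCT).
#' @param fit A `cyclegan` fit or a checkpoint path.
#' @return A [ct_volume()] with `series_kind = "sCECT"`.
#' @export
synthesize <- function(ncct, fit) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  stopifnot(inherits(fit, "cyclegan"), inherits(ncct, "ct_volume"))
  slices <- lapply(ncct$slices, function(sl) {
    ns <- hu_normalize(sl, fit$hu_floor, fit$hu_ceiling)
    out <- ad_value(fit$g_xy$forward(ns$pixels))
    hu_denormalize(out, fit$hu_floor, fit$hu_ceiling)
  })
  ct_volume(ncct$patient_id, slices, ncct$slice_positions,
            ncct$pixel_spacing, series_kind = "sCECT")
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.cyclegan <- function(x, ...) {
  cfg <- x$config
  cat("Attention CycleGAN for NCCT -> sCECT synthesis\n")
  cat(sprintf("  generator: base %d filters, %d levels, %d residual blocks (%s params each)\n",
              cfg$generator$base_filters, cfg$generator$n_levels,
              cfg$generator$n_res_blocks, format(n_params(x$g_xy), big.mark = ",")))
  cat(sprintf("  discriminator widths: %s\n",
              paste(cfg$discriminator$channel_widths, collapse = "-")))
  cat(sprintf("  trained %d epochs (seed %d); final G loss %.4f, D loss %.4f\n",
              nrow(x$history), cfg$seed,
              x$history$total[nrow(x$history)], x$history$disc[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.cyclegan <- function(object, ...) {
  cat("Loss history (per-epoch means):\n")
  print(round(object$history, 4))
  invisible(object$history)
}

#' @export
plot.cyclegan <- function(x, components = c("total", "disc", "cyc", "vox"), ...) {
  h <- x$history[, components, drop = FALSE]
  graphics::matplot(seq_len(nrow(h)), h, type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = components, lty = 1,
                   col = seq_along(components), bty = "n")
  invisible(x)
}

#' @export
predict.cyclegan <- function(object, newdata, ...) synthesize(newdata, object)

#' @export
coef.cyclegan <- function(object, network = c("g_xy", "g_yx", "d_x", "d_y"), ...) {
  network <- match.arg(network)
  get_params(object[[network]])
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint holds the parameter arrays of all four networks together
#' with the full training configuration; loading rebuilds the networks and
#' validates that any supplied configuration matches the stored one.
#'
#' @param fit A `cyclegan` fit.
#' @param path Checkpoint file.
#' @param config Optional [train_config()] that must equal the stored one.
#' @return `load_checkpoint` returns the restored `cyclegan` fit.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "cyclegan"))
  obj <- list(params = list(g_xy = get_params(fit$g_xy),
                            g_yx = get_params(fit$g_yx),
                            d_x = get_params(fit$d_x),
                            d_y = get_params(fit$d_y)),
              config = fit$config, history = fit$history,
              hu_floor = fit$hu_floor, hu_ceiling = fit$hu_ceiling)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, config = NULL) {
  obj <- readRDS(path)
  if (!is.null(config) && !identical(unclass(config), unclass(obj$config)))
    stop("checkpoint was trained with a different configuration")
  g_xy <- build_generator(obj$config$generator)
  g_yx <- build_generator(obj$config$generator)
  d_x <- build_discriminator(obj$config$discriminator)
  d_y <- build_discriminator(obj$config$discriminator)
  set_params(g_xy, obj$params$g_xy); set_params(g_yx, obj$params$g_yx)
  set_params(d_x, obj$params$d_x); set_params(d_y, obj$params$d_y)
  make_fit(g_xy, g_yx, d_x, d_y, as.matrix(obj$history), obj$config,
           obj$hu_floor, obj$hu_ceiling)
}
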