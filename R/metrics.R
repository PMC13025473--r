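#' Image-similarity and ROI conspicuity metrics
#'
#' The quantitative evaluation suite: mean absolute error (MAE), root mean
#' square error (RMSE), peak signal-to-noise ratio (PSNR), structural
#' similarity (SSIM), Pearson correlation (PCC), and ROI-based SNR/CNR.
#' Global metrics are computed on the Hounsfield-unit scale by default so
#' MAE/RMSE are in HU.
#'
#' @name ct_metrics
NULL

check_shapes <- function(a, b) {
  if (!identical(dim(a), dim(b)) || is.null(dim(a)))
    stop("image shapes must match")
  invisible(NULL)
}

#' @describeIn ct_metrics Mean absolute error, `mean(|a - b|)`.
#' @param a,b Numeric image arrays of identical shape.
#' @export
mae <- function(a, b) { check_shapes(a, b); mean(abs(a - b)) }

#' @describeIn ct_metrics Root mean square error, `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) { check_shapes(a, b); sqrt(mean((a - b)^2)) }

#' @describeIn ct_metrics Peak signal-to-noise ratio in dB,
#'   `10 log10(data_range^2 / MSE)`; `Inf` when the images are identical.
#' @param data_range Dynamic range of the images (e.g. `hu_ceiling -
#'   hu_floor` on the HU scale, 2 on the normalized scale).
#' @export
psnr <- function(a, b, data_range) {
  check_shapes(a, b)
  if (!is.numeric(data_range) || data_range <= 0) stop("data_range must be positive")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' @describeIn ct_metrics Pearson correlation over flattened pixels.
#' @export
pcc <- function(a, b) {
  check_shapes(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Pearson correlation undefined: an image has zero variance")
  stats::cor(as.vector(a), as.vector(b))
}

# 1-D factor of the 11x11 Gaussian window, sigma 1.5 (separable)
.ssim_env <- new.env(parent = emptyenv())
ssim_window <- function(size = 11L, sigma = 1.5) {
  key <- paste0(size, "_", sigma)
  if (is.null(.ssim_env[[key]])) {
    r <- (seq_len(size) - (size + 1) / 2)
    g <- exp(-r^2 / (2 * sigma^2))
    .ssim_env[[key]] <- g / sum(g)
  }
  .ssim_env[[key]]
}

ssim_node <- function(a, b, data_range, size = 11L, sigma = 1.5,
                      K1 = 0.01, K2 = 0.03) {
  a <- as_node(a); b <- as_node(b)
  d <- dim(ad_value(a))
  if (min(d[1:2]) < size)
    stop(sprintf("images (%dx%d) smaller than the %dx%d SSIM window",
                 d[1L], d[2L], size, size))
  w <- ssim_window(size, sigma)
  gconv <- function(x) ad_gauss_valid(x, w)
  c1 <- (K1 * data_range)^2
  c2 <- (K2 * data_range)^2
  mx <- gconv(a); my <- gconv(b)
  mx2 <- ad_square(mx); my2 <- ad_square(my)
  mxy <- ad_mul(mx, my)
  sxx <- ad_sub(gconv(ad_square(a)), mx2)
  syy <- ad_sub(gconv(ad_square(b)), my2)
  sxy <- ad_sub(gconv(ad_mul(a, b)), mxy)
  num <- ad_mul(ad_add_const(ad_scale(mxy, 2), c1),
                ad_add_const(ad_scale(sxy, 2), c2))
  den <- ad_mul(ad_add_const(ad_add(mx2, my2), c1),
                ad_add_const(ad_add(sxx, syy), c2))
  ad_mean(ad_div(num, den))
}

#' @describeIn ct_metrics Structural similarity index: 11x11 Gaussian
#'   window (sigma 1.5), K1 = 0.01, K2 = 0.03, averaged over the valid
#'   SSIM map.
#' @export
ssim_index <- function(a, b, data_range) {
  check_shapes(a, b)
  if (!is.numeric(data_range) || data_range <= 0) stop("data_range must be positive")
  if (length(dim(a)) == 2L) { dim(a) <- c(dim(a), 1L); dim(b) <- dim(a) }
  ad_value(ssim_node(a, b, data_range))
}

#' Region-of-interest specification
#'
#' A circular ROI on one slice, as used for SNR/CNR measurements in the
#' ascending aorta (AA), main pulmonary artery (MPA), lymph nodes (LN), or
#' a homogeneous noise-reference region.
#'
#' @param label One of `"AA"`, `"MPA"`, `"LN"`, `"vessel"`, `"node"`,
#'   `"soft_tissue"`, `"noise"`, `"custom"`.
#' @param center `(row, col)` pixel coordinates of the circle center.
#' @param radius Radius in pixels (>= 1).
#' @param slice_index Slice the ROI lives on (1-based).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(label = c("custom", "AA", "MPA", "LN", "vessel", "node",
                               "soft_tissue", "noise"),
                     center, radius, slice_index = 1L) {
  label <- match.arg(label)
  stopifnot(length(center) == 2L, radius >= 1)
  structure(list(label = label, center = as.numeric(center),
                 radius = as.numeric(radius),
                 slice_index = as.integer(slice_index)),
            class = "roi_spec")
}

roi_mask <- function(roi, dims) {
  if (roi$center[1L] - roi$radius < 1 || roi$center[1L] + roi$radius > dims[1L] ||
      roi$center[2L] - roi$radius < 1 || roi$center[2L] + roi$radius > dims[2L])
    stop("ROI circle extends outside the image")
  rr <- outer(seq_len(dims[1L]) - roi$center[1L],
              seq_len(dims[2L]) - roi$center[2L],
              function(i, j) i^2 + j^2)
  rr <= roi$radius^2
}

roi_pixels <- function(image, roi) {
  if (is.array(image) && length(dim(image)) == 3L) image <- image[, , 1L]
  image[roi_mask(roi, dim(image))]
}

#' Signal-to-noise ratio of an ROI
#'
#' `mean(signal ROI) / sd(noise ROI)` — the standard radiological
#' convention with noise taken as the standard deviation inside a dedicated
#' homogeneous reference region.
#'
#' @param image 2D image (HU).
#' @param roi Signal [roi_spec()].
#' @param noise_roi Homogeneous noise-reference [roi_spec()].
#' @return Scalar SNR.
#' @export
snr <- function(image, roi, noise_roi) {
  ns <- stats::sd(roi_pixels(image, noise_roi))
  if (ns == 0) stop("noise ROI has zero standard deviation")
  mean(roi_pixels(image, roi)) / ns
}

#' Contrast-to-noise ratio between two ROIs
#'
#' `(mean(target ROI) - mean(background ROI)) / sd(noise ROI)`.
#'
#' @param image 2D image (HU).
#' @param target_roi,background_roi,noise_roi [roi_spec()] objects.
#' @return Scalar CNR.
#' @export
cnr <- function(image, target_roi, background_roi, noise_roi) {
  ns <- stats::sd(roi_pixels(image, noise_roi))
  if (ns == 0) stop("noise ROI has zero standard deviation")
  (mean(roi_pixels(image, target_roi)) -
     mean(roi_pixels(image, background_roi))) / ns
}

#' Evaluate a candidate volume against a reference volume
#'
#' Computes MAE, RMSE, PSNR, SSIM and PCC per slice (averaged across
#' slices, unweighted) on the HU scale, plus SNR/CNR for each supplied ROI
#' set measured on the candidate volume.
#'
#' @param candidate,reference [ct_volume()] objects with identical
#'   geometry (typically sCECT or NCCT against the ground-truth CECT).
#' @param roi_sets Optional list; each element is a list with `label`,
#'   `target`, `background`, and `noise` [roi_spec()] entries.  A ROI whose
#'   statistic is not measurable (e.g. zero noise variance) yields `NA`
#'   with a warning rather than an error.
#' @param data_range Dynamic range for PSNR/SSIM; default 2048 HU
#'   (`hu_ceiling - hu_floor` of the default normalization).
#' @return Object of class `metric_report`.
#' @export
evaluate_pair <- function(candidate, reference, roi_sets = NULL,
                          data_range = 2048) {
  stopifnot(inherits(candidate, "ct_volume"), inherits(reference, "ct_volume"))
  if (length(candidate$slices) != length(reference$slices))
    stop("volumes have different slice counts")
  per <- lapply(seq_along(candidate$slices), function(i) {
    a <- candidate$slices[[i]]; b <- reference$slices[[i]]
    check_shapes(a, b)
    c(mae = mae(a, b), rmse = rmse(a, b), psnr = psnr(a, b, data_range),
      ssim = ssim_index(a, b, data_range), pcc = pcc(a, b))
  })
  per <- do.call(rbind, per)
  rois <- list()
  for (rs in roi_sets %||% list()) {
    sl <- candidate$slices[[rs$target$slice_index]]
    rois[[rs$label]] <- tryCatch(
      list(snr = snr(sl, rs$target, rs$noise),
           cnr = cnr(sl, rs$target, rs$background, rs$noise)),
      error = function(e) {
        warning("ROI '", rs$label, "' not measurable: ", conditionMessage(e))
        list(snr = NA_real_, cnr = NA_real_)
      })
  }
  structure(list(mae = mean(per[, "mae"]), rmse = mean(per[, "rmse"]),
                 psnr = mean(per[, "psnr"]), ssim = mean(per[, "ssim"]),
                 pcc = mean(per[, "pcc"]), rois = rois,
                 per_slice = per, data_range = data_range,
                 n_slices = nrow(per),
                 candidate_kind = candidate$series_kind,
                 patient_id = candidate$patient_id),
            class = "metric_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report: %s vs reference (%d slices, patient %s)\n",
              x$candidate_kind, x$n_slices, x$patient_id))
  cat(sprintf("  MAE %.3f  RMSE %.3f  PSNR %.3f dB  SSIM %.4f  PCC %.4f\n",
              x$mae, x$rmse, x$psnr, x$ssim, x$pcc))
  for (nm in names(x$rois))
    cat(sprintf("  ROI %-12s SNR %.3f  CNR %.3f\n", nm,
                x$rois[[nm]]$snr, x$rois[[nm]]$cnr))
  invisible(x)
}

#' Write / read a metric report
#'
#' JSON round-trip of a [evaluate_pair()] report (per-slice table included).
#'
#' @param report A `metric_report`.
#' @param path File path.
#' @return `read_metric_report` returns the `metric_report`.
#' @export
write_metric_report <- function(report, path) {
  obj <- unclass(report)
  obj$per_slice <- as.data.frame(obj$per_slice)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_slice <- as.matrix(obj$per_slice)
  if (!is.null(obj$rois) && length(obj$rois) == 0) obj$rois <- list()
  structure(obj, class = "metric_report")
}
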