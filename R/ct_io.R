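#' CT volume container
#'
#' A patient-tagged stack of axial slices holding Hounsfield-unit values.
#'
#' @param patient_id Opaque patient identifier.
#' @param slices List of numeric H x W matrices (HU); all slices must share
#'   one shape and contain only finite values.
#' @param slice_positions Axial table coordinate of each slice in mm;
#'   strictly monotone.
#' @param pixel_spacing `(row mm, col mm)`.
#' @param series_kind `"NCCT"`, `"CECT"` or `"sCECT"`.
#' @return Object of class `ct_volume`.
#' @export
ct_volume <- function(patient_id, slices, slice_positions,
                      pixel_spacing = c(1, 1),
                      series_kind = c("NCCT", "CECT", "sCECT")) {
  series_kind <- match.arg(series_kind)
  if (!length(slices)) stop("a CT volume needs at least one slice")
  d1 <- dim(slices[[1L]])
  for (s in slices) {
    if (!identical(dim(s), d1)) stop("all slices must share the same height/width")
    if (any(!is.finite(s))) stop("HU values must be finite")
  }
  if (length(slice_positions) != length(slices))
    stop("one position per slice required")
  dp <- diff(slice_positions)
  if (length(dp) && !(all(dp > 0) || all(dp < 0)))
    stop("slice positions must be strictly monotone")
  structure(list(patient_id = as.character(patient_id), slices = slices,
                 slice_positions = as.numeric(slice_positions),
                 pixel_spacing = as.numeric(pixel_spacing),
                 series_kind = series_kind),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices[[1L]])
  cat(sprintf("CT volume [%s] patient %s: %d slices of %dx%d, spacing %.2fx%.2f mm\n",
              x$series_kind, x$patient_id, length(x$slices), d[1L], d[2L],
              x$pixel_spacing[1L], x$pixel_spacing[2L]))
  invisible(x)
}

#' Display window setting
#'
#' @param width Window width in HU (> 0); default 450 (mediastinal).
#' @param level Window level in HU; default 60.
#' @return Object of class `window_setting`.
#' @export
window_setting <- function(width = 450, level = 60) {
  if (width <= 0) stop("window width must be positive")
  structure(list(width = width, level = level), class = "window_setting")
}

#' Normalize a HU slice to [-1, 1]
#'
#' Values are clipped to `[hu_floor, hu_ceiling]` and mapped affinely so
#' `hu_floor -> -1` and `hu_ceiling -> +1`.  The mapping parameters are
#' recorded so the transform is exactly invertible via [hu_denormalize()].
#'
#' @param slice Numeric HU matrix (finite values only).
#' @param hu_floor,hu_ceiling Clipping bounds; `hu_ceiling > hu_floor`.
#'   The symmetric default (-1024, 1024) keeps soft tissue near 0 and
#'   covers air through dense bone and iodinated contrast.
#' @param source_patient,source_position Provenance, stored verbatim.
#' @return Object of class `normalized_slice` with fields `pixels`
#'   (`(H, W, 1)` array in `[-1, 1]`), `hu_floor`, `hu_ceiling`,
#'   `source_patient`, `source_position`.
#' @export
hu_normalize <- function(slice, hu_floor = -1024, hu_ceiling = 1024,
                         source_patient = NA_character_,
                         source_position = NA_real_) {
  if (hu_ceiling <= hu_floor) stop("hu_ceiling must exceed hu_floor")
  if (any(!is.finite(slice))) stop("input pixels must be finite")
  v <- pmin(pmax(slice, hu_floor), hu_ceiling)
  px <- 2 * (v - hu_floor) / (hu_ceiling - hu_floor) - 1
  px <- array(px, c(dim(slice), 1L))
  structure(list(pixels = px, hu_floor = hu_floor, hu_ceiling = hu_ceiling,
                 source_patient = source_patient,
                 source_position = source_position),
            class = "normalized_slice")
}

#' Invert the [-1, 1] normalization back to HU
#'
#' Exact affine inverse of [hu_normalize()] on in-range values.
#'
#' @param x A `normalized_slice`, or a numeric array in `[-1, 1]` combined
#'   with explicit `hu_floor`/`hu_ceiling`.
#' @param hu_floor,hu_ceiling Bounds, taken from `x` when it is a
#'   `normalized_slice`.
#' @return HU matrix.
#' @export
hu_denormalize <- function(x, hu_floor = NULL, hu_ceiling = NULL) {
  if (inherits(x, "normalized_slice")) {
    hu_floor <- x$hu_floor; hu_ceiling <- x$hu_ceiling; x <- x$pixels
  }
  if (is.null(hu_floor) || is.null(hu_ceiling))
    stop("hu_floor and hu_ceiling required")
  v <- (x + 1) / 2 * (hu_ceiling - hu_floor) + hu_floor
  if (length(dim(v)) == 3L && dim(v)[3L] == 1L) v <- v[, , 1L]
  v
}

#' Apply a display window
#'
#' Linear window: HU at or below `level - width/2` map to 0, at or above
#' `level + width/2` map to 1, linear in between.  Monotone non-decreasing
#' in HU.
#'
#' @param slice HU matrix.
#' @param w A [window_setting()]; mediastinal (450/60) by default.
#' @return Display matrix in `[0, 1]`.
#' @export
apply_window <- function(slice, w = window_setting()) {
  lo <- w$level - w$width / 2
  pmin(pmax((slice - lo) / w$width, 0), 1)
}

#' Pair NCCT and CECT slices at matching anatomical positions
#'
#' Greedy nearest-position matching within one patient: candidate pairs
#' are considered in order of increasing position difference, each slice is
#' used at most once, and pairs farther apart than `tolerance` are dropped.
#' No spatial registration is applied.
#'
#' @param ncct,cect [ct_volume()] objects sharing a `patient_id` (enforced
#'   to prevent cross-patient leakage).
#' @param tolerance Maximum position difference in mm (default 2.5, the
#'   thickest reconstructed slice).
#' @return List of pairs; each element has `ncct`, `cect` (HU matrices),
#'   `ncct_position`, `cect_position`.
#' @export
pair_slices <- function(ncct, cect, tolerance = 2.5) {
  stopifnot(inherits(ncct, "ct_volume"), inherits(cect, "ct_volume"))
  if (!identical(ncct$patient_id, cect$patient_id))
    stop("refusing to pair slices across patients (", ncct$patient_id,
         " vs ", cect$patient_id, ")")
  np <- ncct$slice_positions; cp <- cect$slice_positions
  cand <- expand.grid(i = seq_along(np), j = seq_along(cp))
  cand$d <- abs(np[cand$i] - cp[cand$j])
  cand <- cand[cand$d <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(length(np)); used_j <- logical(length(cp))
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    out[[length(out) + 1L]] <- list(ncct = ncct$slices[[i]],
                                    cect = cect$slices[[j]],
                                    ncct_position = np[i],
                                    cect_position = cp[j])
  }
  ord <- order(vapply(out, `[[`, numeric(1), "ncct_position"))
  out[ord]
}

# ---- series reading and writing -------------------------------------------

#' Read a CT series from disk
#'
#' Two on-disk layouts are supported: a directory of single-slice DICOM
#' files (uncompressed 16-bit, explicit VR little endian), or the package's
#' portable fallback — PNG slices plus a `series.json` sidecar carrying
#' `rescale_slope`, `rescale_intercept`, `positions_mm` and
#' `pixel_spacing_mm`.  PNG slices are either true 16-bit grayscale images
#' or the package's own lossless two-channel packing (high byte, low byte)
#' of the 16-bit stored value.  Stored values are converted to HU as
#' `HU = stored * slope + intercept` and slices are sorted by ascending
#' position.
#'
#' @param path Directory containing one series.
#' @param format `"auto"` (by file extension), `"dicom"` or `"png"`.
#' @param series_kind Label for the returned volume.
#' @return A [ct_volume()].
#' @export
read_ct_series <- function(path, format = c("auto", "dicom", "png"),
                           series_kind = c("NCCT", "CECT", "sCECT")) {
  format <- match.arg(format)
  series_kind <- match.arg(series_kind)
  if (!dir.exists(path)) stop("no such directory: ", path)
  if (format == "auto") {
    format <- if (length(list.files(path, pattern = "\\.dcm$"))) "dicom" else "png"
  }
  if (format == "dicom") read_dicom_series(path, series_kind)
  else read_png_series(path, series_kind)
}

read_png_series <- function(path, series_kind) {
  sidecar <- file.path(path, "series.json")
  if (!file.exists(sidecar))
    stop("fallback series requires a series.json sidecar with rescale slope/intercept")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("rescale_slope", "rescale_intercept", "positions_mm"))
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) != length(meta$positions_mm))
    stop("sidecar lists ", length(meta$positions_mm), " positions but ",
         length(files), " png slices found")
  slices <- lapply(files, function(f) {
    img <- png::readPNG(f)
    stored <- if (length(dim(img)) == 3L && dim(img)[3L] == 2L) {
      # two 8-bit channels packing one 16-bit stored value (high, low byte)
      round(img[, , 1L] * 255) * 256 + round(img[, , 2L] * 255)
    } else {
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      round(img * 65535)
    }
    stored * meta$rescale_slope + meta$rescale_intercept
  })
  ord <- order(meta$positions_mm)
  ct_volume(patient_id = meta$patient_id %||% basename(dirname(path)),
            slices = slices[ord],
            slice_positions = meta$positions_mm[ord],
            pixel_spacing = meta$pixel_spacing_mm %||% c(1, 1),
            series_kind = series_kind)
}

#' Write a CT series to disk
#'
#' Inverse of [read_ct_series()] for both supported layouts.  In the PNG
#' layout HU values are stored as 16-bit integers with
#' `stored = (HU - intercept) / slope` (default slope 1, intercept -2048,
#' chosen so noisy air stays in range); DICOM output carries the same
#' rescale tags.
#'
#' @param vol A [ct_volume()].
#' @param path Output directory (created).
#' @param format `"png"` or `"dicom"`.
#' @param rescale_slope,rescale_intercept Stored-value transform.
#' @return `path`, invisibly.
#' @export
write_ct_series <- function(vol, path, format = c("png", "dicom"),
                            rescale_slope = 1, rescale_intercept = -2048) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "ct_volume"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (format == "png") {
    for (i in seq_along(vol$slices)) {
      stored <- round((vol$slices[[i]] - rescale_intercept) / rescale_slope)
      if (any(stored < 0 | stored > 65535))
        stop("HU values out of range for 16-bit storage with this rescale")
      # writePNG emits 8 bits per channel, so the 16-bit stored value is
      # split into a high- and a low-byte channel (gray + alpha, lossless)
      packed <- array(0, c(dim(stored), 2L))
      packed[, , 1L] <- (stored %/% 256) / 255
      packed[, , 2L] <- (stored %% 256) / 255
      png::writePNG(packed, file.path(path, sprintf("slice_%04d.png", i)))
    }
    jsonlite::write_json(
      list(patient_id = vol$patient_id, series_kind = vol$series_kind,
           rescale_slope = rescale_slope,
           rescale_intercept = rescale_intercept,
           positions_mm = vol$slice_positions,
           pixel_spacing_mm = vol$pixel_spacing),
      file.path(path, "series.json"), auto_unbox = TRUE, digits = NA)
  } else {
    uid <- dicom_uid(vol$patient_id, vol$series_kind)
    for (i in seq_along(vol$slices))
      write_dicom_slice(vol$slices[[i]], file.path(path, sprintf("slice_%04d.dcm", i)),
                        patient_id = vol$patient_id, series_uid = uid,
                        position = vol$slice_positions[i],
                        pixel_spacing = vol$pixel_spacing,
                        slope = rescale_slope, intercept = rescale_intercept)
  }
  invisible(path)
}

#' Windowed PNG preview of a volume
#'
#' Writes one 8-bit PNG per slice after applying a display window.
#'
#' @param vol A [ct_volume()].
#' @param path Output directory.
#' @param w A [window_setting()].
#' @return `path`, invisibly.
#' @export
write_preview <- function(vol, path, w = window_setting()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(vol$slices))
    png::writePNG(apply_window(vol$slices[[i]], w),
                  file.path(path, sprintf("preview_%04d.png", i)))
  invisible(path)
}
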