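# Minimal DICOM codec: single-frame 16-bit grayscale CT slices, explicit VR
# little endian, uncompressed.  Covers exactly the tags the pipeline needs
# (series UID, rescale slope/intercept, slice location, pixel geometry);
# unknown elements are skipped on read.  Not a general DICOM dialect parser.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dicom_uid <- function(patient_id, series_kind) {
  # deterministic private-root UID derived from patient and series labels
  h <- sum(utf8ToInt(paste0(patient_id, "/", series_kind)) *
             seq_along(utf8ToInt(paste0(patient_id, "/", series_kind)))) %% 1e9
  sprintf("1.2.826.0.1.3680043.9.%d.%d", nchar(patient_id), h)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

even_pad <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L) c(r, pad) else r
}

dcm_element <- function(group, element, vr, value_raw) {
  long_vr <- vr %in% c("OW", "OB", "UN", "UT", "SQ")
  c(u16(group), u16(element), charToRaw(vr),
    if (long_vr) c(as.raw(c(0, 0)), u32(length(value_raw))) else u16(length(value_raw)),
    value_raw)
}

dcm_str <- function(group, element, vr, s, pad = as.raw(0x20))
  dcm_element(group, element, vr, even_pad(charToRaw(s), pad))

dcm_us <- function(group, element, x) dcm_element(group, element, "US", u16(x))

write_dicom_slice <- function(hu, path, patient_id, series_uid, position,
                              pixel_spacing = c(1, 1), slope = 1,
                              intercept = -2048) {
  stored <- round((hu - intercept) / slope)
  if (any(stored < 0 | stored > 32767))
    stop("HU values out of range for 16-bit storage with this rescale")
  d <- dim(hu)
  px <- writeBin(as.integer(as.vector(t(stored))), raw(), size = 2L,
                 endian = "little")
  ds <- function(x) format(x, scientific = FALSE, trim = TRUE)
  body <- c(
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0010, 0x0020, "LO", patient_id),
    dcm_str(0x0020, 0x000E, "UI", series_uid, pad = as.raw(0x00)),
    dcm_str(0x0020, 0x1041, "DS", ds(position)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_us(0x0028, 0x0010, d[1L]),
    dcm_us(0x0028, 0x0011, d[2L]),
    dcm_str(0x0028, 0x0030, "DS", paste0(ds(pixel_spacing[1L]), "\\", ds(pixel_spacing[2L]))),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_str(0x0028, 0x1052, "DS", ds(intercept)),
    dcm_str(0x0028, 0x1053, "DS", ds(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", px))
  ts <- dcm_str(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE, pad = as.raw(0x00))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32(length(ts))), ts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

read_dicom_file <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 132L || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  rd_u16 <- function(at) readBin(r[at:(at + 1L)], "integer", size = 2L,
                                 signed = FALSE, endian = "little")
  rd_u32 <- function(at) readBin(r[at:(at + 3L)], "integer", size = 4L,
                                 endian = "little")
  out <- list()
  while (pos + 7L <= length(r)) {
    group <- rd_u16(pos); element <- rd_u16(pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OW", "OB", "UN", "UT", "SQ")) {
      len <- rd_u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- rd_u16(pos + 6L); vstart <- pos + 8L
    }
    val <- if (len > 0L) r[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04x%04x", group, element)
    out[[key]] <- list(vr = vr, val = val)
    pos <- vstart + len
  }
  get_str <- function(key) {
    el <- out[[key]]
    if (is.null(el)) return(NULL)
    sub("\\s+$", "", rawToChar(el$val[el$val != as.raw(0L)]))
  }
  get_us <- function(key) {
    el <- out[[key]]
    if (is.null(el)) return(NULL)
    readBin(el$val, "integer", size = 2L, signed = FALSE, endian = "little")
  }
  slope_s <- get_str("00281053"); intercept_s <- get_str("00281052")
  if (is.null(slope_s) || is.null(intercept_s))
    stop("DICOM file lacks RescaleSlope/RescaleIntercept tags; cannot convert to HU: ",
         path)
  rows <- get_us("00280010"); cols <- get_us("00280011")
  pixel <- out[["7fe00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pixel))
    stop("DICOM file lacks pixel data or dimensions: ", path)
  stored <- readBin(pixel$val, "integer", n = rows * cols, size = 2L,
                    signed = FALSE, endian = "little")
  hu <- matrix(stored, nrow = rows, byrow = TRUE) * as.numeric(slope_s) +
    as.numeric(intercept_s)
  spacing <- get_str("00280030")
  spacing <- if (is.null(spacing)) c(1, 1) else as.numeric(strsplit(spacing, "\\\\")[[1L]])
  list(hu = hu,
       patient_id = get_str("00100020") %||% "UNKNOWN",
       series_uid = get_str("0020000e") %||% "",
       position = as.numeric(get_str("00201041") %||% NA_real_),
       pixel_spacing = spacing)
}

read_dicom_series <- function(path, series_kind) {
  files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no DICOM files in ", path)
  parsed <- lapply(files, read_dicom_file)
  uids <- unique(vapply(parsed, `[[`, character(1), "series_uid"))
  if (length(uids) > 1L)
    stop("directory mixes ", length(uids), " SeriesInstanceUIDs; one series per directory required")
  shapes <- unique(lapply(parsed, function(p) dim(p$hu)))
  if (length(shapes) > 1L) stop("slices have non-uniform shapes")
  posn <- vapply(parsed, `[[`, numeric(1), "position")
  ord <- order(posn)
  ct_volume(patient_id = parsed[[1L]]$patient_id,
            slices = lapply(parsed[ord], `[[`, "hu"),
            slice_positions = posn[ord],
            pixel_spacing = parsed[[1L]]$pixel_spacing,
            series_kind = series_kind)
}
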