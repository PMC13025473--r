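# Paired synthetic NCCT/CECT phantom slices.  Each slice is a soft-tissue
# body disc over air background carrying elliptical vessel and lymph-node
# structures; the CECT applies a known per-compartment HU shift (contrast
# enhancement acts on vessels and nodes), then independent Gaussian noise
# per image and an optional integer-pixel translation of the CECT emulate
# acquisition noise and residual same-session misalignment.

#' Phantom generation parameters
#'
#' Defaults are plausible thoracic values: air background -1000 HU, soft
#' tissue 40 HU, blood-pool vessels 45 HU and nodes 35 HU before contrast,
#' +250 HU vessel and +60 HU node enhancement, 10 HU noise, and up to 1 px
#' translation between the pre and post image.
#'
#' @param image_size Side of the square slice in pixels (>= 32).
#' @param n_vessels,n_nodes Structure counts (>= 0).
#' @param hu_background,hu_soft_tissue,hu_vessel_pre,hu_node_pre
#'   Compartment HU levels on the NCCT.
#' @param enhancement_vessel,enhancement_node Contrast enhancement in HU
#'   added on the CECT.
#' @param noise_sd Additive Gaussian noise SD in HU (independent between
#'   the two images).
#' @param misalignment_px Maximum integer translation of the CECT in px.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, n_vessels = 3L, n_nodes = 2L,
                         hu_background = -1000, hu_soft_tissue = 40,
                         hu_vessel_pre = 45, hu_node_pre = 35,
                         enhancement_vessel = 250, enhancement_node = 60,
                         noise_sd = 10, misalignment_px = 1L, seed = 1L) {
  stopifnot(image_size >= 32, n_vessels >= 0, n_nodes >= 0, noise_sd >= 0,
            misalignment_px >= 0,
            is.finite(enhancement_vessel), is.finite(enhancement_node))
  structure(list(image_size = as.integer(image_size),
                 n_vessels = as.integer(n_vessels),
                 n_nodes = as.integer(n_nodes),
                 hu_background = hu_background,
                 hu_soft_tissue = hu_soft_tissue,
                 hu_vessel_pre = hu_vessel_pre,
                 hu_node_pre = hu_node_pre,
                 enhancement_vessel = enhancement_vessel,
                 enhancement_node = enhancement_node,
                 noise_sd = noise_sd,
                 misalignment_px = as.integer(misalignment_px),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(size, center, radii) {
  outer(seq_len(size), seq_len(size), function(i, j)
    ((i - center[1L]) / radii[1L])^2 + ((j - center[2L]) / radii[2L])^2 <= 1)
}

translate_int <- function(img, dy, dx, fill) {
  out <- matrix(fill, nrow(img), ncol(img))
  H <- nrow(img); W <- ncol(img)
  src_i <- intersect(seq_len(H), seq_len(H) - dy)
  src_j <- intersect(seq_len(W), seq_len(W) - dx)
  out[src_i + dy, src_j + dx] <- img[src_i, src_j]
  out
}

#' Generate one paired phantom slice
#'
#' Places the body disc and the vessel/node ellipses (rejection sampling,
#' bounded retries, structures never overlap), builds the clean NCCT and
#' CECT, then adds independent noise per image and translates the CECT by a
#' random integer offset of at most `misalignment_px`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return Object of class `phantom_pair` with `ncct`, `cect` (HU
#'   matrices), `masks` (disjoint logical matrices `background`,
#'   `soft_tissue`, `vessel`, `node` covering the image),
#'   `truth_transform` (per-compartment HU shift), the noise-free
#'   `ncct_clean`/`cect_clean`, and the applied `shift`.
#' @export
generate_phantom_pair <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed %||% spec$seed, {
    s <- spec$image_size
    ctr <- c(s, s) / 2 + 0.5
    body_r <- 0.42 * s
    body <- ellipse_mask(s, ctr, c(body_r, body_r))
    vessel <- matrix(FALSE, s, s); node <- matrix(FALSE, s, s)
    place <- function(occupied, r_lo, r_hi) {
      for (try in seq_len(200L)) {
        radii <- stats::runif(2L, r_lo, r_hi) * s
        ang <- stats::runif(1L, 0, 2 * pi)
        rad <- stats::runif(1L, 0, body_r - max(radii) - 2)
        cen <- ctr + rad * c(cos(ang), sin(ang))
        m <- ellipse_mask(s, cen, radii)
        grown <- ellipse_mask(s, cen, radii + 1.5)
        if (!any(grown & occupied)) return(m)
      }
      stop("could not place a structure without overlap; reduce counts or sizes")
    }
    for (k in seq_len(spec$n_vessels)) {
      m <- place(vessel | node, 0.04, 0.09)
      vessel <- vessel | m
    }
    for (k in seq_len(spec$n_nodes)) {
      m <- place(vessel | node, 0.03, 0.06)
      node <- node | m
    }
    soft <- body & !vessel & !node
    background <- !body
    ncct_clean <- matrix(spec$hu_background, s, s)
    ncct_clean[soft] <- spec$hu_soft_tissue
    ncct_clean[vessel] <- spec$hu_vessel_pre
    ncct_clean[node] <- spec$hu_node_pre
    truth <- c(background = 0, soft_tissue = 0,
               vessel = spec$enhancement_vessel, node = spec$enhancement_node)
    cect_clean <- ncct_clean
    cect_clean[vessel] <- cect_clean[vessel] + spec$enhancement_vessel
    cect_clean[node] <- cect_clean[node] + spec$enhancement_node
    ncct <- ncct_clean + matrix(stats::rnorm(s * s, sd = spec$noise_sd), s, s)
    shift <- if (spec$misalignment_px > 0)
      sample(seq(-spec$misalignment_px, spec$misalignment_px), 2L, replace = TRUE)
    else c(0L, 0L)
    cect <- translate_int(cect_clean, shift[1L], shift[2L], spec$hu_background) +
      matrix(stats::rnorm(s * s, sd = spec$noise_sd), s, s)
    structure(list(ncct = ncct, cect = cect,
                   masks = list(background = background, soft_tissue = soft,
                                vessel = vessel, node = node),
                   truth_transform = truth,
                   ncct_clean = ncct_clean, cect_clean = cect_clean,
                   shift = shift, spec = spec),
              class = "phantom_pair")
  })
}

#' Closed-form MAE between the clean NCCT and CECT of a phantom
#'
#' With zero noise and zero misalignment, `mean(|CECT - NCCT|)` equals the
#' area-weighted mean of the absolute per-compartment enhancement.
#'
#' @param pair A [generate_phantom_pair()] result.
#' @return Scalar HU value.
#' @export
phantom_expected_mae <- function(pair) {
  n <- length(pair$ncct_clean)
  (sum(pair$masks$vessel) * abs(pair$truth_transform[["vessel"]]) +
     sum(pair$masks$node) * abs(pair$truth_transform[["node"]])) / n
}

# circular ROIs for SNR/CNR measurement, derived from the masks: the
# largest vessel's inscribed disc, plus a homogeneous soft-tissue disc
# (used both as CNR background and as the noise-reference region).
suggest_rois <- function(pair, slice_index = 1L) {
  lab <- label_components(pair$masks$vessel)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  cen <- round(colMeans(idx))
  r <- max(1, floor(sqrt(sizes[big] / pi) * 0.55))
  inside <- function(c0, rad, mask) {
    all(c0 - rad >= 1) && all(c0 + rad <= dim(mask)) &&
      all(mask[roi_mask(roi_spec("custom", c0, rad), dim(mask))])
  }
  if (!inside(cen, r, pair$masks$vessel)) r <- 1
  soft <- NULL
  s <- nrow(pair$ncct)
  rs <- max(2, floor(0.05 * s))
  for (try in 1:500) {
    c0 <- c(sample(seq(1 + rs, s - rs), 1L), sample(seq(1 + rs, s - rs), 1L))
    if (inside(c0, rs, pair$masks$soft_tissue)) { soft <- c0; break }
  }
  if (is.null(soft)) return(NULL)
  list(label = "vessel",
       target = roi_spec("vessel", cen, r, slice_index),
       background = roi_spec("soft_tissue", soft, rs, slice_index),
       noise = roi_spec("noise", soft, rs, slice_index))
}

# 4-connected component labelling (flood fill); small images only
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  H <- nrow(mask); W <- ncol(mask)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          q <- p + d
          if (q[1L] >= 1L && q[1L] <= H && q[2L] >= 1L && q[2L] <= W &&
              mask[q[1L], q[2L]] && lab[q[1L], q[2L]] == 0L) {
            lab[q[1L], q[2L]] <- nxt
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

#' Generate a patient-grouped phantom dataset on disk
#'
#' Writes paired NCCT/CECT series for `n_patients` synthetic patients in
#' the portable PNG + sidecar layout and returns (and writes) a manifest
#' listing every patient, slice pair, and suggested measurement ROIs.
#'
#' @param spec A [phantom_spec()]; `spec$seed` drives the whole dataset.
#' @param n_patients Number of synthetic patients (>= 1).
#' @param slices_per_patient Paired slices per patient.
#' @param out Output directory; must be empty unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The manifest (class `phantom_manifest`), invisibly written to
#'   `out/manifest.json`.
#' @export
generate_phantom_dataset <- function(spec, n_patients, slices_per_patient = 3L,
                                     out, overwrite = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), n_patients >= 1)
  if (dir.exists(out) && length(list.files(out)) && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE): ", out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  patients <- list()
  thickness <- 2.5
  for (i in seq_len(n_patients)) {
    pid <- sprintf("PHANTOM%03d", i)
    ncct_slices <- list(); cect_slices <- list(); rois <- list()
    for (j in seq_len(slices_per_patient)) {
      pair_seed <- (spec$seed %% 200000L) * 10000L + i * 100L + j
      pair <- generate_phantom_pair(spec, seed = pair_seed)
      ncct_slices[[j]] <- pair$ncct
      cect_slices[[j]] <- pair$cect
      rois[[j]] <- suggest_rois(pair, slice_index = j)
    }
    positions <- (seq_len(slices_per_patient) - 1) * thickness
    nv <- ct_volume(pid, ncct_slices, positions, series_kind = "NCCT")
    cv <- ct_volume(pid, cect_slices, positions, series_kind = "CECT")
    write_ct_series(nv, file.path(out, pid, "ncct"))
    write_ct_series(cv, file.path(out, pid, "cect"))
    patients[[pid]] <- list(id = pid,
                            ncct = file.path(pid, "ncct"),
                            cect = file.path(pid, "cect"),
                            n_slices = slices_per_patient,
                            rois = rois)
  }
  manifest <- structure(list(root = normalizePath(out),
                             patients = patients,
                             spec = unclass(spec),
                             seed = spec$seed),
                        class = "phantom_manifest")
  write_manifest(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  obj <- strip(manifest)
  obj$root <- NULL   # reattached from the manifest location on read
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a dataset manifest
#' @param path Path to `manifest.json` (or its directory).
#' @return A `phantom_manifest`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$root <- dirname(normalizePath(path))
  m$spec <- do.call(phantom_spec, m$spec)
  structure(m, class = "phantom_manifest")
}

#' Split a manifest into disjoint train and test patients
#'
#' Patient-level split: every slice of a patient lands entirely in one
#' side, so no individual can leak between train and test.
#'
#' @param manifest A `phantom_manifest`.
#' @param test_fraction Fraction of patients held out (at least one).
#' @param seed Seed for the random patient assignment.
#' @return List with `train` and `test` manifests (patients disjoint).
#' @export
split_manifest <- function(manifest, test_fraction = 0.25, seed = 1L) {
  ids <- names(manifest$patients)
  n_test <- max(1L, round(test_fraction * length(ids)))
  if (n_test >= length(ids)) stop("test fraction leaves no training patients")
  test_ids <- with_seed(seed, sort(sample(ids, n_test)))
  subset_manifest <- function(keep) {
    m <- manifest
    m$patients <- manifest$patients[keep]
    m
  }
  list(train = subset_manifest(setdiff(ids, test_ids)),
       test = subset_manifest(test_ids))
}

manifest_patients <- function(manifest) names(manifest$patients)

#' Load the paired slices of a manifest into memory
#'
#' Reads each patient's NCCT and CECT series, pairs slices at matching
#' positions, and returns HU pairs tagged by patient.
#'
#' @param manifest A `phantom_manifest`.
#' @param tolerance Pairing tolerance in mm (see [pair_slices()]).
#' @return List of elements `list(patient, ncct, cect)`.
#' @export
load_pairs <- function(manifest, tolerance = 2.5) {
  out <- list()
  for (p in manifest$patients) {
    nv <- read_ct_series(file.path(manifest$root, p$ncct), series_kind = "NCCT")
    cv <- read_ct_series(file.path(manifest$root, p$cect), series_kind = "CECT")
    nv$patient_id <- p$id; cv$patient_id <- p$id
    for (pr in pair_slices(nv, cv, tolerance))
      out[[length(out) + 1L]] <- list(patient = p$id, ncct = pr$ncct,
                                      cect = pr$cect)
  }
  out
}
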