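# Preprocessing: resampling to a common grid, centred cropping/padding,
# Otsu body masking with component/hole cleanup, background assignment,
# intensity scaling to [-1, 1], and common-slice pairing of CT/CBCT volumes.

#' Preprocessing configuration
#'
#' Defaults are the clinical-scale settings: in-plane resolution
#' 0.8789 x 0.8789 mm with 3 mm slice thickness, 512 x 512 crop, background
#' (outside-body) voxels set to -1000 HU, and slice pairing within half a
#' slice thickness. `crop_size` must be divisible by 8 because the generator
#' has three stride-2 stages.
#'
#' @param target_spacing Numeric length-3 (x, y, z) in mm.
#' @param crop_size In-plane side length after cropping/padding.
#' @param background_hu HU value assigned outside the body mask.
#' @param pairing_tolerance_mm Max |z| difference for slices to count as the
#'   same position; default half the target slice thickness.
#' @param interpolation `"linear"` for images (masks always use nearest).
#' @param largest_component,fill_holes Otsu-mask cleanup switches.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing = c(0.8789, 0.8789, 3.0),
                              crop_size = 512L,
                              background_hu = -1000,
                              pairing_tolerance_mm = target_spacing[3] / 2,
                              interpolation = c("linear", "nearest"),
                              largest_component = TRUE,
                              fill_holes = TRUE) {
  validate_that(all(target_spacing > 0), "target spacing must be positive")
  validate_that(crop_size %% 8 == 0, "crop_size must be divisible by 8")
  structure(list(
    target_spacing = as.numeric(target_spacing),
    crop_size = as.integer(crop_size),
    background_hu = background_hu,
    pairing_tolerance_mm = pairing_tolerance_mm,
    interpolation = match.arg(interpolation),
    largest_component = largest_component,
    fill_holes = fill_holes
  ), class = "preprocess_config")
}

# linear (or nearest) interpolation of `arr` along one axis onto a new grid
# defined by old/new spacing; voxel centres sit at origin + index * spacing
interp_axis <- function(arr, axis, old_sp, new_sp, method = "linear") {
  n_old <- dim(arr)[axis]
  n_new <- max(1L, as.integer(round(n_old * old_sp / new_sp)))
  t <- (seq_len(n_new) - 1) * new_sp / old_sp
  if (method == "nearest") {
    idx <- pmin(pmax(round(t), 0), n_old - 1) + 1
    return(index_axis(arr, axis, idx))
  }
  lo <- pmin(pmax(floor(t), 0), n_old - 1)
  hi <- pmin(lo + 1, n_old - 1)
  wt <- t - lo
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  out <- a[lo + 1, , , drop = FALSE] * (1 - wt) + a[hi + 1, , , drop = FALSE] * wt
  aperm(out, order(perm))
}

index_axis <- function(arr, axis, idx) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  aperm(a[idx, , , drop = FALSE], order(perm))
}

#' Resample a volume to a target spacing
#'
#' Separable interpolation (linear for images, nearest for masks). The output
#' size per axis is `round(input_size * input_spacing / target_spacing)`.
#'
#' @param volume A [hu_volume()] or [binary_mask()].
#' @param target_spacing Numeric length-3 (x, y, z) in mm.
#' @param method `"linear"` or `"nearest"`; masks force nearest.
#' @return Resampled object of the same class.
#' @export
resample <- function(volume, target_spacing, method = c("linear", "nearest")) {
  method <- match.arg(method)
  validate_that(all(target_spacing > 0), "target spacing must be positive")
  validate_that(all(dim(volume$voxels) >= 1), "degenerate volume")
  is_mask <- inherits(volume, "binary_mask")
  if (is_mask) method <- "nearest"
  vox <- volume$voxels * 1.0
  # axis order (slice, row, col) maps to spacing components (z, y, x)
  sp_axis <- c(3, 2, 1)
  for (axis in 1:3) {
    s <- sp_axis[axis]
    if (!isTRUE(all.equal(volume$spacing[s], target_spacing[s]))) {
      vox <- interp_axis(vox, axis, volume$spacing[s], target_spacing[s], method)
    }
  }
  if (is_mask) {
    binary_mask(vox != 0, spacing = target_spacing, origin = volume$origin)
  } else {
    hu_volume(vox, spacing = target_spacing, origin = volume$origin,
              clip = FALSE)
  }
}

# centred crop/pad indices for one axis: returns source and target index sets
crop_pad_idx <- function(n_old, n_new) {
  if (n_old >= n_new) {
    m <- n_old - n_new
    lo <- m %/% 2  # extra pixel removed from the high-index side
    list(src = seq_len(n_new) + lo, dst = seq_len(n_new))
  } else {
    m <- n_new - n_old
    lo <- m %/% 2
    list(src = seq_len(n_old), dst = seq_len(n_old) + lo)
  }
}

#' Centred in-plane crop or pad to a square size
#'
#' Cropping and padding are centred; when the margin is odd the extra pixel
#' is taken from (or added to) the high-index side. Padded voxels are filled
#' with the background HU (-1000 by default).
#'
#' @param volume A [hu_volume()] or [binary_mask()].
#' @param size Target in-plane side length.
#' @param background Fill value for padding.
#' @return Object of the same class with in-plane shape `size x size`.
#' @export
crop_or_pad <- function(volume, size = 512L, background = -1000) {
  d <- dim(volume$voxels)
  is_mask <- inherits(volume, "binary_mask")
  if (is_mask) background <- FALSE
  ri <- crop_pad_idx(d[2], size)
  ci <- crop_pad_idx(d[3], size)
  out <- array(background, dim = c(d[1], size, size))
  out[, ri$dst, ci$dst] <- volume$voxels[, ri$src, ci$src]
  if (is_mask) {
    binary_mask(out, spacing = volume$spacing, origin = volume$origin)
  } else {
    hu_volume(out, spacing = volume$spacing, origin = volume$origin,
              clip = FALSE)
  }
}

#' Compute a body mask from an axial HU slice
#'
#' Otsu's threshold (maximising between-class variance over a 256-bin
#' histogram) separates body from air background; the mask is then cleaned to
#' the largest connected foreground component with interior holes filled, so
#' couch fragments are dropped and internal air pockets stay inside the body.
#'
#' @param slice_hu Numeric matrix of HU values.
#' @param largest_component Keep only the largest connected component.
#' @param fill_holes Fill interior holes.
#' @return A [binary_mask()] (2-D).
#' @export
compute_body_mask <- function(slice_hu, largest_component = TRUE,
                              fill_holes = TRUE) {
  validate_that(is.matrix(slice_hu), "slice must be a matrix")
  rng <- range(slice_hu)
  validate_that(diff(rng) > 0, "cannot threshold a constant image")
  u <- (slice_hu - rng[1]) / diff(rng)
  th <- EBImage::otsu(u, range = c(0, 1), levels = 256L)
  m <- u > th
  if (largest_component && any(m)) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  if (fill_holes && any(m)) {
    m <- EBImage::fillHull(EBImage::Image(m * 1)) > 0
  }
  binary_mask(matrix(as.logical(m), nrow(slice_hu), ncol(slice_hu)))
}

#' Assign the background HU outside a body mask
#'
#' Pixels outside the mask become exactly `background` (-1000); pixels inside
#' are untouched.
#'
#' @param slice_hu Numeric matrix.
#' @param mask A [binary_mask()] or logical matrix of the same shape.
#' @param background Outside value.
#' @return Numeric matrix.
#' @export
apply_background <- function(slice_hu, mask, background = -1000) {
  m <- if (inherits(mask, "binary_mask")) mask$voxels else mask
  validate_that(identical(dim(slice_hu), dim(m)), "mask/image shape mismatch")
  slice_hu[!m] <- background
  slice_hu
}

#' Scale HU values to the network range
#'
#' The affine map `s = 2 * (hu + 1000) / 4095 - 1` sends -1000 to -1 and
#' 3095 to 1. Inputs are clipped to that HU domain first, so outputs always
#' lie in `[-1, 1]`.
#'
#' @param hu Numeric vector/array of HU values.
#' @return Scaled values of the same shape.
#' @export
scale_intensity <- function(hu) {
  hu <- pmin(pmax(hu, HU_MIN), HU_MAX)
  2 * (hu + 1000) / 4095 - 1
}

#' Invert the intensity scaling
#'
#' `hu = (s + 1) * 4095 / 2 - 1000`; composition with [scale_intensity()] is
#' the identity on `[-1000, 3095]`.
#'
#' @param s Scaled values in `[-1, 1]`.
#' @return HU values.
#' @export
inverse_scale <- function(s) {
  (s + 1) * 4095 / 2 - 1000
}

#' Preprocess a volume to the common grid (HU domain)
#'
#' Resample to the target spacing, crop/pad in-plane, Otsu body mask per
#' slice, and set outside-body voxels to the background HU. Running the chain
#' a second time on its own output is the identity (up to interpolation
#' tolerance): the grid already conforms and the background is already
#' -1000. Intensity scaling is not applied here; it is tracked separately so
#' that already-scaled data is never rescaled.
#'
#' @param volume A [hu_volume()].
#' @param config A [preprocess_config()].
#' @return List with `volume` (masked, on the target grid) and `mask`
#'   (a [binary_mask()], same grid).
#' @export
preprocess_volume <- function(volume, config = preprocess_config()) {
  v <- resample(volume, config$target_spacing, config$interpolation)
  v <- crop_or_pad(v, config$crop_size, config$background_hu)
  d <- dim(v$voxels)
  mask <- array(FALSE, d)
  for (i in seq_len(d[1])) {
    sl <- v$voxels[i, , ]
    if (diff(range(sl)) == 0) next  # blank slice: all background
    m <- compute_body_mask(sl, config$largest_component, config$fill_holes)
    mask[i, , ] <- m$voxels
    v$voxels[i, , ] <- apply_background(sl, m, config$background_hu)
  }
  v$voxels[] <- pmin(pmax(v$voxels, HU_MIN), HU_MAX)
  list(volume = v,
       mask = binary_mask(mask, spacing = v$spacing, origin = v$origin))
}

# ---- paired datasets -------------------------------------------------------

new_paired_dataset <- function(ct, cbct, mask, meta, config, organs = NULL,
                               seed = NA_integer_) {
  structure(list(ct = ct, cbct = cbct, mask = mask, organs = organs,
                 meta = meta, config = config, seed = seed, processed = TRUE),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  n <- length(x$ct)
  side <- if (n) nrow(x$ct[[1]]) else NA
  cat(sprintf("<paired_dataset>  %d slice pairs  %dx%d  (scaled to [-1, 1])\n",
              n, side, side))
  invisible(x)
}

#' @export
length.paired_dataset <- function(x) length(x$ct)

#' Build a paired, preprocessed CT/CBCT slice dataset
#'
#' Both volumes are resampled to the target spacing; slices whose z positions
#' agree within the pairing tolerance (default half a slice thickness) are
#' selected, cropped, body-masked, background-assigned, and scaled to
#' `[-1, 1]`. Each record keeps its CT-derived body mask; background
#' assignment uses each image's own mask.
#'
#' @param ct,cbct [hu_volume()] objects in the same frame of reference
#'   (already aligned).
#' @param config A [preprocess_config()].
#' @return A `paired_dataset`.
#' @export
build_paired_dataset <- function(ct, cbct, config = preprocess_config()) {
  pct <- preprocess_volume(ct, config)
  pcb <- preprocess_volume(cbct, config)
  z_ct <- slice_positions(pct$volume)
  z_cb <- slice_positions(pcb$volume)
  tol <- config$pairing_tolerance_mm
  pairs <- list()
  for (i in seq_along(z_ct)) {
    j <- which.min(abs(z_cb - z_ct[i]))
    if (abs(z_cb[j] - z_ct[i]) <= tol) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  validate_that(length(pairs) > 0, "no overlapping slices between CT and CBCT")
  ct_s <- list(); cb_s <- list(); masks <- list()
  meta <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    ct_s[[k]] <- scale_intensity(pct$volume$voxels[i, , ])
    cb_s[[k]] <- scale_intensity(pcb$volume$voxels[j, , ])
    masks[[k]] <- binary_mask(pct$mask$voxels[i, , ])
    meta[[k]] <- tibble::tibble(slice = k, ct_index = i, cbct_index = j,
                                z_mm = z_ct[i])
  }
  new_paired_dataset(ct_s, cb_s, masks, dplyr::bind_rows(meta), config)
}

#' Save / load a paired dataset
#'
#' The dataset is stored as an RDS archive next to a plain-text manifest
#' (`<stem>_manifest.tsv`) listing one row per record.
#'
#' @param dataset A `paired_dataset`.
#' @param path Output `.rds` path.
#' @return `load_dataset` returns the `paired_dataset`.
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  manifest <- dataset$meta
  manifest$seed <- dataset$seed
  utils::write.table(manifest, sub("\\.rds$", "_manifest.tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  d <- readRDS(path)
  validate_that(inherits(d, "paired_dataset"), "not a paired_dataset archive")
  d
}
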