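# Volumetric containers and I/O.
#
# A `hu_volume` stores voxels as a 3-D array with axis order
# (slice, row, column), spacing (x, y, z) in mm and origin (x, y, z) in mm,
# where x runs along columns, y along rows and z across slices. Anatomical
# orientation is passed through, never resampled. HU values are clipped to
# [-1000, 3095] on load, the valid domain of the intensity scaling.

HU_MIN <- -1000
HU_MAX <- 3095

#' Construct a Hounsfield-unit volume
#'
#' @param voxels 3-D numeric array, axis order (slice, row, column). A matrix
#'   is promoted to a single-slice volume.
#' @param spacing Numeric length-3, voxel spacing (x, y, z) in mm.
#' @param origin Numeric length-3, position of the first voxel (x, y, z) in mm.
#' @param clip Clip voxel values to the valid HU range `[-1000, 3095]`.
#' @return A `hu_volume` object.
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      clip = TRUE) {
  if (is.matrix(voxels)) dim(voxels) <- c(1L, dim(voxels))
  validate_that(length(dim(voxels)) == 3L, "voxels must be a 3-D array")
  validate_that(all(dim(voxels) >= 1L), "all dimensions must be >= 1")
  validate_that(length(spacing) == 3L && all(spacing > 0),
                "spacing must be three positive numbers")
  validate_that(length(origin) == 3L, "origin must have three components")
  if (clip) voxels[] <- pmin(pmax(voxels, HU_MIN), HU_MAX)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<hu_volume>  %d slices x %d rows x %d cols  spacing %.4f x %.4f x %.4f mm  HU [%g, %g]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.hu_volume <- function(x) dim(x$voxels)

#' Construct a binary mask congruent with a volume
#'
#' @param voxels Logical (or 0/1) matrix or 3-D array.
#' @param spacing Voxel spacing (x, y, z) in mm.
#' @param origin Origin (x, y, z) in mm.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  validate_that(all(voxels %in% c(0, 1, TRUE, FALSE)),
                "mask values must be 0/1")
  storage.mode(voxels) <- "logical"
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

# z positions of slice centres
slice_positions <- function(vol) {
  vol$origin[3] + (seq_len(dim(vol$voxels)[1]) - 1) * vol$spacing[3]
}

#' Read a volume from disk
#'
#' Supports NIfTI (`.nii` / `.nii.gz`) and DICOM series (a directory of
#' single-frame CT instances sharing one series UID). DICOM stored values are
#' mapped to HU with the rescale slope/intercept from the headers; slice
#' ordering follows the z component of the image position. HU values are
#' clipped to `[-1000, 3095]`.
#'
#' @param path File (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom-series"`; inferred from `path` when
#'   missing.
#' @return A [hu_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom-series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom-series" else "nifti"
  }
  if (!file.exists(path)) {
    abort_sctgan(paste0("path does not exist: ", path), "sctgan_io_error")
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    pix <- RNifti::pixdim(img)
    # stored as (col, row, slice); convert to (slice, row, col)
    vox <- aperm(arr, c(3, 2, 1))
    hdr <- RNifti::niftiHeader(img)
    org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    hu_volume(vox, spacing = pix[1:3], origin = org)
  } else {
    read_dicom_series(path)
  }
}

#' Write a volume (or mask) to NIfTI
#'
#' Spacing is recorded in the header `pixdim` and the origin in the qform
#' offsets, so a written volume reads back identically (masks are stored as
#' 8-bit integers).
#'
#' @param volume A [hu_volume()] or [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param format Only `"nifti"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = "nifti") {
  validate_that(format == "nifti", "only NIfTI writing is supported")
  validate_that(dir.exists(dirname(path)),
                paste0("parent directory does not exist: ", dirname(path)),
                class = "sctgan_io_error")
  is_mask <- inherits(volume, "binary_mask")
  vox <- volume$voxels
  if (length(dim(vox)) == 2L) dim(vox) <- c(1L, dim(vox))  # single slice
  arr <- aperm(vox, c(3, 2, 1))  # back to (col, row, slice)
  if (is_mask) storage.mode(arr) <- "integer" else storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  hdr <- list(qoffset_x = volume$origin[1], qoffset_y = volume$origin[2],
              qoffset_z = volume$origin[3], qform_code = 1L)
  if (is_mask) hdr$datatype <- 2L  # uint8
  img <- RNifti::asNifti(img, hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file with 0/1 voxels.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, "nifti")
  binary_mask(v$voxels != 0, spacing = v$spacing, origin = v$origin)
}

#' Split a volume into an ordered list of axial slices
#'
#' @param volume A [hu_volume()].
#' @return List of matrices (row x column), one per slice, in slice order.
#' @export
volume_to_slices <- function(volume) {
  n <- dim(volume$voxels)[1]
  lapply(seq_len(n), function(i) volume$voxels[i, , ])
}

#' Reassemble axial slices into a volume
#'
#' Inverse of [volume_to_slices()] given the source volume's geometry.
#'
#' @param slices List of equally-shaped matrices.
#' @param spacing,origin Geometry for the reassembled volume.
#' @param clip Clip to the valid HU range.
#' @return A [hu_volume()].
#' @export
slices_to_volume <- function(slices, spacing = c(1, 1, 1),
                             origin = c(0, 0, 0), clip = FALSE) {
  validate_that(length(slices) >= 1, "need at least one slice")
  d <- dim(slices[[1]])
  vox <- array(0, dim = c(length(slices), d))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]
  hu_volume(vox, spacing = spacing, origin = origin, clip = clip)
}

#' Plot one axial slice of a volume
#'
#' @param object A [hu_volume()].
#' @param slice Slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object (grey HU raster).
#' @export
autoplot.hu_volume <- function(object, slice = NULL, ...) {
  n <- dim(object$voxels)[1]
  slice <- slice %||% ((n + 1L) %/% 2L)
  m <- object$voxels[slice, , ]
  d <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$hu <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "HU",
                  title = sprintf("slice %d of %d", slice, n)) +
    ggplot2::theme_void()
}
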