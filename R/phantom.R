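# Synthetic pelvic phantom and MV-CBCT degradation simulator.
#
# Anatomy is schematic (ellipses and circles on an air background): a
# soft-tissue body ellipse with a subcutaneous fat rim, two bony femoral
# heads, a bladder, a rectum with an optional air pocket, and a vertebral
# bone block. It is designed to exercise body masking, unpaired translation
# learning and the evaluation metrics, not to model real anatomy.

#' Phantom specification
#'
#' Tissue HU means follow typical CT values: soft tissue ~30, fat ~-90,
#' bladder (urine) ~10, cortical-ish bone ~600, air -1000. `texture_sd` adds
#' Gaussian texture inside the body; organ placement is jittered per slice.
#'
#' @param size Image side length in pixels (64-512; default 128).
#' @param hu Named numeric: tissue mean HU (`soft`, `fat`, `bladder`, `bone`,
#'   `air`).
#' @param texture_sd Within-tissue Gaussian texture SD in HU.
#' @param body_semiaxes Body ellipse semi-axes as fractions of `size`
#'   (column, row).
#' @param jitter Relative jitter applied to sizes/positions (fraction).
#' @param air_pocket_prob Probability that the rectum contains an air pocket.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 128L,
                         hu = c(soft = 30, fat = -90, bladder = 10,
                                bone = 600, air = -1000),
                         texture_sd = 12,
                         body_semiaxes = c(0.42, 0.30),
                         jitter = 0.06,
                         air_pocket_prob = 0.5) {
  validate_that(size >= 32 && size %% 8 == 0,
                "size must be >= 32 and divisible by 8")
  validate_that(all(hu >= HU_MIN & hu <= HU_MAX), "tissue HU out of range")
  validate_that(all(body_semiaxes < 0.5), "body ellipse must fit the image")
  structure(list(size = as.integer(size), hu = hu, texture_sd = texture_sd,
                 body_semiaxes = body_semiaxes, jitter = jitter,
                 air_pocket_prob = air_pocket_prob),
            class = "phantom_spec")
}

#' CBCT degradation specification
#'
#' The degradation emulates the dominant MV-CBCT corruptions relative to
#' fan-beam CT: multiplicative low-frequency shading/cupping, a scatter-like
#' blur admixture, additive noise, a global HU bias and contrast reduction.
#' Applied (in fixed order) as
#' `contrast * (shading * ((1-w) * img + w * blur(img))) + bias + noise`,
#' then clipped to the HU range with the background reset to -1000.
#' Defaults are calibrated so that the within-body MAE between a phantom CT
#' and its pseudo-CBCT is about 135 HU, the scale reported for MV-CBCT
#' versus planning CT.
#'
#' @param shading_amplitude Strength of the multiplicative cupping field.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param blur_weight Admixture weight of the blurred image in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise SD in HU.
#' @param bias Global HU offset.
#' @param contrast Multiplicative contrast scale in `(0, 1]`.
#' @return A `degradation_spec` list.
#' @export
degradation_spec <- function(shading_amplitude = 0.35, blur_sigma = 2,
                             blur_weight = 0.3, noise_sd = 25, bias = -105,
                             contrast = 0.80) {
  validate_that(blur_weight >= 0 && blur_weight <= 1,
                "blur_weight must be in [0, 1]")
  validate_that(blur_sigma >= 0 && noise_sd >= 0, "sigmas must be >= 0")
  validate_that(contrast > 0 && contrast <= 1, "contrast must be in (0, 1]")
  structure(list(shading_amplitude = shading_amplitude,
                 blur_sigma = blur_sigma, blur_weight = blur_weight,
                 noise_sd = noise_sd, bias = bias, contrast = contrast),
            class = "degradation_spec")
}

ellipse_mask <- function(size, c_row, c_col, a_row, a_col, theta = 0) {
  r <- matrix(seq_len(size), size, size) - c_row
  c <- matrix(seq_len(size), size, size, byrow = TRUE) - c_col
  if (theta != 0) {
    rr <- cos(theta) * r - sin(theta) * c
    cc <- sin(theta) * r + cos(theta) * c
    r <- rr; c <- cc
  }
  (r / a_row)^2 + (c / a_col)^2 <= 1
}

jit <- function(x, frac) x * (1 + runif(1, -frac, frac))

#' Generate one phantom slice with ground-truth organ masks
#'
#' Draws a randomly jittered pelvic-like slice. The background is exactly
#' -1000 HU, organ masks are exact by construction, and all HU values lie in
#' `[-1000, 3095]`. Organs are re-placed (bounded retries) if they overlap.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the slice is reproducible in isolation.
#' @return List with `slice_hu` (matrix) and `masks` (named list of
#'   [binary_mask()]: `body`, `bladder`, `femoral_head_l`, `femoral_head_r`,
#'   `rectum`, `vertebra`).
#' @export
make_phantom_slice <- function(spec = phantom_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$size
  hu <- spec$hu
  for (attempt in 1:20) {
    c_row <- n * (0.5 + runif(1, -0.02, 0.02))
    c_col <- n * (0.5 + runif(1, -0.02, 0.02))
    a_col <- n * jit(spec$body_semiaxes[1], spec$jitter)
    a_row <- n * jit(spec$body_semiaxes[2], spec$jitter)
    body <- ellipse_mask(n, c_row, c_col, a_row, a_col)
    inner <- ellipse_mask(n, c_row, c_col, 0.88 * a_row, 0.90 * a_col)
    fat_rim <- body & !inner
    # organ geometry is relative to the body semi-axes so jittered bodies
    # still contain every organ
    fh_r <- jit(0.17, spec$jitter) * a_row
    fh_dr <- jit(0.12, spec$jitter) * a_row
    fh_dc <- jit(0.58, spec$jitter) * a_col
    fh_l <- ellipse_mask(n, c_row + fh_dr, c_col - fh_dc, fh_r, fh_r)
    fh_rt <- ellipse_mask(n, c_row + fh_dr, c_col + fh_dc, fh_r, fh_r)
    bl <- ellipse_mask(n, c_row - jit(0.35, spec$jitter) * a_row, c_col,
                       jit(0.26, spec$jitter) * a_row,
                       jit(0.24, spec$jitter) * a_col)
    re_c_row <- c_row + jit(0.38, spec$jitter / 2) * a_row
    re_r <- jit(0.12, spec$jitter) * a_row
    rectum <- ellipse_mask(n, re_c_row, c_col, re_r, re_r)
    vert <- ellipse_mask(n, c_row + 0.68 * a_row, c_col,
                         0.13 * a_row, 0.17 * a_col)
    organs <- list(bladder = bl, femoral_head_l = fh_l,
                   femoral_head_r = fh_rt, rectum = rectum, vertebra = vert)
    inside <- vapply(organs, function(m) all(inner[m]), logical(1))
    pair_overlap <- FALSE
    nm <- names(organs)
    for (i in seq_along(organs)) {
      for (j in seq_len(i - 1)) {
        if (any(organs[[i]] & organs[[j]])) pair_overlap <- TRUE
      }
    }
    if (all(inside) && !pair_overlap) break
    if (attempt == 20) {
      abort_sctgan("could not place phantom organs without overlap",
                   "sctgan_generation_error")
    }
  }
  slice <- matrix(hu[["air"]], n, n)
  slice[body] <- hu[["soft"]]
  slice[fat_rim] <- hu[["fat"]]
  slice[bl] <- hu[["bladder"]]
  slice[fh_l] <- hu[["bone"]]
  slice[fh_rt] <- hu[["bone"]]
  slice[vert] <- hu[["bone"]]
  slice[rectum] <- hu[["soft"]] - 10
  if (runif(1) < spec$air_pocket_prob) {
    pocket <- ellipse_mask(n, re_c_row, c_col, 0.6 * re_r, 0.6 * re_r)
    slice[pocket] <- hu[["air"]]
  }
  if (spec$texture_sd > 0) {
    noise <- matrix(rnorm(n * n, sd = spec$texture_sd), n, n)
    slice[body] <- slice[body] + noise[body]
  }
  slice <- pmin(pmax(slice, HU_MIN), HU_MAX)
  slice[!body] <- hu[["air"]]
  masks <- c(list(body = body), organs)
  list(slice_hu = slice,
       masks = lapply(masks, binary_mask))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k, k)
  k / sum(k)
}

#' Degrade a CT slice into a pseudo-MV-CBCT slice
#'
#' Applies, in order: scatter-like blur admixture, multiplicative
#' low-frequency shading (radial cupping centred on the body), contrast
#' scaling, global HU bias, and additive Gaussian noise; the result is
#' clipped to the HU range and background pixels (exactly -1000 in the
#' input) are reset to -1000 so the body boundary is preserved.
#'
#' @param slice_hu Phantom CT slice (matrix, background exactly -1000).
#' @param spec A [degradation_spec()].
#' @param seed Optional integer for standalone reproducibility.
#' @param noise_seed Optional separate seed for the additive-noise draw,
#'   letting sensitivity analyses vary the noise realisation while keeping
#'   the shading field fixed.
#' @param noise Optional standardised (unit-sd) noise matrix of the slice's
#'   shape, scaled by `spec$noise_sd` and used instead of a fresh draw —
#'   e.g. for antithetic (`z` / `-z`) noise pairs in sensitivity analyses.
#' @return Degraded HU matrix of the same shape.
#' @export
degrade_to_cbct <- function(slice_hu, spec = degradation_spec(), seed = NULL,
                            noise_seed = NULL, noise = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(slice_hu)
  body <- slice_hu > HU_MIN
  img <- slice_hu
  if (spec$blur_weight > 0 && spec$blur_sigma > 0) {
    blurred <- EBImage::filter2(slice_hu, gaussian_kernel(spec$blur_sigma))
    img <- (1 - spec$blur_weight) * slice_hu + spec$blur_weight * blurred
  }
  if (spec$shading_amplitude > 0) {
    if (any(body)) {
      ctr <- c(mean(row(slice_hu)[body]), mean(col(slice_hu)[body]))
      ext <- max(1, max(abs(row(slice_hu)[body] - ctr[1]),
                        abs(col(slice_hu)[body] - ctr[2])))
    } else {
      ctr <- c(n / 2, n / 2); ext <- n / 2
    }
    r2 <- ((row(slice_hu) - ctr[1])^2 + (col(slice_hu) - ctr[2])^2) / ext^2
    r2 <- pmin(r2, 1)
    phase <- runif(1, 0, 2 * pi)
    theta <- runif(1, 0, pi)
    wave <- cos(2 * pi * (cos(theta) * row(slice_hu) +
                            sin(theta) * col(slice_hu)) / (2 * n) + phase)
    field <- 1 - spec$shading_amplitude * (1 - r2) +
      0.2 * spec$shading_amplitude * wave
    img <- img * field
  }
  img <- spec$contrast * img + spec$bias
  if (spec$noise_sd > 0) {
    if (is.null(noise)) {
      if (!is.null(noise_seed)) set.seed(noise_seed)
      noise <- matrix(rnorm(n * ncol(slice_hu)), n, ncol(slice_hu))
    }
    img <- img + spec$noise_sd * noise
  }
  img <- pmin(pmax(img, HU_MIN), HU_MAX)
  img[!body] <- HU_MIN
  img
}

#' Generate a paired phantom dataset
#'
#' Produces `n_slices` records of (clean phantom CT, degraded pseudo-CBCT)
#' pairs, fully preprocessed to scaled `[-1, 1]` images with ground-truth
#' body and organ masks, plus a train/validation split in the manifest.
#' Deterministic given `seed`.
#'
#' @param n_slices Number of slice pairs (>= 1).
#' @param phantom A [phantom_spec()].
#' @param degradation A [degradation_spec()].
#' @param seed Integer seed.
#' @param val_fraction Fraction of records labelled `"validation"` (taken
#'   from the end).
#' @return A `paired_dataset` with `organs` masks attached.
#' @export
generate_dataset <- function(n_slices, phantom = phantom_spec(),
                             degradation = degradation_spec(), seed = 1L,
                             val_fraction = 0.1) {
  validate_that(n_slices >= 1, "n_slices must be >= 1")
  set.seed(seed)
  ct <- vector("list", n_slices)
  cbct <- vector("list", n_slices)
  masks <- vector("list", n_slices)
  organs <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    ph <- make_phantom_slice(phantom)
    deg <- degrade_to_cbct(ph$slice_hu, degradation)
    ct[[i]] <- scale_intensity(ph$slice_hu)
    cbct[[i]] <- scale_intensity(deg)
    masks[[i]] <- ph$masks$body
    organs[[i]] <- ph$masks[setdiff(names(ph$masks), "body")]
  }
  n_val <- floor(val_fraction * n_slices)
  split <- c(rep("train", n_slices - n_val), rep("validation", n_val))
  meta <- tibble::tibble(slice = seq_len(n_slices), split = split)
  new_paired_dataset(ct, cbct, masks, meta,
                     config = list(phantom = phantom, degradation = degradation),
                     organs = organs, seed = as.integer(seed))
}
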