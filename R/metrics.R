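# Image-quality metrics on HU volumes (MAE, PSNR, NCC, SSIM) and the Dice
# similarity coefficient on binary masks, plus a pairwise evaluation report.
#
# Conventions: population (divide-by-N) moments inside NCC and SSIM;
# sample SD for the "mean +/- SD" aggregates across cases. PSNR uses the
# maximum HU of the reference image as MAX (switchable to a fixed peak).

as_vox <- function(x) {
  if (inherits(x, "hu_volume") || inherits(x, "binary_mask")) x$voxels
  else if (is.numeric(x) || is.logical(x)) x
  else abort_sctgan("expected a volume, mask or numeric array",
                    "sctgan_validation_error")
}

check_congruent <- function(a, b) {
  validate_that(identical(dim(a) %||% length(a), dim(b) %||% length(b)),
                "volumes must have identical shape")
}

#' Mean absolute error (HU)
#'
#' Mean over all voxels of `|I1 - I2|`.
#'
#' @param i1,i2 Volumes or numeric arrays of identical shape.
#' @param mask Optional logical mask restricting the computation.
#' @return Non-negative scalar (HU).
#' @export
mae <- function(i1, i2, mask = NULL) {
  a <- as_vox(i1); b <- as_vox(i2)
  check_congruent(a, b)
  if (!is.null(mask)) {
    m <- as_vox(mask); check_congruent(a, m)
    a <- a[m]; b <- b[m]
  }
  mean(abs(a - b))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(MAX^2 / MSE)` where `MAX` is by default the maximum HU of the
#' reference image `i1` and MSE the mean squared voxel difference. Identical
#' inputs give `Inf`. Note the asymmetry: swapping arguments changes `MAX`.
#'
#' @param i1 Reference volume (supplies `MAX`).
#' @param i2 Test volume.
#' @param peak Override for `MAX` (e.g. a fixed dynamic range).
#' @param mask Optional logical mask.
#' @return Scalar in dB (`Inf` for identical inputs).
#' @export
psnr <- function(i1, i2, peak = NULL, mask = NULL) {
  a <- as_vox(i1); b <- as_vox(i2)
  check_congruent(a, b)
  if (!is.null(mask)) {
    m <- as_vox(mask); a <- a[m]; b <- b[m]
  }
  peak <- peak %||% max(a)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Normalized cross-correlation
#'
#' Mean of centred products over the product of population standard
#' deviations; equals the Pearson correlation of the voxel values and is
#' invariant to positive affine rescaling of either image.
#'
#' @param i1,i2 Volumes or arrays of identical shape (both non-constant).
#' @param mask Optional logical mask.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(i1, i2, mask = NULL) {
  a <- as_vox(i1); b <- as_vox(i2)
  check_congruent(a, b)
  if (!is.null(mask)) {
    m <- as_vox(mask); a <- a[m]; b <- b[m]
  }
  s1 <- sqrt(mean((a - mean(a))^2))
  s2 <- sqrt(mean((b - mean(b))^2))
  validate_that(s1 > 0 && s2 > 0, "NCC undefined for constant images")
  mean((a - mean(a)) * (b - mean(b))) / (s1 * s2)
}

#' SSIM parameters
#'
#' Stabilisation constants default to the standard `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2` with dynamic range `L = 4095` (the full HU span).
#' `mode = "global"` evaluates the SSIM closed form with whole-image moments;
#' `"windowed"` averages the same form over square sliding windows (2-D
#' input only).
#'
#' @param L Dynamic range.
#' @param c1,c2 Stabilisers; computed from `L` when `NULL`.
#' @param mode `"global"` or `"windowed"`.
#' @param window Window side for windowed mode.
#' @return An `ssim_params` list.
#' @export
ssim_params <- function(L = 4095, c1 = NULL, c2 = NULL,
                        mode = c("global", "windowed"), window = 11L) {
  c1 <- c1 %||% (0.01 * L)^2
  c2 <- c2 %||% (0.03 * L)^2
  validate_that(c1 >= 0 && c2 >= 0 && L > 0, "invalid SSIM constants")
  structure(list(L = L, c1 = c1, c2 = c2, mode = match.arg(mode),
                 window = as.integer(window)),
            class = "ssim_params")
}

ssim_formula <- function(m1, m2, v1, v2, cov, c1, c2) {
  ((2 * m1 * m2 + c1) * (2 * cov + c2)) /
    ((m1^2 + m2^2 + c1) * (v1 + v2 + c2))
}

#' Structural similarity index
#'
#' In global mode, the SSIM closed form evaluated with whole-image population
#' means, variances and covariance. In windowed mode, the mean of the same
#' form over sliding windows.
#'
#' @param i1,i2 Volumes or arrays of identical shape.
#' @param params An [ssim_params()].
#' @param mask Optional logical mask (global mode only).
#' @return Scalar (1 for identical non-constant images).
#' @export
ssim <- function(i1, i2, params = ssim_params(), mask = NULL) {
  a <- as_vox(i1); b <- as_vox(i2)
  check_congruent(a, b)
  if (params$mode == "global") {
    if (!is.null(mask)) {
      m <- as_vox(mask); a <- a[m]; b <- b[m]
    }
    m1 <- mean(a); m2 <- mean(b)
    v1 <- mean((a - m1)^2); v2 <- mean((b - m2)^2)
    cv <- mean((a - m1) * (b - m2))
    ssim_formula(m1, m2, v1, v2, cv, params$c1, params$c2)
  } else {
    validate_that(is.matrix(a), "windowed SSIM expects 2-D images")
    w <- params$window
    k <- matrix(1 / (w * w), w, w)
    mu1 <- EBImage::filter2(a, k)
    mu2 <- EBImage::filter2(b, k)
    s11 <- EBImage::filter2(a * a, k) - mu1^2
    s22 <- EBImage::filter2(b * b, k) - mu2^2
    s12 <- EBImage::filter2(a * b, k) - mu1 * mu2
    mean(ssim_formula(mu1, mu2, s11, s22, s12, params$c1, params$c2))
  }
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` using voxel counts.
#'
#' @param m1,m2 Binary masks (or logical arrays) of identical shape, not both
#'   empty.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(m1, m2) {
  a <- as_vox(m1); b <- as_vox(m2)
  check_congruent(a, b)
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  validate_that(denom > 0, "DSC undefined for two empty masks")
  2 * sum(a & b) / denom
}

#' Evaluate image volumes against a reference CT
#'
#' Computes MAE, PSNR, NCC and SSIM for each named volume against the
#' reference, and optionally DSC for named mask pairs. Metrics are computed
#' over the full grid by default (outside-body voxels at -1000 in all
#' images, mirroring preprocessing); pass `body_mask` to restrict to the
#' body.
#'
#' @param ct Reference [hu_volume()] (or array).
#' @param others Named list of volumes to compare against `ct`
#'   (e.g. `list(CBCT = ..., sCT = ...)`).
#' @param masks Optional named list; each element a list/pair of two masks.
#' @param params An [ssim_params()].
#' @param body_mask Optional mask restricting the image metrics.
#' @return A `metric_report`: tibble with one row per comparison
#'   (columns `comparison`, `mae`, `psnr`, `ncc`, `ssim`) and, when masks are
#'   given, a `"dsc"` attribute tibble (`structure`, `dsc`).
#' @export
evaluate <- function(ct, others, masks = NULL, params = ssim_params(),
                     body_mask = NULL) {
  validate_that(is.list(others) && length(others) > 0 &&
                  !is.null(names(others)), "others must be a named list")
  rows <- lapply(names(others), function(nm) {
    o <- others[[nm]]
    check_congruent(as_vox(ct), as_vox(o))
    tibble::tibble(
      comparison = paste0(nm, " vs CT"),
      mae = mae(ct, o, mask = body_mask),
      psnr = psnr(ct, o, mask = body_mask),
      ncc = ncc(ct, o, mask = body_mask),
      ssim = ssim(ct, o, params, mask = body_mask)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_report", class(out))
  if (!is.null(masks)) {
    drows <- lapply(names(masks), function(nm) {
      pr <- masks[[nm]]
      tibble::tibble(structure = nm, dsc = dsc(pr[[1]], pr[[2]]))
    })
    attr(out, "dsc") <- dplyr::bind_rows(drows)
  }
  out
}

#' Aggregate metric reports across cases
#'
#' Mean and sample standard deviation of each metric per comparison label,
#' the "mean +/- SD" convention used for multi-patient summaries.
#'
#' @param reports List of `metric_report` objects (one per case).
#' @return Tibble with columns `comparison`, `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_reports <- function(reports) {
  validate_that(length(reports) > 0, "no reports supplied")
  dplyr::bind_rows(reports, .id = "case") |>
    tidyr::pivot_longer(c("mae", "psnr", "ncc", "ssim"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$comparison, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Image-quality metrics (reference: CT)\n")
  print(tibble::as_tibble(x), ...)
  d <- attr(x, "dsc")
  if (!is.null(d)) {
    cat("\nDice similarity coefficients\n")
    print(d, ...)
  }
  invisible(x)
}

#' Plot a metric report
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object (one panel per metric).
#' @export
autoplot.metric_report <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mae", "psnr", "ncc", "ssim"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$comparison, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
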