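# Resampling, cropping, Otsu masking, background, intensity scaling, pairing.

test_that("resample size arithmetic and constants behave as specified", {
  v <- hu_volume(array(7, c(2, 16, 512)), spacing = c(1, 1, 3))
  out <- resample(v, c(0.8789, 1, 3))
  expect_equal(dim(out$voxels), c(2L, 16L, 583L))  # round(512 / 0.8789)
  expect_true(all(abs(out$voxels - 7) < 1e-9))     # constant stays constant
  expect_equal(out$spacing, c(0.8789, 1, 3))

  same <- resample(toy_volume(), c(1, 1, 3))
  expect_equal(same$voxels, toy_volume()$voxels, tolerance = 1e-9)
})

test_that("resample interpolates linearly between voxel centres", {
  # a ramp along columns: value equals column index - 1 (x = (j-1) * 1 mm)
  v <- hu_volume(array(rep(0:7, each = 1), c(1, 1, 8)), spacing = c(1, 1, 1))
  out <- resample(v, c(0.5, 1, 1))
  # x positions 0, 0.5, 1, ... should read off the ramp values directly
  expect_equal(as.numeric(out$voxels[1, 1, 1:5]), c(0, 0.5, 1, 1.5, 2),
               tolerance = 1e-9)
})

test_that("crop_or_pad centres with the documented tie-break and pads air", {
  v <- hu_volume(array(seq_len(583 * 583), c(1, 583, 583)), clip = FALSE)
  out <- crop_or_pad(v, 512)
  expect_equal(dim(out$voxels)[2:3], c(512L, 512L))
  # low offset 35, high offset 36
  expect_equal(out$voxels[1, 1, 1], v$voxels[1, 36, 36])
  expect_equal(out$voxels[1, 512, 512], v$voxels[1, 547, 547])

  small <- hu_volume(array(100, c(1, 400, 400)))
  padded <- crop_or_pad(small, 512)
  expect_equal(dim(padded$voxels)[2:3], c(512L, 512L))
  expect_equal(padded$voxels[1, 1, 1], -1000)
  expect_equal(padded$voxels[1, 57, 57], 100)   # pad lo = 56
  expect_equal(padded$voxels[1, 456, 456], 100) # 56 + 400
  expect_equal(padded$voxels[1, 457, 457], -1000)

  v512 <- hu_volume(array(rnorm(512 * 512), c(1, 512, 512)), clip = FALSE)
  expect_equal(crop_or_pad(v512, 512)$voxels, v512$voxels)
})

test_that("Otsu body mask matches a perfectly bimodal ellipse exactly", {
  m <- matrix(-1000, 64, 64)
  ell <- (row(m) - 32)^2 / 20^2 + (col(m) - 32)^2 / 25^2 <= 1
  m[ell] <- 0
  mask <- compute_body_mask(m)
  expect_identical(mask$voxels, ell)
  expect_error(compute_body_mask(matrix(5, 8, 8)),
               class = "sctgan_validation_error")
})

test_that("the Otsu threshold agrees with an exhaustive sweep oracle", {
  # two-delta histogram at -1000 and 0: the maximising threshold lies
  # strictly between the modes, for the sweep oracle and the implementation
  m <- matrix(-1000, 32, 32)
  m[10:20, 10:20] <- 0
  th <- oracle_otsu(m)
  expect_gt(th, -1000)
  expect_lt(th, 0)
  expect_identical(compute_body_mask(m)$voxels, m > th)

  # noisy bimodal images: implementation and oracle masks agree
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(-1000 + rnorm(64^2, sd = 30), 64, 64)
    ell <- (row(m) - 32)^2 / 18^2 + (col(m) - 32)^2 / 24^2 <= 1
    m[ell] <- rnorm(sum(ell), mean = 40, sd = 40)
    th_oracle <- oracle_otsu(m)
    expect_gt(th_oracle, min(m))
    expect_lt(th_oracle, 40)
    mask <- compute_body_mask(m, largest_component = FALSE,
                              fill_holes = FALSE)
    agreement <- mean(mask$voxels == (m > th_oracle))
    expect_gt(agreement, 0.995)
  }
})

test_that("hole filling retains internal air pockets; flood-fill oracle agrees", {
  m <- matrix(-1000, 64, 64)
  ell <- (row(m) - 32)^2 / 20^2 + (col(m) - 32)^2 / 25^2 <= 1
  m[ell] <- 30
  pocket <- (row(m) - 36)^2 + (col(m) - 32)^2 <= 9
  m[pocket] <- -1000  # air inside the body
  mask <- compute_body_mask(m)
  expect_true(all(mask$voxels[pocket]))
  raw <- m > oracle_otsu(m)
  holes <- oracle_flood_background(raw)
  expect_identical(mask$voxels, raw | holes)
})

test_that("apply_background zeroes exactly the outside and preserves the body", {
  m <- matrix(rnorm(32 * 32, 50, 20), 32, 32)
  ell <- (row(m) - 16)^2 / 10^2 + (col(m) - 16)^2 / 12^2 <= 1
  out <- apply_background(m, binary_mask(ell))
  expect_true(all(out[!ell] == -1000))
  expect_identical(out[ell], m[ell])
  expect_identical(sort(out[ell]), sort(m[ell]))  # multiset unchanged
  expect_identical(apply_background(m, matrix(TRUE, 32, 32)), m)
  expect_true(all(apply_background(m, matrix(FALSE, 32, 32)) == -1000))
  expect_error(apply_background(m, matrix(TRUE, 2, 2)),
               class = "sctgan_validation_error")
})

test_that("intensity scaling is the printed affine map with exact endpoints", {
  expect_identical(scale_intensity(-1000), -1)
  expect_identical(scale_intensity(3095), 1)
  expect_identical(scale_intensity(1047.5), 0)
  x <- seq(-1000, 3095, length.out = 101)
  expect_true(all(diff(scale_intensity(x)) > 0))  # strictly increasing
  expect_identical(inverse_scale(-1), -1000)
  expect_identical(inverse_scale(1), 3095)
  set.seed(1)
  hu <- runif(1000, -1000, 3095)
  expect_lt(max(abs(inverse_scale(scale_intensity(hu)) - hu)), 1e-3)
})

test_that("build_paired_dataset pairs identical volumes slice for slice", {
  v <- toy_volume(n_slice = 5, side = 24)
  cfg <- preprocess_config(target_spacing = c(1, 1, 3), crop_size = 24L)
  ds <- build_paired_dataset(v, v, cfg)
  expect_s3_class(ds, "paired_dataset")
  expect_length(ds, 5)
  for (k in seq_along(ds$ct)) expect_equal(ds$ct[[k]], ds$cbct[[k]])
  expect_true(all(ds$ct[[1]] >= -1 & ds$ct[[1]] <= 1))
})

test_that("slice pairing counts the z interval intersection", {
  mk <- function(z0, n) {
    v <- toy_volume(n_slice = n, side = 24)
    v$origin[3] <- z0
    v
  }
  cfg <- preprocess_config(target_spacing = c(1, 1, 3), crop_size = 24L)
  ct <- mk(0, 41)     # z in [0, 120]
  cbct <- mk(60, 41)  # z in [60, 180]
  ds <- build_paired_dataset(ct, cbct, cfg)
  expect_length(ds, 21)
  far <- mk(500, 5)
  expect_error(build_paired_dataset(ct, far, cfg),
               class = "sctgan_validation_error")
})

test_that("the preprocessing chain is idempotent on its own output", {
  v <- toy_volume(n_slice = 3, side = 40)
  cfg <- preprocess_config(target_spacing = c(1, 1, 3), crop_size = 48L)
  once <- preprocess_volume(v, cfg)
  twice <- preprocess_volume(once$volume, cfg)
  expect_equal(twice$volume$voxels, once$volume$voxels, tolerance = 1e-6)
  expect_identical(twice$mask$voxels, once$mask$voxels)
})

test_that("dataset save/load round-trips with a manifest", {
  v <- toy_volume(n_slice = 3, side = 24)
  cfg <- preprocess_config(target_spacing = c(1, 1, 3), crop_size = 24L)
  ds <- build_paired_dataset(v, v, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_dataset(ds, path)
  expect_true(file.exists(sub("\\.rds$", "_manifest.tsv", path)))
  ds2 <- load_dataset(path)
  expect_equal(ds2$ct, ds$ct)
})
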