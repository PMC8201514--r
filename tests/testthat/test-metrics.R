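# MAE, PSNR, NCC, SSIM, DSC and the evaluation report.

test_that("mae matches hand examples and the loop oracle", {
  a <- array(rnorm(4^3, 0, 100), c(4, 4, 4))
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, a + 10), 10)
  x <- matrix(c(0, 200, 100, 300), 2, 2)      # [[0,100],[200,300]] by row
  y <- matrix(c(10, 190, 90, 310), 2, 2)
  expect_equal(mae(x, y), 10)
  b <- array(rnorm(4^3, 0, 100), c(4, 4, 4))
  expect_equal(mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
  expect_error(mae(a, array(0, c(2, 2, 2))), class = "sctgan_validation_error")
})

test_that("psnr follows its closed form, log identity, and infinity sentinel", {
  ref <- array(0, c(5, 5, 4)); ref[1] <- 300     # max HU = 300
  test <- ref + 10                                # uniform difference 10
  expect_equal(psnr(ref, test), 10 * log10(300^2 / 100), tolerance = 1e-12)
  expect_equal(psnr(ref, test), 29.5424, tolerance = 1e-4)
  # doubling the MSE costs 10*log10(2) dB
  test2 <- ref + 10 * sqrt(2)
  expect_equal(psnr(ref, test) - psnr(ref, test2), 10 * log10(2),
               tolerance = 1e-9)
  expect_identical(psnr(ref, ref), Inf)
})

test_that("ncc is affine-invariant correlation in [-1, 1]", {
  set.seed(3)
  a <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(ncc(a, a), 1, tolerance = 1e-12)
  expect_equal(ncc(a, 2 * a + 5), 1, tolerance = 1e-12)
  expect_equal(ncc(a, -a), -1, tolerance = 1e-12)
  b <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(ncc(a, b), oracle_ncc(a, b), tolerance = 1e-12)
  expect_error(ncc(a, array(3, c(6, 6, 6))),
               class = "sctgan_validation_error")
})

test_that("global ssim reproduces the printed closed form", {
  a <- array(rnorm(4^3, 100, 50), c(4, 4, 4))
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  # hand-computed example: mu1 = mu2 = 1, var1 = 1, var2 = 3, cov = 1
  i1 <- c(0, 0, 2, 2); i2 <- c(0, 0, 0, 4)
  p0 <- ssim_params(c1 = 0, c2 = 0)
  expect_equal(ssim(i1, i2, p0), 0.5, tolerance = 1e-12)
  set.seed(4)
  b <- array(rnorm(4^3, 120, 80), c(4, 4, 4))
  p <- ssim_params()
  expect_equal(ssim(a, b, p), oracle_ssim_global(a, b, p$c1, p$c2),
               tolerance = 1e-9)
  # self-similarity is exactly 1 for any non-negative constants
  expect_equal(ssim(a, a, ssim_params(c1 = 7, c2 = 0.1)), 1,
               tolerance = 1e-12)
})

test_that("windowed ssim averages the local closed form and is 1 on self", {
  set.seed(5)
  m <- matrix(rnorm(32^2, 0, 50), 32, 32)
  pw <- ssim_params(mode = "windowed", window = 7L)
  expect_equal(ssim(m, m, pw), 1, tolerance = 1e-9)
  m2 <- m + matrix(rnorm(32^2, 0, 25), 32, 32)
  expect_lt(ssim(m, m2, pw), 1)
  expect_gt(ssim(m, m2, pw), -1)
})

test_that("dsc counts overlap as twice the intersection over the sizes", {
  m <- matrix(FALSE, 20, 20)
  a <- m; a[1:10, 1:10] <- TRUE
  expect_equal(dsc(a, a), 1)
  b <- m; b[11:20, 11:20] <- TRUE
  expect_equal(dsc(a, b), 0)
  # two 10x10 squares overlapping in a 5x10 strip: 2*50/(100+100)
  c2 <- m; c2[6:15, 1:10] <- TRUE
  expect_equal(dsc(a, c2), 0.5)
  set.seed(6)
  r1 <- array(runif(16^3) > 0.5, c(16, 16, 16))
  r2 <- array(runif(16^3) > 0.5, c(16, 16, 16))
  expect_equal(dsc(r1, r2), oracle_dsc(r1, r2), tolerance = 1e-12)
  expect_error(dsc(m, m), class = "sctgan_validation_error")
})

test_that("metrics are symmetric except psnr (MAX convention)", {
  set.seed(8)
  a <- array(rnorm(5^3, 0, 100), c(5, 5, 5))
  b <- array(rnorm(5^3, 50, 80), c(5, 5, 5))
  expect_equal(mae(a, b), mae(b, a))
  expect_equal(ncc(a, b), ncc(b, a), tolerance = 1e-12)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  m1 <- array(runif(5^3) > 0.4, c(5, 5, 5))
  m2 <- array(runif(5^3) > 0.6, c(5, 5, 5))
  expect_equal(dsc(m1, m2), dsc(m2, m1))
  expect_false(isTRUE(all.equal(psnr(a, b), psnr(b, a))))
})

test_that("evaluate builds the per-comparison report with DSC rows", {
  v <- toy_volume()
  rep <- evaluate(v, list(copy = v))
  expect_s3_class(rep, "metric_report")
  expect_equal(rep$mae, 0)
  expect_equal(rep$ncc, 1, tolerance = 1e-12)
  expect_equal(rep$ssim, 1, tolerance = 1e-12)
  expect_identical(rep$psnr, Inf)

  m1 <- binary_mask(array(c(TRUE, FALSE), c(2, 4, 4)))
  rep2 <- evaluate(v, list(copy = v), masks = list(body = list(m1, m1)))
  expect_equal(attr(rep2, "dsc")$dsc, 1)
  expect_error(evaluate(v, list(bad = hu_volume(array(0, c(1, 2, 2))))),
               class = "sctgan_validation_error")
})

test_that("aggregation uses the sample SD convention", {
  mk <- function(m) {
    r <- tibble::tibble(comparison = "CBCT vs CT", mae = m, psnr = 20,
                        ncc = 0.9, ssim = 0.5)
    class(r) <- c("metric_report", class(r))
    r
  }
  agg <- aggregate_reports(list(mk(10), mk(20)))
  row <- agg[agg$metric == "mae", ]
  expect_equal(row$mean, 15)
  expect_equal(row$sd, sd(c(10, 20)))  # 7.071..., sample SD
  expect_equal(row$n, 2L)
})
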