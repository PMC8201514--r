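# Architecture contracts and backpropagation correctness.

test_that("the generator preserves spatial shape for sides divisible by 8", {
  set.seed(1)
  p <- sctgan:::init_generator(gen_arch(base = 4L, n_res = 2L))
  for (side in c(16L, 40L, 64L, 96L)) {
    x <- matrix(rnorm(side^2, sd = 0.3), side, side)
    y <- sctgan:::gen_fw(p, x)$y
    expect_identical(dim(y), c(side, side))
    expect_true(all(y >= -1 & y <= 1))  # tanh output
  }
  expect_error(sctgan:::gen_fw(p, matrix(0, 50, 50)),
               class = "sctgan_validation_error")
})

test_that("the discriminator patch map follows the convolution arithmetic", {
  set.seed(2)
  p <- sctgan:::init_discriminator(disc_arch(base = 4L))
  # side s -> s/2 -> s/4 -> s/8 -> s/8 - 1 -> s/8 - 2
  for (side in c(64L, 128L)) {
    y <- sctgan:::disc_fw(p, matrix(0, side, side))$y
    expect_identical(dim(y), c(side %/% 8L - 2L, side %/% 8L - 2L))
  }
  expect_error(sctgan:::disc_fw(p, matrix(0, 16, 16)),
               class = "sctgan_validation_error")
})

test_that("parameter counts match the documented layer-by-layer total", {
  count_conv <- function(cin, cout, k, norm = TRUE) {
    k * k * cin * cout + cout + if (norm) 2 * cout else 0
  }
  count_res <- function(ch) 2 * count_conv(ch, ch, 3)
  expected <- function(C, R) {
    count_conv(1, C, 7) +                 # head
      count_conv(C, C, 3) +               # down 1
      count_conv(C, 2 * C, 3) +           # down 2
      count_conv(2 * C, 4 * C, 3) +       # down 3
      R * count_res(4 * C) +              # bottleneck
      count_conv(6 * C, 2 * C, 3) +       # up 1 (4C + 2C skip)
      count_conv(3 * C, C, 3) +           # up 2 (2C + C skip)
      count_conv(2 * C, C, 3) +           # up 3 (C + C skip)
      count_res(C) +                      # tail residual
      count_conv(C, 1, 7, norm = FALSE)   # output convolution
  }
  p32 <- sctgan:::init_generator(gen_arch(base = 32L, n_res = 9L))
  expect_equal(sctgan:::n_params(p32), expected(32, 9))
  p8 <- sctgan:::init_generator(gen_arch(base = 8L, n_res = 3L))
  expect_equal(sctgan:::n_params(p8), expected(8, 3))

  d_expected <- function(C) {
    count_conv(1, C, 4, norm = FALSE) + count_conv(C, 2 * C, 4) +
      count_conv(2 * C, 4 * C, 4) + count_conv(4 * C, 8 * C, 4) +
      count_conv(8 * C, 1, 4, norm = FALSE)
  }
  d32 <- sctgan:::init_discriminator(disc_arch(base = 32L))
  expect_equal(sctgan:::n_params(d32), d_expected(32))
})

test_that("discriminator channel progression is base, 2x, 4x, 8x, 1", {
  p <- sctgan:::init_discriminator(disc_arch(base = 32L))
  outs <- vapply(p, function(l) nrow(l$W), integer(1))
  expect_identical(unname(outs), c(32L, 64L, 128L, 256L, 1L))
})

test_that("generator backpropagation matches finite differences", {
  # the convolution GEMMs run in single precision, so the finite-difference
  # probe uses a larger step and a matching tolerance; structural backward
  # errors would show up as O(1) disagreement
  set.seed(4)
  p <- sctgan:::init_generator(gen_arch(base = 2L, n_res = 1L))
  x <- matrix(rnorm(16 * 16, sd = 0.5), 16, 16)
  target <- matrix(0.2, 16, 16)
  f <- sctgan:::gen_fw(p, x, keep_cache = TRUE)
  bwd <- sctgan:::gen_bw(p, f$cache, 2 * (f$y - target) / length(f$y))
  loss <- function(pp) mean((sctgan:::gen_fw(pp, x)$y - target)^2)
  paths <- flat_paths(p)
  set.seed(5)
  for (k in sample(seq_along(paths), 12)) {
    pa <- paths[[k]]
    idx <- sample(length(p[[pa]]), 1)
    eps <- 1e-3
    p2 <- p; p2[[pa]][idx] <- p2[[pa]][idx] + eps
    p3 <- p; p3[[pa]][idx] <- p3[[pa]][idx] - eps
    num <- (loss(p2) - loss(p3)) / (2 * eps)
    expect_lt(abs(bwd$g[[pa]][idx] - num),
              5e-3 * max(1, abs(num)))
  }
  # input gradient
  for (idx in sample(length(x), 5)) {
    eps <- 1e-3
    x2 <- x; x2[idx] <- x2[idx] + eps
    x3 <- x; x3[idx] <- x3[idx] - eps
    num <- (mean((sctgan:::gen_fw(p, x2)$y - target)^2) -
              mean((sctgan:::gen_fw(p, x3)$y - target)^2)) / (2 * eps)
    expect_lt(abs(bwd$dx[idx] - num), 5e-3 * max(1, abs(num)))
  }
})

test_that("discriminator backpropagation matches finite differences", {
  set.seed(6)
  p <- sctgan:::init_discriminator(disc_arch(base = 2L))
  x <- matrix(rnorm(32 * 32, sd = 0.5), 32, 32)
  f <- sctgan:::disc_fw(p, x, keep_cache = TRUE)
  bwd <- sctgan:::disc_bw(p, f$cache, 2 * (f$y - 1) / length(f$y))
  loss <- function(pp) mean((sctgan:::disc_fw(pp, x)$y - 1)^2)
  paths <- flat_paths(p)
  set.seed(7)
  fd <- function(pa, idx, eps) {
    p2 <- p; p2[[pa]][idx] <- p2[[pa]][idx] + eps
    p3 <- p; p3[[pa]][idx] <- p3[[pa]][idx] - eps
    (loss(p2) - loss(p3)) / (2 * eps)
  }
  for (k in sample(seq_along(paths), 10)) {
    pa <- paths[[k]]
    idx <- sample(length(p[[pa]]), 1)
    num1 <- fd(pa, idx, 1e-3)
    num2 <- fd(pa, idx, 5e-4)
    # a leaky-ReLU kink inside the probe makes the numeric estimate itself
    # unstable; skip those samples (the two step sizes disagree)
    if (abs(num1 - num2) > 2e-3 * max(1, abs(num1))) next
    # single-precision GEMM tolerance; biases feeding instance norm have
    # true gradient 0, so the comparison is absolute
    expect_lt(abs(bwd$g[[pa]][idx] - num1), 5e-3 * max(1, abs(num1)))
  }
})

test_that("direct convolution agrees with a loop oracle", {
  set.seed(8)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  W <- matrix(rnorm(3 * 2 * 9), nrow = 3)
  b <- rnorm(3)
  out <- sctgan:::conv2d_fw(x, W, b, 3L, 1L, 1L, FALSE)$y
  xp <- array(0, c(7, 7, 2)); xp[2:6, 2:6, ] <- x
  oracle <- array(0, c(5, 5, 3))
  for (co in 1:3) for (i in 1:5) for (j in 1:5) {
    s <- b[co]
    for (ci in 1:2) for (ki in 0:2) for (kj in 0:2) {
      s <- s + W[co, (ci - 1) * 9 + ki * 3 + kj + 1] * xp[i + ki, j + kj, ci]
    }
    oracle[i, j, co] <- s
  }
  expect_equal(out, oracle, tolerance = 1e-5)
})
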