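# Hand-rolled convolutional networks: parameter trees, layer wrappers around
# the compiled primitives, and explicit forward/backward passes for the
# residual U-Net generator and the PatchGAN discriminator.

# ---- parameter-tree utilities ---------------------------------------------

# apply f leaf-wise over one or more congruent nested lists of arrays
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

tree_add <- function(a, b) tree_map(`+`, a, b)
tree_zeros_like <- function(p) tree_map(function(x) x * 0, p)

tree_flatten <- function(p) {
  if (!is.list(p)) return(list(p))
  unlist(lapply(p, tree_flatten), recursive = FALSE)
}

n_params <- function(p) sum(vapply(tree_flatten(p), length, integer(1)))

tree_identical <- function(a, b) {
  fa <- tree_flatten(a); fb <- tree_flatten(b)
  length(fa) == length(fb) &&
    all(mapply(function(x, y) identical(as.numeric(x), as.numeric(y)), fa, fb))
}

# ---- parameter initialisation ---------------------------------------------

# N(0, 0.02) weights throughout — the convention of the image-translation
# network family this architecture belongs to, and measurably faster to
# train here than fan-in-scaled schemes. Draws use the R RNG, so seeding
# `set.seed()` makes initialisation reproducible.
init_conv <- function(c_in, c_out, k, norm = TRUE, weight_sd = 0.02) {
  fan_in <- c_in * k * k
  p <- list(
    W = matrix(rnorm(c_out * fan_in, sd = weight_sd), nrow = c_out),
    b = numeric(c_out)
  )
  if (norm) {
    p$gamma <- rep(1, c_out)
    p$beta <- numeric(c_out)
  }
  p
}

init_res_block <- function(ch, k = 3L) {
  list(c1 = init_conv(ch, ch, k), c2 = init_conv(ch, ch, k))
}

# ---- layer wrappers --------------------------------------------------------

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

act_code <- c(none = 0L, relu = 1L, lrelu = 2L, tanh = 3L)

# conv -> instance norm -> activation (norm + activation fused in C++);
# returns value + cache for backward
conv_block_fw <- function(x, p, k, stride, pad, reflect = FALSE,
                          norm = TRUE, act = "relu") {
  x <- as_cube(x)
  cf <- conv2d_fw(x, p$W, p$b, k, stride, pad, reflect)
  z <- cf$y
  cache <- list(x = x, z = z, cols = cf$cols, k = k, stride = stride,
                pad = pad, reflect = reflect, norm = norm, act = act)
  if (norm) {
    nrm <- instnorm_act_fw(z, p$gamma, p$beta, 1e-5, act_code[[act]])
    y <- nrm$y
    cache$mean <- nrm$mean
    cache$istd <- nrm$istd
    cache$y <- y
  } else {
    y <- switch(act,
      relu = pmax(z, 0),
      lrelu = z * ((z > 0) + 0.2 * (z <= 0)),
      tanh = tanh(z),
      none = z
    )
    if (act != "none") cache$y <- y
  }
  list(y = y, cache = cache)
}

conv_block_bw <- function(dy, cache, p, want_param_grads = TRUE) {
  dy <- as_cube(dy)
  g <- list()
  if (cache$norm) {
    nb <- instnorm_act_bw(cache$z, p$gamma, cache$mean, cache$istd,
                          as_cube(cache$y), dy, act_code[[cache$act]])
    dz <- nb$dx
    g$gamma <- as.numeric(nb$dgamma)
    g$beta <- as.numeric(nb$dbeta)
  } else {
    dz <- switch(cache$act,
      relu = dy * (cache$z > 0),
      lrelu = dy * ((cache$z > 0) + 0.2 * (cache$z <= 0)),
      tanh = dy * (1 - cache$y^2),
      none = dy
    )
  }
  cb <- conv2d_bw(cache$x, p$W, as_cube(dz), cache$k, cache$stride, cache$pad,
                  cache$reflect, want_param_grads, cache$cols)
  if (want_param_grads) {
    g$W <- cb$dW
    g$b <- as.numeric(cb$db)
    # order grads like params (W, b, gamma, beta)
    g <- g[names(p)]
  }
  list(dx = cb$dx, g = g)
}

# pre-activation-free resnet block: y = x + IN(conv(relu(IN(conv(x)))))
res_block_fw <- function(x, p) {
  a <- conv_block_fw(x, p$c1, k = 3L, stride = 1L, pad = 1L, act = "relu")
  b <- conv_block_fw(a$y, p$c2, k = 3L, stride = 1L, pad = 1L, act = "none")
  list(y = x + b$y, cache = list(a = a$cache, b = b$cache))
}

res_block_bw <- function(dy, cache, p, want_param_grads = TRUE) {
  bb <- conv_block_bw(dy, cache$b, p$c2, want_param_grads)
  ab <- conv_block_bw(bb$dx, cache$a, p$c1, want_param_grads)
  list(dx = dy + ab$dx,
       g = if (want_param_grads) list(c1 = ab$g, c2 = bb$g))
}

# ---- generator: residual U-Net --------------------------------------------

#' Generator architecture description
#'
#' The generator is a residual U-Net operating on single-channel images in
#' \eqn{[-1, 1]}: a 7x7 stride-1 head; three 3x3 stride-2 down-convolutions
#' with channels `base`, `2*base`, `4*base`; `n_res` residual blocks; three
#' nearest-neighbour x2 upsampling stages each followed by a 3x3 convolution,
#' with U-Net skip concatenations from the same-resolution down-stage outputs;
#' a tail residual block; and a final 7x7 convolution with a tanh output.
#' Every convolution except the last is followed by instance normalisation and
#' ReLU. The clinical-scale configuration uses `base = 32`, `n_res = 9`
#' (down-path channels 32, 64, 128).
#'
#' @param base First-stage channel count (down path has channels
#'   `base, 2*base, 4*base`). Default 32.
#' @param n_res Number of bottleneck residual blocks. Default 9.
#' @return A `gen_arch` list.
#' @export
gen_arch <- function(base = 32L, n_res = 9L) {
  validate_that(base >= 1 && n_res >= 0, "base >= 1 and n_res >= 0 required")
  structure(list(base = as.integer(base), n_res = as.integer(n_res)),
            class = "gen_arch")
}

#' Initialise generator parameters
#'
#' @param arch A [gen_arch()] description.
#' @return Nested list of weight matrices and bias/normalisation vectors.
#' @export
init_generator <- function(arch = gen_arch()) {
  C <- arch$base
  p <- list(
    head = init_conv(1L, C, 7L),
    d1 = init_conv(C, C, 3L),
    d2 = init_conv(C, 2L * C, 3L),
    d3 = init_conv(2L * C, 4L * C, 3L),
    res = lapply(seq_len(arch$n_res), function(i) init_res_block(4L * C)),
    u1 = init_conv(6L * C, 2L * C, 3L),  # 4C bottleneck + 2C skip
    u2 = init_conv(3L * C, C, 3L),       # 2C + C skip
    u3 = init_conv(2L * C, C, 3L),       # C + C skip
    tail = init_res_block(C),
    out = init_conv(C, 1L, 7L, norm = FALSE)
  )
  attr(p, "arch") <- arch
  p
}

cat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
}

#' Apply the generator to an image
#'
#' Shape-preserving for inputs whose side is divisible by 8 (three stride-2
#' stages). Output values lie in \eqn{[-1, 1]} (tanh).
#'
#' @param p Generator parameters from [init_generator()].
#' @param x Square numeric matrix (values nominally in `[-1, 1]`).
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @return `list(y, cache)`; `y` is a matrix of the input shape.
#' @export
gen_fw <- function(p, x, keep_cache = FALSE) {
  d <- dim(x)
  validate_that(d[1] %% 8 == 0 && d[2] %% 8 == 0,
                "generator input sides must be divisible by 8")
  h0 <- conv_block_fw(x, p$head, k = 7L, stride = 1L, pad = 3L, reflect = TRUE)
  h1 <- conv_block_fw(h0$y, p$d1, k = 3L, stride = 2L, pad = 1L)
  h2 <- conv_block_fw(h1$y, p$d2, k = 3L, stride = 2L, pad = 1L)
  h3 <- conv_block_fw(h2$y, p$d3, k = 3L, stride = 2L, pad = 1L)
  r <- h3$y
  rc <- vector("list", length(p$res))
  for (i in seq_along(p$res)) {
    rb <- res_block_fw(r, p$res[[i]])
    r <- rb$y
    rc[[i]] <- rb$cache
  }
  up1_in <- cat_channels(upsample2_fw(r), h2$y)
  u1 <- conv_block_fw(up1_in, p$u1, k = 3L, stride = 1L, pad = 1L)
  up2_in <- cat_channels(upsample2_fw(u1$y), h1$y)
  u2 <- conv_block_fw(up2_in, p$u2, k = 3L, stride = 1L, pad = 1L)
  up3_in <- cat_channels(upsample2_fw(u2$y), h0$y)
  u3 <- conv_block_fw(up3_in, p$u3, k = 3L, stride = 1L, pad = 1L)
  tl <- res_block_fw(u3$y, p$tail)
  out <- conv_block_fw(tl$y, p$out, k = 7L, stride = 1L, pad = 3L,
                       reflect = TRUE, norm = FALSE, act = "tanh")
  y <- out$y
  dim(y) <- d
  cache <- NULL
  if (keep_cache) {
    cache <- list(h0 = h0$cache, h1 = h1$cache, h2 = h2$cache, h3 = h3$cache,
                  rc = rc, u1 = u1$cache, u2 = u2$cache, u3 = u3$cache,
                  tail = tl$cache, out = out$cache,
                  nch = c(h0 = dim(as_cube(h0$y))[3], h1 = dim(as_cube(h1$y))[3],
                          h2 = dim(as_cube(h2$y))[3], r = dim(r)[3],
                          u1 = dim(u1$y)[3], u2 = dim(u2$y)[3]))
  }
  list(y = y, cache = cache)
}

split_channels <- function(d, n_first) {
  list(first = d[, , seq_len(n_first), drop = FALSE],
       second = d[, , -seq_len(n_first), drop = FALSE])
}

# backward pass through the generator; returns input gradient and a parameter
# gradient tree congruent with `p`
gen_bw <- function(p, cache, dy, want_param_grads = TRUE) {
  dy <- as_cube(dy)
  ob <- conv_block_bw(dy, cache$out, p$out, want_param_grads)
  tb <- res_block_bw(ob$dx, cache$tail, p$tail, want_param_grads)
  u3b <- conv_block_bw(tb$dx, cache$u3, p$u3, want_param_grads)
  s3 <- split_channels(u3b$dx, cache$nch[["u2"]])
  du2 <- upsample2_bw(s3$first); dh0 <- s3$second
  u2b <- conv_block_bw(du2, cache$u2, p$u2, want_param_grads)
  s2 <- split_channels(u2b$dx, cache$nch[["u1"]])
  du1 <- upsample2_bw(s2$first); dh1 <- s2$second
  u1b <- conv_block_bw(du1, cache$u1, p$u1, want_param_grads)
  s1 <- split_channels(u1b$dx, cache$nch[["r"]])
  dr <- upsample2_bw(s1$first); dh2 <- s1$second
  gres <- vector("list", length(p$res))
  for (i in rev(seq_along(p$res))) {
    rb <- res_block_bw(dr, cache$rc[[i]], p$res[[i]], want_param_grads)
    dr <- rb$dx
    gres[[i]] <- rb$g
  }
  d3b <- conv_block_bw(dr, cache$h3, p$d3, want_param_grads)
  d2b <- conv_block_bw(d3b$dx + dh2, cache$h2, p$d2, want_param_grads)
  d1b <- conv_block_bw(d2b$dx + dh1, cache$h1, p$d1, want_param_grads)
  hb <- conv_block_bw(d1b$dx + dh0, cache$h0, p$head, want_param_grads)
  dx <- hb$dx
  dim(dx) <- dim(dx)[1:2]
  g <- NULL
  if (want_param_grads) {
    g <- list(head = hb$g, d1 = d1b$g, d2 = d2b$g, d3 = d3b$g, res = gres,
              u1 = u1b$g, u2 = u2b$g, u3 = u3b$g, tail = tb$g, out = ob$g)
  }
  list(dx = dx, g = g)
}

# ---- discriminator: PatchGAN ----------------------------------------------

#' Discriminator architecture description
#'
#' Three 4x4 stride-2 convolutions with channels `base`, `2*base`, `4*base`,
#' a 4x4 stride-1 convolution to `8*base` channels, and a final 4x4 stride-1
#' convolution to one channel, giving a patch score map. With zero padding 1
#' throughout, an input of side `s` yields a map of side `s/8 - 2`
#' (512 -> 62, 64 -> 6). Leaky ReLU (slope 0.2) follows every convolution
#' except the last; instance normalisation follows all but the first and
#' last (normalising the first linear layer would make the discriminator
#' exactly invariant to global affine intensity changes of its input).
#' Clinical scale: `base = 32` (channels 32, 64, 128, 256, 1).
#'
#' @param base First-stage channel count. Default 32.
#' @return A `disc_arch` list.
#' @export
disc_arch <- function(base = 32L) {
  validate_that(base >= 1, "base >= 1 required")
  structure(list(base = as.integer(base)), class = "disc_arch")
}

#' Initialise discriminator parameters
#' @param arch A [disc_arch()] description.
#' @return Nested parameter list.
#' @export
init_discriminator <- function(arch = disc_arch()) {
  C <- arch$base
  p <- list(
    # no normalisation on the first layer: instance norm directly after a
    # linear convolution of the input would cancel global affine intensity
    # changes exactly, leaving the discriminator blind to the HU bias and
    # contrast errors the translation must correct
    c1 = init_conv(1L, C, 4L, norm = FALSE),
    c2 = init_conv(C, 2L * C, 4L),
    c3 = init_conv(2L * C, 4L * C, 4L),
    c4 = init_conv(4L * C, 8L * C, 4L),
    c5 = init_conv(8L * C, 1L, 4L, norm = FALSE)
  )
  attr(p, "arch") <- arch
  p
}

#' Apply the discriminator to an image
#'
#' @param p Parameters from [init_discriminator()].
#' @param x Square numeric matrix with side at least 32.
#' @param keep_cache Keep activations for backpropagation.
#' @return `list(y, cache)`; `y` is the patch score matrix.
#' @export
disc_fw <- function(p, x, keep_cache = FALSE) {
  d <- dim(x)
  validate_that(min(d[1:2]) >= 32,
                "discriminator input smaller than its receptive field")
  a1 <- conv_block_fw(x, p$c1, k = 4L, stride = 2L, pad = 1L, act = "lrelu",
                      norm = FALSE)
  a2 <- conv_block_fw(a1$y, p$c2, k = 4L, stride = 2L, pad = 1L, act = "lrelu")
  a3 <- conv_block_fw(a2$y, p$c3, k = 4L, stride = 2L, pad = 1L, act = "lrelu")
  a4 <- conv_block_fw(a3$y, p$c4, k = 4L, stride = 1L, pad = 1L, act = "lrelu")
  a5 <- conv_block_fw(a4$y, p$c5, k = 4L, stride = 1L, pad = 1L,
                      norm = FALSE, act = "none")
  y <- a5$y
  dim(y) <- dim(y)[1:2]
  cache <- if (keep_cache) {
    list(a1 = a1$cache, a2 = a2$cache, a3 = a3$cache, a4 = a4$cache,
         a5 = a5$cache)
  }
  list(y = y, cache = cache)
}

disc_bw <- function(p, cache, dy, want_param_grads = TRUE) {
  dy <- as_cube(dy)
  b5 <- conv_block_bw(dy, cache$a5, p$c5, want_param_grads)
  b4 <- conv_block_bw(b5$dx, cache$a4, p$c4, want_param_grads)
  b3 <- conv_block_bw(b4$dx, cache$a3, p$c3, want_param_grads)
  b2 <- conv_block_bw(b3$dx, cache$a2, p$c2, want_param_grads)
  b1 <- conv_block_bw(b2$dx, cache$a1, p$c1, want_param_grads)
  dx <- b1$dx
  dim(dx) <- dim(dx)[1:2]
  g <- if (want_param_grads) {
    list(c1 = b1$g, c2 = b2$g, c3 = b3$g, c4 = b4$g, c5 = b5$g)
  }
  list(dx = dx, g = g)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(p) {
  list(m = tree_zeros_like(p), v = tree_zeros_like(p), t = 0L)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map(function(m, gr) beta1 * m + (1 - beta1) * gr, st$m, g)
  st$v <- tree_map(function(v, gr) beta2 * v + (1 - beta2) * gr^2, st$v, g)
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  p <- tree_map(function(w, m, v) w - lr * (m / c1) / (sqrt(v / c2) + eps),
                p, st$m, st$v)
  list(p = p, st = st)
}
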