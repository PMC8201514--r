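# Independent oracles and small fixture builders used across the suite.
# Every oracle is a direct, brute-force transcription of the defining
# formula, deliberately sharing no code with the package implementation.

# -- metric oracles: straight loops over the printed formulas ---------------

oracle_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

oracle_psnr <- function(a, b, peak = max(a)) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  10 * log10(peak^2 / (s / length(a)))
}

oracle_ncc <- function(a, b) {
  n <- length(a)
  mu1 <- sum(a) / n
  mu2 <- sum(b) / n
  s1 <- sqrt(sum((a - mu1)^2) / n)
  s2 <- sqrt(sum((b - mu2)^2) / n)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - mu1) * (b[i] - mu2)
  (acc / n) / (s1 * s2)
}

oracle_ssim_global <- function(a, b, c1, c2) {
  n <- length(a)
  mu1 <- sum(a) / n
  mu2 <- sum(b) / n
  v1 <- sum((a - mu1)^2) / n
  v2 <- sum((b - mu2)^2) / n
  cv <- sum((a - mu1) * (b - mu2)) / n
  ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
}

oracle_dsc <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    inter <- inter + (a[i] && b[i])
    na <- na + a[i]
    nb <- nb + b[i]
  }
  2 * inter / (na + nb)
}

# -- Otsu oracle: exhaustive sweep maximising between-class variance --------

oracle_otsu <- function(x, levels = 256L) {
  rng <- range(x)
  u <- (x - rng[1]) / diff(rng)
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(u, breaks = breaks, plot = FALSE)$counts
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  best <- -Inf; th <- 0
  for (t in 1:(levels - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h[(t + 1):levels])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; th <- mids[t] }
  }
  th * diff(rng) + rng[1]  # back to HU
}

# flood-fill from the border: TRUE where background air is reachable
oracle_flood_background <- function(mask) {
  # mask: body candidate (logical); returns holes = !mask & !reachable
  h <- nrow(mask); w <- ncol(mask)
  reach <- matrix(FALSE, h, w)
  queue <- list()
  push <- function(i, j) queue[[length(queue) + 1L]] <<- c(i, j)
  for (i in 1:h) { push(i, 1); push(i, w) }
  for (j in 1:w) { push(1, j); push(h, j) }
  while (length(queue)) {
    ij <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i < 1 || i > h || j < 1 || j > w) next
    if (reach[i, j] || mask[i, j]) next
    reach[i, j] <- TRUE
    push(i - 1, j); push(i + 1, j); push(i, j - 1); push(i, j + 1)
  }
  !mask & !reach
}

# -- misc helpers ------------------------------------------------------------

# recursive index paths into a nested parameter list
flat_paths <- function(p, prefix = integer()) {
  if (!is.list(p)) return(list(prefix))
  unlist(lapply(seq_along(p), function(i) flat_paths(p[[i]], c(prefix, i))),
         recursive = FALSE)
}

# a deterministic little volume with structure (HU-ish values)
toy_volume <- function(n_slice = 4, side = 12, seed = 42) {
  set.seed(seed)
  vox <- array(-1000, dim = c(n_slice, side, side))
  for (i in seq_len(n_slice)) {
    m <- matrix(-1000, side, side)
    rr <- row(m) - side / 2; cc <- col(m) - side / 2
    body <- (rr / (side * 0.4))^2 + (cc / (side * 0.45))^2 <= 1
    m[body] <- 30 + rnorm(sum(body), sd = 10)
    vox[i, , ] <- m
  }
  hu_volume(vox, spacing = c(1, 1, 3), origin = c(0, 0, 0))
}

expect_tree_equal <- function(a, b, tol = 0) {
  fa <- sctgan:::tree_flatten(a)
  fb <- sctgan:::tree_flatten(b)
  expect_equal(length(fa), length(fb))
  for (i in seq_along(fa)) {
    if (tol == 0) expect_identical(as.numeric(fa[[i]]), as.numeric(fb[[i]]))
    else expect_equal(as.numeric(fa[[i]]), as.numeric(fb[[i]]), tolerance = tol)
  }
}
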