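# Training loop: determinism, zero-lr identity, loss decrease, checkpoints.

tiny_cfg <- function(seed = 1L, ...) {
  train_config(base = 4L, n_res = 1L, seed = seed, ...)
}

tiny_ds <- function(n = 6, seed = 3) {
  generate_dataset(n, phantom_spec(size = 32L), seed = seed)
}

test_that("a zero learning rate leaves all parameters unchanged", {
  ds <- tiny_ds()
  cfg <- tiny_cfg(lr = 0)
  st <- init_training_state(cfg)
  st2 <- train_step(st, ds$ct[[1]], ds$cbct[[2]], cfg)
  expect_tree_equal(st$g, st2$g)
  expect_tree_equal(st$d, st2$d)
  expect_equal(st2$iter, 1L)
  expect_equal(nrow(st2$history), 1L)
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_ds()
  run <- function() {
    cfg <- tiny_cfg(seed = 42L, epochs = 1L, max_iter = 4)
    train(ds, cfg)
  }
  s1 <- run()
  s2 <- run()
  expect_tree_equal(s1$g, s2$g)
  expect_tree_equal(s1$d, s2$d)
  expect_identical(s1$history, s2$history)
})

test_that("epochs 0 returns the initialised state with no updates", {
  ds <- tiny_ds()
  cfg <- tiny_cfg(epochs = 0L)
  st <- train(ds, cfg)
  expect_equal(st$iter, 0L)
  expect_equal(nrow(st$history), 0L)
  expect_error(train(structure(list(ct = list()), class = "paired_dataset"),
                     cfg),
               class = "sctgan_validation_error")
})

test_that("loss history records all terms and the weighted total", {
  ds <- tiny_ds()
  cfg <- tiny_cfg(max_iter = 3, epochs = 1L)
  st <- train(ds, cfg)
  h <- loss_history(st)
  expect_equal(nrow(h), 3L)
  expect_named(h, c("iteration", "loss_cycle", "loss_idem", "loss_adv_g",
                    "loss_grad", "loss_g", "loss_d"))
  expect_true(all(h$loss_cycle >= 0 & h$loss_idem >= 0 &
                    h$loss_adv_g >= 0 & h$loss_grad >= 0))
  w <- cfg$weights
  expect_equal(h$loss_g,
               w$cycle * h$loss_cycle + w$idem * h$loss_idem +
                 w$adv * h$loss_adv_g + w$grad * h$loss_grad,
               tolerance = 1e-12)
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(glance(st)$iterations, 3L)
})

test_that("the generator objective decreases over a short phantom run", {
  ds <- generate_dataset(10, phantom_spec(size = 32L), seed = 5)
  cfg <- tiny_cfg(seed = 7L, epochs = 20L, max_iter = 150)
  st <- train(ds, cfg)
  h <- loss_history(st)
  early <- mean(h$loss_g[1:10])
  late <- mean(h$loss_g[(nrow(h) - 9):nrow(h)])
  expect_lt(late, early)
})

test_that("checkpoints round-trip and resumed training reproduces the run", {
  ds <- tiny_ds()
  dir <- withr::local_tempdir()
  cfg <- tiny_cfg(seed = 9L, epochs = 1L, max_iter = 6)

  full <- train(ds, cfg)

  cfg_half <- tiny_cfg(seed = 9L, epochs = 1L, max_iter = 3)
  half <- train(ds, cfg_half)
  path <- file.path(dir, "ck.rds")
  save_checkpoint(half, path)

  resumed <- load_checkpoint(path)
  expect_tree_equal(resumed$g, half$g)
  cfg_rest <- tiny_cfg(seed = 9L, epochs = 1L, max_iter = 3)
  rest <- train(ds, cfg_rest, state = resumed)
  expect_tree_equal(rest$g, full$g)
  expect_equal(rest$history, full$history, tolerance = 1e-12)
})

test_that("the identity idem_mode penalises same-domain drift", {
  ds <- tiny_ds()
  cfg <- tiny_cfg(idem_mode = "identity", max_iter = 2, epochs = 1L)
  st <- train(ds, cfg)
  expect_equal(st$iter, 2L)
  expect_true(all(is.finite(loss_history(st)$loss_idem)))
})

test_that("one train step moves parameters against the objective gradient", {
  # independent forward-only oracle of the generator objective
  set.seed(21)
  cfg <- train_config(base = 2L, n_res = 1L, seed = 21L, noise_sd = 0,
                      lr = 1e-6)
  st <- init_training_state(cfg)
  a <- matrix(runif(32 * 32, -1, 0), 32, 32)
  b <- matrix(runif(32 * 32, -1, 0), 32, 32)
  w <- cfg$weights
  total_loss <- function(pga, pgb, d) {
    fA <- sctgan:::gen_fw(pga, a)$y; fB <- sctgan:::gen_fw(pgb, b)$y
    cycA <- sctgan:::gen_fw(pgb, fA)$y; cycB <- sctgan:::gen_fw(pga, fB)$y
    iA <- sctgan:::gen_fw(pga, fA)$y; iB <- sctgan:::gen_fw(pgb, fB)$y
    w$cycle * (mean(abs(cycA - a)) + mean(abs(cycB - b))) +
      w$idem * (mean(abs(iA - fA)) + mean(abs(iB - fB))) +
      w$adv * (mean((sctgan:::disc_fw(d$ct, fA)$y - 1)^2) +
                 mean((sctgan:::disc_fw(d$cbct, fB)$y - 1)^2)) +
      w$grad * (grad_loss(a, fA) + grad_loss(b, fB))
  }
  st2 <- train_step(st, b, a, cfg)
  paths <- flat_paths(st$g$ab)
  set.seed(22)
  checked <- 0L
  for (k in sample(seq_along(paths), 12)) {
    pa <- paths[[k]]
    idx <- sample(length(st$g$ab[[pa]]), 1)
    eps <- 1e-5
    p2 <- st$g$ab; p2[[pa]][idx] <- p2[[pa]][idx] + eps
    p3 <- st$g$ab; p3[[pa]][idx] <- p3[[pa]][idx] - eps
    num <- (total_loss(p2, st$g$ba, st$d) -
              total_loss(p3, st$g$ba, st$d)) / (2 * eps)
    if (abs(num) < 1e-3) next  # skip kink-dominated samples
    delta <- st2$g$ab[[pa]][idx] - st$g$ab[[pa]][idx]
    expect_equal(sign(delta), -sign(num))
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})
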