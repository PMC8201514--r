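# CycleGAN training: two generators (G_cbct->ct, G_ct->cbct), two
# discriminators (D_ct, D_cbct), joint Adam update of the generators against
# the four-term objective and of the discriminators against the
# least-squares discrimination loss. Batch size is 1 (slice-wise training).

#' Training configuration
#'
#' Defaults are the clinical-scale settings: Adam with learning rate 1e-4,
#' batch size 1, 100 epochs, additive Gaussian input noise (sd 0.01 in scaled
#' units) as regularisation, and the full-size architecture (base 32 channels,
#' 9 residual blocks). `idem_mode` selects the idempotence term: `"idempotence"`
#' penalises `|G(G(x)) - G(x)|`; `"identity"` is the same-domain alternative
#' `|G(y) - y|` for `y` already in the generator's target domain.
#'
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the dataset.
#' @param noise_sd Standard deviation of the Gaussian noise added to network
#'   inputs during training (scaled units).
#' @param seed Integer seed controlling initialisation and sampling.
#' @param base,n_res Generator/discriminator width and bottleneck depth.
#' @param weights A [loss_weights()] object.
#' @param beta1 Adam first-moment decay; 0.5 by default, the standard
#'   choice for adversarial training (the paper states only "Adam").
#' @param idem_mode `"idempotence"` or `"identity"`.
#' @param replay_pool Size of the fake-image replay buffer used for
#'   discriminator updates (0 disables it). With probability 1/2 the
#'   discriminator trains on a buffered earlier fake instead of the current
#'   one, damping generator/discriminator oscillation.
#' @param checkpoint_every Iterations between checkpoints (`Inf` = only final).
#' @param max_iter Optional hard cap on total iterations (overrides epochs).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, epochs = 100L, noise_sd = 0.01,
                         seed = 1L, base = 32L, n_res = 9L, beta1 = 0.5,
                         weights = loss_weights(),
                         idem_mode = c("idempotence", "identity"),
                         replay_pool = 50L,
                         checkpoint_every = Inf, max_iter = Inf) {
  validate_that(lr >= 0, "learning rate must be non-negative")
  validate_that(epochs >= 0, "epochs must be non-negative")
  structure(list(
    lr = lr, epochs = as.integer(epochs), batch = 1L, noise_sd = noise_sd,
    beta1 = beta1, seed = as.integer(seed), base = as.integer(base),
    n_res = as.integer(n_res), weights = weights,
    idem_mode = match.arg(idem_mode),
    replay_pool = as.integer(replay_pool),
    checkpoint_every = checkpoint_every, max_iter = max_iter
  ), class = "train_config")
}

history_cols <- c("iteration", "loss_cycle", "loss_idem", "loss_adv_g",
                  "loss_grad", "loss_g", "loss_d")

#' Initialise a training state
#'
#' Draws fresh parameters for both generators and both discriminators using
#' the configuration seed and attaches empty Adam states and loss history.
#'
#' @param config A [train_config()].
#' @return A `training_state` object.
#' @export
init_training_state <- function(config = train_config()) {
  set.seed(config$seed)
  garch <- gen_arch(config$base, config$n_res)
  darch <- disc_arch(config$base)
  g <- list(ab = init_generator(garch), ba = init_generator(garch))
  d <- list(ct = init_discriminator(darch), cbct = init_discriminator(darch))
  structure(list(
    g = g, d = d,
    opt_g = adam_init(g), opt_d = adam_init(d),
    pool = list(ct = list(), cbct = list()),
    iter = 0L,
    history = matrix(numeric(0), ncol = length(history_cols),
                     dimnames = list(NULL, history_cols)),
    config = config,
    rng = get(".Random.seed", envir = globalenv())
  ), class = "training_state")
}

l1_bw <- function(a, b) sign(a - b) / length(a)

# replay buffer: store up to `size` fakes; once full, with probability 1/2
# hand the discriminator a random buffered fake and keep the current one
pool_swap <- function(pool, img, size) {
  if (size <= 0) return(list(pool = pool, img = img))
  if (length(pool) < size) {
    pool[[length(pool) + 1L]] <- img
    return(list(pool = pool, img = img))
  }
  if (runif(1) < 0.5) {
    k <- sample.int(size, 1L)
    out <- pool[[k]]
    pool[[k]] <- img
    list(pool = pool, img = out)
  } else {
    list(pool = pool, img = img)
  }
}

#' One training iteration
#'
#' Performs one Adam update of both generators against the combined
#' four-term objective (cycle consistency in both directions, idempotence,
#' least-squares adversarial, gradient preservation) followed by one Adam
#' update of both discriminators. Gaussian noise of the configured sd is added
#' to the inputs before the forward passes. The four generator loss-term
#' values and the discriminator loss are appended to the state's history.
#'
#' @param state A `training_state`.
#' @param ct,cbct Square matrices in `[-1, 1]` (preprocessed slices).
#' @param config Optional override of `state$config`.
#' @return The updated `training_state`.
#' @export
train_step <- function(state, ct, cbct, config = state$config) {
  w <- config$weights
  a <- cbct + rnorm(length(cbct), sd = config$noise_sd)  # CBCT domain
  b <- ct + rnorm(length(ct), sd = config$noise_sd)      # CT domain
  dim(a) <- dim(cbct); dim(b) <- dim(ct)
  pga <- state$g$ab   # G_cbct->ct
  pgb <- state$g$ba   # G_ct->cbct
  N <- length(a)

  # forward passes (all with caches for backprop). Discriminator inputs get
  # fresh noise of the same sd, real and fake alike, so the discriminator
  # cannot win by detecting the regularisation noise itself (or the exact -1
  # background of real slices) instead of judging anatomy and HU realism.
  fA <- gen_fw(pga, a, keep_cache = TRUE)       # fake CT
  cycA <- gen_fw(pgb, fA$y, keep_cache = TRUE)  # back to CBCT
  fB <- gen_fw(pgb, b, keep_cache = TRUE)       # fake CBCT
  cycB <- gen_fw(pga, fB$y, keep_cache = TRUE)  # back to CT
  dnoise <- function(img) img + rnorm(length(img), sd = config$noise_sd)
  dct_fake <- disc_fw(state$d$ct, dnoise(fA$y), keep_cache = TRUE)
  dcb_fake <- disc_fw(state$d$cbct, dnoise(fB$y), keep_cache = TRUE)

  # cycle and gradient targets are the *clean* slices: the input noise is
  # regularisation, and making the generators reproduce it would reward
  # texture invention in the fakes
  l_cycle <- mean(abs(cycA$y - cbct)) + mean(abs(cycB$y - ct))
  l_adv <- mean((dct_fake$y - 1)^2) + mean((dcb_fake$y - 1)^2)
  l_grad <- grad_loss(cbct, fA$y) + grad_loss(ct, fB$y)

  # cycle: L1(GB(fA), cbct) and L1(GA(fB), ct)
  gb_cyc <- gen_bw(pgb, cycA$cache, w$cycle * l1_bw(cycA$y, cbct))
  ga_cyc <- gen_bw(pga, cycB$cache, w$cycle * l1_bw(cycB$y, ct))
  dfA <- gb_cyc$dx
  dfB <- ga_cyc$dx

  # idempotence (or identity) term
  if (config$idem_mode == "idempotence") {
    iA <- gen_fw(pga, fA$y, keep_cache = TRUE)
    iB <- gen_fw(pgb, fB$y, keep_cache = TRUE)
    l_idem <- mean(abs(iA$y - fA$y)) + mean(abs(iB$y - fB$y))
    dA <- w$idem * l1_bw(iA$y, fA$y)
    dB <- w$idem * l1_bw(iB$y, fB$y)
    ga_idem <- gen_bw(pga, iA$cache, dA)
    gb_idem <- gen_bw(pgb, iB$cache, dB)
    dfA <- dfA + ga_idem$dx - dA
    dfB <- dfB + gb_idem$dx - dB
  } else {
    # identity: G_cbct->ct applied to a real CT should return it (and v.v.)
    idA <- gen_fw(pga, b, keep_cache = TRUE)
    idB <- gen_fw(pgb, a, keep_cache = TRUE)
    l_idem <- mean(abs(idA$y - ct)) + mean(abs(idB$y - cbct))
    ga_idem <- gen_bw(pga, idA$cache, w$idem * l1_bw(idA$y, ct))
    gb_idem <- gen_bw(pgb, idB$cache, w$idem * l1_bw(idB$y, cbct))
  }

  # adversarial term (discriminator parameters frozen here)
  dadv_A <- disc_bw(state$d$ct, dct_fake$cache,
                    w$adv * 2 * (dct_fake$y - 1) / length(dct_fake$y),
                    want_param_grads = FALSE)
  dadv_B <- disc_bw(state$d$cbct, dcb_fake$cache,
                    w$adv * 2 * (dcb_fake$y - 1) / length(dcb_fake$y),
                    want_param_grads = FALSE)
  dfA <- dfA + dadv_A$dx + w$grad * grad_loss_bw(cbct, fA$y)
  dfB <- dfB + dadv_B$dx + w$grad * grad_loss_bw(ct, fB$y)

  # backprop through the primary translations and accumulate per-generator
  ga_f <- gen_bw(pga, fA$cache, dfA)
  gb_f <- gen_bw(pgb, fB$cache, dfB)
  g_ga <- tree_add(tree_add(ga_f$g, ga_cyc$g), ga_idem$g)
  g_gb <- tree_add(tree_add(gb_f$g, gb_cyc$g), gb_idem$g)

  l_g <- generator_loss(c(cycle = l_cycle, idem = l_idem, adv = l_adv,
                          grad = l_grad), w)
  if (!is.finite(l_g)) {
    abort_sctgan(
      sprintf("non-finite generator loss at iteration %d (cycle=%g idem=%g adv=%g grad=%g)",
              state$iter + 1L, l_cycle, l_idem, l_adv, l_grad),
      "sctgan_numeric_error", state = state)
  }

  up_g <- adam_step(state$g, list(ab = g_ga, ba = g_gb), state$opt_g,
                    config$lr, beta1 = config$beta1 %||% 0.5)

  # discriminator update (fakes detached). Reals are the clean slices plus
  # one noise draw — noising the already-noised generator batch would give
  # reals a detectably larger noise floor than fakes. Fakes may come from
  # the replay buffer, which damps generator/discriminator oscillation.
  sw_ct <- pool_swap(state$pool$ct, fA$y, config$replay_pool %||% 0L)
  sw_cb <- pool_swap(state$pool$cbct, fB$y, config$replay_pool %||% 0L)
  state$pool <- list(ct = sw_ct$pool, cbct = sw_cb$pool)
  dct_fake_d <- disc_fw(state$d$ct, dnoise(sw_ct$img), keep_cache = TRUE)
  dcb_fake_d <- disc_fw(state$d$cbct, dnoise(sw_cb$img), keep_cache = TRUE)
  dct_real <- disc_fw(state$d$ct, dnoise(ct), keep_cache = TRUE)
  dcb_real <- disc_fw(state$d$cbct, dnoise(cbct), keep_cache = TRUE)
  l_d <- 0.5 * mean((dct_real$y - 1)^2) + 0.5 * mean(dct_fake_d$y^2) +
    0.5 * mean((dcb_real$y - 1)^2) + 0.5 * mean(dcb_fake_d$y^2)
  dr_ct <- disc_bw(state$d$ct, dct_real$cache,
                   (dct_real$y - 1) / length(dct_real$y))
  df_ct <- disc_bw(state$d$ct, dct_fake_d$cache,
                   dct_fake_d$y / length(dct_fake_d$y))
  dr_cb <- disc_bw(state$d$cbct, dcb_real$cache,
                   (dcb_real$y - 1) / length(dcb_real$y))
  df_cb <- disc_bw(state$d$cbct, dcb_fake_d$cache,
                   dcb_fake_d$y / length(dcb_fake_d$y))
  g_d <- list(ct = tree_add(dr_ct$g, df_ct$g),
              cbct = tree_add(dr_cb$g, df_cb$g))
  if (!is.finite(l_d)) {
    abort_sctgan(sprintf("non-finite discriminator loss at iteration %d",
                         state$iter + 1L),
                 "sctgan_numeric_error", state = state)
  }
  up_d <- adam_step(state$d, g_d, state$opt_d, config$lr,
                    beta1 = config$beta1 %||% 0.5)

  state$g <- up_g$p
  state$opt_g <- up_g$st
  state$d <- up_d$p
  state$opt_d <- up_d$st
  state$iter <- state$iter + 1L
  state$history <- rbind(state$history,
                         c(state$iter, l_cycle, l_idem, l_adv, l_grad, l_g, l_d))
  state
}

#' Train the CycleGAN on a paired dataset (used unpaired)
#'
#' Runs `epochs * n_slices` iterations at batch size 1. Although the dataset
#' stores aligned pairs, training samples the CT and CBCT pools independently
#' each iteration — the pairing is never used, matching the unpaired CycleGAN
#' regime. Fully deterministic given `config$seed`.
#'
#' @param dataset A `paired_dataset` (see [generate_dataset()] /
#'   [build_paired_dataset()]).
#' @param config A [train_config()].
#' @param state Optional state to resume from; default initialises fresh.
#' @param out_dir Optional directory for checkpoints and the loss table.
#' @param verbose Print a progress line per epoch.
#' @return The final `training_state`.
#' @export
train <- function(dataset, config = train_config(), state = NULL,
                  out_dir = NULL, verbose = FALSE) {
  validate_that(inherits(dataset, "paired_dataset"), "dataset must be a paired_dataset")
  n <- length(dataset$ct)
  validate_that(n >= 1, "dataset is empty")
  if (is.null(state)) state <- init_training_state(config)
  total <- min(config$epochs * n, config$max_iter)
  if (total <= 0) return(state)
  done <- 0L
  while (done < total) {
    # per-step independent sampling of the two pools: the pairing is unused,
    # and the RNG stream stays aligned across checkpoint/resume
    i <- sample.int(n, 1L)
    j <- sample.int(n, 1L)
    state <- train_step(state, dataset$ct[[i]], dataset$cbct[[j]], config)
    done <- done + 1L
    if (!is.null(out_dir) && is.finite(config$checkpoint_every) &&
        state$iter %% config$checkpoint_every == 0) {
      save_checkpoint(state, file.path(out_dir,
                                       sprintf("checkpoint_%06d.rds", state$iter)))
    }
    if (verbose && done %% n == 0) {
      k <- nrow(state$history)
      message(sprintf("iter %d/%d  loss_g %.4f  loss_d %.4f",
                      done, total, state$history[k, "loss_g"],
                      state$history[k, "loss_d"]))
    }
  }
  state$rng <- get(".Random.seed", envir = globalenv())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(state, file.path(out_dir, "checkpoint_final.rds"))
    utils::write.table(loss_history(state),
                       file.path(out_dir, "loss_history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  state
}

#' Save / load a training checkpoint
#'
#' The checkpoint round-trips the complete training state (parameters,
#' optimizer moments, iteration counter, RNG state, loss history), so resumed
#' training reproduces the run that was never interrupted.
#'
#' @param state A `training_state`.
#' @param path File path (`.rds`).
#' @return `load_checkpoint` returns the `training_state`.
#' @export
save_checkpoint <- function(state, path) {
  state$rng <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param restore_rng Restore the global RNG state saved in the checkpoint.
#' @export
load_checkpoint <- function(path, restore_rng = TRUE) {
  state <- readRDS(path)
  validate_that(inherits(state, "training_state"), "not a sctgan checkpoint")
  if (restore_rng && !is.null(state$rng)) {
    assign(".Random.seed", state$rng, envir = globalenv())
  }
  state
}

#' Loss history as a tibble
#' @param state A `training_state`.
#' @return Tibble with one row per iteration.
#' @export
loss_history <- function(state) {
  tibble::as_tibble(as.data.frame(state$history))
}

#' @export
tidy.training_state <- function(x, ...) {
  loss_history(x) |>
    tidyr::pivot_longer(-"iteration", names_to = "term", values_to = "value")
}

#' @export
glance.training_state <- function(x, ...) {
  h <- loss_history(x)
  last <- if (nrow(h)) h[nrow(h), ] else NULL
  tibble::tibble(
    iterations = x$iter,
    n_params_g = n_params(x$g),
    n_params_d = n_params(x$d),
    loss_g = if (is.null(last)) NA_real_ else last$loss_g,
    loss_d = if (is.null(last)) NA_real_ else last$loss_d
  )
}

#' @export
print.training_state <- function(x, ...) {
  cat(sprintf(
    "<sctgan training state>  iterations: %d  generator params: %s  discriminator params: %s\n",
    x$iter, format(n_params(x$g), big.mark = ","),
    format(n_params(x$d), big.mark = ",")))
  invisible(x)
}

#' Plot training loss curves
#' @param object A `training_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_state <- function(object, ...) {
  d <- tidy.training_state(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "loss (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}
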