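# Inference: apply the trained CBCT->CT generator slice-wise to a CBCT
# volume and reassemble a synthetic CT in Hounsfield units.

#' Synthesize a CT volume from a CBCT volume
#'
#' Pipeline: preprocess the CBCT (resample to the target grid, crop, Otsu
#' body mask, background assignment), scale each slice to `[-1, 1]`, run the
#' CBCT->CT generator, invert the scaling, and reassemble the volume on the
#' preprocessed grid. The body mask is recomputed from the input CBCT and
#' re-imposed on the output, so outside-body voxels are exactly -1000 and the
#' network cannot hallucinate tissue outside the body. Deterministic given
#' the checkpoint.
#'
#' @param checkpoint A `training_state`, or the path to a checkpoint `.rds`.
#' @param cbct A [hu_volume()].
#' @param config A [preprocess_config()] matching the training resolution.
#' @param keep_grid If `TRUE` (default) the sCT stays on the preprocessed
#'   grid (the grid the networks and metrics operate on); if `FALSE` it is
#'   resampled back to the input CBCT's spacing.
#' @param generator_fn Advanced: a function mapping a scaled slice matrix to
#'   a scaled slice matrix, used instead of the checkpoint's CBCT->CT
#'   generator (e.g. `identity` gives the preprocessed-CBCT baseline).
#' @return A `synthesis_result`: list with `sct` ([hu_volume()]), `mask`,
#'   `runtime` (per-slice seconds), `checkpoint_id`, `config`.
#' @export
synthesize_ct <- function(checkpoint, cbct, config = preprocess_config(),
                          keep_grid = TRUE, generator_fn = NULL) {
  if (is.null(generator_fn)) {
    state <- if (is.character(checkpoint)) load_checkpoint(checkpoint,
                                                           restore_rng = FALSE)
             else checkpoint
    validate_that(inherits(state, "training_state"),
                  "checkpoint must be a training_state or a path to one")
    generator_fn <- function(s) gen_fw(state$g$ab, s)$y
  } else {
    state <- NULL
  }
  pre <- preprocess_volume(cbct, config)
  d <- dim(pre$volume$voxels)
  out <- array(HU_MIN, d)
  runtime <- numeric(d[1])
  for (i in seq_len(d[1])) {
    t0 <- proc.time()[["elapsed"]]
    s <- scale_intensity(pre$volume$voxels[i, , ])
    y <- generator_fn(s)
    hu <- inverse_scale(y)
    m <- pre$mask$voxels[i, , ]
    hu[!m] <- HU_MIN
    out[i, , ] <- pmin(pmax(hu, HU_MIN), HU_MAX)
    runtime[i] <- proc.time()[["elapsed"]] - t0
  }
  sct <- hu_volume(out, spacing = pre$volume$spacing,
                   origin = pre$volume$origin, clip = FALSE)
  mask <- pre$mask
  if (!keep_grid) {
    sct <- resample(sct, cbct$spacing)
    mask <- resample(mask, cbct$spacing)
  }
  structure(list(sct = sct, mask = mask, runtime = runtime,
                 checkpoint_id = if (is.character(checkpoint)) checkpoint
                                 else if (!is.null(state))
                                   sprintf("iteration %d", state$iter)
                                 else "custom generator",
                 config = config),
            class = "synthesis_result")
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("<synthesis_result>  %s  (%.2f s/slice)\n",
              x$checkpoint_id, mean(x$runtime)))
  print(x$sct)
  invisible(x)
}
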