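# The four generator loss terms and the discriminator loss.
#
# Norm choices: L1 for the cycle, idempotence and gradient terms;
# least-squares (LSGAN) regression to all-ones / all-zeros patch-score maps
# for the adversarial terms.

check_same_shape <- function(x, y) {
  validate_that(identical(dim(x) %||% length(x), dim(y) %||% length(y)),
                "images must have identical shape")
}

#' Loss weights for the generator objective
#'
#' The generator objective is the weighted sum
#' `lambda_cycle * L_cycle + lambda_idem * L_idem +
#'  lambda_adv * L_adv + lambda_grad * L_grad`
#' with defaults 20, 1, 1, 1.
#'
#' @param cycle,idem,adv,grad Non-negative weights.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(cycle = 20, idem = 1, adv = 1, grad = 1) {
  w <- c(cycle = cycle, idem = idem, adv = adv, grad = grad)
  validate_that(all(w >= 0), "loss weights must be non-negative")
  structure(as.list(w), class = "loss_weights")
}

#' Cycle-consistency loss
#'
#' Mean absolute (L1) difference between an image and its cycle
#' reconstruction; zero iff the cycle is exact.
#'
#' @param x,x_cycled Numeric arrays of identical shape.
#' @return Non-negative scalar.
#' @export
cycle_loss <- function(x, x_cycled) {
  check_same_shape(x, x_cycled)
  mean(abs(x - x_cycled))
}

#' Idempotence loss
#'
#' L1 distance between `G(x)` and `G(G(x))`; zero when the generator is
#' idempotent on `x`. Applying a generator to its own output should be a
#' no-op: a CBCT already translated to the CT domain must not change again.
#'
#' @param G A function mapping an image to an image of the same shape.
#' @param x Input image.
#' @return Non-negative scalar.
#' @export
idem_loss <- function(G, x) {
  gx <- G(x)
  mean(abs(G(gx) - gx))
}

#' Gradient (edge-preservation) loss
#'
#' Finite-difference gradient magnitudes are compared between the two images:
#' the L1 distance between `|row differences|` of `x` and of `y` plus the L1
#' distance between their `|column differences|`. Invariant to adding a
#' constant to either image.
#'
#' @param x,y Numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
grad_loss <- function(x, y) {
  check_same_shape(x, y)
  dr <- function(m) m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  dc <- function(m) m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  mean(abs(abs(dr(x)) - abs(dr(y)))) + mean(abs(abs(dc(x)) - abs(dc(y))))
}

# gradient of grad_loss with respect to y
grad_loss_bw <- function(x, y) {
  dr <- function(m) m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  dc <- function(m) m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  g <- matrix(0, nrow(y), ncol(y))
  dry <- dr(y)
  s <- sign(abs(dry) - abs(dr(x))) * sign(dry) / length(dry)
  g[-1, ] <- g[-1, ] + s
  g[-nrow(y), ] <- g[-nrow(y), ] - s
  dcy <- dc(y)
  s <- sign(abs(dcy) - abs(dc(x))) * sign(dcy) / length(dcy)
  g[, -1] <- g[, -1] + s
  g[, -ncol(y)] <- g[, -ncol(y)] - s
  g
}

#' Adversarial loss for a generator (least squares)
#'
#' Mean over the discriminator's patch score map of `(D(fake) - 1)^2`: the
#' generator is rewarded when the discriminator scores its output as real.
#'
#' @param D A function mapping an image to a patch score array.
#' @param fake Generated image.
#' @return Non-negative scalar.
#' @export
adv_loss_g <- function(D, fake) {
  mean((D(fake) - 1)^2)
}

#' Adversarial loss for a discriminator (least squares)
#'
#' `0.5 * mean((D(real) - 1)^2) + 0.5 * mean(D(fake)^2)`: the discriminator
#' regresses real images to an all-ones patch map and fakes to all zeros.
#'
#' @param D A function mapping an image to a patch score array.
#' @param real,fake Images from the real domain and the generator.
#' @return Non-negative scalar.
#' @export
adv_loss_d <- function(D, real, fake) {
  0.5 * mean((D(real) - 1)^2) + 0.5 * mean(D(fake)^2)
}

#' Combined generator loss
#'
#' Exact weighted sum of the four generator loss terms.
#'
#' @param terms Numeric vector or list with elements `cycle`, `idem`, `adv`,
#'   `grad` (order is honoured if unnamed).
#' @param weights A [loss_weights()] object.
#' @return Scalar.
#' @export
generator_loss <- function(terms, weights = loss_weights()) {
  terms <- unlist(terms)
  validate_that(length(terms) == 4, "four loss terms required")
  if (!is.null(names(terms)) && all(c("cycle", "idem", "adv", "grad") %in% names(terms))) {
    terms <- terms[c("cycle", "idem", "adv", "grad")]
  }
  sum(terms * unlist(weights))
}
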