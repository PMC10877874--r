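# Training objectives: class-balanced cross-entropy, classical cross-entropy,
# and Dice loss.  All three are summed over pixels (an `average` flag divides
# by the pixel count for optimizer convenience); probabilities are clipped to
# [eps, 1 - eps] before logs.

.clip_eps <- 1e-7

check_same_shape <- function(pred, gold) {
  if (!identical(dim(as.matrix(pred)), dim(as.matrix(gold))))
    stop("pred and gold shapes differ", call. = FALSE)
}

#' Class-balance weight
#'
#' The class-equilibrium weight of the class-balanced cross-entropy:
#' `beta = |Y-| / |Y|` and `1 - beta = |Y+| / |Y|`, exact integer ratios.
#' All-positive and all-negative masks are legal (beta 0 or 1).
#'
#' @param mask Binary 2D mask.
#' @return List with `beta`, `n_pos`, `n_neg`, `n`.
#' @export
class_balance_weight <- function(mask) {
  mask <- as.matrix(mask)
  if (length(mask) == 0L) stop("empty mask", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  n <- length(mask); np <- sum(mask == 1); nn <- n - np
  list(beta = nn / n, n_pos = np, n_neg = nn, n = n)
}

#' Class-balanced cross-entropy loss
#'
#' `-beta * sum_{j in Y+} log p_j - (1 - beta) * sum_{j in Y-} log(1 - p_j)`
#' with `beta = |Y-|/|Y|`, equalizing the contribution of the scarce tumor
#' class against the abundant background class.
#'
#' @param pred Probability map in `[0, 1]`.
#' @param gold Binary gold-standard mask of the same shape.
#' @param average Divide by the pixel count instead of summing.
#' @param eps Clipping bound applied to `pred` before logs.
#' @return Nonnegative scalar.
#' @export
cbce_loss <- function(pred, gold, average = FALSE, eps = .clip_eps) {
  check_same_shape(pred, gold)
  b <- class_balance_weight(gold)
  p <- pmin(pmax(pred, eps), 1 - eps)
  l <- -b$beta * sum(log(p[gold == 1])) - (1 - b$beta) * sum(log(1 - p[gold == 0]))
  if (average) l / b$n else l
}

#' Classical (unweighted) cross-entropy loss
#'
#' @inheritParams cbce_loss
#' @return Nonnegative scalar.
#' @export
ce_loss <- function(pred, gold, average = FALSE, eps = .clip_eps) {
  check_same_shape(pred, gold)
  p <- pmin(pmax(pred, eps), 1 - eps)
  l <- -sum(log(p[gold == 1])) - sum(log(1 - p[gold == 0]))
  if (average) l / length(as.matrix(gold)) else l
}

#' Dice loss
#'
#' Soft Dice: `1 - (2 * sum(p * y) + s) / (sum(p) + sum(y) + s)` with
#' smoothing constant `s` (default 1) guarding the empty-mask case.
#'
#' @inheritParams cbce_loss
#' @param smooth Smoothing constant `s`.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, gold, smooth = 1) {
  check_same_shape(pred, gold)
  1 - (2 * sum(pred * gold) + smooth) / (sum(pred) + sum(gold) + smooth)
}

# Gradients with respect to the pre-sigmoid logit z (p = sigmoid(z)); used by
# the training loop.  For CBCE: dL/dz = -beta*(1-p) on positives,
# (1-beta)*p on negatives; CE is the beta = 1/2 case times 2; Dice chains
# dD/dp through p(1-p).
loss_grad_logit <- function(loss_name, p, y, average = FALSE, smooth = 1) {
  n <- length(p)
  g <- switch(loss_name,
    cbce = {
      b <- class_balance_weight(y)$beta
      -b * y * (1 - p) + (1 - b) * (1 - y) * p
    },
    ce = -(y * (1 - p)) + (1 - y) * p,
    dice = {
      num <- 2 * sum(p * y) + smooth
      den <- sum(p) + sum(y) + smooth
      dLdp <- -(2 * y * den - num) / den^2
      dLdp * p * (1 - p)
    },
    stop("unknown loss: ", loss_name))
  if (average && loss_name != "dice") g / n else g
}

loss_value <- function(loss_name, p, y, average = FALSE, smooth = 1) {
  switch(loss_name,
    cbce = cbce_loss(p, y, average = average),
    ce = ce_loss(p, y, average = average),
    dice = dice_loss(p, y, smooth = smooth),
    stop("unknown loss: ", loss_name))
}
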