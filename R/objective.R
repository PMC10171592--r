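# Focal Tversky training objective.
#
# The Tversky index generalizes soft Dice by weighting false positives and
# false negatives asymmetrically (alpha, beta); the focal variant raises
# (1 - TI) to an exponent gamma > 0 so that hard, low-overlap examples
# dominate the gradient.  Useful for small structures (optic nerve, lacrimal
# gland) that occupy a tiny fraction of a CT slice.

#' Tversky loss parameters
#'
#' @param alpha False-positive weight (>= 0, default 0.7).
#' @param beta False-negative weight (>= 0, default 0.3).
#' @param gamma Focal exponent (> 0, default 4/3).
#' @param epsilon Smoothing constant (> 0, default 1e-6) guarding the
#'   empty-prediction/empty-target case, for which the index is 1 and the
#'   loss 0.
#' @return Object of class `tversky_params`.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.3, gamma = 4 / 3,
                           epsilon = 1e-6) {
  if (alpha < 0 || beta < 0) stop("alpha, beta must be >= 0", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon), class = "tversky_params")
}

check_probs_target <- function(probs, target) {
  if (length(probs) != length(target) ||
      !identical(dim(probs), dim(target))) {
    stop("probs and target shapes differ", call. = FALSE)
  }
  if (min(probs) < 0 || max(probs) > 1) {
    stop("probs must lie in [0, 1]", call. = FALSE)
  }
  if (!all(target %in% c(0, 1))) {
    stop("target must be binary", call. = FALSE)
  }
}

#' Soft Tversky index
#'
#' `TI = (S_tp + eps) / (S_tp + alpha * S_fp + beta * S_fn + eps)` with the
#' soft counts `S_tp = sum(p * t)`, `S_fp = sum(p * (1 - t))`,
#' `S_fn = sum((1 - p) * t)` aggregated over all pixels of the batch.
#' With `alpha = beta = 0.5` this is the soft Dice coefficient.
#'
#' @param probs Predicted probabilities in \[0, 1\], any shape.
#' @param target Binary ground truth of the same shape.
#' @param params A [tversky_params()].
#' @return Scalar in \[0, 1\].
#' @export
soft_tversky_index <- function(probs, target, params = tversky_params()) {
  stopifnot(inherits(params, "tversky_params"))
  check_probs_target(probs, target)
  target <- as.numeric(target)
  s_tp <- sum(probs * target)
  s_fp <- sum(probs) - s_tp              # sum p*(1-t)
  s_fn <- sum(target) - s_tp             # sum (1-p)*t
  (s_tp + params$epsilon) /
    (s_tp + params$alpha * s_fp + params$beta * s_fn + params$epsilon)
}

#' Focal Tversky loss
#'
#' `loss = (1 - TI)^gamma`, in \[0, 1\]: 0 for a perfect prediction, 1 when
#' the overlap vanishes, strictly decreasing in the Tversky index.
#'
#' @inheritParams soft_tversky_index
#' @return Scalar loss.
#' @export
focal_tversky_loss <- function(probs, target, params = tversky_params()) {
  (1 - soft_tversky_index(probs, target, params))^params$gamma
}

# Loss and its gradient w.r.t. the probabilities, for the training loop.
# d loss / d p_i = -gamma (1-TI)^(gamma-1) * dTI/dp_i with
# dTI/dp_i = [t_i * D - (t_i + alpha (1 - t_i) - beta t_i) * Num] / D^2,
# since d s_tp/dp_i = t_i, d s_fp/dp_i = 1 - t_i, d s_fn/dp_i = -t_i.
focal_tversky_grad <- function(probs, target, params = tversky_params()) {
  target <- as.numeric(target)
  s_tp <- sum(probs * target)
  s_fp <- sum(probs) - s_tp
  s_fn <- sum(target) - s_tp
  num <- s_tp + params$epsilon
  den <- s_tp + params$alpha * s_fp + params$beta * s_fn + params$epsilon
  ti <- num / den
  loss <- (1 - ti)^params$gamma
  dloss_dti <- -params$gamma * (1 - ti)^(params$gamma - 1)
  dti_dp <- (target * den -
               (target + params$alpha * (1 - target) -
                  params$beta * target) * num) / den^2
  g <- dloss_dti * dti_dp
  dim(g) <- dim(probs)
  list(loss = loss, grad = g)
}
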