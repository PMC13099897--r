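# Imbalance-aware training losses and the GELU activation.
# Probabilities are clamped to [.eps_num, 1 - .eps_num] before any log.

.eps_num <- 1e-7

.clamp_probs <- function(p) pmin(pmax(p, .eps_num), 1 - .eps_num)

.check_probs <- function(p, tol = 1e-5) {
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop("invalid probability vector (entries must be >= 0 and sum to 1)",
         call. = FALSE)
  }
}

#' Focal loss
#'
#' Cross-entropy scaled by a focusing factor `(1 - p_t)^gamma` and a
#' per-class weight `alpha`, down-weighting easy examples so training
#' concentrates on hard, low-confidence cases of the minority class.
#' For a hard target class `c` the loss is
#' `-alpha[c] * (1 - p[c])^gamma * log(p[c])`; for a soft target vector
#' `y` it is the y-weighted sum of the per-class terms, which reduces to
#' the hard form when `y` is one-hot and to smoothed cross-entropy when
#' `gamma = 0`.
#'
#' @param probs Length-K predicted class probability vector.
#' @param target Either a 0-based class index, or a length-K soft target
#'   vector (e.g. from [smooth_labels()]).
#' @param alpha Per-class weight vector (recycled if scalar). The
#'   default up-weights the medium-risk class (index 1) by 3.
#' @param gamma Focusing exponent, `>= 0`. `gamma = 0` recovers
#'   (weighted) cross-entropy.
#' @return Non-negative scalar loss.
#' @examples
#' focal_loss(c(0.5, 0.25, 0.25), target = 0, alpha = 1, gamma = 0) # log(2)
#' @export
focal_loss <- function(probs, target, alpha = c(1, 3, 1), gamma = 2) {
  .check_probs(probs)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  k <- length(probs)
  alpha <- rep_len(alpha, k)
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  p <- .clamp_probs(probs)
  per_class <- -alpha * (1 - p)^gamma * log(p)
  if (length(target) == 1L && target == floor(target)) {
    per_class[[as.integer(target) + 1L]]
  } else {
    if (length(target) != k) stop("soft target length mismatch", call. = FALSE)
    sum(target * per_class)
  }
}

#' Label smoothing
#'
#' Blends a one-hot target toward the uniform distribution:
#' `y' = (1 - epsilon) * y + epsilon / K`. Improves calibration and
#' guards against overfitting the few minority-class examples.
#'
#' @param onehot Length-K 0/1 indicator vector, or a 0-based class index
#'   with `K` taken from `k`.
#' @param epsilon Smoothing factor in `[0, 1)`.
#' @param k Class count when `onehot` is given as an index.
#' @return Length-K soft target vector summing to 1.
#' @export
smooth_labels <- function(onehot, epsilon = 0.1, k = NULL) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)", call. = FALSE)
  if (length(onehot) == 1L && !is.null(k)) {
    idx <- as.integer(onehot) + 1L
    onehot <- rep(0, k)
    onehot[idx] <- 1
  }
  if (!all(onehot %in% c(0, 1)) || sum(onehot) != 1) {
    stop("target must be one-hot", call. = FALSE)
  }
  (1 - epsilon) * onehot + epsilon / length(onehot)
}

#' Gaussian error linear unit
#'
#' `GELU(x) = x * Phi(x)` with `Phi` the standard normal CDF
#' (`approximate = FALSE`), or the tanh approximation
#' `0.5 * x * (1 + tanh(sqrt(2/pi) * (x + 0.044715 x^3)))`.
#' Smooth around zero, unlike ReLU's hard truncation.
#'
#' @param x Numeric vector/matrix.
#' @param approximate Use the tanh approximation.
#' @return Same shape as `x`.
#' @export
gelu <- function(x, approximate = FALSE) {
  if (approximate) {
    0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
  } else {
    x * stats::pnorm(x)
  }
}

# d/dx GELU(x), exact form: Phi(x) + x * phi(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Weighted cross-entropy
#'
#' `-w[c] * log(p[c])` for hard target class `c`; identical to
#' [focal_loss()] with `gamma = 0` and `alpha = weights`.
#'
#' @inheritParams focal_loss
#' @param weights Per-class positive weight vector (recycled if scalar).
#' @return Non-negative scalar loss.
#' @export
weighted_ce <- function(probs, target, weights = c(1, 3, 1)) {
  focal_loss(probs, target, alpha = weights, gamma = 0)
}

# Gradient of the (soft-target) focal loss w.r.t. the logits that
# produced `probs` via softmax. Used by the model backward passes.
# loss = sum_c y_c * f(p_c), f(p) = -alpha_c (1-p)^gamma log p
# df/dp = alpha_c [ gamma (1-p)^(gamma-1) log p - (1-p)^gamma / p ]
.focal_grad_logits <- function(probs, soft_target, alpha, gamma) {
  k <- length(probs)
  alpha <- rep_len(alpha, k)
  p <- .clamp_probs(probs)
  gpow <- if (gamma == 0) rep(0, k) else gamma * (1 - p)^(gamma - 1) * log(p)
  dldp <- soft_target * alpha * (gpow - (1 - p)^gamma / p)
  # chain through softmax: dL/dz_k = p_k * (dL/dp_k - sum_c dL/dp_c p_c)
  probs * (dldp - sum(dldp * probs))
}
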