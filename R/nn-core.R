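# Minimal dense-layer machinery shared by the MIL models: Xavier
# initialisation, stable softmax, dropout masks, and an Adam optimizer
# over flat named parameter lists. Gradients are hand-derived in each
# model file and validated against finite differences in the tests.

# Xavier/Glorot-normal weight matrix (fan_in x fan_out)
.init_w <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

.init_b <- function(fan_out) rep(0, fan_out)

# Row-stable softmax of a vector
.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Column-wise softmax of a matrix (each column a distribution over rows)
.softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Inverted-dropout mask: multiply activations by mask both forward and
# backward; eval mode uses mask = 1.
.dropout_mask <- function(dim_, rate, train) {
  if (!train || rate <= 0) return(1)
  array(stats::rbinom(prod(dim_), 1L, 1 - rate) / (1 - rate), dim = dim_)
}

# X %*% W + b for row-wise instances (b recycled across rows)
.affine <- function(x, w, b) sweep(x %*% w, 2L, b, "+")

# --- Adam -------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam update. `weight_decay` is an L2 term added to the gradient
# (classic Adam-with-regularisation). Returns list(params, state).
.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Elementwise sum of two same-shaped grad lists (NULL-safe)
.grad_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
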