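# Gated multi-head attention MIL with class-specific attention
# distributions, three-branch aggregation, and a bottleneck classifier
# with per-class (diagonal) readout.

#' ABMIL model configuration
#'
#' Defaults follow the published settings: 768-dim input features,
#' eight gated attention heads, a 256-dim attention space, 512-dim
#' per-head projection, and a 512-dim bottleneck ahead of the per-class
#' readout.
#'
#' @param input_dim Instance feature dimension D.
#' @param n_heads Parallel attention heads.
#' @param attn_space Attention-space width (tanh/gate branches).
#' @param head_dim Per-head linear projection width; `NULL` scores raw
#'   features directly.
#' @param n_classes Risk tiers K.
#' @param bottleneck Bottleneck width of the classifier.
#' @param merge `"mean"` averages per-head class scores;
#'   `"concat"` concatenates heads and remixes with a linear layer.
#' @return An `abmil_config` list.
#' @export
abmil_config <- function(input_dim = 768L, n_heads = 8L, attn_space = 256L,
                         head_dim = 512L, n_classes = 3L, bottleneck = 512L,
                         merge = c("mean", "concat")) {
  merge <- match.arg(merge)
  stopifnot(input_dim > 0, n_heads >= 1, attn_space > 0, n_classes >= 2,
            bottleneck > 0)
  structure(list(input_dim = as.integer(input_dim),
                 n_heads = as.integer(n_heads),
                 attn_space = as.integer(attn_space),
                 head_dim = if (is.null(head_dim)) NULL else
                   as.integer(head_dim),
                 n_classes = as.integer(n_classes),
                 bottleneck = as.integer(bottleneck), merge = merge),
            class = "abmil_config")
}

#' Initialise an ABMIL model
#'
#' @param config An [abmil_config()].
#' @param seed Integer seed.
#' @return A `mil_model` of kind `"abmil"`.
#' @export
abmil_init <- function(config = abmil_config(), seed = 1L) {
  set.seed(seed)
  d <- config$input_dim; a <- config$attn_space; k <- config$n_classes
  dh <- if (is.null(config$head_dim)) d else config$head_dim
  params <- list()
  for (h in seq_len(config$n_heads)) {
    pre <- paste0("h", h, "_")
    if (!is.null(config$head_dim)) {
      params[[paste0(pre, "P")]] <- .init_w(d, dh)
    }
    params[[paste0(pre, "A")]] <- .init_w(dh, a)
    params[[paste0(pre, "a")]] <- .init_b(a)
    params[[paste0(pre, "B")]] <- .init_w(dh, a)
    params[[paste0(pre, "b")]] <- .init_b(a)
    params[[paste0(pre, "C")]] <- .init_w(a, k)
    params[[paste0(pre, "c")]] <- .init_b(k)
  }
  if (config$merge == "concat") {
    params$Wmerge <- .init_w(config$n_heads * k, k)
    params$bmerge <- .init_b(k)
  }
  params$Wbot <- .init_w(d, config$bottleneck)
  params$bbot <- .init_b(config$bottleneck)
  params$R <- .init_w(config$bottleneck, k)
  params$d <- .init_b(k)
  structure(list(kind = "abmil", params = params, config = config),
            class = "mil_model")
}

#' Per-head gated class scores
#'
#' For one head: project instances (optional), `base = tanh(affine(x))`
#' in attention space, `gate = sigmoid(affine(x))`, elementwise product,
#' then a linear map to one score per risk class.
#'
#' @param x N x D (or N x head_dim) instance features.
#' @param head_params Named list with `A`, `a`, `B`, `b`, `C`, `c` and
#'   optionally `P`.
#' @return N x K score matrix.
#' @export
gated_head_scores <- function(x, head_params) {
  hp <- head_params
  xh <- if (!is.null(hp$P)) x %*% hp$P else x
  u <- tanh(.affine(xh, hp$A, hp$a))
  g <- .sigmoid(.affine(xh, hp$B, hp$b))
  .affine(u * g, hp$C, hp$c)
}

#' Merge per-head scores into class-specific attention
#'
#' Averages the heads' N x K score matrices elementwise (default merge),
#' then applies a column-wise softmax so each class's scores form a
#' distribution over the bag's instances.
#'
#' @param per_head_scores List (one per head) of N x K score matrices.
#' @param merge `"mean"` only; the concat merge is applied inside
#'   [abmil_forward()] where the remix weights live.
#' @return N x K `ClassAttention` matrix; every column sums to 1.
#' @export
class_attention <- function(per_head_scores, merge = "mean") {
  if (length(per_head_scores) == 0L) stop("no attention heads", call. = FALSE)
  s <- Reduce(`+`, per_head_scores) / length(per_head_scores)
  .softmax_cols(s)
}

#' Class-wise attention aggregation
#'
#' Branch `c` is the attention-weighted instance sum
#' `sum_i attn[i, c] * x[i, ]`, one bag-level vector per risk class.
#'
#' @param x N x D instance features.
#' @param attn N x K class-attention matrix.
#' @return K x D matrix of branch vectors.
#' @export
three_branch_aggregate <- function(x, attn) {
  stopifnot(nrow(x) == nrow(attn))
  crossprod(attn, x)
}

#' Classify aggregated branch vectors
#'
#' A shared bottleneck (GELU) maps each branch to `bottleneck` dims;
#' class `c`'s logit reads only its own branch's bottleneck output
#' (diagonal readout), respecting the class-specific nature of the
#' branches.
#'
#' @param branches K x D branch matrix.
#' @param params Model params (uses `Wbot`, `bbot`, `R`, `d`).
#' @return Length-K logits.
#' @export
abmil_classify <- function(branches, params) {
  bt <- gelu(.affine(branches, params$Wbot, params$bbot))
  rowSums(bt * t(params$R)) + params$d
}

.abmil_fwd <- function(params, config, x) {
  nh <- config$n_heads; k <- config$n_classes
  heads <- vector("list", nh)
  for (h in seq_len(nh)) {
    pre <- paste0("h", h, "_")
    hp <- list(P = params[[paste0(pre, "P")]],
               A = params[[paste0(pre, "A")]], a = params[[paste0(pre, "a")]],
               B = params[[paste0(pre, "B")]], b = params[[paste0(pre, "b")]],
               C = params[[paste0(pre, "C")]], c = params[[paste0(pre, "c")]])
    xh <- if (!is.null(hp$P)) x %*% hp$P else x
    za <- .affine(xh, hp$A, hp$a); u <- tanh(za)
    zb <- .affine(xh, hp$B, hp$b); g <- .sigmoid(zb)
    z <- u * g
    heads[[h]] <- list(hp = hp, xh = xh, u = u, g = g, z = z,
                       scores = .affine(z, hp$C, hp$c),
                       gate_mean = mean(g))
  }
  raw <- lapply(heads, `[[`, "scores")
  if (config$merge == "concat") {
    cat_scores <- do.call(cbind, raw)
    s <- .affine(cat_scores, params$Wmerge, params$bmerge)
    attn <- .softmax_cols(s)
  } else {
    s <- Reduce(`+`, raw) / length(raw)
    attn <- .softmax_cols(s)
  }
  v <- crossprod(attn, x)                       # K x D
  zbot <- .affine(v, params$Wbot, params$bbot)  # K x bottleneck
  bt <- gelu(zbot)
  logits <- rowSums(bt * t(params$R)) + params$d
  list(x = x, heads = heads, s = s, attn = attn, v = v, zbot = zbot,
       bt = bt, logits = logits, probs = .softmax(logits),
       gate_mean = mean(vapply(heads, `[[`, numeric(1), "gate_mean")))
}

#' Forward pass of the ABMIL model
#'
#' @param model A `mil_model` from [abmil_init()].
#' @param bag A [feature_bag()] or N x D matrix.
#' @param train Unused (the model has no stochastic layers); kept for
#'   interface symmetry.
#' @return List with `logits`, `probs`, `attention` (N x K matrix whose
#'   columns are instance distributions), `branches` (K x D), and
#'   `gate_mean` (mean sigmoid-gate activation, recorded as training
#'   telemetry).
#' @export
abmil_forward <- function(model, bag, train = FALSE) {
  x <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  if (ncol(x) != model$config$input_dim) {
    stop("bag dimension ", ncol(x), " does not match config input_dim ",
         model$config$input_dim, call. = FALSE)
  }
  f <- .abmil_fwd(model$params, model$config, x)
  list(logits = f$logits, probs = f$probs, attention = f$attn,
       branches = f$v, gate_mean = f$gate_mean)
}

.abmil_loss_grad <- function(model, x, tier, loss_spec, train = TRUE,
                             want_grads = TRUE) {
  p <- model$params; cfg <- model$config
  f <- .abmil_fwd(p, cfg, x)
  k <- cfg$n_classes
  y_soft <- smooth_labels(tier, epsilon = loss_spec$epsilon, k = k)
  loss <- focal_loss(f$probs, y_soft, alpha = loss_spec$alpha,
                     gamma = loss_spec$gamma)
  if (!want_grads) return(list(loss = loss, probs = f$probs,
                               gate_mean = f$gate_mean))
  dlogits <- .focal_grad_logits(f$probs, y_soft, loss_spec$alpha,
                                loss_spec$gamma)
  grads <- list()
  grads$R <- t(f$bt * dlogits)              # R[j, c] pairs with bt[c, j]
  grads$d <- dlogits
  dbt <- t(p$R) * dlogits                   # K x bottleneck
  dzbot <- dbt * .gelu_grad(f$zbot)
  grads$Wbot <- crossprod(f$v, dzbot)
  grads$bbot <- colSums(dzbot)
  dv <- dzbot %*% t(p$Wbot)                 # K x D
  dattn <- f$x %*% t(dv)                    # N x K
  # column-wise softmax backward
  ds <- f$attn * sweep(dattn, 2L, colSums(dattn * f$attn), "-")
  if (cfg$merge == "concat") {
    cat_scores <- do.call(cbind, lapply(f$heads, `[[`, "scores"))
    grads$Wmerge <- crossprod(cat_scores, ds)
    grads$bmerge <- colSums(ds)
    dcat <- ds %*% t(p$Wmerge)
    per_head_ds <- lapply(seq_len(cfg$n_heads), function(h) {
      dcat[, ((h - 1L) * k + 1L):(h * k), drop = FALSE]
    })
  } else {
    per_head_ds <- rep(list(ds / cfg$n_heads), cfg$n_heads)
  }
  for (h in seq_len(cfg$n_heads)) {
    pre <- paste0("h", h, "_")
    hd <- f$heads[[h]]
    dsh <- per_head_ds[[h]]
    grads[[paste0(pre, "C")]] <- crossprod(hd$z, dsh)
    grads[[paste0(pre, "c")]] <- colSums(dsh)
    dz <- dsh %*% t(hd$hp$C)
    du <- dz * hd$g; dg <- dz * hd$u
    dza <- du * (1 - hd$u^2); dzb <- dg * hd$g * (1 - hd$g)
    grads[[paste0(pre, "A")]] <- crossprod(hd$xh, dza)
    grads[[paste0(pre, "a")]] <- colSums(dza)
    grads[[paste0(pre, "B")]] <- crossprod(hd$xh, dzb)
    grads[[paste0(pre, "b")]] <- colSums(dzb)
    if (!is.null(hd$hp$P)) {
      dxh <- dza %*% t(hd$hp$A) + dzb %*% t(hd$hp$B)
      grads[[paste0(pre, "P")]] <- crossprod(f$x, dxh)
    }
  }
  list(loss = loss, probs = f$probs, grads = grads, gate_mean = f$gate_mean)
}
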