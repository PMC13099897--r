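# Attention-pooled slide embedding (stage 2) and gradient-boosted tree
# classification over a 23-dimensional enhanced feature vector
# (stage 3). The 23-feature order below is this package's normative
# definition, reconstructed to cover the named categories: MIL logits
# and probabilities, attention statistics, patch count, and
# distribution-level descriptors.

#' Attention-pool model configuration
#'
#' A plain tanh attention network (no gate) over instances; softmax
#' weights; the weighted instance sum `S = sum_i a_i x_i` is the slide
#' embedding, and a small linear head on `S` provides the MIL logits
#' used both for training (focal loss) and as boosted-head inputs.
#'
#' @param input_dim Instance feature dimension D.
#' @param attn_hidden Attention-network hidden width.
#' @param n_classes Risk tiers K.
#' @return A `pool_config` list.
#' @export
pool_config <- function(input_dim = 1024L, attn_hidden = 128L,
                        n_classes = 3L) {
  stopifnot(input_dim > 0, attn_hidden > 0, n_classes >= 2)
  structure(list(input_dim = as.integer(input_dim),
                 attn_hidden = as.integer(attn_hidden),
                 n_classes = as.integer(n_classes)),
            class = "pool_config")
}

#' Initialise the attention-pool model
#'
#' @param config A [pool_config()].
#' @param seed Integer seed.
#' @return A `mil_model` of kind `"attn_pool"`.
#' @export
pool_init <- function(config = pool_config(), seed = 1L) {
  set.seed(seed)
  d <- config$input_dim; a <- config$attn_hidden; k <- config$n_classes
  params <- list(Va = .init_w(d, a), ba = .init_b(a),
                 w = .init_w(a, 1L), cw = 0,
                 Wh = .init_w(d, k), bh = .init_b(k))
  structure(list(kind = "attn_pool", params = params, config = config),
            class = "mil_model")
}

.pool_fwd <- function(params, config, x) {
  u <- tanh(.affine(x, params$Va, params$ba))
  s <- as.numeric(u %*% params$w) + params$cw
  attn <- .softmax(s)
  emb <- as.numeric(crossprod(x, attn))
  logits <- as.numeric(emb %*% params$Wh) + params$bh
  list(x = x, u = u, s = s, attn = attn, emb = emb, logits = logits,
       probs = .softmax(logits))
}

#' Attention-pool a feature bag into a slide embedding
#'
#' @param model A `mil_model` from [pool_init()].
#' @param bag A [feature_bag()] or N x D matrix.
#' @return A `slide_embedding`: `S` (length-D), `attention` (list of
#'   `weights`, `raw_scores`), `mil_logits`, `mil_probs`, `n_patches`.
#' @export
attention_pool <- function(model, bag) {
  x <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  if (ncol(x) != model$config$input_dim) {
    stop("bag dimension ", ncol(x), " does not match config input_dim ",
         model$config$input_dim, call. = FALSE)
  }
  f <- .pool_fwd(model$params, model$config, x)
  structure(list(S = f$emb,
                 attention = list(weights = f$attn, raw_scores = f$s),
                 mil_logits = f$logits, mil_probs = f$probs,
                 n_patches = nrow(x)),
            class = "slide_embedding")
}

.pool_loss_grad <- function(model, x, tier, loss_spec, train = TRUE,
                            want_grads = TRUE) {
  p <- model$params; cfg <- model$config
  f <- .pool_fwd(p, cfg, x)
  y_soft <- smooth_labels(tier, epsilon = loss_spec$epsilon,
                          k = cfg$n_classes)
  loss <- focal_loss(f$probs, y_soft, alpha = loss_spec$alpha,
                     gamma = loss_spec$gamma)
  if (!want_grads) return(list(loss = loss, probs = f$probs))
  dlogits <- .focal_grad_logits(f$probs, y_soft, loss_spec$alpha,
                                loss_spec$gamma)
  grads <- list(Wh = outer(f$emb, dlogits), bh = dlogits)
  demb <- as.numeric(p$Wh %*% dlogits)
  da <- as.numeric(f$x %*% demb)
  ds <- f$attn * (da - sum(da * f$attn))
  grads$w <- crossprod(f$u, ds); grads$cw <- sum(ds)
  du <- outer(ds, as.numeric(p$w))
  dz <- du * (1 - f$u^2)
  grads$Va <- crossprod(f$x, dz); grads$ba <- colSums(dz)
  list(loss = loss, probs = f$probs, grads = grads)
}

# Gini coefficient of a nonnegative weight vector (0 for uniform)
.gini <- function(w) {
  n <- length(w)
  if (n == 1L) return(0)
  ws <- sort(w)
  sum((2 * seq_len(n) - n - 1) * ws) / (n * sum(ws))
}

#' Names of the 23 enhanced features, in order
#' @return Character vector of length 23.
#' @export
enhanced_feature_names <- function() {
  c("mil_logit_low", "mil_logit_med", "mil_logit_high",
    "mil_prob_low", "mil_prob_med", "mil_prob_high",
    "log1p_n_patches",
    "attn_mean", "attn_sd", "attn_min", "attn_max", "attn_median",
    "attn_entropy", "attn_entropy_norm", "attn_gini", "attn_top1",
    "attn_top5_mass",
    "attn_skewness", "attn_kurtosis_excess", "attn_q25", "attn_q75",
    "attn_iqr", "attn_frac_above_mean")
}

#' Compute the 23-dimensional enhanced feature vector
#'
#' Fixed-order summary of a slide embedding: the 3 MIL logits, 3 MIL
#' probabilities, `log(1 + N)`, ten attention-weight statistics (mean,
#' SD, min, max, median, Shannon entropy, entropy normalised by
#' `log(N)` — defined as 0 at N = 1 —, Gini coefficient, top-1 weight,
#' top-5 mass) and six distribution descriptors (skewness, excess
#' kurtosis, 25th/75th percentiles, IQR, fraction of weights above the
#' mean).
#'
#' @param emb A `slide_embedding` from [attention_pool()].
#' @return Named numeric vector of length 23.
#' @export
enhanced_features <- function(emb) {
  stopifnot(inherits(emb, "slide_embedding"))
  w <- emb$attention$weights
  n <- length(w)
  ent <- -sum(ifelse(w > 0, w * log(w), 0))
  mu <- mean(w); sdv <- if (n > 1L) stats::sd(w) else 0
  central <- w - mu
  skew <- if (sdv > 0) mean(central^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean(central^4) / sdv^4 - 3 else 0
  q <- stats::quantile(w, c(0.25, 0.75), names = FALSE)
  out <- c(emb$mil_logits, emb$mil_probs, log1p(emb$n_patches),
           mu, sdv, min(w), max(w), stats::median(w),
           ent, if (n > 1L) ent / log(n) else 0, .gini(w), max(w),
           sum(sort(w, decreasing = TRUE)[seq_len(min(5L, n))]),
           skew, kurt, q[1], q[2], q[2] - q[1], mean(w > mu))
  stats::setNames(out, enhanced_feature_names())
}

#' Build the enhanced-feature table for a set of bags
#'
#' @param model A trained attention-pool `mil_model`.
#' @param bags List of [feature_bag()]s.
#' @return Tibble with `case_id`, `tier` and the 23 named feature
#'   columns.
#' @export
enhanced_feature_table <- function(model, bags) {
  rows <- purrr::map(bags, function(b) {
    fv <- enhanced_features(attention_pool(model, b))
    dplyr::bind_cols(tibble::tibble(case_id = b$case_id, tier = b$tier),
                     tibble::as_tibble_row(as.list(fv)))
  })
  dplyr::bind_rows(rows)
}

#' Boosted-tree head configuration
#'
#' Defaults follow the published classifier settings: 200 trees,
#' learning rate 0.1, maximum depth 6. `reg_gamma` penalises each leaf
#' and `reg_lambda` the squared leaf weights, the usual tree-complexity
#' regulariser of gradient boosting.
#'
#' @param n_trees,learning_rate,max_depth,reg_gamma,reg_lambda See
#'   description.
#' @return A `boost_config` list.
#' @export
boost_config <- function(n_trees = 200L, learning_rate = 0.1,
                         max_depth = 6L, reg_gamma = 0, reg_lambda = 1) {
  stopifnot(n_trees >= 1, learning_rate > 0, max_depth >= 1,
            reg_gamma >= 0, reg_lambda >= 0)
  structure(list(n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 reg_gamma = reg_gamma, reg_lambda = reg_lambda),
            class = "boost_config")
}

#' Fit the boosted-tree classifier on enhanced features
#'
#' Multiclass gradient boosting with the softmax log-loss objective.
#'
#' @param features M x P numeric matrix or a tibble of feature columns
#'   (e.g. from [enhanced_feature_table()], minus id/label columns).
#' @param tiers Length-M labels in `{0, ..., K-1}`.
#' @param config A [boost_config()].
#' @param n_classes K.
#' @param seed Integer seed.
#' @return A `mil_boost` object wrapping the fitted booster.
#' @export
fit_boosted <- function(features, tiers, config = boost_config(),
                        n_classes = 3L, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (nrow(x) < n_classes) stop("need at least K training cases",
                                call. = FALSE)
  if (length(unique(tiers)) < n_classes) {
    stop("training data must contain every class", call. = FALSE)
  }
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(tiers))
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = n_classes,
                  eta = config$learning_rate, max_depth = config$max_depth,
                  gamma = config$reg_gamma, lambda = config$reg_lambda,
                  nthread = 1L, seed = seed),
    data = dtrain, nrounds = config$n_trees, verbose = 0
  )
  structure(list(booster = booster, n_classes = n_classes,
                 feature_names = colnames(x), config = config),
            class = "mil_boost")
}

#' Predict class probabilities from the boosted head
#'
#' @param object A `mil_boost`.
#' @param newdata M x P feature matrix/tibble.
#' @param ... Unused.
#' @return M x K matrix of class probabilities (rows sum to 1).
#' @export
predict.mil_boost <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  p <- predict(object$booster, xgboost::xgb.DMatrix(x))
  if (is.matrix(p)) unname(p) else
    matrix(p, ncol = object$n_classes, byrow = TRUE)
}

#' Per-feature gain importance of the boosted head
#'
#' @param model A `mil_boost` from [fit_boosted()].
#' @return Tibble with `feature` and `gain`, one row per training
#'   feature (zero for features never split on), sorted by gain.
#' @export
boosted_importance <- function(model) {
  stopifnot(inherits(model, "mil_boost"))
  imp <- xgboost::xgb.importance(model = model$booster)
  gain <- stats::setNames(rep(0, length(model$feature_names)),
                          model$feature_names)
  if (nrow(imp)) gain[imp$Feature] <- imp$Gain
  tibble::tibble(feature = names(gain), gain = unname(gain)) |>
    dplyr::arrange(dplyr::desc(.data$gain))
}
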