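# Patient-level stratified cross-validation, Adam training with linear
# learning-rate warmup and early stopping, metric computation, and
# per-fold aggregation.

#' Training configuration
#'
#' Published defaults for the CLAM-style model: Adam at lr 3e-5 with L2
#' coefficient 1e-4, up to 100 epochs with 5 linear-warmup epochs,
#' focal bag loss with medium-class weight 3 and label smoothing 0.1.
#' The ABMIL settings in the same study were lr 4e-4, up to 20 epochs,
#' weighted cross-entropy.
#'
#' @param lr Base learning rate.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param max_epochs Maximum training epochs.
#' @param warmup_epochs Linear warmup epochs (0 disables warmup).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping.
#' @param loss_kind One of `"focal"`, `"weighted_ce"`, `"ce_smoothed"`,
#'   `"ce"`.
#' @param alpha Per-class focal/CE weights.
#' @param gamma Focal focusing exponent.
#' @param epsilon Label-smoothing factor.
#' @param seed Integer seed for shuffling, dropout and initialisation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 3e-5, weight_decay = 1e-4, max_epochs = 100L,
                         warmup_epochs = 5L, early_stop_patience = 20L,
                         loss_kind = c("focal", "weighted_ce", "ce_smoothed",
                                       "ce"),
                         alpha = c(1, 3, 1), gamma = 2, epsilon = 0.1,
                         seed = 1L) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(lr > 0, warmup_epochs <= max_epochs)
  structure(list(lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 loss_kind = loss_kind, alpha = alpha, gamma = gamma,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

# Resolve the loss family into soft-target focal parameters.
.loss_spec <- function(config) {
  switch(config$loss_kind,
    focal = list(alpha = config$alpha, gamma = config$gamma,
                 epsilon = config$epsilon),
    weighted_ce = list(alpha = config$alpha, gamma = 0, epsilon = 0),
    ce_smoothed = list(alpha = 1, gamma = 0, epsilon = config$epsilon),
    ce = list(alpha = 1, gamma = 0, epsilon = 0)
  )
}

#' Learning rate at a given epoch
#'
#' Linear ramp from `lr / warmup_epochs` at epoch 0 up to the base rate
#' at epoch `warmup_epochs - 1`, constant thereafter.
#'
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return Scalar learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  w <- config$warmup_epochs
  if (w <= 0 || epoch >= w) config$lr else config$lr * (epoch + 1) / w
}

#' Patient-level stratified k-fold splits
#'
#' Cases are shuffled within each tier and dealt round-robin into the
#' folds, so every fold's class counts differ by at most one and no
#' case appears on both sides of any fold.
#'
#' @param cohort Tibble with `case_id` and `tier`.
#' @param k Number of folds.
#' @param seed Integer seed; same seed, same folds.
#' @param stratify_by_tier Stratify the deal by tier.
#' @return List of `k` splits, each `list(fold_id, train, val)` of
#'   case-id vectors.
#' @export
make_folds <- function(cohort, k = 5L, seed = 1L, stratify_by_tier = TRUE) {
  stopifnot(nrow(cohort) >= k)
  set.seed(seed)
  fold_of <- integer(nrow(cohort))
  if (stratify_by_tier) {
    if (any(table(cohort$tier) < 1L)) stop("empty class under stratification",
                                           call. = FALSE)
    for (tr in unique(cohort$tier)) {
      idx <- sample(which(cohort$tier == tr))
      fold_of[idx] <- (seq_along(idx) - 1L) %% k
    }
  } else {
    idx <- sample(nrow(cohort))
    fold_of[idx] <- (seq_along(idx) - 1L) %% k
  }
  lapply(0:(k - 1L), function(f) {
    list(fold_id = f,
         train = cohort$case_id[fold_of != f],
         val = cohort$case_id[fold_of == f])
  })
}

.model_loss_grad <- function(model, x, tier, loss_spec, train = TRUE,
                             want_grads = TRUE) {
  switch(model$kind,
    clam_sb = .clam_loss_grad(model, x, tier, loss_spec, train, want_grads),
    abmil = .abmil_loss_grad(model, x, tier, loss_spec, train, want_grads),
    attn_pool = .pool_loss_grad(model, x, tier, loss_spec, train, want_grads),
    stop("unknown model kind: ", model$kind, call. = FALSE)
  )
}

#' Initialise a MIL model by kind
#'
#' @param kind `"clam_sb"`, `"abmil"` or `"attn_pool"`.
#' @param input_dim Instance feature dimension of the bags.
#' @param seed Integer seed.
#' @param config Optional model config; when `NULL` the kind's default
#'   config is used with `input_dim` overridden.
#' @return A `mil_model`.
#' @export
mil_model_init <- function(kind, input_dim, seed = 1L, config = NULL) {
  if (is.null(config)) {
    config <- switch(kind,
      clam_sb = clam_config(input_dim = input_dim),
      abmil = abmil_config(input_dim = input_dim),
      attn_pool = pool_config(input_dim = input_dim),
      stop("unknown model kind: ", kind, call. = FALSE))
  }
  switch(kind,
    clam_sb = clam_init(config, seed),
    abmil = abmil_init(config, seed),
    attn_pool = pool_init(config, seed))
}

#' Forward probabilities of any MIL model
#'
#' @param model A `mil_model`.
#' @param bag A [feature_bag()] or feature matrix.
#' @return List with at least `logits`, `probs`.
#' @export
mil_forward <- function(model, bag) {
  switch(model$kind,
    clam_sb = clam_forward(model, bag),
    abmil = abmil_forward(model, bag),
    attn_pool = {
      emb <- attention_pool(model, bag)
      list(logits = emb$mil_logits, probs = emb$mil_probs,
           attention = emb$attention)
    },
    stop("unknown model kind: ", model$kind, call. = FALSE))
}

#' Train a MIL model on a patient-level split
#'
#' Per-bag Adam steps with linear warmup, L2 weight decay, and early
#' stopping on validation loss; the returned model carries the
#' best-validation-epoch parameters. Fully seeded: the same seed yields
#' an identical history.
#'
#' @param model A `mil_model` (or a kind string; then a default-config
#'   model is initialised from the bags' dimension).
#' @param bags Named list of [feature_bag()]s (names = case ids) with
#'   tiers set.
#' @param split `list(train, val)` of case-id vectors, e.g. one element
#'   of [make_folds()].
#' @param config A [train_config()].
#' @return A `mil_fit`: `model`, `history` tibble (epoch, lr, train
#'   loss/accuracy, validation loss/accuracy, mean gate activation for
#'   gated models), `best_epoch`, `config`.
#' @export
train_model <- function(model, bags, split, config = train_config()) {
  if (is.character(model)) {
    model <- mil_model_init(model, ncol(bags[[1]]$features),
                            seed = config$seed)
  }
  names(bags) <- vapply(bags, `[[`, character(1), "case_id")
  tr_bags <- bags[split$train]; va_bags <- bags[split$val]
  if (length(tr_bags) == 0L || length(va_bags) == 0L) {
    stop("empty train or validation split", call. = FALSE)
  }
  spec <- .loss_spec(config)
  set.seed(config$seed)
  state <- .adam_init(model$params)
  hist <- vector("list", config$max_epochs)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    lr_e <- lr_at_epoch(epoch - 1L, config)
    ord <- sample(length(tr_bags))
    tr_loss <- 0; tr_correct <- 0L; gate_acc <- c()
    for (i in ord) {
      b <- tr_bags[[i]]
      out <- .model_loss_grad(model, b$features, b$tier, spec, train = TRUE)
      if (!is.finite(out$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", case ",
             b$case_id, call. = FALSE)
      }
      upd <- .adam_step(model$params, out$grads, state, lr_e,
                        weight_decay = config$weight_decay)
      model$params <- upd$params; state <- upd$state
      tr_loss <- tr_loss + out$loss
      tr_correct <- tr_correct + (which.max(out$probs) - 1L == b$tier)
      if (!is.null(out$gate_mean)) gate_acc <- c(gate_acc, out$gate_mean)
    }
    va <- vapply(va_bags, function(b) {
      out <- .model_loss_grad(model, b$features, b$tier, spec,
                              train = FALSE, want_grads = FALSE)
      c(out$loss, which.max(out$probs) - 1L == b$tier)
    }, numeric(2))
    va_loss <- mean(va[1, ]); va_acc <- mean(va[2, ])
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr_e,
      train_loss = tr_loss / length(tr_bags),
      train_acc = tr_correct / length(tr_bags),
      val_loss = va_loss, val_acc = va_acc,
      gate_mean = if (length(gate_acc)) mean(gate_acc) else NA_real_)
    if (va_loss < best$loss - 1e-9) {
      best <- list(loss = va_loss, params = model$params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, config = config),
            class = "mil_fit")
}

#' Predict tier probabilities for a set of bags
#'
#' @param model A `mil_model` or `mil_fit`.
#' @param bags List of [feature_bag()]s.
#' @return Tibble with `case_id`, `tier`, probability columns
#'   `prob_0..prob_{K-1}`, and argmax `pred` (ties to the lowest
#'   class).
#' @export
predict_bags <- function(model, bags) {
  if (inherits(model, "mil_fit")) model <- model$model
  rows <- purrr::map(bags, function(b) {
    pr <- mil_forward(model, b)$probs
    out <- tibble::tibble(case_id = b$case_id, tier = b$tier)
    for (k in seq_along(pr)) out[[paste0("prob_", k - 1L)]] <- pr[k]
    out$pred <- which.max(pr) - 1L
    out
  })
  dplyr::bind_rows(rows)
}

# Rank-based one-vs-rest AUC via pROC with fixed direction.
.ovr_auc <- function(is_pos, score) {
  as.numeric(pROC::auc(pROC::roc(response = factor(is_pos,
                                                   levels = c(FALSE, TRUE)),
                                 predictor = score, quiet = TRUE,
                                 direction = "<")))
}

#' Compute a slide-level metrics report
#'
#' Accuracy, K x K confusion matrix, per-class precision/recall/F1 with
#' macro and support-weighted averages, and macro one-vs-rest
#' multiclass AUC of the predicted probabilities. F1 is defined as 0
#' when precision + recall is 0; a class absent from the truth is
#' excluded from the macro AUC with a warning.
#'
#' @param pred_probs M x K matrix of predicted probabilities (or a
#'   tibble from [predict_bags()], whose `prob_*` columns are used).
#' @param tiers Length-M true tiers in `{0, ..., K-1}` (defaults to the
#'   `tier` column when `pred_probs` is a prediction tibble).
#' @param n_classes K.
#' @return A `mil_metrics` object.
#' @export
evaluate <- function(pred_probs, tiers = NULL, n_classes = 3L) {
  if (is.data.frame(pred_probs)) {
    if (is.null(tiers)) tiers <- pred_probs$tier
    pred_probs <- as.matrix(
      pred_probs[, grep("^prob_", names(pred_probs)), drop = FALSE])
  }
  pred_probs <- as.matrix(pred_probs)
  stopifnot(nrow(pred_probs) == length(tiers),
            ncol(pred_probs) == n_classes)
  pred <- max.col(pred_probs, ties.method = "first") - 1L
  k <- n_classes
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(tiers)) {
    confusion[tiers[i] + 1L, pred[i] + 1L] <-
      confusion[tiers[i] + 1L, pred[i] + 1L] + 1L
  }
  support <- unname(rowSums(confusion))
  tp <- unname(diag(confusion))
  pred_n <- unname(colSums(confusion))
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  auc_per_class <- rep(NA_real_, k)
  for (c in seq_len(k)) {
    is_pos <- tiers == (c - 1L)
    if (any(is_pos) && !all(is_pos)) {
      auc_per_class[c] <- .ovr_auc(is_pos, pred_probs[, c])
    }
  }
  if (anyNA(auc_per_class)) {
    warning("class absent from truth; excluded from macro AUC",
            call. = FALSE)
  }
  w <- support / sum(support)
  structure(list(
    accuracy = sum(tp) / sum(support),
    confusion = confusion,
    per_class = tibble::tibble(class = 0:(k - 1), precision = precision,
                               recall = recall, f1 = f1,
                               support = as.integer(support),
                               auc = auc_per_class),
    macro_precision = mean(precision), macro_recall = mean(recall),
    macro_f1 = mean(f1),
    weighted_precision = sum(w * precision),
    weighted_recall = sum(w * recall), weighted_f1 = sum(w * f1),
    auc = mean(auc_per_class, na.rm = TRUE),
    n = length(tiers)), class = "mil_metrics")
}

#' @export
print.mil_metrics <- function(x, ...) {
  cat(sprintf("<mil_metrics> n = %d, accuracy = %.3f, macro F1 = %.3f, macro OvR AUC = %.3f\n",
              x$n, x$accuracy, x$macro_f1, x$auc))
  print(x$per_class)
  invisible(x)
}

#' Aggregate per-fold metric reports
#'
#' Arithmetic mean and sample SD (denominator n - 1) of each scalar
#' metric across folds.
#'
#' @param reports List of `mil_metrics` (>= 2).
#' @return Tibble with `metric`, `mean`, `sd`.
#' @export
aggregate_folds <- function(reports) {
  stopifnot(length(reports) >= 2L)
  scalars <- c("accuracy", "auc", "macro_precision", "macro_recall",
               "macro_f1", "weighted_precision", "weighted_recall",
               "weighted_f1")
  rows <- purrr::map(scalars, function(m) {
    v <- vapply(reports, `[[`, numeric(1), m)
    tibble::tibble(metric = m, mean = mean(v), sd = stats::sd(v))
  })
  dplyr::bind_rows(rows)
}

#' Majority-vote slide prediction from patch predictions
#'
#' The non-MIL baseline protocol: each slide's prediction is the modal
#' class of its patches' predictions; ties resolve to the lowest class
#' index.
#'
#' @param patch_preds List (one element per slide) of integer patch
#'   class predictions.
#' @return Integer vector of slide predictions.
#' @export
majority_vote_baseline <- function(patch_preds) {
  vapply(patch_preds, function(p) {
    if (length(p) == 0L) stop("slide with no patch predictions",
                              call. = FALSE)
    counts <- table(factor(p, levels = sort(unique(p))))
    as.integer(names(counts)[which.max(counts)])
  }, integer(1))
}

#' Non-MIL patch-classifier baseline on feature bags
#'
#' Trains a multinomial logistic patch classifier with every instance
#' inheriting its bag's tier, predicts each validation patch, and
#' majority-votes per slide — the conventional supervised baseline
#' without instance aggregation.
#'
#' @param train_bags,val_bags Lists of labeled [feature_bag()]s.
#' @param seed Integer seed.
#' @return Tibble with `case_id`, `tier`, `pred`, and per-class vote
#'   fractions `prob_0..prob_{K-1}`.
#' @export
patch_baseline <- function(train_bags, val_bags, seed = 1L) {
  set.seed(seed)
  xtr <- do.call(rbind, lapply(train_bags, `[[`, "features"))
  ytr <- factor(unlist(lapply(train_bags,
                              function(b) rep(b$tier, nrow(b$features)))),
                levels = 0:2)
  df <- as.data.frame(xtr); df$..y <- ytr
  fit <- nnet::multinom(..y ~ ., data = df, trace = FALSE,
                        MaxNWts = 100000L)
  rows <- purrr::map(val_bags, function(b) {
    nd <- as.data.frame(b$features)
    colnames(nd) <- colnames(df)[seq_len(ncol(b$features))]
    pp <- predict(fit, newdata = nd, type = "class")
    votes <- table(factor(pp, levels = 0:2)) / length(pp)
    out <- tibble::tibble(case_id = b$case_id, tier = b$tier,
                          pred = majority_vote_baseline(
                            list(as.integer(as.character(pp)))))
    for (k in 0:2) out[[paste0("prob_", k)]] <- as.numeric(votes[k + 1L])
    out
  })
  dplyr::bind_rows(rows)
}

#' Cross-validated training and evaluation
#'
#' Runs [train_model()] (or the patch baseline, or the attention-pool +
#' boosted-tree pipeline) on each fold and evaluates on that fold's
#' held-out cases.
#'
#' @param bags List of labeled [feature_bag()]s.
#' @param folds Folds from [make_folds()].
#' @param kind `"clam_sb"`, `"abmil"`, `"attn_pool"`, `"milboost"` or
#'   `"baseline"`.
#' @param config A [train_config()] (ignored by `"baseline"`).
#' @param model_config Optional model config overriding the kind's
#'   default.
#' @param boost_cfg A [boost_config()] for the `"milboost"` kind.
#' @return A `mil_cv`: `fold_metrics` (list of `mil_metrics`),
#'   `summary` tibble from [aggregate_folds()], `predictions` tibble
#'   with a `fold` column, `fits` (per-fold fitted objects), `kind`.
#' @export
run_cv <- function(bags, folds, kind = "clam_sb", config = train_config(),
                   model_config = NULL, boost_cfg = boost_config()) {
  names(bags) <- vapply(bags, `[[`, character(1), "case_id")
  fold_metrics <- list(); preds <- list(); fits <- list()
  for (fs in folds) {
    f <- fs$fold_id
    fold_seed <- config$seed + 1000L * (f + 1L)
    if (kind == "baseline") {
      pred <- patch_baseline(bags[fs$train], bags[fs$val], seed = fold_seed)
      fits[[f + 1L]] <- NULL
    } else if (kind == "milboost") {
      pool_fit <- train_model(
        mil_model_init("attn_pool", ncol(bags[[1]]$features),
                       seed = fold_seed, config = model_config),
        bags, fs, config = .with_seed_cfg(config, fold_seed))
      feats_tr <- enhanced_feature_table(pool_fit$model, bags[fs$train])
      feats_va <- enhanced_feature_table(pool_fit$model, bags[fs$val])
      fcols <- enhanced_feature_names()
      booster <- fit_boosted(feats_tr[, fcols], feats_tr$tier,
                             config = boost_cfg, seed = fold_seed)
      pp <- predict(booster, feats_va[, fcols])
      pred <- tibble::tibble(case_id = feats_va$case_id,
                             tier = feats_va$tier)
      for (k in seq_len(ncol(pp))) pred[[paste0("prob_", k - 1L)]] <- pp[, k]
      pred$pred <- max.col(pp, ties.method = "first") - 1L
      fits[[f + 1L]] <- list(pool = pool_fit, booster = booster)
    } else {
      fit <- train_model(
        mil_model_init(kind, ncol(bags[[1]]$features), seed = fold_seed,
                       config = model_config),
        bags, fs, config = .with_seed_cfg(config, fold_seed))
      pred <- predict_bags(fit, bags[fs$val])
      fits[[f + 1L]] <- fit
    }
    pred$fold <- f
    preds[[f + 1L]] <- pred
    fold_metrics[[f + 1L]] <- evaluate(pred)
  }
  structure(list(fold_metrics = fold_metrics,
                 summary = aggregate_folds(fold_metrics),
                 predictions = dplyr::bind_rows(preds),
                 fits = fits, kind = kind),
            class = "mil_cv")
}

.with_seed_cfg <- function(config, seed) {
  config$seed <- as.integer(seed %% .Machine$integer.max)
  config
}

#' @export
print.mil_cv <- function(x, ...) {
  cat(sprintf("<mil_cv> %s, %d folds\n", x$kind, length(x$fold_metrics)))
  print(x$summary)
  invisible(x)
}
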