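# broom-style tidiers and ggplot2 autoplot methods for the fitted
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report into a per-class tibble
#'
#' @param x A `mil_metrics` from [evaluate()].
#' @param ... Unused.
#' @return Tibble with one row per class: precision, recall, F1,
#'   support, one-vs-rest AUC.
#' @method tidy mil_metrics
#' @export
tidy.mil_metrics <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @inheritParams tidy.mil_metrics
#' @return One-row tibble: accuracy, macro/weighted precision, recall
#'   and F1, macro one-vs-rest AUC, n.
#' @method glance mil_metrics
#' @export
glance.mil_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 weighted_precision = x$weighted_precision,
                 weighted_recall = x$weighted_recall,
                 weighted_f1 = x$weighted_f1, n = x$n)
}

#' Tidy a cross-validation run into per-fold metrics
#'
#' @param x A `mil_cv` from [run_cv()].
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy mil_cv
#' @export
tidy.mil_cv <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$fold_metrics, function(m, i) {
    dplyr::bind_cols(tibble::tibble(fold = i - 1L), glance(m))
  }))
}

#' Mean +/- SD summary of a cross-validation run
#'
#' @inheritParams tidy.mil_cv
#' @return Tibble with `metric`, `mean`, `sd` across folds.
#' @method glance mil_cv
#' @export
glance.mil_cv <- function(x, ...) x$summary

#' Tidy a fitted model's training history
#'
#' @param x A `mil_fit` from [train_model()].
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @method tidy mil_fit
#' @export
tidy.mil_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @inheritParams tidy.mil_fit
#' @return One-row tibble: kind, best epoch, best validation loss and
#'   accuracy, epochs run.
#' @method glance mil_fit
#' @export
glance.mil_fit <- function(x, ...) {
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(kind = x$model$kind, best_epoch = x$best_epoch,
                 val_loss = best$val_loss, val_acc = best$val_acc,
                 epochs_run = nrow(x$history))
}

#' Plot training curves
#'
#' Train/validation loss and accuracy per epoch.
#'
#' @param object A `mil_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mil_fit
#' @export
autoplot.mil_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "train_acc",
                          "val_acc"),
                        names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion-matrix heat map
#'
#' @param object A `mil_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mil_metrics
#' @export
autoplot.mil_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted tier", y = "true tier") +
    ggplot2::theme_minimal()
}

#' Plot per-fold metrics of a cross-validation run
#'
#' @param object A `mil_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mil_cv
#' @export
autoplot.mil_cv <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("accuracy", "auc", "macro_f1"),
                        names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}
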