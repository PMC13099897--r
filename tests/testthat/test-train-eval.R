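test_that("warmup ramps linearly then holds the base rate", {
  cfg <- train_config(lr = 3e-5, warmup_epochs = 5L)
  expect_equal(lr_at_epoch(0, cfg), 3e-5 / 5)
  expect_equal(lr_at_epoch(2, cfg), 3e-5 * 3 / 5)
  expect_equal(lr_at_epoch(5, cfg), 3e-5)
  expect_equal(lr_at_epoch(50, cfg), 3e-5)
  cfg0 <- train_config(lr = 1e-3, warmup_epochs = 0L)
  expect_equal(lr_at_epoch(0, cfg0), 1e-3)
})

test_that("folds are patient-disjoint, exhaustive, stratified, deterministic", {
  gen <- generate_bags(synth_bag_config(n_cases = 210L, seed = 2L,
                                        bag_size_range = c(1L, 2L)))
  cohort <- gen$truth[, c("case_id", "tier")]
  folds <- make_folds(cohort, k = 5L, seed = 4L)
  all_val <- unlist(lapply(folds, `[[`, "val"))
  expect_setequal(all_val, cohort$case_id)
  expect_false(any(duplicated(all_val)))
  for (fs in folds) {
    expect_length(intersect(fs$train, fs$val), 0L)
    med <- sum(cohort$tier[cohort$case_id %in% fs$val] == 1L)
    expect_true(med %in% 4:5)  # 21 medium cases dealt across 5 folds
  }
  expect_identical(folds, make_folds(cohort, k = 5L, seed = 4L))
  ten <- make_folds(cohort[1:10, ], k = 5L, stratify_by_tier = FALSE)
  expect_true(all(vapply(ten, function(f) length(f$val), integer(1)) == 2L))
})

test_that("evaluate matches a brute-force counting oracle on random sets", {
  set.seed(6)
  for (rep in 1:5) {
    m <- 40L
    tiers <- sample(0:2, m, replace = TRUE)
    probs <- matrix(rexp(m * 3), m, 3)
    probs <- probs / rowSums(probs)
    rep_ <- evaluate(probs, tiers)
    pred <- max.col(probs, ties.method = "first") - 1L
    for (c in 0:2) {
      tp <- sum(pred == c & tiers == c)
      prec <- if (sum(pred == c) > 0) tp / sum(pred == c) else 0
      rec <- if (sum(tiers == c) > 0) tp / sum(tiers == c) else 0
      expect_equal(rep_$per_class$precision[c + 1], prec)
      expect_equal(rep_$per_class$recall[c + 1], rec)
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      expect_equal(rep_$per_class$f1[c + 1], f1)
      # independent rank-statistic AUC oracle
      expect_equal(rep_$per_class$auc[c + 1],
                   wilcoxon_auc(tiers == c, probs[, c + 1]),
                   tolerance = 1e-9)
    }
    expect_equal(rep_$accuracy, mean(pred == tiers))
    expect_equal(rep_$macro_f1, mean(rep_$per_class$f1))
    expect_equal(sum(rep_$confusion), m)
    expect_equal(rowSums(rep_$confusion), table(factor(tiers, 0:2)),
                 ignore_attr = TRUE)
  }
})

test_that("perfect predictions score 1 and label shuffles score about 0.5", {
  tiers <- rep(0:2, each = 10)
  probs <- matrix(0.001, 30, 3)
  probs[cbind(1:30, tiers + 1L)] <- 0.998
  perfect <- evaluate(probs, tiers)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$per_class$f1, rep(1, 3))
  set.seed(15)
  null_auc <- evaluate(probs, sample(tiers))$auc
  expect_lt(abs(null_auc - 0.5), 0.15)
  # class absent from truth is excluded with a warning
  expect_warning(two <- evaluate(probs[1:20, ], tiers[1:20]), "absent")
  expect_true(is.na(two$per_class$auc[3]))
})

test_that("fold aggregation reproduces direct arithmetic", {
  mk <- function(acc, auc) {
    r <- list(accuracy = acc, auc = auc, macro_precision = 0,
              macro_recall = 0, macro_f1 = 0, weighted_precision = 0,
              weighted_recall = 0, weighted_f1 = 0)
    class(r) <- "mil_metrics"
    r
  }
  reports <- Map(mk, c(0.714, 0.810, 0.667, 0.810, 0.810),
                 c(0.774, 0.939, 0.679, 0.929, 0.952))
  agg <- aggregate_folds(reports)
  expect_equal(agg$mean[agg$metric == "auc"],
               mean(c(0.774, 0.939, 0.679, 0.929, 0.952)))
  expect_equal(agg$sd[agg$metric == "accuracy"],
               sd(c(0.714, 0.810, 0.667, 0.810, 0.810)))
  same <- aggregate_folds(list(mk(0.7, 0.8), mk(0.7, 0.8)))
  expect_equal(same$sd, rep(0, nrow(same)))
  expect_error(aggregate_folds(list(mk(1, 1))), "2")
})

test_that("majority voting takes the modal class with ties to the lowest", {
  expect_identical(majority_vote_baseline(list(c(0L, 0L, 1L))), 0L)
  expect_identical(majority_vote_baseline(list(c(0L, 1L))), 0L)
  expect_identical(majority_vote_baseline(list(c(2L, 2L, 2L))), 2L)
  expect_identical(majority_vote_baseline(list(c(1L, 2L, 2L, 1L))), 1L)
  expect_error(majority_vote_baseline(list(integer(0))), "no patch")
})

test_that("training is seeded, improves on separable bags, and early-stops", {
  bags <- tiny_bags(n_bags = 14L, dim = 8L, effect = 3, seed = 77L)
  ids <- vapply(bags, `[[`, character(1), "case_id")
  split <- list(train = ids[1:10], val = ids[11:14])
  mcfg <- clam_config(input_dim = 8L, encoder_hidden = 16L,
                      attn_hidden = 8L, cls_hidden = 8L, dropout = 0.1,
                      k_sample = 3L)
  cfg <- train_config(lr = 2e-3, max_epochs = 25L, warmup_epochs = 2L,
                      early_stop_patience = 25L, seed = 5L)
  fit <- train_model(clam_init(mcfg, seed = 5L), bags, split, cfg)
  expect_s3_class(fit, "mil_fit")
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_gte(dplyr::last(fit$history$train_acc), 0.95)
  # determinism: same seed, identical history
  fit2 <- train_model(clam_init(mcfg, seed = 5L), bags, split, cfg)
  expect_identical(fit$history, fit2$history)
  # three-epoch smoke run has history length 3
  cfg3 <- train_config(lr = 1e-3, max_epochs = 3L, warmup_epochs = 1L,
                       early_stop_patience = 10L, seed = 1L)
  fit3 <- train_model("clam_sb", bags, split, cfg3)
  expect_equal(nrow(fit3$history), 3L)
  expect_error(train_model("clam_sb", bags,
                           list(train = character(0), val = ids[1]), cfg3),
               "empty train")
})

test_that("abmil training records gate-openness telemetry", {
  bags <- tiny_bags(n_bags = 8L, dim = 8L, seed = 31L)
  ids <- vapply(bags, `[[`, character(1), "case_id")
  split <- list(train = ids[1:6], val = ids[7:8])
  mcfg <- abmil_config(input_dim = 8L, n_heads = 2L, attn_space = 4L,
                       head_dim = 6L, bottleneck = 6L)
  cfg <- train_config(lr = 1e-3, max_epochs = 3L, warmup_epochs = 1L,
                      loss_kind = "weighted_ce", seed = 2L)
  fit <- train_model(abmil_init(mcfg, seed = 2L), bags, split, cfg)
  expect_true(all(!is.na(fit$history$gate_mean)))
  expect_true(all(fit$history$gate_mean > 0 & fit$history$gate_mean < 1))
})

test_that("tidiers expose per-fold, per-class and history views", {
  bags <- tiny_bags(n_bags = 10L, dim = 8L, seed = 19L)
  cohort <- tibble::tibble(
    case_id = vapply(bags, `[[`, character(1), "case_id"),
    tier = vapply(bags, `[[`, integer(1), "tier"))
  folds <- make_folds(cohort, k = 2L, seed = 3L)
  mcfg <- clam_config(input_dim = 8L, encoder_hidden = 12L,
                      attn_hidden = 6L, cls_hidden = 6L, dropout = 0)
  cfg <- train_config(lr = 1e-3, max_epochs = 2L, warmup_epochs = 1L,
                      seed = 4L)
  cv <- suppressWarnings(run_cv(bags, folds, "clam_sb", cfg,
                                model_config = mcfg))
  expect_s3_class(cv, "mil_cv")
  td <- tidy(cv)
  expect_equal(nrow(td), 2L)
  expect_true(all(c("fold", "accuracy", "auc") %in% names(td)))
  gl <- glance(cv)
  expect_true(all(c("metric", "mean", "sd") %in% names(gl)))
  fit <- cv$fits[[1]]
  expect_equal(tidy(fit), fit$history)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
  m <- cv$fold_metrics[[1]]
  expect_equal(tidy(m), m$per_class)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(cv), "ggplot")
})
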