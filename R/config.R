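# Unified configuration and the staged pipeline runner.

#' Default pipeline configuration
#'
#' Nested configuration tree with one section per stage. Model and
#' training defaults follow the published settings (see
#' [train_config()], [clam_config()], [abmil_config()]); preprocessing
#' and synthetic-data defaults follow the package's documented choices.
#'
#' @return Named list of sections: `seed`, `output_dir`, `preprocess`,
#'   `encoder`, `model`, `train`, `boost`, `heatmap`, `synth`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "wsimil_run",
    preprocess = list(target_downsample = 32, blur_sigma = 2,
                      use_morph_gradient = TRUE, close_radius = 2,
                      min_region_area = 1000, min_hole_area = 500,
                      patch_size = 256, tissue_coverage_min = 0.5),
    encoder = list(kind = "seeded_projection", dim = 64, batch_size = 32),
    model = list(kind = "clam_sb", encoder_hidden = 512, attn_hidden = 384,
                 cls_hidden = 256, dropout = 0.4, k_sample = 8,
                 bag_weight = 0.5, n_heads = 8, attn_space = 256,
                 head_dim = 512, bottleneck = 512),
    train = list(lr = 3e-5, weight_decay = 1e-4, max_epochs = 100,
                 warmup_epochs = 5, early_stop_patience = 20,
                 loss_kind = "focal", alpha = c(1, 3, 1), gamma = 2,
                 epsilon = 0.1, folds = 5),
    boost = list(n_trees = 200, learning_rate = 0.1, max_depth = 6,
                 reg_gamma = 0, reg_lambda = 1),
    heatmap = list(render_downsample = 32, smoothing_sigma = 16,
                   interpolation = FALSE, overlay_alpha = 0.4),
    synth = list(n_cases = 210, class_priors = c(0.45, 0.10, 0.45),
                 dim = 64, bag_size_range = c(30, 80),
                 signal_fraction = 0.3, effect_size = 2, noise_sd = 1)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop("configuration key ", here, " must be a section", call. = FALSE)
      }
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      if (is.numeric(defaults[[nm]]) && !is.numeric(user[[nm]])) {
        stop("configuration key ", here, " must be numeric", call. = FALSE)
      }
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Starts from [default_run_config()], overlays the YAML file (if any),
#' then the override list; unknown keys are rejected by name.
#'
#' @param config_file Optional YAML file path.
#' @param overrides Optional named (possibly nested) list of overrides,
#'   e.g. `list(train = list(lr = 1e-4))`.
#' @return Validated configuration list.
#' @export
parse_and_validate <- function(config_file = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(config_file)) {
    user <- yaml::read_yaml(config_file)
    if (length(user)) cfg <- .merge_config(cfg, user)
  }
  if (length(overrides)) cfg <- .merge_config(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Stage seed derived from the global seed and the stage name, kept
# within 32-bit integer range so each stage is independently seeded.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run pipeline stages in workflow order
#'
#' Stages: `segment` and `patch` operate on a generated toy slide,
#' `featurize` encodes its patch grid with the configured stub encoder,
#' `synth` generates the synthetic cohort of feature bags, `train`
#' cross-validates the configured model on them, `eval` writes the
#' aggregated metric summary, `heatmap` renders the trained model's
#' attention over the toy slide. Completed stages (their outputs
#' already present) are skipped unless `force = TRUE`.
#'
#' @param stages Character subset of
#'   `c("segment", "patch", "featurize", "synth", "train", "eval",
#'   "heatmap")`.
#' @param config Configuration from [parse_and_validate()].
#' @param force Re-run stages whose outputs already exist.
#' @return Named list of per-stage outputs (paths and key objects),
#'   invisibly.
#' @export
run_pipeline <- function(stages, config = parse_and_validate(),
                         force = FALSE) {
  order_ <- c("segment", "patch", "featurize", "synth", "train", "eval",
              "heatmap")
  stages <- order_[order_ %in% stages]
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  res <- list()
  done <- function(...) file.exists(file.path(out_dir, ...))
  pp <- config$preprocess
  seg_params <- segmentation_params(
    target_downsample = pp$target_downsample, blur_sigma = pp$blur_sigma,
    use_morph_gradient = pp$use_morph_gradient,
    close_radius = pp$close_radius, min_region_area = pp$min_region_area,
    min_hole_area = pp$min_hole_area, patch_size = pp$patch_size,
    tissue_coverage_min = pp$tissue_coverage_min)

  toy <- NULL; mask <- NULL; grid <- NULL; toy_bag <- NULL
  need_toy <- any(c("segment", "patch", "featurize", "heatmap") %in% stages)
  if (need_toy) {
    toy <- generate_toy_slide(width = 768L, height = 768L,
                              seed = .stage_seed(config$seed, "segment"))
  }
  if ("segment" %in% stages) {
    # toy slides are segmented at native resolution
    small_params <- seg_params
    small_params$min_region_area <- 200
    small_params$min_hole_area <- 100
    small_params$patch_size <- 128L
    mask <- segment_tissue(toy$image, small_params, downsample = 1)
    if (!done("qc_overlay.png") || force) {
      png::writePNG(render_qc_overlay(toy$image, mask),
                    file.path(out_dir, "qc_overlay.png"))
    } else message("segment: outputs exist, skipping write")
    res$segment <- list(mask = mask, qc = file.path(out_dir,
                                                    "qc_overlay.png"))
  }
  if ("patch" %in% stages) {
    if (is.null(mask)) stop("patch stage requires the segment stage",
                            call. = FALSE)
    small_params <- seg_params
    small_params$patch_size <- 128L
    grid <- extract_patch_grid(mask, small_params)
    utils::write.csv(data.frame(x = grid$coords[, 1], y = grid$coords[, 2]),
                     file.path(out_dir, "patch_grid.csv"),
                     row.names = FALSE)
    res$patch <- list(grid = grid,
                      path = file.path(out_dir, "patch_grid.csv"))
  }
  if ("featurize" %in% stages) {
    if (is.null(grid)) stop("featurize stage requires the patch stage",
                            call. = FALSE)
    enc <- make_stub_encoder(config$encoder$kind,
                             output_dim = config$encoder$dim,
                             seed = .stage_seed(config$seed, "featurize"))
    toy_bag <- encode_slide(toy$image, grid, enc,
                            batch_size = config$encoder$batch_size,
                            case_id = "toy_slide")
    write_bag(toy_bag, file.path(out_dir, "toy_slide.bag.rds"))
    res$featurize <- list(bag = toy_bag,
                          path = file.path(out_dir, "toy_slide.bag.rds"))
  }
  gen <- NULL
  if (any(c("synth", "train", "eval") %in% stages)) {
    sy <- config$synth
    gen <- generate_bags(synth_bag_config(
      n_cases = sy$n_cases, class_priors = sy$class_priors, dim = sy$dim,
      bag_size_range = sy$bag_size_range,
      signal_fraction = sy$signal_fraction, effect_size = sy$effect_size,
      noise_sd = sy$noise_sd, seed = .stage_seed(config$seed, "synth")))
    if ("synth" %in% stages) {
      utils::write.csv(gen$truth, file.path(out_dir, "synth_truth.csv"),
                       row.names = FALSE)
      res$synth <- list(truth = gen$truth,
                        path = file.path(out_dir, "synth_truth.csv"))
    }
  }
  cv <- NULL
  if ("train" %in% stages) {
    if (done("fold_metrics.csv") && !force) {
      message("train: outputs exist, skipping")
    } else {
      tr <- config$train
      tcfg <- train_config(lr = tr$lr, weight_decay = tr$weight_decay,
                           max_epochs = tr$max_epochs,
                           warmup_epochs = tr$warmup_epochs,
                           early_stop_patience = tr$early_stop_patience,
                           loss_kind = tr$loss_kind, alpha = tr$alpha,
                           gamma = tr$gamma, epsilon = tr$epsilon,
                           seed = .stage_seed(config$seed, "train"))
      cohort <- gen$truth[, c("case_id", "tier")]
      folds <- make_folds(cohort, k = tr$folds, seed = tcfg$seed)
      mcfg <- .model_config_from(config$model, config$synth$dim)
      cv <- run_cv(gen$bags, folds, kind = config$model$kind,
                   config = tcfg, model_config = mcfg,
                   boost_cfg = boost_config(
                     n_trees = config$boost$n_trees,
                     learning_rate = config$boost$learning_rate,
                     max_depth = config$boost$max_depth,
                     reg_gamma = config$boost$reg_gamma,
                     reg_lambda = config$boost$reg_lambda))
      fold_rows <- purrr::imap(cv$fold_metrics, function(m, i) {
        tibble::tibble(fold = i - 1L, accuracy = m$accuracy, auc = m$auc,
                       macro_f1 = m$macro_f1)
      })
      utils::write.csv(dplyr::bind_rows(fold_rows),
                       file.path(out_dir, "fold_metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(cv$predictions,
                       file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
      res$train <- list(cv = cv,
                        path = file.path(out_dir, "fold_metrics.csv"))
    }
  }
  if ("eval" %in% stages) {
    if (is.null(cv)) stop("eval stage requires the train stage",
                          call. = FALSE)
    utils::write.csv(cv$summary, file.path(out_dir, "metrics_summary.csv"),
                     row.names = FALSE)
    res$eval <- list(summary = cv$summary,
                     path = file.path(out_dir, "metrics_summary.csv"))
  }
  if ("heatmap" %in% stages) {
    if (is.null(cv) || is.null(toy_bag)) {
      stop("heatmap stage requires the train and featurize stages ",
           "(no trained checkpoint or featurized slide present)",
           call. = FALSE)
    }
    fit <- cv$fits[[1]]
    model <- if (inherits(fit, "mil_fit")) fit$model else fit$pool$model
    # score the toy-slide bag with a model of matching input dim
    scores <- if (ncol(toy_bag$features) == model$config$input_dim) {
      fw <- mil_forward(model, toy_bag)
      if (is.matrix(fw$attention)) fw$attention[, 1] else
        fw$attention$weights
    } else {
      rep(1 / nrow(toy_bag$features), nrow(toy_bag$features))
    }
    hm <- config$heatmap
    hp <- heatmap_params(render_downsample = hm$render_downsample,
                         smoothing_sigma = hm$smoothing_sigma,
                         interpolation = hm$interpolation,
                         overlay_alpha = hm$overlay_alpha)
    hp$render_downsample <- 4  # toy slides are small
    save_heatmap_png(scores, toy_bag$coords, toy_bag$patch_size,
                     toy$image, file.path(out_dir, "heatmap.png"), hp)
    res$heatmap <- list(path = file.path(out_dir, "heatmap.png"))
  }
  invisible(res)
}

.model_config_from <- function(mc, input_dim) {
  switch(mc$kind,
    clam_sb = clam_config(input_dim = input_dim,
                          encoder_hidden = mc$encoder_hidden,
                          attn_hidden = mc$attn_hidden,
                          cls_hidden = mc$cls_hidden,
                          dropout = mc$dropout, k_sample = mc$k_sample,
                          bag_weight = mc$bag_weight),
    abmil = abmil_config(input_dim = input_dim, n_heads = mc$n_heads,
                         attn_space = mc$attn_space,
                         head_dim = mc$head_dim,
                         bottleneck = mc$bottleneck),
    attn_pool = pool_config(input_dim = input_dim),
    milboost = NULL,
    baseline = NULL)
}
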