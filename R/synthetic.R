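# Synthetic data with the statistical structure the MIL models assume:
# class-conditional instance bags with a controllable signal fraction,
# the study cohort's class imbalance, and toy stained-slide images for
# the segmentation tests.

#' Synthetic bag generator configuration
#'
#' Defaults emulate the study cohort: 210 cases with tier priors
#' (0.45, 0.10, 0.45) — under stratified sampling exactly 21 of 210
#' cases are medium tier — bags of 30--80 instances, 30% of a bag's
#' instances carrying the class signal at effect size 2 against
#' unit-variance isotropic Gaussian noise.
#'
#' @param n_cases Number of cases.
#' @param class_priors Length-3 tier simplex.
#' @param dim Feature dimension D.
#' @param bag_size_range `(min, max)` instances per bag.
#' @param signal_fraction Fraction of signal instances per bag.
#' @param effect_size Distance of each class mean from the origin.
#' @param noise_sd Instance noise SD.
#' @param grey_zone_medium Place the medium-tier mean on the segment
#'   between the low and high means (mimics the intermediate "grey
#'   zone" biology) instead of an orthogonal direction.
#' @param seed Integer seed.
#' @return A `synth_bag_config` list.
#' @export
synth_bag_config <- function(n_cases = 210L,
                             class_priors = c(0.45, 0.10, 0.45),
                             dim = 64L, bag_size_range = c(30L, 80L),
                             signal_fraction = 0.3, effect_size = 2,
                             noise_sd = 1, grey_zone_medium = FALSE,
                             seed = 1L) {
  stopifnot(abs(sum(class_priors) - 1) < 1e-8, all(class_priors >= 0),
            signal_fraction >= 0, signal_fraction <= 1,
            bag_size_range[1] >= 1, bag_size_range[2] >= bag_size_range[1],
            dim >= 3)
  structure(list(n_cases = as.integer(n_cases),
                 class_priors = class_priors, dim = as.integer(dim),
                 bag_size_range = as.integer(bag_size_range),
                 signal_fraction = signal_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 grey_zone_medium = grey_zone_medium,
                 seed = as.integer(seed)),
            class = "synth_bag_config")
}

# Fixed orthogonal unit class directions via seeded QR.
.class_directions <- function(dim, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(dim * 3L), dim, 3L)))
}

#' Generate synthetic feature bags
#'
#' Tiers are assigned by stratified allocation (largest-remainder on
#' `n_cases * class_priors`, so integral expected counts are exact).
#' Each bag draws its size uniformly from the configured range;
#' background instances are `N(0, noise_sd^2 I)` and signal instances
#' `N(mu_c, noise_sd^2 I)` with `mu_c = effect_size * u_c` for fixed
#' orthogonal unit directions `u_c` (equal pairwise class separation).
#' Grid coordinates are assigned row-major as if patches tiled a slide.
#'
#' @param config A [synth_bag_config()].
#' @return List with `bags` (list of [feature_bag()]s) and `truth`
#'   (tibble: `case_id`, `tier`, `n_instances`, `n_signal`).
#' @export
generate_bags <- function(config = synth_bag_config()) {
  set.seed(config$seed)
  u <- .class_directions(config$dim, config$seed)
  mu <- config$effect_size * u
  if (config$grey_zone_medium) mu[, 2] <- (mu[, 1] + mu[, 3]) / 2
  # largest-remainder stratified tier counts
  raw <- config$n_cases * config$class_priors
  counts <- floor(raw)
  rem <- config$n_cases - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  tiers <- sample(rep(0:2, counts))
  bags <- vector("list", config$n_cases)
  truth <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    n <- sample(config$bag_size_range[1]:config$bag_size_range[2], 1L)
    n_sig <- round(config$signal_fraction * n)
    x <- matrix(stats::rnorm(n * config$dim, sd = config$noise_sd),
                n, config$dim)
    if (n_sig > 0) {
      sig_idx <- sample(n, n_sig)
      x[sig_idx, ] <- x[sig_idx, ] +
        matrix(mu[, tiers[i] + 1L], n_sig, config$dim, byrow = TRUE)
    }
    ncol_grid <- ceiling(sqrt(n))
    coords <- cbind(((seq_len(n) - 1L) %% ncol_grid) * 256L,
                    ((seq_len(n) - 1L) %/% ncol_grid) * 256L)
    case_id <- sprintf("case_%03d", i)
    bags[[i]] <- feature_bag(x, coords, case_id, tiers[i],
                             encoder_name = "synthetic")
    truth[[i]] <- tibble::tibble(case_id = case_id, tier = tiers[i],
                                 n_instances = n, n_signal = n_sig)
  }
  list(bags = bags, truth = dplyr::bind_rows(truth))
}

#' Generate a toy stained-slide image
#'
#' Saturated ellipses ("tissue") on a near-white background with
#' optional sub-threshold random specks (staining artifacts). Returns
#' the exact ground-truth foreground mask for segmentation tests.
#'
#' @param width,height Image dims in pixels (>= 64).
#' @param ellipses List of `list(center = c(x, y), axes = c(a, b),
#'   color = c(r, g, b))` in pixel units.
#' @param background Background RGB (near-white by default).
#' @param artifact_specks Number of small random specks to scatter.
#' @param speck_radius Speck radius in px (kept small so area stays
#'   below any sensible minimum-region threshold).
#' @param seed Integer seed for the specks.
#' @return List with `image` (`h x w x 3` in `[0, 1]`) and `mask`
#'   (logical `h x w` ellipse-foreground mask, excluding specks).
#' @export
generate_toy_slide <- function(width = 512L, height = 512L,
                               ellipses = list(list(center = c(256, 256),
                                                    axes = c(140, 90),
                                                    color = c(0.75, 0.35,
                                                              0.55))),
                               background = c(0.97, 0.96, 0.97),
                               artifact_specks = 0L, speck_radius = 2L,
                               seed = 1L) {
  stopifnot(width >= 64, height >= 64)
  set.seed(seed)
  img <- array(rep(background, each = height * width),
               dim = c(height, width, 3L))
  # mild background noise so the image is not constant
  img <- pmin(pmax(img + array(stats::rnorm(length(img), sd = 0.004),
                               dim = dim(img)), 0), 1)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  mask <- matrix(FALSE, height, width)
  for (e in ellipses) {
    inside <- ((xs - e$center[1]) / e$axes[1])^2 +
      ((ys - e$center[2]) / e$axes[2])^2 <= 1
    mask <- mask | inside
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[inside] <- e$color[ch]
      img[, , ch] <- layer
    }
  }
  if (artifact_specks > 0) {
    for (s in seq_len(artifact_specks)) {
      cx <- sample(seq(speck_radius + 1L, width - speck_radius), 1L)
      cy <- sample(seq(speck_radius + 1L, height - speck_radius), 1L)
      inside <- (xs - cx)^2 + (ys - cy)^2 <= speck_radius^2
      inside <- inside & !mask
      col <- c(0.45, 0.3, 0.5)
      for (ch in 1:3) {
        layer <- img[, , ch]
        layer[inside] <- col[ch]
        img[, , ch] <- layer
      }
    }
  }
  list(image = img, mask = mask)
}

#' Linear-probe sanity check of the bag generator
#'
#' Cross-validated macro one-vs-rest AUC of a multinomial logistic
#' model on per-bag mean-pooled features — a generator health check:
#' near 0.5 at zero effect size, near 1 for well-separated classes.
#'
#' @param bags List of labeled [feature_bag()]s.
#' @param k Folds.
#' @param seed Integer seed.
#' @return Scalar macro one-vs-rest AUC.
#' @export
linear_probe_sanity <- function(bags, k = 5L, seed = 1L) {
  tiers <- vapply(bags, `[[`, integer(1), "tier")
  if (length(unique(tiers)) < 2L) stop("need at least two classes",
                                       call. = FALSE)
  pooled <- t(vapply(bags, function(b) colMeans(b$features),
                     numeric(ncol(bags[[1]]$features))))
  cohort <- tibble::tibble(case_id = vapply(bags, `[[`, character(1),
                                            "case_id"),
                           tier = tiers)
  folds <- make_folds(cohort, k = k, seed = seed)
  probs <- matrix(NA_real_, length(bags), 3L)
  rownames(pooled) <- cohort$case_id
  for (fs in folds) {
    tr <- match(fs$train, cohort$case_id)
    va <- match(fs$val, cohort$case_id)
    df <- as.data.frame(pooled[tr, , drop = FALSE])
    df$..y <- factor(tiers[tr], levels = 0:2)
    fit <- nnet::multinom(..y ~ ., data = df, trace = FALSE,
                          MaxNWts = 100000L)
    nd <- as.data.frame(pooled[va, , drop = FALSE])
    pp <- predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pp))) pp <- matrix(pp, nrow = 1L)
    probs[va, ] <- pp
  }
  aucs <- vapply(0:2, function(c) {
    pos <- tiers == c
    if (!any(pos) || all(pos)) return(NA_real_)
    .ovr_auc(pos, probs[, c + 1L])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}
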