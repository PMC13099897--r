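# Shared fixtures and independent oracles used across the suite.

# Tiny labeled bags for fast model tests.
tiny_bags <- function(n_bags = 12L, dim = 8L, n_min = 4L, n_max = 9L,
                      effect = 2.5, seed = 42L) {
  gen <- generate_bags(synth_bag_config(
    n_cases = n_bags, class_priors = c(0.4, 0.2, 0.4), dim = dim,
    bag_size_range = c(n_min, n_max), signal_fraction = 0.5,
    effect_size = effect, seed = seed))
  gen$bags
}

# Central-difference gradient of a scalar loss over a flat param list.
num_grad <- function(loss_fn, params, eps = 1e-5) {
  g <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g[[nm]][i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }
  }
  g
}

max_rel_err <- function(analytic, numeric_) {
  worst <- 0
  for (nm in names(analytic)) {
    a <- as.numeric(analytic[[nm]]); n <- as.numeric(numeric_[[nm]])
    worst <- max(worst, max(abs(a - n) / pmax(abs(a) + abs(n), 1e-8)))
  }
  worst
}

# Exhaustive 256-threshold Otsu oracle: maximise between-class variance
# by explicit loop.
brute_otsu <- function(v, n_bins = 256L) {
  bins <- pmin(pmax(floor(as.numeric(v) * n_bins) + 1L, 1L), n_bins)
  h <- tabulate(bins, nbins = n_bins)
  best <- -1; best_t <- 0L
  for (t in seq_len(n_bins - 1L)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 > 0 && w1 > 0) {
      m0 <- sum(h[1:t] * (1:t)) / w0
      m1 <- sum(h[(t + 1L):n_bins] * ((t + 1L):n_bins)) / w1
      s <- w0 * w1 * (m0 - m1)^2
      if (s > best) { best <- s; best_t <- t }
    }
  }
  best_t / n_bins
}

# Rank-statistic (Wilcoxon) one-vs-rest AUC oracle.
wilcoxon_auc <- function(is_pos, score) {
  r <- rank(score)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
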