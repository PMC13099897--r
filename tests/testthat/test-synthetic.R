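test_that("stratified generation reproduces the cohort's imbalance exactly", {
  gen <- generate_bags(synth_bag_config(n_cases = 210L, seed = 3L,
                                        bag_size_range = c(2L, 4L)))
  counts <- as.integer(table(factor(gen$truth$tier, 0:2)))
  expect_equal(sum(counts), 210L)
  expect_equal(counts[2], 21L)  # 10% medium tier, exactly 21 of 210
  expect_lte(abs(counts[1] - counts[3]), 1L)  # largest-remainder balance
})

test_that("bags are reproducible under a fixed seed and respect the config", {
  cfg <- synth_bag_config(n_cases = 12L, dim = 16L,
                          bag_size_range = c(5L, 9L), seed = 8L)
  g1 <- generate_bags(cfg)
  g2 <- generate_bags(cfg)
  for (i in seq_along(g1$bags)) {
    expect_identical(g1$bags[[i]]$features, g2$bags[[i]]$features)
    expect_identical(g1$bags[[i]]$coords, g2$bags[[i]]$coords)
  }
  sizes <- vapply(g1$bags, function(b) nrow(b$features), integer(1))
  expect_true(all(sizes >= 5 & sizes <= 9))
  expect_true(all(vapply(g1$bags, function(b) ncol(b$features),
                         integer(1)) == 16L))
  expect_error(generate_bags(synth_bag_config(class_priors = c(1, 1, 1))),
               "sum")
})

test_that("signal instances are centred on their class mean", {
  cfg <- synth_bag_config(n_cases = 60L, dim = 32L, signal_fraction = 0.5,
                          effect_size = 2, bag_size_range = c(40L, 60L),
                          seed = 21L)
  gen <- generate_bags(cfg)
  u <- wsimil:::.class_directions(32L, 21L)
  # pooled projection of class-2 bags onto u_2: background instances
  # contribute 0, signal instances effect_size; the bag mean projection
  # is signal_fraction * effect_size
  idx2 <- which(gen$truth$tier == 2L)
  proj <- vapply(gen$bags[idx2],
                 function(b) mean(b$features %*% u[, 3]), numeric(1))
  n_inst <- sum(gen$truth$n_instances[idx2])
  se <- 1 / sqrt(n_inst)  # unit noise variance
  expect_lt(abs(mean(proj) - 0.5 * 2), 3 * se + 0.02)
})

test_that("zero signal fraction removes all class structure", {
  cfg <- synth_bag_config(n_cases = 45L, dim = 16L, signal_fraction = 0,
                          bag_size_range = c(10L, 20L), seed = 5L)
  gen <- generate_bags(cfg)
  auc <- linear_probe_sanity(gen$bags, seed = 2L)
  expect_lt(abs(auc - 0.5), 0.12)
})

test_that("linear probe confirms separability at large effect size", {
  cfg <- synth_bag_config(n_cases = 45L, dim = 16L, signal_fraction = 0.5,
                          effect_size = 3, bag_size_range = c(20L, 30L),
                          seed = 6L)
  auc <- linear_probe_sanity(generate_bags(cfg)$bags, seed = 2L)
  expect_gte(auc, 0.95)
  one_class <- generate_bags(synth_bag_config(
    n_cases = 5L, class_priors = c(1, 0, 0), seed = 1L,
    bag_size_range = c(3L, 4L)))
  expect_error(linear_probe_sanity(one_class$bags), "two classes")
})

test_that("grey-zone mode puts the medium mean between the extremes", {
  cfg <- synth_bag_config(n_cases = 30L, dim = 16L, signal_fraction = 1,
                          effect_size = 4, bag_size_range = c(30L, 30L),
                          grey_zone_medium = TRUE, seed = 9L)
  gen <- generate_bags(cfg)
  mu_hat <- vapply(0:2, function(tr) {
    rows <- do.call(rbind, lapply(gen$bags[gen$truth$tier == tr],
                                  `[[`, "features"))
    colMeans(rows)
  }, numeric(16L))
  expect_lt(sqrt(sum((mu_hat[, 2] - (mu_hat[, 1] + mu_hat[, 3]) / 2)^2)),
            1)
})

test_that("toy slides expose exact ground truth and reproducible specks", {
  zero <- generate_toy_slide(width = 64L, height = 64L, ellipses = list(),
                             seed = 1L)
  expect_identical(sum(zero$mask), 0L)
  one <- generate_toy_slide(width = 256L, height = 256L,
                            ellipses = list(list(center = c(128, 128),
                                                 axes = c(60, 40),
                                                 color = c(0.7, 0.3, 0.5))),
                            seed = 1L)
  expect_lt(abs(sum(one$mask) - pi * 60 * 40) / (pi * 60 * 40), 0.02)
  s1 <- generate_toy_slide(width = 128L, height = 128L,
                           artifact_specks = 6L, seed = 4L)
  s2 <- generate_toy_slide(width = 128L, height = 128L,
                           artifact_specks = 6L, seed = 4L)
  expect_identical(s1$image, s2$image)
})
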