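test_that("feature_bag validates its invariants", {
  x <- matrix(rnorm(12), 4, 3)
  co <- cbind(c(0L, 256L, 0L, 256L), c(0L, 0L, 256L, 256L))
  b <- feature_bag(x, co, "c1", 1L)
  expect_s3_class(b, "feature_bag")
  expect_identical(dim(b), c(4L, 3L))
  expect_error(feature_bag(x[0, , drop = FALSE], co[0, , drop = FALSE],
                           "c1"), "at least one instance")
  expect_error(feature_bag(x, co[1:2, ], "c1"), "row-aligned")
  xbad <- x; xbad[1] <- NA
  expect_error(feature_bag(xbad, co, "c1"), "finite")
  expect_error(feature_bag(x, co, "c1", tier = 5L), "tier")
})

test_that("bag containers round-trip losslessly over random shapes", {
  set.seed(10)
  for (shape in list(c(10L, 8L), c(1L, 1L), c(3L, 17L))) {
    x <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    co <- cbind(seq_len(shape[1]) * 256L, rep(0L, shape[1]))
    b <- feature_bag(x, co, "case", tier = 2L, encoder_name = "enc",
                     patch_size = 256L, level = 0L)
    path <- withr::local_tempfile(fileext = ".bag.rds")
    write_bag(b, path)
    back <- read_bag(path)
    # single-precision payload is bitwise stable across a second cycle
    expect_identical(back$coords, b$coords)
    expect_identical(back$case_id, b$case_id)
    expect_identical(back$tier, b$tier)
    expect_equal(back$features, b$features, tolerance = 1e-6)
    path2 <- withr::local_tempfile(fileext = ".bag.rds")
    write_bag(back, path2)
    expect_identical(read_bag(path2)$features, back$features)
  }
})

test_that("reading a malformed container is a schema error", {
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(schema = "wsimil-bag/1", coords = cbind(0L, 0L)), path)
  expect_error(read_bag(path), "missing schema or datasets")
  saveRDS(list(foo = 1), path)
  expect_error(read_bag(path), "not a wsimil bag")
})

test_that("stub encoders are deterministic and seed-sensitive", {
  patch_a <- array(0.3, dim = c(16, 16, 3))
  patch_b <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  e1 <- make_stub_encoder("seeded_projection", output_dim = 7L, seed = 5L)
  e2 <- make_stub_encoder("seeded_projection", output_dim = 7L, seed = 5L)
  e3 <- make_stub_encoder("seeded_projection", output_dim = 7L, seed = 6L)
  small_a <- EBImage::resize(patch_a, w = 32, h = 32)
  f1 <- e1$encode(list(patch_a, patch_b))
  expect_identical(f1, e2$encode(list(patch_a, patch_b)))
  expect_false(isTRUE(all.equal(f1, e3$encode(list(patch_a, patch_b)))))
  # constant-colour patch under identity_stats reports that colour
  id <- make_stub_encoder("identity_stats", output_dim = 8L)
  f <- id$encode(list(array(rep(c(0.2, 0.5, 0.9), each = 256),
                            dim = c(16, 16, 3))))
  expect_equal(as.numeric(f[1, 1:3]), c(0.2, 0.5, 0.9), tolerance = 1e-12)
  expect_error(make_stub_encoder("bogus"), "arg")
})

test_that("encode_slide reproduces pixel statistics and ignores batching", {
  toy <- generate_toy_slide(width = 256L, height = 256L, seed = 13L)
  grid <- structure(list(coords = cbind(c(0L, 128L, 0L, 128L),
                                        c(0L, 0L, 128L, 128L)),
                         patch_size = 128L, level = 0L),
                    class = "patch_grid")
  enc <- make_stub_encoder("identity_stats", output_dim = 8L,
                           expected_input = 128L)
  bag <- encode_slide(toy$image, grid, enc, batch_size = 3L, case_id = "t")
  expect_identical(dim(bag$features), c(4L, 8L))
  for (i in 1:4) {
    x <- grid$coords[i, 1]; y <- grid$coords[i, 2]
    px <- toy$image[(y + 1):(y + 128), (x + 1):(x + 128), , drop = FALSE]
    expect_equal(as.numeric(bag$features[i, 1:3]), apply(px, 3, mean),
                 tolerance = 1e-10)
  }
  # row order is a function of grid order, not batch partitioning
  bag1 <- encode_slide(toy$image, grid, enc, batch_size = 1L)
  bag4 <- encode_slide(toy$image, grid, enc, batch_size = 4L)
  expect_identical(bag1$features, bag4$features)
  # single-patch grid
  g1 <- grid; g1$coords <- grid$coords[1, , drop = FALSE]
  expect_identical(nrow(encode_slide(toy$image, g1, enc)$features), 1L)
  # out-of-bounds patch names its coordinate
  gbad <- grid; gbad$coords[1, ] <- c(200L, 200L)
  expect_error(encode_slide(toy$image, gbad, enc), "200")
})

test_that("write_bag_set writes one container per case plus a manifest", {
  bags <- tiny_bags(n_bags = 3L)
  dir <- withr::local_tempdir()
  manifest <- write_bag_set(bags, dir)
  expect_equal(nrow(manifest), 3L)
  expect_true(all(file.exists(manifest$path)))
  expect_true(file.exists(file.path(dir, "bags.csv")))
  back <- read_bag(manifest$path[2])
  expect_equal(back$features, bags[[2]]$features, tolerance = 1e-6)
})
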