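small_params <- segmentation_params(min_region_area = 200,
                                    min_hole_area = 100,
                                    patch_size = 128L,
                                    tissue_coverage_min = 0.5)

test_that("select_level picks the highest level within the target", {
  expect_identical(select_level(c(1, 4, 16, 64), 32), 2L)
  expect_identical(select_level(c(1), 32), 0L)
  expect_identical(select_level(c(1, 2, 4), 1), 0L)
  expect_identical(select_level(c(1, 4), 100), 1L)  # clamp to coarsest
  expect_error(select_level(numeric(0), 32), "empty pyramid")
})

test_that("otsu_threshold equals the exhaustive between-class-variance search", {
  set.seed(99)
  for (i in 1:20) {
    # bimodal synthetic saturation images of varying separation
    lo <- rbeta(400, 2, sample(6:14, 1))
    hi <- rbeta(sample(100:500, 1), sample(5:9, 1), 2)
    v <- matrix(c(lo, hi)[seq_len(400)], 20, 20)
    expect_equal(otsu_threshold(v), brute_otsu(v), tolerance = 1e-12)
  }
})

test_that("segmentation recovers a saturated ellipse on white background", {
  toy <- generate_toy_slide(width = 512L, height = 512L,
                            artifact_specks = 4L, seed = 3L)
  mask <- segment_tissue(toy$image, small_params, downsample = 1)
  iou <- sum(mask$mask & toy$mask) / sum(mask$mask | toy$mask)
  expect_gte(iou, 0.95)
  # determinism
  mask2 <- segment_tissue(toy$image, small_params, downsample = 1)
  expect_identical(mask$mask, mask2$mask)
})

test_that("a constant white image yields an empty mask with a warning", {
  img <- array(1, dim = c(128, 128, 3))
  expect_warning(mask <- segment_tissue(img, small_params, downsample = 1),
                 "degenerate")
  expect_identical(sum(mask$mask), 0L)
  expect_error(segment_tissue(matrix(1, 10, 10), small_params), "RGB")
})

test_that("with the gradient term off the threshold is plain Otsu on blurred S", {
  toy <- generate_toy_slide(width = 256L, height = 256L, seed = 8L)
  p <- small_params
  p$use_morph_gradient <- FALSE
  blurred <- pmin(pmax(EBImage::gblur(toy$image, sigma = p$blur_sigma), 0), 1)
  px <- rbind(as.vector(blurred[, , 1]), as.vector(blurred[, , 2]),
              as.vector(blurred[, , 3]))
  s <- matrix(grDevices::rgb2hsv(px, maxColorValue = 1)[2L, ], 256, 256)
  thr <- brute_otsu(s)
  raw <- s > thr  # before morphology, the thresholded S channel
  mask <- segment_tissue(toy$image, p, downsample = 1)
  # the package's pre-morphology binarisation must agree with the oracle
  # threshold: check via the reconstructed threshold itself
  expect_equal(otsu_threshold(s), thr, tolerance = 1e-12)
  # and the final mask stays close to the raw thresholding (morphology
  # only cleans small structures on this clean fixture)
  expect_gt(sum(mask$mask & raw) / sum(mask$mask | raw), 0.9)
})

test_that("patch grid keeps exactly the sufficiently covered footprints", {
  full <- structure(list(mask = matrix(TRUE, 512, 512), downsample = 1,
                         slide_dims_level0 = c(width = 512, height = 512)),
                    class = "tissue_mask")
  p <- small_params; p$patch_size <- 256L
  g <- extract_patch_grid(full, p)
  expect_equal(g$coords[order(g$coords[, 2], g$coords[, 1]), ],
               rbind(c(0L, 0L), c(256L, 0L), c(0L, 256L), c(256L, 256L)))

  empty <- full; empty$mask <- matrix(FALSE, 512, 512)
  expect_equal(nrow(extract_patch_grid(empty, p)$coords), 0L)

  half <- full; half$mask <- cbind(matrix(TRUE, 512, 256),
                                   matrix(FALSE, 512, 256))
  gh <- extract_patch_grid(half, p)
  expect_equal(sort(gh$coords[, 1]), c(0L, 0L))  # only left column kept
  # brute-force per-patch coverage agrees
  for (i in seq_len(nrow(gh$coords))) {
    x <- gh$coords[i, 1]; y <- gh$coords[i, 2]
    cov <- mean(half$mask[(y + 1):(y + 256), (x + 1):(x + 256)])
    expect_gte(cov, 0.5)
  }
})

test_that("patch footprints are disjoint, in-bounds, and coverage is monotone", {
  toy <- generate_toy_slide(width = 640L, height = 512L, seed = 21L)
  mask <- segment_tissue(toy$image, small_params, downsample = 1)
  p_strict <- small_params; p_strict$tissue_coverage_min <- 0.7
  p_loose <- small_params; p_loose$tissue_coverage_min <- 0.2
  g_strict <- extract_patch_grid(mask, p_strict)
  g_loose <- extract_patch_grid(mask, p_loose)
  key <- function(g) paste(g$coords[, 1], g$coords[, 2])
  expect_true(all(key(g_strict) %in% key(g_loose)))
  g <- g_loose
  expect_false(any(duplicated(key(g))))
  expect_true(all(g$coords[, 1] %% g$patch_size == 0))
  expect_true(all(g$coords[, 1] + g$patch_size <= 640))
  expect_true(all(g$coords[, 2] + g$patch_size <= 512))
})

test_that("QC overlay keeps dims and draws patch boxes", {
  toy <- generate_toy_slide(width = 256L, height = 256L, seed = 4L)
  mask <- segment_tissue(toy$image, small_params, downsample = 1)
  grid <- extract_patch_grid(mask, small_params)
  ov <- render_qc_overlay(toy$image, mask, grid)
  expect_identical(dim(ov), dim(toy$image))
  # pure-blue box pixels appear iff the grid is nonempty
  blue <- ov[, , 3] == 1 & ov[, , 1] == 0 & ov[, , 2] == 0
  if (nrow(grid$coords) > 0) expect_gt(sum(blue), 0)
  ov0 <- render_qc_overlay(toy$image, mask, NULL)
  expect_identical(dim(ov0), dim(toy$image))
})
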