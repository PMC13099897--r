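# Tissue segmentation and patch-grid extraction. Slides enter as plain
# RGB rasters (h x w x 3 arrays in [0, 1]); a pyramidal reader is only
# needed upstream to produce the working-level raster.

#' Segmentation parameters
#'
#' @param target_downsample Working-level downsample to aim for
#'   (default 32x vs level 0).
#' @param blur_sigma Gaussian blur SD in pixels at the working level.
#' @param use_morph_gradient Add the morphological gradient of the
#'   saturation channel before thresholding (boosts boundary
#'   saturation); disable to get a plain Otsu pipeline.
#' @param grad_radius Elliptical structuring-element radius for the
#'   gradient.
#' @param close_radius Structuring-element radius for morphological
#'   closing.
#' @param min_region_area Connected components smaller than this (px^2
#'   at the working level) are dropped as artifacts.
#' @param min_hole_area Holes smaller than this are filled.
#' @param patch_size Patch edge length in level-0 pixels.
#' @param tissue_coverage_min Minimum fraction of a patch footprint that
#'   must be tissue for the patch to be kept.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(target_downsample = 32, blur_sigma = 2,
                                use_morph_gradient = TRUE, grad_radius = 2L,
                                close_radius = 2L, min_region_area = 1000,
                                min_hole_area = 500, patch_size = 256L,
                                tissue_coverage_min = 0.5) {
  stopifnot(patch_size > 0, tissue_coverage_min >= 0, tissue_coverage_min <= 1,
            target_downsample > 0)
  structure(list(target_downsample = target_downsample,
                 blur_sigma = blur_sigma,
                 use_morph_gradient = use_morph_gradient,
                 grad_radius = as.integer(grad_radius),
                 close_radius = as.integer(close_radius),
                 min_region_area = min_region_area,
                 min_hole_area = min_hole_area,
                 patch_size = as.integer(patch_size),
                 tissue_coverage_min = tissue_coverage_min),
            class = "segmentation_params")
}

#' Pick the pyramid level closest to a target downsample
#'
#' Returns the highest (most downsampled) level whose downsample does
#' not exceed the target, clamped to the coarsest available level —
#' the standard best-level-for-downsample rule of pyramidal readers.
#'
#' @param pyramid_downsamples Ascending per-level downsample factors,
#'   first equal to 1.
#' @param target_downsample Desired downsample.
#' @return 0-based level index.
#' @export
select_level <- function(pyramid_downsamples, target_downsample) {
  if (length(pyramid_downsamples) == 0L) stop("empty pyramid", call. = FALSE)
  ok <- which(pyramid_downsamples <= target_downsample)
  if (length(ok) == 0L) return(0L)
  as.integer(max(ok) - 1L)
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive maximisation of between-class variance over a 256-bin
#' histogram of values in `[0, 1]`. Returns the threshold as the upper
#' edge of the chosen bin; pixels strictly above it are foreground.
#'
#' @param v Numeric vector/matrix of values in `[0, 1]`.
#' @param n_bins Histogram resolution.
#' @return Scalar threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  bin <- pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins)
  h <- tabulate(bin, nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)                       # class-0 mass at threshold t
  mu <- cumsum(p * seq_len(n_bins))        # first moment
  mu_t <- mu[n_bins]
  # between-class variance for thresholds after bins 1..(n_bins-1)
  t <- seq_len(n_bins - 1L)
  denom <- omega[t] * (1 - omega[t])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[t] - mu[t])^2 / denom, 0)
  best <- which.max(sigma_b)
  best / n_bins
}

# Morphological gradient (dilation - erosion) with an elliptical kernel
.morph_gradient <- function(img, radius) {
  k <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::dilate(img, k) - EBImage::erode(img, k)
}

#' Segment tissue from slide background
#'
#' Pipeline: Gaussian blur, RGB to HSV, saturation channel (optionally
#' enhanced with its morphological gradient), Otsu threshold,
#' morphological closing, removal of small components, filling of small
#' holes. The saturation channel separates stained tissue from the
#' near-achromatic glass background.
#'
#' @param image_rgb Working-level RGB raster (`h x w x 3`, values in
#'   `[0, 1]`).
#' @param params A [segmentation_params()].
#' @param downsample Downsample factor of `image_rgb` relative to
#'   level 0 (recorded in the mask).
#' @return A `tissue_mask` object: binary `mask` matrix (`h x w`),
#'   `downsample`, and `slide_dims_level0` as `(width, height)`.
#' @export
segment_tissue <- function(image_rgb, params = segmentation_params(),
                           downsample = params$target_downsample) {
  d <- dim(image_rgb)
  if (length(d) != 3L || d[3] != 3L) stop("image must be h x w x 3 RGB",
                                          call. = FALSE)
  blurred <- if (params$blur_sigma > 0) {
    EBImage::gblur(image_rgb, sigma = params$blur_sigma)
  } else image_rgb
  blurred <- pmin(pmax(blurred, 0), 1)
  # saturation channel: rgb2hsv wants a 3 x n matrix in [0, 1]
  px <- rbind(as.vector(blurred[, , 1]), as.vector(blurred[, , 2]),
              as.vector(blurred[, , 3]))
  s <- matrix(grDevices::rgb2hsv(px, maxColorValue = 1)[2L, ], d[1], d[2])
  s_work <- if (params$use_morph_gradient) {
    pmin(s + .morph_gradient(s, params$grad_radius), 1)
  } else s
  if (max(s_work) - min(s_work) < 1e-8) {
    warning("degenerate constant image; returning empty mask", call. = FALSE)
    mask <- matrix(FALSE, d[1], d[2])
  } else {
    thr <- otsu_threshold(s_work)
    mask <- s_work > thr
    if (params$close_radius > 0) {
      k <- EBImage::makeBrush(2L * params$close_radius + 1L, shape = "disc")
      mask <- EBImage::closing(mask * 1, k) > 0.5
    }
    mask <- .drop_small_components(mask, params$min_region_area)
    mask <- .fill_small_holes(mask, params$min_hole_area)
  }
  structure(list(mask = mask, downsample = downsample,
                 slide_dims_level0 = c(width = round(d[2] * downsample),
                                       height = round(d[1] * downsample))),
            class = "tissue_mask")
}

.drop_small_components <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

.fill_small_holes <- function(mask, min_area) {
  # holes = background components not touching the border
  bg <- EBImage::bwlabel((!mask) * 1)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0])
  fill <- setdiff(which(sizes < min_area), border_labels)
  mask | matrix(bg %in% fill, nrow(mask), ncol(mask))
}

#' Derive the level-0 patch grid from a tissue mask
#'
#' Lays a non-overlapping grid of `patch_size` x `patch_size` level-0
#' patches over the slide and keeps a patch iff the tissue fraction
#' under its footprint is at least `tissue_coverage_min`. Truncated edge
#' patches are dropped. Coordinates are 0-based `(x, y)` top-left
#' corners in level-0 pixels, sorted row-major.
#'
#' @param mask A `tissue_mask` from [segment_tissue()].
#' @param params A [segmentation_params()].
#' @return A `patch_grid`: integer `coords` (N x 2), `patch_size`,
#'   `level`.
#' @export
extract_patch_grid <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "tissue_mask"))
  ps <- params$patch_size
  w0 <- mask$slide_dims_level0[["width"]]
  h0 <- mask$slide_dims_level0[["height"]]
  nx <- floor(w0 / ps); ny <- floor(h0 / ps)
  coords <- matrix(integer(0), 0L, 2L)
  if (nx > 0 && ny > 0 && any(mask$mask)) {
    m <- mask$mask
    ds <- mask$downsample
    keep <- list()
    for (gy in 0:(ny - 1L)) {
      for (gx in 0:(nx - 1L)) {
        # footprint in working-level pixels (half-open, rounded)
        c0 <- floor(gx * ps / ds) + 1L; c1 <- ceiling((gx + 1L) * ps / ds)
        r0 <- floor(gy * ps / ds) + 1L; r1 <- ceiling((gy + 1L) * ps / ds)
        c1 <- min(c1, ncol(m)); r1 <- min(r1, nrow(m))
        cov <- mean(m[r0:r1, c0:c1])
        if (cov >= params$tissue_coverage_min) {
          keep[[length(keep) + 1L]] <- c(gx * ps, gy * ps)
        }
      }
    }
    if (length(keep)) coords <- do.call(rbind, keep)
  }
  structure(list(coords = matrix(as.integer(coords), ncol = 2L),
                 patch_size = ps, level = 0L),
            class = "patch_grid")
}

#' Render a segmentation/patch QC overlay
#'
#' Draws the tissue-mask contour (green) and patch boxes (blue) over the
#' working-level slide image for manual inspection.
#'
#' @param image_rgb Working-level RGB raster matching the mask dims.
#' @param mask A `tissue_mask`.
#' @param grid Optional `patch_grid`; its level-0 coords are scaled by
#'   the mask downsample.
#' @return RGB raster of the same dims with annotations drawn in.
#' @export
render_qc_overlay <- function(image_rgb, mask, grid = NULL) {
  stopifnot(all(dim(image_rgb)[1:2] == dim(mask$mask)))
  out <- image_rgb
  m <- mask$mask
  # contour = mask minus its erosion
  er <- EBImage::erode(m * 1, EBImage::makeBrush(3L, "box")) > 0.5
  contour <- m & !er
  out[, , 1][contour] <- 0; out[, , 2][contour] <- 1; out[, , 3][contour] <- 0
  if (!is.null(grid) && nrow(grid$coords) > 0) {
    ds <- mask$downsample
    for (i in seq_len(nrow(grid$coords))) {
      c0 <- max(1L, round(grid$coords[i, 1] / ds) + 1L)
      r0 <- max(1L, round(grid$coords[i, 2] / ds) + 1L)
      c1 <- min(ncol(m), round((grid$coords[i, 1] + grid$patch_size) / ds))
      r1 <- min(nrow(m), round((grid$coords[i, 2] + grid$patch_size) / ds))
      out[r0:r1, c(c0, c1), 1] <- 0; out[r0:r1, c(c0, c1), 2] <- 0
      out[r0:r1, c(c0, c1), 3] <- 1
      out[c(r0, r1), c0:c1, 1] <- 0; out[c(r0, r1), c0:c1, 2] <- 0
      out[c(r0, r1), c0:c1, 3] <- 1
    }
  }
  out
}
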