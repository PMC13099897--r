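# Attention-score visualisation: paint patch footprints with
# min-max-normalised scores at a render scale, smooth or upsample, and
# alpha-blend a jet colormap over the slide image.

#' Heatmap rendering parameters
#'
#' @param render_downsample Scale of the heat raster vs level 0.
#' @param smoothing_sigma Gaussian smoothing SD in render-scale pixels
#'   (0 disables; the bilinear path of `interpolation = TRUE` is the
#'   alternative used for per-class attention maps).
#' @param interpolation Use bilinear upsampling of the per-patch score
#'   lattice instead of footprint painting + Gaussian smoothing.
#' @param overlay_alpha Blend weight of the colormapped heat in
#'   `[0, 1]`.
#' @return A `heatmap_params` list.
#' @export
heatmap_params <- function(render_downsample = 32, smoothing_sigma = 16,
                           interpolation = FALSE, overlay_alpha = 0.4) {
  stopifnot(overlay_alpha >= 0, overlay_alpha <= 1, smoothing_sigma >= 0)
  structure(list(render_downsample = render_downsample,
                 smoothing_sigma = smoothing_sigma,
                 interpolation = interpolation,
                 overlay_alpha = overlay_alpha),
            class = "heatmap_params")
}

# Separable Gaussian convolution with reflective padding (conserves
# total mass for interior blobs).
.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  reflect_idx <- function(i, n) {
    i <- abs(i - 1L) + 1L
    i[i > n] <- 2L * n - i[i > n]
    i
  }
  conv1 <- function(mat, along_rows) {
    n <- if (along_rows) nrow(mat) else ncol(mat)
    out <- mat * 0
    for (j in -r:r) {
      idx <- reflect_idx(seq_len(n) + j, n)
      out <- out + k[j + r + 1L] *
        (if (along_rows) mat[idx, , drop = FALSE]
         else mat[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Rasterise attention scores into a heat map
#'
#' Scores are min-max normalised to `[0, 1]` (all-equal score vectors
#' map to the neutral 0.5; a single score maps to 1 so a lone patch
#' stays visible), painted over each patch footprint at the render
#' scale with background 0, then either Gaussian-smoothed or replaced
#' by a bilinear upsampling of the per-patch score lattice.
#'
#' @param scores Length-N raw attention scores.
#' @param coords N x 2 level-0 patch coordinates.
#' @param patch_size Patch edge length in level-0 pixels.
#' @param slide_dims `(width, height)` of the slide at level 0.
#' @param params A [heatmap_params()].
#' @return Heat matrix (rows = y) at the render scale, values in
#'   `[0, 1]`.
#' @export
scores_to_map <- function(scores, coords, patch_size, slide_dims,
                          params = heatmap_params()) {
  stopifnot(length(scores) == nrow(coords))
  rng <- range(scores)
  norm <- if (length(scores) == 1L) {
    1
  } else if (rng[2] - rng[1] < 1e-12) {
    rep(0.5, length(scores))
  } else {
    (scores - rng[1]) / (rng[2] - rng[1])
  }
  ds <- params$render_downsample
  w <- max(1L, floor(slide_dims[[1]] / ds))
  h <- max(1L, floor(slide_dims[[2]] / ds))
  heat <- matrix(0, h, w)
  psd <- patch_size / ds
  for (i in seq_along(norm)) {
    c0 <- floor(coords[i, 1] / ds) + 1L
    r0 <- floor(coords[i, 2] / ds) + 1L
    c1 <- min(w, ceiling((coords[i, 1] + patch_size) / ds))
    r1 <- min(h, ceiling((coords[i, 2] + patch_size) / ds))
    if (c0 <= w && r0 <= h) heat[r0:r1, c0:c1] <- norm[i]
  }
  if (params$interpolation) {
    # bilinear upsampling of the patch-lattice scores
    nx <- max(1L, floor(slide_dims[[1]] / patch_size))
    ny <- max(1L, floor(slide_dims[[2]] / patch_size))
    lattice <- matrix(0, ny, nx)
    gi <- pmin(ny, coords[, 2] %/% patch_size + 1L)
    gj <- pmin(nx, coords[, 1] %/% patch_size + 1L)
    lattice[cbind(gi, gj)] <- norm
    heat <- EBImage::resize(lattice, w = h, h = w, filter = "bilinear")
  } else if (params$smoothing_sigma > 0) {
    heat <- .gauss_smooth(heat, params$smoothing_sigma)
  }
  pmin(pmax(heat, 0), 1)
}

# Jet colormap: dark blue through cyan, yellow, to dark red
.jet <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                 "red", "#7F0000"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Overlay a heat map on a slide image
#'
#' Jet-colormaps the heat and alpha-blends it onto the RGB slide
#' raster; `overlay_alpha = 0` returns the slide unchanged.
#'
#' @param heat Heat matrix in `[0, 1]` (rows = y).
#' @param slide_rgb RGB raster (`h x w x 3`) of matching dims.
#' @param params A [heatmap_params()].
#' @return RGB raster of the same dims.
#' @export
overlay_heatmap <- function(heat, slide_rgb, params = heatmap_params()) {
  stopifnot(all(dim(heat) == dim(slide_rgb)[1:2]))
  cols <- .jet(as.vector(heat))
  a <- params$overlay_alpha
  out <- slide_rgb
  for (ch in 1:3) {
    out[, , ch] <- (1 - a) * slide_rgb[, , ch] +
      a * matrix(cols[, ch], nrow(heat), ncol(heat))
  }
  out
}

#' Render and save an attention heatmap PNG
#'
#' Convenience wrapper: [scores_to_map()] then [overlay_heatmap()] over
#' a downsampled slide image, written with [png::writePNG()].
#'
#' @param scores,coords,patch_size As in [scores_to_map()].
#' @param slide_rgb Level-0 slide raster (downsampled internally to the
#'   render scale).
#' @param path Output PNG path.
#' @param params A [heatmap_params()].
#' @return `path`, invisibly.
#' @export
save_heatmap_png <- function(scores, coords, patch_size, slide_rgb, path,
                             params = heatmap_params()) {
  dims <- c(dim(slide_rgb)[2], dim(slide_rgb)[1])
  heat <- scores_to_map(scores, coords, patch_size, dims, params)
  small <- EBImage::resize(slide_rgb, w = nrow(heat), h = ncol(heat))
  png::writePNG(overlay_heatmap(heat, small, params), path)
  invisible(path)
}
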