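# Pluggable patch encoders. Production pipelines plug pathology
# foundation encoders in behind this same interface; the stub encoders
# below make every downstream stage testable offline with no weights.

#' Construct a stub patch encoder
#'
#' Both stubs are deterministic for a fixed seed and honour the
#' `patch_encoder` contract: `encode()` maps a list of RGB patch arrays
#' (`h x w x 3`, values in `[0, 1]`) to a `B x output_dim` matrix of
#' finite reals, independent of batch partitioning.
#'
#' * `identity_stats`: per-channel mean (columns 1--3) and per-channel
#'   SD (columns 4--6 when `output_dim >= 6`), zero-padded to
#'   `output_dim`. Useful as a pixel-level oracle.
#' * `seeded_projection`: bilinear-downsamples each patch to 8 x 8 x 3
#'   and applies a fixed seeded random linear map to `output_dim`
#'   dimensions.
#'
#' @param kind `"identity_stats"` or `"seeded_projection"`.
#' @param output_dim Feature dimension D (>= 1).
#' @param seed Integer seed fixing the projection weights.
#' @param expected_input Edge length patches are resized to before
#'   encoding.
#' @return A `patch_encoder` object with fields `name`, `output_dim`,
#'   `expected_input` and an `encode` function.
#' @export
make_stub_encoder <- function(kind = c("identity_stats", "seeded_projection"),
                              output_dim = 64L, seed = 1L,
                              expected_input = 32L) {
  kind <- match.arg(kind)
  stopifnot(output_dim >= 1L)
  encode <- switch(
    kind,
    identity_stats = function(patches) {
      t(vapply(patches, function(p) {
        mu <- apply(p, 3L, mean)
        sdv <- apply(p, 3L, stats::sd)
        out <- rep(0, output_dim)
        out[seq_len(min(3L, output_dim))] <- mu[seq_len(min(3L, output_dim))]
        if (output_dim >= 6L) out[4:6] <- sdv
        out
      }, numeric(output_dim)))
    },
    seeded_projection = {
      proj <- withr::with_seed(seed,
        matrix(stats::rnorm(8L * 8L * 3L * output_dim, sd = 1 / sqrt(192)),
               192L, output_dim))
      function(patches) {
        t(vapply(patches, function(p) {
          small <- EBImage::resize(p, w = 8L, h = 8L)
          as.numeric(as.vector(small) %*% proj)
        }, numeric(output_dim)))
      }
    }
  )
  structure(list(name = paste0("stub_", kind), output_dim = as.integer(output_dim),
                 expected_input = as.integer(expected_input), encode = encode),
            class = "patch_encoder")
}

# Extract one level-0 patch from an in-memory raster (h x w x 3 array,
# values in [0, 1]); coords are 0-based (x = column, y = row).
.read_patch <- function(img, x, y, patch_size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (x < 0 || y < 0 || x + patch_size > w || y + patch_size > h) {
    stop(sprintf("patch at (%d, %d) extends outside the slide", x, y),
         call. = FALSE)
  }
  img[(y + 1L):(y + patch_size), (x + 1L):(x + patch_size), , drop = FALSE]
}

#' Encode a slide's patch grid into a feature bag
#'
#' Reads each grid patch from the slide raster, resizes it to the
#' encoder's expected input size, and encodes patches in batches. Bag
#' row order always equals grid order, whatever the batch size.
#'
#' @param slide RGB raster (`h x w x 3` array, values in `[0, 1]`) at
#'   level 0, e.g. as read by [png::readPNG()].
#' @param grid A `patch_grid` from [extract_patch_grid()].
#' @param encoder A `patch_encoder`, e.g. from [make_stub_encoder()].
#' @param batch_size Patches per encoder call.
#' @param case_id,tier Passed through to the bag.
#' @return A [feature_bag()] with one row per grid coordinate.
#' @export
encode_slide <- function(slide, grid, encoder, batch_size = 32L,
                         case_id = "slide", tier = NA_integer_) {
  stopifnot(inherits(encoder, "patch_encoder"))
  n <- nrow(grid$coords)
  if (n == 0L) stop("empty patch grid", call. = FALSE)
  rows <- vector("list", ceiling(n / batch_size))
  for (b in seq_along(rows)) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    patches <- lapply(idx, function(i) {
      p <- .read_patch(slide, grid$coords[i, 1L], grid$coords[i, 2L],
                       grid$patch_size)
      if (dim(p)[1] != encoder$expected_input) {
        p <- EBImage::resize(p, w = encoder$expected_input,
                             h = encoder$expected_input)
      }
      p
    })
    rows[[b]] <- encoder$encode(patches)
  }
  feature_bag(do.call(rbind, rows), grid$coords, case_id, tier,
              encoder_name = encoder$name, patch_size = grid$patch_size,
              level = grid$level)
}
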