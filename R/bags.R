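#' Construct a feature bag
#'
#' A feature bag is one slide represented as an N x D matrix of
#' patch-instance feature vectors plus the level-0 coordinates of the
#' patches they came from — the universal currency between the
#' preprocessing, encoding and MIL stages.
#'
#' @param features N x D numeric matrix, one row per patch instance.
#' @param coords N x 2 integer matrix of level-0 top-left `(x, y)` patch
#'   corners, row-aligned with `features`.
#' @param case_id Case identifier.
#' @param tier Risk tier 0/1/2, or `NA` for unlabeled bags.
#' @param encoder_name Name of the encoder that produced the features.
#' @param patch_size Patch edge length in level-0 pixels.
#' @param level Pyramid level the patches were read at.
#' @return A `feature_bag` object.
#' @export
feature_bag <- function(features, coords, case_id, tier = NA_integer_,
                        encoder_name = "unknown", patch_size = 256L,
                        level = 0L) {
  features <- as.matrix(features)
  coords <- matrix(as.integer(coords), ncol = 2L)
  if (nrow(features) < 1L) stop("bag must contain at least one instance",
                                call. = FALSE)
  if (any(!is.finite(features))) stop("bag features must be finite",
                                      call. = FALSE)
  if (nrow(coords) != nrow(features)) {
    stop("coords must be row-aligned with features", call. = FALSE)
  }
  if (!is.na(tier) && !tier %in% 0:2) stop("tier must be 0, 1 or 2",
                                           call. = FALSE)
  structure(
    list(case_id = as.character(case_id), features = features,
         coords = coords, tier = if (is.na(tier)) NA_integer_ else
           as.integer(tier),
         encoder_name = encoder_name, patch_size = as.integer(patch_size),
         level = as.integer(level)),
    class = "feature_bag"
  )
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("<feature_bag> case %s: %d instances x %d dims (tier %s, %s)\n",
              x$case_id, nrow(x$features), ncol(x$features),
              ifelse(is.na(x$tier), "NA", x$tier), x$encoder_name))
  invisible(x)
}

#' @export
dim.feature_bag <- function(x) dim(x$features)

#' Write / read a feature bag container
#'
#' Bags are persisted as single-file serialized containers holding the
#' feature matrix (snapped to single precision, matching the fidelity
#' of typical patch-embedding stores), the coordinate matrix, and the
#' case attributes. `read_bag(write_bag(bag, path))` is lossless for
#' single-precision payloads.
#'
#' @param bag A [feature_bag()].
#' @param path File path (conventionally `.bag.rds`).
#' @return `write_bag` returns `path` invisibly; `read_bag` returns the
#'   bag.
#' @export
write_bag <- function(bag, path) {
  stopifnot(inherits(bag, "feature_bag"))
  payload <- list(
    schema = "wsimil-bag/1",
    features = .snap_float32(bag$features),
    coords = bag$coords,
    attrs = list(case_id = bag$case_id, tier = bag$tier,
                 encoder_name = bag$encoder_name,
                 patch_size = bag$patch_size, level = bag$level)
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_bag
#' @export
read_bag <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, "wsimil-bag/1") ||
      is.null(payload$features) || is.null(payload$coords)) {
    stop("not a wsimil bag container (missing schema or datasets): ", path,
         call. = FALSE)
  }
  a <- payload$attrs
  feature_bag(payload$features, payload$coords, a$case_id, a$tier,
              a$encoder_name, a$patch_size, a$level)
}

# Round-trip doubles through single precision so on-disk payloads are
# stable across writes.
.snap_float32 <- function(x) {
  d <- dim(x)
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4L)
  r <- rawConnectionValue(con)
  close(con)
  y <- readBin(r, numeric(), n = length(x), size = 4L)
  dim(y) <- d
  y
}

#' Write a bag manifest mapping case ids to bag paths
#'
#' @param bags List of [feature_bag()]s.
#' @param dir Directory to write one container per bag into.
#' @return Tibble with `case_id`, `tier`, `path`.
#' @export
write_bag_set <- function(bags, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::map(bags, function(b) {
    p <- file.path(dir, paste0(b$case_id, ".bag.rds"))
    write_bag(b, p)
    tibble::tibble(case_id = b$case_id, tier = b$tier, path = p)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "bags.csv"), row.names = FALSE)
  manifest
}
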