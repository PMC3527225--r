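#' LBP(8, 2) configuration
#'
#' Local binary patterns with 8 neighbors on a circle of radius 2 pixels.
#' 8 neighbors are required for the 256-bin histogram; the uniform-LBP
#' variant (merging high-transition codes) is deliberately not supported:
#' it discards exactly the irregular patterns that are informative in ISH
#' expression images.
#'
#' @param n_neighbors Number of circular neighbors; must be 8.
#' @param radius Circle radius in pixels (default 2).
#' @param uniform Must be `FALSE`.
#' @return An object of class `lbp_config`.
#' @export
lbp_config <- function(n_neighbors = 8L, radius = 2, uniform = FALSE) {
  if (n_neighbors != 8L) {
    stop("n_neighbors must be 8 (256-bin histograms)", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("radius must be a positive number", call. = FALSE)
  }
  if (isTRUE(uniform)) {
    stop("uniform LBP is not supported", call. = FALSE)
  }
  structure(list(n_neighbors = 8L, radius = radius, uniform = FALSE),
            class = "lbp_config")
}

# Neighbor offsets (row, col) for bit b = 0..7. Bit 0 points east (+col),
# angles run counter-clockwise, rows increase downward.
lbp_offsets <- function(radius) {
  b <- 0:7
  theta <- 2 * pi * b / 8
  cbind(dr = -radius * sin(theta), dc = radius * cos(theta))
}

# Bilinear interpolation in lerp form (exact for flat patches, so ties on
# constant images are exact): value at (r + dr, c + dc).
bilerp_at <- function(image, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- if (fr > 0) r0 + 1L else r0
  c1 <- if (fc > 0) c0 + 1L else c0
  top <- image[r0, c0] + fc * (image[r0, c1] - image[r0, c0])
  bot <- image[r1, c0] + fc * (image[r1, c1] - image[r1, c0])
  top + fr * (bot - top)
}

#' LBP code of a single pixel
#'
#' Bit `b` (b = 0..7, packed with b = 0 as the least significant bit) is 1
#' iff the bilinearly interpolated intensity at angle `2*pi*b/8`
#' (counter-clockwise from east) and distance `radius` from the center is
#' `>=` the center intensity. A neighbor tied with the center sets the bit,
#' so a constant image yields code 255 everywhere.
#'
#' @param image Numeric intensity matrix.
#' @param center Length-2 integer `(row, col)`; must be at least
#'   `ceiling(radius) + 1` pixels from every border.
#' @param config An [lbp_config()].
#' @return Integer code in `[0, 255]`.
#' @export
#' @examples
#' lbp_code(matrix(0.5, 7, 7), c(4, 4))  # 255: all ties
lbp_code <- function(image, center, config = lbp_config()) {
  check_intensity_matrix(image)
  m <- ceiling(config$radius)
  r <- center[1]; c <- center[2]
  if (r <= m || c <= m || r > nrow(image) - m || c > ncol(image) - m) {
    stop("center must be at least ", m + 1, " pixels from every border",
         call. = FALSE)
  }
  off <- lbp_offsets(config$radius)
  code <- 0L
  for (b in 0:7) {
    nb <- bilerp_at(image, r + off[b + 1, "dr"], c + off[b + 1, "dc"])
    if (nb >= image[r, c]) code <- code + bitwShiftL(1L, b)
  }
  code
}

# Vectorized LBP codes over all interior pixels. Returns an integer matrix
# of dimension (H - 2m) x (W - 2m) where m = ceiling(radius). Uses the
# same lerp-form bilinear interpolation as lbp_code.
lbp_code_matrix <- function(image, config = lbp_config()) {
  m <- ceiling(config$radius)
  H <- nrow(image); W <- ncol(image)
  if (H <= 2 * m + 1 || W <= 2 * m + 1) {
    stop("image must be strictly larger than ", 2 * m + 1,
         " in both dimensions", call. = FALSE)
  }
  rr <- (m + 1):(H - m)
  cc <- (m + 1):(W - m)
  center <- image[rr, cc, drop = FALSE]
  off <- lbp_offsets(config$radius)
  code <- matrix(0L, length(rr), length(cc))
  for (b in 0:7) {
    dr <- off[b + 1, "dr"]; dc <- off[b + 1, "dc"]
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    r1 <- if (fr > 0) r0 + 1L else r0
    c1 <- if (fc > 0) c0 + 1L else c0
    sh <- function(dr_, dc_) image[rr + dr_, cc + dc_, drop = FALSE]
    top <- sh(r0, c0) + fc * (sh(r0, c1) - sh(r0, c0))
    bot <- sh(r1, c0) + fc * (sh(r1, c1) - sh(r1, c0))
    nb <- top + fr * (bot - top)
    code <- code + bitwShiftL(1L, b) * (nb >= center)
  }
  code
}

#' LBP code histogram of an image
#'
#' Counts the LBP codes of all interior pixels (those at least
#' `ceiling(radius)` away from the border). Bins sum to the interior pixel
#' count. The raw (unscaled) histogram is invariant to any strictly
#' increasing transform of the pixel intensities.
#'
#' @inheritParams lbp_code
#' @return Integer vector of length 256, names `"0"`..`"255"`.
#' @export
lbp_histogram <- function(image, config = lbp_config()) {
  check_intensity_matrix(image)
  codes <- lbp_code_matrix(image, config)
  h <- tabulate(as.vector(codes) + 1L, nbins = 256L)
  names(h) <- as.character(0:255)
  h
}

#' Multi-scale LBP feature vector of an image
#'
#' For each pyramid level: the 256-bin LBP histogram scaled to `[0, 1]` by
#' dividing by its maximal bin value (the max bin maps to exactly 1),
#' followed by the level's raw mean intensity — 257 features per level.
#' Level blocks are concatenated in pyramid order, so a 6-level pyramid
#' yields 6 x 257 = 1542 features.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param config An [lbp_config()].
#' @return Numeric feature vector of length `257 * length(pyramid)` with
#'   the pyramid factors in `attr(, "factors")`.
#' @export
image_features <- function(pyramid, config = lbp_config()) {
  if (!inherits(pyramid, "scale_pyramid")) {
    stop("pyramid must be a scale_pyramid", call. = FALSE)
  }
  blocks <- lapply(pyramid, function(lv) {
    h <- tryCatch(lbp_histogram(lv$image, config), error = function(e) {
      stop("pyramid level with factor ", lv$factor, ": ",
           conditionMessage(e), call. = FALSE)
    })
    c(h / max(h), mean_intensity = mean(lv$image))
  })
  out <- unlist(blocks, use.names = FALSE)
  attr(out, "factors") <- vapply(pyramid, `[[`, integer(1), "factor")
  out
}

#' Featurize every image in a manifest
#'
#' Reads each image, drops completely black ones ([is_blank()]), builds
#' the multi-resolution pyramid and extracts the multi-scale LBP feature
#' vector. The result bundles the feature matrix with per-image metadata
#' and is the input to the model-fitting and evaluation functions.
#'
#' @param manifest Data frame with columns `gene_id,label,image_path`
#'   (label may be absent for unlabeled genes), e.g. from
#'   [generate_dataset()] or [read_manifest()].
#' @param factors Downsampling factors for the pyramid.
#' @param config An [lbp_config()].
#' @param colormap Passed to [read_expression_image()].
#' @param dir Directory against which relative image paths are resolved;
#'   defaults to `attr(manifest, "dir")`.
#' @param blank_eps Blank-filter tolerance, see [is_blank()].
#' @return An object of class `ish_features`: `list(features, meta,
#'   factors, config)` where `features` is an images x (257 * levels)
#'   matrix and `meta` has columns `gene_id,image_id,label`.
#' @export
featurize_manifest <- function(manifest, factors = c(1, 2, 4, 8, 10, 16),
                               config = lbp_config(),
                               colormap = "auto",
                               dir = attr(manifest, "dir"),
                               blank_eps = 0) {
  paths <- manifest$image_path
  if (!is.null(dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", paths)
    paths[rel] <- file.path(dir, paths[rel])
  }
  images <- lapply(paths, read_expression_image, colormap = colormap)
  meta <- data.frame(
    gene_id = manifest$gene_id,
    image_id = sub("\\.[^.]+$", "", basename(manifest$image_path)),
    label = if ("label" %in% names(manifest)) manifest$label else NA_character_
  )
  featurize_images(images, meta, factors = factors, config = config,
                   blank_eps = blank_eps)
}

#' Featurize a list of in-memory images
#'
#' In-memory counterpart of [featurize_manifest()].
#'
#' @param images List of numeric intensity matrices.
#' @param meta Data frame with one row per image; columns `gene_id`,
#'   `image_id` (optional) and `label` (optional).
#' @inheritParams featurize_manifest
#' @return An `ish_features` object; blank images are dropped.
#' @export
featurize_images <- function(images, meta, factors = c(1, 2, 4, 8, 10, 16),
                             config = lbp_config(), blank_eps = 0) {
  if (nrow(meta) != length(images)) {
    stop("meta must have one row per image", call. = FALSE)
  }
  if (is.null(meta$image_id)) {
    meta$image_id <- paste0(meta$gene_id, "_",
                            stats::ave(seq_along(images), meta$gene_id,
                                       FUN = seq_along))
  }
  if (is.null(meta$label)) meta$label <- NA_character_
  keep <- !vapply(images, is_blank, logical(1), eps = blank_eps)
  if (!any(keep)) stop("all images are blank", call. = FALSE)
  images <- images[keep]
  meta <- meta[keep, c("gene_id", "image_id", "label"), drop = FALSE]
  rownames(meta) <- NULL
  feats <- lapply(images, function(img) {
    image_features(build_pyramid(img, factors), config)
  })
  features <- do.call(rbind, feats)
  rownames(features) <- meta$image_id
  structure(list(features = features, meta = meta,
                 factors = as.integer(factors), config = config),
            class = "ish_features")
}

#' @export
print.ish_features <- function(x, ...) {
  cat(sprintf(
    "<ish_features> %d images, %d genes, %d features (factors %s)\n",
    nrow(x$features), length(unique(x$meta$gene_id)), ncol(x$features),
    paste(x$factors, collapse = ",")))
  if (!all(is.na(x$meta$label))) {
    print(table(x$meta$label))
  }
  invisible(x)
}

# Column indices of the 257-feature block(s) for the given factors.
feature_blocks <- function(dataset, factors) {
  idx <- match(factors, dataset$factors)
  if (anyNA(idx)) {
    stop("factors ", paste(factors[is.na(idx)], collapse = ","),
         " not present in dataset", call. = FALSE)
  }
  unlist(lapply(idx, function(i) (i - 1L) * 257L + 1:257))
}
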