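#' Read a masked expression image as a scalar intensity grid
#'
#' Grayscale PNGs are taken as intensities directly; RGB images are
#' inverted through the heat colormap ([heat_to_intensity()]). With
#' `colormap = "auto"`, a file with three channels that are not all equal
#' is treated as heat-mapped, otherwise as grayscale.
#'
#' @param path Path to a PNG (or any raster `png::readPNG` can parse).
#' @param colormap `"auto"`, `"gray"` or `"heat"`.
#' @return Numeric matrix of intensities in `[0, 1]`.
#' @export
read_expression_image <- function(path, colormap = c("auto", "gray", "heat")) {
  colormap <- match.arg(colormap)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2L) {
    if (colormap == "heat") {
      stop("heat colormap requested but ", path, " is single-channel",
           call. = FALSE)
    }
    return(raw)
  }
  ch <- dim(raw)[3]
  if (ch >= 3L) {
    is_gray <- identical(raw[, , 1], raw[, , 2]) &&
      identical(raw[, , 2], raw[, , 3])
    if (colormap == "gray" || (colormap == "auto" && is_gray)) {
      return(raw[, , 1])
    }
    return(heat_to_intensity(raw[, , 1:3]))
  }
  raw[, , 1]  # gray + alpha
}

#' Write an intensity grid as a PNG
#'
#' @param pixels Numeric intensity matrix in `[0, 1]`.
#' @param path Output path.
#' @param colormap `"gray"` for 8-bit grayscale, `"heat"` for RGB through
#'   the heat colormap.
#' @return `path`, invisibly.
#' @export
write_expression_image <- function(pixels, path,
                                   colormap = c("gray", "heat")) {
  colormap <- match.arg(colormap)
  check_intensity_matrix(pixels)
  img <- if (colormap == "gray") pixels else intensity_to_heat(pixels)
  png::writePNG(img, path)
  invisible(path)
}

#' Is an expression image completely black?
#'
#' Completely black images (no expression detected anywhere) carry no
#' signal and are excluded before feature extraction. The default test is
#' exact zero, matching masked images and the synthetic generator whose
#' backgrounds are exactly 0; `eps` accommodates lossy-compressed inputs.
#'
#' @param image Numeric intensity matrix in `[0, 1]`.
#' @param eps Non-negative tolerance; pixels `<= eps` count as black.
#' @return `TRUE` iff every pixel is `<= eps`.
#' @export
is_blank <- function(image, eps = 0) {
  check_intensity_matrix(image)
  all(image <= eps)
}

#' Downsample an image by block averaging
#'
#' Output pixel `(i, j)` is the arithmetic mean of the `factor x factor`
#' input block anchored at `((i-1)*factor + 1, (j-1)*factor + 1)`. Trailing
#' rows/columns that do not fill a complete block are dropped (no padding,
#' which would bias texture statistics at the edges).
#'
#' @param image Numeric intensity matrix.
#' @param factor Positive integer downsampling factor; both image
#'   dimensions must be at least `factor`.
#' @return A `floor(H/factor) x floor(W/factor)` matrix.
#' @export
#' @examples
#' downsample(matrix(0.5, 4, 4), 2)
downsample <- function(image, factor) {
  check_intensity_matrix(image)
  factor <- as.integer(factor)
  if (length(factor) != 1 || is.na(factor) || factor < 1) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  if (factor == 1L) return(image)
  h2 <- nrow(image) %/% factor
  w2 <- ncol(image) %/% factor
  if (h2 < 1 || w2 < 1) {
    stop("factor ", factor, " larger than image (",
         nrow(image), " x ", ncol(image), ")", call. = FALSE)
  }
  m <- image[seq_len(h2 * factor), seq_len(w2 * factor), drop = FALSE]
  m <- rowsum(m, rep(seq_len(h2), each = factor)) / factor
  m <- t(rowsum(t(m), rep(seq_len(w2), each = factor)) / factor)
  dimnames(m) <- NULL
  m
}

#' Build a multi-resolution pyramid
#'
#' One level per downsampling factor, each produced by [downsample()] from
#' the original image. Structure lives at coarse scales (the folded band
#' geometry) while per-layer texture lives at fine scales; features are
#' later extracted per level and concatenated.
#'
#' @param image Numeric intensity matrix.
#' @param factors Integer downsampling factors, sorted strictly ascending,
#'   all `>= 1`.
#' @return An object of class `scale_pyramid`: a list of
#'   `list(factor, image)` levels.
#' @export
build_pyramid <- function(image, factors = c(1, 2, 4, 8, 10, 16)) {
  factors <- as.integer(factors)
  if (length(factors) == 0 || any(is.na(factors)) || any(factors < 1) ||
      is.unsorted(factors, strictly = TRUE)) {
    stop("factors must be strictly increasing positive integers",
         call. = FALSE)
  }
  levels <- lapply(factors, function(f) {
    list(factor = f, image = downsample(image, f))
  })
  structure(levels, class = "scale_pyramid")
}

#' @export
print.scale_pyramid <- function(x, ...) {
  cat("<scale_pyramid> with", length(x), "levels\n")
  for (lv in x) {
    cat(sprintf("  factor %2d: %d x %d\n", lv$factor,
                nrow(lv$image), ncol(lv$image)))
  }
  invisible(x)
}
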